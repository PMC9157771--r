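#!/usr/bin/env Rscript
# Prediction-based external evaluation of all 14 registered meropenem models
# on the synthetic cohort: population predictions vs observations, PE%
# summaries (MDPE, MAPE, F20, F30) per model and CRRT stratum, and the PE box
# plot. A model "passes" when MDPE is within +/-20%, MAPE <= 30%, F20 >= 35%
# and F30 >= 50%.

library(meroeval)

coh <- read_nonmem("results/cohort_nonmem.csv")
out <- run_evaluation(coh, outdir = "results")

cat("\nPrediction-based diagnostics (per model x stratum):\n")
print(out$prediction, digits = 3)
cat(sprintf("\nmodels passing all four population criteria: %s\n",
            paste(unique(out$prediction$model_id[out$prediction$passes]),
                  collapse = ", ") |> (\(x) if (nzchar(x)) x else "none")()))

# per-observation PE values for the box plot
pe_rows <- do.call(rbind, lapply(list_models(), function(m) {
  strat <- if (m$population_class == "mixed") c(TRUE, FALSE)
           else m$population_class == "crrt"
  sub <- Filter(function(p) p$covariates$crrt %in% strat, coh)
  pred <- unlist(lapply(sub, function(p) predict_concentrations(m, p)))
  obs <- unlist(lapply(sub, function(p) p$obs$conc))
  data.frame(model_id = m$model_id, pe = pe_percent(pred, obs))
}))
write.csv(pe_rows, "results/pe_values.csv", row.names = FALSE)
dir.create("results/figures", showWarnings = FALSE)
ggplot2::ggsave("results/figures/pe_boxplot.png", plot_pe_boxplot(pe_rows),
                width = 8, height = 4.5, dpi = 150)
cat("tables in results/, figure in results/figures/pe_boxplot.png\n")
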