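#!/usr/bin/env Rscript
# Clinical-utility analysis: classify predicted and observed concentrations
# against the 8-45 mg/L meropenem target window on patients with >= 2
# observations (forecasting the last occasion), and score the agreement of
# the implied dose adaptations (increase / maintain / decrease) for the
# a priori and Bayesian methods.

library(meroeval)

coh <- read_nonmem("results/cohort_nonmem.csv")
multi <- Filter(function(p) nrow(p$obs) >= 2, coh)
cat(sprintf("%d patients with >= 2 observations\n", length(multi)))

rows <- list(); trough_rows <- list()
for (m in list_models()) {
  strat <- if (m$population_class == "mixed") c(TRUE, FALSE)
           else m$population_class == "crrt"
  sub <- Filter(function(p) p$covariates$crrt %in% strat, multi)
  if (!length(sub)) next
  obs <- vapply(sub, function(p) p$obs$conc[nrow(p$obs)], 0)
  apriori <- pmax(vapply(sub, function(p)
    predict_concentrations(m, p, NULL, p$obs$time[nrow(p$obs)]), 0), 1e-6)
  bayes <- pmax(vapply(sub, function(p) {
    k <- nrow(p$obs)
    map_estimate(m, p, prior_obs = p$obs[seq_len(k - 1), ],
                 times = p$obs$time[k])$ipred
  }, 0), 1e-6)
  for (method in c("a_priori", "bayesian")) {
    pv <- if (method == "a_priori") apriori else bayes
    a <- adaptation_accuracy(pv, obs)
    rows[[length(rows) + 1]] <- cbind(
      data.frame(model_id = m$model_id, method = method, n = a$n,
                 accuracy = a$accuracy),
      data.frame(t(setNames(a$counts$yes, paste0("yes_", a$counts$category)))))
    trough_rows[[length(trough_rows) + 1]] <-
      data.frame(model_id = m$model_id, method = method, conc = pv)
  }
}
adapt <- do.call(rbind, rows)
write.csv(adapt, "results/dose_adaptation.csv", row.names = FALSE)
cat("\nDose-adaptation accuracy per model and method:\n")
print(adapt, digits = 4)

better <- with(adapt, tapply(accuracy, model_id, function(x) x[2] > x[1]))
cat(sprintf("\nBayesian beats a priori for %d of %d models\n",
            sum(better), length(better)))

dir.create("results/figures", showWarnings = FALSE)
troughs <- do.call(rbind, trough_rows)
ggplot2::ggsave("results/figures/trough_boxplot.png",
                plot_trough_boxplot(troughs), width = 9, height = 4.5,
                dpi = 150)
cat("dose-adaptation table and trough box plot written\n")
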