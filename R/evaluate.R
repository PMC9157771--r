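.strata_for <- function(model) {
  switch(model$population_class,
         mixed = c("all", "crrt", "non_crrt"),
         crrt = "crrt",
         non_crrt = "non_crrt")
}

.subset_stratum <- function(patients, stratum) {
  if (stratum == "all") return(patients)
  want <- stratum == "crrt"
  Filter(function(p) isTRUE(p$covariates$crrt) == want, patients)
}

#' Run the full external-evaluation pipeline
#'
#' For each requested model and each stratum compatible with its source
#' population (CRRT / non-CRRT / both), computes:
#' prediction-based diagnostics (PE%, MDPE, MAPE, F20, F30 with the
#' population pass flag), a priori vs Bayesian-forecast rBias/rRMSE on
#' patients with >= 2 observations (forecasting the last observation from
#' the earlier ones), the dose-adaptation agreement against the 8-45 mg/L
#' window, and optionally pcVPC/NPDE simulation diagnostics and the EBE
#' adequacy comparison. A model that errors is reported and skipped.
#'
#' @param patients A `pk_cohort` (already LLOQ-filtered).
#' @param model_ids Models to evaluate (default: all 14).
#' @param n_rep Simulation replicates for pcVPC/NPDE; 0 skips them.
#' @param run_ebe Compute the EBE adequacy comparison.
#' @param seed Seed for the simulation diagnostics.
#' @param outdir Optional directory: tables are written there as CSVs.
#' @param registry Optional model registry.
#' @return List with `prediction` (one row per model x stratum),
#'   `forecasting` (a priori vs Bayesian rows), `adaptation`, and per-model
#'   `vpc`, `npde`, `ebe` objects; `errors` lists skipped models.
#' @export
run_evaluation <- function(patients, model_ids = NULL, n_rep = 0,
                           run_ebe = FALSE, seed = 1L, outdir = NULL,
                           registry = NULL) {
  models <- list_models(registry = registry)
  if (!is.null(model_ids)) models <- models[model_ids]
  pred_rows <- list(); fc_rows <- list(); adapt_rows <- list()
  vpcs <- list(); npdes <- list(); ebes <- list(); errors <- character()

  for (m in models) {
    res <- tryCatch({
      for (stratum in .strata_for(m)) {
        sub <- .subset_stratum(patients, stratum)
        if (length(sub) == 0) next
        pred <- unlist(lapply(sub, function(p)
          predict_concentrations(m, p)))
        obs <- unlist(lapply(sub, function(p) p$obs$conc))
        s <- summarize_population(pe_percent(pred, obs))
        pred_rows[[length(pred_rows) + 1L]] <- data.frame(
          model_id = m$model_id, stratum = stratum, n = s$n,
          mdpe = s$mdpe, mape = s$mape, f20 = s$f20, f30 = s$f30,
          passes = s$passes_population_criteria)

        multi <- Filter(function(p) nrow(p$obs) >= 2, sub)
        if (length(multi)) {
          last_obs <- vapply(multi, function(p) p$obs$conc[nrow(p$obs)], 0)
          apriori <- vapply(multi, function(p)
            predict_concentrations(m, p, NULL,
                                   p$obs$time[nrow(p$obs)]), 0)
          bayes <- vapply(multi, function(p) {
            k <- nrow(p$obs)
            map_estimate(m, p, prior_obs = p$obs[seq_len(k - 1L), ],
                         times = p$obs$time[k])$ipred
          }, 0)
          for (method in c("a_priori", "bayesian")) {
            pv <- pmax(if (method == "a_priori") apriori else bayes, 1e-6)
            r <- rbias_rrmse(pv, last_obs)
            fc_rows[[length(fc_rows) + 1L]] <- data.frame(
              model_id = m$model_id, stratum = stratum, method = method,
              n = r$n, rbias = r$rbias, rrmse = r$rrmse,
              unbiased = r$unbiased)
            a <- adaptation_accuracy(pv, last_obs)
            adapt_rows[[length(adapt_rows) + 1L]] <- data.frame(
              model_id = m$model_id, stratum = stratum, method = method,
              n = a$n, accuracy = a$accuracy)
          }
        }
      }
      eval_pats <- .subset_stratum(patients,
                                   if (m$population_class == "mixed") "all"
                                   else m$population_class)
      if (n_rep > 0 && length(eval_pats)) {
        ens <- simulate_replicates(m, eval_pats, n_rep = n_rep, seed = seed)
        vpcs[[m$model_id]] <- pcvpc(ens)
        npdes[[m$model_id]] <- npde(ens)
      }
      if (run_ebe && length(eval_pats) >= 20)
        ebes[[m$model_id]] <- ebe_adequacy(m, eval_pats)
      TRUE
    }, error = function(e) {
      warning("model ", m$model_id, " skipped: ", conditionMessage(e))
      FALSE
    })
    if (!isTRUE(res)) errors <- c(errors, m$model_id)
  }

  out <- list(prediction = do.call(rbind, pred_rows),
              forecasting = do.call(rbind, fc_rows),
              adaptation = do.call(rbind, adapt_rows),
              vpc = vpcs, npde = npdes, ebe = ebes, errors = errors)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    for (nm in c("prediction", "forecasting", "adaptation"))
      if (!is.null(out[[nm]]))
        write.csv(out[[nm]], file.path(outdir, paste0(nm, ".csv")),
                  row.names = FALSE)
  }
  out
}

#' Prior-combination forecasting study
#'
#' On patients with at least three observations, forecasts the third
#' observation under the three prior modes and summarizes the individual
#' prediction errors per model and mode.
#'
#' @param patients A `pk_cohort`.
#' @param model_ids Models to include.
#' @param registry Optional registry.
#' @return data.frame with one row per model x prior mode: MDIPE, MAIPE,
#'   IF20, IF30, rBias, rRMSE.
#' @export
prior_combination_study <- function(patients, model_ids = NULL,
                                    registry = NULL) {
  models <- list_models(registry = registry)
  if (!is.null(model_ids)) models <- models[model_ids]
  rich <- Filter(function(p) nrow(p$obs) >= 3, patients)
  if (length(rich) == 0) stop("no patients with >= 3 observations")
  rows <- list()
  for (m in models) {
    for (mode in c("none", "most_recent_only", "first_and_second")) {
      res <- lapply(rich, function(p) forecast_third_interval(m, p, mode))
      ipred <- pmax(vapply(res, function(r) r$ipred, 0), 1e-6)
      obs <- vapply(res, function(r) r$obs, 0)
      s <- summarize_individual(ipe_percent(ipred, obs))
      r2 <- rbias_rrmse(ipred, obs)
      rows[[length(rows) + 1L]] <- data.frame(
        model_id = m$model_id, prior_mode = mode, n = s$n,
        mdipe = s$mdipe, maipe = s$maipe, if20 = s$if20, if30 = s$if30,
        rbias = r2$rbias, rrmse = r2$rrmse)
    }
  }
  do.call(rbind, rows)
}
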