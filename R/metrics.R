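#' Relative prediction error
#'
#' `PE% = (C_pred - C_obs) / C_obs * 100`. The same statistic on individual
#' predictions (IPRED) is conventionally called IPE%; [ipe_percent()] is the
#' alias.
#'
#' @param pred,obs Predicted and observed concentrations, mg/L; `obs` must be
#'   strictly positive (LLOQ filtering guarantees this upstream).
#' @return Prediction errors in percent.
#' @export
pe_percent <- function(pred, obs) {
  if (length(pred) != length(obs)) stop("pred and obs lengths differ")
  if (any(obs <= 0)) stop("observations must be strictly positive")
  (pred - obs) / obs * 100
}

#' @rdname pe_percent
#' @export
ipe_percent <- pe_percent

#' Population-level predictive performance summary
#'
#' MDPE (median PE%), MAPE (median |PE|%), and the fractions of predictions
#' within 20% and 30% of the observations (F20, F30). A model passes the
#' population criteria when MDPE is within +/-20%, MAPE <= 30%, F20 >= 35%
#' and F30 >= 50%. Thresholds on |PE| are inclusive.
#'
#' @param pe Vector of prediction errors in percent (from [pe_percent()]).
#' @return List of class `metrics_report` with `mdpe`, `mape`, `f20`, `f30`,
#'   `n` and `passes_population_criteria`.
#' @export
summarize_population <- function(pe) {
  if (length(pe) == 0) stop("no prediction errors supplied")
  mdpe <- median(pe)
  mape <- median(abs(pe))
  f20 <- mean(abs(pe) <= 20) * 100
  f30 <- mean(abs(pe) <= 30) * 100
  structure(list(mdpe = mdpe, mape = mape, f20 = f20, f30 = f30,
                 n = length(pe),
                 passes_population_criteria =
                   abs(mdpe) <= 20 && mape <= 30 && f20 >= 35 && f30 >= 50),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "MDPE %.2f%%  MAPE %.2f%%  F20 %.1f%%  F30 %.1f%%  (n=%d)  %s\n",
    x$mdpe, x$mape, x$f20, x$f30, x$n,
    if (isTRUE(x$passes_population_criteria)) "PASS" else "fail"))
  invisible(x)
}

#' Individual-level summary (MDIPE, MAIPE, IF20, IF30)
#'
#' Same statistics as [summarize_population()] computed on individual
#' prediction errors.
#'
#' @param ipe Vector of IPE% values.
#' @export
summarize_individual <- function(ipe) {
  s <- summarize_population(ipe)
  list(mdipe = s$mdpe, maipe = s$mape, if20 = s$f20, if30 = s$f30, n = s$n)
}

#' Relative bias and relative root mean squared error
#'
#' Symmetrized relative errors with the mean of prediction and observation as
#' denominator:
#' `rBias = mean( (p - o) / ((p + o)/2) ) * 100` and
#' `rRMSE = sqrt( mean( (p - o)^2 / ((p + o)/2)^2 ) ) * 100`.
#' Each rBias summand lies in (-200, 200) for positive pairs. Predictions are
#' considered unbiased when |rBias| <= 20%.
#'
#' @param preds,obs Equal-length positive vectors, mg/L.
#' @return List with `rbias`, `rrmse`, `n`, `unbiased`.
#' @export
rbias_rrmse <- function(preds, obs) {
  if (length(preds) != length(obs)) stop("preds and obs lengths differ")
  if (length(preds) == 0) stop("no pairs supplied")
  if (any(preds <= 0) || any(obs <= 0)) stop("values must be strictly positive")
  rel <- (preds - obs) / ((preds + obs) / 2)
  rbias <- mean(rel) * 100
  rrmse <- sqrt(mean(rel^2)) * 100
  list(rbias = rbias, rrmse = rrmse, n = length(preds),
       unbiased = abs(rbias) <= 20)
}
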