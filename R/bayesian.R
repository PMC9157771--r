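#' MAP (empirical Bayes) estimation of individual random effects
#'
#' Minimizes the posterior -2 log-density
#' `sum_j [ (y_j - f_j(eta))^2 / g_j^2(eta) + log g_j^2(eta) ] +
#'  eta' Omega^-1 eta`,
#' with the residual SD `g` evaluated at the individual prediction. The exact
#' objective is evaluated (no linearization). Optimization is L-BFGS-B from
#' eta = 0 plus four fixed perturbed starts, eta bounded to +/-5 prior SDs;
#' the result is deterministic given inputs.
#'
#' @param model A `model_spec` with at least one IIV parameter.
#' @param patient A `pk_patient`.
#' @param prior_obs data.frame of observations used as priors (columns
#'   `time`, `conc`); defaults to all of the patient's non-BQL observations.
#'   Observations below the LLOQ are excluded from the likelihood.
#' @param times Times at which to return IPRED (default: the patient's
#'   observation times).
#' @param lloq Quantification limit used for exclusion.
#' @return List of class `forecast_result`: `eta_map` (named vector),
#'   `ipred`, `pred` (a priori), `objective` (posterior -2 log-density at the
#'   optimum, up to a constant), `n_priors_used`.
#' @export
map_estimate <- function(model, patient, prior_obs = NULL, times = NULL,
                         lloq = 0.5) {
  stopifnot(inherits(model, "model_spec"))
  if (is.null(times)) times <- patient$obs$time
  omega <- model$omega
  if (nrow(omega) == 0) stop("model ", model$model_id, " has no IIV to estimate")
  if (is.null(prior_obs)) prior_obs <- patient$obs[!patient$obs$bql, ]
  prior_obs <- prior_obs[prior_obs$conc >= lloq, , drop = FALSE]

  pred <- predict_concentrations(model, patient, NULL, times)
  nm <- rownames(omega)
  if (nrow(prior_obs) == 0) {
    eta0 <- setNames(numeric(length(nm)), nm)
    return(structure(list(eta_map = eta0, ipred = pred, pred = pred,
                          objective = 0, n_priors_used = 0L),
                     class = "forecast_result"))
  }

  oinv <- tryCatch(solve(omega), error = function(e)
    stop("Omega is singular for model ", model$model_id))
  y <- prior_obs$conc
  ty <- prior_obs$time
  sigma <- model$sigma
  base <- compute_individual_parameters(model, patient$covariates)
  obj <- function(eta_raw) {
    eta <- setNames(eta_raw, nm)
    params <- .scale_params(base, eta, model$parametrization)
    f <- concentration(params, patient$doses, ty)
    g2 <- pmax(residual_sd(sigma, f), 1e-8)^2
    sum((y - f)^2 / g2 + log(g2)) + drop(eta_raw %*% oinv %*% eta_raw)
  }
  sds <- sqrt(diag(omega))
  bound <- 5 * sds
  # fixed multi-starts: origin and +/- 1 SD patterns
  starts <- rbind(0, diag(length(nm)) * sds, -diag(length(nm)) * sds)
  starts <- unique(starts)[seq_len(min(5, 1 + 2 * length(nm))), , drop = FALSE]
  best <- NULL
  for (k in seq_len(nrow(starts))) {
    fit <- tryCatch(
      optim(starts[k, ], obj, method = "L-BFGS-B",
            lower = -bound, upper = bound,
            control = list(factr = 1e-8 / .Machine$double.eps)),
      error = function(e) NULL)
    if (!is.null(fit) && is.finite(fit$value) &&
        (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best))
    stop("MAP objective non-finite at all starts (model ", model$model_id,
         ", patient ", patient$id, ")")
  eta_map <- setNames(best$par, nm)
  structure(list(eta_map = eta_map,
                 ipred = predict_concentrations(model, patient, eta_map, times),
                 pred = pred, objective = best$value,
                 n_priors_used = nrow(prior_obs)),
            class = "forecast_result")
}

#' Forecast the third occasion from earlier observations
#'
#' Predicts the patient's third observation using 1) no priors (a priori,
#' covariates only), 2) the most recent (second) observation only, or 3) the
#' first and second observations, mirroring the prior-combination experiment
#' used to justify forecasting from the most recent level.
#'
#' @param model A `model_spec`.
#' @param patient A `pk_patient` with >= 3 observations (distinct occasions).
#' @param prior_mode `"none"`, `"most_recent_only"` or `"first_and_second"`.
#' @return A `forecast_result` with `ipred` at the third observation time and
#'   the observed value in `obs`.
#' @export
forecast_third_interval <- function(model, patient,
                                    prior_mode = c("none", "most_recent_only",
                                                   "first_and_second")) {
  prior_mode <- match.arg(prior_mode)
  obs <- patient$obs[order(patient$obs$time), ]
  if (nrow(obs) < 3) stop("patient ", patient$id, " has fewer than 3 observations")
  target_time <- obs$time[3]
  priors <- switch(prior_mode,
                   none = obs[0, ],
                   most_recent_only = obs[2, ],
                   first_and_second = obs[1:2, ])
  res <- map_estimate(model, patient, prior_obs = priors, times = target_time)
  res$obs <- obs$conc[3]
  res$prior_mode <- prior_mode
  res
}

#' Adequacy of empirical Bayes estimates against the prior
#'
#' Computes per-patient MAP eta for each IIV parameter and compares the
#' estimated EBE distribution with the theoretical N(0, omega^2): returns
#' both samples' 20th/80th percentiles and the shrinkage
#' `1 - SD(EBE)/omega`. Parameters without IIV are skipped with a note.
#'
#' @param model A `model_spec`.
#' @param patients A `pk_cohort` (>= 20 patients with observations advised).
#' @return List of class `ebe_adequacy` with `ebe` (patients x parameters
#'   matrix), and per-parameter `summary` data.frame.
#' @export
ebe_adequacy <- function(model, patients) {
  nm <- rownames(model$omega)
  if (length(nm) == 0) stop("model has no IIV parameters")
  skipped <- setdiff(c("cl", "v1"), nm)
  ebe <- vapply(patients, function(p) map_estimate(model, p)$eta_map,
                setNames(numeric(length(nm)), nm))
  ebe <- if (length(nm) > 1L) t(ebe)
         else matrix(ebe, ncol = 1L, dimnames = list(NULL, nm))
  omega_sd <- sqrt(diag(model$omega))
  summary <- data.frame(
    parameter = nm,
    est_p20 = apply(ebe, 2, quantile, 0.20),
    est_p80 = apply(ebe, 2, quantile, 0.80),
    theo_p20 = qnorm(0.20, 0, omega_sd),
    theo_p80 = qnorm(0.80, 0, omega_sd),
    ebe_sd = apply(ebe, 2, sd),
    omega_sd = omega_sd,
    shrinkage = 1 - apply(ebe, 2, sd) / omega_sd,
    row.names = NULL)
  structure(list(model_id = model$model_id, ebe = ebe, summary = summary,
                 skipped = skipped),
            class = "ebe_adequacy")
}
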