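#' PK parameter set
#'
#' Clearance/volume parametrization of a one- or two-compartment disposition
#' model. Two-compartment models carry the inter-compartmental clearance `q`
#' and peripheral volume `v2`; `q = NULL` (or 0) collapses to one compartment.
#'
#' @param cl Clearance, L/h.
#' @param v1 Central volume, L.
#' @param q Inter-compartmental clearance, L/h (optional).
#' @param v2 Peripheral volume, L (optional).
#' @return List of class `pk_params`.
#' @export
pk_params <- function(cl, v1, q = NULL, v2 = NULL) {
  if (!is.numeric(cl) || !is.finite(cl) || cl <= 0) stop("cl must be positive")
  if (!is.numeric(v1) || !is.finite(v1) || v1 <= 0) stop("v1 must be positive")
  if (!is.null(q) && q > 0 && (is.null(v2) || v2 <= 0))
    stop("two-compartment parameters need v2 > 0")
  structure(list(cl = cl, v1 = v1,
                 q = if (!is.null(q) && q > 0) q else NULL,
                 v2 = if (!is.null(q) && q > 0) v2 else NULL),
            class = "pk_params")
}

#' Dose events
#'
#' @param amount Dose in mg.
#' @param start_time Infusion start, h.
#' @param duration Infusion duration, h (> 0; model a bolus as a short
#'   infusion).
#' @param interval Dosing interval tau in h, or `NA` for a single dose (used
#'   by [expand_regimen()] and [steady_state_profile()]).
#' @return data.frame of dose events sorted by start time.
#' @export
dose_event <- function(amount, start_time = 0, duration = 0.5, interval = NA) {
  if (any(amount <= 0)) stop("dose amount must be positive")
  if (any(duration <= 0)) stop("infusion duration must be positive")
  d <- data.frame(amount = amount, start_time = start_time,
                  duration = duration, interval = interval)
  d[order(d$start_time), , drop = FALSE]
}

#' Expand a periodic regimen into explicit dose events
#'
#' @param regimen A single-row dose event with a finite `interval`.
#' @param n_doses Number of doses.
#' @export
expand_regimen <- function(regimen, n_doses) {
  stopifnot(nrow(regimen) == 1L, is.finite(regimen$interval))
  dose_event(amount = rep(regimen$amount, n_doses),
             start_time = regimen$start_time +
               (seq_len(n_doses) - 1L) * regimen$interval,
             duration = rep(regimen$duration, n_doses))
}

# Disposition as a sum of exponentials: central concentration after a unit
# bolus is sum_i A_i exp(-lambda_i t). Two-compartment macro-constants from
# (CL, V1, Q, V2); the discriminant is guarded against cancellation and the
# (measure-zero) equal-root case is split by a tiny relative perturbation.
disposition_terms <- function(params) {
  cl <- params$cl; v1 <- params$v1
  if (is.null(params$q)) {
    return(list(A = 1 / v1, lambda = cl / v1))
  }
  q <- params$q; v2 <- params$v2
  k10 <- cl / v1; k12 <- q / v1; k21 <- q / v2
  s <- k10 + k12 + k21
  disc2 <- (k10 + k12 - k21)^2 + 4 * k12 * k21   # algebraically >= 0
  disc <- sqrt(disc2)
  if (disc < 1e-10 * s) disc <- 1e-10 * s        # limiting equal-root form
  alpha <- (s + disc) / 2
  beta  <- (s - disc) / 2
  A <- (alpha - k21) / (v1 * (alpha - beta))
  B <- (k21 - beta) / (v1 * (alpha - beta))
  list(A = c(A, B), lambda = c(alpha, beta))
}

# Contribution of one zero-order infusion (rate R over [0, T]) at elapsed
# times u (vectorized); terms from disposition_terms().
.infusion_contrib <- function(u, R, T, terms) {
  out <- numeric(length(u))
  for (i in seq_along(terms$lambda)) {
    Ai <- terms$A[i]; li <- terms$lambda[i]
    during <- u > 0 & u <= T
    after <- u > T
    out[during] <- out[during] + R * Ai / li * (1 - exp(-li * u[during]))
    out[after] <- out[after] +
      R * Ai / li * (1 - exp(-li * T)) * exp(-li * (u[after] - T))
  }
  out
}

#' Concentration under an arbitrary multiple-infusion history
#'
#' Closed-form superposition of per-dose infusion solutions for one- and
#' two-compartment disposition. Continuous and non-negative in time; times
#' before the first dose return 0.
#'
#' @param params A [pk_params()] object.
#' @param doses Dose events from [dose_event()].
#' @param times Numeric vector of times (h) at which to evaluate.
#' @return Concentrations in mg/L, one per time.
#' @export
concentration <- function(params, doses, times) {
  stopifnot(inherits(params, "pk_params"))
  if (any(times < 0)) stop("times must be >= 0")
  terms <- disposition_terms(params)
  out <- numeric(length(times))
  for (j in seq_len(nrow(doses))) {
    R <- doses$amount[j] / doses$duration[j]
    out <- out + .infusion_contrib(times - doses$start_time[j],
                                   R, doses$duration[j], terms)
  }
  out
}

#' Steady-state concentration profile for a periodic regimen
#'
#' Applies the analytic accumulation factor `1/(1 - exp(-lambda * tau))` per
#' exponential term, which equals the infinite superposition of identical
#' doses spaced `tau` apart. Requires the infusion to fit inside the interval
#' (continuous infusion, duration == tau, is allowed).
#'
#' @param params A [pk_params()] object.
#' @param regimen Single-row dose event with finite `interval`.
#' @param times Times within the dosing interval, h (0 = start of infusion);
#'   values are reduced modulo tau.
#' @return Steady-state concentrations, mg/L.
#' @export
steady_state_profile <- function(params, regimen, times) {
  stopifnot(nrow(regimen) == 1L)
  tau <- regimen$interval
  if (!is.finite(tau) || tau <= 0)
    stop("regimen has no finite interval; use concentration() on an explicit dose list")
  T <- regimen$duration
  if (T > tau + 1e-12)
    stop("infusion duration exceeds the dosing interval")
  t <- times %% tau
  terms <- disposition_terms(params)
  R <- regimen$amount / T
  out <- .infusion_contrib(t, R, T, terms)
  for (i in seq_along(terms$lambda)) {
    Ai <- terms$A[i]; li <- terms$lambda[i]
    acc <- exp(-li * (t + tau - T)) / (1 - exp(-li * tau))
    out <- out + R * Ai / li * (1 - exp(-li * T)) * acc
  }
  out
}

#' Per-observation model predictions for a patient
#'
#' Population prediction (PRED) when `eta` is zero/absent; individual
#' prediction (IPRED) for a supplied random-effect vector.
#'
#' @param model A `model_spec`.
#' @param patient A patient as built by [new_patient()] or
#'   [generate_cohort()]: needs `$covariates`, `$doses`, `$obs$time`.
#' @param eta Named random-effect vector (see
#'   [compute_individual_parameters()]).
#' @param times Observation times; defaults to the patient's.
#' @return Predicted concentrations, mg/L.
#' @export
predict_concentrations <- function(model, patient, eta = NULL, times = NULL) {
  if (is.null(times)) times <- patient$obs$time
  params <- compute_individual_parameters(model, patient$covariates, eta)
  if (length(times) && min(times) < min(patient$doses$start_time))
    warning("observation before first dose; predicted 0")
  concentration(params, patient$doses, times)
}

# Residual-error SD g evaluated at a prediction f, from a model's sigma spec.
residual_sd <- function(sigma, f) {
  switch(sigma$kind,
         proportional = sigma$prop * abs(f),
         additive = rep(sigma$add, length(f)),
         combined = sqrt(sigma$add^2 + (sigma$prop * f)^2))
}
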