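# Shared fixtures and independent oracles.

# Numeric ODE oracle for compartmental infusion kinetics, independent of the
# closed-form engine: integrates the mass-balance ODEs segment by segment
# (constant infusion rate within a segment) with lsoda at tight tolerance.
ode_oracle <- function(params, doses, times) {
  k10 <- params$cl / params$v1
  two_cmt <- !is.null(params$q)
  k12 <- if (two_cmt) params$q / params$v1 else 0
  k21 <- if (two_cmt) params$q / params$v2 else 0
  breaks <- sort(unique(c(0, doses$start_time,
                          doses$start_time + doses$duration, times)))
  rate_at <- function(t) {
    on <- t >= doses$start_time & t < doses$start_time + doses$duration - 1e-12
    sum((doses$amount / doses$duration)[on])
  }
  deriv <- function(t, y, parms) {
    r <- parms$rate
    dy1 <- r - (k10 + k12) * y[1] + k21 * y[2]
    dy2 <- k12 * y[1] - k21 * y[2]
    list(c(dy1, dy2))
  }
  y <- c(0, 0)
  sol <- setNames(numeric(length(times)), as.character(times))
  if (0 %in% times) sol["0"] <- 0
  for (i in seq_len(length(breaks) - 1)) {
    t0 <- breaks[i]; t1 <- breaks[i + 1]
    r <- rate_at((t0 + t1) / 2)
    out <- deSolve::lsoda(y, c(t0, t1), deriv, parms = list(rate = r),
                          rtol = 1e-11, atol = 1e-12)
    y <- as.numeric(out[nrow(out), 2:3])
    if (t1 %in% times) sol[as.character(t1)] <- y[1] / params$v1
  }
  as.numeric(sol[as.character(times)])
}

# Dense 1-D grid search of the MAP posterior for a model with a single
# (clearance) random effect: the independent oracle for map_estimate().
map_grid_oracle <- function(model, patient, prior_obs, step = 1e-4,
                            span = 5) {
  w <- sqrt(model$omega[1, 1])
  grid <- seq(-span * w, span * w, by = step)
  y <- prior_obs$conc
  obj <- vapply(grid, function(et) {
    eta <- setNames(et, rownames(model$omega))
    f <- predict_concentrations(model, patient, eta, prior_obs$time)
    g2 <- pmax(residual_sd(model$sigma, f), 1e-8)^2
    sum((y - f)^2 / g2 + log(g2)) + et^2 / model$omega[1, 1]
  }, 0)
  grid[which.min(obj)]
}

# Two-stage dense grid search (coarse then refined around the coarse
# minimum): same oracle, cheaper than a single global fine grid.
map_grid_oracle_refined <- function(model, patient, prior_obs) {
  coarse <- map_grid_oracle(model, patient, prior_obs, step = 2e-3)
  w <- sqrt(model$omega[1, 1])
  grid <- seq(coarse - 5e-3, coarse + 5e-3, by = 1e-5)
  y <- prior_obs$conc
  obj <- vapply(grid, function(et) {
    eta <- setNames(et, rownames(model$omega))
    f <- predict_concentrations(model, patient, eta, prior_obs$time)
    g2 <- pmax(residual_sd(model$sigma, f), 1e-8)^2
    sum((y - f)^2 / g2 + log(g2)) + et^2 / model$omega[1, 1]
  }, 0)
  grid[which.min(obj)]
}

# A typical ICU subject with overridable covariates.
make_covariates <- function(...) {
  args <- list(age = 58, sex = "male", weight = 58.5, height = 166,
               albumin = 29.1, scr = 143, crrt = FALSE,
               residual_diuresis = 2000, sepsis = FALSE, crrt_flow = 2)
  over <- list(...)
  args[names(over)] <- over
  do.call(covariate_record, args)
}

# A small deterministic patient on 1 g q8h with trough-ish samples.
make_patient <- function(id = 1, n_doses = 8, interval = 8, amount = 1000,
                         duration = 1, obs_times = NULL, obs_conc = NULL,
                         cov = make_covariates()) {
  doses <- expand_regimen(dose_event(amount, 0, duration, interval), n_doses)
  if (is.null(obs_times))
    obs_times <- n_doses * interval - c(2, 1, 0.5)
  if (is.null(obs_conc)) obs_conc <- rep(10, length(obs_times))
  new_patient(id, cov, doses,
              data.frame(time = obs_times, conc = obs_conc, bql = FALSE))
}

# Simulate observations for a patient from a model with known eta/noise.
simulate_patient_obs <- function(model, patient, eta = NULL, prop_sd = 0) {
  f <- predict_concentrations(model, patient, eta)
  y <- f * (1 + prop_sd * rnorm(length(f)))
  patient$obs$conc <- pmax(y, 1e-3)
  patient$truth <- list(eta = eta, conc_true = f)
  patient
}

residual_sd <- meroeval:::residual_sd
disposition_terms <- meroeval:::disposition_terms
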