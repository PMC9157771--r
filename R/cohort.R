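#' Construct a patient
#'
#' @param id Patient identifier.
#' @param covariates A [covariate_record()] (or compatible list).
#' @param doses Dose events ([dose_event()]).
#' @param obs data.frame with columns `time` (h), `conc` (mg/L) and
#'   optionally `bql` (below the quantification limit).
#' @param truth Optional list with generator ground truth (`eta`,
#'   `conc_true`) for synthetic patients.
#' @return List of class `pk_patient`.
#' @export
new_patient <- function(id, covariates, doses, obs, truth = NULL) {
  if (is.null(obs$bql)) obs$bql <- FALSE
  structure(list(id = id, covariates = covariates, doses = doses,
                 obs = obs, truth = truth),
            class = "pk_patient")
}

#' Synthetic ICU cohort configuration
#'
#' Defaults emulate the routine meropenem TDM cohort the package's
#' diagnostics are designed around: 134 ICU patients, about a third on CRRT,
#' mostly single trough samples, covariates spanning the full range of renal
#' function, intermittent 0.5-4 h infusions of 0.5-2 g q4-12h, and a 0.5 mg/L
#' assay quantification limit. Continuous covariates are drawn from truncated
#' log-normals parameterized so the median matches the cohort median and the
#' printed range endpoints sit near the 1st/99th percentiles.
#'
#' @param n_patients Number of patients.
#' @param crrt_fraction Fraction on CRRT (default 0.3358).
#' @param male_fraction Fraction male (83/134).
#' @param regimen_probs Named probabilities over regimen labels
#'   `"amount_mg/interval_h"`; the residual `other` mass is split uniformly
#'   over 1 g q12h, 0.5 g q6h, 2 g q6h and continuous infusion.
#' @param infusion_hours,infusion_probs Infusion-duration choices (h) and
#'   their probabilities.
#' @param covariates Per-covariate `c(lo, median, hi)` triples.
#' @param single_sample_fraction Fraction of patients with one sample
#'   (88/134); the rest get 2-4 samples on consecutive dosing intervals.
#' @param multi_sample_probs Probabilities of 2, 3 and 4 samples for
#'   multi-sample patients.
#' @param sampling `"trough"` (default): samples drawn within 1 h before the
#'   next dose, mimicking routine TDM; `"uniform"`: drawn anywhere in the
#'   post-infusion window of the occasion (informative sampling for
#'   identifiability studies).
#' @param generator_model Model id used to simulate concentrations.
#' @param sigma Residual-error spec for simulation (NULL = the generator
#'   model's own).
#' @param iiv_scale Multiplier on the generator's eta SDs (0 = no IIV).
#' @param lloq Lower limit of quantification, mg/L.
#' @param seed Integer seed; every draw flows from it.
#' @return List of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 134,
                          crrt_fraction = 0.3358,
                          male_fraction = 83 / 134,
                          regimen_probs = c("1000/8" = 0.573, "1000/6" = 0.129,
                                            "500/8" = 0.086, "2000/8" = 0.065,
                                            "2000/12" = 0.043, other = 0.104),
                          infusion_hours = c(0.5, 1, 2, 3, 4),
                          infusion_probs = c(0.35, 0.35, 0.15, 0.10, 0.05),
                          covariates = list(
                            age = c(22, 58, 89),
                            weight = c(40, 58.5, 84),
                            height = c(148, 166, 175),
                            albumin = c(16.7, 29.1, 54),
                            scr = c(24, 143, 1145),
                            residual_diuresis = c(10, 2078, 6000),
                            crrt_flow = c(1.5, 2.4, 3.5)),
                          single_sample_fraction = 88 / 134,
                          multi_sample_probs = c(`2` = 0.72, `3` = 0.13,
                                                 `4` = 0.15),
                          sampling = c("trough", "uniform"),
                          generator_model = "li",
                          sigma = NULL,
                          iiv_scale = 1,
                          lloq = 0.5,
                          seed = 2022L) {
  sampling <- match.arg(sampling)
  stopifnot(abs(sum(regimen_probs) - 1) < 1e-9,
            abs(sum(infusion_probs) - 1) < 1e-9,
            abs(sum(multi_sample_probs) - 1) < 1e-9)
  for (cv in covariates)
    if (!(cv[1] <= cv[2] && cv[2] <= cv[3]))
      stop("covariate triples must be ordered lo <= median <= hi")
  structure(as.list(environment()), class = "cohort_config")
}

# Truncated log-normal hitting the median, with range endpoints near the
# 1st/99th percentiles of the untruncated law.
.rtrunc_lnorm <- function(n, lo, med, hi) {
  if (lo == hi) return(rep(med, n))
  sdlog <- max(log(med / lo), log(hi / med)) / stats::qnorm(0.99)
  x <- stats::rlnorm(n, meanlog = log(med), sdlog = sdlog)
  bad <- x < lo | x > hi
  while (any(bad)) {
    x[bad] <- stats::rlnorm(sum(bad), meanlog = log(med), sdlog = sdlog)
    bad <- x < lo | x > hi
  }
  x
}

.regimen_from_label <- function(label, infusion_h) {
  if (label == "ci") {          # continuous infusion: 3 g/day as q8h with
    amt <- 1000; tau <- 8       # infusion spanning the whole interval
    inf <- tau
  } else {
    parts <- as.numeric(strsplit(label, "/", fixed = TRUE)[[1]])
    amt <- parts[1]; tau <- parts[2]
    inf <- min(infusion_h, tau)
  }
  list(amount = amt, interval = tau, infusion = inf)
}

#' Generate a synthetic ICU cohort
#'
#' Draws covariates, CRRT status, regimens and sparse trough-biased sampling
#' times per the configuration, then simulates observed concentrations from
#' the generator model with per-patient log-normal random effects and
#' residual error. Ground truth (eta and noise-free concentrations) is kept
#' on each patient for recovery tests. Observations below the LLOQ are
#' retained but flagged `bql`; use [apply_lloq_filter()] to drop them.
#'
#' @param config A [cohort_config()].
#' @param registry Optional model registry.
#' @return List of `pk_patient` of class `pk_cohort`, with the config as an
#'   attribute.
#' @export
generate_cohort <- function(config = cohort_config(), registry = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  model <- get_model(config$generator_model, registry)
  sigma <- if (is.null(config$sigma)) model$sigma else config$sigma
  n <- config$n_patients
  cv <- config$covariates

  crrt <- runif(n) < config$crrt_fraction
  sex <- ifelse(runif(n) < config$male_fraction, "male", "female")
  age <- pmax(.rtrunc_lnorm(n, cv$age[1], cv$age[2], cv$age[3]), 18)
  weight <- .rtrunc_lnorm(n, cv$weight[1], cv$weight[2], cv$weight[3])
  height <- .rtrunc_lnorm(n, cv$height[1], cv$height[2], cv$height[3])
  albumin <- .rtrunc_lnorm(n, cv$albumin[1], cv$albumin[2], cv$albumin[3])
  scr <- .rtrunc_lnorm(n, cv$scr[1], cv$scr[2], cv$scr[3])
  diuresis <- .rtrunc_lnorm(n, cv$residual_diuresis[1],
                            cv$residual_diuresis[2], cv$residual_diuresis[3])
  # CRRT patients: oliguric as a rule
  diuresis[crrt] <- pmax(diuresis[crrt] * 0.15, cv$residual_diuresis[1])
  crrt_flow <- .rtrunc_lnorm(n, cv$crrt_flow[1], cv$crrt_flow[2],
                             cv$crrt_flow[3])
  sepsis <- runif(n) < 0.6

  reg_labels <- names(config$regimen_probs)
  reg_draw <- sample(reg_labels, n, replace = TRUE,
                     prob = config$regimen_probs)
  other_pool <- c("1000/12", "500/6", "2000/6", "ci")
  reg_draw[reg_draw == "other"] <-
    sample(other_pool, sum(reg_draw == "other"), replace = TRUE)
  inf_draw <- sample(config$infusion_hours, n, replace = TRUE,
                     prob = config$infusion_probs)

  n_samp <- ifelse(runif(n) < config$single_sample_fraction, 1L,
                   as.integer(sample(names(config$multi_sample_probs), n,
                                     replace = TRUE,
                                     prob = config$multi_sample_probs)))

  has_iiv <- nrow(model$omega) > 0 && any(diag(model$omega) > 0) &&
    config$iiv_scale > 0
  omega_chol <- if (has_iiv) chol(model$omega) else NULL

  patients <- vector("list", n)
  for (i in seq_len(n)) {
    rec <- covariate_record(age = age[i], sex = sex[i], weight = weight[i],
                            height = height[i], albumin = albumin[i],
                            scr = scr[i], crrt = crrt[i],
                            residual_diuresis = diuresis[i],
                            sepsis = sepsis[i], crrt_flow = crrt_flow[i])
    reg <- .regimen_from_label(reg_draw[i], inf_draw[i])
    # enough doses to be at steady state (meropenem t1/2 ~ 1-2 h) and to
    # carry the sampled occasions on consecutive trailing intervals
    n_doses <- max(ceiling(48 / reg$interval), 6L) + n_samp[i]
    doses <- expand_regimen(dose_event(reg$amount, 0, reg$infusion,
                                       reg$interval), n_doses)
    # trough-biased sampling: within 1 h before the end of each of the last
    # n_samp dosing intervals (one occasion per interval)
    occ_ends <- (n_doses - n_samp[i] + seq_len(n_samp[i])) * reg$interval
    width <- if (config$sampling == "trough") 1
             else reg$interval - reg$infusion - 0.1
    times <- sort(occ_ends - runif(n_samp[i], 0, max(width, 0.5)))

    eta <- numeric(0)
    if (!is.null(omega_chol) && config$iiv_scale > 0) {
      eta <- drop(crossprod(omega_chol, rnorm(nrow(omega_chol)))) *
        config$iiv_scale
      names(eta) <- rownames(model$omega)
    }
    params <- compute_individual_parameters(model, rec, eta)
    f <- concentration(params, doses, times)
    g <- residual_sd(sigma, f)
    y <- pmax(f + g * rnorm(length(f)), 0)
    obs <- data.frame(time = times, conc = y, bql = y < config$lloq)
    patients[[i]] <- new_patient(
      id = i, covariates = rec, doses = doses, obs = obs,
      truth = list(eta = eta, conc_true = f, regimen = reg_draw[i],
                   model_id = model$model_id))
  }
  structure(patients, class = "pk_cohort", config = config)
}

#' Remove observations below the limit of quantification
#'
#' Mirrors the routine-TDM exclusion rule: concentrations below the assay
#' LLOQ are dropped and counted; patients left without observations are
#' removed from evaluation.
#'
#' @param patients A `pk_cohort` or list of `pk_patient`.
#' @param lloq Quantification limit, mg/L (default 0.5).
#' @return List with `patients` (filtered), `n_removed` (censored
#'   observations) and `dropped_patients` (ids with no remaining
#'   observations).
#' @export
apply_lloq_filter <- function(patients, lloq = 0.5) {
  if (lloq <= 0) stop("lloq must be positive")
  n_removed <- 0L
  dropped <- integer(0)
  kept <- list()
  for (p in patients) {
    keep <- p$obs$conc >= lloq
    n_removed <- n_removed + sum(!keep)
    if (!any(keep)) {
      dropped <- c(dropped, p$id)
      next
    }
    if (!all(keep)) {
      p$obs <- p$obs[keep, , drop = FALSE]
      if (!is.null(p$truth)) p$truth$conc_true <- p$truth$conc_true[keep]
    }
    kept[[length(kept) + 1L]] <- p
  }
  if (length(dropped))
    message(length(dropped), " patient(s) dropped (no observations above LLOQ)")
  list(patients = structure(kept, class = "pk_cohort",
                            config = attr(patients, "config")),
       n_removed = n_removed, dropped_patients = dropped)
}
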