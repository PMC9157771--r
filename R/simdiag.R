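#' Monte-Carlo replicate simulation aligned to an observed design
#'
#' Simulates `n_rep` datasets from a model on the observed design (same
#' patients, dosing histories and sampling times): per replicate, one eta
#' draw from N(0, Omega) per patient and one residual draw per observation.
#' Negative simulated concentrations are truncated at zero.
#'
#' @param model A `model_spec`.
#' @param patients A `pk_cohort`.
#' @param n_rep Number of replicates (default 1000).
#' @param seed Integer seed; identical seeds give identical ensembles.
#' @return List of class `sim_ensemble`: `sims` (n_rep x n_obs matrix),
#'   `pred` (population predictions), `obs`, `patient_index`, `tald`
#'   (time after start of the most recent dose), `crrt` per observation.
#' @export
simulate_replicates <- function(model, patients, n_rep = 1000, seed = 1L) {
  stopifnot(n_rep >= 1)
  set.seed(seed)
  n_obs_per <- vapply(patients, function(p) nrow(p$obs), 0L)
  n_obs <- sum(n_obs_per)
  pred <- numeric(n_obs)
  obs <- numeric(n_obs)
  tald <- numeric(n_obs)
  crrt <- logical(n_obs)
  idx <- rep(seq_along(patients), n_obs_per)
  pos <- 0L
  for (p in patients) {
    k <- nrow(p$obs)
    if (k == 0) next
    rng <- pos + seq_len(k)
    pred[rng] <- predict_concentrations(model, p)
    obs[rng] <- p$obs$conc
    tald[rng] <- vapply(p$obs$time, function(t) {
      starts <- p$doses$start_time[p$doses$start_time <= t]
      if (length(starts)) t - max(starts) else t
    }, 0)
    crrt[rng] <- isTRUE(p$covariates$crrt)
    pos <- pos + k
  }
  has_iiv <- nrow(model$omega) > 0 && any(diag(model$omega) > 0)
  omega_chol <- if (has_iiv) chol(model$omega) else NULL
  nm <- rownames(model$omega)
  # random effects scale the typical parameters exponentially, so the
  # covariate formulas are evaluated once per patient and only the scaled
  # parameters are rebuilt per replicate
  base <- lapply(patients, function(p)
    compute_individual_parameters(model, p$covariates))
  sims <- matrix(0, nrow = n_rep, ncol = n_obs)
  for (r in seq_len(n_rep)) {
    pos <- 0L
    for (pi in seq_along(patients)) {
      p <- patients[[pi]]
      k <- nrow(p$obs)
      if (k == 0) next
      params <- base[[pi]]
      if (!is.null(omega_chol)) {
        eta <- setNames(drop(crossprod(omega_chol, rnorm(length(nm)))), nm)
        params <- .scale_params(params, eta, model$parametrization)
      }
      f <- concentration(params, p$doses, p$obs$time)
      g <- residual_sd(model$sigma, f)
      sims[r, pos + seq_len(k)] <- pmax(f + g * rnorm(k), 0)
      pos <- pos + k
    }
  }
  structure(list(sims = sims, pred = pred, obs = obs, patient_index = idx,
                 tald = tald, crrt = crrt, n_rep = n_rep, seed = seed,
                 model_id = model$model_id),
            class = "sim_ensemble")
}

#' Prediction-corrected visual predictive check
#'
#' Bins observations on time after the most recent dose, corrects observed
#' and simulated values by `bin median PRED / individual PRED`, and compares
#' the observed 5/50/95th percentiles per bin to the 90% confidence band of
#' the same percentiles across simulation replicates. Bins with fewer than
#' two observations are merged with their neighbor.
#'
#' @param ensemble A `sim_ensemble` from [simulate_replicates()].
#' @param n_bins Number of quantile bins on time after dose (default 8).
#' @param probs Percentiles tracked (default 5/50/95%).
#' @param ci Width of the simulated confidence band (default 0.90).
#' @return List of class `vpc_result` with a per-bin data.frame `table`
#'   (bin edges, n, observed percentiles, band lo/hi per percentile) and the
#'   correction factors used.
#' @export
pcvpc <- function(ensemble, n_bins = 8, probs = c(0.05, 0.5, 0.95),
                  ci = 0.90) {
  tald <- ensemble$tald
  edges <- unique(quantile(tald, probs = seq(0, 1, length.out = n_bins + 1)))
  if (length(edges) < 2) edges <- edges[1] + c(-0.5, 0.5)
  bin <- cut(tald, breaks = edges, include.lowest = TRUE)
  # merge under-filled bins with their left neighbor
  repeat {
    cnt <- table(bin)
    small <- which(cnt < 2)
    if (!length(small) || length(levels(bin)) == 1L) break
    i <- small[1]
    j <- if (i == 1L) 2L else i - 1L
    levels(bin)[c(i, j)] <- levels(bin)[j]
    message("pcVPC: merged under-filled time bin")
  }
  bins <- levels(bin)
  pred <- ensemble$pred
  cf <- numeric(length(pred))    # prediction-correction factor per obs
  for (b in bins) {
    in_b <- bin == b
    cf[in_b] <- median(pred[in_b]) / pred[in_b]
  }
  obs_c <- ensemble$obs * cf
  sims_c <- sweep(ensemble$sims, 2, cf, `*`)
  alpha <- (1 - ci) / 2
  rows <- lapply(bins, function(b) {
    in_b <- bin == b
    op <- quantile(obs_c[in_b], probs)
    simq <- apply(sims_c[, in_b, drop = FALSE], 1, quantile, probs)
    if (is.null(dim(simq))) simq <- matrix(simq, nrow = length(probs))
    lo <- apply(simq, 1, quantile, alpha)
    hi <- apply(simq, 1, quantile, 1 - alpha)
    data.frame(bin = b, t_mid = median(ensemble$tald[in_b]), n = sum(in_b),
               pctl = probs * 100, observed = as.numeric(op),
               band_lo = lo, band_hi = hi)
  })
  structure(list(table = do.call(rbind, rows), bins = bins, ci = ci,
                 correction = cf),
            class = "vpc_result")
}

#' Normalized prediction distribution errors
#'
#' Per patient, the observed vector and each simulated replicate are
#' decorrelated with the simulation-based mean and Cholesky factor of the
#' simulated covariance; `pd` is the fraction of decorrelated simulations
#' below the decorrelated observation (ties add 0.5/K), clamped to
#' `[1/(2K), 1 - 1/(2K)]`, and `npde = qnorm(pd)`. The test battery is: mean
#' zero (t test), variance one (chi-square test), normality
#' (Shapiro-Wilk), combined with a Bonferroni correction.
#'
#' @param ensemble A `sim_ensemble`.
#' @param ridge Relative ridge added to a numerically singular simulated
#'   covariance (logged when used).
#' @return List of class `npde_result`: `npde` per observation, test
#'   p-values, `global_p` and `global_decision` at the 5% level.
#' @export
npde <- function(ensemble, ridge = 1e-8) {
  K <- ensemble$n_rep
  out <- numeric(length(ensemble$obs))
  for (i in unique(ensemble$patient_index)) {
    cols <- which(ensemble$patient_index == i)
    Y <- ensemble$sims[, cols, drop = FALSE]
    y <- ensemble$obs[cols]
    mu <- colMeans(Y)
    V <- stats::cov(Y)
    L <- tryCatch(chol(V), error = function(e) {
      message("npde: ridge-regularized simulated covariance (patient ", i, ")")
      chol(V + diag(ridge * mean(diag(V)) + 1e-12, nrow(V)))
    })
    ys <- backsolve(t(L), y - mu, upper.tri = FALSE)
    Ys <- t(backsolve(t(L), t(Y) - mu, upper.tri = FALSE))
    for (j in seq_along(cols)) {
      pd <- (sum(Ys[, j] < ys[j]) + 0.5 * sum(Ys[, j] == ys[j])) / K
      pd <- min(max(pd, 1 / (2 * K)), 1 - 1 / (2 * K))
      out[cols[j]] <- qnorm(pd)
    }
  }
  n <- length(out)
  p_mean <- if (n >= 2) t.test(out)$p.value else NA_real_
  p_var <- if (n >= 2) {
    chi <- (n - 1) * stats::var(out)
    2 * min(pchisq(chi, n - 1), 1 - pchisq(chi, n - 1))
  } else NA_real_
  p_norm <- if (n >= 3 && n <= 5000) shapiro.test(out)$p.value else NA_real_
  ps <- c(mean = p_mean, variance = p_var, normality = p_norm)
  global_p <- if (all(is.na(ps))) NA_real_
              else min(1, 3 * min(ps, na.rm = TRUE))
  structure(list(npde = out, p_mean = p_mean, p_variance = p_var,
                 p_normality = p_norm, global_p = global_p,
                 global_decision = if (isTRUE(global_p < 0.05)) "reject"
                                   else "accept"),
            class = "npde_result")
}
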