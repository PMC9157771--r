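# small self-simulated cohort used across the diagnostics tests
make_sim_cohort <- function(model, n = 30, seed = 1, prop_sd = NULL) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    cov <- make_covariates(scr = exp(runif(1, log(50), log(600))),
                           weight = runif(1, 45, 80))
    k <- sample(1:2, 1)
    pat <- make_patient(id = i, obs_times = 64 - sort(runif(k, 0.2, 6)),
                        cov = cov)
    w <- sqrt(diag(model$omega))
    eta <- setNames(rnorm(length(w), 0, w), names(w))
    f <- predict_concentrations(model, pat, eta)
    sdp <- if (is.null(prop_sd)) model$sigma$prop else prop_sd
    pat$obs$conc <- pmax(f * (1 + sdp * rnorm(k)), 1e-3)
    pat
  })
}

test_that("replicate simulation is seed-deterministic and collapses without randomness", {
  m <- get_model("muro")
  pats <- make_sim_cohort(m, n = 8)
  e1 <- simulate_replicates(m, pats, n_rep = 20, seed = 5)
  e2 <- simulate_replicates(m, pats, n_rep = 20, seed = 5)
  expect_identical(e1$sims, e2$sims)
  expect_true(all(e1$sims >= 0))
  expect_equal(dim(e1$sims), c(20, length(e1$obs)))

  m0 <- m
  m0$omega <- m0$omega * 0
  m0$sigma$prop <- 0
  e0 <- simulate_replicates(m0, pats, n_rep = 5, seed = 1)
  for (r in 1:5) expect_equal(e0$sims[r, ], e0$pred)
})

test_that("ensemble mean approaches the PRED-derived expectation", {
  m <- get_model("muro")
  pats <- make_sim_cohort(m, n = 10)
  ens <- simulate_replicates(m, pats, n_rep = 1000, seed = 9)
  # independent oracle: E[f(eta)] by trapezoid quadrature over the eta prior
  w <- sqrt(m$omega[1, 1])
  grid <- seq(-5 * w, 5 * w, length.out = 201)
  dens <- dnorm(grid, 0, w)
  expectation <- rowSums(vapply(seq_along(grid), function(g) {
    unlist(lapply(pats, function(p)
      predict_concentrations(m, p, c(cl = grid[g])))) * dens[g]
  }, numeric(length(ens$obs)))) * diff(grid)[1]
  mc_mean <- colMeans(ens$sims)
  mc_se <- apply(ens$sims, 2, sd) / sqrt(ens$n_rep)
  expect_true(all(abs(mc_mean - expectation) <= 3.5 * mc_se + 0.02))
})

test_that("pcVPC reduces to a plain VPC when all PRED agree within a bin", {
  m <- get_model("grensemann")   # no covariates: PRED identical across
  pats <- make_sim_cohort(m, n = 12)
  for (p in seq_along(pats)) {   # same design -> same PRED per time
    pats[[p]]$obs$time <- c(63.5)
    pats[[p]]$obs <- pats[[p]]$obs[1, , drop = FALSE]
  }
  ens <- simulate_replicates(m, pats, n_rep = 50, seed = 2)
  v <- pcvpc(ens, n_bins = 1)
  expect_true(all(abs(v$correction - 1) < 1e-12))
  obs_c <- ens$obs
  expect_equal(v$table$observed,
               as.numeric(quantile(obs_c, c(0.05, 0.5, 0.95))))
})

test_that("single-bin toy pcVPC percentiles equal hand computation", {
  m <- get_model("grensemann")
  pats <- make_sim_cohort(m, n = 3)
  for (p in 1:3) pats[[p]]$obs <- pats[[p]]$obs[1, , drop = FALSE]
  ens <- simulate_replicates(m, pats, n_rep = 4, seed = 3)
  # overwrite with hand-listed values (PRED all equal -> correction 1)
  ens$pred <- rep(10, 3)
  ens$obs <- c(4, 9, 16)
  ens$sims <- matrix(c(1, 2, 3,
                       4, 5, 6,
                       7, 8, 9,
                       10, 11, 12), nrow = 4, byrow = TRUE)
  ens$tald <- rep(1, 3)
  v <- pcvpc(ens, n_bins = 1)
  expect_equal(v$table$observed,
               as.numeric(quantile(c(4, 9, 16), c(0.05, 0.5, 0.95))))
  simq <- t(apply(ens$sims, 1, quantile, c(0.05, 0.5, 0.95)))
  expect_equal(v$table$band_lo,
               unname(apply(simq, 2, quantile, 0.05)))
  expect_equal(v$table$band_hi,
               unname(apply(simq, 2, quantile, 0.95)))
  expect_true(all(v$table$band_lo <= v$table$band_hi))
})

test_that("observed percentiles are ordered p5 <= p50 <= p95 per bin", {
  m <- get_model("muro")
  pats <- make_sim_cohort(m, n = 40, seed = 6)
  ens <- simulate_replicates(m, pats, n_rep = 100, seed = 6)
  v <- pcvpc(ens, n_bins = 4)
  wide <- split(v$table$observed, v$table$bin)
  for (b in wide) expect_true(all(diff(b) >= 0))
})

test_that("univariate npde matches the hand rank computation and clamps ties", {
  m <- get_model("grensemann")
  pats <- make_sim_cohort(m, n = 1)
  pats[[1]]$obs <- pats[[1]]$obs[1, , drop = FALSE]
  ens <- simulate_replicates(m, pats, n_rep = 4, seed = 4)
  ens$obs <- 2.5
  ens$sims <- matrix(c(1, 2, 3, 4), ncol = 1)
  r <- npde(ens)
  expect_equal(r$npde, qnorm(0.5))   # pd = 2/4 -> npde = 0

  ens$obs <- 99                       # above all sims: clamped
  r_hi <- npde(ens)
  expect_equal(r_hi$npde, qnorm(1 - 1 / 8))
  ens$obs <- 3                        # equals one sim: tie adds 0.5/K
  r_tie <- npde(ens)
  expect_equal(r_tie$npde, qnorm((2 + 0.5) / 4))
  expect_true(is.finite(r_tie$npde))
})

test_that("npde is invariant to monotone rescaling in the univariate case", {
  m <- get_model("muro")
  pats <- make_sim_cohort(m, n = 15, seed = 8)
  for (p in seq_along(pats)) pats[[p]]$obs <- pats[[p]]$obs[1, , drop = FALSE]
  ens <- simulate_replicates(m, pats, n_rep = 60, seed = 8)
  base <- npde(ens)
  ens3 <- ens                       # affine maps preserve the rank statistic
  ens3$obs <- 3 * ens$obs + 1
  ens3$sims <- 3 * ens$sims + 1
  expect_equal(npde(ens3)$npde, base$npde)
})

test_that("npde under the true model looks standard normal", {
  m <- get_model("muro")
  pats <- make_sim_cohort(m, n = 60, seed = 10)
  ens <- simulate_replicates(m, pats, n_rep = 500, seed = 10)
  r <- npde(ens)
  n <- length(r$npde)
  expect_lt(abs(mean(r$npde)), 3 / sqrt(n))
  expect_lt(abs(var(r$npde) - 1), 3 * sqrt(2 / n))
  expect_true(all(r$npde > -5 & r$npde < 5))
  expect_true(all(c(r$p_mean, r$p_variance, r$p_normality) >= 0 &
                  c(r$p_mean, r$p_variance, r$p_normality) <= 1))
})
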