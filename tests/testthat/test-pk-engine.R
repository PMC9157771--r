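test_that("no drug means zero concentration; pre-dose times are zero", {
  p <- pk_params(10, 20)
  d <- dose_event(1000, 5, 1)
  expect_equal(concentration(p, d, c(0, 2, 4.999)), c(0, 0, 0))
  expect_error(concentration(p, d, -1), ">= 0")
})

test_that("closed-form 1-CMT infusion matches the numeric ODE oracle", {
  skip_if_not_installed("deSolve")
  p <- pk_params(10, 20)
  d <- dose_event(1000, 0, 1)
  tt <- c(0.25, 0.5, 1, 1.5, 3, 6, 12)
  closed <- concentration(p, d, tt)
  ode <- ode_oracle(p, d, tt)
  expect_equal(closed, ode, tolerance = 1e-6)
  # textbook value at end of infusion
  expect_equal(closed[3], 1000 / 10 * (1 - exp(-0.5)), tolerance = 1e-12)
})

test_that("closed-form profiles match the ODE oracle on randomized 1- and 2-CMT draws", {
  skip_if_not_installed("deSolve")
  set.seed(7)
  for (i in 1:50) {
    two <- i %% 2 == 0
    p <- pk_params(cl = runif(1, 2, 20), v1 = runif(1, 5, 40),
                   q = if (two) runif(1, 2, 30) else NULL,
                   v2 = if (two) runif(1, 5, 200) else NULL)
    tau <- sample(c(4, 6, 8, 12), 1)
    dur <- sample(c(0.5, 1, 2, 3), 1)
    n_d <- sample(3:6, 1)
    d <- expand_regimen(dose_event(runif(1, 500, 2000), 0, dur, tau), n_d)
    # drop one interior dose to make the history irregular
    if (n_d > 3) d <- d[-2, ]
    tt <- sort(runif(6, dur * 0.5, n_d * tau))
    closed <- concentration(p, d, tt)
    ode <- ode_oracle(p, d, tt)
    expect_equal(closed, ode, tolerance = 1e-6,
                 label = paste("draw", i))
  }
})

test_that("two-compartment model with vanishing Q collapses to one compartment", {
  d <- expand_regimen(dose_event(1000, 0, 1, 8), 3)
  tt <- seq(0.5, 24, by = 0.5)
  one <- concentration(pk_params(10, 20), d, tt)
  two <- concentration(pk_params(10, 20, q = 1e-12, v2 = 50), d, tt)
  expect_equal(two, one, tolerance = 1e-8)
})

test_that("profiles are continuous at the end of infusion", {
  for (p in list(pk_params(10, 20), pk_params(8, 15, q = 12, v2 = 30))) {
    d <- dose_event(1000, 0, 1)
    eps <- 1e-9
    left <- concentration(p, d, 1 - eps)
    right <- concentration(p, d, 1 + eps)
    expect_equal(left, right, tolerance = 1e-7)
  }
})

test_that("superposition: two dose lists add", {
  p <- pk_params(8, 15, q = 12, v2 = 30)
  d1 <- dose_event(1000, 0, 1)
  d2 <- dose_event(500, 5, 2)
  both <- dose_event(c(1000, 500), c(0, 5), c(1, 2))
  tt <- seq(0.5, 20, by = 0.5)
  expect_equal(concentration(p, both, tt),
               concentration(p, d1, tt) + concentration(p, d2, tt),
               tolerance = 1e-12)
})

test_that("steady-state profile equals brute-force superposition of 50 doses", {
  for (p in list(pk_params(10, 20), pk_params(8, 15, q = 12, v2 = 30))) {
    reg <- dose_event(1000, 0, 1, 8)
    tt <- seq(0.25, 7.75, by = 0.25)
    ss <- steady_state_profile(p, reg, tt)
    many <- expand_regimen(reg, 50)
    brute <- concentration(p, many, 49 * 8 + tt)
    expect_equal(ss, brute, tolerance = 1e-6)
  }
  # trough specifically
  p <- pk_params(10, 20)
  reg <- dose_event(1000, 0, 1, 8)
  expect_equal(steady_state_profile(p, reg, 8 - 1e-9),
               concentration(p, expand_regimen(reg, 50), 50 * 8 - 1e-9),
               tolerance = 1e-6)
})

test_that("steady state scales linearly with dose and tends to the single dose as tau grows", {
  p <- pk_params(10, 20, q = 12, v2 = 30)
  tt <- seq(0.5, 7.5, by = 0.5)
  ss1 <- steady_state_profile(p, dose_event(1000, 0, 1, 8), tt)
  ss2 <- steady_state_profile(p, dose_event(2000, 0, 1, 8), tt)
  expect_equal(ss2, 2 * ss1, tolerance = 1e-12)
  ss_long <- steady_state_profile(p, dose_event(1000, 0, 1, 5000), tt)
  single <- concentration(p, dose_event(1000, 0, 1), tt)
  expect_equal(ss_long, single, tolerance = 1e-9)
  expect_error(steady_state_profile(p, dose_event(1000, 0, 1, NA), tt),
               "interval")
})

test_that("continuous infusion at steady state sits at rate/CL", {
  p <- pk_params(10, 20)
  reg <- dose_event(1000, 0, 8, 8)    # infusion spans the whole interval
  ss <- steady_state_profile(p, reg, c(1, 4, 7.9))
  expect_equal(ss, rep((1000 / 8) / 10, 3), tolerance = 1e-9)
})

test_that("steady-state AUC over one interval equals Dose/CL", {
  for (p in list(pk_params(10, 20), pk_params(8, 15, q = 12, v2 = 30))) {
    reg <- dose_event(1000, 0, 1, 8)
    tt <- seq(0, 8, length.out = 4001)
    ss <- steady_state_profile(p, reg, pmin(tt, 8 - 1e-12))
    auc <- sum((ss[-1] + ss[-length(ss)]) / 2 * diff(tt))
    expect_equal(auc, 1000 / p$cl, tolerance = 1e-4)
  }
})

test_that("PRED ignores observed concentrations; IPRED is self-consistent", {
  m <- get_model("li")
  pat <- make_patient()
  pred1 <- predict_concentrations(m, pat)
  pat2 <- pat
  pat2$obs$conc <- pat2$obs$conc * 100
  expect_identical(predict_concentrations(m, pat2), pred1)
  eta <- c(cl = 0.3, v1 = -0.2)
  sim <- simulate_patient_obs(m, pat, eta, prop_sd = 0)
  expect_equal(predict_concentrations(m, sim, eta), sim$obs$conc)
})

test_that("2-CMT prediction with irregular dosing matches the ODE oracle", {
  skip_if_not_installed("deSolve")
  m <- get_model("li")
  cov <- make_covariates()
  doses <- dose_event(c(1000, 500, 2000), c(0, 7, 18), c(1, 0.5, 2))
  pat <- new_patient(1, cov, doses,
                     data.frame(time = c(6, 12, 24, 30), conc = 1,
                                bql = FALSE))
  params <- compute_individual_parameters(m, cov)
  closed <- predict_concentrations(m, pat)
  ode <- ode_oracle(params, doses, pat$obs$time)
  expect_equal(closed, ode, tolerance = 1e-6)
})

test_that("parameter validation rejects impossible values", {
  expect_error(pk_params(-1, 20), "positive")
  expect_error(pk_params(10, 0), "positive")
  expect_error(pk_params(10, 20, q = 5), "v2")
  expect_error(dose_event(0, 0, 1), "positive")
  expect_error(dose_event(1000, 0, 0), "positive")
})
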