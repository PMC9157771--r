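test_that("registry holds 14 models split 4 mixed / 6 non-CRRT / 4 CRRT", {
  reg <- load_model_registry()
  expect_length(reg, 14)
  expect_length(list_models("mixed", reg), 4)
  expect_length(list_models("non_crrt", reg), 6)
  expect_length(list_models("crrt", reg), 4)
  expect_identical(names(reg), sort(names(reg)))
  expect_error(list_models("dialysis", reg), "unknown population class")
})

test_that("every model validates: omega PSD, provenance flags complete", {
  for (m in list_models()) {
    ev <- eigen(m$omega, symmetric = TRUE, only.values = TRUE)$values
    expect_true(all(ev >= -1e-12), label = paste(m$model_id, "omega PSD"))
    expect_setequal(names(m$theta_provenance), names(m$thetas))
    expect_true(all(unlist(m$theta_provenance) %in%
                    c("printed", "original_publication", "placeholder")))
    expect_true(m$sigma$kind %in% c("proportional", "additive", "combined"))
  }
})

test_that("printed typical values reproduce at reference covariates, eta = 0", {
  for (m in list_models()) {
    typ <- m$reference$typical
    if (is.null(typ) || !length(typ)) next
    p <- compute_individual_parameters(m, reference_covariates(m))
    if (!is.null(typ$cl)) expect_equal(p$cl, typ$cl, tolerance = 1e-12,
                                       label = paste(m$model_id, "CL"))
    if (!is.null(typ$v1)) expect_equal(p$v1, typ$v1, tolerance = 1e-12,
                                       label = paste(m$model_id, "V1"))
    if (!is.null(typ$k10)) expect_equal(p$cl / p$v1, typ$k10,
                                        tolerance = 1e-12,
                                        label = paste(m$model_id, "K10"))
  }
})

test_that("Muro clearance follows the inverse modified-creatinine formula", {
  m <- get_model("muro")
  cov14 <- make_covariates(scr = 1.4 * 88.4)
  expect_equal(compute_individual_parameters(m, cov14)$cl, 5.55)
  # below the floor, mSCR is held at 0.4 mg/dL
  cov_low <- make_covariates(scr = 0.2 * 88.4)
  expect_equal(compute_individual_parameters(m, cov_low)$cl,
               11.1 * (0.4 / 0.7)^-1)
})

test_that("random effects act exponentially: eta_CL = log 2 doubles CL", {
  for (m in list_models()) {
    if (!"cl" %in% names(m$iiv_cv)) next
    cov <- make_covariates()
    base <- compute_individual_parameters(m, cov)
    doubled <- compute_individual_parameters(m, cov, c(cl = log(2)))
    expect_equal(doubled$cl, 2 * base$cl, tolerance = 1e-12,
                 label = paste(m$model_id, "CL doubling"))
  }
  # Crandon's IIV sits on V1; CL = K10 x V1 inherits it
  cr <- get_model("crandon")
  cov <- make_covariates()
  base <- compute_individual_parameters(cr, cov)
  up <- compute_individual_parameters(cr, cov, c(v1 = log(2)))
  expect_equal(up$v1, 2 * base$v1)
  expect_equal(up$cl, 2 * base$cl)
})

test_that("all formulas give positive CL and V across generator covariate ranges", {
  set.seed(41)
  for (i in 1:200) {
    cov <- make_covariates(
      age = runif(1, 22, 89), sex = sample(c("male", "female"), 1),
      weight = runif(1, 40, 84), height = runif(1, 148, 175),
      albumin = runif(1, 16.7, 54), scr = runif(1, 24, 1145),
      crrt = runif(1) < 0.34, residual_diuresis = runif(1, 10, 6000),
      sepsis = runif(1) < 0.5, crrt_flow = runif(1, 1.5, 3.5))
    for (m in list_models()) {
      p <- compute_individual_parameters(m, cov)
      expect_gt(p$cl, 0, label = paste(m$model_id, "CL"))
      expect_gt(p$v1, 0, label = paste(m$model_id, "V1"))
      if (!is.null(p$q)) {
        expect_gt(p$q, 0)
        expect_gt(p$v2, 0)
      }
    }
  }
})

test_that("Li clearance is monotone increasing in CLcr, decreasing in age", {
  m <- get_model("li")
  cl_at <- function(clcr, age)
    compute_individual_parameters(
      m, make_covariates(clcr = clcr, age = age))$cl
  clcrs <- seq(10, 200, by = 10)
  cls <- vapply(clcrs, cl_at, 0, age = 50)
  expect_true(all(diff(cls) > 0))
  ages <- seq(25, 85, by = 5)
  cls_age <- vapply(ages, function(a) cl_at(80, a), 0)
  expect_true(all(diff(cls_age) < 0))
})

test_that("missing required covariate errors with covariate and model name", {
  m <- get_model("li")
  cov <- unclass(make_covariates())
  cov$clcr <- NULL
  expect_error(compute_individual_parameters(m, cov), "li.*clcr")
  expect_error(compute_individual_parameters(m, make_covariates(),
                                             c(bogus = 1)), "eta")
})

test_that("scaling typical parameters by eta agrees with direct computation", {
  set.seed(77)
  for (m in list_models()) {
    cov <- make_covariates(scr = runif(1, 40, 900), crrt = runif(1) < 0.5)
    nm <- rownames(m$omega)
    eta <- setNames(rnorm(length(nm), 0, 0.4), nm)
    direct <- compute_individual_parameters(m, cov, eta)
    scaled <- meroeval:::.scale_params(
      compute_individual_parameters(m, cov), eta, m$parametrization)
    expect_equal(scaled, direct, tolerance = 1e-12, label = m$model_id)
  }
})

test_that("registry round-trips through its YAML serialization", {
  reg <- load_model_registry()
  tmp <- withr::local_tempdir()
  write_model_registry(reg, tmp)
  reg2 <- load_model_registry(tmp)
  expect_identical(names(reg2), names(reg))
  for (id in names(reg)) expect_equal(reg2[[id]], reg[[id]])
})

test_that("cv dialects map CV% to omega as documented", {
  reg_ln <- load_model_registry(cv_dialect = "lognormal")
  reg_d <- load_model_registry(cv_dialect = "direct")
  cv <- 52.1 / 100
  expect_equal(reg_ln$muro$omega["cl", "cl"], log(1 + cv^2))
  expect_equal(reg_d$muro$omega["cl", "cl"], cv^2)
})
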