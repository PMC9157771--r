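#' @importFrom stats median quantile rnorm runif setNames optim qnorm pnorm
#'   t.test shapiro.test pchisq sd cor rbinom approx
#' @importFrom utils read.csv write.csv
NULL

.registry_env <- new.env(parent = emptyenv())

#' Load the meropenem model registry
#'
#' Reads the 14 published population-PK model definitions from their YAML
#' serialization (one document per model, shipped under
#' `inst/extdata/models/`), converts the printed interindividual-variability
#' CV% into log-normal variances and validates each specification.
#'
#' @param path Directory of model YAML files. Defaults to the copies shipped
#'   with the package.
#' @param cv_dialect How printed IIV CV% map to the log-normal variance
#'   omega^2: `"lognormal"` (default) uses omega^2 = log(1 + CV^2);
#'   `"direct"` uses omega = CV.
#' @return Named list of `model_spec` objects, ordered by model id.
#' @export
load_model_registry <- function(path = system.file("extdata", "models",
                                                   package = "meroeval"),
                                cv_dialect = c("lognormal", "direct")) {
  cv_dialect <- match.arg(cv_dialect)
  files <- sort(list.files(path, pattern = "\\.ya?ml$", full.names = TRUE))
  if (length(files) == 0L) stop("no model definitions found in ", path)
  models <- lapply(files, function(f) {
    spec <- yaml::read_yaml(f)
    as_model_spec(spec, cv_dialect = cv_dialect)
  })
  names(models) <- vapply(models, `[[`, "", "model_id")
  models[order(names(models))]
}

#' @rdname load_model_registry
#' @param spec A raw list with the fields of a model definition.
#' @export
as_model_spec <- function(spec, cv_dialect = c("lognormal", "direct")) {
  cv_dialect <- match.arg(cv_dialect)
  needed <- c("model_id", "population_class", "n_compartments",
              "parametrization", "thetas", "theta_provenance", "iiv_cv",
              "sigma")
  missing <- setdiff(needed, names(spec))
  if (length(missing))
    stop("model definition missing fields: ", paste(missing, collapse = ", "))
  if (!spec$population_class %in% c("mixed", "non_crrt", "crrt"))
    stop("unknown population_class: ", spec$population_class)
  if (!spec$n_compartments %in% c(1L, 2L))
    stop("n_compartments must be 1 or 2")
  if (!spec$sigma$kind %in% c("proportional", "additive", "combined"))
    stop("unknown residual-error kind: ", spec$sigma$kind)
  prov <- unlist(spec$theta_provenance)
  if (!setequal(names(prov), names(spec$thetas)))
    stop("theta_provenance must cover exactly the thetas (", spec$model_id, ")")
  if (!all(prov %in% c("printed", "original_publication", "placeholder")))
    stop("invalid provenance flag in ", spec$model_id)
  if (is.null(.pk_formulas[[spec$model_id]]))
    stop("no covariate formula registered for model '", spec$model_id, "'")
  spec$omega <- build_omega(spec$iiv_cv, cv_dialect)
  spec$cv_dialect <- cv_dialect
  structure(spec, class = "model_spec")
}

# CV% -> diagonal log-normal variance-covariance of eta. Off-diagonals are
# zero: only variances are printed.
build_omega <- function(iiv_cv, cv_dialect = "lognormal") {
  cv <- unlist(iiv_cv) / 100
  w2 <- if (cv_dialect == "lognormal") log(1 + cv^2) else cv^2
  diag(w2, nrow = length(w2)) |>
    `dimnames<-`(list(names(iiv_cv), names(iiv_cv)))
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> %s (%s), %dCMT, IIV on: %s\n", x$model_id,
              x$population_class, x$n_compartments,
              paste(names(x$iiv_cv), collapse = ", ")))
  invisible(x)
}

#' List registered models
#'
#' @param filter Optional population class: `"mixed"`, `"non_crrt"` or
#'   `"crrt"`.
#' @param registry A registry as returned by [load_model_registry()]; the
#'   shipped registry is loaded (and cached) when omitted.
#' @return List of `model_spec`, stable-ordered by model id.
#' @export
list_models <- function(filter = NULL, registry = NULL) {
  if (is.null(registry)) {
    if (is.null(.registry_env$models))
      .registry_env$models <- load_model_registry()
    registry <- .registry_env$models
  }
  if (is.null(filter)) return(registry)
  if (!filter %in% c("mixed", "non_crrt", "crrt"))
    stop("unknown population class filter: '", filter,
         "' (use mixed, non_crrt or crrt)")
  Filter(function(m) m$population_class == filter, registry)
}

#' Get one registered model by id
#' @param model_id Short model name, e.g. `"muro"`.
#' @inheritParams list_models
#' @export
get_model <- function(model_id, registry = NULL) {
  models <- list_models(registry = registry)
  if (!model_id %in% names(models))
    stop("unknown model id: ", model_id)
  models[[model_id]]
}

#' Serialize a registry back to YAML
#'
#' Writes one YAML document per model into `path`; reading the directory back
#' with [load_model_registry()] reproduces the registry.
#'
#' @param models Named list of `model_spec`.
#' @param path Output directory (created if absent).
#' @export
write_model_registry <- function(models, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  for (m in models) {
    out <- unclass(m)
    out$omega <- NULL
    out$cv_dialect <- NULL
    yaml::write_yaml(out, file.path(path, paste0(m$model_id, ".yaml")))
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# Covariate formulas: one function per model, mapping (covariate list, thetas)
# to typical-value parameters. Serum creatinine arrives in umol/L; formulas
# written on mg/dL convert via 88.4.

.scr_mgdl <- function(cov) cov$scr / 88.4

.need_cov <- function(cov, fields, model_id) {
  for (f in fields)
    if (is.null(cov[[f]]) || (is.numeric(cov[[f]]) && is.na(cov[[f]])))
      stop("model '", model_id, "' requires covariate '", f, "'")
}

.pk_formulas <- list(
  muro = function(cov, th) {
    mscr <- modified_scr(.scr_mgdl(cov))
    list(cl = th$cl * (mscr / th$mscr_ref)^-1, v1 = th$v1)
  },
  li = function(cov, th) {
    list(cl = th$cl * (cov$clcr / 83)^th$clcr_exp * (cov$age / 35)^th$age_exp,
         v1 = th$v1 * (cov$weight / 70)^th$wt_exp,
         q = th$q, v2 = th$v2)
  },
  ulldemolins = function(cov, th) {
    list(cl = th$cl + th$diuresis_slope * (cov$residual_diuresis / 100),
         v1 = th$v1 * (cov$weight / 73)^th$wt_exp)
  },
  ehmann = function(cov, th) {
    clcr <- min(cov$clcr, th$clcr_inflection)
    alb_gdl <- cov$albumin / 10
    list(cl = th$cl * (1 + th$clcr_slope * (clcr - th$clcr_ref)),
         v1 = th$v1 * (cov$weight / 70)^th$wt_exp,
         q = th$q,
         v2 = th$v2 * (1 - th$alb_slope * (alb_gdl - th$alb_ref)))
  },
  dhaese = function(cov, th) {
    list(cl = th$cl * (cov$clcr / th$clcr_ref), v1 = th$v1)
  },
  crandon = function(cov, th) {
    adjbw <- adjusted_body_weight(cov$weight, cov$height, cov$sex)
    list(k10 = th$k10_intercept + th$k10_slope * cov$clcr,
         v1 = adjbw * th$v1_per_kg,
         k12 = th$k12, k21 = th$k21)
  },
  roberts = function(cov, th) {
    list(cl = th$cl_slope * cov$clcr, v1 = th$v1, q = th$q, v2 = th$v2)
  },
  burger = function(cov, th) {
    cl <- if (isTRUE(cov$crrt)) th$cl_res + th$sieving * cov$crrt_flow
          else th$cl_nocrrt * (1 + th$clcr_slope * (cov$clcr - th$median_clcr))
    list(cl = cl, v1 = th$vc_coef * (cov$weight / th$median_bw),
         q = th$q, v2 = th$v2)
  },
  jaruratanasirikul = function(cov, th) {
    mdrd <- mdrd_clcr(cov$age, cov$scr, cov$sex)
    list(cl = th$cl_intercept + th$cl_slope * mdrd, v1 = th$v1)
  },
  padulles = function(cov, th) {
    list(cl = th$fr_slope * cov$crrt_flow, v1 = th$v1, q = th$q, v2 = th$v2)
  },
  mattioli = function(cov, th) {
    list(cl = th$cl * (1 + th$sepsis_effect * as.numeric(isTRUE(cov$sepsis))) *
               (1 + th$male_effect * as.numeric(cov$sex == "male")),
         v1 = th$v1 * (cov$albumin / th$alb_ref)^th$alb_exp *
              (cov$age / th$age_ref)^th$age_exp)
  },
  onichimowski = function(cov, th) {
    list(cl = th$cl, v1 = th$v1 * (cov$albumin / th$alb_ref)^th$alb_exp,
         q = th$q, v2 = th$v2)
  },
  grensemann = function(cov, th) {
    list(cl = th$cl, v1 = th$v1, q = th$q, v2 = th$v2)
  },
  sjovall = function(cov, th) {
    list(cl = th$tvcl * (2 + cov$clcr * th$clcr_slope),
         v1 = th$v1, q = th$q, v2 = th$v2)
  }
)

.formula_covariates <- list(
  muro = "scr", li = c("clcr", "age", "weight"),
  ulldemolins = c("residual_diuresis", "weight"),
  ehmann = c("clcr", "weight", "albumin"), dhaese = "clcr",
  crandon = c("clcr", "weight", "height", "sex"), roberts = "clcr",
  burger = c("crrt", "crrt_flow", "clcr", "weight"),
  jaruratanasirikul = c("age", "scr", "sex"), padulles = "crrt_flow",
  mattioli = c("sepsis", "sex", "albumin", "age"),
  onichimowski = "albumin", grensemann = character(), sjovall = "clcr"
)

#' Individual PK parameters for one subject
#'
#' Evaluates a model's covariate formulas at a subject's covariates and
#' applies the random effects exponentially (`P_i = TVP * exp(eta)`).
#' Micro-constant models (Crandon's K10/V1 form) are converted to the
#' clearance/volume parametrization after the random effects are applied, so
#' a V1 random effect propagates into CL = K10 x V1.
#'
#' @param model A `model_spec`.
#' @param cov A `covariate_record` (or compatible named list).
#' @param eta Named numeric random-effect vector on the log scale; names must
#'   be a subset of the model's IIV parameters (`cl`, `v1`). `NULL` or an
#'   empty vector means the typical subject (eta = 0).
#' @return A [pk_params()] object.
#' @export
compute_individual_parameters <- function(model, cov, eta = NULL) {
  stopifnot(inherits(model, "model_spec"))
  .need_cov(cov, .formula_covariates[[model$model_id]], model$model_id)
  if (is.null(eta)) eta <- numeric(0)
  iiv_names <- names(model$iiv_cv)
  if (length(eta)) {
    if (is.null(names(eta)) || !all(names(eta) %in% iiv_names))
      stop("eta names must match the model's IIV parameters (",
           paste(iiv_names, collapse = ", "), ") for model ", model$model_id)
  }
  p <- .pk_formulas[[model$model_id]](cov, model$thetas)
  e <- function(nm) if (nm %in% names(eta)) exp(eta[[nm]]) else 1
  if (model$parametrization == "micro") {
    p$v1 <- p$v1 * e("v1")
    p$k10 <- p$k10 * e("cl")
    pk_params(cl = p$k10 * p$v1, v1 = p$v1,
              q = p$k12 * p$v1, v2 = p$k12 * p$v1 / p$k21)
  } else {
    pk_params(cl = p$cl * e("cl"), v1 = p$v1 * e("v1"),
              q = p$q, v2 = p$v2)
  }
}

# Apply an eta vector to already-computed typical parameters. For the
# clearance/volume form, eta acts on its own parameter; for the
# micro-constant form (IIV on V1 with fixed rate constants), CL, V1, Q and
# V2 all scale with exp(eta_v1). Must agree with
# compute_individual_parameters().
.scale_params <- function(params, eta, parametrization) {
  e <- function(x) if (x %in% names(eta)) exp(eta[[x]]) else 1
  if (parametrization == "micro") {
    s <- e("v1")
    pk_params(cl = params$cl * s * e("cl"), v1 = params$v1 * s,
              q = if (!is.null(params$q)) params$q * s,
              v2 = if (!is.null(params$v2)) params$v2 * s)
  } else {
    pk_params(cl = params$cl * e("cl"), v1 = params$v1 * e("v1"),
              q = params$q, v2 = params$v2)
  }
}

#' Reference covariate record for a model's printed typical values
#'
#' Builds a covariate record at the reference covariates stored in the
#' registry (where the source table prints both formula and typical value),
#' defaulting unspecified covariates to a typical ICU subject.
#'
#' @param model A `model_spec`.
#' @return A covariate list usable by [compute_individual_parameters()].
#' @export
reference_covariates <- function(model) {
  ref <- model$reference$covariates
  cov <- list(age = 58, sex = "male", weight = 70, height = 166,
              albumin = 27.9, scr = 0.7 * 88.4, crrt = FALSE,
              residual_diuresis = 2000, sepsis = FALSE, crrt_flow = 2)
  cov$clcr <- cockcroft_gault(cov$age, cov$weight, cov$scr, cov$sex)
  for (nm in names(ref)) {
    if (nm == "mscr") cov$scr <- ref[[nm]] * 88.4
    else cov[[nm]] <- ref[[nm]]
  }
  cov
}
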