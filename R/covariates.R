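#' Cockcroft-Gault creatinine clearance
#'
#' Estimates creatinine clearance (ml/min) from age, body weight, serum
#' creatinine and sex. Serum creatinine is supplied in umol/L and converted
#' internally to mg/dL (88.4 umol/L per mg/dL).
#'
#' @param age Age in years.
#' @param weight Body weight in kg.
#' @param scr Serum creatinine in umol/L.
#' @param sex `"male"` or `"female"`.
#' @return Creatinine clearance in ml/min.
#' @examples
#' cockcroft_gault(40, 72, 88.4, "male")   # 100 ml/min
#' @export
cockcroft_gault <- function(age, weight, scr, sex) {
  sex <- match.arg(sex, c("male", "female"))
  if (any(scr <= 0)) stop("serum creatinine must be positive")
  if (any(age <= 0) || any(weight <= 0)) stop("age and weight must be positive")
  scr_mgdl <- scr / 88.4
  clcr <- (140 - age) * weight / (72 * scr_mgdl)
  if (sex == "female") clcr <- clcr * 0.85
  clcr
}

#' Four-variable MDRD estimated creatinine clearance
#'
#' Standard MDRD eGFR (ml/min/1.73 m^2), used by models whose clearance
#' covariate is the MDRD-estimated creatinine clearance rather than
#' Cockcroft-Gault.
#'
#' @inheritParams cockcroft_gault
#' @return Estimated GFR in ml/min/1.73 m^2.
#' @export
mdrd_clcr <- function(age, scr, sex) {
  sex <- match.arg(sex, c("male", "female"))
  if (any(scr <= 0)) stop("serum creatinine must be positive")
  scr_mgdl <- scr / 88.4
  egfr <- 175 * scr_mgdl^-1.154 * age^-0.203
  if (sex == "female") egfr <- egfr * 0.742
  egfr
}

#' Modified serum creatinine with a lower floor
#'
#' Very low serum creatinine in ICU patients (muscle wasting) overstates renal
#' function; the Muro model therefore floors serum creatinine at 0.4 mg/dL
#' before it enters the clearance formula.
#'
#' @param scr_mgdl Serum creatinine in mg/dL.
#' @param floor Floor value, default 0.4 mg/dL.
#' @return `max(scr_mgdl, floor)`.
#' @export
modified_scr <- function(scr_mgdl, floor = 0.4) {
  if (any(scr_mgdl <= 0)) stop("serum creatinine must be positive")
  pmax(scr_mgdl, floor)
}

#' Adjusted body weight
#'
#' Devine ideal body weight plus 40% of the excess of total over ideal weight;
#' returns total body weight when below ideal.
#'
#' @param weight Total body weight in kg.
#' @param height Height in cm.
#' @param sex `"male"` or `"female"`.
#' @return Adjusted body weight in kg.
#' @export
adjusted_body_weight <- function(weight, height, sex) {
  sex <- match.arg(sex, c("male", "female"))
  inches_over_5ft <- pmax(height / 2.54 - 60, 0)
  ibw <- (if (sex == "male") 50 else 45.5) + 2.3 * inches_over_5ft
  ifelse(weight > ibw, ibw + 0.4 * (weight - ibw), weight)
}

#' Construct a patient covariate record
#'
#' Bundles the covariates required by the registered meropenem models. CLcr
#' (Cockcroft-Gault) is derived from age/weight/creatinine/sex when not
#' supplied.
#'
#' @param age Years (>= 18).
#' @param sex `"male"` or `"female"`.
#' @param weight kg.
#' @param height cm.
#' @param albumin Serum albumin, g/L.
#' @param scr Serum creatinine, umol/L.
#' @param clcr Creatinine clearance ml/min; derived via [cockcroft_gault()]
#'   when `NULL`.
#' @param crrt Logical, on continuous renal replacement therapy.
#' @param residual_diuresis Urine output, ml/day.
#' @param sepsis Logical.
#' @param crrt_flow Filtrate-dialysate flow, L/h (CRRT machine setting).
#' @return A list of class `covariate_record`.
#' @export
covariate_record <- function(age, sex, weight, height, albumin, scr,
                             clcr = NULL, crrt = FALSE,
                             residual_diuresis = 2000, sepsis = FALSE,
                             crrt_flow = 2) {
  sex <- match.arg(sex, c("male", "female"))
  if (age < 18) stop("covariate_record: age must be >= 18 (adult ICU cohort)")
  for (nm in c("weight", "height", "albumin", "scr", "residual_diuresis",
               "crrt_flow")) {
    v <- get(nm)
    if (!is.numeric(v) || v <= 0) stop("covariate_record: ", nm, " must be strictly positive")
  }
  if (is.null(clcr)) clcr <- cockcroft_gault(age, weight, scr, sex)
  structure(list(age = age, sex = sex, weight = weight, height = height,
                 albumin = albumin, scr = scr, clcr = clcr,
                 crrt = isTRUE(crrt), residual_diuresis = residual_diuresis,
                 sepsis = isTRUE(sepsis), crrt_flow = crrt_flow),
            class = "covariate_record")
}
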