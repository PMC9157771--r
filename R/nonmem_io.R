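#' Write a cohort as a NONMEM-style rectangular dataset
#'
#' One row per dosing event (`EVID = 1`, with `AMT`, `RATE`, `DUR`) and per
#' observation (`EVID = 0`, `DV`, `MDV = 0`); covariates repeated on every
#' row. `DV = 0` with `MDV = 1` means missing.
#'
#' @param patients A `pk_cohort` or list of `pk_patient`.
#' @param path CSV output path (written only when non-NULL).
#' @return The data.frame, invisibly when written to file.
#' @export
write_nonmem <- function(patients, path = NULL) {
  rows <- lapply(patients, function(p) {
    cov <- p$covariates
    covdf <- data.frame(AGE = cov$age, SEX = as.integer(cov$sex == "female"),
                        WT = cov$weight, HT = cov$height, ALB = cov$albumin,
                        SCR = cov$scr, CLCR = cov$clcr,
                        CRRT = as.integer(cov$crrt),
                        DIUR = cov$residual_diuresis,
                        SEPSIS = as.integer(cov$sepsis),
                        CRRTFLOW = cov$crrt_flow)
    dose_rows <- data.frame(ID = p$id, TIME = p$doses$start_time,
                            AMT = p$doses$amount,
                            RATE = p$doses$amount / p$doses$duration,
                            DUR = p$doses$duration,
                            DV = 0, EVID = 1, MDV = 1)
    obs_rows <- data.frame(ID = p$id, TIME = p$obs$time, AMT = 0, RATE = 0,
                           DUR = 0, DV = p$obs$conc, EVID = 0, MDV = 0)
    out <- rbind(dose_rows, obs_rows)
    out <- out[order(out$TIME, -out$EVID), ]
    cbind(out, covdf[rep(1, nrow(out)), , drop = FALSE])
  })
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  if (!is.null(path)) {
    write.csv(df, path, row.names = FALSE, quote = FALSE)
    return(invisible(df))
  }
  df
}

#' Read a NONMEM-style dataset into patients
#'
#' @param path CSV path or a data.frame in the layout written by
#'   [write_nonmem()].
#' @return List of `pk_patient` (class `pk_cohort`).
#' @export
read_nonmem <- function(path) {
  df <- if (is.data.frame(path)) path else read.csv(path)
  needed <- c("ID", "TIME", "AMT", "DUR", "DV", "EVID", "MDV")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop("dataset lacks columns: ", paste(missing, collapse = ", "))
  patients <- lapply(split(df, df$ID), function(d) {
    d <- d[order(d$TIME, -d$EVID), ]
    first <- d[1, ]
    rec <- covariate_record(
      age = first$AGE, sex = if (first$SEX == 1) "female" else "male",
      weight = first$WT, height = first$HT, albumin = first$ALB,
      scr = first$SCR, clcr = if (is.null(first$CLCR)) NULL else first$CLCR,
      crrt = first$CRRT == 1, residual_diuresis = first$DIUR,
      sepsis = first$SEPSIS == 1, crrt_flow = first$CRRTFLOW)
    dd <- d[d$EVID == 1, ]
    doses <- dose_event(dd$AMT, dd$TIME, dd$DUR)
    oo <- d[d$EVID == 0 & d$MDV == 0, ]
    new_patient(id = first$ID, covariates = rec, doses = doses,
                obs = data.frame(time = oo$TIME, conc = oo$DV, bql = FALSE))
  })
  structure(unname(patients[order(as.numeric(names(patients)))]),
            class = "pk_cohort")
}
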