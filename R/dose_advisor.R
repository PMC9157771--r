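#' Classify a concentration against the therapeutic window
#'
#' Meropenem target window 8-45 mg/L (100% fT > 4xMIC for MIC 2 mg/L at the
#' lower end, toxicity ceiling at the top). Below the window the dose should
#' be increased, inside maintained (bounds inclusive), above decreased.
#'
#' @param conc Concentration(s), mg/L, non-negative.
#' @param low,high Target bounds, mg/L.
#' @return Factor with levels `increase`, `maintain`, `decrease`.
#' @export
classify_dose <- function(conc, low = 8, high = 45) {
  if (any(conc < 0)) stop("concentration must be non-negative")
  factor(ifelse(conc < low, "increase",
                ifelse(conc <= high, "maintain", "decrease")),
         levels = c("increase", "maintain", "decrease"))
}

#' Dose-adaptation agreement between predicted and observed concentrations
#'
#' Classifies both concentration vectors into increase/maintain/decrease and
#' counts, per observed category, how many predicted categories agree.
#' Accuracy is the percentage of concordant recommendations.
#'
#' @param predicted_conc,observed_conc Equal-length concentration vectors,
#'   mg/L.
#' @inheritParams classify_dose
#' @return List of class `adaptation_table` with a `counts` data.frame
#'   (per-category yes/no), `n` and `accuracy` (%).
#' @export
adaptation_accuracy <- function(predicted_conc, observed_conc,
                                low = 8, high = 45) {
  if (length(predicted_conc) != length(observed_conc))
    stop("predicted and observed lengths differ")
  pred <- classify_dose(predicted_conc, low, high)
  obs <- classify_dose(observed_conc, low, high)
  adaptation_table_from_counts(
    correct = vapply(levels(obs), function(l) sum(obs == l & pred == l), 0L),
    observed_n = vapply(levels(obs), function(l) sum(obs == l), 0L))
}

#' @rdname adaptation_accuracy
#' @param correct Correctly predicted counts per observed category
#'   (increase, maintain, decrease).
#' @param observed_n Total observed counts per category.
#' @export
adaptation_table_from_counts <- function(correct, observed_n) {
  if (length(correct) != length(observed_n))
    stop("correct and observed_n lengths differ")
  if (any(correct > observed_n)) stop("correct counts exceed category totals")
  n <- sum(observed_n)
  if (n == 0) stop("empty adaptation table")
  counts <- data.frame(category = c("increase", "maintain", "decrease")[
                         seq_along(correct)],
                       yes = as.integer(correct),
                       no = as.integer(observed_n - correct))
  structure(list(counts = counts, n = n,
                 accuracy = 100 * sum(correct) / n),
            class = "adaptation_table")
}

#' @export
print.adaptation_table <- function(x, ...) {
  print(x$counts)
  cat(sprintf("accuracy: %.2f%% (n=%d)\n", x$accuracy, x$n))
  invisible(x)
}
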