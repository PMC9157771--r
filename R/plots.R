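#' Box plot of prediction errors per model
#'
#' @param prediction_pe data.frame with columns `model_id` and `pe`.
#' @return A ggplot object with reference lines at 0 and +/-30%.
#' @export
plot_pe_boxplot <- function(prediction_pe) {
  ggplot2::ggplot(prediction_pe,
                  ggplot2::aes(x = .data$model_id, y = .data$pe)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = c(-30, 30), linetype = "dotted") +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::labs(x = NULL, y = "PE (%)") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Prediction-corrected VPC plot
#'
#' Observed percentiles (lines/points) over the shaded simulated 90%
#' confidence bands, per time-after-dose bin.
#'
#' @param vpc A `vpc_result` from [pcvpc()].
#' @export
plot_vpc <- function(vpc) {
  d <- vpc$table
  d$pctl <- factor(paste0("p", d$pctl))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$t_mid, group = .data$pctl)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$band_lo,
                                      ymax = .data$band_hi),
                         fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$observed,
                                    linetype = .data$pctl)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed), size = 1) +
    ggplot2::labs(x = "Time after dose (h)",
                  y = "Prediction-corrected concentration (mg/L)") +
    ggplot2::theme_bw()
}

#' NPDE histogram and QQ panels
#'
#' @param npde_result An `npde_result`.
#' @export
plot_npde <- function(npde_result) {
  d <- data.frame(npde = npde_result$npde)
  ggplot2::ggplot(d, ggplot2::aes(sample = .data$npde)) +
    ggplot2::stat_qq(size = 0.8) +
    ggplot2::stat_qq_line(linetype = "dashed") +
    ggplot2::labs(x = "Theoretical N(0,1) quantiles", y = "NPDE") +
    ggplot2::theme_bw()
}

#' EBE density against the theoretical prior
#'
#' @param ebe An `ebe_adequacy` result.
#' @param parameter Which random effect to plot (default `"cl"`).
#' @export
plot_ebe_density <- function(ebe, parameter = "cl") {
  x <- ebe$ebe[, parameter]
  s <- ebe$summary[ebe$summary$parameter == parameter, ]
  grid <- seq(min(x, -3 * s$omega_sd), max(x, 3 * s$omega_sd),
              length.out = 200)
  theo <- data.frame(eta = grid, dens = stats::dnorm(grid, 0, s$omega_sd))
  ggplot2::ggplot(data.frame(eta = x), ggplot2::aes(x = .data$eta)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = 25, fill = "grey80", colour = "grey40") +
    ggplot2::geom_line(data = theo,
                       ggplot2::aes(x = .data$eta, y = .data$dens),
                       colour = "purple") +
    ggplot2::geom_vline(xintercept = c(s$est_p20, s$est_p80),
                        colour = "blue", linetype = "dashed") +
    ggplot2::geom_vline(xintercept = c(s$theo_p20, s$theo_p80),
                        colour = "purple", linetype = "dashed") +
    ggplot2::labs(x = sprintf("eta(%s), model %s", parameter, ebe$model_id),
                  y = "density") +
    ggplot2::theme_bw()
}

#' Predicted trough box plots with the target band
#'
#' @param trough_df data.frame with columns `model_id`, `method`, `conc`.
#' @param low,high Target window, mg/L.
#' @export
plot_trough_boxplot <- function(trough_df, low = 8, high = 45) {
  ggplot2::ggplot(trough_df,
                  ggplot2::aes(x = .data$model_id, y = .data$conc,
                               fill = .data$method)) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf, ymin = low,
                      ymax = high, alpha = 0.15, fill = "black") +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::scale_y_log10() +
    ggplot2::scale_fill_manual(values = c(a_priori = "white",
                                          bayesian = "lightblue")) +
    ggplot2::labs(x = NULL, y = "Predicted concentration (mg/L)") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @importFrom ggplot2 .data
NULL
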