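#' Histogram of simulated concordance scores
#'
#' Score distribution of a simulation run: uniform under two distinct
#' causal variants (H0), right-skewed with mass near 1 under a shared
#' causal variant (H1).
#'
#' @param object an `rtc_simulation` tibble from [run_rtc_simulation()].
#' @param bins histogram bins (default 20).
#' @param ... unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.rtc_simulation <- function(object, bins = 20, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$rtc)) +
    ggplot2::geom_histogram(bins = bins, boundary = 0,
                            fill = "grey35", colour = "white") +
    ggplot2::facet_wrap(~hypothesis) +
    ggplot2::labs(x = "RTC score", y = "scenarios") +
    ggplot2::theme_minimal()
}

#' Score against an LD metric in simulation output
#'
#' Scatter of the concordance score against the pairwise LD between the
#' observed eQTL and disease SNP (`r2` or `dprime`), or against the
#' interval's overall LD (`median_r2`).
#'
#' @param sim an `rtc_simulation` tibble.
#' @param metric `"r2"`, `"dprime"`, or `"median_r2"`.
#' @return A ggplot object.
#' @export
plot_score_vs_ld <- function(sim, metric = c("r2", "dprime", "median_r2")) {
  metric <- match.arg(metric)
  xcol <- switch(metric, r2 = "r2_eqtl_dsnp", dprime = "dprime_eqtl_dsnp",
                 median_r2 = "interval_median_r2")
  xlab <- switch(metric, r2 = expression(r^2 * " (eQTL, dSNP)"),
                 dprime = "D' (eQTL, dSNP)",
                 median_r2 = expression("interval median " * r^2))
  ggplot2::ggplot(sim, ggplot2::aes(x = .data[[xcol]], y = .data$rtc)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::facet_wrap(~hypothesis) +
    ggplot2::labs(x = xlab, y = "RTC score") +
    ggplot2::theme_minimal()
}

#' QQ plot of observed versus MAF-matched null best P-values
#'
#' @param object a `qq_curves` tibble from [qq_median_ci()].
#' @param ... unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.qq_curves <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$null_median)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$null_median,
                                      ymax = .data$ci_upper),
                         fill = "grey80") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed), size = 0.8) +
    ggplot2::labs(x = expression("expected " * -log[10](P) * " (null median)"),
                  y = expression("observed " * -log[10](P))) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
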