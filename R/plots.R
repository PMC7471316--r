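#' Plot simulated UMI saturation against the no-collision line
#'
#' Mean unique-UMI count per sampling depth (simulated), the analytic
#' expectation, and the x = y line that would hold if no UMI were ever
#' drawn twice; the gap between the curves is the expected number of
#' multiply-drawn UMIs.
#'
#' @param sim A `saturation_sim` from [simulate_saturation()].
#' @return A ggplot object.
#' @export
plot_saturation <- function(sim) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plotting requires the 'ggplot2' package")
  s <- sim$summary
  ggplot2::ggplot(s, ggplot2::aes(x = .data$n)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "red") +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean_unique), colour = "blue") +
    ggplot2::geom_point(ggplot2::aes(y = .data$mean_unique), colour = "blue") +
    ggplot2::geom_line(ggplot2::aes(y = .data$expected_unique),
                       linetype = "dashed") +
    ggplot2::labs(
      x = "molecules sampled (n)", y = "distinct UMIs observed",
      title = sprintf("UMI saturation, L = %d nt (pool %s)",
                      sim$L, format(pool_complexity(sim$L), big.mark = ","))) +
    ggplot2::theme_bw()
}

#' Plot raw versus de-duplicated counts per species
#'
#' Log-log scatter of raw read counts against de-duplicated counts with
#' the x = y line; saturated species bend away from the diagonal toward
#' the horizontal asymptote at the UMI pool size.
#'
#' @param distortion Output of [distortion_report()].
#' @param umi_len Total UMI length (for the pool-size asymptote).
#' @return A ggplot object.
#' @export
plot_distortion <- function(distortion, umi_len = 8) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plotting requires the 'ggplot2' package")
  df <- distortion[distortion$raw_reads > 0 & distortion$dedup_h0 > 0, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$raw_reads, y = .data$dedup_h0,
                                   colour = .data$saturated)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey50") +
    ggplot2::geom_hline(yintercept = pool_complexity(umi_len),
                        linetype = "dashed") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "raw reads", y = "de-duplicated count (Hamming 0)") +
    ggplot2::theme_bw()
}
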