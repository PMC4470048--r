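#' Plot kinetic-energy curves over the cardiac cycle
#'
#' One line per condition, KE (mJ) against the fraction of the cardiac
#' cycle — the standard subject-by-subject presentation.
#'
#' @param curves a `ke_curve` or named list of them.
#' @return a ggplot object.
#' @export
plot_ke_curve <- function(curves) {
  if (inherits(curves, "ke_curve")) curves <- list(KE = curves)
  df <- do.call(rbind, lapply(names(curves), function(nm) {
    k <- curves[[nm]]
    data.frame(condition = nm,
               phase = (seq_along(k$ke) - 1) / length(k$ke),
               ke = k$ke)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = phase, y = ke,
                                   colour = condition)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "fraction of cardiac cycle", y = "KE (mJ)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Bland-Altman plot
#'
#' Scatter of pairwise differences against pairwise means with the bias
#' (solid) and bias +/- 1.96 SD limits of agreement (dashed).
#'
#' @param pm a [paired_measurements()].
#' @param units axis unit label.
#' @return a ggplot object.
#' @export
plot_bland_altman <- function(pm, units = "") {
  ba <- bland_altman(pm)
  df <- data.frame(m = (pm$x + pm$y) / 2, d = pm$x - pm$y)
  ggplot2::ggplot(df, ggplot2::aes(x = m, y = d)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = ba$bias) +
    ggplot2::geom_hline(yintercept = ba$loa, linetype = "dashed") +
    ggplot2::labs(x = paste("mean", units), y = paste("difference", units)) +
    ggplot2::theme_minimal()
}

#' Scatter plot with identity line
#'
#' @param pm a [paired_measurements()].
#' @param xlab,ylab axis labels.
#' @return a ggplot object.
#' @export
plot_scatter_identity <- function(pm, xlab = "condition A",
                                  ylab = "condition B") {
  df <- data.frame(x = pm$x, y = pm$y)
  ggplot2::ggplot(df, ggplot2::aes(x = x, y = y)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::labs(x = xlab, y = ylab) +
    ggplot2::theme_minimal()
}
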