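#' Plot a parameter scan
#'
#' Total score and cluster-size SD against the correlation cutoff, one
#' panel per cluster count, colored by GTOM order. Requires ggplot2.
#'
#' @param scan A `scan_record` data frame from [parameter_scan()].
#' @param what `"total_score"` or `"size_sd"`.
#' @return A ggplot object.
#' @export
plot_scan <- function(scan, what = c("total_score", "size_sd")) {
  what <- match.arg(what)
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  ggplot2::ggplot(scan, ggplot2::aes(x = .data$cutoff, y = .data[[what]],
                                     color = factor(.data$k))) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~ n_clusters, labeller = ggplot2::label_both) +
    ggplot2::labs(color = "k", y = what) +
    ggplot2::theme_minimal()
}

#' Plot separation curves
#'
#' Group-separation score against the patient-correlation cutoff, one line
#' per TF subset. Requires ggplot2.
#'
#' @param curves One `separation_curve` or a list of them (rows are bound).
#' @return A ggplot object.
#' @export
plot_separation <- function(curves) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  if (is.list(curves) && !is.data.frame(curves))
    curves <- do.call(rbind, curves[!vapply(curves, is.null, logical(1))])
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$cutoff, y = .data$separation,
                                       color = .data$subset)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::labs(x = "patient correlation cutoff", y = "separation (within - cross)") +
    ggplot2::theme_minimal()
}
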