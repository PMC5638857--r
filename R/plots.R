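#' @method tidy identity_profile
#' @export
tidy.identity_profile <- function(x, ...) as_tibble(x)

#' Plot a sliding-window identity profile
#'
#' The familiar browser-style conservation curve: percent identity along the
#' reference, with the calling threshold drawn as a dashed line.
#'
#' @param object An `identity_profile` from [windowed_identity()].
#' @param threshold_pct Threshold line to draw (default 70).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot identity_profile
#' @export
autoplot.identity_profile <- function(object, threshold_pct = 70, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$ref_pos, y = .data$identity_pct)) +
    ggplot2::geom_area(fill = "#f4a6c6", alpha = 0.7) +
    ggplot2::geom_hline(yintercept = threshold_pct, linetype = "dashed") +
    ggplot2::coord_cartesian(ylim = c(0, 100)) +
    ggplot2::labs(x = sprintf("position on %s (bp)", object$chrom[1]),
                  y = "identity (%)",
                  title = sprintf("windowed identity (window = %d bp)",
                                  attr(object, "window"))) +
    ggplot2::theme_minimal()
}

#' Plot log2 fold change against distance from the focal element
#'
#' @param object A `de_result` from [de_analyze()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot de_result
#' @export
autoplot.de_result <- function(object, ...) {
  calls <- object$calls
  ggplot2::ggplot(calls, ggplot2::aes(x = .data$distance_bp / 1e6,
                                      y = .data$log2fc,
                                      colour = .data$category)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_hline(yintercept = c(-1, 1) * log2(object$params$fc_threshold),
                        linetype = "dotted") +
    ggplot2::labs(x = "distance from element (Mb)", y = "log2 fold change",
                  subtitle = sprintf("Pearson r = %.2f, p = %.2g",
                                     object$summary$distance_r,
                                     object$summary$distance_p)) +
    ggplot2::theme_minimal()
}

#' Plot a conservation ranking
#'
#' @param ranking Tibble from [rank_elements()].
#' @return A ggplot object.
#' @export
plot_conservation_ranking <- function(ranking) {
  ggplot2::ggplot(ranking,
                  ggplot2::aes(x = stats::reorder(.data$element_id, .data$mean_index),
                               y = .data$mean_index)) +
    ggplot2::geom_col(fill = "#4477aa") +
    ggplot2::geom_point(ggplot2::aes(y = .data$min_index), colour = "#cc3311") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "conservation index (bar: mean, point: min)") +
    ggplot2::theme_minimal()
}

#' Plot a motif map of scanner hits along a sequence
#'
#' Hits are drawn as arrowheads at their position, pointing with their
#' strand; an optional core window is shaded.
#'
#' @param hits Tibble from [iupac_scan()].
#' @param sequence_length Length of the scanned sequence.
#' @param core Optional core-window result from [find_core_window()].
#' @return A ggplot object.
#' @export
plot_motif_map <- function(hits, sequence_length, core = NULL) {
  hits$y <- as.numeric(factor(hits$motif_name))
  p <- ggplot2::ggplot(hits, ggplot2::aes(x = .data$position, y = .data$y,
                                          colour = .data$motif_name,
                                          shape = .data$strand)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::scale_shape_manual(values = c("+" = 62, "-" = 60)) +
    ggplot2::xlim(0, sequence_length) +
    ggplot2::labs(x = "position (bp)", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
  if (!is.null(core)) {
    p <- p + ggplot2::annotate("rect", xmin = core$interval$start,
                               xmax = core$interval$end, ymin = -Inf, ymax = Inf,
                               alpha = 0.15, fill = "grey40")
  }
  p
}
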