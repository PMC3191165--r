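#' Plot a banding map
#'
#' Draws the alternating band/interband tiling as colored rectangles along
#' the chromosome; band classes, when present, get their own fill.
#'
#' @param object a `banding_map`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot banding_map
#' @export
autoplot.banding_map <- function(object, ...) {
  df <- as_plain_tbl(object)
  df$fill <- ifelse(df$type == "interband", "interband",
                    if ("band_class" %in% names(df)) {
                      ifelse(is.na(df$band_class), "band", df$band_class)
                    } else "band")
  ggplot2::ggplot(df) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$start, xmax = .data$end,
                                    ymin = 0, ymax = 1, fill = .data$fill)) +
    ggplot2::scale_fill_manual(values = c(
      interband = "grey90", band = "grey40",
      IH_late = "black", faint_early = "grey60"), name = NULL) +
    ggplot2::scale_y_continuous(breaks = NULL) +
    ggplot2::labs(x = sprintf("position on %s (bp)", df$chrom[1]), y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot interband calls over their evidence panel
#'
#' Evidence features are drawn as one row per (marker, cell type) track,
#' with the called interbands as shaded vertical spans and their consensus
#' peaks as dashed lines.
#'
#' @param calls an `interband_calls` tibble.
#' @param panel the `marker_panel` they were called from.
#' @return a ggplot object.
#' @export
plot_calls <- function(calls, panel) {
  stopifnot(inherits(panel, "marker_panel"))
  feats <- tidyr::unnest(panel$tracks, "features")
  feats$track <- paste(feats$marker, feats$cell_type, sep = "/")
  p <- ggplot2::ggplot(feats)
  if (nrow(calls) > 0) {
    p <- p +
      ggplot2::geom_rect(data = tibble::as_tibble(calls),
                         ggplot2::aes(xmin = .data$start, xmax = .data$end),
                         ymin = -Inf, ymax = Inf, fill = "gold", alpha = 0.3) +
      ggplot2::geom_vline(data = tibble::as_tibble(calls),
                          ggplot2::aes(xintercept = .data$peak),
                          linetype = "dashed", linewidth = 0.3)
  }
  p +
    ggplot2::geom_segment(ggplot2::aes(x = .data$start, xend = .data$end,
                                       y = .data$track, yend = .data$track,
                                       color = .data$class),
                          linewidth = 3) +
    ggplot2::labs(x = sprintf("position on %s (bp)", panel$region$chrom),
                  y = NULL, color = "evidence class") +
    ggplot2::theme_minimal()
}
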