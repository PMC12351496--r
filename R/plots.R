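# ggplot2 visualizations of the result types

#' Volcano plot of a differential-expression table
#'
#' @param object A `de_table` from [select_de()].
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.de_table <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = log2(.data$fold_change),
                                   y = -log10(.data$p_value),
                                   colour = .data$call)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_colour_manual(values = c(up = "#c0392b",
                                            down = "#2980b9",
                                            ns = "grey60")) +
    ggplot2::geom_hline(yintercept = -log10(attr(object, "alpha")),
                        linetype = 2, linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = log2(c(attr(object, "fc_down"),
                                            attr(object, "fc_up"))),
                        linetype = 2, linewidth = 0.3) +
    ggplot2::labs(x = "log2 fold change (B / A)", y = "-log10 p",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Raster + trace overview of a calcium analysis
#'
#' dF/F0 traces (vertically offset per ROI) with detected event peaks.
#'
#' @param object A `calcium_result` from [analyze_calcium()].
#' @param max_cells Plot at most this many ROIs.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.calcium_result <- function(object, max_cells = 20, ...) {
  tr <- object$traces
  sel <- head(seq_len(ncol(tr$dff)), max_cells)
  tt <- (seq_len(nrow(tr$dff)) - 1) / tr$frame_rate_hz
  df <- purrr::map_dfr(sel, function(r)
    tibble::tibble(roi_id = tr$rois$roi_id[r], time_s = tt,
                   dff = tr$dff[, r]))
  offs <- tibble::tibble(roi_id = tr$rois$roi_id[sel],
                         offset = (seq_along(sel) - 1) * 1.0)
  df <- dplyr::left_join(df, offs, by = "roi_id")
  ev <- dplyr::semi_join(object$events, offs, by = "roi_id") |>
    dplyr::left_join(offs, by = "roi_id")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s,
                                        y = .data$dff + .data$offset,
                                        group = .data$roi_id)) +
    ggplot2::geom_line(linewidth = 0.25, colour = "grey30") +
    ggplot2::labs(x = "time (s)", y = expression(Delta * F / F[0] ~
                                                   "(offset per ROI)")) +
    ggplot2::theme_minimal()
  if (nrow(ev))
    p <- p + ggplot2::geom_point(
      data = ev, inherit.aes = FALSE,
      ggplot2::aes(x = .data$peak_time_s,
                   y = .data$amplitude + .data$offset),
      colour = "#c0392b", size = 0.8)
  p
}

#' Fragment length distribution of a skeleton analysis
#'
#' @param object A `skeleton_stats` from [fragment_stats()].
#' @param binwidth_um Histogram bin width.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.skeleton_stats <- function(object, binwidth_um = 0.5, ...) {
  ggplot2::ggplot(object$fragments, ggplot2::aes(x = .data$length_um)) +
    ggplot2::geom_histogram(binwidth = binwidth_um, fill = "#2c3e50") +
    ggplot2::labs(x = "fragment length (um)", y = "count") +
    ggplot2::theme_minimal()
}

#' Activity map with detected ROI centres
#'
#' @param map An [image2d] from [activity_map()].
#' @param rois Optional `roi_set` overlay.
#' @return A ggplot.
#' @export
plot_activity_map <- function(map, rois = NULL) {
  m <- unclass(as.matrix(map))
  df <- tidyr::expand_grid(y = seq_len(nrow(m)), x = seq_len(ncol(m)))
  df$value <- m[cbind(df$y, df$x)]
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                        fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
  if (!is.null(rois) && nrow(rois))
    p <- p + ggplot2::geom_point(data = tibble::as_tibble(rois),
                                 ggplot2::aes(.data$x, .data$y),
                                 inherit.aes = FALSE, shape = 1,
                                 colour = "white", size = 2)
  p
}
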