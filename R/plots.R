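#' Plot a cumulative touch-duration map
#'
#' Renders `counts / n_frames` as a raster heat map with a sequential
#' colour scale, optionally overlaying effective touch-point bounding boxes.
#' Axes follow image convention: origin at the top-left, row increasing
#' downwards.
#'
#' @param cmap a cumulative map from [accumulate_touch()].
#' @param regions optional region list or [region_table()] tibble to
#'   overlay as bounding boxes.
#' @return A ggplot object.
#' @export
plot_cumulative_map <- function(cmap, regions = NULL) {
  counts <- unclass(cmap)
  n <- attr(cmap, "n_frames")
  df <- tibble::tibble(
    row = rep(seq_len(nrow(counts)) - 1L, times = ncol(counts)),
    col = rep(seq_len(ncol(counts)) - 1L, each = nrow(counts)),
    fraction = as.vector(counts) / n
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                        fill = .data$fraction)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "touch\nfraction", limits = c(0, 1)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "column (px)", y = "row (px)") +
    ggplot2::theme_minimal()
  if (!is.null(regions)) {
    tab <- if (is.data.frame(regions)) regions else region_table(regions)
    if (nrow(tab) > 0) {
      p <- p + ggplot2::geom_rect(
        data = tab,
        ggplot2::aes(xmin = .data$col_min - 0.5, xmax = .data$col_max + 0.5,
                     ymin = .data$row_min - 0.5, ymax = .data$row_max + 0.5),
        inherit.aes = FALSE, colour = "red", fill = NA, linewidth = 0.6)
    }
  }
  p
}

#' Plot a single-pixel intensity profile
#'
#' The standard diagnostic trace for touch and occlusion dynamics: a touch
#' shows a ramp followed by an exponential decay; a passing subject shows a
#' transient plateau (two peaks when the subject re-enters).
#'
#' @param profile a [pixel_profile()] tibble.
#' @return A ggplot object.
#' @export
plot_pixel_profile <- function(profile) {
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$time_s,
                                        y = .data$intensity)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "pixel intensity (8-bit)") +
    ggplot2::theme_minimal()
}

#' Training curves of a U-net fit
#'
#' Loss and touch/human validation Dice against epoch, with the selected
#' epoch marked.
#'
#' @param object a `unet_fit`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.unet_fit <- function(object, ...) {
  h <- object$history
  long <- dplyr::bind_rows(
    tibble::tibble(epoch = h$epoch, value = h$train_loss,
                   series = "training loss", panel = "loss"),
    tibble::tibble(epoch = h$epoch, value = h$val_loss,
                   series = "validation loss", panel = "loss"),
    tibble::tibble(epoch = h$epoch, value = h$dice_touch_val,
                   series = "touch-point Dice (val)", panel = "Dice"),
    tibble::tibble(epoch = h$epoch, value = h$dice_human_val,
                   series = "human Dice (val)", panel = "Dice")
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::facet_wrap(ggplot2::vars(.data$panel), scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
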