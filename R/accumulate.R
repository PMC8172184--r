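#' Accumulate touch-point labels across frames
#'
#' The multi-frame stage of the pipeline: per-pixel count of frames carrying
#' the touch-point label (class 1). Human-subject (2) and background (0)
#' labels contribute nothing. The count at a pixel is the touch duration in
#' frames at that location, and doubles as a confidence score.
#'
#' @param label_maps ordered list of H x W label matrices with values in
#'   {0, 1, 2}.
#' @return A `cumulative_map`: an integer count matrix with attribute
#'   `n_frames`.
#' @export
accumulate_touch <- function(label_maps) {
  if (!is.list(label_maps) || length(label_maps) == 0L) {
    stop("no frames", call. = FALSE)
  }
  d <- dim(label_maps[[1]])
  counts <- matrix(0L, d[1], d[2])
  for (m in label_maps) {
    if (!all(dim(m) == d)) stop("shape mismatch", call. = FALSE)
    counts <- counts + (m == 1L)
  }
  structure(counts, n_frames = length(label_maps),
            class = c("cumulative_map", "matrix", "array"))
}

#' Threshold a cumulative map into the final touch mask
#'
#' A pixel is kept when its accumulated touch count reaches the duration
#' threshold; the boundary is inclusive so that a signature persisting for
#' exactly `f_thresh` frames (the stated minimum duration) passes.
#'
#' @param cmap a [accumulate_touch()] cumulative map.
#' @param f_thresh accumulated-frame threshold (default 50, i.e. 3.3 s of
#'   persistence at 15 fps).
#' @return A binary H x W `touch_mask` matrix (0/1 integer).
#' @export
apply_duration_threshold <- function(cmap, f_thresh = 50) {
  if (f_thresh < 0) stop("f_thresh must be >= 0", call. = FALSE)
  mask <- matrix(as.integer(unclass(cmap) >= f_thresh), nrow(cmap), ncol(cmap))
  structure(mask, class = c("touch_mask", "matrix", "array"))
}

#' Minimum touch persistence implied by the duration threshold
#'
#' @param f_thresh accumulated-frame threshold.
#' @param fps processing frame rate.
#' @return Seconds, reported to one decimal place (50 frames at 15 fps is
#'   3.3 s).
#' @export
min_duration_seconds <- function(f_thresh = 50, fps = 15) {
  if (fps <= 0) stop("invalid rate", call. = FALSE)
  round(f_thresh / fps, 1)
}

#' Export a cumulative map
#'
#' Writes the raw counts exactly as a 16-bit TIFF when the `tiff` package is
#' available (falling back to a plain CSV of counts otherwise), and,
#' optionally, an 8-bit PNG of `counts / n_frames` for visual inspection.
#'
#' @param cmap a cumulative map.
#' @param path output path (extension adjusted to the format used).
#' @param preview_path optional path for an 8-bit normalized preview PNG.
#' @return Invisibly, the path written.
#' @export
write_cumulative_map <- function(cmap, path, preview_path = NULL) {
  counts <- unclass(cmap)
  attr(counts, "n_frames") <- NULL
  if (requireNamespace("tiff", quietly = TRUE)) {
    path <- sub("\\.[^.]*$", ".tiff", path)
    tiff::writeTIFF(counts / 65535, path, bits.per.sample = 16L)
  } else {
    path <- sub("\\.[^.]*$", ".csv", path)
    utils::write.table(counts, path, sep = ",",
                       row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(preview_path)) {
    n <- attr(cmap, "n_frames")
    png::writePNG(pmin(counts / n, 1), preview_path)
  }
  invisible(path)
}
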