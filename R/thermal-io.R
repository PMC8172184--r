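#' Construct a thermal frame sequence
#'
#' A thermal sequence is an ordered set of 8-bit grayscale frames sharing one
#' geometry, together with the frame rate. Frames are numeric matrices with
#' intensities in \[0, 255\]; row/column indices are 0-based (row, col) with
#' the origin at the top-left when reported to the user.
#'
#' @param frames list of numeric H x W matrices, all the same size, values in
#'   \[0, 255\].
#' @param fps frames per second (positive).
#' @return An object of class `thermal_sequence`: a list with elements
#'   `frames`, `fps`, `height`, `width`.
#' @export
thermal_sequence <- function(frames, fps) {
  if (!is.list(frames) || length(frames) == 0L) {
    stop("no frames", call. = FALSE)
  }
  if (!is.numeric(fps) || length(fps) != 1L || fps <= 0) {
    stop("fps must be a positive number", call. = FALSE)
  }
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("shape mismatch", call. = FALSE)
  }
  rng <- range(vapply(frames, range, numeric(2)))
  if (rng[1] < 0 || rng[2] > 255) {
    stop("intensities must lie in [0, 255]", call. = FALSE)
  }
  structure(
    list(frames = frames, fps = fps,
         height = dims[1, 1], width = dims[2, 1]),
    class = "thermal_sequence"
  )
}

#' @export
print.thermal_sequence <- function(x, ...) {
  cat(sprintf("<thermal_sequence> %d frames, %d x %d px, %g fps (%.1f s)\n",
              length(x$frames), x$height, x$width, x$fps,
              length(x$frames) / x$fps))
  invisible(x)
}

#' @export
length.thermal_sequence <- function(x) length(x$frames)

#' Frame timestamps of a sequence
#'
#' @param seq a [thermal_sequence()].
#' @return A tibble with `frame` (0-based index) and `time_s`.
#' @export
frame_times <- function(seq) {
  stopifnot(inherits(seq, "thermal_sequence"))
  idx <- seq_along(seq$frames) - 1L
  tibble::tibble(frame = idx, time_s = idx / seq$fps)
}

read_gray_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("png")) {
    img <- png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("reading TIFF frames requires the 'tiff' package", call. = FALSE)
    }
    img <- tiff::readTIFF(path)
  } else {
    stop(sprintf("unsupported image format '%s'", ext), call. = FALSE)
  }
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] > 1L) stop("not grayscale", call. = FALSE)
    img <- img[, , 1L]
  }
  # readers return values in [0,1]; 8- and 16-bit inputs both land on the
  # 0-255 working scale through one linear factor
  img * 255
}

#' Load a thermal frame sequence from a directory
#'
#' Reads every PNG/TIFF in `frame_directory`, sorted by filename (use
#' zero-padded numbering such as `frame_000001.png`), as single-channel
#' 8-bit frames. 16-bit input is linearly rescaled onto \[0, 255\]; the
#' rescaling is the same `x * 255` map because image readers normalise to
#' \[0, 1\] at whatever bit depth.
#'
#' @param frame_directory directory containing the numbered frame images.
#' @param fps frame rate of the recording (frames per second).
#' @param pattern filename regexp selecting frame files.
#' @return A [thermal_sequence()].
#' @export
load_sequence <- function(frame_directory, fps,
                          pattern = "\\.(png|tif|tiff)$") {
  files <- sort(list.files(frame_directory, pattern = pattern,
                           full.names = TRUE, ignore.case = TRUE))
  if (length(files) == 0L) stop("no frames", call. = FALSE)
  frames <- lapply(files, read_gray_image)
  thermal_sequence(frames, fps = fps)
}

#' Write a thermal sequence as 8-bit PNG frames
#'
#' @param seq a [thermal_sequence()] (or a list of matrices).
#' @param dir output directory, created if absent.
#' @param prefix filename prefix; frames are written as
#'   `<prefix>_<000000>.png`.
#' @return Invisibly, the written file paths.
#' @export
write_sequence <- function(seq, dir, prefix = "frame") {
  frames <- if (inherits(seq, "thermal_sequence")) seq$frames else seq
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(length(frames))
  for (i in seq_along(frames)) {
    paths[i] <- file.path(dir, sprintf("%s_%06d.png", prefix, i - 1L))
    png::writePNG(pmin(pmax(frames[[i]], 0), 255) / 255, paths[i])
  }
  invisible(paths)
}

#' Temporally resample a sequence by integer frame decimation
#'
#' Keeps every k-th frame starting from frame 0, where
#' `k = fps / target_fps` must be a positive integer (e.g. 30 fps recordings
#' are processed at 15 fps with k = 2).
#'
#' @param seq a [thermal_sequence()].
#' @param target_fps desired output frame rate.
#' @return A [thermal_sequence()] at `target_fps`.
#' @export
resample_sequence <- function(seq, target_fps) {
  stopifnot(inherits(seq, "thermal_sequence"))
  if (target_fps <= 0) stop("unsupported resampling ratio", call. = FALSE)
  k <- seq$fps / target_fps
  if (abs(k - round(k)) > 1e-9 || round(k) < 1) {
    stop("unsupported resampling ratio", call. = FALSE)
  }
  k <- as.integer(round(k))
  keep <- seq.int(1L, length(seq$frames), by = k)
  thermal_sequence(seq$frames[keep], fps = target_fps)
}

#' Background subtraction of a frame
#'
#' Pixel-wise subtraction of the human-free reference frame; negative
#' differences are clamped to zero because the targets (touch-points, human
#' subject) are strictly warmer than the static background, so sub-background
#' pixels carry no signal.
#'
#' @param frame a numeric H x W matrix (one thermal frame), or a
#'   [thermal_sequence()] to transform every frame.
#' @param bg the background reference frame (numeric matrix, same size).
#' @return A nonnegative difference matrix (or list of them for a sequence),
#'   class `diff_frame`.
#' @export
subtract_background <- function(frame, bg) {
  if (inherits(frame, "thermal_sequence")) {
    return(lapply(frame$frames, subtract_background, bg = bg))
  }
  if (!all(dim(frame) == dim(bg))) stop("shape mismatch", call. = FALSE)
  d <- pmax(frame - bg, 0)
  class(d) <- c("diff_frame", class(d))
  d
}

#' Linear intensity/temperature calibration
#'
#' The camera maps its working temperature span linearly onto the 8-bit
#' intensity range: intensity 0 is `temp_min_c`, 255 is `temp_max_c`.
#'
#' @param temp_min_c,temp_max_c calibration endpoints in degrees Celsius.
#' @return A `thermal_calibration` object.
#' @export
thermal_calibration <- function(temp_min_c = 20, temp_max_c = 35) {
  if (!(temp_min_c < temp_max_c)) {
    stop("temp_min_c must be below temp_max_c", call. = FALSE)
  }
  structure(list(temp_min_c = temp_min_c, temp_max_c = temp_max_c),
            class = "thermal_calibration")
}

#' Convert pixel intensity to temperature
#'
#' @param intensity intensities in \[0, 255\] (vectorised).
#' @param cal a [thermal_calibration()].
#' @return Temperatures in degrees Celsius.
#' @export
intensity_to_temperature <- function(intensity, cal = thermal_calibration()) {
  if (any(intensity < 0 | intensity > 255)) {
    stop("intensity out of range", call. = FALSE)
  }
  cal$temp_min_c + intensity / 255 * (cal$temp_max_c - cal$temp_min_c)
}

#' Convert temperature to pixel intensity
#'
#' Inverse of [intensity_to_temperature()]; temperatures outside the
#' calibrated span saturate at 0 or 255 (the camera clips).
#'
#' @param temp_c temperatures in degrees Celsius (vectorised).
#' @param cal a [thermal_calibration()].
#' @return Intensities in \[0, 255\] (not quantized).
#' @export
temperature_to_intensity <- function(temp_c, cal = thermal_calibration()) {
  i <- (temp_c - cal$temp_min_c) / (cal$temp_max_c - cal$temp_min_c) * 255
  pmin(pmax(i, 0), 255)
}
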