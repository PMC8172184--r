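#' Synthetic thermal scene configuration
#'
#' Describes a static warm room observed by a thermal camera: frame geometry,
#' processing frame rate, duration, ambient surface temperature, and additive
#' Gaussian sensor noise. Defaults follow the recording conditions the
#' pipeline targets: 480 x 640 frames processed at 15 fps, roughly one-minute
#' scenes, a room at 25 degrees C, and noise of 1 intensity unit.
#'
#' @param height,width frame size in pixels.
#' @param fps frames per second.
#' @param duration_s scene length in seconds; `duration_s * fps >= 1`.
#' @param background_temp_c ambient surface temperature (degrees C).
#' @param noise_sd sd of additive Gaussian sensor noise, in 8-bit intensity
#'   units; 0 disables noise.
#' @param seed integer seed controlling the noise stream.
#' @param cal a [thermal_calibration()] used to render temperature as
#'   intensity.
#' @return A `scene_config` object.
#' @export
scene_config <- function(height = 480, width = 640, fps = 15,
                         duration_s = 60, background_temp_c = 25,
                         noise_sd = 1, seed = 1,
                         cal = thermal_calibration()) {
  if (duration_s * fps < 1) stop("duration_s * fps must be >= 1", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(
    list(height = as.integer(height), width = as.integer(width),
         fps = fps, duration_s = duration_s,
         background_temp_c = background_temp_c,
         noise_sd = noise_sd, seed = as.integer(seed), cal = cal),
    class = "scene_config"
  )
}

#' Define a touch event
#'
#' A touch event is a hand contact with a surface: an elliptical footprint
#' whose excess temperature ramps linearly from 0 at `start_frame` to
#' `peak_delta_t_c` at `end_frame` (contact), then relaxes back to ambient by
#' Newtonian cooling, `peak * exp(-(t - t_release) / decay_tau_s)`.
#'
#' Defaults for the contact physics sit mid-range of what bare-hand contact
#' on indoor surfaces plausibly produces (a few degrees of excess, cooling
#' over seconds to tens of seconds); neither is a measured constant.
#'
#' @param row,col footprint centre, 0-based pixel coordinates.
#' @param start_frame,end_frame contact interval in frame indices (0-based,
#'   `start_frame < end_frame`).
#' @param semi_axes ellipse semi-axes `(rows, cols)` in pixels.
#' @param peak_delta_t_c excess temperature at release, degrees C (> 0).
#' @param decay_tau_s cooling time constant, seconds (> 0).
#' @return A one-row tibble; bind rows to build an event table.
#' @export
touch_event <- function(row, col, start_frame, end_frame,
                        semi_axes = c(7, 7), peak_delta_t_c = 5,
                        decay_tau_s = 10) {
  if (start_frame >= end_frame) stop("contact_start must precede contact_end",
                                     call. = FALSE)
  if (peak_delta_t_c <= 0) stop("peak_delta_t_c must be > 0", call. = FALSE)
  if (decay_tau_s <= 0) stop("decay_tau_s must be > 0", call. = FALSE)
  tibble::tibble(
    row = row, col = col,
    start_frame = as.integer(start_frame), end_frame = as.integer(end_frame),
    semi_r = semi_axes[1], semi_c = semi_axes[2],
    peak_delta_t_c = peak_delta_t_c, decay_tau_s = decay_tau_s
  )
}

#' Randomly place well-separated touch events in a scene
#'
#' Centres are rejection-sampled so that any two events are at least
#' `min_separation` pixels apart and footprints stay inside the frame.
#'
#' @param config a [scene_config()].
#' @param n_events number of events.
#' @param seed integer seed.
#' @param semi_axes footprint semi-axes (pixels).
#' @param peak_range,tau_range uniform sampling ranges for the excess
#'   temperature (degrees C) and cooling constant (seconds).
#' @param start_range contact-start range as fractions of the scene length.
#' @param contact_s contact duration in seconds.
#' @param min_separation minimum centre distance in pixels.
#' @return An event tibble as produced by [touch_event()].
#' @export
sample_touch_events <- function(config, n_events, seed = config$seed,
                                semi_axes = c(7, 7),
                                peak_range = c(3, 8), tau_range = c(5, 20),
                                start_range = c(0.05, 0.25), contact_s = 2,
                                min_separation = 50) {
  with_preserved_seed(seed, {
    margin_r <- ceiling(semi_axes[1]) + 2
    margin_c <- ceiling(semi_axes[2]) + 2
    centres <- matrix(NA_real_, 0, 2)
    tries <- 0
    while (nrow(centres) < n_events && tries < 10000) {
      tries <- tries + 1
      cand <- c(stats::runif(1, margin_r, config$height - 1 - margin_r),
                stats::runif(1, margin_c, config$width - 1 - margin_c))
      if (nrow(centres) == 0 ||
          all(sqrt(rowSums((centres - rep(cand, each = nrow(centres)))^2)) >=
              min_separation)) {
        centres <- rbind(centres, cand)
      }
    }
    if (nrow(centres) < n_events) {
      stop("could not place events with the requested separation", call. = FALSE)
    }
    n_frames <- round(config$duration_s * config$fps)
    starts <- round(stats::runif(n_events, start_range[1] * n_frames,
                                 start_range[2] * n_frames))
    purrr::map_dfr(seq_len(n_events), function(i) {
      touch_event(
        row = round(centres[i, 1]), col = round(centres[i, 2]),
        start_frame = starts[i],
        end_frame = starts[i] + round(contact_s * config$fps),
        semi_axes = semi_axes,
        peak_delta_t_c = stats::runif(1, peak_range[1], peak_range[2]),
        decay_tau_s = stats::runif(1, tau_range[1], tau_range[2])
      )
    })
  })
}

#' Linear human-subject sweep across the scene
#'
#' Builds a per-frame track of an elliptical human blob moving in a straight
#' line between two points while present, absent elsewhere. Call repeatedly
#' and bind rows for multiple passes (re-entry events).
#'
#' @param enter_frame,exit_frame frames (0-based) between which the subject
#'   is in view.
#' @param from,to centre positions `(row, col)` at entry and exit.
#' @param semi_axes ellipse semi-axes `(rows, cols)` in pixels.
#' @return A tibble with columns `frame`, `row`, `col`, `semi_r`, `semi_c`.
#' @export
subject_sweep <- function(enter_frame, exit_frame, from, to,
                          semi_axes = c(28, 16)) {
  stopifnot(enter_frame <= exit_frame)
  frames <- seq.int(enter_frame, exit_frame)
  w <- if (length(frames) == 1L) 0 else
    (frames - enter_frame) / (exit_frame - enter_frame)
  tibble::tibble(
    frame = as.integer(frames),
    row = from[1] + w * (to[1] - from[1]),
    col = from[2] + w * (to[2] - from[2]),
    semi_r = semi_axes[1], semi_c = semi_axes[2]
  )
}

# elliptical footprint pixel indices (column-major linear, 1-based) and the
# normalized radius at each; centre/axes in 0-based pixel coordinates
ellipse_pixels <- function(height, width, row, col, semi_r, semi_c) {
  r0 <- max(0L, floor(row - semi_r)); r1 <- min(height - 1L, ceiling(row + semi_r))
  c0 <- max(0L, floor(col - semi_c)); c1 <- min(width - 1L, ceiling(col + semi_c))
  if (r0 > r1 || c0 > c1) return(list(idx = integer(0), rho = numeric(0)))
  rr <- r0:r1; cc <- c0:c1
  rho <- sqrt(outer(((rr - row) / semi_r)^2, ((cc - col) / semi_c)^2, `+`))
  keep <- which(rho <= 1)
  idx <- outer(rr + 1L, cc * height, `+`)[keep]
  list(idx = as.integer(idx), rho = rho[keep])
}

# run expr with a fixed RNG seed, restoring the caller's RNG state after
with_preserved_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Simulate a thermal scene with ground truth
#'
#' Renders a frame sequence of a static warm surface, zero or more touch
#' events, and an optional moving human subject, together with per-frame
#' three-class label maps and true touch bounding boxes.
#'
#' Per frame, the surface temperature is the ambient background plus the sum
#' of event contributions (linear ramp during contact, exponential Newtonian
#' cooling after release). Wherever the subject ellipse is present it
#' occludes the surface: its apparent temperature runs radially from a
#' 35 degree C core to a 25 degree C rim. Temperatures are converted to 8-bit
#' intensity via the calibration, Gaussian sensor noise is added last, and
#' frames are quantized to integers in \[0, 255\].
#'
#' Ground-truth labels mark occluded pixels as human (2); un-occluded event
#' footprints whose noiseless excess intensity exceeds 1 intensity unit as
#' touch-point (1); everything else background (0).
#'
#' @param config a [scene_config()].
#' @param events an event tibble ([touch_event()] rows), or NULL.
#' @param track a subject track ([subject_sweep()] rows), or NULL.
#' @param core_temp_c,rim_temp_c subject core and rim temperatures.
#' @return A list with elements `sequence` (a [thermal_sequence()]),
#'   `labels` (list of H x W label matrices in {0,1,2}), `boxes` (tibble of
#'   true touch boxes with event metadata and touched duration in frames),
#'   and `background` (the clean background frame, quantized, noise-free).
#' @export
simulate_scene <- function(config, events = NULL, track = NULL,
                           core_temp_c = 35, rim_temp_c = 25) {
  H <- config$height; W <- config$width
  n_frames <- round(config$duration_s * config$fps)
  n_events <- if (is.null(events)) 0L else nrow(events)
  cal <- config$cal
  scale_i <- 255 / (cal$temp_max_c - cal$temp_min_c)  # intensity units per C

  ev_px <- vector("list", n_events)
  if (n_events > 0) {
    for (e in seq_len(n_events)) {
      ok <- events$row[e] - events$semi_r[e] >= 0 &&
        events$row[e] + events$semi_r[e] <= H - 1 &&
        events$col[e] - events$semi_c[e] >= 0 &&
        events$col[e] + events$semi_c[e] <= W - 1
      if (!ok) stop("event out of frame", call. = FALSE)
      ev_px[[e]] <- ellipse_pixels(H, W, events$row[e], events$col[e],
                                   events$semi_r[e], events$semi_c[e])$idx
    }
  }

  bg_temp <- matrix(config$background_temp_c, H, W)
  bg_int <- matrix(round(temperature_to_intensity(bg_temp, cal)), H, W)

  track_by_frame <- if (is.null(track)) NULL else split(track, track$frame)

  frames <- vector("list", n_frames)
  labels <- vector("list", n_frames)
  touched <- matrix(FALSE, n_events, n_frames)  # event touch-visible per frame

  with_preserved_seed(config$seed, {
    for (i in seq_len(n_frames)) {
      t_idx <- i - 1L  # frame index, 0-based
      temp <- bg_temp
      delta_i <- matrix(0, H, W)      # noiseless excess intensity, surface only
      per_event_hot <- vector("list", n_events)
      if (n_events > 0) {
        for (e in seq_len(n_events)) {
          s <- events$start_frame[e]; en <- events$end_frame[e]
          dt <- if (t_idx < s) 0
          else if (t_idx <= en) events$peak_delta_t_c[e] * (t_idx - s) / (en - s)
          else events$peak_delta_t_c[e] *
              exp(-((t_idx - en) / config$fps) / events$decay_tau_s[e])
          if (dt > 0) {
            idx <- ev_px[[e]]
            temp[idx] <- temp[idx] + dt
            delta_i[idx] <- delta_i[idx] + dt * scale_i
            per_event_hot[[e]] <- if (dt * scale_i > 1) idx else integer(0)
          } else per_event_hot[[e]] <- integer(0)
        }
      }

      occluded <- integer(0)
      tr <- track_by_frame[[as.character(t_idx)]]
      if (!is.null(tr) && nrow(tr) > 0) {
        for (s in seq_len(nrow(tr))) {
          ep <- ellipse_pixels(H, W, tr$row[s], tr$col[s],
                               tr$semi_r[s], tr$semi_c[s])
          temp[ep$idx] <- core_temp_c + (rim_temp_c - core_temp_c) * ep$rho
          occluded <- c(occluded, ep$idx)
        }
      }

      lab <- matrix(0L, H, W)
      lab[delta_i > 1] <- 1L
      lab[occluded] <- 2L
      labels[[i]] <- lab
      for (e in seq_len(n_events)) {
        hot <- setdiff(per_event_hot[[e]], occluded)
        touched[e, i] <- length(hot) > 0
      }

      int <- temperature_to_intensity(temp, cal)
      if (config$noise_sd > 0) {
        int <- int + stats::rnorm(H * W, sd = config$noise_sd)
      }
      frames[[i]] <- matrix(pmin(pmax(round(int), 0), 255), H, W)
    }
  })

  boxes <- if (n_events == 0) {
    tibble::tibble(event_id = integer(0), row = numeric(0), col = numeric(0),
                   row_min = integer(0), col_min = integer(0),
                   row_max = integer(0), col_max = integer(0),
                   start_frame = integer(0), end_frame = integer(0),
                   peak_delta_t_c = numeric(0), decay_tau_s = numeric(0),
                   duration_frames = integer(0))
  } else {
    purrr::map_dfr(seq_len(n_events), function(e) {
      idx <- ev_px[[e]] - 1L
      rows <- idx %% H; cols <- idx %/% H
      tibble::tibble(
        event_id = e, row = events$row[e], col = events$col[e],
        row_min = min(rows), col_min = min(cols),
        row_max = max(rows), col_max = max(cols),
        start_frame = events$start_frame[e], end_frame = events$end_frame[e],
        peak_delta_t_c = events$peak_delta_t_c[e],
        decay_tau_s = events$decay_tau_s[e],
        duration_frames = sum(touched[e, ])
      )
    })
  }

  list(sequence = thermal_sequence(frames, fps = config$fps),
       labels = labels, boxes = boxes, background = bg_int)
}

#' Intensity time series at one pixel
#'
#' Traces a single pixel through the sequence, the standard diagnostic for
#' touch/occlusion dynamics: a contact shows a ramp then an exponential
#' decay; a passing subject shows a transient plateau at body temperature.
#'
#' @param seq a [thermal_sequence()].
#' @param pixel `(row, col)` 0-based pixel coordinates.
#' @return A tibble with `frame`, `time_s`, `intensity`.
#' @export
pixel_profile <- function(seq, pixel) {
  stopifnot(inherits(seq, "thermal_sequence"))
  r <- pixel[1]; c <- pixel[2]
  if (r < 0 || r >= seq$height || c < 0 || c >= seq$width) {
    stop("pixel out of range", call. = FALSE)
  }
  v <- vapply(seq$frames, function(f) f[r + 1L, c + 1L], numeric(1))
  idx <- seq_along(v) - 1L
  tibble::tibble(frame = idx, time_s = idx / seq$fps, intensity = v)
}

#' Write / read a scene configuration as a flat key-value file
#'
#' Keys are exactly the `scene_config` field names (`height`, `width`,
#' `fps`, `duration_s`, `background_temp_c`, `noise_sd`, `seed`).
#'
#' @param config a [scene_config()].
#' @param path file path.
#' @return `write_scene_config` returns `path` invisibly;
#'   `read_scene_config` returns a [scene_config()].
#' @export
write_scene_config <- function(config, path) {
  yaml::write_yaml(config[c("height", "width", "fps", "duration_s",
                            "background_temp_c", "noise_sd", "seed")], path)
  invisible(path)
}

#' @rdname write_scene_config
#' @export
read_scene_config <- function(path) {
  do.call(scene_config, yaml::read_yaml(path))
}

#' Write simulated scene artefacts to disk
#'
#' Frames and label maps as PNG directories (labels stored with values
#' 0/1/2), events as a CSV table.
#'
#' @param scene result of [simulate_scene()].
#' @param dir output directory.
#' @return Invisibly, `dir`.
#' @export
write_scene <- function(scene, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_sequence(scene$sequence, file.path(dir, "frames"))
  lab_dir <- file.path(dir, "labels")
  if (!dir.exists(lab_dir)) dir.create(lab_dir)
  for (i in seq_along(scene$labels)) {
    png::writePNG(scene$labels[[i]] / 255,
                  file.path(lab_dir, sprintf("label_%06d.png", i - 1L)))
  }
  png::writePNG(scene$background / 255, file.path(dir, "background.png"))
  utils::write.csv(
    scene$boxes[, c("event_id", "row", "col", "start_frame", "end_frame",
                    "peak_delta_t_c", "decay_tau_s")],
    file.path(dir, "events.csv"), row.names = FALSE)
  invisible(dir)
}
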