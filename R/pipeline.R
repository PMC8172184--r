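#' Pipeline configuration
#'
#' Collects every knob of an end-to-end detection run: input paths, the
#' processing frame rate, the duration threshold, region post-processing
#' parameters, the segmenter choice and its parameters, and the seed.
#'
#' @param frames_dir directory of numbered frame images.
#' @param output_dir run output directory.
#' @param background_file optional background reference image; when NULL the
#'   first frame of the sequence is used as the reference.
#' @param weights_file U-net checkpoint (required for `segmenter = "unet"`).
#' @param labels_file optional CSV of labelled touch boxes for evaluation.
#' @param fps frame rate of the input recording.
#' @param target_fps processing frame rate (decimation target).
#' @param f_thresh accumulated-frame duration threshold.
#' @param params a [region_params()].
#' @param segmenter `"unet"` or `"baseline"`.
#' @param intensity_threshold,human_area_threshold [baseline_segment()]
#'   parameters (ignored for the U-net).
#' @param seed integer seed echoed into the provenance record.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(frames_dir, output_dir,
                            background_file = NULL, weights_file = NULL,
                            labels_file = NULL, fps = 30, target_fps = 15,
                            f_thresh = 50, params = region_params(),
                            segmenter = c("unet", "baseline"),
                            intensity_threshold = 5,
                            human_area_threshold = 500, seed = 1) {
  structure(list(frames_dir = frames_dir, output_dir = output_dir,
                 background_file = background_file,
                 weights_file = weights_file, labels_file = labels_file,
                 fps = fps, target_fps = target_fps, f_thresh = f_thresh,
                 params = params, segmenter = match.arg(segmenter),
                 intensity_threshold = intensity_threshold,
                 human_area_threshold = human_area_threshold,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Detect touch-points in a thermal sequence
#'
#' The core detection chain: per-frame background subtraction and 3-class
#' segmentation, accumulation of touch labels into a cumulative duration
#' map, duration thresholding into the binary touch mask, and region
#' post-processing (8-connected components, area filter, centroid and
#' containment merging) into effective touch-points.
#'
#' @param seq a [thermal_sequence()] (already at the processing frame rate).
#' @param background background reference frame (numeric matrix); defaults
#'   to the first frame of `seq`.
#' @param segmenter `"baseline"` or `"unet"`.
#' @param model a `unet_model`/`unet_fit` when `segmenter = "unet"`.
#' @param f_thresh accumulated-frame duration threshold (default 50).
#' @param params a [region_params()].
#' @param intensity_threshold,human_area_threshold passed to
#'   [baseline_segment()].
#' @return A list: `mask` (binary touch mask), `cumulative` (cumulative
#'   map), `regions` (effective region list), `table` (region tibble with
#'   duration summaries), `label_maps` (per-frame segmentations).
#' @export
detect_touch_points <- function(seq, background = NULL,
                                segmenter = c("baseline", "unet"),
                                model = NULL, f_thresh = 50,
                                params = region_params(),
                                intensity_threshold = 5,
                                human_area_threshold = 500) {
  stopifnot(inherits(seq, "thermal_sequence"))
  segmenter <- match.arg(segmenter)
  if (is.null(background)) background <- seq$frames[[1]]
  if (segmenter == "unet" && is.null(model)) {
    stop("weights required", call. = FALSE)
  }
  diffs <- subtract_background(seq, background)
  label_maps <- lapply(diffs, function(d) {
    if (segmenter == "baseline") {
      baseline_segment(d, intensity_threshold, human_area_threshold)
    } else {
      unet_segment(model, d)
    }
  })
  cmap <- accumulate_touch(label_maps)
  mask <- apply_duration_threshold(cmap, f_thresh)
  regions <- extract_regions(mask, params$connectivity)
  regions <- remove_small_regions(regions, params$tau1_area)
  regions <- merge_touch_regions(regions, params$tau2_cluster)
  list(mask = mask, cumulative = cmap, regions = regions,
       table = region_table(regions, cmap, fps = seq$fps),
       label_maps = label_maps)
}

#' Run the full detection pipeline from a configuration
#'
#' Loads frames, resamples to the processing rate, runs
#' [detect_touch_points()], optionally evaluates against labelled boxes,
#' and writes all outputs under `output_dir` with fixed names: `mask.png`,
#' `cumulative.png` (preview) plus an exact counts export, `regions.csv`,
#' `metrics.txt` (when labels are given) and a provenance record `run.json`
#' echoing every threshold and seed.
#'
#' @param cfg a [pipeline_config()].
#' @return Invisibly, the [detect_touch_points()] result plus `metrics`
#'   (or NULL) and `output_dir`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  seq <- load_sequence(cfg$frames_dir, fps = cfg$fps)
  if (cfg$target_fps != cfg$fps) {
    seq <- resample_sequence(seq, cfg$target_fps)
  }
  background <- if (!is.null(cfg$background_file)) {
    read_gray_image(cfg$background_file)
  } else {
    seq$frames[[1]]
  }
  model <- NULL
  if (cfg$segmenter == "unet") {
    if (is.null(cfg$weights_file)) stop("weights required", call. = FALSE)
    model <- load_weights(cfg$weights_file)
  }
  res <- detect_touch_points(
    seq, background, segmenter = cfg$segmenter, model = model,
    f_thresh = cfg$f_thresh, params = cfg$params,
    intensity_threshold = cfg$intensity_threshold,
    human_area_threshold = cfg$human_area_threshold)

  out <- cfg$output_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  png::writePNG(matrix(as.numeric(res$mask), nrow(res$mask)),
                file.path(out, "mask.png"))
  write_cumulative_map(res$cumulative, file.path(out, "cumulative_counts.png"),
                       preview_path = file.path(out, "cumulative.png"))
  utils::write.csv(res$table, file.path(out, "regions.csv"),
                   row.names = FALSE)

  metrics <- NULL
  if (!is.null(cfg$labels_file)) {
    boxes <- read_label_boxes(cfg$labels_file)
    m <- match_regions(res$regions, boxes, cfg$params$tau3_match)
    metrics <- detection_metrics(m)
    report <- metrics_report(list(run = m))
    utils::write.table(report, file.path(out, "metrics.txt"),
                       row.names = FALSE, quote = FALSE, sep = "\t")
  }

  run_info <- list(
    package_version = as.character(utils::packageVersion("thermotouch")),
    r_version = R.version.string,
    config = cfg[setdiff(names(cfg), "params")],
    region_params = unclass(cfg$params),
    n_frames = length(seq),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(run_info, file.path(out, "run.json"),
                       auto_unbox = TRUE, null = "null", pretty = TRUE)

  invisible(c(res, list(metrics = metrics, output_dir = out)))
}
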