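# Shared synthetic-scene builders for the tests: desk-scale 120 x 160
# frames, three well-separated touch events, a human subject sweeping
# through. All seeded and noise-free unless stated.

desk_scene <- function(seed, noise_sd = 0, duration_s = 12,
                       with_subject = TRUE, n_events = 3) {
  cfg <- scene_config(height = 120, width = 160, fps = 15,
                      duration_s = duration_s, noise_sd = noise_sd,
                      seed = seed)
  ev <- sample_touch_events(cfg, n_events, seed = seed,
                            semi_axes = c(7, 7),
                            start_range = c(0.05, 0.2),
                            min_separation = 50)
  tr <- if (with_subject) {
    subject_sweep(10, round(duration_s * cfg$fps * 0.9),
                  from = c(60, -20), to = c(60, 180),
                  semi_axes = c(30, 16))
  } else NULL
  list(cfg = cfg, events = ev, track = tr,
       scene = simulate_scene(cfg, ev, tr))
}

# small labelled (DiffFrame, LabelMap) pairs for training runs: frames
# where both a touch-point and the human subject are visible
training_frames <- function(seed, n_pick = 6, semi_axes = c(9, 9)) {
  cfg <- scene_config(height = 120, width = 160, fps = 15, duration_s = 12,
                      noise_sd = 0, seed = seed)
  ev <- sample_touch_events(cfg, 3, seed = seed, semi_axes = semi_axes,
                            start_range = c(0.05, 0.2), min_separation = 45)
  tr <- subject_sweep(10, 170, from = c(60, -20), to = c(60, 180),
                      semi_axes = c(30, 16))
  sc <- simulate_scene(cfg, ev, tr)
  diffs <- subtract_background(sc$sequence, sc$background)
  ok <- which(vapply(sc$labels, function(l) any(l == 1) && any(l == 2),
                     logical(1)))
  pick <- ok[round(seq(1, length(ok), length.out = n_pick))]
  lapply(pick, function(i) list(x = diffs[[i]], y = sc$labels[[i]]))
}

# miniature training pairs for cheap contract tests (small frames, tiny net)
tiny_training_frames <- function(seed, n_pick = 4) {
  cfg <- scene_config(height = 48, width = 64, fps = 15, duration_s = 6,
                      noise_sd = 0, seed = seed)
  ev <- dplyr::bind_rows(touch_event(14, 16, 10, 30, semi_axes = c(6, 6)),
                         touch_event(34, 48, 12, 32, semi_axes = c(6, 6)))
  tr <- subject_sweep(5, 80, from = c(24, -10), to = c(24, 74),
                      semi_axes = c(14, 8))
  sc <- simulate_scene(cfg, ev, tr)
  diffs <- subtract_background(sc$sequence, sc$background)
  ok <- which(vapply(sc$labels, function(l) any(l == 1), logical(1)))
  pick <- ok[round(seq(1, length(ok), length.out = n_pick))]
  lapply(pick, function(i) list(x = diffs[[i]], y = sc$labels[[i]]))
}
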