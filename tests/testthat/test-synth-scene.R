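test_that("a null scene is constant and equal to the background", {
  cfg <- scene_config(height = 20, width = 24, fps = 15, duration_s = 1,
                      noise_sd = 0, seed = 1)
  sc <- simulate_scene(cfg)
  expect_length(sc$sequence, 15)
  for (f in sc$sequence$frames) expect_equal(f, sc$background)
  expect_true(all(vapply(sc$labels, function(l) all(l == 0L), logical(1))))
  prof <- pixel_profile(sc$sequence, c(10, 12))
  expect_equal(length(unique(prof$intensity)), 1L)
})

test_that("simulation is deterministic and labels partition each frame", {
  build <- function() {
    cfg <- scene_config(height = 40, width = 50, fps = 15, duration_s = 4,
                        noise_sd = 1.5, seed = 99)
    ev <- touch_event(20, 25, 5, 20, semi_axes = c(5, 5))
    tr <- subject_sweep(0, 40, from = c(20, -5), to = c(20, 55),
                        semi_axes = c(10, 6))
    simulate_scene(cfg, ev, tr)
  }
  a <- build(); b <- build()
  expect_identical(a$sequence$frames, b$sequence$frames)
  expect_identical(a$labels, b$labels)
  expect_identical(a$boxes, b$boxes)
  for (l in a$labels) expect_true(all(l %in% 0:2))
})

test_that("post-release decay follows the exponential closed form", {
  tau <- 4; peak <- 6
  cfg <- scene_config(height = 30, width = 30, fps = 15, duration_s = 12,
                      noise_sd = 0, seed = 1)
  ev <- touch_event(15, 15, 5, 20, semi_axes = c(4, 4),
                    peak_delta_t_c = peak, decay_tau_s = tau)
  sc <- simulate_scene(cfg, ev)
  prof <- pixel_profile(sc$sequence, c(15, 15))
  bg <- sc$background[16, 16]
  scale_i <- 255 / 15  # intensity units per degree C

  # at release the excess intensity is the peak
  release <- 20
  expect_equal(prof$intensity[prof$frame == release] - bg,
               peak * scale_i, tolerance = 1)
  # one time constant later the residual is peak / e, within quantization
  at_tau <- release + tau * cfg$fps
  expect_equal(prof$intensity[prof$frame == at_tau] - bg,
               peak * scale_i / exp(1), tolerance = 1)
  # monotone non-increasing after release (noise-free)
  after <- prof$intensity[prof$frame >= release]
  expect_true(all(diff(after) <= 0))
  # and rising during contact
  during <- prof$intensity[prof$frame >= 5 & prof$frame <= release]
  expect_true(all(diff(during) >= 0))
})

test_that("a huge decay constant leaves the footprint at its peak", {
  cfg <- scene_config(height = 20, width = 20, fps = 15, duration_s = 8,
                      noise_sd = 0, seed = 1)
  ev <- touch_event(10, 10, 5, 15, semi_axes = c(3, 3),
                    peak_delta_t_c = 5, decay_tau_s = 1e9)
  sc <- simulate_scene(cfg, ev)
  prof <- pixel_profile(sc$sequence, c(10, 10))
  post <- prof$intensity[prof$frame > 15]
  expect_equal(length(unique(post)), 1L)
  expect_equal(post[1] - sc$background[11, 11], 5 * 255 / 15, tolerance = 1)
})

test_that("an occluding subject produces the two-peak single-pixel pattern", {
  cfg <- scene_config(height = 40, width = 60, fps = 15, duration_s = 10,
                      noise_sd = 0, seed = 1)
  ev <- touch_event(20, 30, 30, 50, semi_axes = c(4, 4),
                    peak_delta_t_c = 4, decay_tau_s = 20)
  # subject crosses the touched pixel before and again after the contact
  tr <- dplyr::bind_rows(
    subject_sweep(0, 25, from = c(20, -10), to = c(20, 70), semi_axes = c(8, 5)),
    subject_sweep(80, 110, from = c(20, 70), to = c(20, -10), semi_axes = c(8, 5))
  )
  sc <- simulate_scene(cfg, ev, tr)
  prof <- pixel_profile(sc$sequence, c(20, 30))
  v <- prof$intensity
  # occupancy level: intensity of a >= 30 C body, above any touch residue
  body_level <- temperature_to_intensity(30)
  visits <- which(v >= body_level)
  expect_gt(max(diff(visits)), 20)  # two separated visits at body temperature
  # between the passes the pixel shows the decaying touch residue, above bg
  mid <- v[seq(40, 75)]
  expect_true(all(mid > sc$background[21, 31]))
  expect_true(all(mid < body_level))
})

test_that("simulator rejects out-of-frame events and bad pixels", {
  cfg <- scene_config(height = 20, width = 20, fps = 15, duration_s = 1,
                      noise_sd = 0, seed = 1)
  expect_error(
    simulate_scene(cfg, touch_event(2, 2, 1, 5, semi_axes = c(5, 5))),
    "event out of frame")
  sc <- simulate_scene(cfg)
  expect_error(pixel_profile(sc$sequence, c(25, 5)), "pixel out of range")
})

test_that("ground-truth touch duration spans at least the contact interval", {
  cfg <- scene_config(height = 30, width = 30, fps = 15, duration_s = 6,
                      noise_sd = 0, seed = 2)
  ev <- touch_event(15, 15, 10, 40, semi_axes = c(4, 4))
  sc <- simulate_scene(cfg, ev)
  expect_gte(sc$boxes$duration_frames, 40 - 10)
})

test_that("scene configs round-trip through the key-value file", {
  cfg <- scene_config(height = 32, width = 48, fps = 15, duration_s = 2,
                      background_temp_c = 24, noise_sd = 0.5, seed = 7)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_scene_config(cfg, path)
  back <- read_scene_config(path)
  expect_equal(back[c("height", "width", "fps", "duration_s",
                      "background_temp_c", "noise_sd", "seed")],
               cfg[c("height", "width", "fps", "duration_s",
                     "background_temp_c", "noise_sd", "seed")])
})
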