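test_that("dataset splitting is seeded, disjoint and exhaustive", {
  items <- as.list(letters[1:10])
  sp <- split_dataset(items, 0.7, seed = 3)
  expect_length(sp$first, 7)
  expect_length(sp$second, 3)
  expect_setequal(c(unlist(sp$first), unlist(sp$second)), letters[1:10])

  thirty <- split_dataset(as.list(1:30), 0.7, seed = 1)
  expect_length(thirty$first, 21)
  expect_length(thirty$second, 9)

  again <- split_dataset(items, 0.7, seed = 3)
  expect_identical(sp, again)
  other <- split_dataset(items, 0.7, seed = 4)
  expect_false(identical(sp$first, other$first))

  expect_error(split_dataset(list(), 0.7), "nothing to split")
})

test_that("the baseline segmenter applies the size rule deterministically", {
  blank <- matrix(0, 30, 30)
  expect_true(all(baseline_segment(blank, 5, 100) == 0L))

  one <- matrix(0, 40, 40)
  one[10:14, 10:14] <- 50           # 25 px < 100 -> touch
  lab <- baseline_segment(one, intensity_threshold = 5,
                          human_area_threshold = 100)
  expect_equal(sum(lab == 1L), 25)
  expect_equal(sum(lab == 2L), 0)

  big <- matrix(0, 40, 40)
  big[10:29, 10:29] <- 50           # 400 px >= 100 -> human
  lab2 <- baseline_segment(big, 5, 100)
  expect_equal(sum(lab2 == 2L), 400)
  expect_equal(sum(lab2 == 1L), 0)

  both <- one + big * 0             # touch blob only below threshold check
  both[30:39, 1:8] <- 20
  lab3 <- baseline_segment(both, 5, 60)
  expect_true(all(lab3 %in% 0:2))
  expect_identical(lab3, baseline_segment(both, 5, 60))  # deterministic
})

test_that("U-net output is shape-correct with normalised class scores", {
  model <- unet_init(base_channels = 4, depth = 2, seed = 1)
  frame <- matrix(runif(30 * 42, 0, 255), 30, 42)  # not divisible by 4
  lab <- unet_segment(model, frame, return_prob = TRUE)
  expect_equal(dim(lab), c(30, 42))
  expect_true(all(lab %in% 0:2))
  p <- attr(lab, "prob")
  expect_equal(dim(p), c(30, 42, 3))
  expect_true(all(abs(apply(p, c(1, 2), sum) - 1) < 1e-5))
})

test_that("backpropagation matches finite-difference gradients", {
  tt <- asNamespace("thermotouch")
  set.seed(10)
  model <- unet_init(base_channels = 3, depth = 2, seed = 20)
  H <- 8; W <- 8
  X <- matrix(runif(H * W), H * W, 1)
  labs <- sample(0:2, H * W, replace = TRUE)
  fwd <- tt$unet_forward(model, X, H, W, keep_cache = TRUE)
  sc <- tt$softmax_ce(fwd$logits, labs)
  g <- tt$unet_backward(model, fwd$cache, sc$dlogits)
  loss_at <- function(m) {
    tt$softmax_ce(tt$unet_forward(m, X, H, W)$logits, labs)$loss
  }
  eps <- 1e-6
  slots <- list(
    list(get = function(m) m$enc[[1]]$conv1$K,
         set = function(m, v) { m$enc[[1]]$conv1$K <- v; m },
         grad = g$enc[[1]]$conv1$K),
    list(get = function(m) m$bottleneck$conv2$K,
         set = function(m, v) { m$bottleneck$conv2$K <- v; m },
         grad = g$bottleneck$conv2$K),
    list(get = function(m) m$dec[[1]]$conv1$K,
         set = function(m, v) { m$dec[[1]]$conv1$K <- v; m },
         grad = g$dec[[1]]$conv1$K),
    list(get = function(m) m$final$K,
         set = function(m, v) { m$final$K <- v; m },
         grad = g$final$K))
  for (s in slots) {
    idx <- sample(length(s$grad), 4)
    for (i in idx) {
      up <- s$get(model); up[i] <- up[i] + eps
      dn <- s$get(model); dn[i] <- dn[i] - eps
      num <- (loss_at(s$set(model, up)) - loss_at(s$set(model, dn))) / (2 * eps)
      expect_equal(s$grad[i], num, tolerance = 1e-4)
    }
  }
})

test_that("training records every epoch and reduces loss on one image", {
  ds <- tiny_training_frames(5, n_pick = 1)
  model <- unet_init(base_channels = 4, depth = 2, seed = 2)
  cfg <- train_config(learning_rate = 0.02, epochs = 6, val_ratio = 0,
                      seed = 4)
  fit <- train_segmenter(model, ds, cfg)
  h <- tidy(fit)
  expect_equal(nrow(h), 6)
  expect_lt(h$train_loss[6], h$train_loss[1])
  expect_s3_class(glance(fit), "tbl_df")
})

test_that("an all-background dataset collapses to background predictions", {
  blank_ds <- lapply(1:4, function(i) {
    list(x = matrix(0, 32, 32), y = matrix(0L, 32, 32))
  })
  model <- unet_init(base_channels = 4, depth = 2, seed = 3)
  expect_warning(
    fit <- train_segmenter(model, blank_ds,
                           train_config(learning_rate = 0.05, epochs = 4,
                                        val_ratio = 0.5, seed = 1)),
    "touch class absent")
  pred <- unet_segment(fit, blank_ds[[1]]$x)
  expect_true(all(pred == 0L))
})

test_that("training selects the epoch with the best validation touch Dice", {
  ds <- tiny_training_frames(6, n_pick = 8)
  model <- unet_init(base_channels = 8, depth = 2, seed = 7)
  fit <- train_segmenter(model, ds, train_config(learning_rate = 0.02,
                                                 epochs = 25, seed = 2))
  h <- tidy(fit)
  best <- h$dice_touch_val[fit$best_epoch]
  expect_true(all(best >= h$dice_touch_val | is.na(h$dice_touch_val)))
  # trained model beats the untrained one (mean touch Dice over the set)
  mean_dice <- function(m) {
    mean(vapply(ds, function(s) {
      d <- dice_coefficient(unet_segment(m, s$x), s$y, class = 1)
      if (is.na(d)) 0 else d
    }, numeric(1)))
  }
  expect_gt(mean_dice(fit), mean_dice(model))
})

test_that("training is reproducible and weights round-trip through disk", {
  ds <- tiny_training_frames(9, n_pick = 3)
  run <- function() {
    train_segmenter(unet_init(base_channels = 4, depth = 2, seed = 11),
                    ds, train_config(learning_rate = 0.02, epochs = 3,
                                     seed = 5))
  }
  a <- run(); b <- run()
  expect_identical(tidy(a), tidy(b))
  expect_identical(a$model, b$model)

  path <- withr::local_tempfile(fileext = ".rds")
  save_weights(a, path)
  back <- load_weights(path)
  frame <- ds[[1]]$x
  expect_identical(unet_segment(back, frame), unet_segment(a, frame))
})
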