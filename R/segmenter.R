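#' Split a dataset into two seeded partitions
#'
#' Membership is determined by a seeded shuffle; the first partition gets
#' `round(ratio * n)` items (so 30 items at ratio 0.7 split 21 / 9).
#'
#' @param items a list or vector.
#' @param ratio fraction assigned to the first partition, in (0, 1).
#' @param seed integer seed.
#' @return A list with elements `first` and `second` (disjoint, union =
#'   `items`).
#' @export
split_dataset <- function(items, ratio = 0.7, seed = 1) {
  n <- length(items)
  if (n == 0L) stop("nothing to split", call. = FALSE)
  if (ratio <= 0 || ratio >= 1) stop("ratio must be in (0, 1)", call. = FALSE)
  ord <- with_preserved_seed(seed, sample.int(n))
  n1 <- round(ratio * n)
  list(first = items[ord[seq_len(n1)]],
       second = items[ord[setdiff(seq_len(n), seq_len(n1))]])
}

#' Training configuration for the U-net segmenter
#'
#' Defaults follow the full-scale recipe: learning rate 0.0005, 40 epochs,
#' pixel-wise multi-class cross-entropy, a 70/30 train/validation split.
#' The optimizer is stochastic gradient descent with momentum 0.9 (batch
#' size 1); both are configurable.
#'
#' @param learning_rate SGD learning rate (> 0).
#' @param epochs number of epochs (>= 1).
#' @param momentum SGD momentum coefficient.
#' @param val_ratio fraction of the dataset held out for validation.
#' @param seed integer seed for the split and the shuffling.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 5e-4, epochs = 40, momentum = 0.9,
                         val_ratio = 0.3, seed = 1) {
  stopifnot(learning_rate > 0, epochs >= 1, momentum >= 0, momentum < 1,
            val_ratio >= 0, val_ratio < 1)
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 momentum = momentum, val_ratio = val_ratio,
                 seed = as.integer(seed)),
            class = "train_config")
}

prepare_sample <- function(x, y, divisor) {
  H <- nrow(x); W <- ncol(x)
  X <- matrix(as.vector(x) / 255, H * W, 1)
  pd <- pad_reflect(X, H, W, divisor)
  list(X = pd$X, H = pd$H, W = pd$W, crop = pd$crop,
       labels = as.integer(as.vector(y)), oh = H, ow = W)
}

# mean over images of the per-class Dice between predicted and true labels;
# images where the class is absent from both are skipped
mean_class_dice <- function(preds, truths, class) {
  vals <- mapply(function(p, t) dice_coefficient(p, t, class = class),
                 preds, truths)
  if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
}

#' Train the U-net segmenter
#'
#' Per-sample stochastic gradient descent under pixel-wise cross-entropy.
#' The dataset is split into training and validation parts with
#' [split_dataset()] (seeded); every epoch shuffles the training order,
#' records training/validation loss and the mean per-class Dice of the
#' touch-point and human classes, and the returned weights are those of the
#' epoch with the highest validation touch-point Dice (ties resolved to the
#' earliest epoch). If the validation set contains no touch pixels at all,
#' selection falls back to the mean Dice over all classes, with a warning.
#'
#' @param model an initial [unet_init()] model.
#' @param dataset list of samples, each a list with elements `x` (difference
#'   frame, H x W matrix) and `y` (label matrix in {0, 1, 2}).
#' @param cfg a [train_config()].
#' @return A `unet_fit`: list with `model` (best weights), `history`
#'   (one-row-per-epoch tibble), `best_epoch`, `cfg`.
#' @export
train_segmenter <- function(model, dataset, cfg = train_config()) {
  stopifnot(inherits(model, "unet_model"), length(dataset) > 0)
  bad <- vapply(dataset, function(s) {
    !all(s$y %in% 0:(model$n_classes - 1))
  }, logical(1))
  if (any(bad)) stop("labels outside the class set", call. = FALSE)

  if (cfg$val_ratio > 0 && length(dataset) > 1) {
    sp <- split_dataset(dataset, ratio = 1 - cfg$val_ratio, seed = cfg$seed)
    train_set <- sp$first; val_set <- sp$second
  } else {
    train_set <- dataset; val_set <- list()
  }
  tr <- lapply(train_set, function(s) prepare_sample(s$x, s$y, model$divisor))
  va <- lapply(val_set, function(s) prepare_sample(s$x, s$y, model$divisor))
  tr_y <- lapply(train_set, `[[`, "y")
  va_y <- lapply(val_set, `[[`, "y")

  velocity <- zero_like(model)
  history <- vector("list", cfg$epochs)
  best <- list(epoch = NA_integer_, score = -Inf, model = model)
  no_touch_val <- length(va) > 0 &&
    !any(vapply(va_y, function(y) any(y == 1L), logical(1)))
  if (no_touch_val) {
    warning("touch class absent; selection falls back to mean Dice",
            call. = FALSE)
  }

  eval_logits <- function(s) {
    out <- unet_forward(model, s$X, s$H, s$W)
    lg <- out$logits
    if (!is.null(s$crop)) lg <- lg[s$crop, , drop = FALSE]
    lg
  }

  with_preserved_seed(cfg$seed + 1L, {
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample.int(length(tr))
      losses <- numeric(length(tr))
      tr_pred <- vector("list", length(tr))
      for (k in seq_along(ord)) {
        s <- tr[[ord[k]]]
        out <- unet_forward(model, s$X, s$H, s$W, keep_cache = TRUE)
        lg <- out$logits
        if (!is.null(s$crop)) lg <- lg[s$crop, , drop = FALSE]
        sc <- softmax_ce(lg, s$labels)
        losses[k] <- sc$loss
        tr_pred[[ord[k]]] <-
          matrix(max.col(sc$prob, ties.method = "first") - 1L, s$oh, s$ow)
        dl <- sc$dlogits
        if (!is.null(s$crop)) {
          full <- matrix(0, nrow(out$logits), ncol(out$logits))
          full[s$crop, ] <- dl
          dl <- full
        }
        grads <- unet_backward(model, out$cache, dl)
        st <- sgd_step(model, grads, velocity, cfg$learning_rate, cfg$momentum)
        model <- st$model; velocity <- st$velocity
      }

      val_loss <- NA_real_
      va_pred <- NULL
      if (length(va) > 0) {
        vl <- numeric(length(va))
        va_pred <- vector("list", length(va))
        for (k in seq_along(va)) {
          s <- va[[k]]
          lg <- eval_logits(s)
          sc <- softmax_ce(lg, s$labels)
          vl[k] <- sc$loss
          va_pred[[k]] <-
            matrix(max.col(sc$prob, ties.method = "first") - 1L, s$oh, s$ow)
        }
        val_loss <- mean(vl)
      }

      rec <- tibble::tibble(
        epoch = epoch,
        train_loss = mean(losses),
        val_loss = val_loss,
        dice_touch_train = mean_class_dice(tr_pred, tr_y, 1L),
        dice_human_train = mean_class_dice(tr_pred, tr_y, 2L),
        dice_touch_val = if (length(va)) mean_class_dice(va_pred, va_y, 1L)
                         else NA_real_,
        dice_human_val = if (length(va)) mean_class_dice(va_pred, va_y, 2L)
                         else NA_real_
      )
      history[[epoch]] <- rec

      score <- if (length(va) == 0) {
        # no validation set: latest weights win (score = epoch order)
        epoch
      } else if (no_touch_val || is.na(rec$dice_touch_val)) {
        mean(c(mean_class_dice(va_pred, va_y, 0L),
               rec$dice_touch_val, rec$dice_human_val), na.rm = TRUE)
      } else {
        rec$dice_touch_val
      }
      if (score > best$score) {
        best <- list(epoch = epoch, score = score, model = model)
      }
    }
  })

  structure(list(model = best$model, history = dplyr::bind_rows(history),
                 best_epoch = best$epoch, cfg = cfg),
            class = "unet_fit")
}

#' @export
print.unet_fit <- function(x, ...) {
  cat(sprintf("<unet_fit> %d epochs, best epoch %d\n",
              nrow(x$history), x$best_epoch))
  b <- x$history[x$best_epoch, ]
  cat(sprintf("  val loss %.4f, touch Dice %.3f, human Dice %.3f\n",
              b$val_loss, b$dice_touch_val, b$dice_human_val))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-epoch training records of a U-net fit
#'
#' @param x a `unet_fit`.
#' @param ... unused.
#' @return The epoch history tibble: losses and per-class Dice on training
#'   and validation sets.
#' @export
tidy.unet_fit <- function(x, ...) x$history

#' One-row summary of a U-net fit
#'
#' @param x a `unet_fit`.
#' @param ... unused.
#' @return A one-row tibble with the best epoch and its validation metrics.
#' @export
glance.unet_fit <- function(x, ...) {
  b <- x$history[x$best_epoch, ]
  tibble::tibble(epochs = nrow(x$history), best_epoch = x$best_epoch,
                 train_loss = b$train_loss, val_loss = b$val_loss,
                 dice_touch_val = b$dice_touch_val,
                 dice_human_val = b$dice_human_val)
}

#' Save / load U-net weights
#'
#' Single-file checkpoint carrying the weights together with an echo of the
#' architecture configuration; loading validates nothing beyond structure.
#'
#' @param fit a `unet_fit` or `unet_model`.
#' @param path checkpoint file path.
#' @return `save_weights` returns `path` invisibly; `load_weights` returns
#'   a `unet_model`.
#' @export
save_weights <- function(fit, path) {
  model <- if (inherits(fit, "unet_fit")) fit$model else fit
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_weights
#' @export
load_weights <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "unet_model"))
  model
}

#' Rule-based baseline segmenter
#'
#' A deterministic stand-in for the learned segmenter that encodes the
#' size prior directly: pixels at or above `intensity_threshold` are grouped
#' into 8-connected components; components with area at or above
#' `human_area_threshold` are labelled human-subject (2), smaller ones
#' touch-point (1), everything else background (0). Useful for exercising
#' the downstream pipeline without trained weights, and as a test oracle.
#'
#' @param frame an H x W difference frame.
#' @param intensity_threshold foreground threshold in intensity units.
#' @param human_area_threshold area (pixels) separating human-sized from
#'   touch-sized components.
#' @return An H x W integer label matrix in {0, 1, 2}.
#' @export
baseline_segment <- function(frame, intensity_threshold = 5,
                             human_area_threshold = 500) {
  stopifnot(intensity_threshold > 0, human_area_threshold > 0)
  fg <- matrix(as.integer(frame >= intensity_threshold),
               nrow(frame), ncol(frame))
  lab <- matrix(0L, nrow(frame), ncol(frame))
  for (r in extract_regions(fg, connectivity = 8)) {
    lab[r$pixels] <- if (r$area >= human_area_threshold) 2L else 1L
  }
  lab
}

#' Read a training manifest
#'
#' A manifest is a CSV with columns `diff_frame` and `label_map`, each row a
#' pair of image paths (difference frame, 8-bit PNG label map with values
#' {0, 1, 2}). Paths are resolved relative to the manifest location.
#'
#' @param path manifest CSV path.
#' @return A dataset list usable by [train_segmenter()].
#' @export
read_manifest <- function(path) {
  tab <- utils::read.csv(path)
  base <- dirname(path)
  resolve <- function(p) ifelse(grepl("^/", p), p, file.path(base, p))
  lapply(seq_len(nrow(tab)), function(i) {
    x <- read_gray_image(resolve(tab$diff_frame[i]))
    y <- read_gray_image(resolve(tab$label_map[i]))
    list(x = x, y = matrix(as.integer(round(y)), nrow(y), ncol(y)))
  })
}
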