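#' Initialise a U-net segmentation model
#'
#' An encoder-decoder convolutional network with skip connections: `depth`
#' resolution levels of double 3x3 convolutions with 2x2 max-pooling on the
#' way down, a double-convolution bottleneck, and nearest-neighbour
#' upsampling + convolution with skip concatenation on the way up, closed by
#' a 1x1 convolution onto the class scores. Channel width doubles per level
#' from `base_channels`. Weights are He-initialised from a seeded RNG.
#'
#' The default width (64 first-stage channels, depth 4) is the full-scale
#' configuration; `base_channels = 16` gives the width-reduced profile used
#' for fast experiments on small frames.
#'
#' @param in_channels input channels (1 for grayscale difference frames).
#' @param n_classes output classes (3: background, touch-point, human).
#' @param base_channels first-stage channel width.
#' @param depth number of pooling levels; inputs are reflect-padded to a
#'   multiple of `2^depth` and cropped back.
#' @param seed integer seed for weight initialisation.
#' @return A `unet_model` object.
#' @export
unet_init <- function(in_channels = 1, n_classes = 3, base_channels = 64,
                      depth = 4, seed = 1) {
  he_conv <- function(cin, cout) {
    list(K = matrix(stats::rnorm(9 * cin * cout, sd = sqrt(2 / (9 * cin))),
                    9 * cin, cout),
         b = rep(0, cout))
  }
  he_lin <- function(cin, cout) {
    list(K = matrix(stats::rnorm(cin * cout, sd = sqrt(2 / cin)), cin, cout),
         b = rep(0, cout))
  }
  with_preserved_seed(seed, {
    F <- base_channels
    enc <- vector("list", depth)
    cin <- in_channels
    for (i in seq_len(depth)) {
      cout <- F * 2^(i - 1)
      enc[[i]] <- list(conv1 = he_conv(cin, cout), conv2 = he_conv(cout, cout))
      cin <- cout
    }
    bott <- list(conv1 = he_conv(F * 2^(depth - 1), F * 2^depth),
                 conv2 = he_conv(F * 2^depth, F * 2^depth))
    dec <- vector("list", depth)
    for (i in rev(seq_len(depth))) {
      ci <- F * 2^i          # channels entering the level from below
      co <- F * 2^(i - 1)    # channels after the level
      dec[[i]] <- list(up = he_conv(ci, co),
                       conv1 = he_conv(2 * co, co),
                       conv2 = he_conv(co, co))
    }
    final <- he_lin(F, n_classes)
    structure(list(enc = enc, bottleneck = bott, dec = dec, final = final,
                   in_channels = in_channels, n_classes = n_classes,
                   base_channels = base_channels, depth = depth,
                   divisor = 2^depth),
              class = "unet_model")
  })
}

#' @export
print.unet_model <- function(x, ...) {
  n_par <- sum(vapply(rapply(x[c("enc", "bottleneck", "dec", "final")],
                             length, how = "unlist"), sum, numeric(1)))
  cat(sprintf(
    "<unet_model> depth %d, base %d channels, %d classes, ~%s parameters\n",
    x$depth, x$base_channels, x$n_classes, format(n_par, big.mark = ",")))
  invisible(x)
}

# reflect-pad an HW x C pixel matrix to (H+pb) x (W+pr); returns list with
# padded matrix, new dims, and the crop index back into the original
pad_reflect <- function(X, H, W, divisor) {
  Hp <- as.integer(ceiling(H / divisor) * divisor)
  Wp <- as.integer(ceiling(W / divisor) * divisor)
  if (Hp == H && Wp == W) {
    return(list(X = X, H = H, W = W, crop = NULL))
  }
  reflect <- function(n, np) {
    i <- seq_len(np) - 1L
    extra <- i >= n
    i[extra] <- 2L * n - 2L - i[extra]  # mirror without repeating the edge
    i + 1L
  }
  ri <- reflect(H, Hp); ci <- reflect(W, Wp)
  map <- as.vector(outer(ri, (ci - 1L) * H, `+`))
  crop <- as.vector(outer(seq_len(H), (seq_len(W) - 1L) * Hp, `+`))
  list(X = X[map, , drop = FALSE], H = Hp, W = Wp, crop = crop)
}

relu <- function(x) x * (x > 0)

# full forward pass; X is an HW x Cin pixel matrix at (H, W), already padded
# to the model divisor. Returns logits and (optionally) the cache backward
# needs: conv inputs, relu masks, pool argmaxes, per-level dims.
unet_forward <- function(model, X, H, W, keep_cache = FALSE) {
  cache <- list(enc = vector("list", model$depth), dims = list())
  skips <- vector("list", model$depth)
  h <- H; w <- W
  for (i in seq_len(model$depth)) {
    p <- model$enc[[i]]
    z1 <- .conv3x3_forward(X, h, w, p$conv1$K, p$conv1$b)
    a1 <- relu(z1)
    z2 <- .conv3x3_forward(a1, h, w, p$conv2$K, p$conv2$b)
    a2 <- relu(z2)
    pool <- .maxpool2_forward(a2, h, w)
    if (keep_cache) {
      cache$enc[[i]] <- list(X = X, a1 = a1, m1 = z1 > 0, m2 = z2 > 0,
                             pool_idx = pool$idx, h = h, w = w)
    }
    skips[[i]] <- a2
    X <- pool$Y
    h <- h %/% 2L; w <- w %/% 2L
  }
  p <- model$bottleneck
  z1 <- .conv3x3_forward(X, h, w, p$conv1$K, p$conv1$b)
  a1 <- relu(z1)
  z2 <- .conv3x3_forward(a1, h, w, p$conv2$K, p$conv2$b)
  a2 <- relu(z2)
  if (keep_cache) {
    cache$bottleneck <- list(X = X, a1 = a1, m1 = z1 > 0, m2 = z2 > 0,
                             h = h, w = w)
  }
  X <- a2
  cache$dec <- vector("list", model$depth)
  for (i in rev(seq_len(model$depth))) {
    p <- model$dec[[i]]
    up_in <- X
    u <- .upsample2_forward(X, h, w)
    h <- h * 2L; w <- w * 2L
    zu <- .conv3x3_forward(u, h, w, p$up$K, p$up$b)
    au <- relu(zu)
    cat_in <- cbind(au, skips[[i]])
    z1 <- .conv3x3_forward(cat_in, h, w, p$conv1$K, p$conv1$b)
    a1 <- relu(z1)
    z2 <- .conv3x3_forward(a1, h, w, p$conv2$K, p$conv2$b)
    a2 <- relu(z2)
    if (keep_cache) {
      cache$dec[[i]] <- list(up_in = up_in, u = u, mu = zu > 0,
                             cat_in = cat_in, a1 = a1,
                             m1 = z1 > 0, m2 = z2 > 0, h = h, w = w)
    }
    X <- a2
  }
  logits <- X %*% model$final$K +
    matrix(model$final$b, nrow(X), model$n_classes, byrow = TRUE)
  if (keep_cache) cache$pre_final <- X
  list(logits = logits, cache = if (keep_cache) cache else NULL)
}

# softmax cross-entropy over pixels; labels are an integer vector in
# {0, .., n_classes-1}; returns loss and dLogits
softmax_ce <- function(logits, labels) {
  n <- nrow(logits)
  m <- apply(logits, 1, max)
  e <- exp(logits - m)
  p <- e / rowSums(e)
  picked <- p[cbind(seq_len(n), labels + 1L)]
  loss <- -mean(log(pmax(picked, 1e-12)))
  onehot <- matrix(0, n, ncol(logits))
  onehot[cbind(seq_len(n), labels + 1L)] <- 1
  list(loss = loss, dlogits = (p - onehot) / n, prob = p)
}

# backward pass; returns gradients in the same nested shape as the model
unet_backward <- function(model, cache, dlogits) {
  g <- list(enc = vector("list", model$depth),
            dec = vector("list", model$depth))
  g$final <- list(K = t(cache$pre_final) %*% dlogits,
                  b = colSums(dlogits))
  dX <- dlogits %*% t(model$final$K)
  for (i in seq_len(model$depth)) {   # decoder levels, highest res first
    cc <- cache$dec[[i]]
    p <- model$dec[[i]]
    d2 <- dX * cc$m2
    b2 <- .conv3x3_backward(cc$a1, cc$h, cc$w, p$conv2$K, d2)
    d1 <- b2$dX * cc$m1
    b1 <- .conv3x3_backward(cc$cat_in, cc$h, cc$w, p$conv1$K, d1)
    co <- ncol(cc$a1)
    dau <- b1$dX[, seq_len(co), drop = FALSE] * cc$mu
    dskip <- b1$dX[, co + seq_len(ncol(b1$dX) - co), drop = FALSE]
    bu <- .conv3x3_backward(cc$u, cc$h, cc$w, p$up$K, dau)
    dbelow <- .upsample2_backward(bu$dX, cc$h %/% 2L, cc$w %/% 2L)
    g$dec[[i]] <- list(up = list(K = bu$dK, b = as.numeric(bu$db)),
                       conv1 = list(K = b1$dK, b = as.numeric(b1$db)),
                       conv2 = list(K = b2$dK, b = as.numeric(b2$db)))
    if (is.null(g$dskip)) g$dskip <- vector("list", model$depth)
    g$dskip[[i]] <- dskip
    dX <- dbelow
  }
  cc <- cache$bottleneck
  p <- model$bottleneck
  d2 <- dX * cc$m2
  b2 <- .conv3x3_backward(cc$a1, cc$h, cc$w, p$conv2$K, d2)
  d1 <- b2$dX * cc$m1
  b1 <- .conv3x3_backward(cc$X, cc$h, cc$w, p$conv1$K, d1)
  g$bottleneck <- list(conv1 = list(K = b1$dK, b = as.numeric(b1$db)),
                       conv2 = list(K = b2$dK, b = as.numeric(b2$db)))
  dX <- b1$dX
  for (i in rev(seq_len(model$depth))) {  # encoder levels, lowest res first
    cc <- cache$enc[[i]]
    p <- model$enc[[i]]
    dpool <- .maxpool2_backward(dX, cc$pool_idx, cc$h, cc$w)
    da2 <- dpool + g$dskip[[i]]
    d2 <- da2 * cc$m2
    b2 <- .conv3x3_backward(cc$a1, cc$h, cc$w, p$conv2$K, d2)
    d1 <- b2$dX * cc$m1
    b1 <- .conv3x3_backward(cc$X, cc$h, cc$w, p$conv1$K, d1)
    g$enc[[i]] <- list(conv1 = list(K = b1$dK, b = as.numeric(b1$db)),
                       conv2 = list(K = b2$dK, b = as.numeric(b2$db)))
    dX <- b1$dX
  }
  g$dskip <- NULL
  g
}

# walk two parameter trees applying f(param, grad) leaf-wise
map_params <- function(p, q, f) {
  if (is.list(p) && !is.null(names(p)) && all(c("K", "b") %in% names(p)) &&
      is.matrix(p$K)) {
    return(list(K = f(p$K, q$K), b = f(p$b, q$b)))
  }
  if (is.list(p)) {
    out <- p
    for (i in seq_along(p)) {
      if (is.list(p[[i]])) out[[i]] <- map_params(p[[i]], q[[i]], f)
    }
    return(out)
  }
  p
}

param_slots <- c("enc", "bottleneck", "dec", "final")

sgd_step <- function(model, grads, velocity, lr, momentum) {
  for (s in param_slots) {
    velocity[[s]] <- map_params(velocity[[s]], grads[[s]],
                                function(v, g) momentum * v + g)
    model[[s]] <- map_params(model[[s]], velocity[[s]],
                             function(p, v) p - lr * v)
  }
  list(model = model, velocity = velocity)
}

zero_like <- function(model) {
  out <- list()
  for (s in param_slots) {
    out[[s]] <- map_params(model[[s]], model[[s]], function(p, q) p * 0)
  }
  out
}

#' Segment a difference frame with a U-net model
#'
#' Reflect-pads the frame to the model's divisibility requirement, runs the
#' forward pass, crops back, and takes the per-pixel argmax over the
#' softmax-normalised class scores.
#'
#' @param model a `unet_model` or a fitted `unet_fit` (its best weights are
#'   used).
#' @param frame an H x W difference frame (numeric matrix).
#' @param return_prob also return the H x W x L probability array.
#' @return An H x W integer label matrix in {0, 1, 2} (with the probability
#'   array as attribute `prob` when requested).
#' @export
unet_segment <- function(model, frame, return_prob = FALSE) {
  if (inherits(model, "unet_fit")) model <- model$model
  stopifnot(inherits(model, "unet_model"))
  H <- nrow(frame); W <- ncol(frame)
  # inputs scaled to [0,1] so activations are in a sane range
  X <- matrix(as.vector(frame) / 255, H * W, 1)
  pd <- pad_reflect(X, H, W, model$divisor)
  out <- unet_forward(model, pd$X, pd$H, pd$W)
  logits <- out$logits
  if (!is.null(pd$crop)) logits <- logits[pd$crop, , drop = FALSE]
  m <- apply(logits, 1, max)
  e <- exp(logits - m)
  p <- e / rowSums(e)
  lab <- matrix(max.col(p, ties.method = "first") - 1L, H, W)
  if (return_prob) {
    attr(lab, "prob") <- array(p, c(H, W, model$n_classes))
  }
  lab
}
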