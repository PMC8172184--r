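# Brute-force reference implementations, written directly from the
# definitions and kept independent of the package internals. Used to
# cross-check accumulation, region extraction/merging and matching on
# small instances.

# per-pixel loop accumulation of touch labels
oracle_accumulate <- function(label_maps) {
  H <- nrow(label_maps[[1]]); W <- ncol(label_maps[[1]])
  counts <- matrix(0L, H, W)
  for (r in seq_len(H)) {
    for (c in seq_len(W)) {
      for (m in label_maps) {
        if (m[r, c] == 1L) counts[r, c] <- counts[r, c] + 1L
      }
    }
  }
  counts
}

# connected components by repeated neighbour scanning over all pixel pairs
oracle_components <- function(mask, connectivity = 8) {
  pix <- which(mask != 0, arr.ind = TRUE)
  n <- nrow(pix)
  if (n == 0) return(list())
  adjacent <- function(a, b) {
    dr <- abs(pix[a, 1] - pix[b, 1]); dc <- abs(pix[a, 2] - pix[b, 2])
    if (connectivity == 8) max(dr, dc) == 1 else dr + dc == 1
  }
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (a in seq_len(n)) for (b in seq_len(n)) {
      if (a != b && adjacent(a, b) && comp[b] != comp[a]) {
        new <- min(comp[a], comp[b])
        comp[comp == comp[a] | comp == comp[b]] <- new
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  lapply(unique(comp), function(k) pix[comp == k, , drop = FALSE])
}

oracle_region_summary <- function(pixels_rc) {
  rows <- pixels_rc[, 1] - 1  # to 0-based
  cols <- pixels_rc[, 2] - 1
  list(pixels_rc = pixels_rc, area = nrow(pixels_rc),
       centroid = c(mean(rows), mean(cols)),
       bbox = c(min(rows), min(cols), max(rows), max(cols)))
}

# literal region chain: components -> area filter -> transitive centroid
# grouping -> containment passes to fixed point
oracle_region_chain <- function(mask, tau1 = 100, tau2 = 30,
                                connectivity = 8) {
  regs <- lapply(oracle_components(mask, connectivity), oracle_region_summary)
  regs <- Filter(function(r) r$area >= tau1, regs)
  n <- length(regs)
  if (n > 1) {
    group <- seq_len(n)
    repeat {
      changed <- FALSE
      for (a in seq_len(n)) for (b in seq_len(n)) {
        if (a != b && group[a] != group[b] &&
            sqrt(sum((regs[[a]]$centroid - regs[[b]]$centroid)^2)) < tau2) {
          new <- min(group[a], group[b])
          group[group == group[a] | group == group[b]] <- new
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    regs <- lapply(unique(group), function(g) {
      oracle_region_summary(do.call(rbind, lapply(regs[group == g],
                                                  `[[`, "pixels_rc")))
    })
    # containment: a centroid inside another bbox merges the pair
    repeat {
      m <- length(regs)
      hit <- NULL
      if (m > 1) {
        for (a in seq_len(m)) {
          for (b in seq_len(m)) {
            if (a == b) next
            ca <- regs[[a]]$centroid; bb <- regs[[b]]$bbox
            if (ca[1] >= bb[1] && ca[1] <= bb[3] &&
                ca[2] >= bb[2] && ca[2] <= bb[4]) { hit <- c(a, b); break }
          }
          if (!is.null(hit)) break
        }
      }
      if (is.null(hit)) break
      merged <- oracle_region_summary(
        rbind(regs[[hit[1]]]$pixels_rc, regs[[hit[2]]]$pixels_rc))
      regs <- c(regs[-hit], list(merged))
    }
  }
  regs
}

# canonical form for comparing region sets regardless of ordering
canon_regions <- function(regs, from_oracle = FALSE) {
  keys <- lapply(regs, function(r) {
    if (from_oracle) {
      px <- (r$pixels_rc[, 2] - 1) * 10000 + (r$pixels_rc[, 1] - 1)
    } else {
      idx <- r$pixels - 1
      px <- (idx %/% r$height) * 10000 + (idx %% r$height)
    }
    paste(sort(px), collapse = ",")
  })
  sort(unlist(keys))
}

# optimal one-to-one assignment by exhaustive enumeration: maximise the
# number of matched pairs under the distance threshold, then minimise the
# total distance
oracle_match_tp <- function(pred_cent, label_cent, tau3) {
  np <- nrow(pred_cent); nl <- nrow(label_cent)
  if (np == 0 || nl == 0) return(0L)
  d <- outer(seq_len(np), seq_len(nl), Vectorize(function(i, j) {
    sqrt(sum((pred_cent[i, ] - label_cent[j, ])^2))
  }))
  best <- 0L
  assign_rec <- function(i, used_l, tp) {
    if (i > np) { best <<- max(best, tp); return(invisible()) }
    assign_rec(i + 1L, used_l, tp)  # leave pred i unmatched
    for (j in seq_len(nl)) {
      if (!used_l[j] && d[i, j] < tau3) {
        used_l[j] <- TRUE
        assign_rec(i + 1L, used_l, tp + 1L)
        used_l[j] <- FALSE
      }
    }
  }
  assign_rec(1L, rep(FALSE, nl), 0L)
  best
}

# seeded random binary mask with a few blobs, for property tests
random_blob_mask <- function(H, W, n_blobs, seed) {
  set.seed(seed)
  mask <- matrix(0L, H, W)
  for (i in seq_len(n_blobs)) {
    r0 <- sample.int(H, 1); c0 <- sample.int(W, 1)
    rad <- sample(1:4, 1)
    rr <- pmax(1, r0 - rad):pmin(H, r0 + rad)
    cc <- pmax(1, c0 - rad):pmin(W, c0 + rad)
    mask[rr, cc] <- 1L
  }
  mask
}
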