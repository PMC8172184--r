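#' Region post-processing parameters
#'
#' Thresholds governing which connected touch regions survive as "effective
#' touch-points": `tau1_area` removes small speckle regions (area below 100
#' square pixels), `tau2_cluster` groups regions whose centroids are close
#' (within 30 pixels), and `tau3_match` is the centroid distance (30 pixels)
#' under which a prediction matches a labelled touch-point at evaluation.
#'
#' @param tau1_area area threshold, square pixels.
#' @param tau2_cluster centroid grouping distance, pixels.
#' @param tau3_match evaluation matching distance, pixels.
#' @param connectivity pixel connectivity for component extraction, 4 or 8.
#' @return A `region_params` list.
#' @export
region_params <- function(tau1_area = 100, tau2_cluster = 30,
                          tau3_match = 30, connectivity = 8) {
  stopifnot(tau1_area >= 0, tau2_cluster >= 0, tau3_match >= 0,
            connectivity %in% c(4, 8))
  structure(list(tau1_area = tau1_area, tau2_cluster = tau2_cluster,
                 tau3_match = tau3_match, connectivity = connectivity),
            class = "region_params")
}

# internal region representation: pixels are 1-based column-major linear
# indices into an H x W grid; all reported coordinates are 0-based (row, col)
new_region <- function(pixels, height, width) {
  pixels <- sort(unique(as.integer(pixels)))
  idx <- pixels - 1L
  rows <- idx %% height
  cols <- idx %/% height
  list(pixels = pixels, height = height, width = width,
       area = length(pixels),
       centroid = c(mean(rows), mean(cols)),
       bbox = c(row_min = min(rows), col_min = min(cols),
                row_max = max(rows), col_max = max(cols)))
}

# merge diagonal-adjacent 4-connected labels into 8-connected ones via
# union-find over the (small) label graph
merge_diagonal_labels <- function(lab) {
  H <- nrow(lab); W <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-H, -W]), as.vector(lab[-1, -1])),  # down-right
    cbind(as.vector(lab[-1, -W]), as.vector(lab[-H, -1]))   # up-right
  )
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2],
                 , drop = FALSE]
  n <- max(lab)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (k in seq_len(nrow(pairs))) {
    a <- find(pairs[k, 1]); b <- find(pairs[k, 2])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  root <- vapply(seq_len(n), find, integer(1))
  remap <- c(0L, match(root, sort(unique(root))))
  matrix(remap[lab + 1L], H, W)
}

#' Extract connected touch regions from a binary mask
#'
#' Maximal connected components of 1-pixels, returned in raster order of
#' their top-left (first column-major) pixel. 8-connectivity is the default:
#' thermal blobs are diffuse, and diagonal splits of one signature are
#' artefacts.
#'
#' @param mask binary H x W matrix (a touch mask).
#' @param connectivity 4 or 8.
#' @return A list of regions; see [region_table()] for a tabular view.
#' @export
extract_regions <- function(mask, connectivity = 8) {
  stopifnot(connectivity %in% c(4, 8))
  m <- matrix(as.numeric(unclass(mask) != 0), nrow(mask), ncol(mask))
  if (!any(m > 0)) return(list())
  lab <- EBImage::bwlabel(m)
  if (connectivity == 8) lab <- merge_diagonal_labels(lab)
  ids <- sort(unique(lab[lab > 0]))
  px <- split(which(lab > 0), lab[lab > 0])
  regions <- lapply(ids, function(i) {
    new_region(px[[as.character(i)]], nrow(m), ncol(m))
  })
  # raster order of the first (column-major) member pixel
  first <- vapply(regions, function(r) r$pixels[1], integer(1))
  regions[order(first)]
}

#' Remove regions below the area threshold
#'
#' Keeps exactly the regions with `area >= tau1_area` (inclusive boundary:
#' a region of exactly the threshold area is kept), preserving order.
#'
#' @param regions list of regions.
#' @param tau1_area area threshold in square pixels (default 100).
#' @return The filtered region list.
#' @export
remove_small_regions <- function(regions, tau1_area = 100) {
  Filter(function(r) r$area >= tau1_area, regions)
}

# single-linkage components of an undirected adjacency matrix
adjacency_groups <- function(adj) {
  n <- nrow(adj)
  group <- integer(n); g <- 0L
  for (i in seq_len(n)) {
    if (group[i] > 0L) next
    g <- g + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (group[v] > 0L) next
      group[v] <- g
      queue <- c(queue, which(adj[v, ] & group == 0L))
    }
  }
  group
}

merge_group <- function(regions) {
  if (length(regions) == 1L) return(regions[[1]])
  new_region(unlist(lapply(regions, `[[`, "pixels")),
             regions[[1]]$height, regions[[1]]$width)
}

#' Group nearby touch regions into effective touch-points
#'
#' Two-stage merging: (a) regions whose centroids lie strictly closer than
#' `tau2_cluster` pixels are grouped transitively (single linkage) and each
#' group is replaced by one region whose pixel set is the union, whose
#' bounding box is the componentwise min/max, and whose centroid is
#' recomputed from the union; (b) a containment pass — whenever one region's
#' centroid falls inside another's bounding box the two are merged —
#' iterated to a fixed point.
#'
#' @param regions list of regions.
#' @param tau2_cluster centroid grouping distance in pixels (default 30).
#' @return The merged region list, in raster order of first pixel.
#' @export
merge_touch_regions <- function(regions, tau2_cluster = 30) {
  n <- length(regions)
  if (n <= 1L) return(regions)

  cent <- t(vapply(regions, `[[`, numeric(2), "centroid"))
  d <- as.matrix(stats::dist(cent))
  adj <- d < tau2_cluster
  diag(adj) <- TRUE
  groups <- adjacency_groups(adj)
  merged <- lapply(split(regions, groups), merge_group)

  # containment pass to fixed point
  repeat {
    m <- length(merged)
    if (m <= 1L) break
    cent <- t(vapply(merged, `[[`, numeric(2), "centroid"))
    bb <- t(vapply(merged, `[[`, numeric(4), "bbox"))
    hit <- NULL
    for (i in seq_len(m)) {
      inside <- cent[i, 1] >= bb[, 1] & cent[i, 1] <= bb[, 3] &
        cent[i, 2] >= bb[, 2] & cent[i, 2] <= bb[, 4]
      inside[i] <- FALSE
      j <- which(inside)[1]
      if (!is.na(j)) { hit <- c(i, j); break }
    }
    if (is.null(hit)) break
    keep <- setdiff(seq_len(m), hit)
    merged <- c(merged[keep], list(merge_group(merged[hit])))
  }

  first <- vapply(merged, function(r) r$pixels[1], integer(1))
  unname(merged[order(first)])
}

#' Tabulate regions
#'
#' @param regions list of regions.
#' @param cmap optional cumulative map; adds `max_count` (peak accumulated
#'   frames inside the region) and `min_duration_s`.
#' @param fps frame rate used for `min_duration_s`.
#' @return A tibble with one row per region: bounding box, centroid, area,
#'   and optionally duration summaries. Coordinates are 0-based (row, col).
#' @export
region_table <- function(regions, cmap = NULL, fps = 15) {
  if (length(regions) == 0L) {
    out <- tibble::tibble(region_id = integer(0),
                          row_min = numeric(0), col_min = numeric(0),
                          row_max = numeric(0), col_max = numeric(0),
                          centroid_row = numeric(0), centroid_col = numeric(0),
                          area_px = integer(0))
    if (!is.null(cmap)) {
      out$max_count <- integer(0); out$min_duration_s <- numeric(0)
    }
    return(out)
  }
  out <- purrr::map_dfr(seq_along(regions), function(i) {
    r <- regions[[i]]
    tibble::tibble(region_id = i,
                   row_min = r$bbox[["row_min"]], col_min = r$bbox[["col_min"]],
                   row_max = r$bbox[["row_max"]], col_max = r$bbox[["col_max"]],
                   centroid_row = r$centroid[1], centroid_col = r$centroid[2],
                   area_px = r$area)
  })
  if (!is.null(cmap)) {
    counts <- unclass(cmap)
    out$max_count <- vapply(regions, function(r) max(counts[r$pixels]),
                            numeric(1))
    out$min_duration_s <- min_duration_seconds(out$max_count, fps)
  }
  out
}
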