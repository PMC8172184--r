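#' Match predicted touch regions to labelled touch-points
#'
#' Greedy nearest-first one-to-one matching on centroid distance: all
#' candidate (prediction, label) pairs with distance strictly below
#' `tau3_match` are sorted by ascending distance (ties broken by lower
#' prediction id, then lower label id) and accepted whenever both endpoints
#' are still unused. Unmatched predictions are false positives, unmatched
#' labels false negatives. True negatives are not defined for region-level
#' detection and are never computed.
#'
#' @param preds predicted regions: a region list from [extract_regions()] /
#'   [merge_touch_regions()], or a tibble with `centroid_row`/`centroid_col`
#'   columns.
#' @param labels labelled touch-points: same forms as `preds`, or a
#'   bounding-box tibble with `row_min`, `col_min`, `row_max`, `col_max`
#'   columns (the box centre is used as its centroid).
#' @param tau3_match matching distance threshold in pixels (default 30).
#' @return A `match_result`: list with `pairs` (tibble of `pred_id`,
#'   `label_id`, `distance`), and counts `TP`, `FP`, `FN`.
#' @export
match_regions <- function(preds, labels, tau3_match = 30) {
  pc <- region_centroids(preds)
  lc <- region_centroids(labels)
  np <- nrow(pc); nl <- nrow(lc)

  pairs <- tibble::tibble(pred_id = integer(0), label_id = integer(0),
                          distance = numeric(0))
  if (np > 0 && nl > 0) {
    d <- outer(seq_len(np), seq_len(nl), Vectorize(function(i, j) {
      sqrt(sum((pc[i, ] - lc[j, ])^2))
    }))
    cand <- which(d < tau3_match, arr.ind = TRUE)
    if (nrow(cand) > 0) {
      dist <- d[cand]
      ord <- order(dist, cand[, 1], cand[, 2])
      used_p <- logical(np); used_l <- logical(nl)
      for (k in ord) {
        i <- cand[k, 1]; j <- cand[k, 2]
        if (!used_p[i] && !used_l[j]) {
          used_p[i] <- TRUE; used_l[j] <- TRUE
          pairs <- dplyr::bind_rows(pairs, tibble::tibble(
            pred_id = as.integer(unname(i)), label_id = as.integer(unname(j)),
            distance = unname(dist[k])))
        }
      }
    }
  }
  structure(list(pairs = pairs,
                 TP = nrow(pairs), FP = np - nrow(pairs),
                 FN = nl - nrow(pairs)),
            class = "match_result")
}

region_centroids <- function(x) {
  if (is.data.frame(x)) {
    if (all(c("centroid_row", "centroid_col") %in% names(x))) {
      return(cbind(x$centroid_row, x$centroid_col))
    }
    if (all(c("row_min", "col_min", "row_max", "col_max") %in% names(x))) {
      return(cbind((x$row_min + x$row_max) / 2, (x$col_min + x$col_max) / 2))
    }
    stop("cannot locate centroids in data frame", call. = FALSE)
  }
  if (length(x) == 0L) return(matrix(numeric(0), 0, 2))
  t(vapply(x, `[[`, numeric(2), "centroid"))
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> TP %d, FP %d, FN %d\n", x$TP, x$FP, x$FN))
  invisible(x)
}

#' Pool confusion counts across videos
#'
#' @param results list of [match_regions()] results.
#' @return A `match_result` with elementwise-summed TP/FP/FN (pairs dropped).
#' @export
aggregate_matches <- function(results) {
  structure(list(
    pairs = NULL,
    TP = sum(vapply(results, `[[`, numeric(1), "TP")),
    FP = sum(vapply(results, `[[`, numeric(1), "FP")),
    FN = sum(vapply(results, `[[`, numeric(1), "FN"))
  ), class = "match_result")
}

#' Detection metrics from confusion counts
#'
#' Precision TP/(TP+FP), recall TP/(TP+FN), F1 = 2PR/(P+R), false negative
#' rate FN/(TP+FN) = 1 - recall, and false discovery rate FP/(TP+FP) =
#' 1 - precision. Any 0/0 is reported as `NA` (undefined), never silently 0.
#'
#' @param m a `match_result`, or anything with `TP`, `FP`, `FN` fields.
#' @return A one-row tibble: `TP`, `FP`, `FN`, `precision`, `recall`, `f1`,
#'   `fnr`, `fdr`, all rates as fractions in \[0, 1\].
#' @export
detection_metrics <- function(m) {
  tp <- m$TP; fp <- m$FP; fn <- m$FN
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  tibble::tibble(TP = tp, FP = fp, FN = fn,
                 precision = precision, recall = recall, f1 = f1,
                 fnr = if (is.na(recall)) NA_real_ else 1 - recall,
                 fdr = if (is.na(precision)) NA_real_ else 1 - precision)
}

#' Dice similarity coefficient
#'
#' `2 |A intersect B| / (|A| + |B|)` between two binary masks, or between one
#' class of two label maps when `class` is given. When both masks are empty
#' the coefficient is undefined and `NA` is returned (documented convention,
#' never silently 0 or 1).
#'
#' @param a,b binary masks (or label maps with `class`), same dimensions.
#' @param class optional class value; masks become `a == class`, `b == class`.
#' @return A fraction in \[0, 1\], or `NA` if both masks are empty.
#' @export
dice_coefficient <- function(a, b, class = NULL) {
  if (!all(dim(a) == dim(b))) stop("shape mismatch", call. = FALSE)
  if (!is.null(class)) {
    a <- a == class
    b <- b == class
  } else {
    a <- a != 0
    b <- b != 0
  }
  tot <- sum(a) + sum(b)
  if (tot == 0) return(NA_real_)
  2 * sum(a & b) / tot
}

#' Read labelled touch boxes
#'
#' Ground-truth boxes in a flat CSV table with columns `video_id`,
#' `label_id`, `row_min`, `col_min`, `row_max`, `col_max`.
#'
#' @param path CSV file path.
#' @return A tibble of boxes.
#' @export
read_label_boxes <- function(path) {
  tibble::as_tibble(utils::read.csv(path))
}

#' Format a metrics report
#'
#' Percentages to one decimal place, per video plus the pooled aggregate.
#'
#' @param per_video named list of `match_result`s (names are video ids).
#' @return A tibble with one row per video and one `aggregate` row; rate
#'   columns in percent.
#' @export
metrics_report <- function(per_video) {
  rows <- purrr::imap_dfr(per_video, function(m, id) {
    dplyr::mutate(detection_metrics(m), video_id = id, .before = 1)
  })
  agg <- dplyr::mutate(detection_metrics(aggregate_matches(per_video)),
                       video_id = "aggregate", .before = 1)
  out <- dplyr::bind_rows(rows, agg)
  dplyr::mutate(out, dplyr::across(
    c("precision", "recall", "f1", "fnr", "fdr"),
    ~ round(100 * .x, 1)))
}
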