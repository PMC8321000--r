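#' Match detections against ground-truth nodules
#'
#' Matching is per slice, greedy nearest-first and one-to-one: a detection is
#' a true positive when its center lies within `match_radius` of a still
#' unmatched truth center on the same slice. Unmatched detections are false
#' positives and unmatched truths false negatives. Candidates classified
#' `non_nodule` (passed via `rejected`) with no truth center within
#' `match_radius` count as true negatives; rejected candidates near a truth
#' are not double counted -- the miss is already recorded by the unmatched
#' truth.
#'
#' @param detections Data frame with `slice_index`, `center_r`, `center_c`
#'   (predicted nodules).
#' @param truth Data frame with `slice_index`, `center_r`, `center_c`
#'   (ground-truth nodules, one row per slice occurrence).
#' @param match_radius Matching tolerance in pixels.
#' @param rejected Optional data frame of candidates classified non-nodule,
#'   same columns as `detections`.
#' @return List of counts `TP`, `FP`, `FN`, `TN`.
#' @export
match_detections <- function(detections, truth, match_radius = 5,
                             rejected = NULL) {
  det <- detections
  tp <- 0L
  matched_det <- logical(NROW(det))
  matched_tru <- logical(NROW(truth))
  if (NROW(det) > 0L && NROW(truth) > 0L) {
    pairs <- do.call(rbind, lapply(seq_len(NROW(det)), function(i) {
      j <- which(truth$slice_index == det$slice_index[i] & !is.na(truth$center_r))
      if (length(j) == 0L) return(NULL)
      d <- sqrt((truth$center_r[j] - det$center_r[i])^2 +
                (truth$center_c[j] - det$center_c[i])^2)
      ok <- d <= match_radius
      if (!any(ok)) return(NULL)
      data.frame(det = i, tru = j[ok], dist = d[ok])
    }))
    if (!is.null(pairs) && nrow(pairs) > 0L) {
      pairs <- pairs[order(pairs$dist, pairs$det, pairs$tru), , drop = FALSE]
      for (k in seq_len(nrow(pairs))) {
        i <- pairs$det[k]; j <- pairs$tru[k]
        if (!matched_det[i] && !matched_tru[j]) {
          matched_det[i] <- TRUE
          matched_tru[j] <- TRUE
          tp <- tp + 1L
        }
      }
    }
  }
  fp <- sum(!matched_det)
  fn <- sum(!matched_tru)
  tn <- 0L
  if (!is.null(rejected) && NROW(rejected) > 0L) {
    for (i in seq_len(NROW(rejected))) {
      j <- which(truth$slice_index == rejected$slice_index[i])
      near <- length(j) > 0L &&
        any(sqrt((truth$center_r[j] - rejected$center_r[i])^2 +
                 (truth$center_c[j] - rejected$center_c[i])^2) <= match_radius)
      if (!near) tn <- tn + 1L
    }
  }
  list(TP = tp, TN = tn, FP = as.integer(fp), FN = as.integer(fn))
}

safe_ratio <- function(num, den) if (den == 0) 0 else num / den

#' Detection metrics from confusion counts
#'
#' Computes sensitivity (recall) `TP/(TP+FN)`, specificity `TN/(TN+FP)`,
#' precision `TP/(TP+FP)`, accuracy `(TP+TN)/(TP+TN+FP+FN)`, the F-beta score
#' `(1+beta^2) P R / (beta^2 P + R)`, the Matthews correlation coefficient,
#' and the detection-burden rates FPI `= FP / n_images` and FPE
#' `= FP / n_exams`. Any metric whose denominator is zero is reported as 0
#' and listed in the `degenerate` field; MCC is 0 whenever a marginal sum is
#' zero.
#'
#' @param counts List or vector with `TP`, `TN`, `FP`, `FN` (all >= 0).
#' @param beta Recall weight of the F score; the reported default is 0.5.
#' @param n_images Number of images (slices) evaluated.
#' @param n_exams Number of exams (scans) evaluated.
#' @return A `metric_report` list with the eight metrics, the counts, `beta`,
#'   `n_images`, `n_exams` and `degenerate` (names of zero-denominator
#'   metrics).
#' @export
compute_metrics <- function(counts, beta = 0.5, n_images = 1L, n_exams = 1L) {
  tp <- counts[["TP"]]; tn <- counts[["TN"]]
  fp <- counts[["FP"]]; fn <- counts[["FN"]]
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0, tp + tn + fp + fn >= 1,
            beta > 0, n_images >= 1, n_exams >= 1)
  degenerate <- character(0)
  note <- function(name, den) {
    if (den == 0) degenerate <<- c(degenerate, name)
    invisible(NULL)
  }
  note("sensitivity", tp + fn)
  note("specificity", tn + fp)
  note("precision", tp + fp)
  sens <- safe_ratio(tp, tp + fn)
  spec <- safe_ratio(tn, tn + fp)
  prec <- safe_ratio(tp, tp + fp)
  acc <- safe_ratio(tp + tn, tp + tn + fp + fn)
  fden <- beta^2 * prec + sens
  note("f_beta", fden)
  fbeta <- safe_ratio((1 + beta^2) * prec * sens, fden)
  marg <- c(tp + fp, tp + fn, tn + fp, tn + fn)
  mcc <- if (any(marg == 0)) {
    degenerate <- c(degenerate, "mcc")
    0
  } else (tp * tn - fp * fn) / sqrt(prod(marg))
  structure(list(sensitivity = sens, specificity = spec, precision = prec,
                 accuracy = acc, f_beta = fbeta, beta = beta, mcc = mcc,
                 fpi = fp / n_images, fpe = fp / n_exams,
                 counts = list(TP = tp, TN = tn, FP = fp, FN = fn),
                 n_images = n_images, n_exams = n_exams,
                 degenerate = unique(degenerate)),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf(
    "Detection metrics (TP=%d TN=%d FP=%d FN=%d; %d images, %d exams)\n",
    x$counts$TP, x$counts$TN, x$counts$FP, x$counts$FN, x$n_images, x$n_exams))
  cat(sprintf("  sensitivity %.4f  specificity %.4f  precision %.4f\n",
              x$sensitivity, x$specificity, x$precision))
  cat(sprintf("  accuracy    %.4f  F%.1f        %.4f  MCC       %.4f\n",
              x$accuracy, x$beta, x$f_beta, x$mcc))
  cat(sprintf("  FPI %.4f  FPE %.4f\n", x$fpi, x$fpe))
  if (length(x$degenerate))
    cat("  zero-denominator metrics reported as 0:",
        paste(x$degenerate, collapse = ", "), "\n")
  invisible(x)
}

#' Read or write ground-truth nodule annotations (JSON lines)
#'
#' One object per line: `{"exam_id": ..., "slice_index": j,
#' "center": [r, c], "radius_px": r}`.
#'
#' @param path File path.
#' @return `read_ground_truth` returns a data frame with columns `exam_id`,
#'   `slice_index`, `center_r`, `center_c`, `radius_px`.
#' @export
read_ground_truth <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  rows <- lapply(lines, function(l) {
    x <- jsonlite::fromJSON(l)
    data.frame(exam_id = as.character(x$exam_id),
               slice_index = as.integer(x$slice_index),
               center_r = as.numeric(x$center[1]),
               center_c = as.numeric(x$center[2]),
               radius_px = as.numeric(x$radius_px))
  })
  do.call(rbind, rows)
}

#' @rdname read_ground_truth
#' @param truth Data frame in the same column layout.
#' @export
write_ground_truth <- function(truth, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(NROW(truth))) {
    writeLines(jsonlite::toJSON(list(
      exam_id = truth$exam_id[i], slice_index = truth$slice_index[i],
      center = c(truth$center_r[i], truth$center_c[i]),
      radius_px = truth$radius_px[i]), auto_unbox = TRUE, digits = NA), con)
  }
  invisible(NULL)
}
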