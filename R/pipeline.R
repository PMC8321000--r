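#' Pipeline configuration
#'
#' Every tunable of the CAD pipeline with its default. Defaults follow the
#' reported operating point where one exists: histogram step `kappa = 5`,
#' region-growing `max_intensity_distance = 0.18`, consistency half-window
#' `k = 1` (window of size 3), 3 x 3 median filtering, and F-score weight
#' `beta = 0.5`.
#'
#' @param kappa Histogram bin step (intensity units).
#' @param smooth_width Odd moving-average width applied to histogram counts
#'   before the minima scan; 1 = no smoothing.
#' @param min_area Minimum lung-mask component area (pixels).
#' @param dilation_radius Disc radius of the mask dilation (pixels).
#' @param fill_holes Fill interior mask holes before dilating.
#' @param circ_min Minimum candidate circularity in `(0, 1]`.
#' @param min_candidate_area Minimum candidate component area (pixels).
#' @param max_intensity_distance Region-growing similarity bound on
#'   `[0, 1]`-normalized intensities.
#' @param k Consistency half-window: neighbours `j-k..j+k` are searched.
#' @param match_radius Consistency match tolerance in pixels; `NULL` uses
#'   `max(3, equivalent_diameter / 2)` per candidate.
#' @param consistency_mode How the consistency bit enters classification:
#'   `"feature"`, `"filter"` or `"both"` (see [classify_candidates()]).
#' @param eval_match_radius Detection-to-truth matching tolerance (pixels).
#' @param beta F-score recall weight.
#' @param svm_cost SVM regularization constant.
#' @param seed RNG seed for training.
#' @return A `cad_config` list.
#' @export
cad_config <- function(kappa = 5L, smooth_width = 1L, min_area = 50L,
                       dilation_radius = 2L, fill_holes = TRUE,
                       circ_min = 0.6, min_candidate_area = 9L,
                       max_intensity_distance = 0.18, k = 1L,
                       match_radius = NULL, consistency_mode = "feature",
                       eval_match_radius = 5, beta = 0.5, svm_cost = 1,
                       seed = 1L) {
  structure(list(kappa = kappa, smooth_width = smooth_width,
                 min_area = min_area, dilation_radius = dilation_radius,
                 fill_holes = fill_holes, circ_min = circ_min,
                 min_candidate_area = min_candidate_area,
                 max_intensity_distance = max_intensity_distance, k = k,
                 match_radius = match_radius,
                 consistency_mode = consistency_mode,
                 eval_match_radius = eval_match_radius, beta = beta,
                 svm_cost = svm_cost, seed = seed),
            class = "cad_config")
}

as_cad_config <- function(x) {
  if (inherits(x, "cad_config")) return(x)
  if (is.list(x)) return(do.call(cad_config, x))
  stop("params must be a cad_config or a list of overrides", call. = FALSE)
}

#' Segment, detect and featurize all candidates of one exam
#'
#' Runs [segment_lungs()] and [detect_candidates()] on every slice, computes
#' the across-slice consistency bit of every candidate over the `k`-slice
#' window, and assembles the per-candidate feature vectors.
#'
#' @param stack A `slice_stack`.
#' @param config A [cad_config()].
#' @return List with `candidates` (one data frame row per candidate: indices,
#'   center, shape and the six features), `regions` (list of
#'   `candidate_region`), and `thresholds` (per-slice `lambda`, `tau`,
#'   `lambda_source`).
#' @export
detect_exam <- function(stack, config = cad_config()) {
  cfg <- as_cad_config(config)
  m <- length(stack$slices)
  per_slice <- vector("list", m)
  thresholds <- vector("list", m)
  for (j in seq_len(m)) {
    sl <- stack$slices[[j]]
    seg <- suppressWarnings(segment_lungs(sl, cfg))
    thresholds[[j]] <- data.frame(slice_index = j,
                                  lambda = seg$thresholds$lambda,
                                  tau = seg$thresholds$tau,
                                  lambda_source = seg$thresholds$lambda_source)
    per_slice[[j]] <- list(cands = detect_candidates(sl, seg, cfg),
                           lung_image = seg$lung_image)
  }
  centers_of <- function(j) {
    if (j < 1L || j > m) return(NULL)
    cs <- lapply(per_slice[[j]]$cands, function(x) x$candidate)
    if (length(cs) == 0L) return(NULL)
    do.call(rbind, cs)
  }
  rows <- list()
  regions <- list()
  for (j in seq_len(m)) {
    for (cand in per_slice[[j]]$cands) {
      cd <- cand$candidate
      radius <- if (is.null(cfg$match_radius))
        max(3, cd$equivalent_diameter / 2) else cfg$match_radius
      nb <- lapply(setdiff((j - cfg$k):(j + cfg$k), j), centers_of)
      t <- consistency_feature(c(cd$center_r, cd$center_c), nb, radius)
      fv <- build_feature_vector(cand$region, t, per_slice[[j]]$lung_image)
      rows[[length(rows) + 1L]] <- cbind(cd, as.data.frame(as.list(fv)))
      regions[[length(regions) + 1L]] <- cand$region
    }
  }
  cand_df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(slice_index = integer(0), center_r = integer(0),
               center_c = integer(0), area = numeric(0),
               circularity = numeric(0), equivalent_diameter = numeric(0),
               mean = numeric(0), median = numeric(0), mode = numeric(0),
               variance = numeric(0), sd = numeric(0), consistency = numeric(0))
  rownames(cand_df) <- NULL
  list(candidates = cand_df, regions = regions,
       thresholds = do.call(rbind, thresholds))
}

#' Label detected candidates against planted ground truth
#'
#' A candidate is labelled `"nodule"` when its center lies within
#' `radius_px + 2` pixels of a ground-truth nodule center on the same slice,
#' else `"non_nodule"`. Used to build SVM training sets from phantom exams.
#'
#' @param candidates Candidate data frame from [detect_exam()].
#' @param truth_nodules Ground-truth data frame (`slice_index`, `center_r`,
#'   `center_c`, `radius_px`).
#' @return Character vector of labels.
#' @export
label_candidates <- function(candidates, truth_nodules) {
  vapply(seq_len(NROW(candidates)), function(i) {
    j <- which(truth_nodules$slice_index == candidates$slice_index[i])
    if (length(j) == 0L) return("non_nodule")
    d <- sqrt((truth_nodules$center_r[j] - candidates$center_r[i])^2 +
              (truth_nodules$center_c[j] - candidates$center_c[i])^2)
    if (any(d <= truth_nodules$radius_px[j] + 2)) "nodule" else "non_nodule"
  }, character(1))
}

write_jsonl <- function(rows, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (r in rows)
    writeLines(jsonlite::toJSON(r, auto_unbox = TRUE, digits = NA), con)
  invisible(NULL)
}

#' Run the full CAD pipeline on one exam
#'
#' Per slice: lung segmentation and candidate detection; per exam:
#' consistency features over the slice window, SVM classification, and --
#' when ground truth is supplied -- detection matching and the metric report.
#' Every automatically chosen threshold (lambda, tau per slice) is part of
#' the result and of the written log. The run is fully automatic and
#' deterministic: no interactive input is read at any stage.
#'
#' @param exam A `slice_stack`, or a directory readable by [load_series()].
#' @param model A trained `nodule_classifier` (or path to one saved with
#'   [save_classifier()]).
#' @param config A [cad_config()].
#' @param truth Optional ground-truth data frame or JSONL path
#'   (see [read_ground_truth()]).
#' @param out_dir Optional output directory: writes `detections.jsonl` and
#'   `thresholds.jsonl` (and `metrics.json` when truth is given).
#' @return List with `candidates`, `labels`, `detections`, `rejected`,
#'   `thresholds` and (with truth) `metrics`.
#' @export
run_exam <- function(exam, model, config = cad_config(), truth = NULL,
                     out_dir = NULL) {
  cfg <- as_cad_config(config)
  if (missing(model) || is.null(model))
    stop("config error: a trained model is required", call. = FALSE)
  if (is.character(model)) model <- load_classifier(model)
  stack <- if (inherits(exam, "slice_stack")) exam else load_series(exam)
  if (is.character(truth)) truth <- read_ground_truth(truth)
  det <- detect_exam(stack, cfg)
  labels <- if (nrow(det$candidates) > 0L)
    classify_candidates(model, det$candidates, cfg$consistency_mode)
  else character(0)
  detections <- det$candidates[labels == "nodule", , drop = FALSE]
  rejected <- det$candidates[labels == "non_nodule", , drop = FALSE]
  res <- list(candidates = det$candidates, labels = labels,
              detections = detections, rejected = rejected,
              thresholds = det$thresholds)
  if (!is.null(truth)) {
    counts <- match_detections(detections, truth,
                               match_radius = cfg$eval_match_radius,
                               rejected = rejected)
    res$metrics <- compute_metrics(counts, beta = cfg$beta,
                                   n_images = length(stack$slices),
                                   n_exams = 1L)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_jsonl(lapply(seq_len(NROW(detections)), function(i) list(
      slice_index = detections$slice_index[i],
      center = c(detections$center_r[i], detections$center_c[i]),
      area = detections$area[i], circularity = detections$circularity[i],
      consistency = detections$consistency[i])),
      file.path(out_dir, "detections.jsonl"))
    write_jsonl(lapply(seq_len(NROW(det$thresholds)), function(i) list(
      slice_index = det$thresholds$slice_index[i],
      lambda = det$thresholds$lambda[i], tau = det$thresholds$tau[i],
      lambda_source = det$thresholds$lambda_source[i])),
      file.path(out_dir, "thresholds.jsonl"))
    if (!is.null(res$metrics)) {
      m <- res$metrics
      jsonlite::write_json(
        list(sensitivity = m$sensitivity, specificity = m$specificity,
             precision = m$precision, accuracy = m$accuracy,
             f_beta = m$f_beta, beta = m$beta, mcc = m$mcc, fpi = m$fpi,
             fpe = m$fpe, counts = m$counts),
        file.path(out_dir, "metrics.json"), auto_unbox = TRUE, digits = NA)
    }
  }
  res
}
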