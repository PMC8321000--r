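#' Lung-segmentation recovery on seeded phantoms
#'
#' Generates `n` single-slice phantoms (seeds `base_seed + 1..n`), segments
#' each with the default pipeline and scores the Jaccard overlap between the
#' segmented mask and the planted lung region.
#'
#' @param n Number of phantom slices.
#' @param base_seed Base RNG seed; phantom i uses `base_seed + i`.
#' @param config A [cad_config()].
#' @param phantom Template [phantom_config()]; its seed is overridden.
#' @return Numeric vector of per-slice Jaccard indices.
#' @export
segmentation_jaccard <- function(n = 20L, base_seed = 0L,
                                 config = cad_config(),
                                 phantom = phantom_config()) {
  vapply(seq_len(n), function(i) {
    pc <- phantom
    pc$seed <- as.integer(base_seed + i)
    pc$n_slices <- 1L
    ph <- generate_stack(pc, exam_id = sprintf("seg%03d", i))
    seg <- suppressWarnings(segment_lungs(ph$stack$slices[[1]], config))
    truth <- ph$truth$lung_masks[[1]]
    got <- seg$mask$mask
    sum(got & truth) / sum(got | truth)
  }, numeric(1))
}

#' End-to-end phantom recovery experiment
#'
#' Trains the candidate classifier on `n_train` seeded phantom exams and
#' evaluates the full pipeline on `n_test` disjointly seeded exams:
#' segmentation, candidate detection, consistency features over the slice
#' window, SVM classification, detection matching and the metric battery.
#' Also reports how often the consistency bit agrees with the planted
#' geometry (nodules should receive 1, drifting vessels 0).
#'
#' @param n_train,n_test Number of training and test exams.
#' @param base_seed Base RNG seed; training exams use `base_seed + 1..n_train`
#'   and test exams `base_seed + 10000 + 1..n_test`.
#' @param config A [cad_config()].
#' @param phantom Template [phantom_config()]; its seed is overridden.
#' @return List with `metrics` (a `metric_report` pooled over test exams),
#'   `model`, `consistency_nodule_rate`, `consistency_vessel_rate`,
#'   `n_train_examples`, `training_accuracy`.
#' @export
phantom_recovery_experiment <- function(n_train = 10L, n_test = 20L,
                                        base_seed = 0L,
                                        config = cad_config(),
                                        phantom = phantom_config()) {
  cfg <- as_cad_config(config)
  make_exam <- function(seed, tag) {
    pc <- phantom
    pc$seed <- as.integer(seed)
    generate_stack(pc, exam_id = sprintf("%s%05d", tag, seed))
  }

  feats <- list()
  labels <- character(0)
  for (i in seq_len(n_train)) {
    ph <- make_exam(base_seed + i, "train")
    det <- detect_exam(ph$stack, cfg)
    if (nrow(det$candidates) == 0L) next
    feats[[length(feats) + 1L]] <- det$candidates
    labels <- c(labels, label_candidates(det$candidates, ph$truth$nodules))
  }
  train_df <- do.call(rbind, feats)
  model <- train_classifier(train_df, labels, cost = cfg$svm_cost,
                            seed = cfg$seed)
  train_acc <- mean(classify_candidates(model, train_df) == labels)

  counts <- c(TP = 0L, TN = 0L, FP = 0L, FN = 0L)
  n_images <- 0L
  nod_t <- c(hit = 0L, total = 0L)
  ves_t <- c(hit = 0L, total = 0L)
  for (i in seq_len(n_test)) {
    ph <- make_exam(base_seed + 10000L + i, "test")
    res <- run_exam(ph$stack, model, cfg, truth = ph$truth$nodules)
    cc <- res$metrics$counts
    counts <- counts + c(TP = cc$TP, TN = cc$TN, FP = cc$FP, FN = cc$FN)
    n_images <- n_images + length(ph$stack$slices)
    # consistency agreement on candidates matched to planted structures
    cands <- res$candidates
    if (nrow(cands) > 0L) {
      is_nod <- label_candidates(cands, ph$truth$nodules) == "nodule"
      is_ves <- label_candidates(cands, ph$truth$vessels) == "nodule"
      nod_t <- nod_t + c(hit = sum(cands$consistency[is_nod] == 1),
                         total = sum(is_nod))
      ves_t <- ves_t + c(hit = sum(cands$consistency[is_ves & !is_nod] == 0),
                         total = sum(is_ves & !is_nod))
    }
  }
  metrics <- compute_metrics(as.list(counts), beta = cfg$beta,
                             n_images = n_images, n_exams = n_test)
  list(metrics = metrics, model = model,
       consistency_nodule_rate = safe_ratio(nod_t[["hit"]], nod_t[["total"]]),
       consistency_vessel_rate = safe_ratio(ves_t[["hit"]], ves_t[["total"]]),
       n_train_examples = length(labels), training_accuracy = train_acc)
}
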