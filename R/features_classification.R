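#' Statistical features of a candidate region
#'
#' For the intensities of a grown region: mean; median (midpoint of the
#' sorted values, averaging the two central values for even counts); mode
#' (most frequent 8-bit value, smallest value on a tie); population variance
#' (divided by the region size, not n-1); and its square root.
#'
#' @param region A `candidate_region` from [grow_region()], or a numeric
#'   vector of intensities.
#' @param image Grayscale matrix the region was grown on (ignored when
#'   `region` is already a vector).
#' @return Named numeric vector `c(mean, median, mode, variance, sd)`.
#' @export
stat_features <- function(region, image = NULL) {
  v <- if (inherits(region, "candidate_region")) {
    stopifnot(!is.null(image))
    as.numeric(image[region$pixels])
  } else as.numeric(region)
  if (length(v) == 0L) stop("empty region", call. = FALSE)
  tab <- table(v)
  mo <- as.numeric(names(tab)[which.max(tab)])  # ties: smallest value first
  mu <- mean(v)
  c(mean = mu, median = stats::median(v), mode = mo,
    variance = mean((v - mu)^2), sd = sqrt(mean((v - mu)^2)))
}

#' Across-slice consistency feature
#'
#' A nodule re-appears at the same location in adjacent slices while vessel
#' cross-sections drift, so a candidate on slice j is traced in the 2k
#' neighbouring slices j-k..j+k (excluding j itself; missing slices at stack
#' boundaries are simply absent). The feature is 1 iff any neighbour-slice
#' candidate center lies within Euclidean distance `match_radius` (inclusive)
#' of this candidate's center.
#'
#' @param center `c(row, col)` of the candidate, or a 1-row candidate data
#'   frame from [detect_round_centers()].
#' @param neighbor_centers List (one entry per neighbour slice) of data
#'   frames or 2-column matrices of candidate centers.
#' @param match_radius Matching tolerance in pixels.
#' @return `0L` or `1L`.
#' @export
consistency_feature <- function(center, neighbor_centers, match_radius = 3) {
  if (is.data.frame(center)) center <- c(center$center_r[1], center$center_c[1])
  for (nb in neighbor_centers) {
    if (is.null(nb)) next
    if (is.data.frame(nb)) nb <- cbind(nb$center_r, nb$center_c)
    if (NROW(nb) == 0L) next
    d <- sqrt((nb[, 1] - center[1])^2 + (nb[, 2] - center[2])^2)
    if (any(d <= match_radius)) return(1L)
  }
  0L
}

#' Assemble the six-element candidate feature vector
#'
#' The classifier input, in fixed order: mean, median, mode, variance,
#' standard deviation and the binary across-slice consistency bit.
#'
#' @param region A `candidate_region` or numeric intensity vector.
#' @param t Consistency bit in `{0, 1}`.
#' @param image Grayscale matrix (see [stat_features()]).
#' @return Named numeric vector of length 6.
#' @export
build_feature_vector <- function(region, t, image = NULL) {
  stopifnot(t %in% c(0, 1))
  c(stat_features(region, image), consistency = as.numeric(t))
}

FEATURE_NAMES <- c("mean", "median", "mode", "variance", "sd", "consistency")

as_feature_matrix <- function(vectors) {
  x <- if (is.data.frame(vectors)) as.matrix(vectors[, FEATURE_NAMES, drop = FALSE])
  else if (is.matrix(vectors)) vectors[, FEATURE_NAMES, drop = FALSE]
  else matrix(vectors[FEATURE_NAMES], nrow = 1,
              dimnames = list(NULL, FEATURE_NAMES))
  storage.mode(x) <- "double"
  x
}

#' Train the linear SVM separating nodules from vessels and bronchi
#'
#' Features are standardized (center and scale from the training data; a
#' zero-variance feature gets scale 1) and a linear-kernel SVM with fixed
#' regularization is fit. The fitted decision function is stored as explicit
#' weights and bias so that classification -- and on-disk persistence -- are
#' exactly reproducible.
#'
#' @param features Matrix or data frame of six-element feature vectors (see
#'   [build_feature_vector()]).
#' @param labels Character/factor vector with values `"nodule"` /
#'   `"non_nodule"`; both classes must be present.
#' @param cost SVM regularization constant.
#' @param seed RNG seed used around the fit.
#' @return A `nodule_classifier`: list with `weights`, `bias`, `center`,
#'   `scale` and `classes`.
#' @export
train_classifier <- function(features, labels, cost = 1, seed = 1L) {
  x <- as_feature_matrix(features)
  y <- factor(as.character(labels), levels = c("nodule", "non_nodule"))
  if (anyNA(y)) stop("labels must be 'nodule' or 'non_nodule'", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("single-class training set: need both nodule and non_nodule examples",
         call. = FALSE)
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  xs <- scale(x, center = ctr, scale = scl)
  fit <- with_seed(seed,
    e1071::svm(xs, y, type = "C-classification", kernel = "linear",
               cost = cost, scale = FALSE))
  w <- drop(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  # libsvm orients the decision value by class appearance order in the data;
  # anchor the sign so that positive values mean "nodule"
  dv <- drop(xs %*% w) + b
  pred <- predict(fit, xs)
  if (mean((dv > 0) == (pred == "nodule")) < 0.5) { w <- -w; b <- -b }
  structure(list(weights = w, bias = b, center = ctr, scale = scl,
                 classes = c("nodule", "non_nodule"), cost = cost),
            class = "nodule_classifier")
}

#' @export
print.nodule_classifier <- function(x, ...) {
  cat("<nodule_classifier: linear SVM, weights ",
      paste(sprintf("%.3f", x$weights), collapse = " "),
      ", bias ", sprintf("%.3f", x$bias), ">\n", sep = "")
  invisible(x)
}

decision_values <- function(model, x) {
  xs <- scale(as_feature_matrix(x), center = model$center, scale = model$scale)
  drop(xs %*% model$weights) + model$bias
}

#' Classify candidate feature vectors
#'
#' In `mode = "feature"` (the default) every candidate is scored by the SVM
#' on the full six-element vector, consistency bit included. In
#' `mode = "filter"` candidates with consistency 0 are assigned `non_nodule`
#' without scoring -- the behaviour of dropping candidates untraceable in the
#' adjacent slices -- and the rest are scored. `mode = "both"` is the filter
#' composed with SVM scoring of the survivors (identical to `"filter"` here,
#' spelled out for configs that treat the two stages separately).
#'
#' @param model A `nodule_classifier` from [train_classifier()].
#' @param vectors Matrix/data frame of feature vectors.
#' @param mode One of `"feature"`, `"filter"`, `"both"`.
#' @return Character vector of `"nodule"` / `"non_nodule"`.
#' @export
classify_candidates <- function(model, vectors,
                                mode = c("feature", "filter", "both")) {
  mode <- match.arg(mode)
  x <- as_feature_matrix(vectors)
  if (nrow(x) == 0L) return(character(0))
  out <- ifelse(decision_values(model, x) > 0, "nodule", "non_nodule")
  if (mode %in% c("filter", "both"))
    out[x[, "consistency"] == 0] <- "non_nodule"
  out
}

#' Save or load a trained classifier
#'
#' The model is persisted as versioned JSON holding the linear weights, bias
#' and standardization parameters at full double precision; a load after save
#' reproduces the decision function exactly.
#'
#' @param model A `nodule_classifier`.
#' @param path JSON file path.
#' @export
save_classifier <- function(model, path) {
  payload <- list(format = "lungcad-nodule-classifier", version = 1L,
                  weights = model$weights, bias = model$bias,
                  center = model$center, scale = model$scale,
                  classes = model$classes, cost = model$cost)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}

#' @rdname save_classifier
#' @param path JSON file path.
#' @return `load_classifier` returns the restored `nodule_classifier`.
#' @export
load_classifier <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "lungcad-nodule-classifier"))
    stop("not a lungcad classifier file: ", path, call. = FALSE)
  structure(list(weights = stats::setNames(as.numeric(p$weights), FEATURE_NAMES),
                 bias = as.numeric(p$bias),
                 center = stats::setNames(as.numeric(p$center), FEATURE_NAMES),
                 scale = stats::setNames(as.numeric(p$scale), FEATURE_NAMES),
                 classes = p$classes, cost = p$cost),
            class = "nodule_classifier")
}
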