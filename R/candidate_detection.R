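#' Extract bright inner structures from the segmented lungs
#'
#' Vessels, bronchi and nodules appear as bright spots against the dark
#' parenchyma, so an Otsu threshold computed over the lung-mask pixels only
#' separates them: the structure mask is the set of lung pixels strictly
#' above that threshold.
#'
#' @param lung_image Masked, median-filtered grayscale matrix from
#'   [segment_lungs()].
#' @param lung_mask A `lung_mask` or logical matrix.
#' @return Logical structure mask (a subset of the lung mask).
#' @export
extract_inner_structures <- function(lung_image, lung_mask) {
  m <- if (inherits(lung_mask, "lung_mask")) lung_mask$mask else lung_mask
  if (!any(m)) {
    warning("empty lung mask: no inner structures", call. = FALSE)
    return(matrix(FALSE, nrow(lung_image), ncol(lung_image)))
  }
  vals <- lung_image[m]
  if (length(unique(vals)) < 2L) {
    warning("constant lung region: no inner structures", call. = FALSE)
    return(matrix(FALSE, nrow(lung_image), ncol(lung_image)))
  }
  t <- otsu_threshold(lung_image, domain_mask = m)
  m & (lung_image > t)
}

#' Detect round and near-round shapes as nodule-candidate seeds
#'
#' Every 8-connected structure component with at least `min_candidate_area`
#' pixels whose isoperimetric circularity `4*pi*A/P^2` (outer chain-code
#' perimeter, capped at 1) reaches `circ_min` yields one candidate at its
#' centroid. There is no upper size bound, making the detector size
#' invariant.
#'
#' @param structures Logical structure mask from [extract_inner_structures()].
#' @param circ_min Minimum circularity, dimensionless in `(0, 1]`.
#' @param min_candidate_area Minimum component area in pixels.
#' @param slice_index Ordinal slice index stamped on each candidate.
#' @return Data frame of candidates: `slice_index`, `center_r`, `center_c`
#'   (pixel inside the component nearest the centroid), `area`,
#'   `circularity`, `equivalent_diameter`.
#' @export
detect_round_centers <- function(structures, circ_min = 0.6,
                                 min_candidate_area = 9L, slice_index = 1L) {
  empty <- data.frame(slice_index = integer(0), center_r = integer(0),
                      center_c = integer(0), area = numeric(0),
                      circularity = numeric(0), equivalent_diameter = numeric(0))
  lab <- .label_components_cpp(structures)
  nlab <- attr(lab, "n_components")
  if (nlab == 0L) return(empty)
  st <- .component_stats_cpp(lab, nlab)
  st$circularity <- pmin(1, 4 * pi * st$area / st$perimeter^2)
  st <- st[st$area >= min_candidate_area & st$circularity >= circ_min, ,
           drop = FALSE]
  if (nrow(st) == 0L) return(empty)
  # snap the centroid to a pixel of the component (centroids of annular or
  # crescent shapes can fall outside it)
  ctr <- t(vapply(seq_len(nrow(st)), function(i) {
    r <- round(st$centroid_r[i]); c <- round(st$centroid_c[i])
    if (r >= 1 && r <= nrow(lab) && c >= 1 && c <= ncol(lab) &&
        lab[r, c] == st$id[i]) return(c(r, c))
    idx <- which(lab == st$id[i], arr.ind = TRUE)
    d2 <- (idx[, 1] - st$centroid_r[i])^2 + (idx[, 2] - st$centroid_c[i])^2
    as.numeric(idx[which.min(d2), ])
  }, numeric(2)))
  data.frame(slice_index = as.integer(slice_index),
             center_r = as.integer(ctr[, 1]), center_c = as.integer(ctr[, 2]),
             area = st$area, circularity = st$circularity,
             equivalent_diameter = 2 * sqrt(st$area / pi))
}

#' Grow a candidate region from a seed point
#'
#' Region growing with a running-mean similarity rule: intensities are
#' normalized to `[0, 1]` and any 8-neighbour of the region whose normalized
#' intensity lies within `max_distance` of the current region mean is
#' absorbed, until no pixel qualifies. The frontier is processed
#' first-in-first-out with neighbours visited in row-major order, so the
#' result is deterministic; the region is confined to the lung mask.
#'
#' @param lung_image Masked grayscale matrix.
#' @param seed `c(row, col)` seed point, or a 1-row candidate data frame.
#' @param lung_mask A `lung_mask` or logical matrix confining the growth.
#' @param max_distance Maximum normalized intensity distance in `(0, 1]`;
#'   the pipeline default is 0.18.
#' @return A `candidate_region`: list with logical `region`, integer `pixels`
#'   (linear indices, column-major), `area`, and the `seed`.
#' @export
grow_region <- function(lung_image, seed, lung_mask, max_distance = 0.18) {
  if (is.data.frame(seed)) seed <- c(seed$center_r[1], seed$center_c[1])
  if (max_distance < 0 || max_distance > 1)
    stop("max_distance must be in [0, 1]", call. = FALSE)
  m <- if (inherits(lung_mask, "lung_mask")) lung_mask$mask else lung_mask
  reg <- .grow_region_cpp(lung_image + 0, m, as.integer(seed[1]),
                          as.integer(seed[2]), max_distance)
  structure(list(region = reg, pixels = which(reg), area = sum(reg),
                 seed = as.integer(seed)),
            class = "candidate_region")
}

#' Detect nodule-candidate regions on one segmented slice
#'
#' Orchestrates [extract_inner_structures()], [detect_round_centers()] and
#' [grow_region()] per seed; regions that grew to identical pixel sets are
#' deduplicated (the first seed wins).
#'
#' @param slice A [grayscale_slice()] (used for its index).
#' @param seg Result of [segment_lungs()] for that slice.
#' @param params A [cad_config()].
#' @return List of candidates, each a list with `candidate` (1-row data
#'   frame) and `region` (a `candidate_region`).
#' @export
detect_candidates <- function(slice, seg, params = cad_config()) {
  p <- as_cad_config(params)
  idx <- if (inherits(slice, "grayscale_slice")) slice$slice_index else 1L
  if (seg$mask$empty) return(list())
  structures <- suppressWarnings(
    extract_inner_structures(seg$lung_image, seg$mask))
  cands <- detect_round_centers(structures, circ_min = p$circ_min,
                                min_candidate_area = p$min_candidate_area,
                                slice_index = idx)
  if (nrow(cands) == 0L) return(list())
  out <- list()
  seen <- character(0)
  for (i in seq_len(nrow(cands))) {
    reg <- grow_region(seg$lung_image, c(cands$center_r[i], cands$center_c[i]),
                       seg$mask, p$max_intensity_distance)
    key <- paste(reg$pixels, collapse = ",")
    if (key %in% seen) next
    seen <- c(seen, key)
    out[[length(out) + 1L]] <- list(candidate = cands[i, , drop = FALSE],
                                    region = reg)
  }
  out
}
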