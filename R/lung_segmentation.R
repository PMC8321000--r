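#' Intensity histogram of a slice with bin step kappa
#'
#' Bins cover `[0, kappa)`, `[kappa, 2*kappa)`, ... with the last bin
#' truncated at 255 inclusive, so there are `ceiling(256 / kappa)` bins and
#' the counts conserve the total pixel count.
#'
#' @param slice A [grayscale_slice()] or an integer matrix in `[0, 255]`.
#' @param kappa Bin step in intensity units, `1 <= kappa <= 128`. The
#'   pipeline default is 5.
#' @return A `slice_histogram`: list with `bin_step`, `counts`, `bin_edges`
#'   (lower edge of each bin) and `n_pixels`.
#' @export
compute_histogram <- function(slice, kappa = 5L) {
  kappa <- as.integer(kappa)
  if (is.na(kappa) || kappa < 1L || kappa > 128L)
    stop("kappa must be in [1, 128]", call. = FALSE)
  px <- if (inherits(slice, "grayscale_slice")) slice$pixels else slice
  nb <- as.integer(ceiling(256 / kappa))
  bin <- pmin(px %/% kappa, nb - 1L)
  counts <- tabulate(bin + 1L, nbins = nb)
  structure(list(bin_step = kappa, counts = counts,
                 bin_edges = kappa * (seq_len(nb) - 1L),
                 n_pixels = length(px)),
            class = "slice_histogram")
}

# locate local minima of a count sequence; a flat run bounded by strictly
# larger neighbours counts as one minimum at its centre bin (1-based indices)
find_local_minima <- function(counts) {
  nb <- length(counts)
  minima <- integer(0)
  i <- 2L
  while (i <= nb - 1L) {
    j <- i
    while (j < nb && counts[j + 1L] == counts[i]) j <- j + 1L
    # run i..j of equal counts; interior run is a minimum iff both strict
    if (j <= nb - 1L && counts[i - 1L] > counts[i] && counts[j + 1L] > counts[i])
      minima <- c(minima, i + (j - i) %/% 2L)
    i <- j + 1L
  }
  minima
}

#' Estimate the background-removal threshold from a slice histogram
#'
#' Scans the (optionally smoothed) bin counts from intensity 0 upward and
#' takes the second local minimum; the threshold lambda is the highest
#' intensity contained in that bin, i.e. the valley where the low-intensity
#' peaks (black background and dark body rim) end. When fewer than two local
#' minima exist the Otsu threshold of the source slice is used instead and
#' flagged as the fallback.
#'
#' @param hist A [compute_histogram()] result.
#' @param slice The source slice; only required for the Otsu fallback.
#' @param smooth_width Odd width of a centred moving average applied to the
#'   counts before the scan (edge bins copied); 1 disables smoothing.
#' @return List with `lambda`, `lambda_source` (`"second_minimum"` or
#'   `"otsu_fallback"`) and the minima bin indices found.
#' @export
estimate_background_threshold <- function(hist, slice = NULL, smooth_width = 1L) {
  stopifnot(inherits(hist, "slice_histogram"))
  counts <- hist$counts
  nb <- length(counts)
  if (nb < 3L) stop("histogram must have at least 3 bins", call. = FALSE)
  smooth_width <- as.integer(smooth_width)
  if (smooth_width > 1L) {
    if (smooth_width %% 2L == 0L) stop("smooth_width must be odd", call. = FALSE)
    h <- smooth_width %/% 2L
    sm <- counts
    for (i in (1L + h):(nb - h)) sm[i] <- mean(counts[(i - h):(i + h)])
    counts <- sm
  }
  minima <- find_local_minima(counts)
  if (length(minima) >= 2L) {
    b <- minima[2L]
    lambda <- min(hist$bin_edges[b] + hist$bin_step - 1L, 255L)
    src <- "second_minimum"
  } else {
    if (is.null(slice))
      stop("fewer than 2 local minima and no slice supplied for the Otsu fallback",
           call. = FALSE)
    px <- if (inherits(slice, "grayscale_slice")) slice$pixels else slice
    lambda <- otsu_threshold(px)
    src <- "otsu_fallback"
  }
  list(lambda = as.integer(lambda), lambda_source = src, minima_bins = minima)
}

#' Remove the image background and complement
#'
#' Pixels at or below the threshold are set to 0 (strict `I > lambda` keeps a
#' pixel), then the result is complemented (`255 - value`) so the retained
#' anatomy appears dark and the removed background bright.
#'
#' @param slice A [grayscale_slice()] or integer matrix.
#' @param lambda_bg Background threshold in `[0, 255]`.
#' @return Integer matrix: the complemented, background-removed image.
#' @export
remove_background <- function(slice, lambda_bg) {
  px <- if (inherits(slice, "grayscale_slice")) slice$pixels else slice
  if (lambda_bg < 0 || lambda_bg > 255)
    stop("lambda_bg must be in [0, 255]", call. = FALSE)
  thr <- ifelse(px > lambda_bg, px, 0L)
  matrix(255L - as.integer(thr), nrow(px), ncol(px))
}

#' Otsu threshold of a grayscale image
#'
#' Returns the 8-bit threshold `t` maximizing the between-class variance of
#' the split `<= t` versus `> t`, computed over the pixels inside
#' `domain_mask` (the whole image when absent). Ties are broken by the
#' smallest threshold.
#'
#' @param image Integer matrix in `[0, 255]` or a [grayscale_slice()].
#' @param domain_mask Optional logical matrix restricting the computation.
#' @return Integer threshold in `[0, 254]`.
#' @export
otsu_threshold <- function(image, domain_mask = NULL) {
  px <- if (inherits(image, "grayscale_slice")) image$pixels else image
  v <- if (is.null(domain_mask)) as.vector(px) else px[domain_mask]
  if (length(v) == 0L || length(unique(v)) < 2L)
    stop("degenerate input: Otsu needs >= 2 distinct intensities in the domain",
         call. = FALSE)
  counts <- tabulate(v + 1L, nbins = 256L)
  p <- counts / sum(counts)
  omega <- cumsum(p)             # P(class0) for t = 0..255
  mu <- cumsum(p * (0:255))      # partial mean
  mu_t <- mu[256L]
  t_all <- 0:254
  w0 <- omega[t_all + 1L]
  m0 <- mu[t_all + 1L]
  valid <- w0 > 0 & w0 < 1
  sigma_b <- rep(-Inf, 255L)
  sigma_b[valid] <- (mu_t * w0[valid] - m0[valid])^2 / (w0[valid] * (1 - w0[valid]))
  as.integer(t_all[which.max(sigma_b)])   # which.max takes the first (smallest) tie
}

disc_brush <- function(radius) {
  EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
}

# flood-fill the background from the border; unreached background = holes
fill_mask_holes <- function(mask) {
  inv <- !mask
  lab <- .label_components_cpp(inv)
  nlab <- attr(lab, "n_components")
  if (nlab == 0L) return(mask)
  border_labs <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  border_labs <- border_labs[border_labs > 0L]
  hole <- inv & !(lab %in% border_labs)
  mask | matrix(hole, nrow(mask), ncol(mask))
}

#' Refine a thresholded map into the lung mask
#'
#' Applies the binary rule `B = (complemented > tau)`, then labels
#' 8-connected components and (i) deletes the largest component by pixel
#' count -- the bright region enclosing the lungs (exact ties: all tied
#' components are deleted); (ii) deletes any remaining component touching the
#' image border; (iii) deletes components smaller than `min_area`; (iv)
#' optionally fills interior holes left by bright inner structures; and (v)
#' dilates the survivors with a disc, recovering structure pixels lost to the
#' complement thresholding.
#'
#' @param complemented Integer matrix from [remove_background()].
#' @param tau_lung Otsu threshold from [otsu_threshold()].
#' @param min_area Minimum surviving component area in pixels.
#' @param dilation_radius Disc radius of the final dilation (pixels).
#' @param fill_holes Fill interior holes before dilating.
#' @return A `lung_mask`: list with logical `mask`, a `components` data frame
#'   (id, area, centroid, bounding box) and an `empty` flag.
#' @export
make_lung_mask <- function(complemented, tau_lung, min_area = 50L,
                           dilation_radius = 2L, fill_holes = TRUE) {
  B <- complemented > tau_lung
  lab <- .label_components_cpp(B)
  nlab <- attr(lab, "n_components")
  empty_result <- function() {
    warning("empty lung segmentation: no component survived refinement",
            call. = FALSE)
    structure(list(mask = matrix(FALSE, nrow(B), ncol(B)),
                   components = component_stats(matrix(0L, nrow(B), ncol(B)), 0L),
                   empty = TRUE),
              class = "lung_mask")
  }
  if (nlab == 0L) return(empty_result())
  st <- .component_stats_cpp(lab, nlab)
  keep <- rep(TRUE, nlab)
  keep[st$area == max(st$area)] <- FALSE          # enclosing bright region
  keep[st$border] <- FALSE                        # border-touching leftovers
  keep[st$area < min_area] <- FALSE               # specks
  if (!any(keep)) return(empty_result())
  mask <- matrix(lab %in% st$id[keep], nrow(B), ncol(B))
  if (fill_holes) mask <- fill_mask_holes(mask)
  if (dilation_radius > 0L)
    mask <- EBImage::dilate(mask * 1L, disc_brush(dilation_radius)) > 0
  lab2 <- .label_components_cpp(mask)
  structure(list(mask = mask,
                 components = component_stats(lab2, attr(lab2, "n_components")),
                 empty = FALSE),
            class = "lung_mask")
}

component_stats <- function(labels, n) {
  if (n == 0L)
    return(data.frame(id = integer(0), area = numeric(0),
                      centroid_r = numeric(0), centroid_c = numeric(0),
                      rmin = integer(0), rmax = integer(0),
                      cmin = integer(0), cmax = integer(0),
                      border = logical(0), perimeter = numeric(0)))
  .component_stats_cpp(labels, n)
}

#' Segment the lungs from one chest CT slice
#'
#' The end-to-end per-slice segmentation: intensity histogram with step
#' `kappa`, second-local-minimum background threshold (Otsu fallback),
#' background removal and complement, Otsu separation of the lungs from the
#' surrounding bright region, connected-component refinement with dilation,
#' and a 3 x 3 median filter on the masked grayscale lungs.
#'
#' @param slice A [grayscale_slice()].
#' @param params A [cad_config()] or list overriding `kappa`, `min_area`,
#'   `dilation_radius`, `fill_holes`, `smooth_width`.
#' @return List with `mask` (a `lung_mask`), `lung_image` (median-filtered
#'   masked grayscale matrix, 0 outside the mask), and `thresholds`
#'   (`lambda`, `tau`, `lambda_source`).
#' @export
segment_lungs <- function(slice, params = cad_config()) {
  p <- as_cad_config(params)
  px <- if (inherits(slice, "grayscale_slice")) slice$pixels else slice
  empty <- function(lambda, tau, src) {
    warning("empty lung segmentation for slice", call. = FALSE)
    list(mask = structure(list(mask = matrix(FALSE, nrow(px), ncol(px)),
                               components = component_stats(matrix(0L, 1, 1), 0L),
                               empty = TRUE), class = "lung_mask"),
         lung_image = matrix(0L, nrow(px), ncol(px)),
         thresholds = list(lambda = lambda, tau = tau, lambda_source = src))
  }
  if (length(unique(as.vector(px))) < 2L) return(empty(NA, NA, "degenerate"))
  h <- compute_histogram(px, p$kappa)
  bg <- estimate_background_threshold(h, slice = px, smooth_width = p$smooth_width)
  comp <- remove_background(px, bg$lambda)
  if (length(unique(as.vector(comp))) < 2L)
    return(empty(bg$lambda, NA, bg$lambda_source))
  tau <- otsu_threshold(comp)
  mask <- suppressWarnings(
    make_lung_mask(comp, tau, min_area = p$min_area,
                   dilation_radius = p$dilation_radius,
                   fill_holes = p$fill_holes))
  if (mask$empty) {
    warning("empty lung segmentation for slice", call. = FALSE)
    lung <- matrix(0L, nrow(px), ncol(px))
  } else {
    masked <- matrix(as.integer(px * mask$mask), nrow(px), ncol(px))
    filt <- .median3x3_cpp(masked)
    lung <- matrix(as.integer(filt * mask$mask), nrow(px), ncol(px))
  }
  list(mask = mask, lung_image = lung,
       thresholds = list(lambda = bg$lambda, tau = tau,
                         lambda_source = bg$lambda_source))
}
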