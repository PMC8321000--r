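#' Construct a grayscale CT slice
#'
#' A `grayscale_slice` is one axial CT slice held as an M x N integer matrix
#' of 8-bit intensities, together with its ordinal position in the exam.
#'
#' @param pixels Integer matrix with values in `[0, 255]`, at least 8 x 8.
#' @param slice_index Ordinal position of the slice within its exam (>= 1).
#' @param source_id Opaque, de-identified origin string (e.g. a file name).
#' @return An object of class `grayscale_slice` with fields `pixels`, `rows`,
#'   `cols`, `slice_index` and `source_id`.
#' @export
grayscale_slice <- function(pixels, slice_index = 1L, source_id = "") {
  if (!is.matrix(pixels)) stop("pixels must be a matrix", call. = FALSE)
  storage.mode(pixels) <- "integer"
  if (anyNA(pixels) || min(pixels) < 0L || max(pixels) > 255L)
    stop("intensities must lie in [0, 255]", call. = FALSE)
  if (nrow(pixels) < 8L || ncol(pixels) < 8L)
    stop("slice must be at least 8 x 8", call. = FALSE)
  slice_index <- as.integer(slice_index)
  if (is.na(slice_index) || slice_index < 1L)
    stop("slice_index must be >= 1", call. = FALSE)
  structure(
    list(pixels = pixels, rows = nrow(pixels), cols = ncol(pixels),
         slice_index = slice_index, source_id = as.character(source_id)),
    class = "grayscale_slice")
}

#' @export
print.grayscale_slice <- function(x, ...) {
  cat(sprintf("<grayscale_slice %dx%d, index %d, source '%s'>\n",
              x$rows, x$cols, x$slice_index, x$source_id))
  invisible(x)
}

is_png_file <- function(path) {
  sig <- readBin(path, "raw", n = 8L)
  length(sig) == 8L &&
    identical(sig, as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a)))
}

#' Load one CT slice from a PNG or DICOM file
#'
#' PNG slices (8-bit grayscale) are read verbatim. Single-frame grayscale
#' DICOM slices are linearly mapped to `[0, 255]`: by default stored-value
#' min-max scaling per slice, or an explicit intensity window. No
#' patient-identifying metadata is retained on the returned value.
#'
#' @param path Path to an 8-bit grayscale PNG or a single-frame grayscale
#'   DICOM file.
#' @param window Optional `c(center, width)` intensity window applied to
#'   DICOM stored values before the 8-bit mapping. Ignored for PNG.
#' @param slice_index Ordinal index to stamp on the returned slice.
#' @return A [grayscale_slice()].
#' @export
load_slice <- function(path, window = NULL, slice_index = 1L) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is_png_file(path)) {
    img <- png::readPNG(path)
    if (length(dim(img)) != 2L)
      stop("color or alpha PNG payloads are unsupported; ",
           "expected single-channel grayscale", call. = FALSE)
    px <- matrix(as.integer(round(img * 255)), nrow(img), ncol(img))
    return(grayscale_slice(px, slice_index, basename(path)))
  }
  dc <- read_dicom_slice(path)
  px <- map_to_8bit(dc$pixels, window)
  sl <- grayscale_slice(px, slice_index, basename(path))
  attr(sl, "instance_number") <- dc$instance_number
  attr(sl, "spacing_mm") <- dc$spacing_mm
  sl
}

# linear stored-value -> [0,255] mapping; degenerate range maps to all zeros
map_to_8bit <- function(values, window = NULL) {
  v <- as.numeric(values)
  if (is.null(window)) {
    lo <- min(v); hi <- max(v)
    if (hi == lo) return(matrix(0L, nrow(values), ncol(values)))
  } else {
    if (length(window) != 2L || window[2] <= 0)
      stop("window must be c(center, width) with width > 0", call. = FALSE)
    lo <- window[1] - window[2] / 2
    hi <- window[1] + window[2] / 2
  }
  out <- round((v - lo) / (hi - lo) * 255)
  out <- pmin(pmax(out, 0), 255)
  matrix(as.integer(out), nrow(values), ncol(values))
}

#' Load an ordered exam series from a directory
#'
#' Reads every PNG/DICOM slice in `dir`, orders the series by DICOM instance
#' number when every file carries one, else by lexicographic file name, and
#' stamps `slice_index` 1..m in that order.
#'
#' @param dir Directory containing the slice files of one exam.
#' @param window Optional DICOM intensity window, see [load_slice()].
#' @param exam_id Opaque exam identifier; defaults to the directory name.
#' @return A `slice_stack`: list with `slices` (list of [grayscale_slice()]),
#'   `exam_id` and optional `spacing_mm`.
#' @export
load_series <- function(dir, window = NULL, exam_id = basename(dir)) {
  if (!dir.exists(dir)) stop("directory not found: ", dir, call. = FALSE)
  files <- list.files(dir, pattern = "\\.(png|dcm|dicom|PNG|DCM)$",
                      full.names = TRUE)
  if (length(files) == 0L)
    files <- Filter(function(f) !dir.exists(f), list.files(dir, full.names = TRUE))
  files <- sort(files, method = "radix")
  if (length(files) == 0L) stop("empty series directory: ", dir, call. = FALSE)
  slices <- lapply(files, load_slice, window = window)
  inst <- vapply(slices, function(s) {
    i <- attr(s, "instance_number")
    if (is.null(i) || is.na(i)) NA_integer_ else as.integer(i)
  }, integer(1))
  ord <- if (!anyNA(inst)) order(inst) else seq_along(slices)
  slices <- slices[ord]
  dims <- vapply(slices, function(s) c(s$rows, s$cols), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("inconsistent series: slices have mixed dimensions", call. = FALSE)
  for (j in seq_along(slices)) slices[[j]]$slice_index <- j
  slice_stack(slices, exam_id = exam_id)
}

#' Assemble slices into an exam stack
#'
#' @param slices List of [grayscale_slice()], already in exam order.
#' @param exam_id Opaque exam identifier.
#' @param spacing_mm Optional `(row, col, between-slice)` physical spacing.
#' @return A `slice_stack` object.
#' @export
slice_stack <- function(slices, exam_id = "exam", spacing_mm = NULL) {
  idx <- vapply(slices, function(s) s$slice_index, integer(1))
  if (any(diff(idx) <= 0))
    stop("slices must be sorted strictly ascending by slice_index", call. = FALSE)
  structure(list(slices = slices, exam_id = exam_id, spacing_mm = spacing_mm),
            class = "slice_stack")
}

#' @export
print.slice_stack <- function(x, ...) {
  cat(sprintf("<slice_stack '%s': %d slices of %dx%d>\n", x$exam_id,
              length(x$slices), x$slices[[1]]$rows, x$slices[[1]]$cols))
  invisible(x)
}

#' Write a binary mask as a loss-less PNG
#'
#' Foreground is written as 255, background as 0; reading the file back with
#' [load_slice()] reproduces the mask exactly.
#'
#' @param mask Logical or 0/1 matrix.
#' @param path Output PNG path.
#' @export
write_mask_image <- function(mask, path) {
  m <- mask * 1
  if (anyNA(m) || !all(m %in% c(0, 1)))
    stop("mask must be binary", call. = FALSE)
  png::writePNG(m, path)
  invisible(NULL)
}

#' Write a grayscale slice as a loss-less PNG
#'
#' @param slice A [grayscale_slice()] or an integer matrix in `[0, 255]`.
#' @param path Output PNG path.
#' @export
write_slice_image <- function(slice, path) {
  px <- if (inherits(slice, "grayscale_slice")) slice$pixels else slice
  png::writePNG(px / 255, path)
  invisible(NULL)
}
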