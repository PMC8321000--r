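# Minimal single-frame grayscale DICOM reader.
#
# Supports Part-10 files (128-byte preamble + "DICM") in the Explicit and
# Implicit VR Little Endian transfer syntaxes, which covers plain CT slice
# exports. Only the geometric attributes needed to decode the pixel grid are
# interpreted; patient demographics and free-text attributes are skipped
# outright so that nothing identifying can leak into downstream values.

u16 <- function(raw2) as.integer(raw2[1]) + 256L * as.integer(raw2[2])
u32 <- function(raw4) sum(as.numeric(raw4) * c(1, 256, 65536, 16777216))

TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
TS_IMPLICIT_LE <- "1.2.840.10008.1.2"

read_dicom_slice <- function(path) {
  buf <- readBin(path, "raw", n = file.size(path))
  if (length(buf) < 140L || rawToChar(buf[129:132]) != "DICM")
    stop("unreadable file: not a PNG and not a DICOM part-10 file: ",
         path, call. = FALSE)
  pos <- 133L
  n <- length(buf)
  ts <- TS_EXPLICIT_LE
  fields <- list(rows = NA, cols = NA, bits = 16L, pixrep = 0L,
                 samples = 1L, frames = 1L, instance = NA,
                 spacing = NULL, thickness = NA, pixeldata = NULL)
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")

  read_element <- function(pos, explicit) {
    if (pos + 7L > n) return(NULL)
    group <- u16(buf[pos:(pos + 1L)])
    elem <- u16(buf[(pos + 2L):(pos + 3L)])
    if (explicit) {
      vr <- rawToChar(buf[(pos + 4L):(pos + 5L)])
      if (vr %in% long_vrs) {
        len <- u32(buf[(pos + 8L):(pos + 11L)])
        hdr <- 12L
      } else {
        len <- u16(buf[(pos + 6L):(pos + 7L)])
        hdr <- 8L
      }
    } else {
      vr <- NA_character_
      len <- u32(buf[(pos + 4L):(pos + 7L)])
      hdr <- 8L
    }
    if (len == 4294967295) # undefined length (sequences): unsupported profile
      stop("unsupported DICOM: undefined-length element", call. = FALSE)
    list(group = group, elem = elem, vr = vr, len = len,
         start = pos + hdr, next_pos = pos + hdr + as.integer(len))
  }
  val_str <- function(el) trimws(rawToChar(buf[el$start:(el$start + el$len - 1L)]))
  val_u16 <- function(el) u16(buf[el$start:(el$start + 1L)])

  # file meta group (always explicit VR LE)
  while (pos + 7L <= n) {
    el <- read_element(pos, explicit = TRUE)
    if (is.null(el) || el$group != 2L) break
    if (el$elem == 16L && el$len > 0L) ts <- gsub("\\x00", "", val_str(el))
    pos <- el$next_pos
  }
  if (!ts %in% c(TS_EXPLICIT_LE, TS_IMPLICIT_LE))
    stop("unsupported DICOM transfer syntax: ", ts, call. = FALSE)
  explicit <- ts == TS_EXPLICIT_LE

  while (pos + 7L <= n) {
    el <- read_element(pos, explicit)
    if (is.null(el)) break
    tag <- sprintf("%04x,%04x", el$group, el$elem)
    if (el$len > 0L) {
      switch(tag,
        "0020,0013" = { fields$instance <- suppressWarnings(as.integer(val_str(el))) },
        "0028,0002" = { fields$samples <- val_u16(el) },
        "0028,0008" = { fields$frames <- suppressWarnings(as.integer(val_str(el))) },
        "0028,0010" = { fields$rows <- val_u16(el) },
        "0028,0011" = { fields$cols <- val_u16(el) },
        "0028,0030" = {
          sp <- suppressWarnings(as.numeric(strsplit(val_str(el), "\\\\")[[1]]))
          if (length(sp) == 2L && !anyNA(sp)) fields$spacing <- sp
        },
        "0018,0050" = { fields$thickness <- suppressWarnings(as.numeric(val_str(el))) },
        "0028,0100" = { fields$bits <- val_u16(el) },
        "0028,0103" = { fields$pixrep <- val_u16(el) },
        "7fe0,0010" = {
          fields$pixeldata <- buf[el$start:(el$start + el$len - 1L)]
        },
        NULL)
    }
    pos <- el$next_pos
  }

  if (is.na(fields$rows) || is.na(fields$cols) || is.null(fields$pixeldata))
    stop("unreadable DICOM: missing Rows/Columns/PixelData", call. = FALSE)
  if (!is.na(fields$frames) && fields$frames > 1L)
    stop("unsupported DICOM: multi-frame payload", call. = FALSE)
  if (fields$samples != 1L)
    stop("unsupported DICOM: color payload (SamplesPerPixel > 1)", call. = FALSE)
  if (!fields$bits %in% c(8L, 16L))
    stop("unsupported DICOM: BitsAllocated must be 8 or 16", call. = FALSE)

  npx <- fields$rows * fields$cols
  if (fields$bits == 8L) {
    vals <- as.integer(fields$pixeldata[seq_len(npx)])
  } else {
    con <- rawConnection(fields$pixeldata)
    on.exit(close(con))
    vals <- readBin(con, "integer", n = npx, size = 2L,
                    signed = fields$pixrep == 1L, endian = "little")
    if (fields$pixrep == 0L) vals <- ifelse(vals < 0L, vals + 65536L, vals)
  }
  if (length(vals) < npx)
    stop("unreadable DICOM: truncated PixelData", call. = FALSE)
  # DICOM pixel order is row by row
  px <- matrix(vals, nrow = fields$rows, ncol = fields$cols, byrow = TRUE)
  spacing <- if (!is.null(fields$spacing))
    c(fields$spacing, if (is.na(fields$thickness)) NA_real_ else fields$thickness)
  else NULL
  list(pixels = px, instance_number = fields$instance, spacing_mm = spacing)
}
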