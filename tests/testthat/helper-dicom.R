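# Minimal synthetic DICOM writer for fixtures (Part 10, Little Endian).
# Fixtures are built at test time; nothing binary is stored in the repo.

dcm_u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
dcm_u32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

dcm_pad <- function(raw_val, pad = as.raw(0x20)) {
  if (length(raw_val) %% 2 == 1) c(raw_val, pad) else raw_val
}

dcm_element <- function(group, elem, vr, value, explicit = TRUE) {
  tag <- c(dcm_u16(group), dcm_u16(elem))
  val <- if (vr %in% c("US")) dcm_u16(value)
  else if (vr %in% c("UL")) dcm_u32(value)
  else if (vr %in% c("OW", "OB")) value
  else dcm_pad(charToRaw(as.character(value)),
               pad = if (vr == "UI") as.raw(0) else as.raw(0x20))
  if (!explicit)
    return(c(tag, dcm_u32(length(val)), val))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN"))
    c(tag, charToRaw(vr), as.raw(c(0, 0)), dcm_u32(length(val)), val)
  else
    c(tag, charToRaw(vr), dcm_u16(length(val)), val)
}

# pixels: integer matrix (row-major pixel order in the file)
write_test_dicom <- function(path, pixels, instance = 1L, bits = 16L,
                             pixel_representation = 0L,
                             patient_name = "DOE^JANE", patient_id = "PAT001",
                             implicit = FALSE, samples = 1L, frames = NULL,
                             spacing = NULL) {
  vals <- as.integer(t(pixels)) # row by row
  pix <- if (bits == 8L) as.raw(vals)
  else writeBin(vals, raw(), size = 2, endian = "little")
  ts <- if (implicit) "1.2.840.10008.1.2" else "1.2.840.10008.1.2.1"
  meta_body <- dcm_element(0x0002, 0x0010, "UI", ts)
  meta <- c(dcm_element(0x0002, 0x0000, "UL", length(meta_body)), meta_body)
  el <- function(...) dcm_element(..., explicit = !implicit)
  body <- c(
    el(0x0010, 0x0010, "PN", patient_name),
    el(0x0010, 0x0020, "LO", patient_id),
    if (!is.null(spacing))
      el(0x0018, 0x0050, "DS", format(spacing[3])),
    el(0x0020, 0x0013, "IS", format(instance)),
    el(0x0028, 0x0002, "US", samples),
    if (!is.null(frames)) el(0x0028, 0x0008, "IS", format(frames)),
    el(0x0028, 0x0010, "US", nrow(pixels)),
    el(0x0028, 0x0011, "US", ncol(pixels)),
    if (!is.null(spacing))
      el(0x0028, 0x0030, "DS", paste(spacing[1], spacing[2], sep = "\\")),
    el(0x0028, 0x0100, "US", bits),
    el(0x0028, 0x0103, "US", pixel_representation),
    el(0x7fe0, 0x0010, "OW", pix))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128), charToRaw("DICM"), meta, body), con)
  invisible(path)
}
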