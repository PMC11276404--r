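# Minimal explicit-VR little-endian DICOM writer for fixtures built at
# test time. Produces uncompressed 16-bit axial slices with the geometry
# and rescale tags the reader needs.

raw_u16 <- function(x) as.raw(c(x %% 256, x %/% 256))
raw_u32 <- function(x) as.raw(c(x %% 256, (x %/% 256) %% 256,
                                (x %/% 65536) %% 256, (x %/% 16777216) %% 256))

dcm_element <- function(group, elem, vr, value) {
  if (is.character(value)) {
    v <- charToRaw(value)
    if (length(v) %% 2 == 1)
      v <- c(v, if (vr %in% c("UI")) as.raw(0) else charToRaw(" "))
  } else {
    v <- value  # already raw
  }
  hdr <- c(raw_u16(group), raw_u16(elem), charToRaw(vr))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    c(hdr, as.raw(c(0, 0)), raw_u32(length(v)), v)
  } else {
    c(hdr, raw_u16(length(v)), v)
  }
}

# pixels: integer matrix [x, y] (column = image row), stored signed 16-bit
write_dicom_slice <- function(path, pixels, ipp = c(0, 0, 0),
                              pixel_spacing = c(1, 1),  # (row, col) mm
                              slope = 1, intercept = -1024,
                              series_uid = "1.2.3.4", sop_uid = "1.2.3.4.1",
                              transfer = "1.2.840.10008.1.2.1",
                              omit_rescale = FALSE) {
  px <- writeBin(as.integer(pixels), raw(), size = 2L, endian = "little")
  body <- c(
    dcm_element(0x0008, 0x0018, "UI", sop_uid),
    dcm_element(0x0020, 0x000E, "UI", series_uid),
    dcm_element(0x0020, 0x0032, "DS", paste(ipp, collapse = "\\")),
    dcm_element(0x0028, 0x0010, "US", raw_u16(ncol(pixels))),  # Rows
    dcm_element(0x0028, 0x0011, "US", raw_u16(nrow(pixels))),  # Columns
    dcm_element(0x0028, 0x0030, "DS", paste(pixel_spacing, collapse = "\\")),
    dcm_element(0x0028, 0x0100, "US", raw_u16(16)),
    dcm_element(0x0028, 0x0103, "US", raw_u16(1))
  )
  if (!omit_rescale) {
    body <- c(body,
              dcm_element(0x0028, 0x1052, "DS", as.character(intercept)),
              dcm_element(0x0028, 0x1053, "DS", as.character(slope)))
  }
  body <- c(body, dcm_element(0x7FE0, 0x0010, "OW", px))
  meta <- dcm_element(0x0002, 0x0010, "UI", transfer)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128), charToRaw("DICM"), meta, body), con)
  invisible(path)
}

write_dicom_stack <- function(dir, stored, spacing = c(1, 1, 1),
                              slope = 1, intercept = -1024, ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nz <- dim(stored)[3]
  for (k in seq_len(nz)) {
    write_dicom_slice(
      file.path(dir, sprintf("slice%03d.dcm", k)), stored[, , k],
      ipp = c(0, 0, (k - 1) * spacing[3]),
      pixel_spacing = c(spacing[2], spacing[1]),
      slope = slope, intercept = intercept,
      sop_uid = paste0("1.2.3.4.", k), ...)
  }
  invisible(dir)
}
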