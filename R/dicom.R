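# Minimal DICOM reader for axial CT series: little-endian explicit or
# implicit VR, uncompressed 16-bit pixel data. Only the tags needed to
# assemble a calibrated HU volume are decoded.

u16 <- function(r, pos) as.integer(r[pos]) + 256L * as.integer(r[pos + 1L])
u32 <- function(r, pos) {
  as.numeric(r[pos]) + 256 * as.numeric(r[pos + 1L]) +
    65536 * as.numeric(r[pos + 2L]) + 16777216 * as.numeric(r[pos + 3L])
}
dcm_str <- function(bytes) {
  s <- rawToChar(bytes[bytes != as.raw(0)])
  sub("[[:space:]]+$", "", s)
}
dcm_ds <- function(bytes) as.numeric(strsplit(dcm_str(bytes), "\\\\")[[1]])

LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

# Parse one DICOM file into a named list of the tags of interest.
read_dicom_file <- function(path) {
  r <- readBin(path, "raw", file.size(path))
  if (length(r) < 140 || rawToChar(r[129:132]) != "DICM")
    stop("not a DICOM file (missing DICM magic): ", path)
  pos <- 133L
  explicit <- TRUE
  transfer <- "1.2.840.10008.1.2.1"
  out <- list()
  want <- c("00080018", "0020000E", "00200032", "00280010", "00280011",
            "00280030", "00280100", "00280103", "00281052", "00281053",
            "7FE00010", "00020010")
  while (pos + 7L <= length(r)) {
    group <- u16(r, pos); elem <- u16(r, pos + 2L)
    in_meta <- group == 2L
    use_explicit <- in_meta || explicit
    if (use_explicit) {
      vr <- rawToChar(r[(pos + 4L):(pos + 5L)])
      if (vr %in% LONG_VRS) {
        len <- u32(r, pos + 8L); hdr <- 12L
      } else {
        len <- u16(r, pos + 6L); hdr <- 8L
      }
    } else {
      vr <- NA_character_
      len <- u32(r, pos + 4L); hdr <- 8L
    }
    key <- sprintf("%04X%04X", group, elem)
    if (len == 4294967295) {
      # undefined length (sequences): scan for the sequence delimiter
      body <- pos + hdr
      delim <- as.raw(c(0xFE, 0xFF, 0xDD, 0xE0))
      found <- NA_integer_
      i <- body
      while (i + 7L <= length(r)) {
        if (identical(r[i:(i + 3L)], delim)) { found <- i; break }
        i <- i + 2L
      }
      if (is.na(found)) stop("unterminated undefined-length element in ", path)
      pos <- found + 8L
      next
    }
    if (key %in% want) {
      val <- if (len > 0) r[(pos + hdr):(pos + hdr + len - 1L)] else raw(0)
      out[[key]] <- val
    }
    pos <- pos + hdr + as.integer(len)
    if (in_meta && !is.null(out[["00020010"]]) && group == 2L && elem == 16L) {
      transfer <- dcm_str(out[["00020010"]])
      if (transfer == "1.2.840.10008.1.2") {
        explicit <- FALSE
      } else if (transfer != "1.2.840.10008.1.2.1") {
        stop("unsupported transfer syntax ", transfer, " in ", path)
      }
    }
  }
  need <- c("00280010", "00280011", "00280030", "00200032")
  if (any(vapply(need, function(k) is.null(out[[k]]), logical(1))))
    stop("DICOM file lacks image geometry tags: ", path)
  if (is.null(out[["00281052"]]) || is.null(out[["00281053"]]))
    stop("DICOM file lacks rescale slope/intercept tags: ", path)
  if (is.null(out[["7FE00010"]]))
    stop("DICOM file lacks pixel data: ", path)
  rows <- u16(out[["00280010"]], 1L)
  cols <- u16(out[["00280011"]], 1L)
  bits <- if (!is.null(out[["00280100"]])) u16(out[["00280100"]], 1L) else 16L
  if (bits != 16L) stop("only 16-bit pixel data is supported: ", path)
  signed <- !is.null(out[["00280103"]]) && u16(out[["00280103"]], 1L) == 1L
  px <- readBin(out[["7FE00010"]], "integer", n = rows * cols, size = 2L,
                signed = signed, endian = "little")
  if (length(px) != rows * cols)
    stop("pixel data length does not match Rows x Columns: ", path)
  list(
    rows = rows, cols = cols,
    pixel_spacing = dcm_ds(out[["00280030"]]),    # (row, col) mm
    ipp = dcm_ds(out[["00200032"]]),              # (x, y, z) mm
    slope = dcm_ds(out[["00281053"]])[1],
    intercept = dcm_ds(out[["00281052"]])[1],
    series_uid = if (!is.null(out[["0020000E"]])) dcm_str(out[["0020000E"]]) else NA_character_,
    pixels = matrix(px, nrow = cols)              # [x, y]
  )
}

#' Read an axial DICOM series as a calibrated HU volume
#'
#' Loads every file in `path`, converts stored pixel values to Hounsfield
#' Units with the per-slice rescale slope and intercept
#' (`HU = value * slope + intercept`), orders the slices by their spatial
#' position and checks the stack geometry. Slice gaps may differ from the
#' median gap by at most 10%; overlapping reconstructions with a regular
#' centre-to-centre spacing are accepted, irregular stacks are not.
#'
#' @param path directory containing exactly one axial series.
#' @param scan_id identifier for the resulting volume; defaults to the
#'   directory name.
#' @return A [ct_volume()] in HU.
#' @export
read_dicom_series <- function(path, scan_id = basename(path)) {
  files <- list.files(path, full.names = TRUE, no.. = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) < 2L) stop("need at least two DICOM slices in ", path)
  slices <- lapply(files, read_dicom_file)

  uid <- unique(stats::na.omit(vapply(slices, `[[`, "", "series_uid")))
  if (length(uid) > 1L)
    stop("mixed series: ", length(uid), " distinct SeriesInstanceUIDs in ", path)
  dims <- unique(t(vapply(slices, function(s) c(s$rows, s$cols), integer(2))))
  if (nrow(dims) != 1L) stop("mixed series: inconsistent slice shapes in ", path)
  ps <- t(vapply(slices, `[[`, numeric(2), "pixel_spacing"))
  if (max(ps) - min(ps) > 1e-4 * max(ps) && any(apply(ps, 2, function(v) diff(range(v)) > 1e-6)))
    stop("mixed series: inconsistent pixel spacing in ", path)

  zs <- vapply(slices, function(s) s$ipp[3], numeric(1))
  ord <- order(zs)
  slices <- slices[ord]; zs <- zs[ord]
  gaps <- diff(zs)
  if (any(gaps <= 0)) stop("duplicate or non-increasing slice positions in ", path)
  med_gap <- median(gaps)
  if (any(abs(gaps - med_gap) > 0.10 * med_gap))
    stop(sprintf(
      "non-uniform slice spacing in %s: gaps range %.3f-%.3f mm vs median %.3f mm (10%% tolerance)",
      path, min(gaps), max(gaps), med_gap))

  nx <- slices[[1]]$cols; ny <- slices[[1]]$rows; nz <- length(slices)
  vox <- array(0, c(nx, ny, nz))
  for (k in seq_len(nz)) {
    s <- slices[[k]]
    vox[, , k] <- s$slope * s$pixels + s$intercept
  }
  frac_out <- mean(vox < -1100 | vox > 3200)
  if (frac_out > 0.005)
    stop(sprintf(
      "%.1f%% of voxels outside [-1100, 3200] HU: stored values do not look rescaled",
      100 * frac_out))
  spacing <- c(slices[[1]]$pixel_spacing[2], slices[[1]]$pixel_spacing[1], med_gap)
  ct_volume(vox, spacing, origin = slices[[1]]$ipp, scan_id = scan_id)
}
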