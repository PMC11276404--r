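# NIfTI I/O for volumes and masks, through RNifti.

nifti_affine <- function(spacing, origin) {
  m <- diag(c(spacing, 1))
  m[1:3, 4] <- origin
  m
}

#' Write a CT volume to NIfTI
#'
#' Voxels are written as 64-bit floats so a write/read round trip preserves
#' the grid bit-exactly; spacing and origin go into the sform affine.
#'
#' @param vol a [ct_volume()].
#' @param path output file, `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "ct_volume"))
  img <- RNifti::asNifti(vol$voxels)
  RNifti::pixdim(img) <- vol$spacing
  img <- RNifti::`sform<-`(img, structure(nifti_affine(vol$spacing, vol$origin),
                                          code = 2L))
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Read a NIfTI volume as a CT volume in HU
#'
#' The file is assumed to hold already-rescaled Hounsfield Units; spacing
#' is taken from the NIfTI pixdim, the origin from the stored affine.
#'
#' @param path a `.nii` / `.nii.gz` file.
#' @param scan_id identifier for the volume; defaults to the file name.
#' @return A [ct_volume()].
#' @export
read_volume <- function(path, scan_id = sub("\\.nii(\\.gz)?$", "", basename(path))) {
  img <- RNifti::readNifti(path)
  vox <- as.array(img)
  if (length(dim(vox)) != 3L) stop("expected a 3-D NIfTI volume: ", path)
  vox <- array(as.numeric(vox), dim(vox))  # drop NIfTI attributes
  spacing <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("degenerate affine: non-positive voxel spacing in ", path)
  origin <- RNifti::xform(img)[1:3, 4]
  frac_out <- mean(vox < -1100 | vox > 3200)
  if (frac_out > 0.005)
    stop(sprintf(
      "%.1f%% of voxels outside [-1100, 3200] HU in %s: not rescaled HU?",
      100 * frac_out, path))
  ct_volume(vox, spacing, origin = origin, scan_id = scan_id)
}

#' Write a binary mask to NIfTI
#'
#' Masks are stored as unsigned 8-bit volumes of 0/1 with the same affine
#' convention as [write_volume()].
#'
#' @param mask a [binary_mask()].
#' @param path output file.
#' @param origin world origin (mm) of the linked volume.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path, origin = c(0, 0, 0)) {
  stopifnot(inherits(mask, "binary_mask"))
  img <- RNifti::asNifti(array(as.integer(mask$grid), dim(mask$grid)))
  RNifti::pixdim(img) <- mask$spacing
  img <- RNifti::`sform<-`(img, structure(nifti_affine(mask$spacing, origin),
                                          code = 2L))
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' Read a binary mask from NIfTI
#'
#' @param path a `.nii` / `.nii.gz` file holding values in \{0, 1\}.
#' @param role anatomical role of the mask (see [binary_mask()]).
#' @param scan_id identifier of the linked volume.
#' @return A [binary_mask()].
#' @export
read_mask <- function(path, role, scan_id = "scan") {
  img <- RNifti::readNifti(path)
  g <- as.array(img)
  g <- array(as.numeric(g), dim(g))
  if (!all(g %in% c(0, 1))) stop("mask file contains values other than 0/1: ", path)
  spacing <- RNifti::pixdim(img)[1:3]
  if (any(spacing <= 0)) stop("degenerate affine in mask ", path)
  binary_mask(array(g == 1, dim(g)), role = role, spacing = spacing,
              scan_id = scan_id)
}
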