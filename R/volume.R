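#' CT volume container
#'
#' A 3-D grid of CT attenuation values in Hounsfield Units (HU) together
#' with its voxel spacing and world origin. Arrays are stored in the NIfTI
#' axis convention `[x, y, z]` (column, row, slice), with z increasing
#' toward the head; `spacing` gives the voxel edge lengths `(dx, dy, dz)`
#' along those axes in millimetres.
#'
#' @param voxels 3-D numeric array of attenuation values in HU.
#' @param spacing numeric length-3, voxel spacing in mm; all strictly
#'   positive.
#' @param origin numeric length-3, world coordinates (mm) of the centre of
#'   voxel `[1, 1, 1]`.
#' @param scan_id opaque identifier carried through to results.
#'
#' @return An object of class `ct_volume`: a list with elements `voxels`,
#'   `spacing`, `origin` and `scan_id`.
#' @examples
#' vol <- ct_volume(array(-850, c(4, 4, 3)), spacing = c(1.5, 1.5, 1.5))
#' dim(vol$voxels)
#' @export
ct_volume <- function(voxels, spacing, origin = c(0, 0, 0), scan_id = "scan") {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3-D array")
  if (any(dim(voxels) < 2L))
    stop("volume must have at least 2 voxels along every axis")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive values (mm)")
  structure(
    list(voxels = voxels, spacing = spacing, origin = as.numeric(origin),
         scan_id = as.character(scan_id)[1]),
    class = "ct_volume"
  )
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<ct_volume> %s: %d x %d x %d voxels @ %.3g x %.3g x %.3g mm\n",
              x$scan_id, d[1], d[2], d[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  HU range [%.1f, %.1f]\n",
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' Binary mask co-registered with a CT volume
#'
#' Boolean grid marking one anatomical role (`lung`, `airway`,
#' `exterior_air` or `cyst`) on the same grid as a [ct_volume()]. The voxel
#' volume in millilitres is derived from the spacing, so
#' `mask_volume_ml(mask)` is exactly the true-voxel count times the voxel
#' volume.
#'
#' @param grid 3-D logical array.
#' @param role one of `"lung"`, `"airway"`, `"exterior_air"`, `"cyst"`.
#' @param spacing voxel spacing (mm) of the linked volume.
#' @param scan_id identifier of the linked volume.
#' @return An object of class `binary_mask` with elements `grid`, `role`,
#'   `spacing`, `scan_id` and `voxel_volume_ml`.
#' @seealso [mask_volume_ml()]
#' @export
binary_mask <- function(grid, role, spacing, scan_id = "scan") {
  if (!is.array(grid) || length(dim(grid)) != 3L)
    stop("`grid` must be a 3-D array")
  if (!is.logical(grid)) {
    u <- unique(as.vector(grid))
    if (!all(u %in% c(0, 1))) stop("mask values must be logical or 0/1")
    grid <- array(as.logical(grid), dim(grid))
  }
  role <- match.arg(role, c("lung", "airway", "exterior_air", "cyst"))
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive values (mm)")
  structure(
    list(grid = grid, role = role, spacing = spacing,
         scan_id = as.character(scan_id)[1],
         voxel_volume_ml = prod(spacing) / 1000),
    class = "binary_mask"
  )
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> role=%s, %d voxels set (%.3f mL)\n",
              x$role, sum(x$grid), mask_volume_ml(x)))
  invisible(x)
}

#' Volume of a binary mask in millilitres
#'
#' @param mask a [binary_mask()].
#' @return true-voxel count multiplied by the voxel volume, in mL.
#' @export
mask_volume_ml <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  sum(mask$grid) * mask$voxel_volume_ml
}

check_registered <- function(vol, ...) {
  d <- dim(vol$voxels)
  for (m in list(...)) {
    if (is.null(m)) next
    if (!identical(dim(m$grid), d))
      stop("mask shape does not match the volume grid")
  }
  invisible(TRUE)
}

# Dice overlap between two logical arrays of the same shape.
#' Dice similarity coefficient of two masks
#' @param a,b `binary_mask` objects (or logical arrays) of identical shape.
#' @return 2|A∩B| / (|A| + |B|); 1 when both are empty.
#' @export
dice <- function(a, b) {
  ga <- if (inherits(a, "binary_mask")) a$grid else a
  gb <- if (inherits(b, "binary_mask")) b$grid else b
  stopifnot(identical(dim(ga), dim(gb)))
  s <- sum(ga) + sum(gb)
  if (s == 0) return(1)
  2 * sum(ga & gb) / s
}
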