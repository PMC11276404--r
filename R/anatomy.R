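# Automatic isolation of exterior air, lung fields and large airways.
# Cuts sit at canonical densitometry midpoints between the air (-1000 HU),
# parenchyma (~ -850 HU) and soft-tissue (~ 0 HU) modes.

label_array <- function(grid) {
  d <- dim(grid)
  lab <- .cc_label6(as.logical(grid), d)
  array(lab, d)
}

#' Exterior air mask
#'
#' Voxels below the air/tissue cut that are 6-connected to the lateral
#' border of the volume, i.e. the air surrounding the body. This region is
#' one of the attenuation references for the adaptive threshold.
#'
#' @param vol a [ct_volume()].
#' @param air_cut HU cut separating air-like voxels from tissue.
#' @return A [binary_mask()] with role `exterior_air`.
#' @export
exterior_air_mask <- function(vol, air_cut = -500) {
  stopifnot(inherits(vol, "ct_volume"))
  d <- dim(vol$voxels)
  lab <- label_array(vol$voxels < air_cut)
  border <- unique(c(lab[1, , ], lab[d[1], , ], lab[, 1, ], lab[, d[2], ]))
  border <- border[border > 0]
  if (length(border) == 0L)
    stop("no exterior air found (volume cropped to the body?); use the airway as the sole air reference")
  ext <- array(lab %in% border, d)
  binary_mask(ext, "exterior_air", vol$spacing, vol$scan_id)
}

#' Segment the lung fields
#'
#' Air-like voxels (below `lung_cut`) inside the body — the exterior-air
#' component is removed — are labelled; the largest connected component is
#' kept, plus the second largest when it holds at least 20% of the first
#' (separate left/right lungs). A morphological closing fills vessel-scale
#' gaps. Cystic voxels are air-like and therefore inside the mask.
#'
#' @param vol a [ct_volume()].
#' @param lung_cut HU cut for air-like voxels inside the body.
#' @param exterior optional precomputed [exterior_air_mask()]; when `NULL`
#'   it is computed (an absent exterior is tolerated).
#' @param closing_radius_vox radius (voxels) of the closing ball.
#' @param min_lung_ml smallest credible lung volume; below it the
#'   segmentation fails with "no lung found".
#' @param second_component_min fraction of the largest component above
#'   which the second largest is kept as the other lung.
#' @return A [binary_mask()] with role `lung`.
#' @export
segment_lungs <- function(vol, lung_cut = -320, exterior = NULL,
                          closing_radius_vox = 2, min_lung_ml = 50,
                          second_component_min = 0.2) {
  stopifnot(inherits(vol, "ct_volume"))
  d <- dim(vol$voxels)
  if (is.null(exterior)) {
    exterior <- tryCatch(exterior_air_mask(vol),
                         error = function(e) NULL)
  }
  interior_air <- vol$voxels < lung_cut
  if (!is.null(exterior)) {
    check_registered(vol, exterior)
    interior_air <- interior_air & !exterior$grid
  }
  lab <- label_array(interior_air)
  sizes <- tabulate(lab)
  voxvol <- prod(vol$spacing) / 1000
  if (length(sizes) == 0L || max(sizes) * voxvol < min_lung_ml)
    stop("no lung found: no interior air component of at least ",
         min_lung_ml, " mL")
  ord <- order(sizes, decreasing = TRUE)
  keep <- ord[1]
  if (length(ord) > 1L && sizes[ord[2]] >= second_component_min * sizes[ord[1]])
    keep <- c(keep, ord[2])
  lung <- array(lab %in% keep, d)
  if (closing_radius_vox > 0) {
    r <- rep(closing_radius_vox, 3)
    lung <- array(.morph_ball(.morph_ball(lung, d, r, TRUE), d, r, FALSE), d)
  }
  binary_mask(lung, "lung", vol$spacing, vol$scan_id)
}

# Geodesic dilation: add 6-neighbours of the mask that satisfy `cond`,
# `iter` times. Used to refine a conservative lumen core out to the 50%
# partial-volume boundary.
grow_into <- function(mask, cond, iter) {
  d <- dim(mask)
  for (i in seq_len(iter)) {
    grown <- array(.morph_ball(mask, d, c(1, 1, 1), TRUE), d)
    nxt <- mask | (grown & cond)
    if (identical(nxt, mask)) break
    mask <- nxt
  }
  mask
}

# Locate a trachea seed: the most superior interior-air component whose
# in-plane centroid lies near the body centroid. Returns a 0-based linear
# index, or NA when nothing qualifies.
find_trachea_seed <- function(vol, exterior, airway_cut, min_seed_ml = 0.2) {
  d <- dim(vol$voxels)
  air <- vol$voxels < airway_cut
  if (!is.null(exterior)) air <- air & !exterior$grid
  lab <- label_array(air)
  sizes <- tabulate(lab)
  voxvol <- prod(vol$spacing) / 1000
  cand <- which(sizes * voxvol >= min_seed_ml)
  if (length(cand) == 0L) return(NA_integer_)
  body <- vol$voxels > -500
  if (!any(body)) return(NA_integer_)
  bidx <- which(body, arr.ind = TRUE)
  bc <- colMeans(bidx)[1:2] * vol$spacing[1:2]
  fov <- d[1:2] * vol$spacing[1:2]
  best <- NA_integer_; best_top <- -Inf
  for (cc in cand) {
    idx <- which(lab == cc, arr.ind = TRUE)
    ctr <- colMeans(idx)[1:2] * vol$spacing[1:2]
    if (sqrt(sum((ctr - bc)^2)) > 0.1 * min(fov)) next
    top <- max(idx[, 3])
    if (top > best_top) {
      best_top <- top
      sel <- idx[idx[, 3] == top, , drop = FALSE]
      # of the topmost voxels, take the one nearest the component axis
      dc <- (sel[, 1] * vol$spacing[1] - ctr[1])^2 +
            (sel[, 2] * vol$spacing[2] - ctr[2])^2
      s <- sel[which.min(dc), ]
      best <- (s[1] - 1L) + d[1] * ((s[2] - 1L) + d[2] * (s[3] - 1L))
    }
  }
  as.integer(best)
}

#' Segment the large airways
#'
#' Seeded region growing from a trachea seed (the most superior interior
#' air component near the body centroid) with inclusion criterion
#' `HU < airway_cut`. Leak control: if one breadth-first layer more than
#' doubles the grown volume (once the region exceeds `leak_min_ml`), the
#' threshold is stepped down 10 HU and the growth retried, at most
#' `max_retries` times. When no seed is found an empty mask is returned
#' with a warning and the pipeline falls back to the exterior-air
#' reference alone.
#'
#' The strict `HU < -950` criterion finds a conservative lumen core: for
#' an air-filled lumen inside soft tissue it stops at the 5%
#' partial-volume level, about `1.6 * psf_sigma` inside the anatomical
#' wall. The core is therefore refined by a geodesic dilation of at most
#' `refine_iter` voxels constrained to voxels below `refine_cut` (the
#' air / soft-tissue midpoint, i.e. the 50% partial-volume level), which
#' places the mask boundary at the physical lumen wall without risking
#' leaks into the parenchyma.
#'
#' @param vol a [ct_volume()].
#' @param lung a lung [binary_mask()] (asserts lungs were found).
#' @param airway_cut initial inclusion threshold (HU).
#' @param exterior optional precomputed exterior-air mask.
#' @param leak_factor per-layer growth factor that triggers leak control.
#' @param leak_min_ml grown volume below which leak control stays off
#'   (early layers grow geometrically from a point seed).
#' @param step_hu threshold decrement per retry.
#' @param max_retries maximum leak-control retries.
#' @param refine_iter maximum lumen-boundary refinement distance (voxels).
#' @param refine_cut HU cut bounding the refinement (50% partial-volume
#'   level of an air lumen in soft tissue).
#' @return A [binary_mask()] with role `airway`.
#' @export
segment_airways <- function(vol, lung, airway_cut = -950, exterior = NULL,
                            leak_factor = 2, leak_min_ml = 0.5,
                            step_hu = 10, max_retries = 5,
                            refine_iter = 2, refine_cut = -500) {
  stopifnot(inherits(vol, "ct_volume"), inherits(lung, "binary_mask"))
  check_registered(vol, lung)
  d <- dim(vol$voxels)
  if (is.null(exterior))
    exterior <- tryCatch(exterior_air_mask(vol), error = function(e) NULL)
  seed <- find_trachea_seed(vol, exterior, airway_cut)
  if (is.na(seed)) {
    warning("no trachea seed found; returning an empty airway mask ",
            "(air reference falls back to exterior air)")
    return(binary_mask(array(FALSE, d), "airway", vol$spacing, vol$scan_id))
  }
  min_check <- as.integer(ceiling(leak_min_ml / (prod(vol$spacing) / 1000)))
  thr <- airway_cut
  res <- NULL
  for (attempt in seq_len(max_retries + 1L)) {
    res <- .region_grow(as.numeric(vol$voxels), d, seed, thr,
                        leak_factor, min_check)
    if (!res$leaked) break
    thr <- thr - step_hu
  }
  if (res$leaked) {
    warning(sprintf(
      "airway growth still leaking after %d retries (final threshold %g HU); using last attempt",
      max_retries, thr))
  } else if (res$size == 0L && attempt > 1L) {
    warning(sprintf(
      "airway leak control stepped the threshold to %g HU, below the seed attenuation; returning an empty airway mask",
      thr))
  }
  mask <- array(res$mask, d)
  if (refine_iter > 0 && any(mask)) {
    cond <- vol$voxels < refine_cut
    if (!is.null(exterior)) cond <- cond & !exterior$grid
    mask <- grow_into(mask, cond, refine_iter)
  }
  binary_mask(mask, "airway", vol$spacing, vol$scan_id)
}

#' Run the full anatomy segmentation
#'
#' Convenience wrapper producing the exterior-air, lung and airway masks
#' used by [run_automatic()].
#'
#' @param vol a [ct_volume()].
#' @param config pipeline constants, see [cyst_config()].
#' @return list with elements `exterior`, `lung`, `airway`.
#' @export
segment_anatomy <- function(vol, config = cyst_config()) {
  exterior <- tryCatch(exterior_air_mask(vol, config$air_cut),
                       error = function(e) NULL)
  lung <- segment_lungs(vol, lung_cut = config$lung_cut, exterior = exterior,
                        closing_radius_vox = config$closing_radius_vox,
                        min_lung_ml = config$min_lung_ml)
  airway <- segment_airways(vol, lung, airway_cut = config$airway_cut,
                            exterior = exterior,
                            leak_factor = config$leak_factor,
                            leak_min_ml = config$leak_min_ml,
                            step_hu = config$leak_step_hu,
                            max_retries = config$leak_retries)
  # contract: the three masks are pairwise disjoint
  if (!is.null(exterior)) {
    lung$grid <- lung$grid & !exterior$grid
    airway$grid <- airway$grid & !exterior$grid
  }
  lung$grid <- lung$grid & !airway$grid
  list(exterior = exterior, lung = lung, airway = airway)
}
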