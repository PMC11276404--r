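# Synthetic thoracic CT phantom with known lung / airway / cyst geometry.

#' Phantom specification
#'
#' Parameters of the synthetic thoracic CT phantom: a soft-tissue body
#' (elliptic cylinder) surrounded by air, two ellipsoidal lung fields of
#' noisy parenchyma, a tracheal air tube between them, and air-filled
#' spherical cysts placed inside the lungs. The anatomy is blurred with a
#' Gaussian point-spread function (partial-volume effect), white
#' reconstruction noise is added, and finally a uniform calibration shift
#' emulates scanner drift.
#'
#' Cyst sizes follow the morphology of diffuse cystic lung disease:
#' numerous small cysts and progressively fewer large ones. Radii are the
#' quantiles of a power-law number-size distribution
#' `n(r) proportional to r^-cyst_size_alpha` over `cyst_radius_range`,
#' taken deterministically (largest placed first) so the total cyst
#' volume — and hence the true cyst fraction — is stable across seeds;
#' only the positions are random. The defaults give a true fraction near
#' 10% of the roughly 460 mL lung field, with about a quarter of the cyst
#' volume in sub-4 mm cysts whose partial-volume-blurred attenuation sits
#' near the segmentation threshold, as in real disease.
#'
#' @param shape grid dimensions `(nx, ny, nz)`.
#' @param spacing voxel spacing in mm.
#' @param body_hu mean soft-tissue attenuation (HU).
#' @param parenchyma_mu,parenchyma_sigma mean and texture SD of the lung
#'   parenchyma (HU), applied before the PSF blur.
#' @param cyst_hu attenuation inside cysts and other air spaces (HU).
#' @param cyst_count number of cysts.
#' @param cyst_radius_range `(min, max)` cyst radius in mm.
#' @param cyst_size_alpha exponent of the power-law number-size
#'   distribution; larger values skew the population toward small cysts.
#' @param cyst_radii optional explicit radius vector (mm) overriding the
#'   size distribution (e.g. a single sphere for analytic checks).
#' @param airway_radius tracheal tube radius in mm (adult trachea scale).
#' @param airway_z_mm axial extent `(z_lo, z_hi)` of the tube in mm; the
#'   top must clear the lung apices so the trachea is the most superior
#'   interior air structure.
#' @param lung_semi_axes_mm semi-axes of each lung ellipsoid in mm.
#' @param lung_offset_mm lateral offset of each lung centre from the body
#'   axis in mm.
#' @param body_semi_axes_mm in-plane semi-axes of the body cylinder in mm.
#' @param psf_sigma Gaussian point-spread sigma in mm.
#' @param noise_sigma SD of white reconstruction noise (HU), added after
#'   the blur.
#' @param calibration_shift uniform additive HU drift applied last.
#' @param seed integer seed; identical spec + seed gives bit-identical
#'   output.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(128, 128, 96),
                         spacing = c(1.5, 1.5, 1.5),
                         body_hu = 0,
                         parenchyma_mu = -850, parenchyma_sigma = 40,
                         cyst_hu = -1000,
                         cyst_count = 180,
                         cyst_radius_range = c(2, 10),
                         cyst_size_alpha = 3,
                         cyst_radii = NULL,
                         airway_radius = 9,
                         airway_z_mm = c(60, 138),
                         lung_semi_axes_mm = c(27, 36, 57),
                         lung_offset_mm = 45,
                         body_semi_axes_mm = c(84, 66),
                         psf_sigma = 0.8,
                         noise_sigma = 33,
                         calibration_shift = 0,
                         seed = 20240715) {
  spec <- list(shape = as.integer(shape), spacing = as.numeric(spacing),
               body_hu = body_hu, parenchyma_mu = parenchyma_mu,
               parenchyma_sigma = parenchyma_sigma, cyst_hu = cyst_hu,
               cyst_count = as.integer(cyst_count),
               cyst_radius_range = as.numeric(cyst_radius_range),
               cyst_size_alpha = cyst_size_alpha,
               cyst_radii = if (is.null(cyst_radii)) NULL else as.numeric(cyst_radii),
               airway_radius = airway_radius, airway_z_mm = as.numeric(airway_z_mm),
               lung_semi_axes_mm = as.numeric(lung_semi_axes_mm),
               lung_offset_mm = lung_offset_mm,
               body_semi_axes_mm = as.numeric(body_semi_axes_mm),
               psf_sigma = psf_sigma, noise_sigma = noise_sigma,
               calibration_shift = calibration_shift,
               seed = as.integer(seed))
  if (length(spec$shape) != 3L || any(spec$shape < 8L))
    stop("`shape` must be 3 dimensions of at least 8 voxels")
  if (any(spec$spacing <= 0)) stop("`spacing` must be positive")
  if (!(spec$cyst_hu < spec$parenchyma_mu && spec$parenchyma_mu < spec$body_hu))
    stop("need cyst_hu < parenchyma_mu < body_hu")
  if (spec$cyst_count < 0) stop("`cyst_count` must be non-negative")
  rr <- spec$cyst_radius_range
  if (length(rr) != 2L || any(rr <= 0) || rr[1] > rr[2])
    stop("`cyst_radius_range` must be positive (min, max)")
  if (!is.null(spec$cyst_radii)) {
    if (any(spec$cyst_radii <= 0)) stop("explicit cyst radii must be positive")
    spec$cyst_count <- length(spec$cyst_radii)
  }
  rmax <- if (is.null(spec$cyst_radii)) rr[2] else max(spec$cyst_radii)
  if (rmax >= min(spec$lung_semi_axes_mm))
    stop("cyst radii must be smaller than the lung minor semi-axis")
  if (spec$airway_radius < 0) stop("`airway_radius` must be non-negative")
  class(spec) <- "phantom_spec"
  spec
}

# Deterministic cyst radii: mid-quantiles of the power-law number-size
# distribution n(r) ~ r^-alpha over [rmin, rmax].
cyst_radii_for <- function(spec) {
  if (!is.null(spec$cyst_radii)) return(spec$cyst_radii)
  n <- spec$cyst_count
  if (n == 0L) return(numeric(0))
  rr <- spec$cyst_radius_range
  a <- spec$cyst_size_alpha
  q <- (seq_len(n) - 0.5) / n
  if (abs(a - 1) < 1e-12) {
    exp(log(rr[1]) + q * (log(rr[2]) - log(rr[1])))
  } else {
    p <- 1 - a
    (rr[1]^p + q * (rr[2]^p - rr[1]^p))^(1 / p)
  }
}

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

#' Generate a synthetic thoracic CT phantom
#'
#' Builds the phantom described by a [phantom_spec()]: anatomy is laid down
#' at its mean attenuations, cysts are placed by seeded rejection sampling
#' (fully inside the lung field, never touching the airway tube; mutual
#' overlap is allowed, as real cysts can abut), then the grid is blurred,
#' noise is added and the calibration shift applied. Ground-truth masks are
#' recorded before any degradation, so the true cyst fraction is a purely
#' geometric quantity, unaffected by blur, noise or calibration shift.
#'
#' @param spec a [phantom_spec()].
#' @return A list of class `cyst_phantom` with elements `volume`
#'   ([ct_volume()]), `lung`, `airway`, `cyst` (truth [binary_mask()]s),
#'   `true_fraction_pct` (100 x cyst-truth voxels within the lung truth /
#'   lung-truth voxels) and `spec`.
#' @examples
#' ph <- generate_phantom(phantom_spec(shape = c(48, 48, 40), spacing = c(3, 3, 3),
#'                                     cyst_count = 4, cyst_radius_range = c(6, 10),
#'                                     seed = 1))
#' ph$true_fraction_pct
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, build_phantom(spec))
}

build_phantom <- function(spec) {
  d <- spec$shape; sp <- spec$spacing
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  xs <- (seq_len(nx) - 0.5) * sp[1]
  ys <- (seq_len(ny) - 0.5) * sp[2]
  zs <- (seq_len(nz) - 0.5) * sp[3]
  cx <- nx * sp[1] / 2; cy <- ny * sp[2] / 2

  # body: elliptic cylinder along z
  bx <- ((xs - cx) / spec$body_semi_axes_mm[1])^2
  by <- ((ys - cy) / spec$body_semi_axes_mm[2])^2
  body2d <- outer(bx, by, `+`) <= 1
  body <- array(body2d, c(nx, ny, nz))

  # lungs: two ellipsoids, centred at the mid-plane of the grid
  cz <- nz * sp[3] / 2
  ax <- spec$lung_semi_axes_mm[1]; ay <- spec$lung_semi_axes_mm[2]
  az <- spec$lung_semi_axes_mm[3]
  lung_centres <- list(c(cx - spec$lung_offset_mm, cy, cz),
                       c(cx + spec$lung_offset_mm, cy, cz))
  lung <- array(FALSE, d)
  for (ctr in lung_centres) {
    ex <- ((xs - ctr[1]) / ax)^2
    ey <- ((ys - ctr[2]) / ay)^2
    ez <- ((zs - ctr[3]) / az)^2
    lung <- lung | outer(outer(ex, ey, `+`), ez, `+`) <= 1
  }
  if (!all(lung <= body)) stop("lung field extends outside the body; adjust geometry")

  # airway: vertical tube between the lungs
  tx <- (xs - cx)^2
  ty <- (ys - cy)^2
  airway <- array(FALSE, d)
  if (spec$airway_radius > 0) {
    tube2d <- outer(tx, ty, `+`) <= spec$airway_radius^2
    inz <- zs >= spec$airway_z_mm[1] & zs <= spec$airway_z_mm[2]
    airway[, , inz] <- tube2d
  }
  if (any(airway & lung)) stop("airway tube intersects the lung field; adjust geometry")

  # cysts: evenly spaced radii, largest first; random positions
  cyst <- array(FALSE, d)
  centres <- NULL
  if (spec$cyst_count > 0) {
    radii <- sort(cyst_radii_for(spec), decreasing = TRUE)
    centres <- matrix(NA_real_, spec$cyst_count, 4)
    for (i in seq_len(spec$cyst_count)) {
      r <- radii[i]
      if (1.02 * r >= min(c(ax, ay, az)))
        stop(sprintf(
          "cyst radius %.1f mm cannot fit inside lung semi-axes (%g, %g, %g) mm",
          r, ax, ay, az))
      placed <- FALSE
      for (try in seq_len(500L)) {
        ctr <- lung_centres[[sample.int(2L, 1L)]]
        # sample inside the margin-shrunk ellipsoid
        u <- runif(3, -1, 1)
        if (sum(u^2) > 1) next
        pos <- ctr + u * (c(ax, ay, az) - 1.02 * r)
        # keep clear of the airway tube
        dxy <- sqrt((pos[1] - cx)^2 + (pos[2] - cy)^2)
        z_clear <- pos[3] - r > spec$airway_z_mm[2] || pos[3] + r < spec$airway_z_mm[1]
        if (dxy < spec$airway_radius + r && !z_clear) next
        centres[i, ] <- c(pos, r)
        placed <- TRUE
        break
      }
      if (!placed)
        stop(sprintf(
          "could not place cyst %d (radius %.1f mm) inside the lung field away from the airway after 500 tries",
          i, r))
      # stamp the sphere over its bounding box
      ix <- which(abs(xs - centres[i, 1]) <= r)
      iy <- which(abs(ys - centres[i, 2]) <= r)
      iz <- which(abs(zs - centres[i, 3]) <= r)
      dx2 <- (xs[ix] - centres[i, 1])^2
      dy2 <- (ys[iy] - centres[i, 2])^2
      dz2 <- (zs[iz] - centres[i, 3])^2
      inside <- outer(outer(dx2, dy2, `+`), dz2, `+`) <= r^2
      cyst[ix, iy, iz] <- cyst[ix, iy, iz] | inside
    }
    cyst <- cyst & lung
  }

  # attenuation map, then degradation
  hu <- array(-1000, d)
  hu[body] <- spec$body_hu
  nlung <- sum(lung)
  hu[lung] <- rnorm(nlung, spec$parenchyma_mu, spec$parenchyma_sigma)
  hu[airway] <- spec$cyst_hu
  hu[cyst] <- spec$cyst_hu
  sigma_vox <- spec$psf_sigma / sp
  v <- .gauss_blur3(as.numeric(hu), d, sigma_vox)
  if (spec$noise_sigma > 0) v <- v + rnorm(length(v), 0, spec$noise_sigma)
  v <- v + spec$calibration_shift
  hu <- array(v, d)

  vol <- ct_volume(hu, sp, scan_id = sprintf("phantom-seed%d", spec$seed))
  structure(list(
    volume = vol,
    lung = binary_mask(lung, "lung", sp, vol$scan_id),
    airway = binary_mask(airway, "airway", sp, vol$scan_id),
    cyst = binary_mask(cyst, "cyst", sp, vol$scan_id),
    true_fraction_pct = if (sum(lung) > 0) 100 * sum(cyst & lung) / sum(lung) else NA_real_,
    cyst_centres = centres,
    spec = spec
  ), class = "cyst_phantom")
}

#' @export
print.cyst_phantom <- function(x, ...) {
  cat(sprintf("<cyst_phantom> %s: lung %.0f mL, %d cysts, true fraction %.2f%%\n",
              x$volume$scan_id, mask_volume_ml(x$lung),
              if (is.null(x$cyst_centres)) 0L else nrow(x$cyst_centres),
              x$true_fraction_pct))
  invisible(x)
}

#' Apply a uniform calibration shift to a volume
#'
#' Adds `delta` HU to every voxel, emulating scanner calibration drift
#' (the variability the adaptive threshold method is designed to absorb).
#' Metadata is unchanged.
#'
#' @param vol a [ct_volume()].
#' @param delta shift in HU.
#' @return The shifted [ct_volume()].
#' @export
apply_calibration_shift <- function(vol, delta) {
  stopifnot(inherits(vol, "ct_volume"))
  vol$voxels <- vol$voxels + delta
  vol
}
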