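# Core method: location-specific adaptive thresholds from air references
# and local parenchyma; cyst segmentation and scoring; fixed-threshold
# semi-automatic baseline.

#' Pipeline constants
#'
#' All constants of the automatic pipeline in one flat list, embedded in
#' every result for provenance. `f` is calibrated so that nominal anatomy
#' (air reference -1000 HU, parenchyma -850 HU) reproduces the standard
#' global cyst threshold of -940 HU.
#'
#' @param air_cut HU cut for exterior air (midpoint air / soft tissue).
#' @param lung_cut HU cut for air-like voxels inside the body.
#' @param airway_cut inclusion threshold for airway region growing.
#' @param closing_radius_vox closing radius (voxels) for the lung mask.
#' @param min_lung_ml smallest credible lung volume (mL).
#' @param window_radius_mm half-width of the cubic local-parenchyma window.
#' @param percentile percentile of windowed lung HU used as the local
#'   parenchyma estimate (an upper percentile suppresses the darker cyst
#'   voxels).
#' @param min_window_count windows with fewer lung voxels fall back to the
#'   global lung percentile.
#' @param f interpolation fraction between the air reference and the local
#'   parenchyma, in (0, 1).
#' @param theta_fixed fixed global threshold of the semi-automatic method
#'   (HU).
#' @param min_component_ml cyst components smaller than this are removed.
#' @param leak_factor,leak_min_ml,leak_step_hu,leak_retries airway leak
#'   control, see [segment_airways()].
#' @return A named list of class `cyst_config`.
#' @export
cyst_config <- function(air_cut = -500, lung_cut = -320, airway_cut = -950,
                        closing_radius_vox = 2, min_lung_ml = 50,
                        window_radius_mm = 15, percentile = 75,
                        min_window_count = 100, f = 0.4,
                        theta_fixed = -940, min_component_ml = 0.004,
                        leak_factor = 2, leak_min_ml = 0.5,
                        leak_step_hu = 10, leak_retries = 5) {
  cfg <- list(air_cut = air_cut, lung_cut = lung_cut, airway_cut = airway_cut,
              closing_radius_vox = closing_radius_vox, min_lung_ml = min_lung_ml,
              window_radius_mm = window_radius_mm, percentile = percentile,
              min_window_count = min_window_count, f = f,
              theta_fixed = theta_fixed, min_component_ml = min_component_ml,
              leak_factor = leak_factor, leak_min_ml = leak_min_ml,
              leak_step_hu = leak_step_hu, leak_retries = leak_retries)
  if (cfg$f <= 0 || cfg$f >= 1) stop("`f` must lie strictly in (0, 1)")
  if (cfg$percentile <= 0 || cfg$percentile >= 100)
    stop("`percentile` must lie strictly in (0, 100)")
  class(cfg) <- "cyst_config"
  cfg
}

#' Air attenuation reference
#'
#' The scan-specific air reference A: the mean of the median HU over the
#' exterior air and the median HU over the airway lumen. When one region
#' is empty the other's median is used alone; both empty is an error.
#' Because medians track a uniform calibration shift exactly, A carries
#' the scanner drift into the adaptive threshold.
#'
#' Boundary voxels of either region are partial-volume mixtures with the
#' adjacent tissue and would bias the median upward, so each mask is
#' eroded by `erode_vox` voxels before the median is taken — the standard
#' practice for tracheal-air calibration ROIs. A mask whose eroded core
#' falls below 32 voxels is used uneroded.
#'
#' @param vol a [ct_volume()].
#' @param exterior exterior-air [binary_mask()] or `NULL`.
#' @param airway airway [binary_mask()] or `NULL` / empty.
#' @param erode_vox erosion radius (voxels) applied to each reference
#'   region before its median.
#' @return Air reference in HU (scalar).
#' @export
air_reference <- function(vol, exterior = NULL, airway = NULL, erode_vox = 2) {
  stopifnot(inherits(vol, "ct_volume"))
  d <- dim(vol$voxels)
  core_median <- function(mask) {
    g <- mask$grid
    if (erode_vox > 0) {
      er <- array(.morph_ball(g, d, rep(erode_vox, 3), FALSE), d)
      if (sum(er) >= 32L) g <- er
    }
    median(vol$voxels[g])
  }
  meds <- c()
  if (!is.null(exterior) && sum(exterior$grid) > 0) {
    check_registered(vol, exterior)
    meds <- c(meds, core_median(exterior))
  }
  if (!is.null(airway) && sum(airway$grid) > 0) {
    check_registered(vol, airway)
    meds <- c(meds, core_median(airway))
  }
  if (length(meds) == 0L)
    stop("both air-reference masks are empty: cannot estimate the air attenuation")
  mean(meds)
}

# Global lung percentile with the same 1-HU quantisation and nearest-rank
# definition as the windowed field, so a window covering the whole lung
# reproduces it exactly.
#' Global lung HU percentile (quantised nearest-rank)
#' @param vol a [ct_volume()].
#' @param lung lung [binary_mask()].
#' @param percentile percentile in (0, 100).
#' @return HU value (1-HU quantised).
#' @export
lung_percentile <- function(vol, lung, percentile = 75) {
  check_registered(vol, lung)
  v <- sort(round(vol$voxels[lung$grid]))
  if (length(v) == 0L) stop("empty lung mask")
  v[max(1L, ceiling(percentile / 100 * length(v)))]
}

#' Local parenchyma attenuation field
#'
#' For every lung voxel, the `percentile`-th percentile of lung-voxel HU
#' within the cubic window of half-width `window_radius_mm` centred on it.
#' The upper percentile suppresses cyst voxels, which are darker than the
#' parenchyma; windows holding fewer than `min_window_count` lung voxels
#' fall back to the global lung percentile. Values are quantised to 1 HU
#' (nearest-rank on a histogram), which makes the field exactly
#' equivariant under integer calibration shifts.
#'
#' @inheritParams lung_percentile
#' @param window_radius_mm window half-width in mm (converted per axis to
#'   voxels).
#' @param min_window_count minimum lung voxels per window.
#' @return 3-D numeric array: HU over lung voxels, `NA` elsewhere.
#' @export
parenchyma_field <- function(vol, lung, window_radius_mm = 15,
                             percentile = 75, min_window_count = 100) {
  stopifnot(inherits(vol, "ct_volume"), inherits(lung, "binary_mask"))
  check_registered(vol, lung)
  if (sum(lung$grid) == 0L) stop("empty lung mask")
  d <- dim(vol$voxels)
  hw <- as.integer(pmax(0, floor(window_radius_mm / vol$spacing)))
  fallback <- lung_percentile(vol, lung, percentile)
  p <- .local_percentile(as.numeric(vol$voxels), as.logical(lung$grid), d,
                         hw, percentile, as.integer(min_window_count),
                         as.numeric(fallback))
  array(p, d)
}

#' Location-specific adaptive threshold field
#'
#' The cyst threshold interpolates between the scan's air reference A and
#' the local parenchyma estimate P(x):
#' \deqn{T(x) = A + f (P(x) - A)}
#' With nominal anatomy (A = -1000, P = -850) the default f = 0.4
#' reproduces the standard global threshold of -940 HU exactly. Any voxel
#' where P(x) <= A is clamped to A + 1 HU and counted in the
#' `n_clamped` attribute.
#'
#' @param A air reference (HU).
#' @param P local parenchyma estimate: array from [parenchyma_field()] or
#'   a scalar.
#' @param f interpolation fraction in (0, 1).
#' @return A `threshold_field` object: list with `values` (same shape as
#'   `P`), `mode = "adaptive"`, `air_reference`, `f`, `n_clamped` and a
#'   min/median/max `summary` over defined voxels.
#' @examples
#' adaptive_threshold_field(-1000, -850)$values  # -940
#' @export
adaptive_threshold_field <- function(A, P, f = 0.4) {
  if (f < 0 || f >= 1) stop("`f` must lie in [0, 1)")
  values <- A + f * (P - A)
  bad <- !is.na(values) & P <= A
  n_clamped <- sum(bad)
  if (n_clamped > 0) {
    values[bad] <- A + 1
    warning(n_clamped, " voxel(s) had parenchyma estimate <= air reference; ",
            "threshold clamped to A + 1 HU")
  }
  threshold_field(values, "adaptive", A, f, n_clamped)
}

threshold_field <- function(values, mode, air_reference, f = NA_real_,
                            n_clamped = 0L) {
  def <- values[!is.na(values)]
  structure(list(
    values = values, mode = mode, air_reference = air_reference, f = f,
    n_clamped = n_clamped,
    summary = c(min = if (length(def)) min(def) else NA_real_,
                median = if (length(def)) median(def) else NA_real_,
                max = if (length(def)) max(def) else NA_real_)
  ), class = "threshold_field")
}

#' @export
print.threshold_field <- function(x, ...) {
  cat(sprintf("<threshold_field> mode=%s, A=%.1f HU, T in [%.0f, %.0f] (median %.0f)\n",
              x$mode, x$air_reference, x$summary["min"], x$summary["max"],
              x$summary["median"]))
  invisible(x)
}

#' Segment cysts under a threshold field
#'
#' Cyst voxels are lung voxels strictly below their threshold
#' (`HU < T(x)`; a tie at the threshold is not a cyst), minus the airway;
#' 6-connected components smaller than `min_component_ml` are removed as
#' noise.
#'
#' @param vol a [ct_volume()].
#' @param lung,airway [binary_mask()]s; `airway` may be `NULL`.
#' @param threshold a `threshold_field`, or a scalar HU threshold.
#' @param min_component_ml minimum component volume retained (mL).
#' @return A [binary_mask()] with role `cyst`.
#' @export
segment_cysts <- function(vol, lung, airway = NULL, threshold,
                          min_component_ml = 0.004) {
  stopifnot(inherits(vol, "ct_volume"), inherits(lung, "binary_mask"))
  check_registered(vol, lung, airway)
  d <- dim(vol$voxels)
  tv <- if (inherits(threshold, "threshold_field")) threshold$values else threshold
  cyst <- lung$grid & (vol$voxels < tv)
  cyst[is.na(cyst)] <- FALSE
  if (!is.null(airway)) cyst <- cyst & !airway$grid
  if (min_component_ml > 0 && any(cyst)) {
    lab <- label_array(cyst)
    sizes <- tabulate(lab)
    voxvol <- prod(vol$spacing) / 1000
    small <- which(sizes * voxvol < min_component_ml)
    if (length(small)) cyst[array(lab %in% small, d)] <- FALSE
  }
  binary_mask(cyst, "cyst", vol$spacing, vol$scan_id)
}

#' Fixed-threshold (semi-automatic) cyst segmentation
#'
#' The standard semi-automatic core: a constant global threshold
#' `theta + operator_offset`, where the offset stands in for the trained
#' operator's visual up/down adjustment around the fixed -940 HU default.
#'
#' @inheritParams segment_cysts
#' @param theta fixed global threshold (HU).
#' @param operator_offset operator adjustment (HU), positive or negative.
#' @return A [binary_mask()] with role `cyst`.
#' @export
fixed_threshold_segment <- function(vol, lung, airway = NULL, theta = -940,
                                    operator_offset = 0,
                                    min_component_ml = 0.004) {
  segment_cysts(vol, lung, airway, threshold = theta + operator_offset,
                min_component_ml = min_component_ml)
}

#' Cyst score from masks
#'
#' The cyst score is the percentage of lung volume occupied by cysts:
#' `100 * volume(cyst) / volume(lung minus airway)`. The denominator
#' includes the cyst voxels themselves; the large airways are excluded
#' from both numerator and denominator.
#'
#' @param cyst,lung,airway [binary_mask()]s; `airway` may be `NULL`.
#' @param method method tag stored in the result.
#' @param threshold optional `threshold_field` for the summary.
#' @param parameters optional config list stored for provenance.
#' @return A `cyst_score_result`: list with `scan_id`, `method`,
#'   `cyst_volume_ml`, `lung_volume_ml`, `score_pct`, `threshold_summary`,
#'   `parameters`.
#' @export
cyst_score <- function(cyst, lung, airway = NULL, method = "automatic",
                       threshold = NULL, parameters = NULL) {
  stopifnot(inherits(cyst, "binary_mask"), inherits(lung, "binary_mask"))
  if (!identical(dim(cyst$grid), dim(lung$grid)))
    stop("cyst and lung masks have different shapes")
  denom_grid <- lung$grid
  if (!is.null(airway)) denom_grid <- denom_grid & !airway$grid
  if (any(cyst$grid & !denom_grid))
    stop("cyst mask is not contained in lung-minus-airway")
  lung_ml <- sum(denom_grid) * lung$voxel_volume_ml
  if (lung_ml <= 0) stop("empty lung denominator")
  cyst_ml <- mask_volume_ml(cyst)
  structure(list(
    scan_id = lung$scan_id, method = method,
    cyst_volume_ml = cyst_ml, lung_volume_ml = lung_ml,
    score_pct = 100 * cyst_ml / lung_ml,
    threshold_summary = if (!is.null(threshold)) threshold$summary else NULL,
    parameters = parameters
  ), class = "cyst_score_result")
}

#' @export
print.cyst_score_result <- function(x, ...) {
  cat(sprintf("<cyst_score_result> %s [%s]: score %.2f%% (cysts %.1f mL / lung %.1f mL)\n",
              x$scan_id, x$method, x$score_pct, x$cyst_volume_ml,
              x$lung_volume_ml))
  invisible(x)
}

#' Fully automatic cyst score
#'
#' End-to-end automatic pipeline: anatomy segmentation (exterior air,
#' lungs, large airways), air reference from the exterior/airway medians,
#' local parenchyma field, adaptive threshold field
#' `T(x) = A + f (P(x) - A)`, cyst segmentation and scoring. Deterministic
#' given the volume.
#'
#' @param vol a [ct_volume()].
#' @param config pipeline constants, see [cyst_config()].
#' @return A `cyst_score_result` with `method = "automatic"`; the cyst
#'   mask and anatomy masks are attached as attribute `masks`.
#' @export
run_automatic <- function(vol, config = cyst_config()) {
  stopifnot(inherits(vol, "ct_volume"))
  anat <- segment_anatomy(vol, config)
  A <- air_reference(vol, anat$exterior, anat$airway)
  P <- parenchyma_field(vol, anat$lung,
                        window_radius_mm = config$window_radius_mm,
                        percentile = config$percentile,
                        min_window_count = config$min_window_count)
  thr <- adaptive_threshold_field(A, P, f = config$f)
  cyst <- segment_cysts(vol, anat$lung, anat$airway, thr,
                        min_component_ml = config$min_component_ml)
  res <- cyst_score(cyst, anat$lung, anat$airway, method = "automatic",
                    threshold = thr, parameters = unclass(config))
  attr(res, "masks") <- list(cyst = cyst, lung = anat$lung,
                             airway = anat$airway, exterior = anat$exterior)
  res
}

#' Semi-automatic (fixed-threshold) cyst score
#'
#' Same anatomy segmentation as [run_automatic()] but with the constant
#' global threshold `theta + operator_offset` of the standard
#' semi-automatic procedure.
#'
#' @inheritParams run_automatic
#' @param operator_offset operator threshold adjustment (HU).
#' @return A `cyst_score_result` with `method = "semiauto"`.
#' @export
run_semiauto <- function(vol, operator_offset = 0, config = cyst_config()) {
  stopifnot(inherits(vol, "ct_volume"))
  anat <- segment_anatomy(vol, config)
  theta <- config$theta_fixed + operator_offset
  cyst <- fixed_threshold_segment(vol, anat$lung, anat$airway,
                                  theta = config$theta_fixed,
                                  operator_offset = operator_offset,
                                  min_component_ml = config$min_component_ml)
  thr <- threshold_field(theta, "fixed", theta)
  res <- cyst_score(cyst, anat$lung, anat$airway, method = "semiauto",
                    threshold = thr, parameters = c(unclass(config),
                                                    operator_offset = operator_offset))
  attr(res, "masks") <- list(cyst = cyst, lung = anat$lung,
                             airway = anat$airway, exterior = anat$exterior)
  res
}
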