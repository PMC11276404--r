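# Independent oracles used to cross-check the pipeline implementation.

# Per-voxel enumeration oracle for cyst segmentation: direct vectorised
# thresholding plus component filtering through igraph (an implementation
# route independent of the package's C++ labelling).
enum_cyst_oracle <- function(vox, lung, airway, tvals, spacing,
                             min_component_ml = 0) {
  d <- dim(vox)
  sel <- lung & (vox < tvals)
  if (!is.null(airway)) sel <- sel & !airway
  idx <- which(sel)
  out <- array(FALSE, d)
  if (length(idx) == 0L) return(out)
  if (min_component_ml <= 0) { out[idx] <- TRUE; return(out) }
  ai <- arrayInd(idx, d)
  edges <- NULL
  offs <- c(1L, d[1], d[1] * d[2])
  for (axis in 1:3) {
    ok <- ai[, axis] < d[axis]
    nb <- idx[ok] + offs[axis]
    m <- match(nb, idx)
    keep <- !is.na(m)
    if (any(keep))
      edges <- rbind(edges, cbind(which(ok)[keep], m[keep]))
  }
  if (is.null(edges)) {
    memb <- seq_along(idx); csize <- rep(1L, length(idx))
  } else {
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
    comp <- igraph::components(g)
    memb <- comp$membership; csize <- comp$csize
  }
  voxvol <- prod(spacing) / 1000
  keepvox <- idx[csize[memb] * voxvol >= min_component_ml]
  out[keepvox] <- TRUE
  out
}

# Windowed percentile oracle: direct sort-based nearest-rank percentile of
# 1-HU-quantised values, evaluated at selected voxels.
window_percentile_oracle <- function(vox, lung, at, hw_vox, p, min_count,
                                     fallback) {
  d <- dim(vox)
  vapply(seq_len(nrow(at)), function(i) {
    c0 <- at[i, ]
    lo <- pmax(c0 - hw_vox, 1L)
    hi <- pmin(c0 + hw_vox, d)
    sub_v <- vox[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
    sub_m <- lung[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
    v <- sort(round(sub_v[sub_m]))
    if (length(v) < min_count) return(fallback)
    v[max(1L, ceiling(p / 100 * length(v)))]
  }, numeric(1))
}

# Draw n samples from a trivariate normal with unit variances and the
# given correlations (via Cholesky).
rmvnorm3 <- function(n, r12, r13, r23) {
  R <- matrix(c(1, r12, r13, r12, 1, r23, r13, r23, 1), 3, 3)
  matrix(rnorm(3 * n), n, 3) %*% chol(R)
}

williams_t_of <- function(x) {
  r12 <- cor(x[, 1], x[, 2]); r13 <- cor(x[, 1], x[, 3])
  r23 <- cor(x[, 2], x[, 3])
  williams_test(r12, r13, r23, nrow(x))
}
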