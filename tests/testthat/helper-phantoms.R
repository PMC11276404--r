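# Shared phantom fixtures, built once per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# Desk-scale phantom for module tests: smaller grid, same physics.
small_spec <- function(seed = 5, cyst_count = 30,
                       cyst_radius_range = c(2, 8), airway_radius = 7, ...) {
  phantom_spec(shape = c(96, 96, 64), spacing = c(1.5, 1.5, 1.5),
               body_semi_axes_mm = c(62, 50),
               lung_semi_axes_mm = c(18, 24, 30), lung_offset_mm = 31,
               airway_radius = airway_radius, airway_z_mm = c(30, 88),
               cyst_count = cyst_count, cyst_radius_range = cyst_radius_range,
               seed = seed, ...)
}

small_phantom <- function() cached("small", generate_phantom(small_spec()))

small_anatomy <- function() cached("small_anat", segment_anatomy(small_phantom()$volume))

default_phantom <- function() cached("default", generate_phantom(phantom_spec(seed = 101)))

default_auto <- function() cached("default_auto", run_automatic(default_phantom()$volume))

# Analytic body mask for a phantom spec (elliptic cylinder).
phantom_body_mask <- function(spec) {
  d <- spec$shape; sp <- spec$spacing
  xs <- (seq_len(d[1]) - 0.5) * sp[1]
  ys <- (seq_len(d[2]) - 0.5) * sp[2]
  cx <- d[1] * sp[1] / 2; cy <- d[2] * sp[2] / 2
  bx <- ((xs - cx) / spec$body_semi_axes_mm[1])^2
  by <- ((ys - cy) / spec$body_semi_axes_mm[2])^2
  array(outer(bx, by, `+`) <= 1, d)
}
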