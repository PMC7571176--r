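# Small in-code fixtures shared across test files.

# Flat-value scan with an arbitrary small geometry.
flat_scan <- function(nl = 3, nd = 5, wn = seq(500, 600, by = 5),
                      value = 1, processed = FALSE) {
  depth_scan(array(value, dim = c(nl, nd, length(wn))),
             lateral_um = seq(0, by = 0.5, length.out = nl),
             depth_um = seq(0, by = 0.5, length.out = nd),
             wavenumber_cm1 = wn, processed = processed)
}

# Scan built from a matrix of spectra (rows = spectra in depth-major,
# lateral-fastest order), mirroring the internal layout.
scan_from_spectra <- function(M, nl, nd, wn, processed = FALSE) {
  depth_scan(array(M, dim = c(nl, nd, length(wn))),
             lateral_um = seq(0, by = 0.5, length.out = nl),
             depth_um = seq(0, by = 0.5, length.out = nd),
             wavenumber_cm1 = wn, processed = processed)
}

# Downsized synthetic skin config: full spectral physics on a coarser axis
# and grid so unit tests stay fast. Axis still covers the 556 and 1008 1/cm
# bands.
small_skin_cfg <- function(...) {
  args <- list(n_lateral = 6, n_depth = 30, wn_start = 501,
               wn_stop = 1100, wn_step = 2)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(synthetic_config, args)
}

# Preprocess config matched to the shorter small-axis spectra.
small_pre_cfg <- function(...) {
  preprocess_config(shape_size = 100, ...)
}

expect_scan_equal <- function(a, b, tol = 1e-9) {
  expect_equal(a$intensities, b$intensities, tolerance = tol)
  expect_equal(a$lateral_um, b$lateral_um, tolerance = tol)
  expect_equal(a$depth_um, b$depth_um, tolerance = tol)
  expect_equal(a$wavenumber_cm1, b$wavenumber_cm1, tolerance = tol)
}
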