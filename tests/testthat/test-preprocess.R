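test_that("cosmic-ray removal is a no-op on clean scans and idempotent", {
  cfg <- small_skin_cfg(seed = 7, spike_rate = 0)
  scan <- simulate_skin_scan(cfg)$scan
  clean <- remove_cosmic_rays(scan, small_pre_cfg())
  expect_equal(clean$intensities, scan$intensities)
  expect_equal(attr(clean, "n_replaced"), 0L)

  # idempotence on a scan that did contain spikes
  spiked <- simulate_skin_scan(small_skin_cfg(seed = 8,
                                              spike_rate = 0.05))$scan
  once <- remove_cosmic_rays(spiked, small_pre_cfg())
  twice <- remove_cosmic_rays(once, small_pre_cfg())
  expect_equal(twice$intensities, once$intensities)
})

test_that("a single multiplied channel is the only value replaced", {
  cfg <- small_skin_cfg(seed = 9, spike_rate = 0)
  scan <- simulate_skin_scan(cfg)$scan
  scan$intensities[3, 10, 120] <- scan$intensities[3, 10, 120] * 50
  out <- remove_cosmic_rays(scan, small_pre_cfg())
  changed <- which(out$intensities != scan$intensities, arr.ind = TRUE)
  expect_equal(nrow(changed), 1L)
  expect_equal(unname(changed[1, ]), c(3L, 10L, 120L))
})

test_that("seeded spike injection is recovered with no false positives", {
  cfg <- small_skin_cfg(seed = 10, spike_rate = 0, noise_sd = 0.5)
  scan <- simulate_skin_scan(cfg)$scan
  nl <- dim(scan)[1]; nd <- dim(scan)[2]; nw <- dim(scan)[3]
  set.seed(123)
  n_spikes <- 40
  sites <- cbind(sample.int(nl, n_spikes, replace = TRUE),
                 sample.int(nd, n_spikes, replace = TRUE),
                 sample.int(nw, n_spikes, replace = TRUE))
  sites <- unique(sites)
  spiked <- scan
  # amplitude 20x the local (noise) SD
  spiked$intensities[sites] <- spiked$intensities[sites] + 20 * cfg$noise_sd
  out <- remove_cosmic_rays(spiked, small_pre_cfg())
  changed <- which(out$intensities != spiked$intensities, arr.ind = TRUE)
  key <- function(m) paste(m[, 1], m[, 2], m[, 3])
  hit <- key(sites) %in% key(changed)
  expect_gte(mean(hit), 0.95)
  # no modifications beyond a +-1 channel margin of injected sites
  margin <- rbind(sites,
                  cbind(sites[, 1], sites[, 2], pmax(sites[, 3] - 1, 1)),
                  cbind(sites[, 1], sites[, 2], pmin(sites[, 3] + 1, nw)))
  expect_true(all(key(changed) %in% key(margin)))
})

test_that("cosmic-ray removal needs at least 3 spectra", {
  tiny <- flat_scan(nl = 1, nd = 2)
  expect_error(remove_cosmic_rays(tiny, small_pre_cfg()), "at least 3")
})

test_that("background subtraction maps constant spectra to zero", {
  scan <- flat_scan(nl = 2, nd = 3, wn = seq(500, 1000, by = 2), value = 37)
  out <- subtract_background(scan, preprocess_config(shape_size = 80))
  expect_equal(max(abs(out$intensities)), 0)
})

test_that("background subtraction preserves a narrow peak on an offset", {
  wn <- seq_len(1024) + 500
  peak <- 40 * exp(-(wn - 900)^2 / (2 * (10 / 2.3548)^2)) # FWHM 10 samples
  spec <- peak + 100
  scan <- scan_from_spectra(matrix(spec, nrow = 1), 1, 1, wn)
  out <- subtract_background(scan, preprocess_config(shape_size = 400))
  res <- out$intensities[1, 1, ]
  expect_lt(abs(max(res) - 40) / 40, 0.05)
  free <- abs(wn - 900) > 50
  expect_lt(abs(mean(res[free])), 0.01 * 40)
})

test_that("band areas survive subtraction of a linear ramp baseline", {
  wn <- seq(501, 1300, by = 1)
  peaks <- 30 * exp(-(wn - 700)^2 / (2 * 3.4^2)) +
    50 * exp(-(wn - 1100)^2 / (2 * 3.4^2))
  ramp <- 0.05 * (wn - 501)
  cfg <- preprocess_config(shape_size = 300)
  mk <- function(spec) scan_from_spectra(matrix(spec, 1), 1, 1, wn)
  b1 <- band("p1", 700, 680, 720)
  b2 <- band("p2", 1100, 1080, 1120)
  ref <- mk(peaks)
  sub <- subtract_background(mk(peaks + ramp), cfg)
  for (b in list(b1, b2)) {
    a_ref <- band_auc(ref$intensities[1, 1, ], wn, b)
    a_sub <- band_auc(sub$intensities[1, 1, ], wn, b)
    expect_lt(abs(a_sub - a_ref) / a_ref, 0.05)
  }
})

test_that("background subtraction is invariant under a constant shift", {
  scan <- simulate_skin_scan(small_skin_cfg(seed = 4, spike_rate = 0))$scan
  cfg <- small_pre_cfg()
  base <- subtract_background(scan, cfg)
  shifted <- scan
  shifted$intensities <- shifted$intensities + 123.4
  out <- subtract_background(shifted, cfg)
  expect_equal(out$intensities, base$intensities, tolerance = 1e-8)
})

test_that("shape_size must be smaller than the spectrum length", {
  scan <- flat_scan(wn = seq(500, 600, by = 5)) # 21 channels
  expect_error(subtract_background(scan, preprocess_config(shape_size = 21)),
               "smaller than the spectrum length")
})

test_that("PCA reconstructs rank-3 data exactly with 3 components", {
  set.seed(1)
  wn <- seq(501, 700, by = 2)
  basis <- matrix(rnorm(3 * length(wn)), nrow = 3)
  coefs <- matrix(runif(12 * 3), ncol = 3)
  M <- coefs %*% basis
  scan <- scan_from_spectra(M, 3, 4, wn, processed = TRUE)
  out <- pca_denoise(scan, preprocess_config(n_components = 3))
  expect_equal(out$intensities, scan$intensities, tolerance = 1e-8)
})

test_that("PCA denoising reduces error to the noise-free truth", {
  set.seed(2)
  wn <- seq(501, 900, by = 2)
  basis <- matrix(rnorm(3 * length(wn)), nrow = 3)
  coefs <- matrix(runif(60 * 3), ncol = 3)
  truth <- coefs %*% basis
  noisy <- truth + rnorm(length(truth), sd = 0.05 * max(abs(truth)))
  scan <- scan_from_spectra(noisy, 6, 10, wn, processed = TRUE)
  out <- pca_denoise(scan, preprocess_config(n_components = 3))
  mse <- function(M) mean((M - truth)^2)
  denoised <- matrix(out$intensities, nrow = 60)
  expect_lt(mse(denoised), mse(noisy))
})

test_that("PCA with maximal components is the identity and error is monotone", {
  scan <- simulate_skin_scan(small_skin_cfg(seed = 5, n_lateral = 3,
                                            n_depth = 8))$scan
  n <- n_spectra(scan)
  full <- pca_denoise(scan, preprocess_config(n_components = n - 1))
  expect_equal(full$intensities, scan$intensities, tolerance = 1e-8)
  with3 <- pca_denoise(scan, preprocess_config(n_components = 3))
  err <- function(s) mean((s$intensities - scan$intensities)^2)
  expect_lte(err(full), err(with3))
  expect_error(pca_denoise(scan, preprocess_config(n_components = n)),
               "smaller than the number of spectra")
})

test_that("every preprocessing step preserves scan shape and axes", {
  scan <- simulate_skin_scan(small_skin_cfg(seed = 6,
                                            spike_rate = 0.02))$scan
  cfg <- small_pre_cfg()
  for (step in list(remove_cosmic_rays, subtract_background, pca_denoise)) {
    out <- step(scan, cfg)
    expect_equal(dim(out), dim(scan))
    expect_equal(out$depth_um, scan$depth_um)
    expect_equal(out$wavenumber_cm1, scan$wavenumber_cm1)
  }
})
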