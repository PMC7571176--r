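test_that("band_auc matches closed forms and a fine-grid oracle", {
  wn <- seq(501, 700, by = 1)
  b <- band("caffeine", 556, 540, 575)

  # constant spectrum: the endpoint baseline removes it entirely
  expect_equal(band_auc(rep(5, length(wn)), wn, b), 0)

  # triangle of height h and base w sampled exactly on its vertices
  h <- 12; w_base <- 20
  tri <- pmax(0, h * (1 - abs(wn - 557) / (w_base / 2)))
  expect_equal(band_auc(tri, wn, b), h * w_base / 2)

  # Gaussian band: area a * s * sqrt(2*pi) within 0.5%
  a <- 5; s <- 4
  g <- a * exp(-(wn - 557)^2 / (2 * s^2))
  wide <- band("wide", 557, 510, 610)
  expect_equal(band_auc(g, wn, wide), a * s * sqrt(2 * pi),
               tolerance = 0.005)

  # fine-grid numerical oracle for the same band
  wn_fine <- seq(510, 610, by = 0.01)
  oracle <- pracma::trapz(wn_fine, a * exp(-(wn_fine - 557)^2 / (2 * s^2)))
  expect_equal(band_auc(g, wn, wide), oracle, tolerance = 0.005)
})

test_that("lateral grouping partitions positions as equally as possible", {
  scan <- flat_scan(nl = 10, nd = 4)
  for (i in 1:10) scan$intensities[i, , ] <- i
  groups <- split_lateral_groups(scan, 3)
  expect_length(groups, 3)
  # sizes 3, 3, 4: group means of 1:10 are 2, 5, 8.5
  expect_equal(vapply(groups, function(g) g$intensities[1, 1, 1],
                      numeric(1)), c(2, 5, 8.5))
  for (g in groups) expect_equal(dim(g)[1], 1L)

  one <- split_lateral_groups(scan, 1)[[1]]
  expect_equal(one$intensities[1, 1, 1], mean(1:10))

  ident <- split_lateral_groups(scan, 10)
  expect_equal(vapply(ident, function(g) g$intensities[1, 1, 1],
                      numeric(1)), as.numeric(1:10))
  expect_error(split_lateral_groups(scan, 11), "between 1 and")
})

test_that("extract_profile turns band areas into a depth profile", {
  wn <- seq(501, 700, by = 1)
  b <- band("caffeine", 556, 540, 575)
  nd <- 8
  spec <- 3 * exp(-(wn - 556)^2 / (2 * 3.4^2))
  M <- matrix(rep(spec, nd), nrow = nd, byrow = TRUE)
  scan <- scan_from_spectra(M, 1, nd, wn, processed = TRUE)
  prof <- extract_profile(scan, b)
  expect_s3_class(prof, "depth_profile")
  expect_equal(prof$state, "raw")
  expect_length(prof$values, nd)
  expect_lt(diff(range(prof$values)), 1e-12) # depth-constant band

  zero <- scan_from_spectra(matrix(0, nd, length(wn)), 1, nd, wn,
                            processed = TRUE)
  expect_equal(extract_profile(zero, b)$values, rep(0, nd))

  expect_error(extract_profile(flat_scan(nl = 2), b),
               "laterally averaged")
})

test_that("surface detection finds steps and PSF-blurred edges", {
  d <- seq(0, 15, by = 0.5)

  step_prof <- depth_profile(d, as.numeric(d >= 5) * 10, "keratin")
  expect_lte(abs(detect_surface(step_prof) - 5), 0.25)

  sigma <- 1.86 / (2 * sqrt(2 * log(2)))
  edge <- depth_profile(d, pnorm(d, 5, sigma), "keratin")
  expect_lte(abs(detect_surface(edge) - 5), 0.25)

  falling <- depth_profile(d, rev(pnorm(d, 5, sigma)), "keratin")
  expect_error(detect_surface(falling), "surface detection failed")
})

test_that("cropping re-zeroes at the surface and interpolates when needed", {
  d <- seq(0, 25, by = 0.5)
  v <- seq_along(d)
  p <- depth_profile(d, v, "caffeine")

  at_first <- crop_to_surface(p, 0)
  expect_equal(at_first$depths, d)
  expect_equal(at_first$values, v)
  expect_equal(at_first$state, "cropped")

  at2 <- crop_to_surface(p, 2.0)
  expect_equal(range(at2$depths), c(0, 23))
  expect_equal(at2$depths[1], 0)

  between <- crop_to_surface(p, 2.3)
  expect_equal(between$depths[1], 0)
  expect_equal(between$values[1],
               approx(d, v, xout = 2.3)$y)

  # cropping again at surface 0 is the identity
  again <- crop_to_surface(at2, 0)
  expect_equal(again$depths, at2$depths)
  expect_equal(again$values, at2$values)

  expect_error(crop_to_surface(p, 26), "outside profile depth range")
})

test_that("normalization divides by the mean keratin signal", {
  d <- seq(0, 10, by = 0.5)
  drug <- depth_profile(d, 2 + sin(d), "caffeine", "cropped")
  ker <- depth_profile(d, rep(4, length(d)), "keratin", "cropped")
  out <- normalize_profile(drug, ker)
  expect_equal(out$values, (2 + sin(d)) / 4)
  expect_equal(out$state, "normalized")

  ker_var <- depth_profile(d, 3 + cos(d), "keratin", "cropped")
  out2 <- normalize_profile(drug, ker_var)
  expect_equal(out2$values, drug$values / mean(ker_var$values))

  bad <- depth_profile(d, rep(-1, length(d)), "keratin", "cropped")
  expect_error(normalize_profile(drug, bad), "non-positive mean keratin")
  short <- depth_profile(d[-1] - d[2], drug$values[-1], "keratin", "cropped")
  expect_error(normalize_profile(drug, short), "different depth grids")
})

test_that("pipeline output is invariant to global intensity rescaling", {
  res <- simulate_skin_scan(small_skin_cfg(seed = 21, spike_rate = 0))
  scan <- res$scan
  scaled <- scan
  scaled$intensities <- scaled$intensities * 7.5
  cfg <- small_pre_cfg()
  p1 <- scan_to_profiles(preprocess_scan(scan, cfg))
  p2 <- scan_to_profiles(preprocess_scan(scaled, cfg))
  for (g in seq_along(p1)) {
    expect_equal(p2[[g]]$depths, p1[[g]]$depths, tolerance = 1e-9)
    expect_equal(p2[[g]]$values, p1[[g]]$values, tolerance = 1e-9)
  }
})

test_that("twin scans differing 2x in caffeine differ 2x after normalization", {
  base <- small_skin_cfg(seed = 22, spike_rate = 0, noise_sd = 0)
  doubled <- base
  doubled$caffeine_amp <- base$caffeine_amp * 2
  cfg <- small_pre_cfg()
  p1 <- scan_to_profiles(preprocess_scan(simulate_skin_scan(base)$scan, cfg))
  p2 <- scan_to_profiles(preprocess_scan(simulate_skin_scan(doubled)$scan,
                                         cfg))
  a1 <- cumulative_auc(p1[[1]], 15)
  a2 <- cumulative_auc(p2[[1]], 15)
  expect_equal(a2 / a1, 2, tolerance = 0.05)
})

test_that("normalized profiles track the PSF-blurred true concentration", {
  cfg <- small_skin_cfg(seed = 23, spike_rate = 0, noise_sd = 0)
  res <- simulate_skin_scan(cfg)
  prof <- scan_to_profiles(preprocess_scan(res$scan, small_pre_cfg()))[[1]]
  # independent oracle: erfc concentration convolved with the Gaussian PSF
  # on a fine grid, in skin-depth coordinates
  sigma <- cfg$psf_fwhm_um / (2 * sqrt(2 * log(2)))
  zf <- seq(-6, 26, by = 0.01)
  conc <- ifelse(zf >= 0,
                 pracma::erfc(zf / (2 * sqrt(cfg$diffusion_um2_h *
                                               cfg$incubation_h))), 0)
  kern <- dnorm(seq(-4 * sigma, 4 * sigma, by = 0.01), 0, sigma)
  blurred <- stats::filter(conc, kern / sum(kern), sides = 2)
  truth <- approx(zf, as.numeric(blurred), xout = prof$depths)$y
  expect_gt(cor(prof$values, truth), 0.98)
})

test_that("aggregation computes mean and sample SD on a common grid", {
  d <- seq(0, 10, by = 0.5)
  mk <- function(v) depth_profile(d, v, "caffeine", "normalized")
  same <- replicate(3, mk(2 + sin(d)), simplify = FALSE)
  agg <- aggregate_profiles(same, label = "identical")
  expect_equal(agg$mean$values, 2 + sin(d))
  expect_equal(agg$mean$sd, rep(0, length(d)))

  two <- aggregate_profiles(list(mk(rep(3, length(d))),
                                 mk(rep(7, length(d)))))
  expect_equal(two$mean$values, rep(5, length(d)))
  expect_equal(two$mean$sd, rep(abs(3 - 7) / sqrt(2), length(d)))

  expect_error(aggregate_profiles(list(mk(d))), "at least 2")
  mixed <- list(mk(d), depth_profile(d, d, "keratin", "normalized"))
  expect_error(aggregate_profiles(mixed), "share band and state")
})

test_that("replicate SD estimates the known noise level", {
  set.seed(99)
  d <- seq(0, 10, by = 0.5)
  sigma <- 0.3
  reps <- replicate(9, depth_profile(d, 5 + rnorm(length(d), sd = sigma),
                                     "caffeine", "normalized"),
                    simplify = FALSE)
  agg <- aggregate_profiles(reps)
  # chi-square bounds for a sample SD at n = 9 (8 df, ~99.9% band)
  lo <- sigma * sqrt(qchisq(0.0005, 8) / 8)
  hi <- sigma * sqrt(qchisq(0.9995, 8) / 8)
  expect_true(all(agg$mean$sd > lo & agg$mean$sd < hi))
  expect_equal(median(agg$mean$sd), sigma, tolerance = 0.3)
})
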