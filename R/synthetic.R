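#' Configuration for synthetic depth scans
#'
#' Ground-truth parameters for simulated confocal Raman depth scans of the
#' three measurement situations handled by this package: caffeine-incubated
#' skin, a silica plate (axial-resolution check) and a PET film (thickness
#' check). Defaults mirror the measurement geometry the pipeline is designed
#' for: a 10 x 50 grid over 5 x 25 um, spectra on a 501-1635 1/cm axis, the
#' first plane about 2 um above the skin surface, and an axial resolution of
#' 1.86 um FWHM. The diffusion coefficient is illustrative (no reference
#' value exists for caffeine in stratum corneum); its default reaches ~20 um
#' penetration after 6 h of incubation.
#'
#' @param seed integer RNG seed; identical configs give bit-identical scans.
#' @param n_lateral,n_depth grid size (spectra per line, number of lines).
#' @param lateral_span_um,depth_span_um scanned extents, micrometres.
#' @param wn_start,wn_stop,wn_step spectral axis, 1/cm.
#' @param surface_z_um stage depth of the skin surface (or silica plane).
#' @param psf_fwhm_um axial point-spread-function FWHM, micrometres.
#' @param diffusion_um2_h caffeine diffusion coefficient in skin, um^2/h.
#' @param incubation_h incubation time, hours.
#' @param caffeine_amp caffeine band amplitude (area units); also used as the
#'   emitting-band amplitude of the silica and PET simulations.
#' @param keratin_amp keratin reference band amplitude.
#' @param enhancer_factor multiplicative enhancement applied by
#'   \code{\link{apply_enhancer}}.
#' @param attenuation_len_um e-folding depth of the keratin signal
#'   attenuation.
#' @param baseline_amp fluorescence baseline amplitude, counts.
#' @param noise_sd additive Gaussian noise SD, counts.
#' @param spike_rate cosmic-ray probability per spectrum, in [0, 1].
#' @param spike_amp multiplier applied to the struck channel.
#' @return An object of class \code{synthetic_config}.
#' @export
synthetic_config <- function(seed = 1L,
                             n_lateral = 10L, n_depth = 50L,
                             lateral_span_um = 5, depth_span_um = 25,
                             wn_start = 501, wn_stop = 1635, wn_step = 1,
                             surface_z_um = 2.0, psf_fwhm_um = 1.86,
                             diffusion_um2_h = 8, incubation_h = 6,
                             caffeine_amp = 100, keratin_amp = 200,
                             enhancer_factor = 1.5,
                             attenuation_len_um = 15,
                             baseline_amp = 20, noise_sd = 0.5,
                             spike_rate = 0.01, spike_amp = 50) {
  cfg <- list(seed = as.integer(seed), n_lateral = as.integer(n_lateral),
              n_depth = as.integer(n_depth),
              lateral_span_um = lateral_span_um,
              depth_span_um = depth_span_um,
              wn_start = wn_start, wn_stop = wn_stop, wn_step = wn_step,
              surface_z_um = surface_z_um, psf_fwhm_um = psf_fwhm_um,
              diffusion_um2_h = diffusion_um2_h, incubation_h = incubation_h,
              caffeine_amp = caffeine_amp, keratin_amp = keratin_amp,
              enhancer_factor = enhancer_factor,
              attenuation_len_um = attenuation_len_um,
              baseline_amp = baseline_amp, noise_sd = noise_sd,
              spike_rate = spike_rate, spike_amp = spike_amp)
  positives <- c("lateral_span_um", "depth_span_um", "wn_step",
                 "surface_z_um", "psf_fwhm_um", "diffusion_um2_h",
                 "incubation_h", "attenuation_len_um", "enhancer_factor")
  for (f in positives)
    if (cfg[[f]] <= 0) stop("`", f, "` must be positive")
  if (cfg$n_lateral < 1L || cfg$n_depth < 2L)
    stop("grid must have >= 1 lateral and >= 2 depth positions")
  if (cfg$wn_stop <= cfg$wn_start) stop("wn_stop must exceed wn_start")
  if (cfg$spike_rate < 0 || cfg$spike_rate > 1)
    stop("spike_rate must lie in [0, 1]")
  if (cfg$noise_sd < 0 || cfg$baseline_amp < 0 || cfg$caffeine_amp < 0 ||
      cfg$keratin_amp < 0)
    stop("amplitudes and noise_sd must be non-negative")
  structure(cfg, class = "synthetic_config")
}

#' Enhancer-arm variant of a synthetic config
#'
#' @param cfg a \code{\link{synthetic_config}}.
#' @param mode what the enhancer multiplies: the caffeine amplitude (donor
#'   concentration effect), the diffusivity, or both.
#' @return The modified config.
#' @export
apply_enhancer <- function(cfg, mode = c("amplitude", "diffusivity", "both")) {
  mode <- match.arg(mode)
  if (mode %in% c("amplitude", "both"))
    cfg$caffeine_amp <- cfg$caffeine_amp * cfg$enhancer_factor
  if (mode %in% c("diffusivity", "both"))
    cfg$diffusion_um2_h <- cfg$diffusion_um2_h * cfg$enhancer_factor
  cfg
}

sim_axes <- function(cfg) {
  list(wn = seq(cfg$wn_start, cfg$wn_stop, by = cfg$wn_step),
       z = seq(0, by = cfg$depth_span_um / cfg$n_depth,
               length.out = cfg$n_depth),
       x = seq(0, by = cfg$lateral_span_um / cfg$n_lateral,
               length.out = cfg$n_lateral))
}

# Unit-area Gaussian band profile on the wavenumber axis.
gauss_band <- function(wn, center, fwhm = 8) {
  stats::dnorm(wn, center, fwhm / (2 * sqrt(2 * log(2))))
}

#' Peak spectral height of a simulated band
#'
#' Bands are unit-area Gaussians of 8 1/cm FWHM, so a band of area amplitude
#' \code{amp} has peak height \code{amp / (sigma * sqrt(2 * pi))}. Useful to
#' express noise levels as a fraction of a band peak.
#'
#' @param amp band area amplitude.
#' @param fwhm_cm1 band FWHM, 1/cm.
#' @return Peak height, counts.
#' @export
band_peak_height <- function(amp, fwhm_cm1 = 8) {
  s <- fwhm_cm1 / (2 * sqrt(2 * log(2)))
  amp / (s * sqrt(2 * pi))
}

# Convolve an analytic depth profile with the Gaussian axial PSF on a fine
# grid, then sample at the query depths.
convolve_psf <- function(f, z_query, psf_fwhm, step = 0.02) {
  if (psf_fwhm <= 0) return(f(z_query))
  s <- psf_fwhm / (2 * sqrt(2 * log(2)))
  half_n <- ceiling(4 * s / step)
  pad <- (half_n + 2) * step
  zf <- seq(min(z_query) - pad, max(z_query) + pad, by = step)
  kern <- stats::dnorm(seq(-half_n, half_n) * step, 0, s)
  kern <- kern / sum(kern)
  yc <- stats::filter(f(zf), kern, sides = 2)
  stats::approx(zf, as.numeric(yc), xout = z_query)$y
}

erfc_ <- function(x) pracma::erfc(x)

#' Simulate a caffeine-incubated skin scan with ground truth
#'
#' Builds each spectrum as fluorescence baseline + keratin band + nuisance
#' skin bands + caffeine band + noise + cosmic spikes. Depth dependencies:
#' the keratin amplitude is a step at the skin surface decaying with the
#' attenuation length; the caffeine amplitude follows the erfc solution of
#' one-dimensional Fickian diffusion from a constant-concentration boundary
#' (infinite dose), \code{erfc((z - surface) / (2 sqrt(D t)))}; both are
#' convolved with the Gaussian axial PSF. All bands are unit-area Gaussians
#' of 8 1/cm FWHM.
#'
#' @param cfg a \code{\link{synthetic_config}}.
#' @return A list with elements \code{scan} (a raw \code{\link{depth_scan}})
#'   and \code{truth} (class \code{ground_truth}: the noiseless caffeine
#'   concentration versus skin depth on a fine grid, the surface depth, and
#'   the injected spike sites).
#' @export
simulate_skin_scan <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  ax <- sim_axes(cfg)
  required <- c(556, 1008)
  if (any(required < min(ax$wn)) || any(required > max(ax$wn)))
    stop("spectral axis must include the 556 and 1008 1/cm band centers")
  zs <- cfg$surface_z_um
  pen <- 2 * sqrt(cfg$diffusion_um2_h * cfg$incubation_h)

  ker_shape <- convolve_psf(function(z)
    ifelse(z >= zs, exp(-(z - zs) / cfg$attenuation_len_um), 0),
    ax$z, cfg$psf_fwhm_um)
  caf_shape <- convolve_psf(function(z)
    ifelse(z >= zs, erfc_((z - zs) / pen), 0),
    ax$z, cfg$psf_fwhm_um)
  presence <- convolve_psf(function(z) as.numeric(z >= zs),
                           ax$z, cfg$psf_fwhm_um)

  base_nu <- cfg$baseline_amp * (0.6 + 0.4 * exp(-((ax$wn - 900) / 400)^2))
  ker_spec <- cfg$keratin_amp * gauss_band(ax$wn, 1008)
  nuisance <- c("850" = 0.15, "935" = 0.20, "1300" = 0.15, "1450" = 0.30)
  for (ctr in as.numeric(names(nuisance)))
    if (ctr > min(ax$wn) + 10 && ctr < max(ax$wn) - 10)
      ker_spec <- ker_spec + cfg$keratin_amp * nuisance[[as.character(ctr)]] *
        gauss_band(ax$wn, ctr)
  caf_spec <- gauss_band(ax$wn, 556)

  # noiseless spectrum per depth (identical across the lateral axis)
  S <- outer(0.3 + 0.7 * presence, base_nu) +
    outer(ker_shape, ker_spec) +
    outer(cfg$caffeine_amp * caf_shape, caf_spec)

  set.seed(cfg$seed)
  nl <- cfg$n_lateral
  nz <- cfg$n_depth
  nw <- length(ax$wn)
  cube <- aperm(array(rep(t(S), nl), dim = c(nw, nz, nl)), c(3, 2, 1))
  if (cfg$noise_sd > 0)
    cube <- cube + array(stats::rnorm(length(cube), sd = cfg$noise_sd),
                         dim = dim(cube))
  spikes <- data.frame(lateral = integer(), depth = integer(),
                       channel = integer())
  if (cfg$spike_rate > 0) {
    hit <- stats::runif(nl * nz) < cfg$spike_rate
    for (sidx in which(hit)) {
      i <- ((sidx - 1L) %% nl) + 1L
      j <- ((sidx - 1L) %/% nl) + 1L
      ch <- sample.int(nw, 1L)
      cube[i, j, ch] <- abs(cube[i, j, ch]) * cfg$spike_amp +
        cfg$spike_amp
      spikes <- rbind(spikes,
                      data.frame(lateral = i, depth = j, channel = ch))
    }
  }
  cube <- pmax(cube, 0)
  scan <- depth_scan(cube, ax$x, ax$z, ax$wn,
                     metadata = list(label = "synthetic caffeine skin scan"))
  dd <- seq(0, cfg$depth_span_um - zs, by = 0.05)
  truth <- structure(
    list(depth_um = dd,
         concentration = cfg$caffeine_amp * erfc_(dd / pen),
         surface_z_um = zs,
         spike_sites = spikes),
    class = "ground_truth")
  list(scan = scan, truth = truth)
}

#' Simulate a silica-plate depth scan
#'
#' The plate is modelled as a thin emitting plane at \code{surface_z_um}, so
#' the 521 1/cm band amplitude versus depth is exactly the axial PSF: a
#' Gaussian whose FWHM is the depth resolution of the setup.
#'
#' @inheritParams simulate_skin_scan
#' @return A raw \code{\link{depth_scan}}.
#' @export
simulate_silica_scan <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  ax <- sim_axes(cfg)
  if (521 < min(ax$wn) || 521 > max(ax$wn))
    stop("spectral axis must include the 521 1/cm band center")
  s <- cfg$psf_fwhm_um / (2 * sqrt(2 * log(2)))
  amp_z <- cfg$caffeine_amp *
    exp(-(ax$z - cfg$surface_z_um)^2 / (2 * s^2))
  S <- outer(amp_z, gauss_band(ax$wn, 521)) + 0.2 * cfg$baseline_amp
  set.seed(cfg$seed)
  cube <- aperm(array(rep(t(S), cfg$n_lateral),
                      dim = c(length(ax$wn), cfg$n_depth, cfg$n_lateral)),
                c(3, 2, 1))
  if (cfg$noise_sd > 0)
    cube <- cube + array(stats::rnorm(length(cube), sd = cfg$noise_sd),
                         dim = dim(cube))
  depth_scan(pmax(cube, 0), ax$x, ax$z, ax$wn,
             metadata = list(label = "synthetic silica plate scan"))
}

#' Simulate a PET-film depth scan
#'
#' The film gives a boxcar of the given thickness centred in the depth span,
#' convolved with the axial PSF; its 1614 1/cm band depth profile is the
#' plateau whose half-maximum width is the film thickness.
#'
#' @inheritParams simulate_skin_scan
#' @param thickness_um film thickness, micrometres; must be smaller than the
#'   depth span.
#' @return A raw \code{\link{depth_scan}}.
#' @export
simulate_pet_scan <- function(cfg = synthetic_config(), thickness_um = 21.6) {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (thickness_um >= cfg$depth_span_um)
    stop("thickness_um (", thickness_um,
         ") must be smaller than the depth span (", cfg$depth_span_um, ")")
  if (thickness_um <= 0) stop("thickness_um must be positive")
  ax <- sim_axes(cfg)
  if (1614 < min(ax$wn) || 1614 > max(ax$wn))
    stop("spectral axis must include the 1614 1/cm band center")
  ctr <- (min(ax$z) + max(ax$z)) / 2
  amp_z <- cfg$caffeine_amp * convolve_psf(function(z)
    as.numeric(abs(z - ctr) <= thickness_um / 2),
    ax$z, cfg$psf_fwhm_um)
  S <- outer(amp_z, gauss_band(ax$wn, 1614)) + 0.2 * cfg$baseline_amp
  set.seed(cfg$seed)
  cube <- aperm(array(rep(t(S), cfg$n_lateral),
                      dim = c(length(ax$wn), cfg$n_depth, cfg$n_lateral)),
                c(3, 2, 1))
  if (cfg$noise_sd > 0)
    cube <- cube + array(stats::rnorm(length(cube), sd = cfg$noise_sd),
                         dim = dim(cube))
  depth_scan(pmax(cube, 0), ax$x, ax$z, ax$wn,
             metadata = list(label = "synthetic PET film scan"))
}

#' True cumulative AUC of a simulated concentration profile
#'
#' Trapezoidal integral of the ground-truth caffeine concentration over skin
#' depth \code{[0, depth_max]}, evaluated on a 10x-refined grid; the oracle
#' against which pipeline recovery is judged.
#'
#' @param truth the \code{ground_truth} from \code{\link{simulate_skin_scan}}.
#' @param depth_max integration bound, micrometres.
#' @return Concentration-units times micrometres.
#' @export
true_cumulative_auc <- function(truth, depth_max = 20) {
  stopifnot(inherits(truth, "ground_truth"))
  if (depth_max <= 0) return(0)
  hi <- min(depth_max, max(truth$depth_um))
  step <- stats::median(diff(truth$depth_um)) / 10
  grid <- seq(0, hi, by = step)
  if (grid[length(grid)] < hi) grid <- c(grid, hi)
  vals <- stats::approx(truth$depth_um, truth$concentration, xout = grid)$y
  pracma::trapz(grid, vals)
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_config> %dx%d grid over %gx%g um, axis ",
                     "%g-%g 1/cm, surface %g um, PSF %g um, D=%g um^2/h, ",
                     "t=%g h, seed=%d\n"),
              x$n_lateral, x$n_depth, x$lateral_span_um, x$depth_span_um,
              x$wn_start, x$wn_stop, x$surface_z_um, x$psf_fwhm_um,
              x$diffusion_um2_h, x$incubation_h, x$seed))
  invisible(x)
}
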