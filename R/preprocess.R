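#' Preprocessing configuration
#'
#' Parameters for the spectral cleaning chain, applied in fixed order:
#' cosmic-ray spike removal, shape-based background subtraction, PCA noise
#' reduction.
#'
#' @param spike_zscore robust z-score threshold for spike detection; a value
#'   is flagged when it deviates from the median of neighbouring spectra by
#'   more than this many robust standard deviations (1.4826 x MAD).
#' @param spike_window neighbourhood half-width in spectra: the filter
#'   compares each value against the \code{2 * spike_window} adjacent spectra
#'   in acquisition order.
#' @param shape_size width of the flat structuring element, in spectral
#'   samples, for the morphological-opening baseline estimate.
#' @param n_components number of principal components retained in the PCA
#'   reconstruction; must stay below the number of spectra of the scan it is
#'   applied to.
#' @return An object of class \code{preprocess_config}.
#' @export
preprocess_config <- function(spike_zscore = 8, spike_window = 2,
                              shape_size = 400, n_components = 3) {
  if (spike_zscore <= 0) stop("spike_zscore must be > 0")
  if (spike_window < 1) stop("spike_window must be >= 1")
  if (shape_size < 3) stop("shape_size must be >= 3")
  if (n_components < 1) stop("n_components must be >= 1")
  structure(list(spike_zscore = spike_zscore,
                 spike_window = as.integer(spike_window),
                 shape_size = as.integer(shape_size),
                 n_components = as.integer(n_components)),
            class = "preprocess_config")
}

#' Remove cosmic-ray spikes
#'
#' Cosmic rays hit single CCD channels of single spectra, so they are
#' uncorrelated between adjacent grid positions while genuine Raman bands are
#' strongly correlated. For every wavenumber channel, each intensity is
#' compared against the median of the same channel in the
#' \code{2 * spike_window} neighbouring spectra (acquisition order, reflected
#' at the scan ends); values deviating by more than \code{spike_zscore}
#' robust standard deviations (1.4826 x median absolute deviation of the
#' neighbours) are replaced by that median. All other values pass through
#' unchanged.
#'
#' @param scan a \code{\link{depth_scan}} with at least 3 spectra.
#' @param cfg a \code{\link{preprocess_config}}.
#' @return A \code{depth_scan} of identical shape; the number of replaced
#'   values is available as \code{attr(, "n_replaced")}.
#' @export
remove_cosmic_rays <- function(scan, cfg = preprocess_config()) {
  stopifnot(inherits(scan, "depth_scan"), inherits(cfg, "preprocess_config"))
  X <- scan_matrix(scan)
  n <- nrow(X)
  if (n < 3L) stop("cosmic-ray removal needs at least 3 spectra")
  w <- min(cfg$spike_window, n - 1L)
  reflect <- function(i) {
    i[i < 1L] <- 2L - i[i < 1L]
    i[i > n] <- 2L * n - i[i > n]
    i
  }
  offsets <- c(-(w:1), 1:w)
  neigh <- lapply(offsets, function(o) X[reflect(seq_len(n) + o), ,
                                         drop = FALSE])
  med <- elementwise_median(neigh)
  rsd <- 1.4826 * elementwise_median(lapply(neigh,
                                            function(M) abs(M - med)))
  # guards: a relative floor for locally constant data, and the scan-wide
  # median robust SD against chance near-zero MADs in small neighbourhoods
  floor_sd <- pmax(1e-8 * (1 + abs(med)), stats::median(rsd))
  mask <- abs(X - med) > cfg$spike_zscore * pmax(rsd, floor_sd)
  X[mask] <- med[mask]
  out <- scan_from_matrix(scan, X)
  attr(out, "n_replaced") <- sum(mask)
  out
}

# Elementwise median across a list of equally shaped matrices, via an
# elementwise exchange (bubble) sorting network; cheap for small lists.
elementwise_median <- function(mats) {
  k <- length(mats)
  for (pass in seq_len(k - 1L)) {
    for (j in seq_len(k - pass)) {
      lo <- pmin(mats[[j]], mats[[j + 1L]])
      hi <- pmax(mats[[j]], mats[[j + 1L]])
      mats[[j]] <- lo
      mats[[j + 1L]] <- hi
    }
  }
  if (k %% 2L == 1L) mats[[(k + 1L) / 2L]]
  else (mats[[k / 2L]] + mats[[k / 2L + 1L]]) / 2
}

#' Subtract the fluorescence background ("shape" baseline)
#'
#' Per spectrum, a smooth baseline is estimated by grey-scale morphological
#' opening (erosion then dilation with a flat structuring element of
#' \code{shape_size} spectral samples) followed by a moving-average smooth of
#' width \code{shape_size / 4} (rounded, at least 3), and subtracted. The
#' opening removes any peak much narrower than the structuring element while
#' following the broad fluorescence background, so narrow Raman bands survive
#' with their height intact and a constant offset maps to zero.
#'
#' @inheritParams remove_cosmic_rays
#' @return A background-subtracted \code{depth_scan} of identical shape;
#'   values may be negative where noise dips below the baseline.
#' @export
subtract_background <- function(scan, cfg = preprocess_config()) {
  stopifnot(inherits(scan, "depth_scan"), inherits(cfg, "preprocess_config"))
  X <- scan_matrix(scan)
  w <- cfg$shape_size
  if (w >= ncol(X))
    stop("shape_size (", w, ") must be smaller than the spectrum length (",
         ncol(X), ")")
  opened <- running_extremum(running_extremum(X, w, pmin), w, pmax)
  baseline <- moving_average(opened, max(3L, round(w / 4)))
  scan_from_matrix(scan, X - baseline)
}

# Centred windowed running extremum along the columns (spectral axis) of a
# matrix of spectra, edge-replicated; van Herk two-pass scheme, O(n) in the
# number of channels regardless of window width.
running_extremum <- function(X, w, op) {
  n <- ncol(X)
  w <- as.integer(w)
  if (w <= 1L) return(X)
  hl <- (w - 1L) %/% 2L
  hr <- w - 1L - hl
  Xp <- X[, c(rep(1L, hl), seq_len(n), rep(n, hr)), drop = FALSE]
  np <- ncol(Xp)
  nb <- as.integer(ceiling(np / w))
  pad <- nb * w - np
  if (pad > 0L) Xp <- Xp[, c(seq_len(np), rep(np, pad)), drop = FALSE]
  pref <- Xp
  suff <- Xp
  for (b in seq_len(nb)) {
    s <- (b - 1L) * w + 1L
    for (j in seq_len(w - 1L)) {
      pref[, s + j] <- op(pref[, s + j], pref[, s + j - 1L])
      suff[, s + w - 1L - j] <- op(suff[, s + w - 1L - j],
                                   suff[, s + w - j])
    }
  }
  out <- X
  for (i in seq_len(n)) out[, i] <- op(suff[, i], pref[, i + w - 1L])
  out
}

# Centred moving average along columns, edge-replicated padding.
moving_average <- function(X, w) {
  n <- ncol(X)
  w <- as.integer(w)
  if (w <= 1L) return(X)
  hl <- (w - 1L) %/% 2L
  hr <- w - 1L - hl
  Xp <- X[, c(rep(1L, hl), seq_len(n), rep(n, hr)), drop = FALSE]
  cs <- Xp
  for (i in seq.int(2L, ncol(Xp))) cs[, i] <- cs[, i - 1L] + Xp[, i]
  out <- X
  out[, 1L] <- cs[, w] / w
  for (i in seq.int(2L, n)) out[, i] <- (cs[, i + w - 1L] - cs[, i - 1L]) / w
  out
}

#' PCA noise reduction
#'
#' All spectra of one image scan are mean-centred and projected onto the top
#' \code{n_components} principal components of the spectral covariance; each
#' spectrum is replaced by the mean plus its projection. With three
#' components (the default) the systematic depth variation of the skin and
#' drug signals is retained while uncorrelated detector noise is discarded.
#'
#' @inheritParams remove_cosmic_rays
#' @return A denoised \code{depth_scan} of identical shape.
#' @export
pca_denoise <- function(scan, cfg = preprocess_config()) {
  stopifnot(inherits(scan, "depth_scan"), inherits(cfg, "preprocess_config"))
  X <- scan_matrix(scan)
  n <- nrow(X)
  k <- cfg$n_components
  if (k >= n)
    stop("n_components (", k, ") must be smaller than the number of spectra (",
         n, ")")
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  sv <- svd(Xc, nu = k, nv = k)
  recon <- sv$u %*% (diag(sv$d[seq_len(k)], k, k) %*% t(sv$v))
  scan_from_matrix(scan, sweep(recon, 2L, mu, `+`))
}

#' Run the full preprocessing chain
#'
#' Applies, in order: \code{\link{remove_cosmic_rays}},
#' \code{\link{subtract_background}}, \code{\link{pca_denoise}}.
#'
#' @inheritParams remove_cosmic_rays
#' @return A preprocessed \code{depth_scan}.
#' @export
preprocess_scan <- function(scan, cfg = preprocess_config()) {
  pca_denoise(subtract_background(remove_cosmic_rays(scan, cfg), cfg), cfg)
}
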