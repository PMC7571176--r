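#' Depth profile of a Raman band
#'
#' A band signal (trapezoidal band area) as a function of depth. A profile is
#' \code{raw} straight after extraction (stage depth coordinate),
#' \code{cropped} once re-zeroed at the detected skin surface, and
#' \code{normalized} after division by the mean keratin reference signal.
#'
#' @param depths strictly increasing depth positions, micrometres. For
#'   cropped and normalized profiles, 0 is the skin surface.
#' @param values band signal per depth, arbitrary units.
#' @param band band name the profile was computed from.
#' @param state one of \code{"raw"}, \code{"cropped"}, \code{"normalized"}.
#' @param sd optional per-depth standard deviation (aggregated profiles).
#' @return An object of class \code{depth_profile}.
#' @export
depth_profile <- function(depths, values, band, state = "raw", sd = NULL) {
  state <- match.arg(state, c("raw", "cropped", "normalized"))
  depths <- as.numeric(depths)
  values <- as.numeric(values)
  if (length(depths) != length(values))
    stop("depths and values must have equal length")
  if (length(depths) == 0L) stop("empty profile")
  check_increasing(depths, "depths")
  if (state != "raw" && abs(depths[1L]) > 1e-6)
    stop("a ", state, " profile must start at depth 0 (skin surface)")
  if (!is.null(sd)) {
    sd <- as.numeric(sd)
    if (length(sd) != length(depths)) stop("sd length mismatch")
  }
  structure(list(depths = depths, values = values, band = band,
                 state = state, sd = sd),
            class = "depth_profile")
}

#' @export
print.depth_profile <- function(x, ...) {
  cat(sprintf("<depth_profile> band=%s state=%s, %d depths [%g, %g] um%s\n",
              x$band, x$state, length(x$depths), min(x$depths),
              max(x$depths), if (!is.null(x$sd)) ", with sd" else ""))
  invisible(x)
}

#' @export
plot.depth_profile <- function(x, ..., xlab = "skin depth [um]",
                               ylab = paste(x$band, "band signal [a.u.]")) {
  graphics::plot(x$depths, x$values, type = "l", xlab = xlab, ylab = ylab,
                 ...)
  if (!is.null(x$sd))
    graphics::arrows(x$depths, x$values - x$sd, x$depths, x$values + x$sd,
                     angle = 90, code = 3, length = 0.03)
  invisible(x)
}

#' @export
as.data.frame.depth_profile <- function(x, ...) {
  df <- data.frame(depth_um = x$depths, value = x$values)
  if (!is.null(x$sd)) df$sd <- x$sd
  df
}

#' Band area of a single spectrum
#'
#' Subtracts a local linear baseline anchored at the two window ends (each
#' anchor the mean of the 3 outermost in-window samples) and integrates the
#' remaining intensity over the band window with the trapezoidal rule. The
#' result may be negative for noise-only windows.
#'
#' @param intensity intensity vector of one spectrum.
#' @param wavenumber_cm1 matching spectral axis, 1/cm.
#' @param band a \code{\link{band}} whose window lies inside the axis.
#' @return Band area, arbitrary units times 1/cm.
#' @export
band_auc <- function(intensity, wavenumber_cm1, band) {
  idx <- band_indices(band, wavenumber_cm1)
  w <- wavenumber_cm1[idx]
  y <- intensity[idx]
  k <- min(3L, length(idx) %/% 2L)
  x_lo <- mean(w[seq_len(k)])
  y_lo <- mean(y[seq_len(k)])
  x_hi <- mean(w[seq.int(length(w) - k + 1L, length(w))])
  y_hi <- mean(y[seq.int(length(y) - k + 1L, length(y))])
  baseline <- y_lo + (y_hi - y_lo) * (w - x_lo) / (x_hi - x_lo)
  pracma::trapz(w, y - baseline)
}

#' Split a scan into laterally averaged sub-scans
#'
#' Partitions the lateral positions into \code{n_groups} contiguous groups of
#' as-equal-as-possible size (10 positions, 3 groups: sizes 3, 3, 4) and
#' averages each group over its lateral axis, yielding one
#' 1 x depth scan per group. This is how several independent depth profiles
#' are extracted from a single image scan.
#'
#' @param scan a \code{\link{depth_scan}}.
#' @param n_groups number of groups, at most the lateral count.
#' @return List of \code{n_groups} depth scans with a single lateral position.
#' @export
split_lateral_groups <- function(scan, n_groups = 3L) {
  stopifnot(inherits(scan, "depth_scan"))
  nl <- dim(scan$intensities)[1L]
  n_groups <- as.integer(n_groups)
  if (n_groups < 1L || n_groups > nl)
    stop("n_groups (", n_groups, ") must be between 1 and the lateral count (",
         nl, ")")
  base <- nl %/% n_groups
  sizes <- rep(base, n_groups)
  extra <- nl %% n_groups
  if (extra > 0L)
    sizes[seq.int(n_groups - extra + 1L, n_groups)] <- base + 1L
  ends <- cumsum(sizes)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  lapply(seq_len(n_groups), function(g) {
    sel <- starts[g]:ends[g]
    sub <- scan$intensities[sel, , , drop = FALSE]
    avg <- array(colMeans(sub, dims = 1L),
                 dim = c(1L, dim(sub)[2L], dim(sub)[3L]))
    depth_scan(avg, mean(scan$lateral_um[sel]), scan$depth_um,
               scan$wavenumber_cm1, scan$metadata,
               processed = scan$processed)
  })
}

#' Extract a raw band depth profile from a 1 x depth scan
#'
#' @param scan_1d a laterally averaged \code{\link{depth_scan}} with a single
#'   lateral position (see \code{\link{split_lateral_groups}}).
#' @param band the \code{\link{band}} to integrate.
#' @return A raw \code{\link{depth_profile}} on the scan's depth grid.
#' @export
extract_profile <- function(scan_1d, band) {
  stopifnot(inherits(scan_1d, "depth_scan"))
  if (dim(scan_1d$intensities)[1L] != 1L)
    stop("extract_profile expects a laterally averaged 1 x depth scan")
  vals <- vapply(seq_along(scan_1d$depth_um), function(j)
    band_auc(scan_1d$intensities[1L, j, ], scan_1d$wavenumber_cm1, band),
    numeric(1))
  depth_profile(scan_1d$depth_um, vals, band$name, "raw")
}

#' Locate the skin surface from a keratin depth profile
#'
#' The keratin 1008 1/cm signal rises from near zero above the skin to a
#' plateau inside the skin; the depth at which the profile first crosses half
#' of its maximum marks the skin surface. The maximum is taken after a
#' 3-point moving-average smooth and the crossing is interpolated linearly
#' between the bracketing samples.
#'
#' @param keratin_profile a raw \code{\link{depth_profile}} of the reference
#'   band.
#' @return Surface depth in micrometres (stage coordinate).
#' @export
detect_surface <- function(keratin_profile) {
  stopifnot(inherits(keratin_profile, "depth_profile"))
  v <- keratin_profile$values
  d <- keratin_profile$depths
  if (length(v) < 3L) stop("profile too short for surface detection")
  s <- as.numeric(moving_average(matrix(v, nrow = 1L), 3L))
  m <- max(s)
  if (m <= 0) stop("surface detection failed: non-positive profile maximum")
  half <- m / 2
  if (s[1L] >= half)
    stop("surface detection failed: profile starts at or above half-maximum",
         " (scan may have started below the skin surface)")
  below <- s < half
  cross <- which(below[-length(s)] & !below[-1L])
  if (length(cross) == 0L)
    stop("surface detection failed: profile never crosses half-maximum")
  i <- cross[1L]
  d[i] + (half - s[i]) * (d[i + 1L] - d[i]) / (s[i + 1L] - s[i])
}

#' Crop a depth profile to the skin surface
#'
#' Drops samples above the surface and re-zeroes the depth axis at the
#' surface; if no sample falls on the surface, a linearly interpolated sample
#' at depth 0 is inserted.
#'
#' @param profile a \code{\link{depth_profile}}.
#' @param surface surface depth in the profile's current coordinate,
#'   micrometres; must lie within the depth range.
#' @return A \code{depth_profile} with \code{state = "cropped"} and depth 0 at
#'   the skin surface.
#' @export
crop_to_surface <- function(profile, surface) {
  stopifnot(inherits(profile, "depth_profile"))
  d <- profile$depths
  if (surface > d[length(d)] || surface < d[1L])
    stop("surface (", surface, " um) outside profile depth range [",
         d[1L], ", ", d[length(d)], "]")
  keep <- which(d >= surface - 1e-6)
  nd <- d[keep] - surface
  nv <- profile$values[keep]
  ns <- if (!is.null(profile$sd)) profile$sd[keep]
  if (abs(nd[1L]) > 1e-6) {
    v0 <- stats::approx(d, profile$values, xout = surface)$y
    nd <- c(0, nd)
    nv <- c(v0, nv)
    if (!is.null(ns))
      ns <- c(stats::approx(d, profile$sd, xout = surface)$y, ns)
  } else {
    nd[1L] <- 0
  }
  depth_profile(nd, nv, profile$band, "cropped", sd = ns)
}

#' Normalize a drug profile by the mean keratin signal
#'
#' Divides the drug band profile by the arithmetic mean of the keratin
#' reference profile over the same cropped depth grid. The keratin signal
#' attenuates with depth in the same way as any Raman signal, so this single
#' scalar per profile corrects overall signal loss and laser/focus variation
#' between measurements while leaving the profile shape untouched.
#'
#' @param drug_profile,keratin_profile cropped \code{\link{depth_profile}}s on
#'   the same depth grid.
#' @return A \code{depth_profile} with \code{state = "normalized"}.
#' @export
normalize_profile <- function(drug_profile, keratin_profile) {
  stopifnot(inherits(drug_profile, "depth_profile"),
            inherits(keratin_profile, "depth_profile"))
  if (drug_profile$state == "raw" || keratin_profile$state == "raw")
    stop("profiles must be cropped before normalization")
  if (length(drug_profile$depths) != length(keratin_profile$depths) ||
      max(abs(drug_profile$depths - keratin_profile$depths)) > 1e-6)
    stop("drug and keratin profiles are on different depth grids")
  k <- mean(keratin_profile$values)
  if (k <= 0)
    stop("non-positive mean keratin signal (", format(k),
         "); cannot normalize")
  depth_profile(drug_profile$depths, drug_profile$values / k,
                drug_profile$band, "normalized", sd = drug_profile$sd)
}

#' Aggregate replicate profiles into a mean profile with SD
#'
#' Replicates are linearly interpolated onto a common grid bounded by the
#' overlap of all replicates, with step equal to the median replicate step;
#' the mean and sample standard deviation are computed per depth.
#'
#' @param replicates list of at least two \code{\link{depth_profile}}s sharing
#'   band and state.
#' @param label free-text formulation / time-point identifier.
#' @return An object of class \code{profile_set} with elements
#'   \code{replicates}, \code{mean} (a \code{depth_profile} carrying
#'   \code{sd}) and \code{label}.
#' @export
aggregate_profiles <- function(replicates, label = "") {
  if (!is.list(replicates) || length(replicates) < 2L)
    stop("need at least 2 replicate profiles to aggregate")
  for (p in replicates) stopifnot(inherits(p, "depth_profile"))
  bands <- unique(vapply(replicates, `[[`, "", "band"))
  states <- unique(vapply(replicates, `[[`, "", "state"))
  if (length(bands) != 1L || length(states) != 1L)
    stop("replicates must share band and state")
  lo <- max(vapply(replicates, function(p) p$depths[1L], numeric(1)))
  hi <- min(vapply(replicates, function(p) max(p$depths), numeric(1)))
  if (hi <= lo) stop("replicate depth ranges do not overlap")
  step <- stats::median(unlist(lapply(replicates,
                                      function(p) diff(p$depths))))
  grid <- seq(lo, hi, by = step)
  vals <- vapply(replicates, function(p)
    stats::approx(p$depths, p$values, xout = grid)$y,
    numeric(length(grid)))
  vals <- matrix(vals, nrow = length(grid))
  mean_p <- depth_profile(grid, rowMeans(vals), bands, states,
                          sd = apply(vals, 1L, stats::sd))
  structure(list(replicates = replicates, mean = mean_p, label = label),
            class = "profile_set")
}

#' @export
print.profile_set <- function(x, ...) {
  cat(sprintf("<profile_set> %s: %d replicates, band=%s state=%s\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              length(x$replicates), x$mean$band, x$mean$state))
  invisible(x)
}

#' @export
plot.profile_set <- function(x, ...) {
  plot(x$mean, main = x$label, ...)
  invisible(x)
}

#' Cropped, normalized drug profiles from one preprocessed scan
#'
#' Convenience wrapper for the per-scan profiling chain: split the scan into
#' lateral groups, extract drug and reference band profiles per group, locate
#' the skin surface on the reference profile, crop both to the surface, and
#' normalize the drug profile by the mean reference signal.
#'
#' @param scan a preprocessed \code{\link{depth_scan}}.
#' @param drug_band,ref_band \code{\link{band}}s for drug and keratin
#'   reference.
#' @param n_groups number of lateral groups (profiles per scan).
#' @return List of normalized \code{\link{depth_profile}}s, one per group,
#'   with the detected surface depths attached as
#'   \code{attr(, "surface_um")}.
#' @export
scan_to_profiles <- function(scan, drug_band = default_bands()$caffeine,
                             ref_band = default_bands()$keratin,
                             n_groups = 3L) {
  groups <- split_lateral_groups(scan, n_groups)
  surfaces <- numeric(length(groups))
  out <- vector("list", length(groups))
  for (g in seq_along(groups)) {
    drug <- extract_profile(groups[[g]], drug_band)
    ref <- extract_profile(groups[[g]], ref_band)
    surfaces[g] <- detect_surface(ref)
    out[[g]] <- normalize_profile(crop_to_surface(drug, surfaces[g]),
                                  crop_to_surface(ref, surfaces[g]))
  }
  attr(out, "surface_um") <- surfaces
  out
}
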