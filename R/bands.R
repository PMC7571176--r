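#' Raman band definition
#'
#' A named wavenumber window with a band centre, used for trapezoidal band
#' integration. The window must bracket the centre and, when applied to a
#' scan, lie fully inside its spectral axis.
#'
#' @param name short band identifier, e.g. \code{"caffeine"}.
#' @param center band centre in 1/cm.
#' @param window_lo,window_hi integration window bounds in 1/cm;
#'   \code{window_lo < center < window_hi}.
#' @param assignment free-text vibrational assignment.
#' @return An object of class \code{raman_band}.
#' @export
#' @examples
#' band("caffeine", 556, 540, 575, "O=C-N deformation")
band <- function(name, center, window_lo, window_hi, assignment = "") {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("`name` must be a non-empty string")
  center <- as.numeric(center)
  window_lo <- as.numeric(window_lo)
  window_hi <- as.numeric(window_hi)
  if (!(window_lo < center && center < window_hi))
    stop("band '", name, "': need window_lo < center < window_hi (got ",
         window_lo, ", ", center, ", ", window_hi, ")")
  structure(list(name = name, center = center,
                 window_lo = window_lo, window_hi = window_hi,
                 assignment = as.character(assignment)),
            class = "raman_band")
}

#' @export
print.raman_band <- function(x, ...) {
  cat(sprintf("<band> %s: %g 1/cm, window [%g, %g]%s\n", x$name, x$center,
              x$window_lo, x$window_hi,
              if (nzchar(x$assignment)) paste0(" - ", x$assignment) else ""))
  invisible(x)
}

#' Default band set
#'
#' The bands used throughout this pipeline: the caffeine 556 1/cm band
#' (O=C-N deformation; free of skin interference), the keratin aromatic
#' amino-acid 1008 1/cm ring-breathing band used as the skin reference, the
#' silica 521 1/cm band used for axial-resolution checks, and the PET
#' 1614 1/cm band for film-thickness validation. Windows are symmetric
#' defaults clear of neighbouring skin bands; all are configurable via
#' \code{\link{band}} or \code{\link{read_band_config}}.
#'
#' @return Named list of \code{raman_band} objects.
#' @export
default_bands <- function() {
  list(
    caffeine = band("caffeine", 556, 540, 575, "O=C-N deformation mode"),
    keratin  = band("keratin", 1008, 990, 1025,
                    "aromatic amino acid ring breathing mode"),
    silica   = band("silica", 521, 505, 540, "Si-Si lattice mode"),
    pet      = band("pet", 1614, 1600, 1628, "aromatic ring C=C stretch")
  )
}

# Indices of the axis samples inside a band window; errors if the window is
# not fully inside the axis range.
band_indices <- function(band, wavenumber_cm1) {
  stopifnot(inherits(band, "raman_band"))
  if (band$window_lo < min(wavenumber_cm1) ||
      band$window_hi > max(wavenumber_cm1))
    stop("band '", band$name, "' window [", band$window_lo, ", ",
         band$window_hi, "] outside spectral axis [",
         min(wavenumber_cm1), ", ", max(wavenumber_cm1), "]")
  idx <- which(wavenumber_cm1 >= band$window_lo &
               wavenumber_cm1 <= band$window_hi)
  if (length(idx) < 2L)
    stop("band '", band$name, "': fewer than 2 axis samples in window")
  idx
}
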