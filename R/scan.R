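#' Hyperspectral depth scan
#'
#' A \code{depth_scan} holds one confocal Raman image scan: an intensity cube
#' indexed \code{[lateral, depth, wavenumber]} together with its three axes and
#' free-form metadata. Depth is the stage coordinate in micrometres, increasing
#' downward into the sample; depth 0 is the first acquired plane, which for
#' skin scans typically lies a couple of micrometres above the skin surface, so
#' raw depth is not skin depth until the profile is cropped.
#'
#' @param intensities numeric array of dimension
#'   \code{c(n_lateral, n_depth, n_wavenumber)}, detector counts. Raw scans
#'   must be non-negative; processed scans may contain negative values.
#' @param lateral_um strictly increasing numeric vector of lateral positions
#'   (micrometres).
#' @param depth_um strictly increasing numeric vector of depth positions
#'   (micrometres, stage coordinate).
#' @param wavenumber_cm1 strictly increasing numeric vector of Raman shifts
#'   (1/cm), length at least 2.
#' @param metadata named list of free-form key/value metadata (laser power,
#'   integration time, label, ...). Values are stored as character.
#' @param processed logical; \code{FALSE} for raw instrument data (enforces
#'   non-negative intensities), \code{TRUE} after any processing step.
#'
#' @return An object of class \code{depth_scan}.
#' @export
#' @examples
#' scan <- depth_scan(
#'   intensities = array(1, dim = c(2, 3, 4)),
#'   lateral_um = c(0, 1), depth_um = c(0, 0.5, 1),
#'   wavenumber_cm1 = c(500, 510, 520, 530)
#' )
#' dim(scan)
depth_scan <- function(intensities, lateral_um, depth_um, wavenumber_cm1,
                       metadata = list(), processed = FALSE) {
  if (!is.array(intensities) || length(dim(intensities)) != 3L)
    stop("`intensities` must be a 3-d array [lateral, depth, wavenumber]")
  lateral_um <- as.numeric(lateral_um)
  depth_um <- as.numeric(depth_um)
  wavenumber_cm1 <- as.numeric(wavenumber_cm1)
  d <- dim(intensities)
  if (d[1] != length(lateral_um) || d[2] != length(depth_um) ||
      d[3] != length(wavenumber_cm1))
    stop("intensity cube shape ", paste(d, collapse = "x"),
         " does not match axis lengths (",
         length(lateral_um), ", ", length(depth_um), ", ",
         length(wavenumber_cm1), ")")
  if (length(wavenumber_cm1) < 2L)
    stop("wavenumber axis must have length >= 2")
  check_increasing(lateral_um, "lateral_um")
  check_increasing(depth_um, "depth_um")
  check_increasing(wavenumber_cm1, "wavenumber_cm1")
  if (anyNA(intensities)) stop("intensities contain NA")
  if (!processed && min(intensities) < 0)
    stop("raw intensities must be non-negative")
  if (!is.list(metadata)) stop("`metadata` must be a list")
  structure(
    list(intensities = intensities,
         lateral_um = lateral_um,
         depth_um = depth_um,
         wavenumber_cm1 = wavenumber_cm1,
         metadata = metadata,
         processed = isTRUE(processed)),
    class = "depth_scan")
}

check_increasing <- function(x, name) {
  if (length(x) > 1L && any(diff(x) <= 0))
    stop("`", name, "` must be strictly increasing")
  invisible(x)
}

#' @export
dim.depth_scan <- function(x) dim(x$intensities)

#' Number of spectra in a scan
#'
#' @param scan a \code{depth_scan}.
#' @return integer, lateral count times depth count.
#' @export
n_spectra <- function(scan) {
  stopifnot(inherits(scan, "depth_scan"))
  prod(dim(scan$intensities)[1:2])
}

#' @export
print.depth_scan <- function(x, ...) {
  d <- dim(x$intensities)
  cat("<depth_scan> ", d[1], " lateral x ", d[2], " depth x ", d[3],
      " wavenumbers", if (x$processed) " (processed)", "\n", sep = "")
  cat("  lateral: ", format_range(x$lateral_um), " um\n", sep = "")
  cat("  depth:   ", format_range(x$depth_um), " um\n", sep = "")
  cat("  shifts:  ", format_range(x$wavenumber_cm1), " 1/cm\n", sep = "")
  if (length(x$metadata))
    cat("  metadata:", paste(names(x$metadata), collapse = ", "), "\n")
  invisible(x)
}

format_range <- function(x) {
  paste0(format(min(x)), "..", format(max(x)), " (n=", length(x), ")")
}

# Spectra as a matrix, one row per (lateral, depth) position, lateral index
# varying fastest (depth-major rows); this matches acquisition order, one
# lateral line after another, so adjacent rows are physical neighbours.
scan_matrix <- function(scan) {
  d <- dim(scan$intensities)
  matrix(scan$intensities, nrow = d[1] * d[2], ncol = d[3])
}

# Inverse of scan_matrix(); keeps axes and metadata, marks the scan processed.
scan_from_matrix <- function(scan, m) {
  d <- dim(scan$intensities)
  stopifnot(nrow(m) == d[1] * d[2], ncol(m) == d[3])
  depth_scan(array(m, dim = d), scan$lateral_um, scan$depth_um,
             scan$wavenumber_cm1, scan$metadata, processed = TRUE)
}
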