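#' Read a hyperspectral depth scan from a text file
#'
#' Reads the self-describing tab-delimited "matrix" dialect: header lines
#' prefixed \code{#} of the form \code{# key: value}, including the three axis
#' vectors \code{lateral_um}, \code{depth_um} and \code{wavenumber_cm1} as
#' comma-separated values, followed by one tab-separated intensity row per
#' (lateral, depth) position in lateral-major order (the depth index varies
#' fastest within a lateral block).
#'
#' @param path path to the scan file.
#' @param dialect file dialect; only \code{"matrix"} is defined.
#' @return A validated \code{\link{depth_scan}}.
#' @seealso \code{\link{write_scan}}
#' @export
read_scan <- function(path, dialect = "matrix") {
  dialect <- match.arg(dialect, "matrix")
  if (!file.exists(path)) stop("scan file not found: ", path)
  lines <- readLines(path)
  is_header <- startsWith(lines, "#")
  n_header <- match(FALSE, is_header, nomatch = length(lines) + 1L) - 1L
  header <- lines[seq_len(n_header)]
  meta <- parse_header(header, path)
  for (key in c("lateral_um", "depth_um", "wavenumber_cm1"))
    if (is.null(meta[[key]]))
      stop("malformed scan header in ", path, ": missing '", key, "'")
  lateral <- parse_num_csv(meta$lateral_um, "lateral_um")
  depth <- parse_num_csv(meta$depth_um, "depth_um")
  wn <- parse_num_csv(meta$wavenumber_cm1, "wavenumber_cm1")
  processed <- identical(tolower(meta$processed %||% "false"), "true")
  meta[c("lateral_um", "depth_um", "wavenumber_cm1", "processed")] <- NULL

  body <- lines[seq.int(n_header + 1L, length.out = length(lines) - n_header)]
  body <- body[nzchar(body)]
  n_expected <- length(lateral) * length(depth)
  if (length(body) != n_expected)
    stop("scan body in ", path, " has ", length(body),
         " spectra but header declares ", n_expected)
  fields <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != length(wn))
  if (length(bad))
    stop("scan body in ", path, ": row ", bad[1L], " has ",
         lengths(fields)[bad[1L]], " channels but header declares ",
         length(wn))
  m <- matrix(as.numeric(unlist(fields)), nrow = n_expected, byrow = TRUE)
  if (anyNA(m)) stop("non-numeric intensity value in ", path)
  # file rows are lateral-major: row = (i_lat - 1) * n_depth + i_depth
  cube <- aperm(array(t(m), dim = c(length(wn), length(depth),
                                    length(lateral))), c(3, 2, 1))
  depth_scan(cube, lateral, depth, wn, metadata = meta,
             processed = processed)
}

#' Write a hyperspectral depth scan to a text file
#'
#' Writes the "matrix" dialect read by \code{\link{read_scan}}; the
#' read-write round trip reproduces the scan to better than 1e-9 relative.
#'
#' @param scan a \code{\link{depth_scan}}.
#' @param path output file path.
#' @return Invisibly, \code{path}.
#' @export
write_scan <- function(scan, path) {
  stopifnot(inherits(scan, "depth_scan"))
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot write scan file ", path, ": ", conditionMessage(e)))
  on.exit(close(con))
  wnum <- function(x) paste(sprintf("%.15g", x), collapse = ",")
  writeLines(c(
    sprintf("# lateral_um: %s", wnum(scan$lateral_um)),
    sprintf("# depth_um: %s", wnum(scan$depth_um)),
    sprintf("# wavenumber_cm1: %s", wnum(scan$wavenumber_cm1)),
    sprintf("# processed: %s", if (scan$processed) "true" else "false")
  ), con)
  for (key in names(scan$metadata))
    writeLines(sprintf("# %s: %s", key, as.character(scan$metadata[[key]])),
               con)
  d <- dim(scan$intensities)
  for (i in seq_len(d[1]))
    for (j in seq_len(d[2]))
      writeLines(paste(sprintf("%.15g", scan$intensities[i, j, ]),
                       collapse = "\t"), con)
  invisible(path)
}

parse_header <- function(header, path) {
  meta <- list()
  for (line in header) {
    txt <- sub("^#[ \t]*", "", line)
    if (!nzchar(txt)) next
    if (!grepl(":", txt, fixed = TRUE))
      stop("malformed scan header line in ", path, ": '", line, "'")
    key <- trimws(sub(":.*$", "", txt))
    val <- trimws(sub("^[^:]*:", "", txt))
    if (!nzchar(key))
      stop("malformed scan header line in ", path, ": '", line, "'")
    meta[[key]] <- val
  }
  meta
}

parse_num_csv <- function(s, name) {
  x <- suppressWarnings(as.numeric(strsplit(s, ",", fixed = TRUE)[[1]]))
  if (anyNA(x)) stop("malformed numeric header field '", name, "'")
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read band definitions from a YAML config
#'
#' The config is a YAML sequence of records with keys \code{name},
#' \code{center}, \code{window_lo}, \code{window_hi} and optionally
#' \code{assignment}; unknown keys are rejected. An empty file yields an
#' empty list.
#'
#' @param path path to the YAML band config.
#' @return Named list of \code{\link{band}} objects.
#' @export
read_band_config <- function(path) {
  if (!file.exists(path)) stop("band config not found: ", path)
  records <- yaml::read_yaml(path)
  if (is.null(records)) return(list())
  if (!is.list(records)) stop("band config must be a YAML sequence of records")
  allowed <- c("name", "center", "window_lo", "window_hi", "assignment")
  bands <- lapply(records, function(rec) {
    extra <- setdiff(names(rec), allowed)
    if (length(extra))
      stop("unknown band config key(s): ", paste(extra, collapse = ", "))
    for (key in c("name", "center", "window_lo", "window_hi"))
      if (is.null(rec[[key]]))
        stop("band config record missing '", key, "'")
    band(rec$name, rec$center, rec$window_lo, rec$window_hi,
         rec$assignment %||% "")
  })
  names(bands) <- vapply(bands, `[[`, "", "name")
  bands
}

#' Write a depth profile to CSV
#'
#' Columns \code{depth_um}, \code{value} and (when present) \code{sd}, with a
#' comment header carrying the package version.
#'
#' @param profile a \code{\link{depth_profile}}.
#' @param path output CSV path.
#' @return Invisibly, \code{path}.
#' @export
write_profile_csv <- function(profile, path) {
  stopifnot(inherits(profile, "depth_profile"))
  df <- data.frame(depth_um = profile$depths, value = profile$values)
  if (!is.null(profile$sd)) df$sd <- profile$sd
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# ramanpen %s depth profile: band=%s state=%s",
                     as.character(utils::packageVersion("ramanpen")),
                     profile$band, profile$state), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Write an enhancement table to CSV and/or JSON
#'
#' @param table an \code{\link{enhancement_table}} result.
#' @param csv,json output paths; either may be \code{NULL} to skip.
#' @return Invisibly, the table.
#' @export
write_enhancement <- function(table, csv = NULL, json = NULL) {
  stopifnot(inherits(table, "enhancement_table"))
  if (!is.null(csv)) {
    con <- file(csv, "w")
    writeLines(sprintf("# ramanpen %s enhancement table",
                       as.character(utils::packageVersion("ramanpen"))), con)
    utils::write.csv(as.data.frame(table), con, row.names = FALSE)
    close(con)
  }
  if (!is.null(json))
    jsonlite::write_json(as.data.frame(table), json, digits = NA)
  invisible(table)
}
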