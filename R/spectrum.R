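# CD spectra: a wavelength grid plus molar ellipticity values, with
# plain two-column ASCII read/write (the common dialect of CD
# instruments and spectral databases).

#' Construct a CD spectrum
#'
#' @param grid wavelengths in nm, strictly increasing.
#' @param values molar ellipticity theta (deg cm^2 dmol^-1), or theta/Nr
#'   when `per_residue` is TRUE; may be complex for optical-activity
#'   curves.
#' @param per_residue logical; values are per-residue ellipticities.
#' @param source free-text provenance tag.
#' @return Object of class `cd_spectrum`.
#' @export
cd_spectrum <- function(grid, values, per_residue = FALSE, source = "") {
  grid <- as.numeric(grid)
  if (length(grid) != length(values))
    stop("grid and values differ in length")
  if (length(grid) > 1L && any(diff(grid) <= 0))
    stop("wavelength grid must be strictly increasing")
  if (!all(is.finite(Re(values))) || !all(is.finite(Im(values))))
    stop("non-finite spectrum values")
  structure(list(grid = grid, values = values,
                 meta = list(per_residue = per_residue, source = source)),
            class = "cd_spectrum")
}

#' @export
print.cd_spectrum <- function(x, ...) {
  unit <- if (isTRUE(x$meta$per_residue)) "theta/Nr" else "theta"
  cat(sprintf("<cd_spectrum> %d points, %.1f-%.1f nm (%s)\n",
              length(x$grid), min(x$grid), max(x$grid), unit))
  if (nzchar(x$meta$source)) cat("  source: ", x$meta$source, "\n", sep = "")
  invisible(x)
}

#' Read a two-column ASCII spectrum
#'
#' Whitespace- or comma-delimited wavelength/ellipticity pairs;
#' '#'-prefixed comment lines are ignored. Rows are sorted by
#' wavelength.
#'
#' @param path input file.
#' @param per_residue logical flag stored in the spectrum metadata.
#' @return A [cd_spectrum()].
#' @export
read_spectrum <- function(path, per_residue = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("format error: no data lines in ", path)
  parts <- strsplit(gsub(",", " ", lines), "\\s+")
  nums <- suppressWarnings(lapply(parts, as.numeric))
  ok <- vapply(nums, function(v) length(v) >= 2L && all(is.finite(v[1:2])), logical(1))
  if (!any(ok)) stop("format error: unparseable spectrum file ", path)
  m <- do.call(rbind, lapply(nums[ok], function(v) v[1:2]))
  m <- m[order(m[, 1L]), , drop = FALSE]
  m <- m[!duplicated(m[, 1L]), , drop = FALSE]
  cd_spectrum(m[, 1L], m[, 2L], per_residue = per_residue, source = path)
}

#' Write a spectrum as two-column ASCII
#'
#' Fixed precision (wavelength %.1f, ellipticity %.6e) so repeated runs
#' diff cleanly.
#'
#' @param x a [cd_spectrum()].
#' @param path output file.
#' @param header optional '#' comment lines (without the '#').
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(x, path, header = character(0)) {
  lines <- sprintf("%.1f %.6e", x$grid, Re(x$values))
  if (length(header)) lines <- c(paste0("# ", header), lines)
  writeLines(lines, path)
  invisible(path)
}

# Linear-interpolation resampling of two spectra onto the overlap of
# their grids (no extrapolation). Returns list(grid, exp, mod).
common_grid <- function(exp, mod) {
  lo <- max(min(exp$grid), min(mod$grid))
  hi <- min(max(exp$grid), max(mod$grid))
  if (lo > hi) stop("spectra have no overlapping wavelength range")
  g <- exp$grid[exp$grid >= lo & exp$grid <= hi]
  if (length(g) < 1L) stop("spectra have no overlapping wavelength range")
  e <- stats::approx(exp$grid, Re(exp$values), xout = g)$y
  m <- stats::approx(mod$grid, Re(mod$values), xout = g)$y
  list(grid = g, exp = e, mod = m)
}
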