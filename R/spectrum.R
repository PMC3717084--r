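# Canonical grid: ascending, endpoints inclusive. All band windows are
# interpreted on this grid and all spectra are resampled onto it at read time.
GRID_MIN <- 600
GRID_MAX <- 4000
GRID_STEP <- 1

#' Canonical wavenumber grid
#'
#' The pipeline-wide wavenumber axis: 600 to 4000 cm^-1, ascending,
#' 1 cm^-1 point spacing, endpoints inclusive (3401 points). Every spectrum
#' is resampled onto this grid when read, and every band window is
#' interpreted on it.
#'
#' @return Numeric vector of wavenumbers (cm^-1).
#' @export
canonical_grid <- function() {
  seq(GRID_MIN, GRID_MAX, by = GRID_STEP)
}

#' Construct a spectrum object
#'
#' A `ftir_spectrum` couples a strictly ascending wavenumber axis with an
#' absorbance vector of the same length and sample metadata (strain, animal,
#' tissue, replicate).
#'
#' @param wavenumber Numeric vector, strictly ascending, cm^-1.
#' @param absorbance Numeric vector, same length, finite.
#' @param strain,animal,tissue,replicate Sample metadata. `tissue` must be
#'   one of `"adipose"`, `"liver"`, `"muscle"` or `NA`.
#' @return Object of class `ftir_spectrum`.
#' @export
spectrum <- function(wavenumber, absorbance,
                     strain = NA_character_, animal = NA_character_,
                     tissue = NA_character_, replicate = NA_integer_) {
  wavenumber <- as.numeric(wavenumber)
  absorbance <- as.numeric(absorbance)
  if (length(wavenumber) != length(absorbance))
    stop("wavenumber and absorbance must have equal length")
  if (length(wavenumber) < 2L)
    stop("spectrum needs at least 2 points")
  if (anyNA(wavenumber) || anyNA(absorbance) ||
      any(!is.finite(wavenumber)) || any(!is.finite(absorbance)))
    stop("spectrum contains NA or non-finite values")
  if (any(diff(wavenumber) <= 0))
    stop("wavenumber must be strictly ascending")
  if (!is.na(tissue) && !tissue %in% TISSUES)
    stop("unknown tissue: ", tissue)
  structure(
    list(wavenumber = wavenumber, absorbance = absorbance,
         meta = list(strain = as.character(strain),
                     animal = as.character(animal),
                     tissue = as.character(tissue),
                     replicate = as.integer(replicate))),
    class = "ftir_spectrum")
}

TISSUES <- c("adipose", "liver", "muscle")

#' @export
print.ftir_spectrum <- function(x, ...) {
  m <- x$meta
  cat(sprintf(
    "<ftir_spectrum> %d points, %.0f-%.0f cm^-1 | strain=%s animal=%s tissue=%s rep=%s\n",
    length(x$wavenumber), min(x$wavenumber), max(x$wavenumber),
    m$strain, m$animal, m$tissue, m$replicate))
  invisible(x)
}

#' Resample a spectrum onto the canonical grid
#'
#' Linear interpolation onto the 600-4000 cm^-1, 1 cm^-1 axis. Inputs already
#' on the canonical grid are returned value-identical.
#'
#' @param s A `ftir_spectrum`.
#' @return A `ftir_spectrum` on the canonical grid.
#' @export
resample_canonical <- function(s) {
  grid <- canonical_grid()
  if (length(s$wavenumber) == length(grid) && all(s$wavenumber == grid))
    return(s)
  if (min(s$wavenumber) > GRID_MIN || max(s$wavenumber) < GRID_MAX)
    stop(sprintf(
      "spectrum coverage %.1f-%.1f cm^-1 does not span the canonical grid %d-%d",
      min(s$wavenumber), max(s$wavenumber), GRID_MIN, GRID_MAX))
  y <- stats::approx(s$wavenumber, s$absorbance, xout = grid, method = "linear")$y
  out <- s
  out$wavenumber <- grid
  out$absorbance <- y
  out
}

#' Read a two-column spectrum file
#'
#' Parses a two-column text file (wavenumber cm^-1, absorbance; comma or
#' whitespace separated, optional header) and resamples it onto the canonical
#' grid by linear interpolation. Descending input axes are reversed first.
#'
#' @param path Path to the file.
#' @param strain,animal,tissue,replicate Metadata attached to the result.
#' @return A `ftir_spectrum` on the canonical grid.
#' @export
read_spectrum <- function(path, strain = NA, animal = NA, tissue = NA,
                          replicate = NA) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty spectrum file: ", path)
  parts <- strsplit(trimws(lines), "[,;\t ]+")
  first <- suppressWarnings(as.numeric(parts[[1L]]))
  start <- if (anyNA(first)) 2L else 1L  # tolerate a single header line
  parts <- parts[seq(start, length(parts))]
  n <- length(parts)
  bad <- which(lengths(parts) < 2L)
  wn <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 1L)))
  ab <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2L)))
  bad <- sort(unique(c(bad, which(is.na(wn) | is.na(ab)))))
  if (length(bad))
    stop(sprintf("cannot parse line %d of %s as two numbers",
                 bad[1L] + start - 1L, path))
  if (wn[1L] > wn[n]) { wn <- rev(wn); ab <- rev(ab) }
  o <- order(wn)
  s <- spectrum(wn[o], ab[o], strain = strain, animal = animal,
                tissue = tissue, replicate = replicate)
  resample_canonical(s)
}

#' Write a spectrum as two-column CSV
#'
#' @param s A `ftir_spectrum`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(s, path) {
  utils::write.table(
    data.frame(wavenumber = s$wavenumber, absorbance = s$absorbance),
    path, sep = ",", row.names = FALSE, col.names = TRUE, quote = FALSE)
  invisible(path)
}

# index window [lo, hi] (inclusive) on a spectrum's own grid
window_idx <- function(s, lo, hi) {
  which(s$wavenumber >= lo & s$wavenumber <= hi)
}
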