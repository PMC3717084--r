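# Band integration above a local linear baseline (endpoint-anchored,
# signed, unclipped -- an emulation of vendor "method B" integration) and
# the per-tissue composite/ratio trait menu.

#' Load the band registry
#'
#' The registry ships as a versioned TSV
#' (`inst/extdata/band_registry.tsv`): per tissue, the named integration
#' windows, the composite areas (A_FAT, A_SATF, A_UNSATF, A_COL, A_PROT,
#' A_GLYC) and the four band-area ratios. Adipose has no glycogen entry;
#' liver and muscle have no unsaturated-fat or saturated-to-unsaturated
#' entries.
#'
#' @param path Optional override of the shipped registry file.
#' @return data.frame with columns `tissue`, `type`, `name`, `lower`,
#'   `upper`, `numerator`, `denominator`.
#' @export
band_registry <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "band_registry.tsv", package = "ftirqtl",
                        mustWork = TRUE)
  reg <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(lower = "character",
                                          upper = "character"))
  reg$lower <- suppressWarnings(as.numeric(reg$lower))
  reg$upper <- suppressWarnings(as.numeric(reg$upper))
  b <- reg$type == "band"
  stopifnot(all(reg$lower[b] < reg$upper[b]),
            all(reg$lower[b] >= GRID_MIN), all(reg$upper[b] <= GRID_MAX))
  reg
}

reg_lookup <- function(reg, tissue, type, name) {
  row <- reg[reg$tissue == tissue & reg$type == type & reg$name == name, ]
  if (!nrow(row)) return(NULL)
  row[1L, ]
}

#' Integrate a band above a local linear baseline
#'
#' Signed trapezoidal integral of `absorbance - baseline` over
#' `[lower, upper]`, where the baseline is the straight line joining the
#' spectrum's values at the two borders. Borders falling between grid
#' points are linearly interpolated and the integral runs border to border,
#' not snapped to the grid. Negative lobes are not clipped, so the operator
#' is exactly linear in the spectrum and invariant to adding constants.
#'
#' @param s A `ftir_spectrum`.
#' @param lower,upper Integration borders (cm^-1), inside coverage.
#' @return Area in absorbance x cm^-1 units.
#' @export
band_area <- function(s, lower, upper) {
  stopifnot(lower < upper)
  if (lower < min(s$wavenumber) || upper > max(s$wavenumber))
    stop(sprintf("band window %g-%g outside spectrum coverage %g-%g",
                 lower, upper, min(s$wavenumber), max(s$wavenumber)))
  inner <- s$wavenumber[s$wavenumber > lower & s$wavenumber < upper]
  x <- c(lower, inner, upper)
  y <- stats::approx(s$wavenumber, s$absorbance, xout = x,
                     method = "linear")$y
  base <- y[1L] + (y[length(y)] - y[1L]) * (x - lower) / (upper - lower)
  r <- y - base
  sum(diff(x) * (r[-length(r)] + r[-1L]) / 2)
}

named_band_area <- function(s, tissue, name, reg) {
  row <- reg_lookup(reg, tissue, "band", name)
  if (is.null(row)) stop("band ", name, " not defined for tissue ", tissue)
  band_area(s, row$lower, row$upper)
}

# resolve a "+"-joined list of band or composite names into a summed area
resolve_sum <- function(s, tissue, expr, reg) {
  total <- 0
  for (nm in strsplit(expr, "+", fixed = TRUE)[[1L]]) {
    if (!is.null(reg_lookup(reg, tissue, "band", nm))) {
      total <- total + named_band_area(s, tissue, nm, reg)
    } else if (!is.null(reg_lookup(reg, tissue, "composite", nm))) {
      total <- total + composite_area(s, tissue, nm, reg)
    } else {
      stop("name ", nm, " unresolved in registry for tissue ", tissue)
    }
  }
  total
}

#' Composite band area
#'
#' Sum of member band areas for one of the named composites (A_FAT,
#' A_SATF, A_UNSATF, A_COL, A_PROT, A_GLYC), using the tissue's own
#' integration borders.
#'
#' @param s A `ftir_spectrum`.
#' @param tissue Tissue name.
#' @param name Composite name.
#' @param reg Band registry (default shipped).
#' @return Area.
#' @export
composite_area <- function(s, tissue, name, reg = band_registry()) {
  row <- reg_lookup(reg, tissue, "composite", name)
  if (is.null(row))
    stop("composite ", name, " not defined for tissue ", tissue)
  resolve_sum(s, tissue, row$numerator, reg)
}

#' Band-area ratio trait
#'
#' One of: saturated-to-unsaturated fat ratio (adipose only), acyl chain
#' length (CH2-asymmetric over CH3-asymmetric stretch area), collagen
#' integrity (amide II over collagen areas), lipid-to-protein (A_FAT over
#' A_PROT).
#'
#' @param s A `ftir_spectrum`.
#' @param tissue Tissue name.
#' @param name Ratio name.
#' @param reg Band registry.
#' @return Dimensionless value.
#' @export
ratio_trait <- function(s, tissue, name, reg = band_registry()) {
  row <- reg_lookup(reg, tissue, "ratio", name)
  if (is.null(row)) stop("ratio ", name, " not defined for tissue ", tissue)
  num <- resolve_sum(s, tissue, row$numerator, reg)
  den <- resolve_sum(s, tissue, row$denominator, reg)
  if (den == 0)
    stop(sprintf("undefined ratio %s for sample %s/%s: zero denominator",
                 name, s$meta$strain, s$meta$animal))
  num / den
}

# per-tissue trait menu: trait name -> (type, registry name)
TRAIT_MENU <- list(
  adipose = list(
    total_fat          = c("composite", "A_FAT"),
    saturated_fat      = c("composite", "A_SATF"),
    unsaturated_fat    = c("composite", "A_UNSATF"),
    sat_to_unsat_ratio = c("ratio", "sat_to_unsat_ratio"),
    acyl_chain_length  = c("ratio", "acyl_chain_length"),
    collagen           = c("composite", "A_COL"),
    collagen_integrity = c("ratio", "collagen_integrity"),
    lipid_to_protein   = c("ratio", "lipid_to_protein")),
  liver = list(
    total_fat          = c("composite", "A_FAT"),
    saturated_fat      = c("composite", "A_SATF"),
    acyl_chain_length  = c("ratio", "acyl_chain_length"),
    collagen           = c("composite", "A_COL"),
    collagen_integrity = c("ratio", "collagen_integrity"),
    lipid_to_protein   = c("ratio", "lipid_to_protein"),
    glycogen           = c("composite", "A_GLYC")),
  muscle = list(
    total_fat          = c("composite", "A_FAT"),
    saturated_fat      = c("composite", "A_SATF"),
    acyl_chain_length  = c("ratio", "acyl_chain_length"),
    collagen           = c("composite", "A_COL"),
    collagen_integrity = c("ratio", "collagen_integrity"),
    lipid_to_protein   = c("ratio", "lipid_to_protein"),
    glycogen           = c("composite", "A_GLYC")))

#' Extract the full trait vector of a tissue
#'
#' Emits exactly the per-tissue trait menu: adipose has 8 traits (including
#' unsaturated fat and the saturated-to-unsaturated ratio, no glycogen);
#' liver and muscle each have 7 (glycogen, no unsaturated-fat traits).
#'
#' @param s A preprocessed (normalized) `ftir_spectrum`.
#' @param tissue Tissue name.
#' @param reg Band registry.
#' @return Named numeric vector of trait values.
#' @export
extract_traits <- function(s, tissue, reg = band_registry()) {
  menu <- TRAIT_MENU[[tissue]]
  if (is.null(menu)) stop("unknown tissue: ", tissue)
  vapply(menu, function(entry) {
    if (entry[1L] == "composite") composite_area(s, tissue, entry[2L], reg)
    else ratio_trait(s, tissue, entry[2L], reg)
  }, numeric(1))
}

#' Trait table from preprocessed strain-mean spectra
#'
#' @param strain_means Named list of `ftir_spectrum` (one per strain).
#' @param tissue Tissue name.
#' @param reg Band registry.
#' @return Tidy data.frame: `strain`, `tissue`, `trait`, `value`.
#' @export
traits_from_spectra <- function(strain_means, tissue, reg = band_registry()) {
  rows <- lapply(names(strain_means), function(st) {
    tv <- extract_traits(strain_means[[st]], tissue, reg)
    data.frame(strain = st, tissue = tissue, trait = names(tv),
               value = unname(tv), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
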