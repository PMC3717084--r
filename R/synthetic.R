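# Synthetic study generator: RI genotypes under the Haldane-Waddington
# map-expansion law, genetically structured spectral-component amplitudes,
# and tissue spectra built from Gaussian sub-bands plus instrument artifacts.

#' Spectral component models for a tissue
#'
#' Each macromolecular component is a mixture of Gaussian sub-bands
#' (center cm^-1, width sigma cm^-1, relative weight summing to 1 per
#' component). Band centers follow the standard assignments for adipose,
#' liver and muscle tissue: CH stretches of lipid acyl chains near
#' 2850-2960 cm^-1, the olefinic =CH stretch of unsaturated lipid at
#' 3006 cm^-1 (adipose only), the ester carbonyl near 1743 cm^-1, amide I/II
#' protein bands at 1650/1550 cm^-1, collagen CH2 side-chain bands at
#' 1340/1320/1280 cm^-1, and glycogen C-O stretches near 1150-1040 cm^-1
#' (liver and muscle).
#'
#' @param tissue `"adipose"`, `"liver"` or `"muscle"`.
#' @return Named list of components; each a data.frame with columns
#'   `center`, `sigma`, `weight`.
#' @export
component_models <- function(tissue = c("adipose", "liver", "muscle")) {
  tissue <- match.arg(tissue)
  comp <- function(centers, sigmas, weights) {
    w <- weights / sum(weights)
    data.frame(center = centers, sigma = sigmas, weight = w)
  }
  m <- switch(tissue,
    adipose = list(
      lipid_CH    = comp(c(2957, 2922, 2853, 1464, 1160),
                         c(10, 14, 10, 9, 20), c(0.18, 0.38, 0.24, 0.10, 0.10)),
      ester       = comp(1743, 13, 1),
      unsaturated = comp(3006, 8, 1),
      amide       = comp(c(1650, 1550), c(22, 20), c(0.55, 0.45)),
      collagen    = comp(c(1340, 1320, 1280), c(5, 5, 4), c(0.4, 0.35, 0.25)),
      baseline    = comp(2300, 900, 1)),
    liver = list(
      lipid_CH    = comp(c(2963, 2927, 2854, 1455),
                         c(10, 14, 10, 12), c(0.2, 0.4, 0.26, 0.14)),
      ester       = comp(1745, 10, 1),
      amide       = comp(c(1645, 1547), c(22, 20), c(0.55, 0.45)),
      collagen    = comp(1340, 6, 1),
      glycogen    = comp(c(1154, 1081, 1044), c(12, 9, 11), c(0.35, 0.3, 0.35)),
      baseline    = comp(2300, 900, 1)),
    muscle = list(
      lipid_CH    = comp(c(2961, 2927, 2854, 1457),
                         c(10, 14, 10, 10), c(0.2, 0.4, 0.26, 0.14)),
      ester       = comp(1741, 9, 1),
      amide       = comp(c(1645, 1550), c(22, 20), c(0.55, 0.45)),
      collagen    = comp(c(1340, 1282), c(8, 5), c(0.65, 0.35)),
      glycogen    = comp(c(1081, 1046), c(12, 9), c(0.55, 0.45)),
      baseline    = comp(2300, 900, 1))
  )
  for (nm in names(m)) {
    d <- m[[nm]]
    stopifnot(all(d$center > GRID_MIN & d$center < GRID_MAX),
              all(d$sigma > 0),
              abs(sum(d$weight) - 1) < 1e-12)
  }
  m
}

# Default mean amplitudes per component, chosen so an adipose spectrum is
# lipid-dominated and liver/muscle are protein-dominated, as in real tissue.
default_component_means <- function(tissue) {
  switch(tissue,
    adipose = c(lipid_CH = 1.8, ester = 0.5, unsaturated = 0.12,
                amide = 0.6, collagen = 0.05, baseline = 0.05),
    liver   = c(lipid_CH = 0.5, ester = 0.15, amide = 1.2,
                collagen = 0.1, glycogen = 0.3, baseline = 0.05),
    muscle  = c(lipid_CH = 0.4, ester = 0.1, amide = 1.3,
                collagen = 0.15, glycogen = 0.15, baseline = 0.05))
}

#' Recombinant-inbred panel design
#'
#' Bundles every knob of the synthetic study: panel size, replicate
#' structure (four to five males per strain, each sample measured three
#' times), genetic map geometry, environmental noise, and the single seed
#' all randomness flows from.
#'
#' @param n_strains Number of RI strains (default 30).
#' @param males_per_strain Animals per strain (default 5).
#' @param replicates Technical replicates per sample (default 3).
#' @param chr_lengths_cM Named numeric vector of chromosome lengths in cM.
#' @param marker_spacing_cM Spacing between adjacent markers, cM (> 0).
#' @param strain_sd Named (or scalar) SD of the per-strain genetic deviate
#'   on each component amplitude.
#' @param animal_sd Named (or scalar) SD of the per-animal deviate.
#' @param seed Integer seed.
#' @return A `panel_design` list.
#' @export
panel_design <- function(n_strains = 30L, males_per_strain = 5L,
                         replicates = 3L,
                         chr_lengths_cM = c("1" = 80, "2" = 60, "3" = 50),
                         marker_spacing_cM = 5,
                         strain_sd = 0.08, animal_sd = 0.05,
                         seed = 1L) {
  if (n_strains < 1 || males_per_strain < 1 || replicates < 1)
    stop("invalid design: all counts must be >= 1")
  if (any(marker_spacing_cM <= 0))
    stop("invalid design: marker spacing must be positive")
  if (any(chr_lengths_cM <= 0)) stop("invalid design: chromosome lengths must be positive")
  if (any(c(strain_sd, animal_sd) < 0)) stop("invalid design: SDs must be >= 0")
  if (is.null(names(chr_lengths_cM)))
    names(chr_lengths_cM) <- as.character(seq_along(chr_lengths_cM))
  structure(list(n_strains = as.integer(n_strains),
                 males_per_strain = as.integer(males_per_strain),
                 replicates = as.integer(replicates),
                 chr_lengths_cM = chr_lengths_cM,
                 marker_spacing_cM = marker_spacing_cM,
                 strain_sd = strain_sd, animal_sd = animal_sd,
                 seed = as.integer(seed)),
            class = "panel_design")
}

#' Map-expansion discordance for RI strains by sib mating
#'
#' For a meiotic recombination fraction `r` between adjacent markers, the
#' probability that a fixed RI strain carries discordant parental alleles at
#' the two markers is `R = 4r / (1 + 6r)` (the Haldane-Waddington expansion).
#'
#' @param r Meiotic recombination fraction in `[0, 0.5]`.
#' @return RI-strain discordance probability.
#' @export
ri_discordance <- function(r) {
  stopifnot(all(r >= 0), all(r <= 0.5))
  4 * r / (1 + 6 * r)
}

# Haldane map function: cM distance -> meiotic recombination fraction
haldane_r <- function(d_cM) 0.5 * (1 - exp(-2 * d_cM / 100))

#' Simulate RI genotypes
#'
#' Generates a `genotype_panel`: every strain x marker call homozygous for
#' one of the two parental alleles (coded `B`/`D`). Along each chromosome
#' alleles form a Markov mosaic whose adjacent-marker discordance equals the
#' Haldane-Waddington expansion `4r/(1+6r)` of the meiotic recombination
#' fraction implied by the marker spacing; breeding is not simulated
#' generation by generation.
#'
#' @param design A [panel_design()].
#' @return A `genotype_panel`: list with `map` (data.frame chr, locus, cM,
#'   Mb) and `geno` (strain x marker character matrix of `"B"`/`"D"`).
#' @export
simulate_ri_genotypes <- function(design) {
  stopifnot(inherits(design, "panel_design"))
  set.seed(design$seed)
  maps <- list(); genos <- list()
  strains <- sprintf("RIX%03d", seq_len(design$n_strains))
  for (chr in names(design$chr_lengths_cM)) {
    pos <- seq(0, design$chr_lengths_cM[[chr]], by = design$marker_spacing_cM)
    nm <- sprintf("c%s.m%03d", chr, seq_along(pos))
    maps[[chr]] <- data.frame(chr = chr, locus = nm, cM = pos,
                              Mb = pos / 2, stringsAsFactors = FALSE)
    R <- ri_discordance(haldane_r(diff(pos)))
    g <- matrix(NA_integer_, design$n_strains, length(pos))
    g[, 1L] <- sample(c(1L, -1L), design$n_strains, replace = TRUE)
    for (j in seq_along(R)) {
      flip <- stats::runif(design$n_strains) < R[j]
      g[, j + 1L] <- ifelse(flip, -g[, j], g[, j])
    }
    genos[[chr]] <- g
  }
  map <- do.call(rbind, maps)
  rownames(map) <- NULL
  geno <- do.call(cbind, genos)
  dimnames(geno) <- list(strains, map$locus)
  alleles <- matrix(ifelse(geno > 0, "B", "D"), nrow(geno), ncol(geno),
                    dimnames = dimnames(geno))
  structure(list(map = map, geno = alleles), class = "genotype_panel")
}

#' Planted QTL specification
#'
#' @param chr Chromosome id (must exist in the panel).
#' @param pos_cM Position in cM; the QTL acts through the nearest marker.
#' @param component Target spectral component name.
#' @param effect Additive effect `a` in amplitude units per allele
#'   substitution; with +/-1 allele coding the two homozygous class means
#'   differ by `2a` (B class higher for positive `a`).
#' @return A `planted_qtl` list.
#' @export
planted_qtl <- function(chr, pos_cM, component, effect) {
  stopifnot(is.finite(effect))
  structure(list(chr = as.character(chr), pos_cM = pos_cM,
                 component = component, effect = effect),
            class = "planted_qtl")
}

# nearest marker on the QTL's chromosome; error if chromosome unknown
qtl_marker <- function(panel, q) {
  rows <- panel$map$chr == q$chr
  if (!any(rows)) stop("unknown locus: no markers on chromosome ", q$chr)
  sub <- panel$map[rows, ]
  sub$locus[which.min(abs(sub$cM - q$pos_cM))]
}

#' Simulate component amplitudes for every animal
#'
#' Generative model per animal and component:
#' `amplitude = component mean + sum(allele code x additive effect)
#'  + strain deviate + animal deviate`, floored at zero. Allele coding is
#' +1 for `B`, -1 for `D`. The ground truth (QTL marker assignments, strain
#' deviates) is retained in attributes for recovery tests.
#'
#' @param panel A `genotype_panel`.
#' @param qtls List of [planted_qtl()] objects (possibly empty).
#' @param design A [panel_design()].
#' @param tissue Tissue whose component set and means to use.
#' @return data.frame with columns `strain`, `animal`, one column per
#'   component; attribute `ground_truth`.
#' @export
simulate_amplitudes <- function(panel, qtls = list(), design,
                                tissue = "adipose") {
  stopifnot(inherits(panel, "genotype_panel"), inherits(design, "panel_design"))
  means <- default_component_means(tissue)
  comps <- names(means)
  for (q in qtls) {
    if (!q$component %in% comps)
      stop("QTL targets unknown component: ", q$component)
  }
  markers <- vapply(qtls, function(q) qtl_marker(panel, q), character(1))
  set.seed(design$seed + 1L)
  strains <- rownames(panel$geno)
  nS <- length(strains); nA <- design$males_per_strain
  sd_s <- rep_len(design$strain_sd, length(comps)); names(sd_s) <- comps
  sd_a <- rep_len(design$animal_sd, length(comps)); names(sd_a) <- comps
  # strain-level genetic deviates
  dev_s <- sapply(comps, function(cp) stats::rnorm(nS, 0, sd_s[cp]))
  dim(dev_s) <- c(nS, length(comps)); dimnames(dev_s) <- list(strains, comps)
  out <- data.frame(strain = rep(strains, each = nA),
                    animal = paste0(rep(strains, each = nA), "_a",
                                    rep(seq_len(nA), nS)),
                    stringsAsFactors = FALSE)
  for (cp in comps) {
    g_eff <- numeric(nS)
    for (k in seq_along(qtls)) {
      q <- qtls[[k]]
      if (q$component != cp) next
      code <- ifelse(panel$geno[, markers[k]] == "B", 1, -1)
      g_eff <- g_eff + code * q$effect
    }
    base <- means[[cp]] + g_eff + dev_s[, cp]
    vals <- rep(base, each = nA) + stats::rnorm(nS * nA, 0, sd_a[cp])
    out[[cp]] <- pmax(vals, 0)
  }
  attr(out, "ground_truth") <- list(
    qtls = qtls, qtl_markers = markers, strain_deviates = dev_s,
    component_means = means[comps], tissue = tissue)
  out
}

# Fixed comb of narrow water-vapor lines (rotational fine structure) in the
# 1300-1900 cm^-1 region; one line pair sits inside the 1837-1847 cm^-1
# QC window so the vapor-residual score has a target.
VAPOR_LINES <- data.frame(
  center = c(1844, 1830, 1790, 1772, 1734, 1700, 1670, 1653, 1617, 1560,
             1540, 1507, 1457, 1420, 1395, 1340),
  weight = c(1.0, 0.7, 0.8, 0.5, 0.6, 0.9, 0.7, 0.8, 1.0, 0.9,
             0.6, 0.8, 0.5, 0.7, 0.4, 0.5))

#' Reference water-vapor spectrum
#'
#' A fixed comb of narrow (sigma 1.3 cm^-1) Gaussian lines between 1300 and
#' 1900 cm^-1 emulating rotational water-vapor fine structure, normalized to
#' unit maximum. The generator adds `vapor_scale` times this reference; the
#' corrector fits one coefficient against it.
#'
#' @return A `ftir_spectrum` on the canonical grid.
#' @export
vapor_reference <- function() {
  grid <- canonical_grid()
  y <- numeric(length(grid))
  for (i in seq_len(nrow(VAPOR_LINES)))
    y <- y + VAPOR_LINES$weight[i] *
      exp(-(grid - VAPOR_LINES$center[i])^2 / (2 * 1.3^2))
  spectrum(grid, y / max(y))
}

#' Synthesize a tissue spectrum
#'
#' `spectrum = sum_component amplitude x sum_subband weight x
#'  Gaussian(center, sigma) + linear baseline + vapor comb + white noise`,
#' evaluated on the canonical grid. All generation parameters are logged in
#' the `generation` attribute.
#'
#' @param amplitudes Named numeric vector, one entry per component of
#'   `model`.
#' @param model Component model set from [component_models()].
#' @param baseline_slope Absorbance units per cm^-1.
#' @param baseline_offset Constant absorbance offset.
#' @param vapor_scale Coefficient on the [vapor_reference()] comb.
#' @param noise_sd SD of additive white noise.
#' @param seed Optional seed for the noise draw (`NULL` = use current RNG
#'   state).
#' @param meta Named list of metadata fields passed to [spectrum()].
#' @return A `ftir_spectrum`.
#' @export
synthesize_spectrum <- function(amplitudes, model,
                                baseline_slope = 0, baseline_offset = 0,
                                vapor_scale = 0, noise_sd = 0,
                                seed = NULL, meta = list()) {
  missing <- setdiff(names(model), names(amplitudes))
  if (length(missing))
    stop("amplitude table missing component(s): ",
         paste(missing, collapse = ", "))
  grid <- canonical_grid()
  y <- numeric(length(grid))
  for (cp in names(model)) {
    d <- model[[cp]]
    a <- amplitudes[[cp]]
    if (a == 0) next
    for (i in seq_len(nrow(d)))
      y <- y + a * d$weight[i] *
        exp(-(grid - d$center[i])^2 / (2 * d$sigma[i]^2))
  }
  y <- y + baseline_offset + baseline_slope * (grid - GRID_MIN)
  if (vapor_scale != 0) y <- y + vapor_scale * vapor_reference()$absorbance
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    y <- y + stats::rnorm(length(grid), 0, noise_sd)
  }
  s <- do.call(spectrum, c(list(wavenumber = grid, absorbance = y), meta))
  attr(s, "generation") <- list(amplitudes = amplitudes,
                                baseline_slope = baseline_slope,
                                baseline_offset = baseline_offset,
                                vapor_scale = vapor_scale,
                                noise_sd = noise_sd, seed = seed)
  s
}

#' Simulate a complete synthetic study
#'
#' Genotypes, per-animal amplitudes, and per-replicate spectra with baseline
#' drift, a water-vapor comb and white noise, for one or more tissues.
#' Artifact levels default to small values a real well-purged ATR
#' measurement would show; they are the levels the preprocessing QC
#' thresholds are calibrated against.
#'
#' @param design A [panel_design()].
#' @param qtls List of [planted_qtl()] per tissue, e.g.
#'   `list(adipose = list(planted_qtl(...)))`.
#' @param tissues Character vector of tissues to generate.
#' @param vapor_scale,noise_sd,baseline_sd Artifact levels; baseline slope
#'   and offset are drawn per replicate with SD `baseline_sd`.
#' @return List with `panel`, `amplitudes` (per tissue), `spectra` (list of
#'   `ftir_spectrum`), and `manifest` (data.frame).
#' @export
simulate_study <- function(design, qtls = list(),
                           tissues = c("adipose", "liver"),
                           vapor_scale = 0.002, noise_sd = 2e-4,
                           baseline_sd = 0.01) {
  panel <- simulate_ri_genotypes(design)
  spectra <- list(); manifest <- list(); amps <- list()
  k <- 0L
  for (tis in tissues) {
    model <- component_models(tis)
    amp <- simulate_amplitudes(panel, qtls[[tis]] %||% list(), design,
                               tissue = tis)
    amps[[tis]] <- amp
    set.seed(design$seed + 1000L + match(tis, TISSUES))
    for (i in seq_len(nrow(amp))) {
      a <- unlist(amp[i, names(model)])
      for (rep_i in seq_len(design$replicates)) {
        k <- k + 1L
        s <- synthesize_spectrum(
          a, model,
          baseline_slope = stats::rnorm(1, 0, baseline_sd / 3400),
          baseline_offset = stats::rnorm(1, 0, baseline_sd),
          vapor_scale = vapor_scale * stats::runif(1, 0.5, 1.5),
          noise_sd = noise_sd,
          meta = list(strain = amp$strain[i], animal = amp$animal[i],
                      tissue = tis, replicate = rep_i))
        spectra[[k]] <- s
        manifest[[k]] <- data.frame(
          file = sprintf("%s_%s_r%d.csv", tis, amp$animal[i], rep_i),
          strain = amp$strain[i], animal = amp$animal[i], tissue = tis,
          replicate = rep_i, stringsAsFactors = FALSE)
      }
    }
  }
  list(panel = panel, amplitudes = amps, spectra = spectra,
       manifest = do.call(rbind, manifest))
}

#' Write a synthetic study to disk
#'
#' Writes the genotype panel as `.geno`, each replicate spectrum as
#' two-column CSV, the manifest as TSV, and the ground truth as JSON.
#'
#' @param study Result of [simulate_study()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_geno(study$panel, file.path(dir, "panel.geno"))
  sp_dir <- file.path(dir, "spectra")
  dir.create(sp_dir, showWarnings = FALSE)
  for (i in seq_along(study$spectra))
    write_spectrum(study$spectra[[i]],
                   file.path(sp_dir, study$manifest$file[i]))
  utils::write.table(study$manifest, file.path(dir, "manifest.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  gt <- lapply(study$amplitudes, function(a) attr(a, "ground_truth"))
  jsonlite::write_json(
    lapply(gt, function(g) list(
      qtls = lapply(g$qtls, unclass), qtl_markers = g$qtl_markers,
      component_means = as.list(g$component_means), tissue = g$tissue)),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
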