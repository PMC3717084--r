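# Fixture builders shared across test files. Everything is generated in
# code; no binary fixtures.

grid <- ftirqtl::canonical_grid()

# spectrum that is zero except for narrow triangles of given area centered
# inside chosen windows (window endpoints stay at zero, so the local
# baseline is the zero line)
triangle_spectrum <- function(centers, areas, half_width = 3, tissue = NA) {
  y <- numeric(length(grid))
  for (i in seq_along(centers)) {
    h <- areas[i] / half_width  # triangle area = half_width * height
    tri <- pmax(0, 1 - abs(grid - centers[i]) / half_width) * h
    y <- y + tri
  }
  ftirqtl::spectrum(grid, y, tissue = tissue)
}

# smooth random spectrum (sum of a few broad Gaussians), reproducible
random_smooth_spectrum <- function(seed, n_peaks = 6) {
  set.seed(seed)
  y <- numeric(length(grid))
  for (i in seq_len(n_peaks)) {
    c0 <- runif(1, 700, 3900); s0 <- runif(1, 10, 80); a <- runif(1, 0.1, 1)
    y <- y + a * exp(-(grid - c0)^2 / (2 * s0^2))
  }
  ftirqtl::spectrum(grid, y)
}

# clean adipose-like spectrum from the generator, optionally with artifacts
clean_adipose_spectrum <- function(vapor_scale = 0, noise_sd = 0, seed = 1) {
  m <- ftirqtl::component_models("adipose")
  amp <- c(lipid_CH = 1.8, ester = 0.5, unsaturated = 0.12,
           amide = 0.6, collagen = 0.05, baseline = 0.05)
  ftirqtl::synthesize_spectrum(amp, m, vapor_scale = vapor_scale,
                               noise_sd = noise_sd, seed = seed,
                               meta = list(tissue = "adipose"))
}

# tiny gene annotation table: n_in genes inside [lo, hi) Mb on chr, n_out
# outside, with controllable annotation columns
gene_fixture <- function(chr = "12", lo = 26, hi = 30, n_in = 21, n_out = 3,
                         seed = 42) {
  set.seed(seed)
  start_in <- runif(n_in, lo, hi - 0.2)
  start_out <- c(runif(ceiling(n_out / 2), lo - 10, lo - 1),
                 runif(floor(n_out / 2), hi + 1, hi + 10))
  start <- c(start_in, start_out)
  data.frame(
    symbol = sprintf("Gene%02d", seq_along(start)),
    chr = chr,
    start_Mb = start, end_Mb = start + runif(length(start), 0.01, 0.15),
    expressed_adipose = rep(c(TRUE, FALSE), length.out = length(start)),
    nsSNP = rpois(length(start), 1), InDel = rpois(length(start), 0.5),
    cis_eqtl = rep(c(TRUE, TRUE, FALSE), length.out = length(start)),
    keywords = rep(c("lipid, immunity", "transport", ""),
                   length.out = length(start)),
    stringsAsFactors = FALSE)
}
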