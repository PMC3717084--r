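# Marker regression scans, LOD/LRS conversion, permutation thresholds,
# support intervals, QTL summaries, and the .geno dialect.

make_panel <- function(n_strains = 24, seed = 13,
                       chr_lengths = c("1" = 60, "2" = 40)) {
  simulate_ri_genotypes(panel_design(n_strains = n_strains,
                                     chr_lengths_cM = chr_lengths,
                                     marker_spacing_cM = 10, seed = seed))
}

test_that(".geno files round-trip and censor heterozygote codes", {
  panel <- make_panel()
  f <- withr::local_tempfile(fileext = ".geno")
  write_geno(panel, f)
  back <- read_geno(f)
  expect_equal(back$geno, panel$geno)
  expect_equal(back$map$chr, panel$map$chr)
  expect_equal(back$map$Mb, panel$map$Mb)
  # H and U load as missing
  lines <- readLines(f)
  i <- grep("^1\t", lines)[1]
  parts <- strsplit(lines[i], "\t")[[1]]
  parts[5] <- "H"; parts[6] <- "U"
  lines[i] <- paste(parts, collapse = "\t")
  writeLines(lines, f)
  back2 <- read_geno(f)
  expect_true(is.na(back2$geno[1, parts[2]]))
  expect_true(is.na(back2$geno[2, parts[2]]))
})

test_that("scan LRS equals the correlation-path oracle", {
  set.seed(99)
  panel <- make_panel()
  strains <- rownames(panel$geno)
  y <- setNames(rnorm(length(strains)), strains)
  sc <- marker_regression_scan(panel, y)
  X <- ifelse(panel$geno == "B", 1, -1)
  for (j in seq_len(ncol(X))) {
    g <- X[, j]
    if (sc$skipped[j]) {
      expect_true(min(sum(g > 0), sum(g < 0)) < 2)
      next
    }
    r <- cor(y, g)
    expect_equal(sc$lrs[j], -length(y) * log(1 - r^2), tolerance = 1e-9)
  }
  # constant phenotype: both class means equal the grand mean -> LRS 0
  sc0 <- marker_regression_scan(panel, setNames(rep(3, length(strains)),
                                                strains))
  expect_true(all(sc0$lrs[!sc0$skipped] == 0))
})

test_that("scan reports additive effects and allele polarity correctly", {
  panel <- make_panel(seed = 5)
  strains <- rownames(panel$geno)
  g <- ifelse(panel$geno[, 4] == "B", 1, -1)
  set.seed(1)
  y <- setNames(2 + 0.8 * g + rnorm(length(g), sd = 0.2), strains)
  sc <- marker_regression_scan(panel, y)
  expect_equal(sc$additive[4],
               abs(mean(y[g > 0]) - mean(y[g < 0])) / 2, tolerance = 1e-12)
  expect_equal(sc$increasing_allele[4], "B6")
  # perfect fit -> capped LRS with flag
  yp <- setNames(as.numeric(g), strains)
  scp <- marker_regression_scan(panel, yp)
  expect_true(scp$perfect_fit[4])
  expect_equal(scp$lrs[4], 1e4)
  # affine invariance of LRS
  sc2 <- marker_regression_scan(panel, 5 - 3 * y)
  expect_equal(sc2$lrs, sc$lrs, tolerance = 1e-9)
  expect_equal(sc2$increasing_allele[4], "D2")
  # swapping all B/D labels preserves LRS, flips the increasing allele
  swapped <- panel
  swapped$geno[] <- ifelse(panel$geno == "B", "D", "B")
  sc3 <- marker_regression_scan(swapped, y)
  expect_equal(sc3$lrs, sc$lrs, tolerance = 1e-9)
  expect_equal(sc3$increasing_allele[4], "D2")
  expect_error(marker_regression_scan(panel, c(S1 = 1, S2 = 2)),
               "insufficient")
})

test_that("LOD/LRS conversion uses the exact 2 ln 10 factor", {
  expect_equal(lod_lrs_convert(0), 0)
  expect_equal(round(lod_lrs_convert(1.5), 1), 6.9)
  x <- c(0.3, 1.7, 12)
  expect_equal(lod_lrs_convert(lod_lrs_convert(x), "lrs_to_lod"), x)
  expect_error(lod_lrs_convert(-1), "domain")
})

test_that("permutation thresholds are the stated order statistics", {
  panel <- make_panel(seed = 31)
  strains <- rownames(panel$geno)
  set.seed(2)
  y <- setNames(rnorm(length(strains)), strains)
  th <- permutation_thresholds(panel, y, n_perm = 1000, seed = 17)
  srt <- sort(th$max_lrs)
  expect_equal(th$significant, srt[ceiling(0.95 * 1000)])
  expect_equal(th$suggestive, srt[ceiling(0.37 * 1000)])
  expect_lte(th$suggestive, th$significant)
  # reproducible under the seed
  th2 <- permutation_thresholds(panel, y, n_perm = 1000, seed = 17)
  expect_identical(th$max_lrs, th2$max_lrs)
  expect_warning(permutation_thresholds(panel, y, n_perm = 50, seed = 1),
                 "unstable")
})

test_that("support intervals interpolate the LOD-drop crossing", {
  sc <- data.frame(chr = "7", locus = paste0("m", 1:5),
                   cM = c(0, 10, 20, 30, 40), Mb = c(0, 5, 10, 15, 20),
                   lrs = c(0, 10, 20, 10, 0),
                   lod = c(0, 10, 20, 10, 0) / (2 * log(10)),
                   additive = 1, increasing_allele = "B6", n = 20,
                   skipped = FALSE, perfect_fit = FALSE)
  class(sc) <- c("scan_result", "data.frame")
  si <- support_interval(sc, "7", drop = 6.9)
  expect_equal(si$peak_locus, "m3")
  expect_equal(si$left_cM, 13.1)   # crossing of the rising flank at 13.1
  expect_equal(si$right_cM, 26.9)
  expect_true(si$left_cM <= 20 && 20 <= si$right_cM)
  # drop exceeding the peak spans the whole chromosome
  si2 <- support_interval(sc, "7", drop = 50)
  expect_equal(c(si2$left_cM, si2$right_cM), c(0, 40))
  # flat scan -> no interval
  sc$lrs <- 0
  expect_null(support_interval(sc, "7"))
})

test_that("a planted large-effect QTL yields exactly one significant region", {
  design <- panel_design(n_strains = 30, males_per_strain = 4,
                         strain_sd = 0.05, animal_sd = 0.05, seed = 77)
  panel <- simulate_ri_genotypes(design)
  q <- planted_qtl("2", 30, "ester", 0.4)
  amp <- simulate_amplitudes(panel, list(q), design, tissue = "adipose")
  means <- tapply(amp$ester, amp$strain, mean)
  sc <- marker_regression_scan(panel, means)
  th <- permutation_thresholds(panel, means, n_perm = 1000, seed = 7)
  qrep <- summarize_qtls(list(ester = sc), list(ester = th))
  sig <- qrep[qrep$significance == "**", ]
  expect_equal(nrow(sig), 1)
  expect_equal(sig$chr, "2")
  expect_true(sig$left_cM <= 30 && 30 <= sig$right_cM)
  # two traits driven by the same locus peak in overlapping intervals
  amp2 <- simulate_amplitudes(panel, list(planted_qtl("2", 30, "amide", 0.4)),
                              design, tissue = "adipose")
  means2 <- tapply(amp2$amide, amp2$strain, mean)
  sc2 <- marker_regression_scan(panel, means2)
  si1 <- support_interval(sc, "2")
  si2 <- support_interval(sc2, "2")
  expect_true(si1$left_cM <= si2$right_cM && si2$left_cM <= si1$right_cM)
  # all-flat trait -> empty report
  flat <- setNames(rep(1, 30), rownames(panel$geno))
  scf <- marker_regression_scan(panel, flat)
  repf <- summarize_qtls(list(f = scf), list(f = th))
  expect_equal(nrow(repf), 0)
})
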