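# Band integration above a local linear baseline, the registry snapshot,
# composites, ratios and per-tissue trait menus.

test_that("band_area integrates above the endpoint-anchored baseline", {
  g <- canonical_grid()
  zero <- spectrum(g, numeric(length(g)))
  expect_equal(band_area(zero, 1500, 1600), 0)
  # any straight line integrates to zero (baseline coincides)
  line <- spectrum(g, 0.3 + 0.001 * g)
  expect_equal(band_area(line, 1200, 1900), 0, tolerance = 1e-12)
  # symmetric triangle height 1 on zero endpoints over width w -> w / 2
  for (w in c(20, 31, 50)) {
    lo <- 1500; hi <- lo + w
    mid <- (lo + hi) / 2
    tri <- spectrum(g, pmax(0, 1 - abs(g - mid) / (w / 2)))
    # odd widths put the apex between grid points; 1 cm^-1 sampling then
    # under-integrates the peak by O(1/w)
    expect_equal(band_area(tri, lo, hi), w / 2, tolerance = 2e-3)
  }
  expect_error(band_area(zero, 300, 700), "coverage")
})

test_that("band_area is linear and translation-invariant", {
  for (seed in 1:8) {
    s1 <- random_smooth_spectrum(seed)
    s2 <- random_smooth_spectrum(seed + 100)
    lo <- 1300 + 37 * seed; hi <- lo + 60.5  # off-grid upper border
    a1 <- band_area(s1, lo, hi); a2 <- band_area(s2, lo, hi)
    both <- s1; both$absorbance <- s1$absorbance + s2$absorbance
    expect_equal(band_area(both, lo, hi), a1 + a2, tolerance = 1e-10)
    scaled <- s1; scaled$absorbance <- 3.7 * s1$absorbance
    expect_equal(band_area(scaled, lo, hi), 3.7 * a1, tolerance = 1e-10)
    shifted <- s1; shifted$absorbance <- s1$absorbance + 2.2
    expect_equal(band_area(shifted, lo, hi), a1, tolerance = 1e-10)
  }
})

test_that("the shipped registry matches the published border set cell-for-cell", {
  reg <- band_registry()
  b <- reg[reg$type == "band", c("tissue", "name", "lower", "upper")]
  expected <- rbind(
    data.frame(tissue = "adipose",
               name = c("A3006", "A2957", "A2922", "A2853", "A1743",
                        "A1464", "A1160", "A1550", "A1340", "A1320", "A1280"),
               lower = c(2997, 2950, 2905, 2840, 1730, 1454, 1133, 1506,
                         1336, 1315, 1275),
               upper = c(3017, 2966, 2936, 2861, 1760, 1474, 1200, 1571,
                         1345, 1327, 1285)),
    data.frame(tissue = "liver",
               name = c("A2963", "A2927", "A2854", "A1745", "A1455",
                        "A1547", "A1340", "A1154", "A1081", "A1044"),
               lower = c(2952, 2900, 2840, 1737, 1437, 1500, 1332, 1141,
                         1071, 1020),
               upper = c(2968, 2938, 2861, 1759, 1475, 1565, 1346, 1174,
                         1091, 1050)),
    data.frame(tissue = "muscle",
               name = c("A2961", "A2927", "A2854", "A1741", "A1457",
                        "A1550", "A1340", "A1282", "A1081", "A1046"),
               lower = c(2951, 2900, 2840, 1735, 1450, 1500, 1334, 1275,
                         1067, 1030),
               upper = c(2968, 2939, 2861, 1755, 1472, 1570, 1355, 1287,
                         1100, 1052)))
  for (i in seq_len(nrow(expected))) {
    row <- b[b$tissue == expected$tissue[i] & b$name == expected$name[i], ]
    expect_equal(nrow(row), 1L, info = paste(expected$tissue[i], expected$name[i]))
    expect_equal(row$lower, expected$lower[i])
    expect_equal(row$upper, expected$upper[i])
  }
  expect_equal(nrow(b), nrow(expected))
  expect_true(all(b$lower >= 600 & b$upper <= 4000))
})

test_that("composites sum their member bands per tissue", {
  # signal only in the two saturated-fat windows
  s <- triangle_spectrum(c(2920, 2850), c(2, 3), tissue = "adipose")
  a2922 <- band_area(s, 2905, 2936)
  a2853 <- band_area(s, 2840, 2861)
  expect_equal(composite_area(s, "adipose", "A_SATF"), a2922 + a2853)
  # liver collagen is the single A1340 band
  sl <- triangle_spectrum(1339, 1.5, half_width = 2, tissue = "liver")
  expect_equal(composite_area(sl, "liver", "A_COL"),
               band_area(sl, 1332, 1346))
  zero <- spectrum(grid, numeric(length(grid)))
  for (nm in c("A_FAT", "A_SATF", "A_COL", "A_PROT"))
    expect_equal(composite_area(zero, "adipose", nm), 0)
  expect_error(composite_area(zero, "adipose", "A_GLYC"), "not defined")
  expect_error(composite_area(zero, "liver", "A_UNSATF"), "not defined")
})

test_that("ratio traits follow their defining formulas", {
  # unit-area triangles inside A1550, A1340, A1320, A1280 -> integrity 1/3
  s <- triangle_spectrum(c(1538, 1340.5, 1321, 1280), rep(1, 4),
                         half_width = 2)
  expect_equal(ratio_trait(s, "adipose", "collagen_integrity"), 1 / 3,
               tolerance = 1e-6)
  # equal CH2/CH3 areas -> acyl chain length 1
  s2 <- triangle_spectrum(c(2920, 2958), c(1, 1), half_width = 2)
  expect_equal(ratio_trait(s2, "adipose", "acyl_chain_length"), 1,
               tolerance = 1e-6)
  zero <- spectrum(grid, numeric(length(grid)))
  expect_error(ratio_trait(zero, "adipose", "lipid_to_protein"),
               "zero denominator")
})

test_that("trait menus match the per-tissue published sets", {
  s <- min_max_normalize(clean_adipose_spectrum())
  tv <- extract_traits(s, "adipose")
  expect_length(tv, 8)
  expect_false("glycogen" %in% names(tv))
  expect_true(all(c("unsaturated_fat", "sat_to_unsat_ratio") %in% names(tv)))
  design <- panel_design(n_strains = 1, males_per_strain = 1, replicates = 1,
                         chr_lengths_cM = c("1" = 10), seed = 4)
  for (tis in c("liver", "muscle")) {
    st <- simulate_study(design, tissues = tis)
    sm <- min_max_normalize(correct_water_vapor(st$spectra[[1]]))
    tvt <- extract_traits(sm, tis)
    expect_length(tvt, 7)
    expect_true("glycogen" %in% names(tvt))
    expect_false(any(c("unsaturated_fat", "sat_to_unsat_ratio") %in%
                       names(tvt)))
  }
  expect_error(extract_traits(s, "kidney"), "unknown tissue")
})

test_that("extracted lipid-to-protein ratio is monotone in planted lipid amplitude", {
  m <- component_models("adipose")
  base <- c(lipid_CH = 1, ester = 0.3, unsaturated = 0.1,
            amide = 0.6, collagen = 0.05, baseline = 0.05)
  ratios <- vapply(c(0.5, 1, 2, 4, 8), function(k) {
    amp <- base
    amp[c("lipid_CH", "ester", "unsaturated")] <-
      amp[c("lipid_CH", "ester", "unsaturated")] * k
    s <- min_max_normalize(synthesize_spectrum(amp, m))
    ratio_trait(s, "adipose", "lipid_to_protein")
  }, numeric(1))
  expect_true(all(diff(ratios) > 0))
})
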