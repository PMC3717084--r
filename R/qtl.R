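# Single-marker regression QTL scans on strain means, permutation-derived
# genome-wide thresholds, LOD/LRS conversion, and LOD-drop support
# intervals.

LRS_PER_LOD <- 2 * log(10)   # exact; 4.6 is display rounding
PERFECT_FIT_LRS <- 1e4       # cap for RSS1 = 0 markers

#' Read a GeneNetwork-style .geno file
#'
#' Tab-delimited with `@`-prefixed header directives and `#` comments, then
#' a header row `Chr Locus cM [Mb] <strain...>` and one row per marker.
#' Allele codes `B` and `D` are kept; heterozygote/unknown codes (`H`,
#' `U`, `?`) load as missing. Markers are sorted by position within
#' chromosome.
#'
#' @param path Path to the `.geno` file.
#' @return A `genotype_panel`.
#' @export
read_geno <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  body <- lines[!grepl("^[@#]", lines)]
  if (length(body) < 2L) stop("no marker rows in ", path)
  header <- strsplit(body[[1L]], "\t", fixed = TRUE)[[1L]]
  fixed <- intersect(c("Chr", "Locus", "cM", "Mb"), header)
  strain_cols <- setdiff(header, fixed)
  rows <- strsplit(body[-1L], "\t", fixed = TRUE)
  mat <- do.call(rbind, rows)
  colnames(mat) <- header
  map <- data.frame(chr = mat[, "Chr"], locus = mat[, "Locus"],
                    cM = as.numeric(mat[, "cM"]),
                    Mb = if ("Mb" %in% header) as.numeric(mat[, "Mb"])
                         else as.numeric(mat[, "cM"]) / 2,
                    stringsAsFactors = FALSE)
  geno <- t(mat[, strain_cols, drop = FALSE])
  geno[!geno %in% c("B", "D")] <- NA_character_
  dimnames(geno) <- list(strain_cols, map$locus)
  ord <- order(match(map$chr, unique(map$chr)), map$cM)
  map <- map[ord, ]; rownames(map) <- NULL
  geno <- geno[, ord, drop = FALSE]
  structure(list(map = map, geno = geno), class = "genotype_panel")
}

#' Write a genotype panel as .geno
#'
#' @param panel A `genotype_panel`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_geno <- function(panel, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("@type:riset", "@mat:B", "@pat:D",
               "# synthetic RI panel written by ftirqtl"), con)
  header <- c("Chr", "Locus", "cM", "Mb", rownames(panel$geno))
  writeLines(paste(header, collapse = "\t"), con)
  g <- panel$geno; g[is.na(g)] <- "U"
  for (i in seq_len(nrow(panel$map))) {
    row <- c(panel$map$chr[i], panel$map$locus[i],
             format(panel$map$cM[i], trim = TRUE),
             format(panel$map$Mb[i], trim = TRUE), g[, i])
    writeLines(paste(row, collapse = "\t"), con)
  }
  invisible(path)
}

# +1/-1 coding of the allele matrix (B = +1, D = -1), NA preserved
code_geno <- function(geno) {
  x <- matrix(NA_real_, nrow(geno), ncol(geno), dimnames = dimnames(geno))
  x[geno == "B"] <- 1; x[geno == "D"] <- -1
  x
}

# LRS for one marker from class RSS; returns c(lrs, add, perfect)
marker_lrs <- function(y, g) {
  ok <- !is.na(g) & !is.na(y)
  y <- y[ok]; g <- g[ok]
  nB <- sum(g > 0); nD <- sum(g < 0)
  if (nB < 2L || nD < 2L) return(c(NA_real_, NA_real_, NA_real_, 0))
  n <- length(y)
  mB <- mean(y[g > 0]); mD <- mean(y[g < 0])
  rss0 <- sum((y - mean(y))^2)
  rss1 <- sum((y[g > 0] - mB)^2) + sum((y[g < 0] - mD)^2)
  if (rss0 == 0) return(c(0, 0, n, 0))
  if (rss1 <= rss0 * 1e-12)
    return(c(PERFECT_FIT_LRS, (mB - mD) / 2, n, 1))
  c(n * log(rss0 / rss1), (mB - mD) / 2, n, 0)
}

#' Single-marker regression scan
#'
#' Per marker, regresses strain means on genotype coded B = +1, D = -1
#' with intercept; `LRS = n ln(RSS0 / RSS1)` with `RSS0` about the grand
#' mean. The additive effect is half the difference between the two
#' homozygous class means, reported as magnitude plus increasing allele.
#' Strains with a missing genotype are dropped at that marker; markers
#' with fewer than two strains in either class are skipped (LRS NA,
#' `skipped` flag). Perfect fits (RSS1 = 0) are capped at `1e4` LRS with a
#' `perfect_fit` flag.
#'
#' @param panel A `genotype_panel`.
#' @param means Named numeric vector of strain means (names matched to
#'   panel strains).
#' @return A `scan_result` data.frame: `chr`, `locus`, `cM`, `Mb`, `lrs`,
#'   `lod`, `additive`, `increasing_allele`, `n`, `skipped`,
#'   `perfect_fit`.
#' @export
marker_regression_scan <- function(panel, means) {
  strains <- intersect(rownames(panel$geno), names(means))
  if (length(strains) < 3L)
    stop("insufficient data: fewer than 3 strains shared between panel and trait")
  y <- means[strains]
  X <- code_geno(panel$geno[strains, , drop = FALSE])
  res <- t(apply(X, 2L, function(g) marker_lrs(y, g)))
  out <- data.frame(panel$map,
                    lrs = res[, 1L], lod = res[, 1L] / LRS_PER_LOD,
                    additive = abs(res[, 2L]),
                    increasing_allele = ifelse(is.na(res[, 2L]), NA_character_,
                                               ifelse(res[, 2L] >= 0, "B6", "D2")),
                    n = res[, 3L],
                    skipped = is.na(res[, 1L]),
                    perfect_fit = res[, 4L] == 1,
                    stringsAsFactors = FALSE)
  attr(out, "signed_additive") <- res[, 2L]
  class(out) <- c("scan_result", "data.frame")
  out
}

#' Convert between LOD and LRS
#'
#' Uses the exact relation `LRS = 2 ln(10) x LOD` (about 4.605); the
#' conventional display factor 4.6 is rounding only.
#'
#' @param value Non-negative statistic value.
#' @param direction `"lod_to_lrs"` or `"lrs_to_lod"`.
#' @return Converted value.
#' @export
lod_lrs_convert <- function(value, direction = c("lod_to_lrs", "lrs_to_lod")) {
  direction <- match.arg(direction)
  if (any(value < 0)) stop("domain error: negative LOD/LRS")
  if (direction == "lod_to_lrs") value * LRS_PER_LOD else value / LRS_PER_LOD
}

# vectorized null scan: max LRS for each column of a strains x nperm
# phenotype matrix against a complete +1/-1 genotype matrix
max_lrs_matrix <- function(Y, X) {
  # per marker: r^2 between y and g; LRS = -n log(1 - r^2)
  n <- nrow(Y)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  ssy <- colSums(Yc^2); ssx <- colSums(Xc^2)
  cross <- crossprod(Yc, Xc)                 # nperm x markers
  r2 <- cross^2 / outer(ssy, ssx)
  r2[r2 > 1 - 1e-12] <- 1 - 1e-12
  lrs <- -n * log(1 - r2)
  apply(lrs, 1L, max)
}

#' Permutation-derived genome-wide LRS thresholds
#'
#' Permutes the trait values across strain labels `n_perm` times, records
#' the genome-wide maximum LRS of each permuted scan, and returns the
#' empirical order statistics at `ceil((1 - p) n_perm)`: significant at
#' genome-wide p < 0.05, suggestive at p < 0.63.
#'
#' @param panel A `genotype_panel`.
#' @param means Named strain means.
#' @param n_perm Number of permutations (default 1000; below 100 warns).
#' @param seed Integer seed.
#' @return A `qtl_thresholds` list: `significant`, `suggestive`,
#'   `n_perm`, `seed`, `max_lrs` (the permutation sample).
#' @export
permutation_thresholds <- function(panel, means, n_perm = 1000L, seed = 1L) {
  if (n_perm < 100L) warning("n_perm < 100: thresholds will be unstable")
  strains <- intersect(rownames(panel$geno), names(means))
  y <- means[strains]
  X <- code_geno(panel$geno[strains, , drop = FALSE])
  # markers usable under the >=2-per-class rule, fixed across permutations
  usable <- apply(X, 2L, function(g) {
    ok <- !is.na(g); sum(g[ok] > 0) >= 2 && sum(g[ok] < 0) >= 2
  })
  X <- X[, usable, drop = FALSE]
  set.seed(seed)
  maxima <- numeric(n_perm)
  if (!anyNA(X)) {
    Y <- vapply(seq_len(n_perm), function(i) sample(y), numeric(length(y)))
    maxima <- max_lrs_matrix(Y, X)
  } else {
    for (i in seq_len(n_perm)) {
      yp <- sample(y); names(yp) <- strains
      sc <- apply(X, 2L, function(g) marker_lrs(yp, g)[1L])
      maxima[i] <- max(sc, na.rm = TRUE)
    }
  }
  srt <- sort(maxima)
  ord_stat <- function(p) srt[min(max(ceiling((1 - p) * n_perm), 1L), n_perm)]
  structure(list(significant = ord_stat(0.05), suggestive = ord_stat(0.63),
                 n_perm = n_perm, seed = seed, max_lrs = maxima),
            class = "qtl_thresholds")
}

#' LOD-drop support interval around a chromosome peak
#'
#' From the peak marker, walks outward until the scan falls below
#' `peak - drop` LRS (default 6.9, i.e. a 1.5-LOD drop) and places each
#' bound by linear interpolation in position between the bracketing
#' markers; truncated at chromosome ends.
#'
#' @param scan A `scan_result`.
#' @param chr Chromosome id.
#' @param drop LRS drop (default 6.9).
#' @param min_lrs If given, return NULL when the chromosome peak is below
#'   this (e.g. the suggestive threshold).
#' @return List: `chr`, `peak_locus`, `peak_lrs`, `left_cM`, `right_cM`,
#'   `left_Mb`, `right_Mb`; or NULL for a flat/sub-threshold chromosome.
#' @export
support_interval <- function(scan, chr, drop = 6.9, min_lrs = NULL) {
  sub <- scan[scan$chr == chr & !is.na(scan$lrs), , drop = FALSE]
  if (!nrow(sub)) return(NULL)
  pk <- which.max(sub$lrs)
  peak <- sub$lrs[pk]
  if (peak <= 0) return(NULL)
  if (!is.null(min_lrs) && peak < min_lrs) return(NULL)
  target <- peak - drop
  interp <- function(i_in, i_out, col) {
    # crossing between marker i_in (>= target) and i_out (< target)
    f <- (sub$lrs[i_in] - target) / (sub$lrs[i_in] - sub$lrs[i_out])
    sub[[col]][i_in] + f * (sub[[col]][i_out] - sub[[col]][i_in])
  }
  left_cM <- sub$cM[1L]; left_Mb <- sub$Mb[1L]
  i <- pk
  while (i > 1L && sub$lrs[i - 1L] >= target) i <- i - 1L
  if (i > 1L) { left_cM <- interp(i, i - 1L, "cM"); left_Mb <- interp(i, i - 1L, "Mb") }
  j <- pk
  nM <- nrow(sub)
  while (j < nM && sub$lrs[j + 1L] >= target) j <- j + 1L
  if (j < nM) { right_cM <- interp(j, j + 1L, "cM"); right_Mb <- interp(j, j + 1L, "Mb") }
  else { right_cM <- sub$cM[nM]; right_Mb <- sub$Mb[nM] }
  list(chr = chr, peak_locus = sub$locus[pk], peak_lrs = peak,
       left_cM = left_cM, right_cM = right_cM,
       left_Mb = left_Mb, right_Mb = right_Mb)
}

#' Summarize QTLs across traits
#'
#' For each trait, reports every chromosome whose LRS maximum exceeds the
#' trait's suggestive threshold, with significance class (`"*"` suggestive,
#' `"**"` significant), increasing allele, additive effect, and the
#' LOD-drop support interval.
#'
#' @param scans Named list of `scan_result`, one per trait.
#' @param thresholds Named list of `qtl_thresholds`, same names.
#' @param drop LRS drop rule for support intervals (default 6.9).
#' @return data.frame: `trait`, `chr`, `peak_locus`, `peak_cM`, `peak_Mb`,
#'   `lrs`, `significance`, `increasing_allele`, `additive`, `left_Mb`,
#'   `right_Mb`.
#' @export
summarize_qtls <- function(scans, thresholds, drop = 6.9) {
  rows <- list()
  for (tr in names(scans)) {
    sc <- scans[[tr]]; th <- thresholds[[tr]]
    for (chr in unique(sc$chr)) {
      sub <- sc[sc$chr == chr & !is.na(sc$lrs), , drop = FALSE]
      if (!nrow(sub)) next
      pk <- which.max(sub$lrs)
      if (sub$lrs[pk] < th$suggestive) next
      si <- support_interval(sc, chr, drop = drop)
      rows[[length(rows) + 1L]] <- data.frame(
        trait = tr, chr = chr, peak_locus = sub$locus[pk],
        peak_cM = sub$cM[pk], peak_Mb = sub$Mb[pk], lrs = sub$lrs[pk],
        significance = if (sub$lrs[pk] >= th$significant) "**" else "*",
        increasing_allele = sub$increasing_allele[pk],
        additive = sub$additive[pk],
        left_Mb = si$left_Mb, right_Mb = si$right_Mb,
        left_cM = si$left_cM, right_cM = si$right_cM,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(trait = character(0), chr = character(0),
                      peak_locus = character(0), peak_cM = numeric(0),
                      peak_Mb = numeric(0), lrs = numeric(0),
                      significance = character(0),
                      increasing_allele = character(0),
                      additive = numeric(0), left_Mb = numeric(0),
                      right_Mb = numeric(0), left_cM = numeric(0),
                      right_cM = numeric(0), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
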