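# Trait-level statistics: single-pass 3-SD winsorization, strain
# summaries, Pearson correlation matrices with multiplicity adjustment,
# Wright-style broad-sense heritability, and delta-delta-Ct relative
# expression.

#' Winsorize a trait vector at 3 standard deviations
#'
#' Values more than `z` SDs from the mean (mean and SD over all animals of
#' all strains for the trait) are replaced by the nearest non-outlier value
#' on the same side. Applied once; statistics are not recomputed after
#' replacement.
#'
#' @param values Numeric vector (>= 3 values).
#' @param z Threshold in SD units (default 3).
#' @return List: `values` (winsorized), `flags` (logical, TRUE where
#'   replaced).
#' @export
winsorize_trait <- function(values, z = 3) {
  stopifnot(length(values) >= 3L)
  m <- mean(values); s <- stats::sd(values)
  if (s == 0) {
    warning("zero SD: winsorization is a no-op")
    return(list(values = values, flags = rep(FALSE, length(values))))
  }
  zz <- (values - m) / s
  hi_out <- zz > z; lo_out <- zz < -z
  out <- values
  if (any(hi_out)) {
    repl <- max(values[!hi_out & !lo_out])
    out[hi_out] <- repl
  }
  if (any(lo_out)) {
    repl <- min(values[!hi_out & !lo_out])
    out[lo_out] <- repl
  }
  list(values = out, flags = hi_out | lo_out)
}

#' Per-strain trait summaries
#'
#' Mean, SD, SE = SD/sqrt(n) and n per strain. Strains listed in `exclude`
#' (e.g. whole-strain QC failures) are dropped. A strain with a single
#' animal gets SD = 0 with a warning.
#'
#' @param df data.frame with columns `strain`, `value` (winsorized).
#' @param exclude Character vector of strain names to drop.
#' @return data.frame: `strain`, `mean`, `sd`, `se`, `n`.
#' @export
strain_summary <- function(df, exclude = character(0)) {
  df <- df[!df$strain %in% exclude, , drop = FALSE]
  out <- lapply(split(df$value, df$strain), function(v) {
    n <- length(v)
    s <- if (n > 1L) stats::sd(v) else {
      warning("strain with n=1: SD recorded as 0"); 0
    }
    c(mean = mean(v), sd = s, se = s / sqrt(n), n = n)
  })
  res <- data.frame(strain = names(out),
                    do.call(rbind, out), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Pearson correlation matrix over strain means
#'
#' Pairwise-complete Pearson r with two-sided p from the t transform and
#' Holm (default) or Bonferroni adjustment over the upper triangle.
#' Constant traits yield NA with a warning-free record.
#'
#' @param means Matrix or data.frame, strains x traits.
#' @param adjust `"holm"` or `"bonferroni"`.
#' @param min_pairs Minimum complete pairs per trait pair (default 3).
#' @return List of matrices `r`, `p`, `p_adj`, `n`.
#' @export
correlation_matrix <- function(means, adjust = c("holm", "bonferroni"),
                               min_pairs = 3L) {
  adjust <- match.arg(adjust)
  means <- as.matrix(means)
  k <- ncol(means)
  traits <- colnames(means)
  r <- p <- n <- matrix(NA_real_, k, k, dimnames = list(traits, traits))
  for (i in seq_len(k)) for (j in i:k) {
    ok <- stats::complete.cases(means[, c(i, j)])
    nn <- sum(ok)
    n[i, j] <- n[j, i] <- nn
    if (nn < min_pairs) next
    x <- means[ok, i]; y <- means[ok, j]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) next
    rr <- stats::cor(x, y)
    r[i, j] <- r[j, i] <- rr
    if (i == j) { p[i, j] <- 0; next }
    tt <- rr * sqrt((nn - 2) / max(1 - rr^2, .Machine$double.eps))
    pp <- 2 * stats::pt(-abs(tt), df = nn - 2)
    p[i, j] <- p[j, i] <- pp
  }
  upper <- upper.tri(p)
  p_adj <- p
  p_adj[upper] <- stats::p.adjust(p[upper], method = adjust)
  p_adj[lower.tri(p_adj)] <- t(p_adj)[lower.tri(p_adj)]
  list(r = r, p = p, p_adj = p_adj, n = n)
}

#' Broad-sense heritability from isogenic and RI variances
#'
#' `Ve` is the pooled (df-weighted) within-strain variance of the isogenic
#' groups (the two parental strains and the F1); `Vp` is the variance of
#' all RI animal-level values (configurable to strain means);
#' `H2 = clip((Vp - Ve) / Vp, 0, 1)`.
#'
#' @param ri_values Numeric vector of RI animal-level trait values (or
#'   strain means when `vp_scope = "strain_means"`).
#' @param isogenic List of numeric vectors, one per isogenic group, each
#'   with >= 2 values.
#' @param vp_scope `"animals"` (default) or `"strain_means"`.
#' @return List: `Ve`, `Vp`, `H2` (NA when `Vp` is 0).
#' @export
broad_sense_heritability <- function(ri_values, isogenic,
                                     vp_scope = c("animals", "strain_means")) {
  vp_scope <- match.arg(vp_scope)
  stopifnot(length(isogenic) >= 1L,
            all(vapply(isogenic, length, integer(1)) >= 2L))
  dfs <- vapply(isogenic, function(v) length(v) - 1L, integer(1))
  vars <- vapply(isogenic, stats::var, numeric(1))
  Ve <- sum(dfs * vars) / sum(dfs)
  Vp <- stats::var(ri_values)
  if (!is.finite(Vp) || Vp == 0)
    return(list(Ve = Ve, Vp = Vp, H2 = NA_real_, vp_scope = vp_scope))
  H2 <- min(max((Vp - Ve) / Vp, 0), 1)
  list(Ve = Ve, Vp = Vp, H2 = H2, vp_scope = vp_scope)
}

#' Relative expression by the delta-delta-Ct method
#'
#' Per group: `dCt = mean(target Ct) - mean(reference Ct)`;
#' `ddCt = dCt(group) - dCt(calibrator)`; `RQ = 2^(-ddCt)`. The calibrator
#' group has RQ = 1 by construction.
#'
#' @param target Named list of numeric Ct replicate vectors, one per group.
#' @param reference Named list with the same group names, reference-gene
#'   Cts.
#' @param calibrator Name of the calibrator group.
#' @return data.frame: `group`, `dCt`, `ddCt`, `RQ`.
#' @export
ddct_relative_quantity <- function(target, reference, calibrator) {
  groups <- names(target)
  if (is.null(groups) || !calibrator %in% groups)
    stop("calibrator group not found among target groups")
  if (!all(groups %in% names(reference)))
    stop("missing reference-gene Cts for some groups")
  stopifnot(all(vapply(target, function(v) all(is.finite(v)), logical(1))),
            all(vapply(reference, function(v) all(is.finite(v)), logical(1))))
  dct <- vapply(groups, function(g) mean(target[[g]]) - mean(reference[[g]]),
                numeric(1))
  ddct <- dct - dct[[calibrator]]
  data.frame(group = groups, dCt = unname(dct), ddCt = unname(ddct),
             RQ = 2^(-unname(ddct)), stringsAsFactors = FALSE)
}

#' Winsorize and summarize a tidy trait table
#'
#' Applies [winsorize_trait()] per (tissue, trait) over all animals, then
#' [strain_summary()] per trait.
#'
#' @param df data.frame: `strain`, `animal`, `tissue`, `trait`, `value`.
#' @param z Winsorization threshold.
#' @param exclude Strains to drop (per tissue), e.g.
#'   `list(adipose = "BXD14")`.
#' @return List: `values` (df with winsorized `value` and `winsorized`
#'   flag), `summary` (df with per-strain stats per tissue/trait).
#' @export
trait_table <- function(df, z = 3, exclude = list()) {
  df <- df[order(df$tissue, df$trait, df$strain, df$animal), , drop = FALSE]
  df$winsorized <- FALSE
  summaries <- list()
  for (key in unique(paste(df$tissue, df$trait, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1L]]
    idx <- df$tissue == parts[1L] & df$trait == parts[2L]
    w <- winsorize_trait(df$value[idx], z = z)
    df$value[idx] <- w$values
    df$winsorized[idx] <- w$flags
    summ <- strain_summary(df[idx, c("strain", "value")],
                           exclude = exclude[[parts[1L]]] %||% character(0))
    summ$tissue <- parts[1L]; summ$trait <- parts[2L]
    summaries[[key]] <- summ
  }
  summary <- do.call(rbind, summaries)
  rownames(summary) <- NULL
  list(values = df, summary = summary)
}
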