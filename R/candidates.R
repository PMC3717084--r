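# Candidate-gene filter cascade over user-supplied annotation tables:
# location in the QTL interval, expression in the target tissue, nsSNP +
# InDel density, cis-eQTL evidence, and function keywords. All filters are
# pure predicates so the cascade runs offline.

#' Genes overlapping a QTL interval
#'
#' Returns genes overlapping `[start, end)` (Mb, half-open) on the given
#' chromosome; any overlap counts, so genes spanning a boundary are
#' included.
#'
#' @param genes data.frame with columns `symbol`, `chr`, `start_Mb`,
#'   `end_Mb` (start <= end).
#' @param chr Chromosome id.
#' @param start,end Interval bounds in Mb, `start < end`.
#' @return Subset of `genes`, sorted by symbol.
#' @export
genes_in_interval <- function(genes, chr, start, end) {
  stopifnot(start < end)
  if (!nrow(genes)) return(genes)
  stopifnot(all(genes$start_Mb <= genes$end_Mb))
  hit <- genes$chr == as.character(chr) &
    genes$start_Mb < end & genes$end_Mb >= start
  out <- genes[hit, , drop = FALSE]
  out[order(out$symbol), , drop = FALSE]
}

#' Candidate-gene filter cascade
#'
#' Applies the sequential boolean filters to genes already restricted to a
#' QTL interval: (1) location (satisfied by construction), (2) expression
#' in the target tissue, (3) variant density -- nsSNP + InDel count at
#' least `min_variants`, (4) cis-eQTL flag, (5) function-keyword
#' intersection with `keywords` non-empty. A missing annotation column
#' fails its filter with a warning rather than erroring. Genes passing all
#' filters are retained; rank is the number of filters passed.
#'
#' @param genes data.frame of interval genes. Recognized columns:
#'   `symbol`, `expressed_<tissue>` (logical), `nsSNP`, `InDel`,
#'   `cis_eqtl` (logical), `keywords` (comma/semicolon-separated).
#' @param tissue Target tissue (selects the `expressed_<tissue>` column).
#' @param keywords Character vector of function keywords to match
#'   (case-insensitive).
#' @param min_variants Minimum nsSNP + InDel count (default 1).
#' @return A `candidate_report` data.frame: one row per gene (sorted by
#'   symbol), logical columns `location`, `expression`, `variants`,
#'   `cis_eqtl`, `func`, plus `rank` and `retained`.
#' @export
filter_candidates <- function(genes, tissue, keywords,
                              min_variants = 1L) {
  genes <- genes[order(genes$symbol), , drop = FALSE]
  n <- nrow(genes)
  get_col <- function(col, filter) {
    if (!col %in% names(genes)) {
      warning("annotation column '", col, "' missing: ", filter,
              " filter fails for all genes")
      return(rep(NA, n))
    }
    genes[[col]]
  }
  expr_col <- paste0("expressed_", tissue)
  expression <- isTRUE_vec(get_col(expr_col, "expression"))
  nssnp <- get_col("nsSNP", "variants")
  indel <- get_col("InDel", "variants")
  variants <- !is.na(nssnp) & !is.na(indel) &
    (as.numeric(nssnp) + as.numeric(indel)) >= min_variants
  cis <- isTRUE_vec(get_col("cis_eqtl", "cis-eQTL"))
  kw <- get_col("keywords", "function")
  func <- vapply(seq_len(n), function(i) {
    if (is.na(kw[i])) return(FALSE)
    gk <- tolower(trimws(strsplit(kw[i], "[,;]")[[1L]]))
    any(tolower(keywords) %in% gk)
  }, logical(1))
  location <- rep(TRUE, n)
  rank <- location + expression + variants + cis + func
  report <- data.frame(symbol = genes$symbol, location = location,
                       expression = expression, variants = variants,
                       cis_eqtl = cis, func = func, rank = rank,
                       retained = expression & variants & cis & func,
                       stringsAsFactors = FALSE)
  rownames(report) <- NULL
  class(report) <- c("candidate_report", "data.frame")
  report
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' Read a gene annotation TSV
#'
#' @param path TSV with at least `symbol`, `chr`, `start_Mb`, `end_Mb`.
#' @return data.frame.
#' @export
read_gene_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(chr = "character"))
}
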