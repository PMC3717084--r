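# End-to-end orchestration: simulate -> preprocess -> features -> trait
# stats -> QTL scan -> candidate filter, driven by one JSON config, with
# seed-stamped TSV artifacts.

#' Build a pipeline configuration
#'
#' @param spectra_dir Directory of two-column CSV replicate spectra.
#' @param manifest Path to the TSV manifest (file, strain, animal, tissue,
#'   replicate).
#' @param geno Path to the `.geno` genotype file.
#' @param out_dir Output directory.
#' @param tissues Tissues to process.
#' @param gene_table Optional annotation TSV for candidate filtering.
#' @param keywords Function keywords for the candidate filter.
#' @param winsor_z Winsorization threshold (SD units).
#' @param n_perm Permutations per trait.
#' @param drop_lrs Support-interval drop rule (LRS units).
#' @param seed Seed for the permutation RNG.
#' @param thresholds Quality-test thresholds.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(spectra_dir, manifest, geno, out_dir,
                            tissues = c("adipose", "liver"),
                            gene_table = NULL, keywords = character(0),
                            winsor_z = 3, n_perm = 1000L, drop_lrs = 6.9,
                            seed = 1L,
                            thresholds = default_quality_thresholds()) {
  structure(list(spectra_dir = spectra_dir, manifest = manifest,
                 geno = geno, out_dir = out_dir, tissues = tissues,
                 gene_table = gene_table, keywords = keywords,
                 winsor_z = winsor_z, n_perm = as.integer(n_perm),
                 drop_lrs = drop_lrs, seed = as.integer(seed),
                 thresholds = thresholds),
            class = "pipeline_config")
}

#' Read a pipeline configuration from JSON
#'
#' @param path JSON file whose keys mirror [pipeline_config()] arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, cfg)
}

validate_config <- function(config) {
  for (p in c(config$spectra_dir, config$manifest, config$geno,
              config$gene_table)) {
    if (!is.null(p) && !file.exists(p))
      stop("validation error: path does not exist: ", p)
  }
  invisible(TRUE)
}

write_artifact <- function(df, path, seed) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# ftirqtl seed=%d", seed), con)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full pipeline
#'
#' Reads replicate spectra per the manifest, preprocesses them (vapor
#' correction, QC, min-max normalization, replicate averaging), extracts
#' the per-tissue trait menus from strain-mean spectra, winsorizes and
#' summarizes traits, computes the trait correlation matrix, scans every
#' trait against the genotype panel with permutation thresholds, and --
#' when an annotation table is configured -- filters candidate genes in
#' each significant interval. All artifacts are written under
#' `config$out_dir` with the seed in their header line.
#'
#' @param config A [pipeline_config()].
#' @return Invisible list of the in-memory artifacts: `trait_values`,
#'   `trait_summary`, `correlations`, `qc`, `scans`, `thresholds`,
#'   `qtl_report`, `candidates`.
#' @export
run_pipeline <- function(config) {
  validate_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- utils::read.delim(config$manifest, stringsAsFactors = FALSE)
  panel <- read_geno(config$geno)
  all_traits <- list(); qc_all <- list()
  for (tis in config$tissues) {
    sub <- manifest[manifest$tissue == tis, , drop = FALSE]
    if (!nrow(sub)) stop("stage preprocess: no manifest rows for tissue ", tis)
    spectra <- lapply(seq_len(nrow(sub)), function(i)
      read_spectrum(file.path(config$spectra_dir, sub$file[i]),
                    strain = sub$strain[i], animal = sub$animal[i],
                    tissue = tis, replicate = sub$replicate[i]))
    prep <- preprocess_spectra(spectra, thresholds = config$thresholds)
    qc_all[[tis]] <- cbind(tissue = tis, prep$qc)
    # traits per animal (sample means) feed winsorization; strain means
    # feed the scan after summary
    sm <- prep$sample_means
    rows <- lapply(names(sm), function(a) {
      tv <- extract_traits(sm[[a]], tis)
      data.frame(strain = sm[[a]]$meta$strain, animal = a, tissue = tis,
                 trait = names(tv), value = unname(tv),
                 stringsAsFactors = FALSE)
    })
    all_traits[[tis]] <- do.call(rbind, rows)
  }
  traits <- do.call(rbind, all_traits)
  tt <- trait_table(traits, z = config$winsor_z)
  write_artifact(tt$values, file.path(config$out_dir, "trait_values.tsv"),
                 config$seed)
  write_artifact(tt$summary, file.path(config$out_dir, "trait_summary.tsv"),
                 config$seed)
  write_artifact(do.call(rbind, qc_all),
                 file.path(config$out_dir, "quality_reports.tsv"),
                 config$seed)
  # broad-sense heritability per trait: every RI strain is isogenic, so Ve
  # is the pooled within-strain variance and Vp the animal-level variance
  herit <- do.call(rbind, lapply(
    split(tt$values, paste(tt$values$tissue, tt$values$trait, sep = ":")),
    function(d) {
      groups <- split(d$value, d$strain)
      groups <- groups[vapply(groups, length, integer(1)) >= 2L]
      h <- broad_sense_heritability(d$value, groups)
      data.frame(tissue = d$tissue[1L], trait = d$trait[1L],
                 Ve = h$Ve, Vp = h$Vp, H2 = h$H2, stringsAsFactors = FALSE)
    }))
  rownames(herit) <- NULL
  write_artifact(herit, file.path(config$out_dir, "heritability.tsv"),
                 config$seed)
  # correlation matrix over strain means, traits tagged tissue:trait
  summ <- tt$summary
  summ$key <- paste(summ$tissue, summ$trait, sep = ":")
  strains <- sort(unique(summ$strain))
  mat <- sapply(split(summ, summ$key), function(d)
    d$mean[match(strains, d$strain)])
  rownames(mat) <- strains
  cors <- correlation_matrix(mat)
  cor_df <- data.frame(trait = rownames(cors$r), cors$r, check.names = FALSE)
  write_artifact(cor_df, file.path(config$out_dir, "correlations.tsv"),
                 config$seed)
  # QTL scans per tissue:trait
  scans <- list(); thr <- list()
  for (key in colnames(mat)) {
    means <- mat[, key]; names(means) <- strains
    means <- means[!is.na(means)]
    scans[[key]] <- marker_regression_scan(panel, means)
    thr[[key]] <- permutation_thresholds(panel, means,
                                         n_perm = config$n_perm,
                                         seed = config$seed)
  }
  scan_df <- do.call(rbind, lapply(names(scans), function(k)
    cbind(trait = k, scans[[k]])))
  write_artifact(scan_df, file.path(config$out_dir, "scans.tsv"),
                 config$seed)
  report <- summarize_qtls(scans, thr, drop = config$drop_lrs)
  write_artifact(report, file.path(config$out_dir, "qtl_report.tsv"),
                 config$seed)
  candidates <- NULL
  if (!is.null(config$gene_table) && nrow(report)) {
    genes <- read_gene_table(config$gene_table)
    cand_rows <- list()
    for (i in which(report$significance == "**")) {
      tis <- sub(":.*", "", report$trait[i])
      gi <- genes_in_interval(genes, report$chr[i], report$left_Mb[i],
                              report$right_Mb[i])
      if (!nrow(gi)) next
      rep_i <- filter_candidates(gi, tis, config$keywords)
      cand_rows[[length(cand_rows) + 1L]] <-
        cbind(trait = report$trait[i], chr = report$chr[i], rep_i)
    }
    candidates <- if (length(cand_rows)) do.call(rbind, cand_rows) else
      data.frame()
    write_artifact(candidates,
                   file.path(config$out_dir, "candidates.tsv"), config$seed)
  }
  log_df <- data.frame(stage = c("preprocess", "traits", "stats", "scan"),
                       status = "ok")
  write_artifact(log_df, file.path(config$out_dir, "run_log.tsv"),
                 config$seed)
  invisible(list(trait_values = tt$values, trait_summary = tt$summary,
                 heritability = herit,
                 correlations = cors, qc = do.call(rbind, qc_all),
                 scans = scans, thresholds = thr, qtl_report = report,
                 candidates = candidates))
}
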