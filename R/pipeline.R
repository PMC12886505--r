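# One seeded, logged run of the whole assessment: scan -> DE ->
# classification -> enrichment -> entropy, emitting the standard report
# shapes as TSV plus a machine-readable summary.

#' Run configuration for a full assessment
#'
#' @param dsrna,transcriptome,counts,gene_sets input file paths (FASTA,
#'   FASTA, TSV, GMT). `gene_sets` may be NULL to skip pathway stages.
#' @param groups named character vector (sample -> group) or
#'   tibble(sample, group).
#' @param de_table optional precomputed DE TSV; when given, the internal
#'   NB test is skipped and the table is imported (classes recomputed).
#' @param out_dir output directory.
#' @param min_match_len,lfc_thresh,fdr_thresh,evalue_thresh,max_level
#'   thresholds (defaults 7 bp, 1, 0.05, 1e-10, 3).
#' @param boundary DEG boundary convention, `"strict"` or `"inclusive"`.
#' @param universe enrichment universe: `"tested"` (genes in the DE
#'   table) or `"all"` (whole transcriptome).
#' @param seed integer seed recorded in the log (the pipeline itself is
#'   deterministic; the seed also fixes any stochastic downstream use).
#' @return config list of class `run_config`.
#' @export
run_config <- function(dsrna, transcriptome, counts, groups,
                       gene_sets = NULL, de_table = NULL,
                       out_dir = "assessment_out",
                       min_match_len = 7, lfc_thresh = 1, fdr_thresh = 0.05,
                       evalue_thresh = 1e-10, max_level = 3,
                       boundary = c("strict", "inclusive"),
                       universe = c("tested", "all"),
                       seed = 1) {
  boundary <- match.arg(boundary)
  universe <- match.arg(universe)
  stopifnot(min_match_len > 0, lfc_thresh > 0, fdr_thresh > 0,
            evalue_thresh > 0, max_level >= 1)
  structure(list(dsrna = dsrna, transcriptome = transcriptome,
                 counts = counts, groups = groups, gene_sets = gene_sets,
                 de_table = de_table, out_dir = out_dir,
                 min_match_len = min_match_len, lfc_thresh = lfc_thresh,
                 fdr_thresh = fdr_thresh, evalue_thresh = evalue_thresh,
                 max_level = max_level, boundary = boundary,
                 universe = universe, seed = seed),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose keys mirror the arguments of
#'   [run_config()]; `groups` is a mapping sample -> group.
#' @return `run_config` list.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  y$groups <- unlist(y$groups)
  do.call(run_config, y)
}

#' Run the full off-target risk assessment
#'
#' Executes every stage on the configured inputs and writes
#' `match.tsv`, `de.tsv`, `match_summary.tsv`, `level_summary.tsv`,
#' `correlation.tsv`, `enrichment.tsv`, `entropy.tsv`, `run.log` and
#' `summary.json` into the output directory. Identical inputs and config
#' give byte-identical TSVs.
#'
#' @param config `run_config` list (or path to a YAML config).
#' @return invisible list with every stage result and `out_dir`.
#' @export
run_assessment <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c(sprintf("rnaisafe %s", as.character(utils::packageVersion("rnaisafe"))),
                 sprintf("seed: %d", config$seed),
                 sprintf("thresholds: match >= %d bp, |log2FC| %s %g, FDR %s %g, E < %g, levels <= %d",
                         config$min_match_len,
                         if (config$boundary == "strict") ">" else ">=",
                         config$lfc_thresh,
                         if (config$boundary == "strict") "<" else "<=",
                         config$fdr_thresh, config$evalue_thresh,
                         config$max_level))
  set.seed(config$seed)

  dsrna <- read_fasta(config$dsrna)
  transcripts <- read_fasta(config$transcriptome)
  cm <- read_counts(config$counts, config$groups)

  unknown <- setdiff(cm$counts$gene, transcripts$id)
  if (length(unknown)) {
    abort(sprintf("gene id(s) in the count matrix but not the transcriptome: %s",
                  paste(head(unknown, 10), collapse = ", ")))
  }

  scan <- scan_transcriptome(transcripts, dsrna$sequence[1],
                             min_report_len = config$min_match_len)
  match_tab <- scan[, c("gene", "max_match_sense", "max_match_antisense",
                        "max_match", "n_positions")]
  readr::write_tsv(match_tab, file.path(config$out_dir, "match.tsv"),
                   progress = FALSE)

  de <- if (!is.null(config$de_table)) {
    read_de_table(config$de_table, lfc_thresh = config$lfc_thresh,
                  fdr_thresh = config$fdr_thresh, boundary = config$boundary)
  } else {
    nb_wald_test(cm$counts, cm$groups, lfc_thresh = config$lfc_thresh,
                 fdr_thresh = config$fdr_thresh, boundary = config$boundary)
  }
  write_de_table(de, file.path(config$out_dir, "de.tsv"))
  n_deg <- sum(de$change_class == "significant_deg")
  log_lines <- c(log_lines,
                 sprintf("genes tested: %d; DEGs: %d", nrow(de), n_deg))

  bins <- bin_by_match_length(scan, de)
  readr::write_tsv(render_match_summary(bins),
                   file.path(config$out_dir, "match_summary.tsv"),
                   progress = FALSE)
  log_lines <- c(log_lines,
                 sprintf("matched genes (>= %d bp): %d; absent from DE table: %d",
                         config$min_match_len, sum(bins$total_genes),
                         attr(bins, "n_missing_de")))

  corr <- match_fold_change_correlation(scan, de, min_len = config$min_match_len)
  readr::write_tsv(corr$genes, file.path(config$out_dir, "correlation.tsv"),
                   progress = FALSE)

  homologs <- find_homologs(dsrna$sequence[1], transcripts,
                            evalue_thresh = config$evalue_thresh)
  log_lines <- c(log_lines, sprintf("homolog hits (E < %g): %d",
                                    config$evalue_thresh, nrow(homologs)))

  levels_out <- NULL
  enrich_out <- NULL
  if (!is.null(config$gene_sets)) {
    gene_sets <- read_gene_sets(config$gene_sets)
    seed_genes <- unique(c(homologs$gene))
    if (length(seed_genes)) {
      assignment <- assign_pathway_levels(gene_sets, seed_genes,
                                          max_level = config$max_level)
      if (nrow(assignment$genes)) {
        levels_out <- summarize_levels(assignment, de,
                                       max_level = config$max_level)
        readr::write_tsv(render_level_summary(levels_out),
                         file.path(config$out_dir, "level_summary.tsv"),
                         progress = FALSE)
      }
    } else {
      log_lines <- c(log_lines, "no homolog seeds; pathway levels skipped")
    }
    deg_genes <- de$gene[de$change_class == "significant_deg"]
    universe <- if (config$universe == "tested") de$gene else transcripts$id
    enrich_out <- enrich(deg_genes, universe, gene_sets)
    readr::write_tsv(enrich_out, file.path(config$out_dir, "enrichment.tsv"),
                     progress = FALSE)
  }

  ent <- compare_group_entropy(cm$counts, cm$groups)
  readr::write_tsv(ent$samples, file.path(config$out_dir, "entropy.tsv"),
                   progress = FALSE)
  log_lines <- c(log_lines,
                 sprintf("entropy comparison: t = %.4f, p = %.4g",
                         ent$t_statistic, ent$pvalue))

  summary <- list(n_genes = nrow(transcripts), n_tested = nrow(de),
                  n_deg = n_deg,
                  n_matched = sum(bins$total_genes),
                  n_homolog_hits = nrow(homologs),
                  match_fc_rho = corr$rho,
                  entropy_p = ent$pvalue)
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  log_lines <- c(log_lines,
                 sprintf("elapsed: %.1f s",
                         as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  writeLines(log_lines, file.path(config$out_dir, "run.log"))

  invisible(list(scan = scan, de = de, bins = bins, correlation = corr,
                 homologs = homologs, levels = levels_out,
                 enrichment = enrich_out, entropy = ent,
                 summary = summary, out_dir = config$out_dir))
}
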