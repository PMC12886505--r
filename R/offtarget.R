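# Off-target scanning: longest contiguous exact match between each
# transcript and either strand of the dsRNA, match-length binning, and the
# match-length vs fold-change correlation.
#
# A dsRNA is processed into siRNAs from both strands, so by default both
# the sense sequence and its reverse complement are scanned; contiguous
# identity to either is the off-target surface.

#' Reverse complement of a DNA sequence
#'
#' N is carried through unchanged (it complements to itself as an unknown
#' base placeholder).
#'
#' @param sequence character vector over `{A, C, G, T, N}`.
#' @return character vector of reverse complements.
#' @export
reverse_complement <- function(sequence) {
  bad <- grepl("[^ACGTN]", sequence)
  if (any(bad)) abort("invalid character(s) outside {A,C,G,T,N}")
  out <- chartr("ACGT", "TGCA", sequence)
  vapply(strsplit(out, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

#' Longest contiguous exact match between two sequences
#'
#' Longest common substring over `{A, C, G, T}`; windows containing N are
#' excluded from matching. Positions of every maximal occurrence are
#' returned 0-based.
#'
#' @param query,subject DNA strings.
#' @return list with `length` (integer) and `positions` (tibble
#'   `query_start`, `subject_start`, 0-based starts of the maximal match).
#' @export
longest_contiguous_match <- function(query, subject) {
  stopifnot(is_string(query), is_string(subject), nzchar(query), nzchar(subject))
  if (grepl("[^ACGTN]", query) || grepl("[^ACGTN]", subject)) {
    abort("invalid character(s) outside {A,C,G,T,N}")
  }
  res <- cpp_longest_match(query, subject)
  pos <- res$positions
  list(length = res$length,
       positions = tibble(query_start = pos[, 1], subject_start = pos[, 2]))
}

#' Scan a transcriptome for contiguous matches with a dsRNA
#'
#' For every transcript, computes the maximal contiguous exact match with
#' the dsRNA sense sequence and (unless `strands = "sense"`) its reverse
#' complement. Genes below `min_report_len` are flagged, not dropped.
#'
#' @param transcripts sequence tibble (`id`, `sequence`).
#' @param dsrna single dsRNA sequence (string, or one-row sequence tibble).
#' @param min_report_len matches at least this long count as reportable
#'   (default 7 bp, the shortest contiguous identity observed to trigger
#'   silencing).
#' @param strands scan `"both"` dsRNA strands (default) or `"sense"` only.
#' @return tibble of class `match_scan`: `gene`, `max_match_sense`,
#'   `max_match_antisense`, `max_match`, `n_positions`, `below_threshold`,
#'   and a list-column `positions` of tibbles
#'   (`transcript_start`, `dsrna_start`, `strand`), 0-based.
#' @export
scan_transcriptome <- function(transcripts, dsrna, min_report_len = 7,
                               strands = c("both", "sense")) {
  strands <- match.arg(strands)
  transcripts <- as_sequences(transcripts)
  if (nrow(transcripts) == 0) abort("empty transcriptome")
  if (is.data.frame(dsrna)) {
    stopifnot(nrow(dsrna) == 1)
    dsrna <- dsrna$sequence
  }
  stopifnot(is_string(dsrna))
  if (nchar(dsrna) < min_report_len) {
    abort("dsRNA shorter than min_report_len")
  }
  ds_rc <- reverse_complement(dsrna)

  rows <- purrr::map(seq_len(nrow(transcripts)), function(i) {
    tx <- transcripts$sequence[i]
    sense <- cpp_longest_match(tx, dsrna)
    anti <- if (strands == "both") cpp_longest_match(tx, ds_rc) else list(length = 0L, positions = matrix(integer(), 0, 2))
    mm <- max(sense$length, anti$length)
    pos <- list(
      if (sense$length == mm && mm > 0) tibble(
        transcript_start = sense$positions[, 1],
        dsrna_start = sense$positions[, 2], strand = "sense"),
      if (strands == "both" && anti$length == mm && mm > 0) tibble(
        transcript_start = anti$positions[, 1],
        dsrna_start = anti$positions[, 2], strand = "antisense")
    )
    pos <- dplyr::bind_rows(pos[!vapply(pos, is.null, logical(1))])
    if (nrow(pos) == 0) pos <- tibble(transcript_start = integer(),
                                      dsrna_start = integer(),
                                      strand = character())
    tibble(gene = transcripts$id[i],
           max_match_sense = sense$length,
           max_match_antisense = anti$length,
           max_match = mm,
           n_positions = nrow(pos),
           below_threshold = mm < min_report_len,
           positions = list(pos))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("match_scan", class(out))
  attr(out, "min_report_len") <- min_report_len
  out
}

#' Bin genes by maximal contiguous match length
#'
#' Each gene whose maximal match reaches the reporting threshold lands in
#' exactly one bin equal to its match length; the last bin is open-ended
#' (`15` means 15 bp or more). Direction comes from the DE table: up =
#' significant DEG with positive log2 fold change, down = significant DEG
#' with negative log2 fold change, everything else (including genes absent
#' from the DE table, e.g. filtered upstream for low counts) is unchanged.
#'
#' @param results `match_scan` tibble from [scan_transcriptome()].
#' @param de_table DE tibble with `gene`, `log2fc`, `change_class`.
#' @param bins integer bin labels; the last is open-ended.
#' @return tibble of class `match_summary`: `bin`, `total_genes`, `n_up`,
#'   `n_down`, `n_unchanged`, `pct_up`, `pct_down`, `pct_unchanged`
#'   (numeric, rounded half-up to 2 decimals; NA for empty bins).
#' @export
bin_by_match_length <- function(results, de_table, bins = 7:15) {
  stopifnot(all(c("gene", "max_match") %in% names(results)))
  min_bin <- min(bins); max_bin <- max(bins)
  kept <- results[results$max_match >= min_bin, c("gene", "max_match")]
  de <- de_table[, c("gene", "log2fc", "change_class")]
  kept <- dplyr::left_join(kept, de, by = "gene")
  n_missing <- sum(is.na(kept$change_class))
  if (n_missing > 0) {
    inform(sprintf("%d gene(s) with a reportable match are absent from the DE table; counted as unchanged",
                   n_missing))
  }
  kept$direction <- dplyr::case_when(
    !is.na(kept$change_class) & kept$change_class == "significant_deg" & kept$log2fc > 0 ~ "up",
    !is.na(kept$change_class) & kept$change_class == "significant_deg" & kept$log2fc < 0 ~ "down",
    TRUE ~ "unchanged"
  )
  kept$bin <- pmin(kept$max_match, max_bin)
  counts <- purrr::map_dfr(bins, function(b) {
    sub <- kept[kept$bin == b, ]
    tibble(bin = b,
           total_genes = nrow(sub),
           n_up = sum(sub$direction == "up"),
           n_down = sum(sub$direction == "down"),
           n_unchanged = sum(sub$direction == "unchanged"))
  })
  out <- add_summary_percentages(counts)
  class(out) <- c("match_summary", class(out))
  attr(out, "n_missing_de") <- n_missing
  out
}

# add pct_* columns (numeric, half-up 2 dp, NA when total is 0)
add_summary_percentages <- function(counts) {
  pct <- function(n, tot) ifelse(tot > 0, round_half_up(100 * n / tot, 2), NA_real_)
  counts$pct_up <- pct(counts$n_up, counts$total_genes)
  counts$pct_down <- pct(counts$n_down, counts$total_genes)
  counts$pct_unchanged <- pct(counts$n_unchanged, counts$total_genes)
  counts
}

#' Render a match-length summary with formatted percentages
#'
#' Takes per-bin counts (columns `bin`, `total_genes`, `n_up`, `n_down`,
#' `n_unchanged`; `n_unchanged` is derived when absent) and renders the
#' printed report shape: counts with percentages in parentheses, empty
#' bins as en dashes.
#'
#' @param counts per-bin count tibble.
#' @param legacy use the mixed percentage style (whole numbers without
#'   decimals, e.g. `"0%"`, `"100%"`).
#' @return tibble with character columns `bin`, `total_genes`, `up`,
#'   `down`, `unchanged`.
#' @export
render_match_summary <- function(counts, legacy = TRUE) {
  counts <- complete_summary_counts(counts)
  cell <- function(n, tot) {
    ifelse(tot == 0, "–",
           sprintf("%d (%s)", n, format_percent(n, tot, legacy = legacy)))
  }
  tibble(bin = as.character(counts$bin),
         total_genes = as.character(counts$total_genes),
         up = cell(counts$n_up, counts$total_genes),
         down = cell(counts$n_down, counts$total_genes),
         unchanged = cell(counts$n_unchanged, counts$total_genes))
}

complete_summary_counts <- function(counts) {
  counts <- as_tibble(counts)
  if (!"n_unchanged" %in% names(counts)) {
    counts$n_unchanged <- counts$total_genes - counts$n_up - counts$n_down
  }
  bad <- counts$n_up + counts$n_down + counts$n_unchanged != counts$total_genes
  if (any(bad)) abort("bin counts do not sum to the bin total")
  counts
}

#' Correlate contiguous match length with expression change
#'
#' Spearman rank correlation between each matched gene's maximal
#' contiguous match length and the absolute log2 fold change, over genes
#' whose match reaches `min_len`. Each gene also receives the scatter-plot
#' colour class: red = significant (|log2FC| >= 1 and FDR <= 0.05),
#' blue = fold change without significance (|log2FC| >= 1, FDR >= 0.05),
#' gray = |log2FC| < 1.
#'
#' @param results `match_scan` tibble.
#' @param de_table DE tibble (`gene`, `log2fc`, `fdr`).
#' @param min_len minimal match length for inclusion (default 7).
#' @return list of class `match_correlation`: `genes` (tibble `gene`,
#'   `max_match`, `log2fc`, `abs_log2fc`, `color_class`), `rho`, `pvalue`,
#'   `n`, `tied` (TRUE when rho is undefined because one vector is
#'   constant; rho is then reported as 0).
#' @export
match_fold_change_correlation <- function(results, de_table, min_len = 7) {
  genes <- dplyr::inner_join(
    results[results$max_match >= min_len, c("gene", "max_match")],
    de_table[, c("gene", "log2fc", "fdr")], by = "gene")
  genes <- genes[complete.cases(genes[c("log2fc", "fdr")]), ]
  if (nrow(genes) < 3) abort("need >= 3 matched genes with fold changes")
  genes$abs_log2fc <- abs(genes$log2fc)
  genes$color_class <- dplyr::case_when(
    genes$abs_log2fc >= 1 & genes$fdr <= 0.05 ~ "red",
    genes$abs_log2fc >= 1 & genes$fdr >= 0.05 ~ "blue",
    TRUE ~ "gray"
  )
  tied <- sd(genes$abs_log2fc) == 0 || sd(genes$max_match) == 0
  if (tied) {
    rho <- 0; pval <- NA_real_
  } else {
    ct <- suppressWarnings(stats::cor.test(genes$max_match, genes$abs_log2fc,
                                           method = "spearman", exact = FALSE))
    rho <- unname(ct$estimate); pval <- ct$p.value
  }
  structure(list(genes = genes, rho = rho, pvalue = pval,
                 n = nrow(genes), tied = tied),
            class = "match_correlation")
}

#' @export
print.match_correlation <- function(x, ...) {
  cat(sprintf("Match-length vs |log2FC| correlation (n = %d genes)\n", x$n))
  if (x$tied) {
    cat("  rho = 0 (flagged: one variable constant, correlation undefined)\n")
  } else {
    cat(sprintf("  Spearman rho = %.3f, p = %.3g\n", x$rho, x$pvalue))
  }
  invisible(x)
}
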