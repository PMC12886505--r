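# Three-class DEG attribution: homologs of the target gene (local
# alignment with Karlin-Altschul E-values), KEGG pathway proximity levels
# built from shared-gene overlap between gene sets, and contiguous-match
# classes; plus the per-level summary table.

#' Smith-Waterman local alignment with affine gaps
#'
#' Optimal local alignment under blastn-style scoring (+2 match, -3
#' mismatch, gap existence 5, gap extension 2; a gap of length L costs
#' `gap_open + L * gap_extend`). N scores as a mismatch against every
#' base, including another N. Ties are broken deterministically by the
#' lowest query start, then lowest subject start.
#'
#' @param query,subject DNA strings over `{A, C, G, T, N}`.
#' @param match,mismatch,gap_open,gap_extend scoring parameters.
#' @return list: `score`, and `query_start`, `query_end`, `subject_start`,
#'   `subject_end` (0-based half-open; all 0 with an empty alignment when
#'   the best score is 0).
#' @export
smith_waterman <- function(query, subject, match = 2, mismatch = -3,
                           gap_open = 5, gap_extend = 2) {
  stopifnot(is_string(query), is_string(subject))
  if (!nzchar(query) || !nzchar(subject)) abort("empty sequence")
  if (grepl("[^ACGTN]", query) || grepl("[^ACGTN]", subject)) {
    abort("invalid character(s) outside {A,C,G,T,N}")
  }
  res <- cpp_smith_waterman(query, subject, match, mismatch, gap_open, gap_extend)
  list(score = res$score,
       query_start = res$query_start, query_end = res$query_end,
       subject_start = res$subject_start, subject_end = res$subject_end)
}

#' Karlin-Altschul E-value from a local alignment score
#'
#' `E = K * m * n * exp(-lambda * S)` with m the query length and n the
#' total database length. Defaults are the ungapped constants for the
#' blastn +2/-3 scoring scheme.
#'
#' @param score raw alignment score S.
#' @param query_len query length m (> 0).
#' @param db_len total database length n (> 0).
#' @param K,lambda_nat Karlin-Altschul parameters (lambda in nats per
#'   raw score unit).
#' @return expected number of chance alignments scoring >= S.
#' @export
evalue_from_score <- function(score, query_len, db_len,
                              K = 0.41, lambda_nat = 0.625) {
  if (query_len <= 0 || db_len <= 0) abort("lengths must be positive")
  K * query_len * db_len * exp(-lambda_nat * score)
}

#' Find homologs of a target gene in a transcriptome
#'
#' Aligns the target against both strands of every transcript with
#' [smith_waterman()], converts the best score per transcript to an
#' E-value against the whole transcriptome (n = total transcript length),
#' and returns hits below the threshold sorted by E-value.
#'
#' @param target target sequence (string or one-row sequence tibble).
#' @param transcriptome sequence tibble (`id`, `sequence`).
#' @param evalue_thresh report hits with E below this (default 1e-10).
#' @return tibble: `gene`, `score`, `evalue`, `strand`, `query_start`,
#'   `query_end`, `subject_start`, `subject_end` (0-based half-open,
#'   subject coordinates on the aligned strand).
#' @export
find_homologs <- function(target, transcriptome, evalue_thresh = 1e-10) {
  transcriptome <- as_sequences(transcriptome)
  if (nrow(transcriptome) == 0) abort("empty transcriptome")
  if (is.data.frame(target)) {
    stopifnot(nrow(target) == 1)
    target <- target$sequence
  }
  m <- nchar(target)
  db_len <- sum(nchar(transcriptome$sequence))

  rows <- purrr::map(seq_len(nrow(transcriptome)), function(i) {
    tx <- transcriptome$sequence[i]
    fwd <- cpp_smith_waterman(tx, target, 2, -3, 5, 2)
    rev <- cpp_smith_waterman(reverse_complement(tx), target, 2, -3, 5, 2)
    if (fwd$score >= rev$score) { best <- fwd; strand <- "sense" }
    else { best <- rev; strand <- "antisense" }
    tibble(gene = transcriptome$id[i],
           score = best$score,
           evalue = evalue_from_score(best$score, m, db_len),
           strand = strand,
           query_start = best$subject_start, query_end = best$subject_end,
           subject_start = best$query_start, subject_end = best$query_end)
  })
  hits <- dplyr::bind_rows(rows)
  hits <- hits[hits$evalue < evalue_thresh, ]
  hits[order(hits$evalue, hits$gene), ]
}

#' Assign pathway proximity levels from seed genes
#'
#' Level-1 gene sets contain at least one seed gene (the target's
#' homologs); level-(k+1) sets are the still-unassigned sets sharing at
#' least `min_overlap` genes with any level-k set (breadth-first, so every
#' set gets its minimal level). Genes take the minimum level over the sets
#' containing them; seed genes are excluded from gene-level assignments
#' (they are the cause of the proximity structure, not part of its
#' effect).
#'
#' @param gene_sets long tibble (`set`, `gene`).
#' @param seed_genes character vector of seed gene ids.
#' @param max_level deepest level to assign (default 3).
#' @param min_overlap minimum number of shared genes linking two sets.
#' @return list of class `pathway_levels`: `pathways` (tibble `set`,
#'   `level`; `NA` = unreached), `genes` (tibble `gene`, `level`),
#'   `seed_genes`.
#' @export
assign_pathway_levels <- function(gene_sets, seed_genes, max_level = 3,
                                  min_overlap = 1) {
  stopifnot(length(seed_genes) > 0)
  sets <- split(gene_sets$gene, factor(gene_sets$set, levels = unique(gene_sets$set)))
  sets <- lapply(sets, unique)
  set_names <- names(sets)
  level <- setNames(rep(NA_integer_, length(sets)), set_names)

  frontier <- set_names[vapply(sets, function(g) any(g %in% seed_genes), logical(1))]
  if (!length(frontier)) {
    warn("no gene set contains a seed gene; empty level assignment")
  }
  level[frontier] <- 1L
  k <- 1L
  while (length(frontier) && k < max_level) {
    unassigned <- set_names[is.na(level)]
    nxt <- unassigned[vapply(sets[unassigned], function(g) {
      any(vapply(sets[frontier], function(f) sum(g %in% f) >= min_overlap,
                 logical(1)))
    }, logical(1))]
    level[nxt] <- k + 1L
    frontier <- nxt
    k <- k + 1L
  }

  gene_level <- gene_sets
  gene_level$level <- level[gene_level$set]
  gene_level <- gene_level[!is.na(gene_level$level) &
                             !(gene_level$gene %in% seed_genes), ]
  genes <- if (nrow(gene_level) == 0) {
    tibble(gene = character(), level = integer())
  } else {
    dplyr::summarise(dplyr::group_by(gene_level, .data$gene),
                     level = min(.data$level), .groups = "drop")
  }

  structure(list(pathways = tibble(set = set_names, level = unname(level)),
                 genes = genes,
                 seed_genes = unique(seed_genes)),
            class = "pathway_levels")
}

#' Per-level expression summary
#'
#' Counts each assigned gene once, at its minimum level, with direction
#' from the DE table (up/down = significant DEG by sign of log2FC,
#' everything else unchanged, including genes absent from the table), and
#' appends a Total row summing the levels.
#'
#' @param assignment `pathway_levels` from [assign_pathway_levels()].
#' @param de_table DE tibble (`gene`, `log2fc`, `change_class`).
#' @param max_level levels reported individually (default 3).
#' @return tibble of class `level_summary`: `level` (`"1"`..`"3"`,
#'   `"Total"`), `total_genes`, `n_up`, `n_down`, `n_unchanged`, and
#'   numeric `pct_*` columns (half-up, 2 decimals).
#' @export
summarize_levels <- function(assignment, de_table, max_level = 3) {
  genes <- assignment$genes
  if (nrow(genes) == 0) abort("empty level assignment")
  genes <- dplyr::left_join(genes, de_table[, c("gene", "log2fc", "change_class")],
                            by = "gene")
  genes$direction <- dplyr::case_when(
    !is.na(genes$change_class) & genes$change_class == "significant_deg" & genes$log2fc > 0 ~ "up",
    !is.na(genes$change_class) & genes$change_class == "significant_deg" & genes$log2fc < 0 ~ "down",
    TRUE ~ "unchanged"
  )
  counts <- purrr::map_dfr(seq_len(max_level), function(k) {
    sub <- genes[genes$level == k, ]
    tibble(level = as.character(k),
           total_genes = nrow(sub),
           n_up = sum(sub$direction == "up"),
           n_down = sum(sub$direction == "down"),
           n_unchanged = sum(sub$direction == "unchanged"))
  })
  out <- add_level_total(counts)
  class(out) <- c("level_summary", class(out))
  out
}

# append the Total row and percentage columns to per-level counts
add_level_total <- function(counts) {
  counts$level <- as.character(counts$level)
  total <- tibble(level = "Total",
                  total_genes = sum(counts$total_genes),
                  n_up = sum(counts$n_up),
                  n_down = sum(counts$n_down),
                  n_unchanged = sum(counts$n_unchanged))
  add_summary_percentages(dplyr::bind_rows(counts, total))
}

#' Render a per-level summary with formatted percentages
#'
#' Takes per-level counts (`level`, `total_genes`, `n_up`, `n_down`,
#' `n_unchanged`; unchanged derived when absent), appends the Total row
#' when not present, and renders counts with percentages in parentheses.
#'
#' @param counts per-level count tibble.
#' @param legacy use the mixed whole-number percentage style.
#' @return tibble with character columns `level`, `total_genes`, `up`,
#'   `down`, `unchanged`.
#' @export
render_level_summary <- function(counts, legacy = FALSE) {
  counts <- complete_summary_counts(counts)
  if (!"Total" %in% counts$level) counts <- add_level_total(counts)
  cell <- function(n, tot) {
    ifelse(tot == 0, "–",
           sprintf("%d (%s)", n, format_percent(n, tot, legacy = legacy)))
  }
  tibble(level = as.character(counts$level),
         total_genes = as.character(counts$total_genes),
         up = cell(counts$n_up, counts$total_genes),
         down = cell(counts$n_down, counts$total_genes),
         unchanged = cell(counts$n_unchanged, counts$total_genes))
}

#' Attribute DEGs to homology, pathway-proximity and match classes
#'
#' Labels each DEG with every class that applies: `homolog_of_target`
#' (present in the homolog hit list), `pathway_level_k` (assigned level
#' k), `continuous_match_k` (maximal contiguous match of k bp, k >=
#' `min_match_len`). Classes are non-exclusive; DEGs matching nothing fall
#' into the unattributed bucket.
#'
#' @param de_table DE tibble; rows with `change_class == "significant_deg"`
#'   are the DEGs.
#' @param homolog_hits tibble from [find_homologs()] (or NULL).
#' @param assignment `pathway_levels` (or NULL).
#' @param match_results `match_scan` tibble (or NULL).
#' @param min_match_len minimal contiguous match for the match class.
#' @return list of class `deg_classes`: `genes` (tibble `gene`, `log2fc`,
#'   `labels` list-column, `unattributed`), `class_counts` (tibble
#'   `label`, `n`), `n_deg`, `n_unattributed`.
#' @export
classify_degs <- function(de_table, homolog_hits = NULL, assignment = NULL,
                          match_results = NULL, min_match_len = 7) {
  degs <- de_table[de_table$change_class == "significant_deg", c("gene", "log2fc")]
  labels <- purrr::map(degs$gene, function(g) {
    lab <- character()
    if (!is.null(homolog_hits) && g %in% homolog_hits$gene) {
      lab <- c(lab, "homolog_of_target")
    }
    if (!is.null(assignment)) {
      lev <- assignment$genes$level[assignment$genes$gene == g]
      if (length(lev)) lab <- c(lab, sprintf("pathway_level_%d", lev))
    }
    if (!is.null(match_results)) {
      mm <- match_results$max_match[match_results$gene == g]
      if (length(mm) && mm >= min_match_len) {
        lab <- c(lab, sprintf("continuous_match_%d", mm))
      }
    }
    lab
  })
  genes <- tibble(gene = degs$gene, log2fc = degs$log2fc,
                  labels = labels,
                  unattributed = lengths(labels) == 0)
  all_labels <- unlist(labels, use.names = FALSE)
  class_counts <- if (length(all_labels)) {
    dplyr::count(tibble(label = all_labels), .data$label, name = "n")
  } else {
    tibble(label = character(), n = integer())
  }
  structure(list(genes = genes, class_counts = class_counts,
                 n_deg = nrow(genes),
                 n_unattributed = sum(genes$unattributed)),
            class = "deg_classes")
}

#' @export
print.deg_classes <- function(x, ...) {
  cat(sprintf("DEG attribution: %d DEGs, %d unattributed\n",
              x$n_deg, x$n_unattributed))
  print(x$class_counts)
  invisible(x)
}
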