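# Readers and writers for the external formats the pipeline touches.
#
# In-memory conventions (all tibbles, so every stage chains with the pipe):
#   sequences : tibble(id, sequence)           -- DNA over {A,C,G,T,N}
#   counts    : tibble(gene, <one col/sample>) -- non-negative integers
#   groups    : tibble(sample, group)
#   gene sets : tibble(set, gene)              -- long format
#   DE table  : tibble(gene, base_mean, log2fc, pvalue, fdr, change_class)

#' Read a FASTA file into a sequence table
#'
#' Sequences are uppercased and U is mapped to T so RNA input is accepted;
#' any character outside `{A, C, G, T, N}` is rejected. Record ids must be
#' unique and sequences non-empty.
#'
#' @param path FASTA file.
#' @return tibble with columns `id` and `sequence`.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  seqs <- chartr("U", "T", seqs)
  names(seqs) <- NULL
  as_sequences(tibble(id = ids, sequence = seqs))
}

#' Validate a sequence table
#'
#' @param x tibble (or data frame) with columns `id` and `sequence`.
#' @return the validated tibble.
#' @export
as_sequences <- function(x) {
  x <- as_tibble(x)
  stopifnot(all(c("id", "sequence") %in% names(x)))
  if (anyDuplicated(x$id)) {
    dup <- unique(x$id[duplicated(x$id)])
    abort(sprintf("duplicate sequence id(s): %s",
                  paste(head(dup, 5), collapse = ", ")))
  }
  if (any(!nzchar(x$id)) || any(is.na(x$id))) abort("empty sequence id")
  if (any(nchar(x$sequence) < 1)) {
    abort(sprintf("empty sequence for id(s): %s",
                  paste(head(x$id[nchar(x$sequence) < 1], 5), collapse = ", ")))
  }
  bad <- grepl("[^ACGTN]", x$sequence)
  if (any(bad)) {
    abort(sprintf("invalid character(s) outside {A,C,G,T,N} in sequence(s): %s",
                  paste(head(x$id[bad], 5), collapse = ", ")))
  }
  x[, c("id", "sequence")]
}

#' Write a sequence table to FASTA
#'
#' @param x sequence tibble (`id`, `sequence`).
#' @param path output file.
#' @param width line width for wrapped sequence lines.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70) {
  x <- as_sequences(x)
  set <- Biostrings::BStringSet(setNames(x$sequence, x$id))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a gene-by-sample count matrix from TSV
#'
#' The file must carry a header row of sample ids with gene ids in the
#' first column. Counts must parse as non-negative integers; a violation is
#' reported with its gene and sample location. Every sample must be covered
#' by `groups`.
#'
#' @param path TSV file.
#' @param groups tibble(sample, group) or a named character vector
#'   (names = samples, values = group labels).
#' @return list with elements `counts` (tibble, `gene` + sample columns)
#'   and `groups` (tibble `sample`, `group`).
#' @export
read_counts <- function(path, groups) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (ncol(raw) < 3) abort("count matrix needs a gene column and >= 2 samples")
  names(raw)[1] <- "gene"
  counts <- parse_count_columns(raw)
  groups <- as_group_table(groups)
  validate_counts(counts, groups)
  list(counts = counts, groups = groups)
}

parse_count_columns <- function(raw) {
  out <- raw["gene"]
  for (s in setdiff(names(raw), "gene")) {
    v <- raw[[s]]
    num <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(num) | num < 0 | num != floor(num))
    if (length(bad)) {
      abort(sprintf("count for gene '%s', sample '%s' is '%s' (must be a non-negative integer)",
                    raw$gene[bad[1]], s, v[bad[1]]))
    }
    out[[s]] <- as.integer(num)
  }
  as_tibble(out)
}

#' @rdname read_counts
#' @param x groups given as a tibble or named vector.
#' @export
as_group_table <- function(x) {
  if (is.character(x) && !is.null(names(x))) {
    x <- tibble(sample = names(x), group = unname(x))
  }
  x <- as_tibble(x)
  stopifnot(all(c("sample", "group") %in% names(x)))
  if (anyDuplicated(x$sample)) abort("duplicate sample in group table")
  x[, c("sample", "group")]
}

validate_counts <- function(counts, groups = NULL) {
  stopifnot("gene" %in% names(counts))
  samples <- setdiff(names(counts), "gene")
  if (length(samples) < 2) abort("need >= 2 samples")
  if (nrow(counts) < 1) abort("need >= 1 gene")
  if (anyDuplicated(counts$gene)) abort("duplicate gene ids in count matrix")
  mat <- as.matrix(counts[samples])
  if (any(mat < 0)) abort("negative counts")
  if (any(mat != floor(mat))) abort("non-integer counts")
  if (!is.null(groups)) {
    missing <- setdiff(samples, groups$sample)
    if (length(missing)) {
      abort(sprintf("sample(s) without a group label: %s",
                    paste(missing, collapse = ", ")))
    }
  }
  invisible(counts)
}

#' Write a count table to TSV
#'
#' @param counts tibble (`gene` + sample columns).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  readr::write_tsv(counts, path, progress = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, fields `name`, `description`, then
#' member genes, tab-separated. The description is discarded and members
#' are deduplicated. A line with fewer than three fields is an error.
#'
#' @param path GMT file.
#' @return long tibble with columns `set` and `gene`.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) abort("empty GMT file")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    abort(sprintf("GMT line %d has %d field(s); need name, description and >= 1 gene",
                  which(nf < 3)[1], nf[which(nf < 3)[1]]))
  }
  names_ <- vapply(fields, `[[`, character(1), 1)
  if (anyDuplicated(names_)) {
    abort(sprintf("duplicate gene-set name(s): %s",
                  paste(unique(names_[duplicated(names_)]), collapse = ", ")))
  }
  out <- purrr::map2_dfr(names_, fields, function(nm, f) {
    tibble(set = nm, gene = unique(f[-(1:2)]))
  })
  out
}

#' Write gene sets to a GMT file
#'
#' @param gene_sets long tibble (`set`, `gene`).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(gene_sets, path) {
  stopifnot(all(c("set", "gene") %in% names(gene_sets)))
  sets <- split(gene_sets$gene, factor(gene_sets$set, levels = unique(gene_sets$set)))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "na", unique(sets[[nm]])), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a differential-expression table from TSV
#'
#' The file must have columns `gene`, `log2fc`, `pvalue`, `fdr` (a
#' `base_mean` column is kept when present). The three-tier change class is
#' always recomputed from the thresholds, never trusted from the file.
#'
#' @param path TSV file.
#' @param lfc_thresh,fdr_thresh thresholds passed to [classify_changes()].
#' @param boundary `"strict"` or `"inclusive"`; see [classify_changes()].
#' @return tibble `gene`, (`base_mean`), `log2fc`, `pvalue`, `fdr`,
#'   `change_class`.
#' @export
read_de_table <- function(path, lfc_thresh = 1, fdr_thresh = 0.05,
                          boundary = c("strict", "inclusive")) {
  tab <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  needed <- c("gene", "log2fc", "pvalue", "fdr")
  missing <- setdiff(needed, names(tab))
  if (length(missing)) {
    abort(sprintf("DE table is missing column(s): %s", paste(missing, collapse = ", ")))
  }
  for (col in c("pvalue", "fdr")) {
    v <- tab[[col]]
    if (any(is.na(v)) || any(v < 0 | v > 1)) {
      abort(sprintf("column '%s' has values outside [0, 1]", col))
    }
  }
  keep <- intersect(c("gene", "base_mean", "log2fc", "pvalue", "fdr"), names(tab))
  classify_changes(as_tibble(tab[keep]), lfc_thresh = lfc_thresh,
                   fdr_thresh = fdr_thresh, boundary = boundary)
}

#' Write a differential-expression table to TSV
#'
#' @param de_table DE tibble.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_de_table <- function(de_table, path) {
  readr::write_tsv(de_table, path, progress = FALSE)
  invisible(path)
}
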