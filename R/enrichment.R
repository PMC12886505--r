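# Hypergeometric over-representation of gene sets among DEGs, with
# Benjamini-Hochberg correction across the tested sets.

#' Upper-tail hypergeometric p-value
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): k DEGs observed in a set of
#' K universe genes, with n DEGs drawn from a universe of N. The observed
#' k is included in the tail (the standard over-representation
#' convention).
#'
#' @param k DEGs in the set.
#' @param K universe genes in the set.
#' @param n number of DEGs.
#' @param N universe size.
#' @return exact upper-tail probability.
#' @export
hypergeom_pvalue <- function(k, K, n, N) {
  ok <- k >= 0 & K >= 0 & n >= 0 & N >= 1 & k <= pmin(K, n) & K <= N & n <= N
  if (!all(ok)) abort("inconsistent hypergeometric arguments (need 0 <= k <= min(K, n), K <= N, n <= N)")
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Gene-set over-representation among DEGs
#'
#' One upper-tail hypergeometric test per gene set (sets intersected with
#' the universe; sets smaller than `min_set_size` after intersection are
#' skipped with a message), BH correction across the tested sets, sorted
#' by p-value.
#'
#' @param deg_genes character vector of DEG ids (must lie in `universe`).
#' @param universe character vector of background gene ids.
#' @param gene_sets long tibble (`set`, `gene`).
#' @param min_set_size smallest in-universe set tested (default 3).
#' @return tibble of class `enrichment_result`: `set`, `k`, `K`, `n`, `N`,
#'   `fold_enrichment`, `pvalue`, `fdr`.
#' @export
enrich <- function(deg_genes, universe, gene_sets, min_set_size = 3) {
  deg_genes <- unique(deg_genes)
  universe <- unique(universe)
  outside <- setdiff(deg_genes, universe)
  if (length(outside)) {
    abort(sprintf("DEG(s) outside the universe: %s",
                  paste(head(outside, 10), collapse = ", ")))
  }
  N <- length(universe)
  n <- length(deg_genes)
  sets <- split(gene_sets$gene, factor(gene_sets$set, levels = unique(gene_sets$set)))
  rows <- purrr::imap(sets, function(members, nm) {
    in_univ <- intersect(unique(members), universe)
    K <- length(in_univ)
    if (K < min_set_size) return(NULL)
    k <- length(intersect(in_univ, deg_genes))
    tibble(set = nm, k = k, K = K, n = n, N = N,
           fold_enrichment = if (n > 0 && K > 0) (k / n) / (K / N) else NA_real_,
           pvalue = hypergeom_pvalue(k, K, n, N))
  })
  skipped <- sum(vapply(rows, is.null, logical(1)))
  if (skipped > 0) {
    inform(sprintf("%d gene set(s) below min_set_size after intersecting with the universe; skipped",
                   skipped))
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(set = character(), k = integer(), K = integer(),
                  n = integer(), N = integer(), fold_enrichment = double(),
                  pvalue = double(), fdr = double())
  } else {
    out$fdr <- bh_fdr(out$pvalue)
    out <- out[order(out$pvalue, out$set), ]
  }
  class(out) <- c("enrichment_result", class(out))
  out
}
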