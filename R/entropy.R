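# Shannon transcriptomic entropy: a scalar index of transcriptome
# homeostasis. Per sample, H = -sum p_i log2 p_i over the relative
# transcript abundances; the treatment/control comparison (not the
# absolute value, which depends on the log base and abundance unit) is
# what carries a risk-assessment conclusion.

#' Relative transcript abundances of one sample
#'
#' Normalizes a count column by a size factor and rescales to sum to 1.
#' The size factor cancels in the proportions and is accepted for
#' interface symmetry with length- or depth-aware workflows.
#'
#' @param counts_column non-negative numeric vector, not all zero.
#' @param size_factor positive scalar.
#' @return probability vector summing to 1 (zeros preserved).
#' @export
relative_abundance <- function(counts_column, size_factor = 1) {
  if (any(counts_column < 0)) abort("negative counts")
  if (all(counts_column == 0)) abort("all-zero sample column")
  stopifnot(size_factor > 0)
  norm <- counts_column / size_factor
  norm / sum(norm)
}

#' Shannon entropy of a probability vector
#'
#' `H = -sum_{p_i > 0} p_i log2(p_i)` (0 log 0 = 0). With
#' `base = exp(1)`, nats instead of bits.
#'
#' @param p probability vector (non-negative, sums to 1 within 1e-9).
#' @param base logarithm base (default 2 = bits).
#' @return entropy (non-negative scalar).
#' @export
shannon_entropy <- function(p, base = 2) {
  if (any(p < 0)) abort("negative probabilities")
  if (abs(sum(p) - 1) > 1e-9) abort("probabilities must sum to 1")
  p <- p[p > 0]
  -sum(p * log(p, base = base))
}

#' Compare transcriptome entropy between two groups
#'
#' Computes per-sample Shannon entropy on relative abundances, group
#' means with standard errors (sd / sqrt(n)), and a two-sided Student's
#' t-test between the groups. When both groups have zero variance the
#' comparison is flagged and p is reported as 1.
#'
#' @param counts count tibble (`gene` + sample columns).
#' @param groups tibble(sample, group) or named character vector; two
#'   groups with >= 2 replicates each.
#' @param base logarithm base (default 2 = bits).
#' @return list of class `entropy_result`: `samples` (tibble `sample`,
#'   `group`, `H`, `effective_gene_count`), `groups` (tibble `group`,
#'   `n`, `mean_H`, `se_H`), `t_statistic`, `pvalue`, `zero_variance`.
#' @export
compare_group_entropy <- function(counts, groups, base = 2) {
  groups <- as_group_table(groups)
  validate_counts(counts, groups)
  labels <- unique(groups$group)
  if (length(labels) != 2) abort("need exactly two groups")
  mat <- counts_matrix(counts)
  groups <- groups[match(colnames(mat), groups$sample), ]
  for (g in labels) {
    if (sum(groups$group == g) < 2) abort("each group needs >= 2 replicates")
  }
  H <- apply(mat, 2, function(col) shannon_entropy(relative_abundance(col), base = base))
  samples <- tibble(sample = colnames(mat), group = groups$group,
                    H = unname(H), effective_gene_count = base^unname(H))
  by_group <- dplyr::summarise(dplyr::group_by(samples, .data$group),
                               n = dplyr::n(),
                               mean_H = mean(.data$H),
                               se_H = sd(.data$H) / sqrt(dplyr::n()),
                               .groups = "drop")
  h1 <- samples$H[samples$group == labels[1]]
  h2 <- samples$H[samples$group == labels[2]]
  zero_var <- sd(h1) == 0 && sd(h2) == 0
  if (zero_var) {
    t_stat <- 0; pval <- 1
  } else {
    tt <- t.test(h1, h2, var.equal = TRUE)
    t_stat <- unname(tt$statistic); pval <- tt$p.value
  }
  structure(list(samples = samples, groups = by_group,
                 t_statistic = t_stat, pvalue = pval,
                 zero_variance = zero_var, base = base),
            class = "entropy_result")
}

#' @export
print.entropy_result <- function(x, ...) {
  cat("Shannon transcriptome entropy\n")
  print(x$groups)
  if (x$zero_variance) {
    cat("  zero variance in both groups; p reported as 1\n")
  } else {
    cat(sprintf("  Student's t = %.3f, p = %.3g\n", x$t_statistic, x$pvalue))
  }
  invisible(x)
}
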