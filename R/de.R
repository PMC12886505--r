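# Differential expression from a count matrix: median-of-ratios size
# factors, a negative-binomial Wald test with moment-based dispersion
# shrunk toward a mean-dispersion trend, Benjamini-Hochberg FDR, the
# three-tier change classification, and the 2^-ddCt qPCR helper.
#
# The NB test is deliberately simple (no MAP dispersion, no LFC shrinkage,
# no outlier filtering): the downstream attribution and thresholding are
# the point, and the test's accuracy is certified by planted-truth
# recovery and type-I-error simulations in the test suite.

counts_matrix <- function(counts) {
  samples <- setdiff(names(counts), "gene")
  mat <- as.matrix(counts[samples])
  rownames(mat) <- counts$gene
  storage.mode(mat) <- "double"
  mat
}

#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over genes (restricted to
#' genes with positive counts in every sample) of the ratio between the
#' sample's count and the gene's geometric mean across samples.
#'
#' @param counts count tibble (`gene` + sample columns).
#' @return tibble `sample`, `size_factor`.
#' @export
median_of_ratios <- function(counts) {
  validate_counts(counts)
  mat <- counts_matrix(counts)
  all_pos <- rowSums(mat > 0) == ncol(mat)
  if (!any(all_pos)) {
    abort(paste("no gene has positive counts in every sample;",
                "consider a pseudo-reference on nonzero genes upstream"))
  }
  log_geo <- rowMeans(log(mat[all_pos, , drop = FALSE]))
  sf <- apply(mat[all_pos, , drop = FALSE], 2, function(col) {
    exp(median(log(col) - log_geo))
  })
  tibble(sample = colnames(mat), size_factor = unname(sf))
}

#' Benjamini-Hochberg false discovery rates
#'
#' Standard step-up adjustment; order-preserving and capped at 1.
#'
#' @param pvalues numeric vector in \\[0, 1\\].
#' @return adjusted values (same order as input).
#' @export
bh_fdr <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(pvalues, method = "BH")
}

#' Negative-binomial Wald test for two-group differential expression
#'
#' Counts are normalized by median-of-ratios size factors; per gene, a
#' method-of-moments dispersion (floored at 1e-8) is blended 50/50 with a
#' fitted mean-dispersion trend, the log2 fold change uses a 0.5
#' pseudo-count, and a two-sided Wald p-value comes from a delta-method
#' standard error of the log2 fold change under the NB variance function.
#' FDR is Benjamini-Hochberg. Genes with identical counts everywhere (or
#' all zeros) report log2fc = 0, p = 1.
#'
#' @param counts count tibble (`gene` + sample columns).
#' @param groups tibble(sample, group) or named character vector; exactly
#'   two groups, each with >= 2 samples.
#' @param treatment,control group labels; by default the first and second
#'   distinct labels in `groups`.
#' @param lfc_thresh,fdr_thresh,boundary passed to [classify_changes()].
#' @return tibble of class `de_result`: `gene`, `base_mean`, `log2fc`,
#'   `pvalue`, `fdr`, `change_class`.
#' @export
nb_wald_test <- function(counts, groups, treatment = NULL, control = NULL,
                         lfc_thresh = 1, fdr_thresh = 0.05,
                         boundary = c("strict", "inclusive")) {
  groups <- as_group_table(groups)
  validate_counts(counts, groups)
  labels <- unique(groups$group)
  if (length(labels) != 2) abort("need exactly two groups")
  treatment <- treatment %||% labels[1]
  control <- control %||% labels[2]
  stopifnot(all(c(treatment, control) %in% labels))

  mat <- counts_matrix(counts)
  groups <- groups[match(colnames(mat), groups$sample), ]
  t_cols <- which(groups$group == treatment)
  c_cols <- which(groups$group == control)
  if (length(t_cols) < 2 || length(c_cols) < 2) {
    abort("each group needs >= 2 samples")
  }

  sf <- median_of_ratios(counts)$size_factor
  norm <- sweep(mat, 2, sf, "/")

  mean_t <- rowMeans(norm[, t_cols, drop = FALSE])
  mean_c <- rowMeans(norm[, c_cols, drop = FALSE])
  base_mean <- rowMeans(norm)

  disp <- shrunken_dispersion(norm, t_cols, c_cols)

  log2fc <- log2((mean_t + 0.5) / (mean_c + 0.5))

  # delta method on log2 of the shifted group means:
  # Var(mean_g) = (1/n^2) sum_j (mu_g / sf_j + alpha mu_g^2) under NB
  var_mean <- function(mu, cols) {
    vm <- mu %o% (1 / sf[cols]) + disp * mu^2
    rowSums(vm) / length(cols)^2
  }
  v_t <- var_mean(mean_t, t_cols)
  v_c <- var_mean(mean_c, c_cols)
  se <- sqrt(v_t / (mean_t + 0.5)^2 + v_c / (mean_c + 0.5)^2) / log(2)

  z <- ifelse(se > 0, log2fc / se, 0)
  pvalue <- 2 * pnorm(-abs(z))

  # degenerate genes: identical counts in all samples carry no evidence
  flat <- apply(mat, 1, function(r) length(unique(r)) == 1)
  pvalue[flat] <- 1
  log2fc[flat & mean_t == mean_c] <- 0

  out <- tibble(gene = rownames(mat), base_mean = unname(base_mean),
                log2fc = unname(log2fc), pvalue = unname(pvalue),
                fdr = bh_fdr(unname(pvalue)))
  out <- classify_changes(out, lfc_thresh = lfc_thresh,
                          fdr_thresh = fdr_thresh, boundary = boundary)
  class(out) <- c("de_result", class(out))
  attr(out, "groups") <- c(treatment = treatment, control = control)
  attr(out, "size_factors") <- setNames(sf, colnames(mat))
  out
}

# method-of-moments dispersion per gene (pooled within groups), floored at
# 1e-8, blended 50/50 with a mean-dispersion trend alpha(mu) = a0 + a1/mu
shrunken_dispersion <- function(norm, t_cols, c_cols) {
  mom_group <- function(cols) {
    mu <- rowMeans(norm[, cols, drop = FALSE])
    s2 <- apply(norm[, cols, drop = FALSE], 1, var)
    ifelse(mu > 0, (s2 - mu) / mu^2, 0)
  }
  n_t <- length(t_cols); n_c <- length(c_cols)
  alpha_gene <- (mom_group(t_cols) * n_t + mom_group(c_cols) * n_c) / (n_t + n_c)
  alpha_gene <- pmax(alpha_gene, 1e-8)

  mu_all <- rowMeans(norm)
  use <- mu_all > 1 & alpha_gene > 1e-8 & alpha_gene < 10
  if (sum(use) >= 10) {
    fit <- lm(alpha_gene[use] ~ I(1 / mu_all[use]))
    a <- coef(fit)
    trend <- pmax(a[1] + a[2] / pmax(mu_all, 1e-8), 1e-8)
  } else {
    trend <- rep(max(median(alpha_gene), 1e-8), length(alpha_gene))
  }
  pmax(0.5 * alpha_gene + 0.5 * trend, 1e-8)
}

#' Three-tier change classification
#'
#' Default (strict) thresholds call a significant DEG at |log2FC| > 1 and
#' FDR < 0.05; `boundary = "inclusive"` switches to >= 1 and <= 0.05.
#' Genes with |log2FC| at or above the fold threshold but without
#' significance are `fold_only`; genes below the fold threshold are
#' `unchanged`.
#'
#' @param de_table tibble with `log2fc` and `fdr`.
#' @param lfc_thresh log2 fold-change threshold (default 1).
#' @param fdr_thresh FDR threshold (default 0.05).
#' @param boundary `"strict"` (>, <) or `"inclusive"` (>=, <=).
#' @return the table with a recomputed `change_class` column.
#' @export
classify_changes <- function(de_table, lfc_thresh = 1, fdr_thresh = 0.05,
                             boundary = c("strict", "inclusive")) {
  boundary <- match.arg(boundary)
  lfc <- abs(de_table$log2fc)
  sig <- if (boundary == "strict") {
    lfc > lfc_thresh & de_table$fdr < fdr_thresh
  } else {
    lfc >= lfc_thresh & de_table$fdr <= fdr_thresh
  }
  de_table$change_class <- dplyr::case_when(
    sig ~ "significant_deg",
    lfc >= lfc_thresh ~ "fold_only",
    TRUE ~ "unchanged"
  )
  de_table
}

#' Relative expression by the 2^-ddCt method
#'
#' Relative transcript level of a target gene in treated vs control
#' samples, each normalized by a reference gene's cycle threshold.
#'
#' @param ct_target_treated,ct_ref_treated,ct_target_control,ct_ref_control
#'   qPCR cycle thresholds (finite).
#' @return fold change `2^-((Ct_t,tr - Ct_ref,tr) - (Ct_t,ctl - Ct_ref,ctl))`.
#' @examples
#' ddct(25, 20, 24, 20) # 0.5
#' @export
ddct <- function(ct_target_treated, ct_ref_treated,
                 ct_target_control, ct_ref_control) {
  vals <- c(ct_target_treated, ct_ref_treated, ct_target_control, ct_ref_control)
  if (any(!is.finite(vals))) abort("Ct values must be finite")
  ddct <- (ct_target_treated - ct_ref_treated) -
    (ct_target_control - ct_ref_control)
  2^(-ddct)
}
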