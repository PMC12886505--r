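# broom-style tidiers for the package's result objects.

#' @describeIn nb_wald_test per-gene tibble (the result itself).
#' @param x a `de_result`.
#' @param ... ignored.
#' @method tidy de_result
#' @export
tidy.de_result <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "de_result")
  out
}

#' @describeIn nb_wald_test one-row tibble: gene, DEG and direction counts.
#' @method glance de_result
#' @export
glance.de_result <- function(x, ...) {
  sig <- x$change_class == "significant_deg"
  tibble(n_genes = nrow(x),
         n_deg = sum(sig),
         n_up = sum(sig & x$log2fc > 0),
         n_down = sum(sig & x$log2fc < 0),
         n_fold_only = sum(x$change_class == "fold_only"))
}

#' @describeIn compare_group_entropy per-sample entropy tibble.
#' @param x an `entropy_result`.
#' @param ... ignored.
#' @method tidy entropy_result
#' @export
tidy.entropy_result <- function(x, ...) x$samples

#' @describeIn compare_group_entropy one-row tibble with the group
#'   comparison.
#' @method glance entropy_result
#' @export
glance.entropy_result <- function(x, ...) {
  g <- x$groups
  tibble(mean_H_1 = g$mean_H[1], mean_H_2 = g$mean_H[2],
         se_H_1 = g$se_H[1], se_H_2 = g$se_H[2],
         t_statistic = x$t_statistic, pvalue = x$pvalue,
         zero_variance = x$zero_variance)
}

#' @describeIn match_fold_change_correlation per-gene tibble.
#' @param x a `match_correlation`.
#' @param ... ignored.
#' @method tidy match_correlation
#' @export
tidy.match_correlation <- function(x, ...) x$genes

#' @describeIn match_fold_change_correlation one-row tibble with rho and p.
#' @method glance match_correlation
#' @export
glance.match_correlation <- function(x, ...) {
  tibble(rho = x$rho, pvalue = x$pvalue, n = x$n, tied = x$tied)
}

#' @describeIn assign_pathway_levels per-gene level tibble.
#' @param x a `pathway_levels`.
#' @param ... ignored.
#' @method tidy pathway_levels
#' @export
tidy.pathway_levels <- function(x, ...) x$genes

#' @describeIn assign_pathway_levels one-row tibble with level counts.
#' @method glance pathway_levels
#' @export
glance.pathway_levels <- function(x, ...) {
  lv <- x$pathways$level
  tibble(n_pathways = length(lv),
         n_level1 = sum(lv == 1, na.rm = TRUE),
         n_level2 = sum(lv == 2, na.rm = TRUE),
         n_level3 = sum(lv == 3, na.rm = TRUE),
         n_unreached = sum(is.na(lv)),
         n_genes_assigned = nrow(x$genes))
}
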