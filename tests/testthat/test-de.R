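test_that("median-of-ratios recovers exact and planted depth factors", {
  counts <- tibble::tibble(gene = sprintf("g%d", 1:50),
                           a = as.integer(10 + 1:50),
                           b = as.integer(2 * (10 + 1:50)))
  sf <- median_of_ratios(counts)
  expect_equal(sf$size_factor[2] / sf$size_factor[1], 2, tolerance = 1e-12)

  same <- tibble::tibble(gene = c("g1", "g2"), a = c(5L, 9L), b = c(5L, 9L))
  expect_equal(median_of_ratios(same)$size_factor, c(1, 1))

  zero <- tibble::tibble(gene = c("g1", "g2"), a = c(0L, 3L), b = c(2L, 0L))
  expect_error(median_of_ratios(zero), "pseudo-reference")

  cfg <- simulation_config(seed = 21, n_genes = 3000, de_fraction = 0,
                           nb_dispersion = 0.05, mean_depth = 5e5,
                           n_replicates = 3,
                           depth_factors = c(0.5, 1, 2, 0.5, 1, 2))
  cnt <- generate_counts(cfg)
  sf <- median_of_ratios(cnt$counts)$size_factor
  sf <- sf / exp(mean(log(sf)))
  truth <- cnt$depth_factors / exp(mean(log(cnt$depth_factors)))
  expect_equal(sf, unname(truth), tolerance = 0.05)
})

test_that("BH step-up matches hand-derived values and its invariants", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(10)
  p <- stats::runif(100)
  fdr <- bh_fdr(p)
  expect_true(all(fdr >= p))
  expect_true(all(diff(fdr[order(p)]) >= -1e-15))
})

test_that("change classification follows strict and inclusive boundaries", {
  tab <- tibble::tibble(gene = c("a", "b", "c", "d"),
                        log2fc = c(2.0, 1.5, 0.3, 1.0),
                        pvalue = c(1e-3, 0.2, 1e-3, 1e-3),
                        fdr = c(0.01, 0.20, 0.001, 0.05))
  strict <- classify_changes(tab)
  expect_equal(strict$change_class,
               c("significant_deg", "fold_only", "unchanged", "fold_only"))
  incl <- classify_changes(tab, boundary = "inclusive")
  expect_equal(incl$change_class[4], "significant_deg")
})

test_that("NB Wald test handles degenerate genes and label swaps", {
  counts <- toy_counts()
  de <- nb_wald_test(counts, toy_groups())
  # g3 nearly flat and mostly zero, g4 strongly down in treatment
  expect_equal(de$change_class[de$gene == "g4"], "significant_deg")
  expect_lt(de$log2fc[de$gene == "g4"], -1)

  flat <- tibble::tibble(gene = c("flat", "zero"),
                         s1 = c(7L, 0L), s2 = c(7L, 0L), s3 = c(7L, 0L),
                         s4 = c(7L, 0L), s5 = c(7L, 0L), s6 = c(7L, 0L))
  de_flat <- nb_wald_test(flat, toy_groups())
  expect_equal(de_flat$log2fc, c(0, 0))
  expect_equal(de_flat$pvalue, c(1, 1))

  swapped <- nb_wald_test(counts, toy_groups(),
                          treatment = "control", control = "treatment")
  expect_equal(swapped$log2fc, -de$log2fc, tolerance = 1e-12)
  expect_equal(swapped$pvalue, de$pvalue, tolerance = 1e-12)

  one_group <- c(s1 = "g", s2 = "g", s3 = "g", s4 = "g", s5 = "g", s6 = "g")
  expect_error(nb_wald_test(counts, one_group), "two groups")
})

test_that("planted DEGs are recovered with controlled error", {
  stats <- vapply(1:10, function(s) {
    cfg <- simulation_config(seed = 100 + s, n_genes = 2000, de_fraction = 0.1,
                             de_log2fc_magnitude = 2, nb_dispersion = 0.05,
                             mean_depth = 1e6, n_replicates = 3)
    cnt <- generate_counts(cfg)
    de <- nb_wald_test(cnt$counts, cnt$groups)
    truth <- cnt$truth
    called <- de$gene[de$change_class == "significant_deg"]
    planted <- truth$gene[truth$is_de]
    c(recall = mean(planted %in% called),
      fdr = if (length(called)) mean(!called %in% planted) else 0)
  }, c(recall = 0, fdr = 0))
  expect_gte(mean(stats["recall", ]), 0.7)
  expect_lte(mean(stats["fdr", ]), 0.15)
})

test_that("type-I error under the NB null stays near nominal", {
  rates <- vapply(1:20, function(s) {
    cfg <- simulation_config(seed = 200 + s, n_genes = 2000, de_fraction = 0,
                             nb_dispersion = 0.1, mean_depth = 1e6)
    cnt <- generate_counts(cfg)
    de <- nb_wald_test(cnt$counts, cnt$groups)
    mean(de$pvalue < 0.05)
  }, numeric(1))
  expect_gte(mean(rates), 0.02)
  expect_lte(mean(rates), 0.09)
})

test_that("ddCt fold changes follow the closed form", {
  expect_equal(ddct(20, 20, 20, 20), 1.0)
  expect_equal(ddct(25, 20, 24, 20), 0.5)
  expect_equal(ddct(23, 20, 24, 20), 2.0)
  expect_error(ddct(Inf, 20, 20, 20), "finite")
})
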