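test_that("Smith-Waterman matches the exhaustive alignment oracle", {
  s <- smith_waterman("ACGTACGTAC", "ACGTACGTAC")
  expect_equal(s$score, 20)
  expect_equal(c(s$query_start, s$query_end), c(0, 10))

  s0 <- smith_waterman("AAAA", "TTTT")
  expect_equal(s0$score, 0)
  expect_equal(s0$query_end, 0) # empty alignment

  expect_error(smith_waterman("", "ACGT"), "empty")

  set.seed(17)
  for (i in 1:100) {
    a <- random_dna_str(sample(5:40, 1), alphabet = c("A", "C", "G", "T", "N"))
    b <- random_dna_str(sample(5:40, 1))
    expect_equal(smith_waterman(a, b)$score, sw_oracle(a, b), info = paste(a, b))
  }
})

test_that("Smith-Waterman score is symmetric in its arguments", {
  set.seed(23)
  for (i in 1:25) {
    a <- random_dna_str(sample(10:35, 1))
    b <- random_dna_str(sample(10:35, 1))
    expect_equal(smith_waterman(a, b)$score, smith_waterman(b, a)$score)
  }
})

test_that("E-values follow the Karlin-Altschul form", {
  m <- 400; n <- 1e7; K <- 0.41; lam <- 0.625
  s_unit <- log(K * m * n) / lam
  expect_equal(evalue_from_score(s_unit, m, n), 1.0, tolerance = 1e-12)
  expect_equal(evalue_from_score(80, m, 2 * n) / evalue_from_score(80, m, n), 2)
  expect_equal(evalue_from_score(100, 400, 1e7),
               0.41 * 400 * 1e7 * exp(-62.5))
  s <- seq(10, 200, by = 10)
  expect_true(all(diff(evalue_from_score(s, m, n)) < 0))
  expect_error(evalue_from_score(10, 0, n), "positive")
})

test_that("homolog search finds exact and mutated copies, not noise", {
  set.seed(31)
  target <- random_dna_str(403)
  tx <- tibble::tibble(
    id = c("exact", "noise1", "noise2"),
    sequence = c(target, random_dna_str(800), random_dna_str(600)))
  hits <- find_homologs(target, tx)
  expect_equal(hits$gene[1], "exact")
  expect_lt(hits$evalue[1], 1e-100)

  # planted homologs at 90% identity are recovered end to end
  cfg <- simulation_config(seed = 11, n_genes = 30,
                           transcript_length_range = c(500, 800),
                           planted_homologs = tibble::tibble(
                             gene_index = c(5, 12, 25),
                             identity = c(0.9, 0.9, 0.95)))
  sim <- generate_transcriptome(cfg)
  hits <- find_homologs(sim$dsrna, sim$transcripts)
  expect_setequal(hits$gene, c("gene00005", "gene00012", "gene00025"))
  expect_true(all(hits$evalue < 1e-10))
})

test_that("random transcriptomes yield no homolog hits at the threshold", {
  clean <- vapply(1:50, function(s) {
    set.seed(400 + s)
    target <- random_dna_str(403)
    tx <- tibble::tibble(id = sprintf("t%02d", 1:50),
                         sequence = vapply(rep(1000, 50),
                                           random_dna_str, character(1)))
    nrow(find_homologs(target, tx)) == 0
  }, logical(1))
  expect_gte(mean(clean), 0.95)
})

test_that("pathway levels follow breadth-first overlap from seeds", {
  chain <- tibble::tibble(set = c("P1", "P1", "P2", "P2", "P3", "P3"),
                          gene = c("a", "b", "b", "c", "c", "d"))
  asg <- assign_pathway_levels(chain, seed_genes = "a")
  expect_equal(asg$pathways$level[match(c("P1", "P2", "P3"), asg$pathways$set)],
               c(1L, 2L, 3L))
  expect_equal(asg$genes$level[asg$genes$gene == "c"], 2L)
  # seed gene is excluded from gene-level assignments
  expect_false("a" %in% asg$genes$gene)

  disconnected <- dplyr::bind_rows(chain,
                                   tibble::tibble(set = "P9", gene = c("x", "y")))
  asg2 <- assign_pathway_levels(disconnected, seed_genes = "a")
  expect_true(is.na(asg2$pathways$level[asg2$pathways$set == "P9"]))

  asg3 <- assign_pathway_levels(chain, seed_genes = c("a", "b", "c", "d"))
  expect_equal(asg3$pathways$level, c(1L, 1L, 1L))

  expect_warning(assign_pathway_levels(chain, seed_genes = "zzz"), "no gene set")
})

test_that("pathway levels are invariant to input order and take gene minima", {
  sets <- tibble::tibble(
    set = rep(c("A", "B", "C", "D"), times = c(3, 3, 3, 2)),
    gene = c("s", "g1", "g2", "g2", "g3", "g4", "g4", "g5", "shared",
             "shared", "g1"))
  base <- assign_pathway_levels(sets, seed_genes = "s")
  set.seed(5)
  for (i in 1:10) {
    perm <- sets[sample(nrow(sets)), ]
    shuf <- assign_pathway_levels(perm, seed_genes = "s")
    expect_equal(
      shuf$pathways$level[match(base$pathways$set, shuf$pathways$set)],
      base$pathways$level)
    merged <- dplyr::left_join(base$genes, shuf$genes, by = "gene")
    expect_equal(merged$level.x, merged$level.y)
  }
  # gene in both a level-1 and level-2 set sits at level 1
  lvl_sets <- tibble::tibble(set = c("L1", "L1", "L2", "L2"),
                             gene = c("s", "both", "both", "deep"))
  asg <- assign_pathway_levels(lvl_sets, seed_genes = "s")
  expect_equal(asg$genes$level[asg$genes$gene == "both"], 1L)
})

test_that("level summary counts each gene once with a consistent Total row", {
  asg <- list(genes = tibble::tibble(gene = c("g1", "g2", "g3", "g4", "g5"),
                                     level = c(1L, 1L, 2L, 2L, 3L)),
              seed_genes = "s")
  class(asg) <- "pathway_levels"
  de <- classify_changes(tibble::tibble(
    gene = c("g1", "g2", "g3", "g4"), # g5 untested -> unchanged
    log2fc = c(2, -2, 1.5, 0.1),
    pvalue = c(1e-4, 1e-4, 1e-4, 0.9),
    fdr = c(1e-3, 1e-3, 1e-3, 0.95)))
  summ <- summarize_levels(asg, de)
  expect_equal(summ$total_genes, c(2L, 2L, 1L, 5L))
  expect_equal(summ$n_up, c(1L, 1L, 0L, 2L))
  expect_equal(summ$n_down, c(1L, 0L, 0L, 1L))
  expect_equal(summ$n_unchanged, c(0L, 1L, 1L, 2L))
  expect_equal(summ$n_up + summ$n_down + summ$n_unchanged, summ$total_genes)
})

test_that("rendered level summary reproduces the published-style percentages", {
  counts <- readr::read_tsv(system.file("extdata", "kegg_level_counts.tsv",
                                        package = "rnaisafe"),
                            show_col_types = FALSE)
  nymph <- render_level_summary(counts[counts$transcriptome == "nymph",
                                       c("level", "total_genes", "n_up", "n_down", "n_unchanged")])
  expect_equal(nymph$up, c("17 (48.57%)", "47 (16.79%)", "23 (22.33%)", "87 (20.81%)"))
  expect_equal(nymph$down, c("18 (51.43%)", "40 (14.29%)", "22 (21.36%)", "80 (19.14%)"))
  expect_equal(nymph$unchanged, c("0 (0.00%)", "193 (68.93%)", "58 (56.31%)", "251 (60.05%)"))
  expect_equal(nymph$total_genes[4], "418")
})

test_that("DEG attribution applies non-exclusive labels", {
  de <- classify_changes(tibble::tibble(
    gene = c("d1", "d2", "d3", "u1"),
    log2fc = c(3, -2, 2, 0.1),
    pvalue = c(1e-5, 1e-5, 1e-5, 0.9),
    fdr = c(1e-4, 1e-4, 1e-4, 0.95)))
  hits <- tibble::tibble(gene = "d1")
  asg <- list(genes = tibble::tibble(gene = c("d1", "d2"), level = c(1L, 2L)),
              seed_genes = character())
  class(asg) <- "pathway_levels"
  matches <- tibble::tibble(gene = c("d1", "d3"), max_match = c(9L, 5L))
  res <- classify_degs(de, hits, asg, matches)
  expect_equal(res$n_deg, 3)
  d1 <- res$genes$labels[[which(res$genes$gene == "d1")]]
  expect_setequal(d1, c("homolog_of_target", "pathway_level_1", "continuous_match_9"))
  expect_true(res$genes$unattributed[res$genes$gene == "d3"]) # match below threshold
  expect_equal(res$n_unattributed, 1)
})
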