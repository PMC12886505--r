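test_that("reverse complement is an involution that fixes N", {
  expect_equal(reverse_complement("ACGT"), "ACGT")
  expect_equal(reverse_complement("AAAC"), "GTTT")
  expect_equal(reverse_complement("ANT"), "ANT")
  expect_error(reverse_complement("ACGX"), "invalid")
  set.seed(41)
  for (i in 1:20) {
    s <- random_dna_str(sample(5:60, 1), alphabet = c("A", "C", "G", "T", "N"))
    rc <- reverse_complement(s)
    expect_equal(nchar(rc), nchar(s))
    expect_equal(reverse_complement(rc), s)
  }
})

test_that("longest contiguous match agrees with the substring-set oracle", {
  expect_equal(longest_contiguous_match("ACGTACGT", "ACGTACGT")$length, 8)
  expect_equal(longest_contiguous_match("AAAA", "CCCC")$length, 0)
  # N never matches, even against N
  expect_equal(longest_contiguous_match("AANTT", "AANTT")$length, 2)

  set.seed(42)
  for (i in 1:200) {
    a <- random_dna_str(sample(5:50, 1), alphabet = c("A", "C", "G", "T", "N"))
    b <- random_dna_str(sample(5:50, 1))
    got <- longest_contiguous_match(a, b)
    expect_equal(got$length, lcs_oracle(a, b), info = paste(a, b))
    # every reported position re-verifies as an exact N-free match
    if (got$length > 0) {
      for (r in seq_len(nrow(got$positions))) {
        qa <- substr(a, got$positions$query_start[r] + 1,
                     got$positions$query_start[r] + got$length)
        sb <- substr(b, got$positions$subject_start[r] + 1,
                     got$positions$subject_start[r] + got$length)
        expect_identical(qa, sb)
        expect_false(grepl("N", qa, fixed = TRUE))
      }
    }
  }
})

test_that("scanning reports both strands and planted lengths exactly", {
  set.seed(7)
  ds <- random_dna_str(60)
  tx <- tibble::tibble(
    id = c("copy", "rc_copy"),
    sequence = c(ds, reverse_complement(ds)))
  scan <- scan_transcriptome(tx, ds)
  expect_equal(scan$max_match, c(60L, 60L))
  expect_equal(scan$positions[[1]]$strand[1], "sense")
  expect_equal(scan$positions[[2]]$strand[1], "antisense")

  cfg <- simulation_config(seed = 7, n_genes = 40,
                           transcript_length_range = c(200, 400),
                           dsrna_length = 60,
                           planted_matches = tibble::tibble(
                             gene_index = c(3, 10, 20),
                             match_length = c(7, 9, 12),
                             strand = c("sense", "antisense", "sense")))
  sim <- generate_transcriptome(cfg)
  scan <- scan_transcriptome(sim$transcripts, sim$dsrna)
  planted <- scan$max_match[match(c("gene00003", "gene00010", "gene00020"), scan$gene)]
  expect_identical(planted, c(7L, 9L, 12L))
  expect_true(all(scan$max_match[-c(3, 10, 20)] < 7))
  expect_error(scan_transcriptome(tx[0, ], ds), "empty")
})

test_that("strand swap of the transcriptome leaves max_match invariant", {
  cfg <- simulation_config(seed = 19, n_genes = 15,
                           transcript_length_range = c(100, 200),
                           dsrna_length = 50,
                           planted_matches = tibble::tibble(
                             gene_index = 4, match_length = 10, strand = "sense"))
  sim <- generate_transcriptome(cfg)
  fwd <- scan_transcriptome(sim$transcripts, sim$dsrna)
  flipped <- sim$transcripts
  flipped$sequence <- reverse_complement(flipped$sequence)
  rev <- scan_transcriptome(flipped, sim$dsrna)
  expect_equal(rev$max_match, fwd$max_match)
  expect_equal(rev$max_match_sense, fwd$max_match_antisense)
  expect_equal(rev$max_match_antisense, fwd$max_match_sense)
})

test_that("match-length bins partition the matched genes with conserved counts", {
  scan <- tibble::tibble(gene = sprintf("g%d", 1:8),
                         max_match = c(5L, 7L, 7L, 9L, 12L, 15L, 18L, 8L))
  de <- classify_changes(tibble::tibble(
    gene = sprintf("g%d", 1:6), # g7, g8 missing from the DE table
    log2fc = c(0, 2, -3, 0.2, 1.6, 0),
    pvalue = c(1, 1e-4, 1e-5, 0.9, 1e-3, 1),
    fdr = c(1, 1e-3, 1e-4, 0.95, 1e-2, 1)))
  expect_message(bins <- bin_by_match_length(scan, de), "2 gene")
  expect_equal(sum(bins$total_genes), sum(scan$max_match >= 7))
  expect_equal(bins$total_genes, c(2L, 1L, 1L, 0L, 0L, 1L, 0L, 0L, 2L))
  expect_equal(bins$n_up + bins$n_down + bins$n_unchanged, bins$total_genes)
  expect_equal(bins$n_up[bins$bin == 7], 1L)   # g2
  expect_equal(bins$n_down[bins$bin == 7], 1L) # g3
  expect_equal(bins$n_up[bins$bin == 12], 1L)  # g5
  expect_equal(bins$n_up[bins$bin == 15], 0L)  # g6, g7 beyond table: unchanged
  expect_true(is.na(bins$pct_up[bins$bin == 10]))
})

test_that("rendered match summary reproduces the published-style percentages", {
  counts <- readr::read_tsv(system.file("extdata", "match_bin_counts.tsv",
                                        package = "rnaisafe"),
                            show_col_types = FALSE)
  tab <- render_match_summary(counts, legacy = TRUE)
  expect_equal(tab$up[tab$bin == "7"], "71 (0.25%)")
  expect_equal(tab$down[tab$bin == "7"], "91 (0.32%)")
  expect_equal(tab$unchanged[tab$bin == "7"], "28582 (99.44%)")
  expect_equal(tab$up[tab$bin == "12"], "1 (3.57%)")
  expect_equal(tab$unchanged[tab$bin == "12"], "27 (96.43%)")
  expect_equal(tab$down[tab$bin == "11"], "0 (0%)")
  expect_equal(tab$unchanged[tab$bin == "13"], "13 (100%)")
  expect_equal(tab$up[tab$bin == "15"], "–")
  bad <- counts
  bad$n_up[1] <- bad$n_up[1] + 1L
  expect_error(render_match_summary(bad), "sum")
})

test_that("correlation handles monotone, tied and null relationships", {
  scan <- tibble::tibble(gene = sprintf("g%d", 1:10), max_match = 7:16)
  de <- classify_changes(tibble::tibble(
    gene = sprintf("g%d", 1:10), log2fc = seq(0.1, 1, by = 0.1),
    pvalue = rep(0.5, 10), fdr = rep(0.6, 10)))
  res <- match_fold_change_correlation(scan, de)
  expect_equal(res$rho, 1)

  de_tied <- classify_changes(tibble::tibble(
    gene = sprintf("g%d", 1:10), log2fc = rep(0.4, 10),
    pvalue = rep(0.5, 10), fdr = rep(0.6, 10)))
  res_tied <- match_fold_change_correlation(scan, de_tied)
  expect_true(res_tied$tied)
  expect_equal(res_tied$rho, 0)

  expect_error(match_fold_change_correlation(scan[1:2, ], de), ">= 3")

  # independence: |rho| < 0.15 at n = 500 in at least 95% of 100 replicates
  ok <- vapply(1:100, function(s) {
    set.seed(s)
    scan_null <- tibble::tibble(gene = sprintf("g%d", 1:500),
                                max_match = sample(7:15, 500, replace = TRUE))
    de_null <- classify_changes(tibble::tibble(
      gene = sprintf("g%d", 1:500), log2fc = stats::rnorm(500),
      pvalue = stats::runif(500), fdr = stats::runif(500)))
    abs(match_fold_change_correlation(scan_null, de_null)$rho) < 0.15
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("color classes follow the scatter-plot legend conventions", {
  scan <- tibble::tibble(gene = c("a", "b", "c"), max_match = c(8L, 9L, 10L))
  de <- classify_changes(tibble::tibble(
    gene = c("a", "b", "c"),
    log2fc = c(2, 1.5, 0.3),
    pvalue = c(1e-4, 0.3, 1e-4),
    fdr = c(0.01, 0.4, 0.001)))
  res <- match_fold_change_correlation(scan, de)
  expect_equal(res$genes$color_class, c("red", "blue", "gray"))
})
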