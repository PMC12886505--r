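# Seeded synthetic-data generator with recorded ground truth: random
# transcriptomes with planted contiguous dsRNA matches of exact lengths,
# planted homologs at controlled identity, negative-binomial count
# matrices with planted log2 fold changes, and gene-set collections with
# a controlled overlap-level structure. Every planted feature is
# self-validated against the package's own oracles before being returned,
# so violating draws are resampled rather than silently emitted.

#' Simulation configuration
#'
#' Defaults mirror the shape of a bulk RNA-seq risk-assessment study on a
#' non-target insect: a transcriptome of ~30,000 unigenes, a 403-bp dsRNA,
#' three replicates per group, about 1% of genes differentially expressed
#' at |log2FC| = 2, NB dispersion 0.05, and one million counted fragments
#' per sample.
#'
#' @param seed integer seed fixing every emitted artifact.
#' @param n_genes number of transcripts.
#' @param transcript_length_range min/max transcript length (bp).
#' @param gc_content GC fraction of random sequence in (0, 1).
#' @param dsrna_length dsRNA length (bp).
#' @param planted_matches tibble (`gene_index`, `match_length`, `strand`)
#'   of contiguous matches to plant, or NULL.
#' @param planted_homologs tibble (`gene_index`, `identity`) of target
#'   homologs to plant, or NULL; identity in (0.5, 1].
#' @param de_fraction fraction of genes with a planted fold change.
#' @param de_log2fc_magnitude |log2FC| of planted DE genes.
#' @param nb_dispersion NB dispersion (variance = mu + dispersion * mu^2).
#' @param mean_depth expected total counts per sample.
#' @param n_replicates replicates per group.
#' @param depth_factors optional per-sample depth multipliers (length
#'   2 * n_replicates), e.g. to plant known size factors.
#' @param pathway_spec list: `n_per_level` (sets per proximity level),
#'   `size_range`, `n_unconnected` (sets reachable from no seed).
#' @param min_report_len background transcripts are guaranteed below this
#'   match length (default 7).
#' @return validated config list of class `sim_config`.
#' @export
simulation_config <- function(seed = 1,
                              n_genes = 30000,
                              transcript_length_range = c(300, 1500),
                              gc_content = 0.42,
                              dsrna_length = 403,
                              planted_matches = NULL,
                              planted_homologs = NULL,
                              de_fraction = 0.01,
                              de_log2fc_magnitude = 2,
                              nb_dispersion = 0.05,
                              mean_depth = 1e6,
                              n_replicates = 3,
                              depth_factors = NULL,
                              pathway_spec = list(n_per_level = c(3, 3, 3),
                                                  size_range = c(8, 25),
                                                  n_unconnected = 2),
                              min_report_len = 7) {
  stopifnot(gc_content > 0, gc_content < 1,
            de_fraction >= 0, de_fraction < 1,
            n_replicates >= 2, dsrna_length >= min_report_len,
            nb_dispersion >= 0)
  if (!is.null(planted_matches)) {
    planted_matches <- as_tibble(planted_matches)
    stopifnot(all(c("gene_index", "match_length", "strand") %in% names(planted_matches)),
              all(planted_matches$match_length >= min_report_len),
              all(planted_matches$match_length <= dsrna_length),
              all(planted_matches$strand %in% c("sense", "antisense")),
              !anyDuplicated(planted_matches$gene_index),
              all(planted_matches$gene_index <= n_genes))
  }
  if (!is.null(planted_homologs)) {
    planted_homologs <- as_tibble(planted_homologs)
    stopifnot(all(c("gene_index", "identity") %in% names(planted_homologs)),
              all(planted_homologs$identity > 0.5),
              all(planted_homologs$identity <= 1),
              all(planted_homologs$gene_index <= n_genes))
  }
  if (!is.null(depth_factors)) {
    stopifnot(length(depth_factors) == 2 * n_replicates, all(depth_factors > 0))
  }
  structure(list(seed = seed, n_genes = n_genes,
                 transcript_length_range = transcript_length_range,
                 gc_content = gc_content, dsrna_length = dsrna_length,
                 planted_matches = planted_matches,
                 planted_homologs = planted_homologs,
                 de_fraction = de_fraction,
                 de_log2fc_magnitude = de_log2fc_magnitude,
                 nb_dispersion = nb_dispersion, mean_depth = mean_depth,
                 n_replicates = n_replicates, depth_factors = depth_factors,
                 pathway_spec = pathway_spec,
                 min_report_len = min_report_len),
            class = "sim_config")
}

random_dna <- function(length, gc) {
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(probs), length, replace = TRUE, prob = probs), collapse = "")
}

seq_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character())
  starts <- seq_len(n - k + 1)
  substring(seq, starts, starts + k - 1)
}

# mutate bases inside windows sharing a k-mer with the dsRNA until none
# remain; positions in `protect` (1-based) are never touched
scrub_kmers <- function(seq, kmer_set, k, protect = integer(), max_passes = 200) {
  bases <- c("A", "C", "G", "T")
  for (pass in seq_len(max_passes)) {
    kmers <- seq_kmers(seq, k)
    bad <- which(kmers %in% kmer_set)
    if (!length(bad)) return(seq)
    ch <- strsplit(seq, "", fixed = TRUE)[[1]]
    for (i in bad) {
      cand <- setdiff(seq(i, i + k - 1), protect)
      if (!length(cand)) next
      pos <- cand[sample.int(length(cand), 1)]
      ch[pos] <- sample(setdiff(bases, ch[pos]), 1)
    }
    seq <- paste(ch, collapse = "")
  }
  abort("could not scrub shared k-mers from a synthetic transcript")
}

#' Generate a synthetic transcriptome with planted contiguous matches
#'
#' Background transcripts are i.i.d. at the configured GC content, then
#' scrubbed of every k-mer (k = `min_report_len`) shared with either
#' dsRNA strand, so their maximal contiguous match is guaranteed below
#' the reporting threshold. Planted matches are exact dsRNA substrings
#' (reverse-complemented for antisense plants) copied into scrubbed
#' backgrounds with flanking bases chosen to break extension; each
#' planted transcript is verified with the match oracle to attain exactly
#' the requested length, and is re-drawn on violation.
#'
#' @param config `sim_config` from [simulation_config()].
#' @return list: `dsrna` (string), `transcripts` (sequence tibble),
#'   `truth` (tibble `gene`, `true_max_match`, `planted_strand`).
#' @export
generate_transcriptome <- function(config) {
  set.seed(config$seed)
  k <- config$min_report_len
  dsrna <- random_dna(config$dsrna_length, config$gc_content)
  ds_rc <- reverse_complement(dsrna)
  kmer_set <- unique(c(seq_kmers(dsrna, k), seq_kmers(ds_rc, k)))

  lens <- sample(config$transcript_length_range[1]:config$transcript_length_range[2],
                 config$n_genes, replace = TRUE)
  ids <- sprintf("gene%05d", seq_len(config$n_genes))
  seqs <- vapply(lens, function(L) {
    scrub_kmers(random_dna(L, config$gc_content), kmer_set, k)
  }, character(1))

  truth <- tibble(gene = ids, true_max_match = 0L,
                  planted_strand = NA_character_)

  pm <- config$planted_matches
  if (!is.null(pm)) {
    for (r in seq_len(nrow(pm))) {
      gi <- pm$gene_index[r]
      L <- pm$match_length[r]
      strand <- pm$strand[r]
      source_seq <- if (strand == "sense") dsrna else ds_rc
      seqs[gi] <- plant_match(seqs[gi], dsrna, ds_rc, source_seq, L,
                              kmer_set, k, config$gc_content)
      truth$true_max_match[gi] <- L
      truth$planted_strand[gi] <- strand
    }
  }

  ph <- config$planted_homologs
  if (!is.null(ph)) {
    for (r in seq_len(nrow(ph))) {
      gi <- ph$gene_index[r]
      hom <- mutate_to_identity(dsrna, ph$identity[r])
      flank_len <- max(nchar(seqs[gi]) - nchar(hom$sequence), 0)
      left <- if (flank_len > 0) {
        scrub_kmers(random_dna(flank_len, config$gc_content), kmer_set, k)
      } else ""
      seqs[gi] <- paste0(left, hom$sequence)
      truth$true_max_match[gi] <- NA_integer_ # dominated by the homolog copy
      truth$planted_strand[gi] <- NA_character_
    }
    truth$is_homolog <- seq_len(config$n_genes) %in% ph$gene_index
    truth$realized_identity <- NA_real_
    truth$realized_identity[ph$gene_index] <-
      vapply(ph$identity, function(id) mutate_to_identity(dsrna, id, count_only = TRUE),
             numeric(1))
  } else {
    truth$is_homolog <- FALSE
    truth$realized_identity <- NA_real_
  }

  list(dsrna = dsrna,
       transcripts = tibble(id = ids, sequence = seqs),
       truth = truth)
}

# copy a length-L substring of `source_seq` into `background`, guard the
# flanks against extension, and verify the realized maximal match is
# exactly L on either strand; resample the insertion on violation
plant_match <- function(background, dsrna, ds_rc, source_seq, L,
                        kmer_set, k, gc, max_tries = 50) {
  bases <- c("A", "C", "G", "T")
  n <- nchar(background)
  if (n < L + 2) abort("transcript too short for the planted match")
  for (try in seq_len(max_tries)) {
    src_start <- sample.int(nchar(source_seq) - L + 1, 1)
    insert <- substr(source_seq, src_start, src_start + L - 1)
    pos <- sample.int(n - L - 1, 1) + 1 # keep one flank base on each side
    ch <- strsplit(background, "", fixed = TRUE)[[1]]
    ch[pos:(pos + L - 1)] <- strsplit(insert, "", fixed = TRUE)[[1]]
    # break direct extension of the planted occurrence
    if (src_start > 1) {
      prev <- substr(source_seq, src_start - 1, src_start - 1)
      if (ch[pos - 1] == prev) ch[pos - 1] <- sample(setdiff(bases, prev), 1)
    }
    if (src_start + L <= nchar(source_seq)) {
      nxt <- substr(source_seq, src_start + L, src_start + L)
      if (ch[pos + L] == nxt) ch[pos + L] <- sample(setdiff(bases, nxt), 1)
    }
    candidate <- paste(ch, collapse = "")
    got <- max(cpp_longest_match_len(candidate, dsrna),
               cpp_longest_match_len(candidate, ds_rc))
    if (got == L) return(candidate)
    # junction windows occasionally create a longer coincidental match;
    # redraw the insertion point
  }
  abort("could not plant a contiguous match of the requested length")
}

#' Mutated copies of a target sequence at controlled identity
#'
#' Point substitutions at uniformly drawn positions bring a copy of the
#' target down to the requested identity (to within one position's
#' rounding).
#'
#' @param target target sequence (string or one-row sequence tibble).
#' @param identities numeric vector of identities in (0.5, 1].
#' @param seed optional seed (set when given).
#' @param prefix id prefix for the emitted records.
#' @return tibble: `id`, `sequence`, `requested_identity`,
#'   `n_substitutions`, `realized_identity`.
#' @export
generate_homologs <- function(target, identities, seed = NULL, prefix = "hom") {
  if (!is.null(seed)) set.seed(seed)
  if (is.data.frame(target)) target <- target$sequence[1]
  stopifnot(all(identities > 0.5), all(identities <= 1))
  rows <- purrr::imap(identities, function(id, i) {
    hom <- mutate_to_identity(target, id)
    tibble(id = sprintf("%s%02d", prefix, i), sequence = hom$sequence,
           requested_identity = id, n_substitutions = hom$n_sub,
           realized_identity = hom$realized)
  })
  dplyr::bind_rows(rows)
}

mutate_to_identity <- function(target, identity, count_only = FALSE) {
  L <- nchar(target)
  n_sub <- round((1 - identity) * L)
  if (count_only) return(1 - n_sub / L)
  ch <- strsplit(target, "", fixed = TRUE)[[1]]
  if (n_sub > 0) {
    pos <- sample.int(L, n_sub)
    for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  }
  list(sequence = paste(ch, collapse = ""), n_sub = n_sub,
       realized = 1 - n_sub / L)
}

#' Generate a negative-binomial count matrix with planted fold changes
#'
#' Gene means are log-normal, rescaled so each unit-depth sample expects
#' `mean_depth` counts; a `de_fraction` of genes carries a fold change of
#' `±de_log2fc_magnitude` (random sign) in the treatment group; counts
#' are independent NB draws with the configured dispersion (Poisson in
#' the zero-dispersion limit). Optional per-sample depth factors plant
#' known size factors.
#'
#' @param config `sim_config`.
#' @param gene_ids optional gene ids (default `gene00001`...).
#' @return list: `counts` (tibble), `groups` (tibble `sample`, `group`),
#'   `truth` (tibble `gene`, `is_de`, `true_log2fc`),
#'   `depth_factors` (named vector).
#' @export
generate_counts <- function(config, gene_ids = NULL) {
  set.seed((config$seed + 1) %% .Machine$integer.max)
  n <- config$n_genes
  gene_ids <- gene_ids %||% sprintf("gene%05d", seq_len(n))
  stopifnot(length(gene_ids) == n)
  nr <- config$n_replicates
  samples <- c(sprintf("trt%d", seq_len(nr)), sprintf("ctl%d", seq_len(nr)))
  groups <- tibble(sample = samples,
                   group = rep(c("treatment", "control"), each = nr))
  depth <- config$depth_factors %||% rep(1, 2 * nr)
  names(depth) <- samples

  base_mu <- rlnorm(n, meanlog = log(50), sdlog = 1.3)
  base_mu <- base_mu / sum(base_mu) * config$mean_depth

  n_de <- round(config$de_fraction * n)
  de_idx <- if (n_de > 0) sample.int(n, n_de) else integer()
  lfc <- rep(0, n)
  if (n_de > 0) {
    lfc[de_idx] <- sample(c(-1, 1), n_de, replace = TRUE) * config$de_log2fc_magnitude
  }
  mu_trt <- base_mu * 2^lfc
  mu_ctl <- base_mu

  draw <- function(mu) {
    if (config$nb_dispersion < 1e-12) stats::rpois(length(mu), mu)
    else rnbinom(length(mu), mu = mu, size = 1 / config$nb_dispersion)
  }
  counts <- tibble(gene = gene_ids)
  for (j in seq_along(samples)) {
    mu <- (if (groups$group[j] == "treatment") mu_trt else mu_ctl) * depth[j]
    counts[[samples[j]]] <- as.integer(draw(mu))
  }
  list(counts = counts, groups = groups,
       truth = tibble(gene = gene_ids, is_de = seq_len(n) %in% de_idx,
                      true_log2fc = lfc),
       depth_factors = depth)
}

#' Generate gene sets with a controlled proximity-level structure
#'
#' Builds disjoint member chunks per set from the non-seed gene pool,
#' places one seed gene in each level-1 set, and bridges each level-(k+1)
#' set to a level-k set through a single shared gene drawn from that
#' set's private chunk, so the realized overlap graph has exactly the
#' configured levels. Unconnected sets share no gene with any level.
#' The emitted collection is self-validated with
#' [assign_pathway_levels()]; a construction that fails validation is an
#' error, never returned.
#'
#' @param config `sim_config` (uses `pathway_spec` and `seed`).
#' @param gene_ids pool of available gene ids.
#' @param seed_genes seed (level-defining) gene ids.
#' @return list: `gene_sets` (long tibble `set`, `gene`), `truth`
#'   (tibble `set`, `true_level`; `NA` = unconnected).
#' @export
generate_pathways <- function(config, gene_ids, seed_genes) {
  set.seed((config$seed + 2) %% .Machine$integer.max)
  spec <- config$pathway_spec
  n_per_level <- spec$n_per_level
  n_unconnected <- spec$n_unconnected %||% 0
  size_range <- spec$size_range
  stopifnot(length(seed_genes) >= 1)

  pool <- setdiff(gene_ids, seed_genes)
  n_sets <- sum(n_per_level) + n_unconnected
  sizes <- sample(size_range[1]:size_range[2], n_sets, replace = TRUE)
  if (sum(sizes) > length(pool)) abort("gene pool too small for the pathway spec")
  pool <- sample(pool)
  chunk_ends <- cumsum(sizes)
  chunks <- purrr::map2(c(1, head(chunk_ends, -1) + 1), chunk_ends,
                        function(a, b) pool[a:b])

  levels_of_set <- c(rep(seq_along(n_per_level), n_per_level),
                     rep(NA_integer_, n_unconnected))
  set_names <- sprintf("path%02d", seq_len(n_sets))
  members <- chunks
  for (i in seq_len(n_sets)) {
    lev <- levels_of_set[i]
    if (is.na(lev)) next
    if (lev == 1) {
      members[[i]] <- c(sample(seed_genes, 1), members[[i]])
    } else {
      parents <- which(levels_of_set == lev - 1)
      parent <- if (length(parents) == 1) parents else sample(parents, 1)
      bridge <- sample(chunks[[parent]], 1) # private chunk, not seed/bridge
      members[[i]] <- c(bridge, members[[i]])
    }
  }
  gene_sets <- purrr::map2_dfr(set_names, members,
                               function(nm, g) tibble(set = nm, gene = g))
  truth <- tibble(set = set_names, true_level = levels_of_set)

  realized <- assign_pathway_levels(gene_sets, seed_genes,
                                    max_level = length(n_per_level))
  if (!identical(realized$pathways$level[match(truth$set, realized$pathways$set)],
                 truth$true_level)) {
    abort("pathway construction failed self-validation against the level oracle")
  }
  list(gene_sets = gene_sets, truth = truth)
}

#' Simulate a complete risk-assessment dataset
#'
#' Orchestrates [generate_transcriptome()], [generate_counts()] and
#' [generate_pathways()] under one config; homolog genes (when planted)
#' seed the pathway levels.
#'
#' @param config `sim_config`.
#' @return list: `dsrna`, `transcripts`, `counts`, `groups`, `gene_sets`,
#'   `truth` (per-gene tibble joining match/homolog/DE truth),
#'   `pathway_truth`, `config`.
#' @export
simulate_dataset <- function(config) {
  tx <- generate_transcriptome(config)
  cnt <- generate_counts(config, gene_ids = tx$transcripts$id)
  truth <- dplyr::left_join(tx$truth, cnt$truth, by = "gene")
  seed_genes <- truth$gene[truth$is_homolog]
  if (!length(seed_genes)) seed_genes <- truth$gene[1]
  pw <- generate_pathways(config, gene_ids = tx$transcripts$id,
                          seed_genes = seed_genes)
  list(dsrna = tx$dsrna, transcripts = tx$transcripts,
       counts = cnt$counts, groups = cnt$groups,
       gene_sets = pw$gene_sets, truth = truth,
       pathway_truth = pw$truth, config = config)
}

#' Write a simulated dataset to a directory
#'
#' Emits `dsrna.fasta`, `transcriptome.fasta`, `counts.tsv`,
#' `groups.tsv`, `gene_sets.gmt`, `truth.tsv`, `pathway_truth.tsv` and a
#' YAML echo of the configuration. Re-running with the same config is
#' byte-identical.
#'
#' @param sim output of [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(tibble(id = "dsrna", sequence = sim$dsrna),
              file.path(dir, "dsrna.fasta"))
  write_fasta(sim$transcripts, file.path(dir, "transcriptome.fasta"))
  write_counts(sim$counts, file.path(dir, "counts.tsv"))
  readr::write_tsv(sim$groups, file.path(dir, "groups.tsv"), progress = FALSE)
  write_gene_sets(sim$gene_sets, file.path(dir, "gene_sets.gmt"))
  readr::write_tsv(sim$truth, file.path(dir, "truth.tsv"), progress = FALSE)
  readr::write_tsv(sim$pathway_truth, file.path(dir, "pathway_truth.tsv"),
                   progress = FALSE)
  cfg <- sim$config
  cfg$planted_matches <- if (!is.null(cfg$planted_matches)) as.list(cfg$planted_matches)
  cfg$planted_homologs <- if (!is.null(cfg$planted_homologs)) as.list(cfg$planted_homologs)
  yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  invisible(dir)
}
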