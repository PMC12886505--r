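# Independent oracles, deliberately implemented through different routes
# than the package kernels they check.

# longest common substring by k-mer set intersection, ascending in length;
# substrings containing N are excluded from both sides
lcs_oracle <- function(a, b) {
  kmers <- function(s, k) {
    n <- nchar(s)
    if (n < k) return(character())
    out <- substring(s, 1:(n - k + 1), k:n)
    out[!grepl("N", out, fixed = TRUE)]
  }
  best <- 0
  k <- 1
  while (k <= min(nchar(a), nchar(b))) {
    if (length(intersect(kmers(a, k), kmers(b, k))) == 0) break
    best <- k
    k <- k + 1
  }
  best
}

# local affine-gap alignment score via Biostrings (same scoring convention:
# a gap of length L costs gapOpening + L * gapExtension; N vs anything is a
# mismatch by explicit substitution matrix)
sw_oracle <- local({
  submat <- matrix(-3, 5, 5,
                   dimnames = list(c("A", "C", "G", "T", "N"),
                                   c("A", "C", "G", "T", "N")))
  diag(submat)[1:4] <- 2
  function(a, b) {
    s <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(a), Biostrings::DNAString(b), type = "local",
      substitutionMatrix = submat, gapOpening = 5, gapExtension = 2,
      scoreOnly = TRUE)
    max(s, 0)
  }
})

# upper-tail hypergeometric probability by full enumeration of C(N, n)
# draws (feasible for N <= 12)
hyper_oracle <- function(k, K, n, N) {
  draws <- utils::combn(N, n)
  successes <- colSums(draws <= K) # items 1..K are the marked ones
  mean(successes >= k)
}

random_dna_str <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# small two-group count tibble built by hand
toy_counts <- function() {
  tibble::tibble(gene = c("g1", "g2", "g3", "g4"),
                 s1 = c(10L, 100L, 0L, 5L),
                 s2 = c(12L, 90L, 0L, 7L),
                 s3 = c(9L, 110L, 1L, 6L),
                 s4 = c(11L, 95L, 0L, 50L),
                 s5 = c(10L, 105L, 2L, 60L),
                 s6 = c(10L, 98L, 0L, 55L))
}

toy_groups <- function() {
  c(s1 = "treatment", s2 = "treatment", s3 = "treatment",
    s4 = "control", s5 = "control", s6 = "control")
}
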