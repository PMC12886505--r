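---
title: "Methods: transcriptome-based risk assessment of dsRNA off-target effects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: transcriptome-based risk assessment of dsRNA off-target effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnaisafe)
```

## The problem

RNAi crops express an insecticidal double-stranded RNA (dsRNA) that
silences an essential gene in the target pest. A predator or other
non-target organism (NTO) feeding on exposed prey ingests that dsRNA, and
the regulatory question is whether it perturbs the NTO's transcriptome:
directly, through short stretches of contiguous sequence identity that the
siRNA machinery can act on; or indirectly, through homologs of the target
gene, through pathway neighbours, or as a general loss of transcriptome
homeostasis. `rnaisafe` implements that assessment as a chain of testable
stages starting from a gene-by-sample count matrix, a transcriptome
assembly (one record per unigene), the dsRNA sequence, and flat gene-set
(GMT) annotations. Read QC, assembly and quantification are upstream and
out of scope.

All stages exchange plain tibbles, so a full analysis is a handful of
piped calls, and every intermediate is inspectable.

## Off-target surface: contiguous exact matches

A dsRNA is diced into siRNAs from both strands, so the off-target surface
of a transcript is its longest contiguous exact match to **either** the
dsRNA sense sequence or its reverse complement (a sense-only mode is
available). `scan_transcriptome()` computes, per transcript, the maximal
longest-common-substring length against both strands. The kernel is a
plain dynamic program over the two sequences, written in C++: at the
scales this package targets (transcriptomes of tens of thousands of
records against a ~400 bp trigger) the quadratic table is already fast,
and a single unambiguous kernel is easier to certify against the
independent substring-set oracle used in the tests than a seeded
heuristic. Windows containing `N` are excluded from matching on either
side — assemblies contain `N`s, and letting them match would inflate
off-target lengths.

Matches of at least 7 bp are reportable, following the shortest
contiguous identity that has been observed to trigger silencing;
shorter-matched genes are flagged, not dropped. `bin_by_match_length()`
assigns each reportable gene to **exactly one** bin equal to its maximal
match length, with the last bin open-ended (15 means ≥ 15 bp). We read
the published per-bin tables as per-gene maximal values, so exclusive
bins make the totals a partition; a cumulative "≥ k" reading is monotone-
consistent with the same tables but loses the partition property.
Direction comes from the DE table (up/down = significant DEG by the sign
of the log2 fold change); genes filtered out of the DE stage upstream
count as unchanged, because the binning universe is the transcriptome,
not the tested subset, and the number of such genes is logged.

Percentages in rendered summaries are rounded **half-up** to two
decimals. The published table style mixes `"0.32%"` with `"0%"` and
`"100%"`; `format_percent(legacy = TRUE)` reproduces that mixed style,
the default renders trailing zeros uniformly. Empty bins render as en
dashes.

`match_fold_change_correlation()` reports the Spearman rank correlation
between match length and |log2FC| over the matched genes, with the
conventional scatter colour classes (red: |log2FC| ≥ 1 and FDR ≤ 0.05;
blue: |log2FC| ≥ 1 and FDR ≥ 0.05; gray: |log2FC| < 1). When either
variable is constant the correlation is undefined; it is reported as 0
with an explicit `tied` flag rather than `NA`, so downstream tabulation
never silently drops the comparison. Both the signed and absolute fold
change are available for plotting since published practice varies.

## Differential expression

The DE stage is a deliberately simple negative-binomial Wald test — a
stand-in with the same inferential shape as the standard NB tools, whose
accuracy is certified by planted-truth recovery and type-I-error
simulations rather than by numerical parity with any external engine:

* **Normalization** is median-of-ratios: per sample, the median over
  all-positive genes of the count divided by the gene's geometric mean.
* **Dispersion** per gene is a method-of-moments estimate pooled within
  groups, floored at `1e-8`, then blended 50/50 with a fitted
  mean-dispersion trend `a0 + a1/mu`. With n = 3 per group the gene-wise
  moment estimate is noisy and would otherwise make the Wald statistic
  anticonservative; the trend blend stabilises it without full MAP
  shrinkage.
* **Fold change** is `log2((mean_t + 0.5) / (mean_c + 0.5))`; the 0.5
  pseudo-count keeps fold changes finite for zero-count groups.
* **Inference** is a two-sided Wald test with a delta-method standard
  error of the log2 fold change under the NB variance function, and
  Benjamini–Hochberg FDR (via `stats::p.adjust`). Genes with identical
  counts everywhere report log2FC = 0, p = 1.

There is no LFC shrinkage, no outlier filtering and no independent
filtering: the contribution downstream of DE is thresholding and
attribution, and simpler machinery is easier to certify. Under the null
(dispersion 0.1, n = 3 vs 3) the measured type-I error at nominal 0.05
averages ≈ 0.07 over 20 seeds, and on planted data (10% DEGs at |log2FC|
= 2, dispersion 0.05, 1M reads/sample) recall is ≈ 0.99 at empirical FDR
≈ 0.01 — both computed by the test suite and the acceptance script, not
quoted from elsewhere.

DEG calling uses the strict rule `|log2FC| > 1 AND FDR < 0.05` by
default. The non-strict variant (`≥`, `≤`) appears in some published
legends; `boundary = "inclusive"` switches to it. Methods-text
conventions take precedence over legend typography, which is why strict
is the default. `fold_only` (fold change without significance) and
`unchanged` complete the three-tier class.

`ddct()` implements the 2^-ΔΔCt relative-expression estimate used for
qPCR validation of called DEGs, and `max_hazard_dose()` the worst-case
feeding-dose arithmetic (in-planta concentration × hazard factor,
default 100).

## DEG attribution

Attribution asks *why* a DEG changed, with three non-exclusive classes:

1. **Homologs of the target gene.** `find_homologs()` aligns the target
   against both strands of every transcript with an affine-gap
   Smith–Waterman (blastn-style scoring: +2/−3, gap existence 5,
   extension 2; `N` is a mismatch against everything) and converts the
   best score per transcript to a Karlin–Altschul E-value,
   `E = K·m·n·exp(−λS)`, with the ungapped constants for that scoring
   scheme (K = 0.41, λ = 0.625) and n the total transcriptome length.
   The E-value threshold (default `1e-10`), not the engine, is the
   contract: hits are validated in the tests against an independent
   alignment oracle and against planted mutated copies, and random
   1 kb transcriptomes produce no hits at the threshold.
2. **Pathway proximity.** With flat GMT sets and no relation graph,
   "pathways that interact" is operationalized as shared-gene overlap:
   level-1 sets contain a seed gene (the target's homologs plus any
   caller-supplied ids), level-(k+1) sets share at least `min_overlap`
   (default 1) genes with a level-k set, breadth-first, so every set
   receives its minimal level. Genes take the minimum level over their
   sets and are counted once; seed genes are excluded from per-level
   gene counts because they are the cause of the structure, not its
   effect. Whether published per-level tables deduplicate the same way
   is not stated anywhere we can check; minimum-level counting is the
   reproducible choice.
3. **Contiguous matches**, from the scan above.

`summarize_levels()` emits the per-level direction table with a Total
row; `classify_degs()` emits the per-DEG label sets and the
unattributed bucket.

## Enrichment

`enrich()` is an upper-tail hypergeometric over-representation test per
gene set — `P(X ≥ k)` including the observed k, the standard
convention — with BH correction across tested sets. Sets are intersected
with the universe first, and sets smaller than `min_set_size` (default
3) are skipped with a message. The universe defaults to the tested genes
(those in the DE table) and can be widened to the whole transcriptome;
both conventions are common and the choice is the caller's.

## Transcriptome entropy

Shannon entropy of a sample's relative transcript abundances,
`H = −Σ p_i log2 p_i`, is a scalar index of transcriptome homeostasis: a
transcriptome that concentrates mass on fewer transcripts after exposure
has lower entropy. Bits (log base 2) are the default and a natural-log
option exists; the treatment/control **comparison** is base-invariant,
and it — not the absolute value, which also depends on the abundance
unit — is what carries a conclusion. Entropy is computed on relative
abundances of counts (proportions are invariant to per-sample scaling,
so depth normalization cancels; optional length normalization would
not, and is left to the caller's abundance choice upstream).
`compare_group_entropy()` reports per-sample H, group means ± SE
(sd/√n), and a two-sided Student's t-test; identical groups are flagged
`zero_variance` with p = 1.

## Synthetic data and what passing tests mean

`simulation_config()` defaults mirror the study shape this package was
built around: ~30,000 unigenes of 300–1500 bp at GC 0.42, a 403 bp
dsRNA, 3 replicates per group, ~1% DE genes at |log2FC| = 2, NB
dispersion 0.05, one million counted fragments per sample. Tests and the
acceptance script run scaled-down versions of that scenario (tens to
thousands of genes, shorter triggers), chosen so each suite certifies
the same contracts at desk cost; the sizes are stated in each test.

Generator guarantees, each self-validated before emission:

* **Background transcripts** are guaranteed below the 7 bp reporting
  threshold against both dsRNA strands. Whole-transcript resampling
  cannot deliver that — a random 500 bp transcript shares some 7-mer
  with a 403 bp trigger with probability near 1 — so the generator
  scrubs: it locates every shared 7-mer window and mutates one base
  inside it, iterating until none remain. That is verify-and-resample at
  window granularity, and it terminates because each pass strictly
  reduces shared windows in expectation while the verification is exact.
* **Planted matches** copy a dsRNA substring of the exact requested
  length into a scrubbed background, force the flanking bases to differ
  from the dsRNA's continuation so the match cannot extend, and verify
  with the match kernel that the realized maximum equals the request on
  either strand, redrawing the insertion point otherwise (junction
  windows occasionally create a longer coincidental match).
* **Planted homologs** are mutated copies of the target at a requested
  identity (substitutions at uniform positions, realized identity
  recorded). A homolog gene naturally carries long contiguous identity
  runs, so its `true_max_match` is recorded as `NA` rather than
  pretending the scan truth is known.
* **Planted pathways** build disjoint member chunks per set, seed the
  level-1 sets, and bridge each level-(k+1) set to a level-k set through
  one gene from that set's private chunk; the emitted collection must
  reproduce the configured levels under `assign_pathway_levels()` or
  generation errors out.
* **Counts** are independent NB draws around log-normal means scaled to
  the configured depth, with the planted fold change applied to the
  treatment means and optional per-sample depth factors to plant known
  size factors. One integer seed fixes every emitted artifact
  byte-for-byte.

What passing does **not** show about real data: the generator plants
i.i.d. bases (no repeats, paralog families, or GC structure beyond the
global fraction), independent genes (no correlation structure or
compositional coupling), and clean group labels (no batch effects).
Recovery rates on synthetic data certify the machinery, not the
biology of any particular transcriptome.

## Numerical choices and degenerate inputs

* Percentages: half-up rounding to 2 decimals (`round_half_up()`), with
  an epsilon guard against binary representation of exact halves.
* Ties in the correlation: rho reported as 0 with a flag (see above).
* Smith–Waterman tie-break: lowest query start, then lowest subject
  start, so alignments are reproducible across platforms.
* All-zero genes: log2FC = 0, p = 1. All-zero sample columns are an
  error for entropy (no abundance distribution exists).
* Size factors require at least one gene positive in every sample;
  otherwise the error suggests constructing a pseudo-reference upstream
  rather than silently switching method.
* Counts must be integers; estimated counts must be rounded by the
  caller, keeping the NB model honest and runs reproducible.

## Orchestration

`run_assessment()` executes scan → DE → attribution → enrichment →
entropy from a `run_config()` (or YAML), writing the per-stage TSVs, a
`run.log` with thresholds, per-stage exclusion counts and timings, and a
machine-readable `summary.json`. Outputs are pure functions of the
inputs and config — reruns are byte-identical. Two life stages (e.g.
nymph and adult datasets) are analysed as two independent runs. A thin
wrapper script (`inst/scripts/run_assessment.R`) exposes the same entry
point to the shell.

## Known limitations

* The NB test is a stand-in: no shrinkage of fold changes, no outlier
  handling. Effect sizes near the threshold on real, noisy data deserve
  a dedicated DE engine.
* Homology is nucleotide-level local alignment with fixed ungapped
  Karlin–Altschul constants; protein-level homology and
  composition-adjusted statistics are out of scope.
* Pathway "interaction" is shared-gene overlap of flat sets; curated
  relation graphs would refine levels.
* Mismatch-tolerant and thermodynamic siRNA scoring are deliberately
  excluded: the contiguous-identity surface is the assessment target
  here.
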