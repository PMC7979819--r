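---
title: "Post-caller genomic evidence integration: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Post-caller genomic evidence integration: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shhland)
```

# Scope

Upstream callers — fusion detectors on RNA-seq, allele-specific copy-number
fitting on SNP arrays, somatic variant callers on RNA-seq — produce candidate
lists that are dominated by recurrent artifacts: readthrough transcription,
circular RNA chimeras, library-preparation chimeras shared with normal brain,
germline copy-number polymorphisms, RNA editing and alignment artifacts.
`shhland` implements the evidence-integration layer that sits *after* those
callers for sonic-hedgehog (Shh) medulloblastoma-style tumor cohorts: it
filters candidate calls against control libraries and annotation, corroborates
surviving calls with orthogonal genomic evidence, derives gene-level summaries
and tests cohort-level association structure. Calling engines themselves
(alignment, fusion/variant/SV calling, ASCAT, GISTIC) are out of scope; their
outputs are this package's inputs.

All internal coordinates are 0-based half-open; SEG, GTF, and the unified
fusion dialect convert at the I/O boundary (the upstream formats are 1-based
inclusive). This makes interval arithmetic — overlap lengths, reciprocal
overlap, gap computations — uniform and off-by-one free.

# Fusion screening

## Blacklist construction

Two evidence routes mark a fusion gene pair as a control artifact:

1. **Contig route.** For each tumor call a chimeric contig is built from up to
   110 bp on each side of the junction (truncated at chromosome and gene
   boundaries). A control read qualifies when it matches the contig exactly
   (ungapped, full length), has mean base quality strictly above 30, spans the
   junction and extends at least 20 bp past it. The 20 bp overhang is counted
   on the far (3') side of the junction only: a read that crosses the junction
   with a long downstream anchor is what distinguishes a genuine chimeric
   molecule in the control library from a read that merely ends near the
   junction.
2. **Call route.** The pair is itself reported by a caller in a control
   library.

A pair is blacklisted when either kind of evidence occurs in at least two
control libraries (the two routes are pooled per library — whether the
published rule counts contig hits, called pairs, or both is ambiguous, so the
union is used and recorded here), or when the pair is called in the designated
fetal control plus at least two adult controls. Every breakpoint called in any
control library is blacklisted outright, with an optional ±N bp matching
window (default 0) for caller jitter.

## Filter cascade

Each tumor call is annotated with *every* failing rule; the final status
depends only on the set of failing rules, never on evaluation order:

| rule id | condition (defaults) |
|---|---|
| `blacklist_pair` / `blacklist_bp` | pair or breakpoint in the control blacklist |
| `circular` | both breakpoints within one gene (circular RNA artifact) |
| `readthrough` | gene bodies < 50 kb apart |
| `recurrent` | same breakpoint pair in > 15 samples |
| `expr_ratio` | ((fusion reads)/200 bp)/RPKM < 0.01 at either partner |
| `junction_prop` | junction read proportion < 0.05 at *both* partners |

Design choices where the published description is silent:

* "Fusion reads" in the expression ratio means spanning + bridging reads
  (configurable to spanning-only via `fusion.reads`).
* The readthrough distance is measured between the nearest boundaries of the
  two gene bodies and applied to all pairs regardless of strand. Requiring
  collinear same-strand partners would be the biologically narrower reading;
  applying the rule broadly is the conservative screen, and the per-call rule
  annotations keep the alternative auditable.
* The readthrough and recurrent rules are waived when another distinct fusion
  breakpoint is detected in either partner gene across the cohort — genes
  that recurrently break in different places look like genuine rearrangement
  targets, not positional artifacts.
* The junction-proportion denominator needs wildtype junction read counts
  (`wt_reads5`/`wt_reads3` in the unified dialect); when absent the rule is
  skipped with a warning rather than guessed.

## Structural-variant support tiering

Passing fusions are tiered `sv_supported` versus `expressed_only`:

* **WGS confidence.** Per partner: (1) the fused exon is terminal and a WGS
  breakpoint falls in the intergenic gap to the adjacent gene; (2) the fused
  exon is internal and a breakpoint falls in an intron adjacent to it (either
  side is accepted); (3) a breakpoint lies within 100 kb of the fused exon
  edge. High = both partners (1)/(2); Intermediate = one (1)/(2) + one (3);
  Low = both (3).
* **SNP-array support.** Fusion breakpoints are matched against copy-number
  change points (boundaries between post-merge segments of unequal state)
  padded by 250 kb, reported per side (`left`/`right`/`both`/`none`).
  Pre-merge boundaries are never used: they are segmentation noise by
  construction.
* **Multi-isoform evidence.** At least two distinct breakpoint pairs for the
  same sample and gene pair, with one call having spanning and bridging reads
  both positive and summing above 20.
* **Salvage.** Recurrent-gene calls removed by the screen are restored when
  SV-validated or when the read-depth step statistic at the junction — the
  absolute difference of mean depth left and right of the junction divided by
  the pooled standard deviation — reaches 3.0. This statistic replaces a
  manual coverage-plot inspection; the threshold is a z-score-like effect
  size, so 3.0 demands a step well outside depth noise. Every salvage carries
  its score so the automated decision stays reviewable.

# Copy-number post-processing

Segment log-ratios are `log2(copy number / ploidy)`; copy number 0 is floored
at 0.5 (configurable) so homozygous deletions stay finite but extreme
(log-ratio −2 at diploidy). Adjacent segments whose log-ratios differ by less
than 0.25 merge into their length-weighted mean, iterated to a fixpoint;
merging conserves covered length and the weighted mean log-ratio exactly. The
strict `<` at the threshold is enforced with a 1e-9 guard so differences
sitting on the boundary up to float representation never merge.

Germline polymorphisms are removed in two stages with re-merging after each:
segments with ≥ 50% reciprocal overlap to a gold-catalog variant (population
frequency ≥ 1%), then segments with ≥ 80% reciprocal overlap to a
supporting-catalog variant (studies of ≥ 50 subjects, ≥ 1% in-study
frequency). Reciprocal overlap is `min(|a∩b|/|a|, |a∩b|/|b|)`. The published
text does not state whether the overlap cutoffs are strict; inclusive (≥) is
used.

States derive from log-ratio and ploidy: deletion at copy number 0, loss at
log-ratio ≤ −0.25, gain at ≥ 0.25, amplification at ≥ 1.0. The ±0.25/1.0
cutoffs are this package's defaults — the source method states only that
states follow from log-ratio and ploidy — and they live in the configuration
so every report can print them. Segments longer than 12 Mb are broad, the
rest focal.

Gene-level states are "first past the post": the gene takes the state of the
segment overlapping it most, regardless of majority; a gain/amplification
winner must additionally cover ≥ 50% of the gene (else neutral), while any
overlap by a loss/deletion winner suffices — deletions are biologically
meaningful even when partial, whereas a partial gain of a gene body rarely
increases its dosage.

Copy-number-responsive genes: samples are grouped per gene into loss-like
(deletion + loss), neutral, and gain-like (gain + amplification); expression
differences across groups are tested with the Kruskal-Wallis rank test
(chi-square approximation, tie-corrected) and Benjamini-Hochberg adjusted
across tested genes, flagging genes at adjusted p < 0.05. Genes without two
groups of at least two samples are reported NA and stay out of the FDR. For
display, expression can be normalized by the median of the neutral-state
samples. Note the chi-square approximation is crude at very small group
sizes: on a 3-versus-3 example it differs from the exact permutation p-value
by about 0.05, which the tests document explicitly.

# Promoter-methylation drivers

Probes within 1500 bp of the TSS are promoter probes. Within a gene, probes
whose beta profiles correlate at Pearson r ≥ 0.7 (complete linkage, so every
within-set pair meets the bar) are averaged into a probe set; the rest are
analyzed individually. Each unit's beta values are fitted with univariate
Gaussian mixtures (1–3 components, unequal variances) selected by BIC. The
published method names a mixture-model approach without parameters; this
implementation uses `mclust`, whose model-based hierarchical initialization
makes the fit fully deterministic — a stronger property than seeded random
restarts, and one less degree of freedom to document.

A unit is a driver candidate when: no cluster holds fewer than 5% of samples;
the beta difference between the two extreme clusters (lowest and highest
mean) is at least 0.25; the z-scored expression difference between the same
clusters is at least 0.75. Direction is `hyper` when the higher-beta cluster
expresses lower. Candidates are ranked by |diff_mean × diff_exp|, and every
rejected unit carries its rejection reason so near-misses are auditable.

# RNA-seq variant filters

The cascade applies order-independent pure predicates to annotated calls;
every failing rule is recorded:

* population allele frequency > 0.01 (maximum over the configured databases;
  strictly greater, so a variant at exactly 0.01 survives);
* RADAR-registered RNA editing sites; deletions exactly matching an
  annotated intron (splice junctions miscalled as deletions); calls supported
  only by soft-clipped reads; fewer than 5 variant reads;
* insertions/deletions on reference homopolymer runs ≥ 5 bp whose
  inserted/deleted bases are a run of the homopolymer base — read as "the
  indel sequence is a run of that base", the only reading that is a
  computable predicate;
* calls inside germline SNP clusters: maximal runs of ≥ 10 consecutive
  positions all present in the SNP database;
* dbSNP-registered missense/synonymous/non-frameshift variants, unless
  rescued as COSMIC hotspots (≥ 10 samples);
* benign-prediction removal for non-hotspot variants when *any* available
  predictor calls them benign (SIFT ≥ 0.05, PolyPhen-2 HDIV ≤ 0.908, HVAR ≤
  0.956, MutationTaster polymorphism, MutationAssessor non-functional). The
  published list's formatting leaves OR/AND ambiguous; OR is used — any
  benign signal on a non-hotspot call removes it — and missing scores can
  never fail a clause;
* empirical-Bayes p ≥ 1e-3, unless realignment-rescued (the pileup caller
  saw < 5 variant reads or less than half the primary caller's count —
  pileup cannot see reads recovered by local realignment).

# Co-occurrence and exclusivity

The binary alteration matrix marks a gene event per sample for passing
mutations, amplification/deletion gene states, and SV-supported fusions;
arm-level events pass through as features. Co-occurrence is the two-sided
Fisher exact test per pair with Benjamini-Hochberg adjustment (significant at
q < 0.01 with odds ratio > 1).

Exclusivity uses a margin-preserving permutation null labelled a stand-in:
the groupwise test published alongside the original analysis is another
method's software, so this package implements checkerboard swap
randomization, which preserves every gene's event count and every sample's
event burden exactly at every step — the same margins-aware intent. The
one-sided p-value is `(1 + #{null overlap ≤ observed}) / (1 + n_perm)`.

Two structural facts matter when designing panels for this test and are easy
to miss. First, a two-feature matrix is *invariant* under margin-preserving
swaps — the column sums fix the overlap — so exclusivity is only testable
inside a panel of several features. Second, the smallest attainable p with
`n_perm` permutations is `1/(n_perm + 1)`, so after multiplicity adjustment
over P pairs the most significant achievable q is about `P/(n_perm + 1)`;
reaching q < 0.01 at n_perm = 1000 therefore requires a pair universe of at
most ~10 pairs or proportionally more permutations. The acceptance scenario
plants a perfectly exclusive 40+40-event pair in a five-feature panel (10
pairs), where the null essentially never reproduces zero overlap and the
planted pair lands at q ≈ 0.00999.

# Synthetic cohorts and what passing tests show

The generator produces cohorts whose statistical structure matches what each
stage assumes, with every planted item recorded in a truth table, so all
end-to-end tests are joins of pipeline verdicts against planted truth:

* **Genomes**: random sequence, three-exon genes, alternating close (~20 kb)
  and wide gene spacing so readthrough-range and distant pairs both exist.
  Default fusion cohort: 60 tumors, 8 controls, two 5 Mb chromosomes — sized
  for fast end-to-end runs; copy-number/methylation cohorts use two 30 Mb
  chromosomes of 110 genes so broad (> 12 Mb) events are representable.
* **Fusion classes**: `true_sv` (WGS breakpoints in adjacent introns,
  copy-number change points at both breakpoints, coverage steps, read support
  above every threshold), `expressed_only`, `readthrough`, `circular`,
  `control_shared` (qualifying contig reads in two control libraries, plus
  ~10% low-quality decoy reads exercising the quality clause),
  `recurrent_artifact` (one event in 16 tumors).
* **Copy number**: 40 samples, 24% aneuploid (ploidy 3) matching the reported
  aneuploidy fraction in Shh-MB; 10 responsive genes with a 1.0 log2 shift in
  12 aberrant samples over 0.5 log2 noise; broad gains giving null genes real
  category splits without expression shifts; germline losses drawn to overlap
  the emitted catalogs above the filtering thresholds.
* **Methylation**: 100 samples; driver genes bimodal at beta 0.2/0.6 (Δβ 0.4)
  with a −1.5 z expression shift in the 30% hypermethylated cluster; decoy
  genes with 4% minor clusters and Δβ 0.2; 200 unimodal null genes.
* **Variants**: one exemplar per filter rule, each violating exactly its rule,
  plus clean calls, a COSMIC-rescued dbSNP hotspot and a realignment-rescued
  low-pileup call.

What passing does *not* show: the generator draws independent Gaussian noise
and uniform random sequence — no GC structure, repeats, mappability artifacts,
correlated probe noise, subclonality, or purity gradients. Recovery rates of
100% on planted truth demonstrate that the rules are implemented exactly as
specified and are internally consistent, not that these thresholds achieve
any particular sensitivity on real tumors. Cohort-scale published quantities
(subtype sizes, per-gene alteration frequencies) depend on the original
250-patient cohort and are deliberately not targeted.

# Numerical and degenerate-input choices

* CN = 0 maps to log2(0.5/ploidy), keeping deletions extreme but finite.
* Merge threshold comparisons carry a 1e-9 epsilon guard (strict `<` at the
  documented boundary).
* Mixture fits floor degenerate variances (constant betas yield k = 1
  directly); fit failures fall back to a single component.
* Kruskal-Wallis uses the tie-corrected chi-square approximation; groups with
  fewer than two samples are dropped from a gene's test.
* Ties in "largest overlap" for gene-level states resolve to the first
  segment in coordinate order (deterministic and matched by the brute-force
  oracle tests).
* Swap-chain burn-in defaults to 10× the event count and thinning to 1× —
  enough decorrelation for the matrix sizes used here, and both are
  arguments.
* Zero controls, empty catalogs, empty panels, all-zero coverage and
  missing annotations each have a documented behavior (warning + identity,
  or error) rather than silent propagation.

# Limitations

* The exclusivity null is a permutation stand-in, not the published groupwise
  test; its p-value resolution is bounded by `n_perm`.
* Fusion contigs are built on the forward strand; the synthetic cohorts and
  the unified dialect use forward-strand breakpoints. Reverse-strand contig
  assembly would need strand-aware sequence extraction.
* The multinomial exact test and the published cohort Fisher p-values are not
  reproducible from printed information (their contingency tables are not
  published) and are excluded rather than guessed.
* Arm-level event calling from methylation arrays is consumed as input, not
  computed.
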