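---
title: "Methods: purity-corrected CNA analysis, C-Norm, enrichment, and amplicon indel calling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: purity-corrected CNA analysis, C-Norm, enrichment, and amplicon indel calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistics and algorithms
it implements, the assumptions behind them, and the design choices made
where the procedure was genuinely open.

## Purity-corrected copy-number calling

A segmented SNP-array copy-number profile reports, per interval, a log2
ratio `x` of observed to expected copy number. A tumor sample is a mixture
of malignant cells (fraction `p`, the purity) and copy-neutral normal
cells, so the linear-scale ratio decomposes as `2^x = p · 2^c + (1 − p)`,
with `c` the tumor-intrinsic log2 ratio. `purity_correct()` inverts this:

```
c = log2( (2^x − (1 − p)) / p )
```

Assumptions: the normal compartment is diploid-neutral on every segment;
purity is a single per-sample scalar (no subclonal mixtures); `x` is an
unbiased segment mean. When `2^x ≤ 1 − p`, the observed ratio is below
anything the mixture can produce (a loss deeper than purity can explain, or
noise at low purity) and the logarithm is undefined; we floor the result at
a **deep-loss sentinel of −8** (≈ 1/256 of baseline, far below any calling
threshold) and flag it, keeping the value usable for loss calls without
infinities. At `p = 1` the correction is exactly the identity, and for any
`p ∈ (0, 1]` correcting the forward mixture recovers `c` to machine
precision — both are enforced by tests on a 100 × 100 (c, p) grid.

**Thresholds.** Calling is referenced to a *triploid* tumor background:
losing one copy from three leaves 2/3 of the copies (a 33% decrease), and
gaining one makes 4/3. Hence loss when `c ≤ log2(2/3) ≈ −0.585`, gain when
`c ≥ log2(4/3) ≈ +0.415`. Both comparisons are inclusive: "at least one
copy" is inclusive language, and the boundary case is exactly the one-copy
event. The triploid convention is deliberately conservative for
near-diploid tumors: a one-copy diploid loss (`c = −1`) clears the
threshold with margin, while shallow subclonal changes do not.

**Aggregation.** The calling rules above leave gene-level aggregation open
when several segments overlap a gene; we use the *length-weighted mean* of
corrected ratios — continuous, deterministic, and consistent with
segment-mean semantics. A gene with no overlapping segment is reported
neutral with `uncovered = TRUE` rather than dropped, keeping cohort tables
rectangular while letting users exclude uncovered calls. Arm calls instead
ask how much of the arm is altered: the length fraction of the arm covered
by segments at or beyond a threshold, with state assigned when that support
reaches 0.75 ("at least 75% of the arm affected"). The two directions
cannot both reach 0.75. Fraction genome altered is the altered length over
the surveyed length (all segments), so it is invariant to splitting a
segment at constant `c`; aneuploidy terciles partition the cohort by rank,
ties broken by sample id, remainders assigned to the lower terciles.

Samples present in the SEG input but absent from the purity table are
excluded from corrected analyses (with a message) — corrected and
uncorrected ratios must never be mixed within one cohort.

**Coordinates.** On-disk SEG is read as 1-based inclusive (the common
dialect; the dialect of any given provider should be verified), BED
annotations as 0-based half-open; everything internal is 0-based half-open
with a single conversion point in `read_seg()`. "chr8" and "8" are
canonicalized at read time.

## C-Norm: cohort covariate normalization

Arm-level events travel together, so a group defined by one lesion (the
*defining* CNA, e.g. `8p_loss`) differs from its complement in many other
lesion frequencies; any phenotype contrast between the groups is then
ambiguous. C-Norm removes the measured copy-number confounding directly:

1. compute each non-defining arm event's frequency in both groups (always
   against *current* retained group sizes);
2. stop when the maximum absolute frequency difference is ≤ the convergence
   tolerance (default 0.05);
3. otherwise label events enriched in a group when the difference is
   *strictly* greater than the 0.05 margin, score each sample by the number
   of **own-group**-enriched events it carries, and remove `batch_size`
   (default 1) samples drawn uniformly at random from the pooled
   maximum-score samples;
4. never let either group lose more than 50% of its initial size; if no
   removal is possible (all scores zero, or caps reached), stop at the best
   concordance achieved.

Open choices and how we fixed them: "several samples" per iteration is
interpreted as the smallest batch (1), which maximizes concordance per
sample removed and is configurable; "near-equivalent frequencies" is
quantified as the enrichment margin itself; the removal pool spans both
groups jointly rather than alternating. The returned retained sets
correspond to the best (minimum maximum-difference) point along the
removal trace, so the reported final concordance never exceeds the initial
value even when the loop overshoots before stalling; the full trace remains
recorded, and with a fixed seed the whole procedure is bit-reproducible and
replayable. Groups are fixed throughout — only membership masks change — so
the defining contrast is preserved by construction.

The degenerate case of a covariate at 100% vs 0% is not normalizable by
removal (each removal changes numerator and denominator together);
the algorithm stops at the cap with `achieved = FALSE`, which is the
correct answer, not a failure.

Association on the retained cohort uses Wilcoxon rank-sum tests on
per-sample signature scores with BH adjustment across gene sets, refusing
groups smaller than 3.

## Preranked weighted enrichment

The enrichment score walks the ranked list; hits add
`|s_i|^w / Σ_hits |s|^w` (weight `w = 1`), misses subtract `1/(N − N_hit)`;
ES is the signed extremum of the running sum. Numerical details that
matter: ties in the input ranking are broken by gene symbol (stable,
documented, since upstream FDR-ranked lists carry ties); when the positive
and negative extrema tie exactly (within 1e−12, absorbing accumulation
error), the negative extremum is reported; if all hit scores are zero the
hit increments fall back to equal weights. ES is invariant to positive
rescaling of the scores and antisymmetric under list reversal with
negation; it agrees with an exhaustive brute-force oracle on all subsets of
small universes and with an independent preranked implementation (fgsea) to
1e−10 in tests.

Significance uses a **gene-permutation null** — random same-size gene sets
from the ranked universe — which is the preranked convention forced by the
absence of raw per-sample expression; it tests positional concentration,
not inter-gene correlation, and is anticonservative when member genes are
strongly co-expressed (a known property of preranked GSEA generally). Null
ES are generated per distinct set size from a seed derived from the user
seed and the size, so results do not depend on the order or duplication of
query sets. NES divides ES by the mean same-sign null |ES|; the nominal p
is the same-sign null tail fraction; FDR q is the standard null/observed
NES tail ratio, capped at 1 and made monotone nonincreasing in |NES|.

The upstream differential-expression fit that produces real ranked lists is
out of scope by design: any `(gene, score)` list is accepted, and the
synthetic pipeline ranks genes with a built-in signed rank-sum statistic.
Per-sample signature scores are means of z-scored (cohort-standardized)
member-gene log expression; note the z denominator includes between-group
variance, so a group shift of β per-gene SDs is recovered as
`β / sqrt(1 + β²/4)` for balanced groups — within 10% of β for β ≤ 0.9.

## Co-occurrence tests

Lesion overlap uses the exact hypergeometric upper tail `P(X ≥ k)`
(`stats::phyper`; verified against exhaustive enumeration of all draws for
N ≤ 15). Enrichment claims use the upper tail; depletion is reported as the
explicit lower tail rather than by doubling, and both are shown with BH FDR
across events in the anchor-versus-all arm table. TP53 loss of function is
non-synonymous mutation (vocabulary: missense, nonsense, frameshifts,
splice site, nonstop, translation start, in-frame indels — configurable) or
copy-number loss of the gene.

## Amplicon indel quantification

The aligner is specialized for amplicon sequencing, where every read pair
comes from one known reference (the target locus plus 10 bp flanks):

- **Anchoring.** Each read end's terminal 10-mer is looked up for exact
  matches, sliding inwards one base at a time up to a 10 bp soft-clip
  limit. The exact-match index is a 10-mer hash over the reference — at
  amplicon scale (hundreds of bp) this provides the same lookup contract as
  a suffix array (every exact-match position of a query, N never matching)
  with constant-time queries. Among candidate placements the consistent
  pair spanning the maximal reference distance is chosen; reads with no
  consistent pair are discarded and counted.
- **Extension.** The inter-anchor read segment is aligned to the
  inter-anchor reference by global affine-gap dynamic programming
  (Needleman–Wunsch–Gotoh, in C++ via Rcpp): match +2, mismatch −2, a gap
  of length L costs 4 + 0.5·L. These values are not dictated by the
  procedure's description; they were chosen so that long indels (cheap
  extension) and short ones both beat mismatch chains, while the
  "up to four mismatches" rule is enforced as an explicit post-filter
  rather than through the score. Soft-clipped bases are excluded from
  mismatch counting. On reads whose ends are error-free, the anchored score
  equals an unanchored full-DP oracle (asserted in tests against an
  independent implementation).
- **Normalization.** Indels are left-aligned to their leftmost equivalent
  position (deletions by end-base rotation, insertions by sequence
  rotation), making mate-concordance comparisons well-defined in repeat
  context.
- **Pairing.** Mates must align on opposite strands with the forward mate
  upstream; an event inside the mates' reference overlap must be reported
  identically (kind, position, size) by both, while an event covered by
  only one mate stands on that mate alone.
- **Windowing.** Only pairs overlapping the sgRNA + PAM window by ≥ 20 bp
  contribute; a contributing pair is edited if it carries a retained indel
  intersecting the window. Counting is per *pair* (the generator's truth is
  per molecule); an insertion's footprint is the two reference bases
  flanking its junction. Substitutions are never counted as edits.

The module is fully deterministic. Padding the reference shifts event
coordinates by exactly the padding.

## The synthetic generator

`simulate_cohort()` encodes the statistical structure the cohort analyses
assume: per-arm events on 22 autosomes (approximate human arm lengths,
acrocentric p-arms kept short but present); a triploid baseline so one-copy
arm losses sit exactly at the calling boundary — boundary inclusivity is
exercised by construction, with a documented ±1e−6 epsilon on generated
one-copy ratios so floating-point round trips cannot flap across the
boundary; −8p coupled to +8q on the odds scale (default odds multiplier 4,
marginals 0.35 and 0.30; odds-scale coupling keeps probabilities valid by
construction); purity ~ Beta(5, 2) truncated to [0.1, 1] (right-skewed,
typical of resected tumors); GATA4 focal status following the 8p arm plus a
3% focal-only deletion rate; TP53 loss-of-function mutations at baseline
0.25 with 2.5× odds given GATA4 loss, plus deletion through 17p; latent
infiltration `z = N(0,1) + gata4_effect·[GATA4 lost] +
covariate_effect·[covariate]`, scaling immune-signature gene means by
`exp(0.5 z)`; negative-binomial counts (dispersion 0.2) emitted raw and
log-CPM. Segment means are exact mixtures by default (`seg_noise_sd = 0`)
so calling correctness is separable from noise robustness.

What it does *not* emulate: subclonal copy-number mixtures, focal
breakpoint realism, segmentation noise and probe-level artifacts,
co-expression structure within signatures, batch effects. Passing tests
therefore demonstrate algorithmic correctness under the stated generative
model, not robustness to every artifact of real SNP-array or RNA-seq data.

`simulate_amplicon()` emulates paired 150 bp reads over a 240 bp amplicon:
editing fraction 0.5 at a central cut site, geometric indel sizes
(`1 + Geom(0.3)`), ±2 bp position jitter, 60% deletions, substitution
errors at 0.3%, configurable insert size (inserts below twice the read
length create mate overlap, deliberately exercising the concordance rule).
Truth records each molecule's left-aligned canonical event.

## Problem sizes and reproducibility

The shipped tests and the acceptance script use: a 10,000-point grid for
the purity round trip; 20 seeded cohorts of 400 samples (~200/group) for
the C-Norm confound-removal and effect-preservation checks; exhaustive
enumeration up to 12-gene universes (enrichment) and 15-sample cohorts
(hypergeometric); 200 seeds for the permutation-p uniformity check; and
2,000 read pairs per amplicon condition. These sizes give stable
pass/fail behavior at desk scale while keeping a full run in minutes.
Every stochastic step takes an explicit integer seed, restores the caller's
RNG state, and records the seed in its outputs; workflow manifests record
config hashes, input/output checksums and per-stage timings, and identical
configs reproduce identical result files.

## Known limitations

- Purity correction assumes a clonal tumor copy state; subclonal events
  yield intermediate `c` that under-calls against the triploid thresholds.
- C-Norm balances *measured arm-level* covariates only; focal events and
  unmeasured confounders are untouched, and the removal is random among
  ties, so retained cohorts are one draw from a family of balanced
  subsets.
- The gene-permutation enrichment null ignores inter-gene correlation.
- The amplicon caller requires both terminal 10-mers to anchor within
  10 bp of clipping: indels within ~20 bp of a read end, or amplicons with
  repeated 10-mers at the anchor positions, can reduce sensitivity (the
  generator places cut sites centrally, matching primer design practice).
- Editing fractions are not purity-corrected; for in vivo amplicons the
  reported fraction is a lower bound on the edited-cell fraction.
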