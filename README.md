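# cnakit

Tumor aneuploidy reshapes the immune microenvironment, and cohort-scale
claims about any one lesion — say, deletion of chromosome arm 8p and the
*GATA4* locus it carries — are confounded by everything that travels with
it (most prominently 8q gain, via the isochromosome-8q mechanism). `cnakit`
is an R toolkit for making such claims carefully, plus the sequence-level
tooling needed to validate them with CRISPR experiments. It is aimed at
cancer genomicists working with TCGA-style level-3 data (segmented SNP-array
copy number, purity estimates, expression matrices, MAF mutation calls) and
at anyone quantifying indels in amplicon sequencing.

## What it computes

**Purity-corrected CNA calling.** An observed segment mean is a log2 copy
ratio of a tumor/normal mixture. With tumor purity *p* and observed ratio
*x*, the tumor-intrinsic ratio is

    c = log2( (2^x − (1 − p)) / p )

Calls are made against thresholds for the gain or loss of at least one copy
in a triploid background, i.e. a 33% change: loss when `c ≤ log2(2/3)`,
gain when `c ≥ log2(4/3)`. Arm-level events additionally require ≥ 75% of
the arm affected; fraction genome altered (FGA) and aneuploidy terciles are
derived from the same corrected ratios.

**C-Norm.** An iterative cohort-normalization algorithm that equalizes the
frequencies of all arm-level covariate CNAs between a group of interest
(e.g. GATA4/8p-lost) and its complement: CNAs differing by > 5% in frequency
are flagged as group-enriched, each sample is scored by the number of
own-group-enriched CNAs it carries, and maximum-score samples are removed
at random (seeded) until all non-defining CNAs are near-equivalent — never
removing more than 50% of either group. Group contrasts on the retained
cohort (rank-based tests on immune-signature scores) are then free of the
measured copy-number confounding.

**Co-occurrence statistics.** Exact hypergeometric tail probabilities for
lesion overlap (e.g. GATA4 loss × TP53 loss-of-function, defined as
non-synonymous mutation or copy loss), and anchor-versus-all arm
co-association tables with Benjamini–Hochberg FDR.

**Preranked weighted gene-set enrichment.** The weighted running-sum
(Kolmogorov–Smirnov-like) enrichment statistic over a signed ranked gene
list, with a seeded gene-permutation null, NES, nominal p and FDR q, plus
per-sample signature scores (mean of z-scored member genes).

**CRISPR amplicon indel quantification.** An anchor-and-extend aligner:
read ends are anchored by exact 10-mer lookup (sliding inwards with a 10 bp
soft-clip limit), the inter-anchor segment is aligned by optimal affine-gap
dynamic programming (Rcpp), reads with more than four mismatches are
discarded, indels are left-aligned, paired mates must agree on any event
inside their overlap, and editing is summarized over the sgRNA + PAM window
(≥ 20 bp alignment overlap required).

**Synthetic data.** `simulate_cohort()` and `simulate_amplicon()` generate
every input with recorded ground truth (purity-mixed segment ratios,
coupled arm events, infiltration-scaled expression, error-bearing read
pairs), so the whole pipeline is testable offline.

## Worked example

```r
library(cnakit)

sim       <- simulate_cohort(cohort_sim_config(n_samples = 300, rng_seed = 19))
corrected <- correct_segments(sim$seg, sim$purity)
calls     <- cohort_cna_calls(corrected, genes = sim$genes, arms = sim$arms)
carriers  <- arm_event_matrix(calls$arm_calls)

gata4 <- subset(calls$gene_calls, target == "GATA4")
group <- factor(ifelse(gata4$state[match(rownames(carriers), gata4$sample)] == "loss",
                       "GATA4_loss", "GATA4_wt"), c("GATA4_loss", "GATA4_wt"))
table(group)
#> GATA4_loss   GATA4_wt
#>        105        195

head(pairwise_arm_coassociation(carriers, "8p_loss"), 3)
#>       event   N   K   n  k     p_enrich p_deplete   fdr_enrich fdr_deplete
#> 59  8q_gain 300 100 135 69 2.920087e-09 1.0000000 2.540476e-07           1
#> 44  1p_gain 300 100  42 22 4.790538e-03 0.9982986 2.083884e-01           1
#> 71 14q_gain 300 100  44 21 2.337108e-02 0.9898779 6.777613e-01           1

cn <- run_cnorm(carriers, group, cnorm_config(rng_seed = 1))
cn
#> C-Norm result: 212 samples retained (101 removed), best achievable
#>   max non-defining frequency difference: 0.3187 -> 0.0995 (tol 0.050)

scores <- signature_score_matrix(sim$expression, sim$signatures)
association_after_cnorm(scores, group, cn)
#>      geneset statistic     delta      p_value          fdr
#> 1      CD8_T      6141 0.4596800 1.355568e-05 1.355568e-05
#> 2         NK      6394 0.5202559 6.043700e-07 1.145906e-06
#> 3 Macrophage      6376 0.5076932 7.639376e-07 1.145906e-06
```

+8q is correctly recovered as the top covariate of −8p (it was generated
with a 4× odds coupling); after C-Norm masks 101 covariate-enriched samples
the immune-score contrast between GATA4-lost and wt tumors remains strongly
significant — as it should here, since this cohort was simulated with a
true 1 SD GATA4 effect on infiltration.

The amplicon side:

```r
amp <- simulate_amplicon(amplicon_sim_config(n_pairs = 500, rng_seed = 3))
res <- run_amplicon_pipeline(amp$reads, amp$reference, amp$window)
res$summary
#> Edit summary: 249 edited / 500 contributing pairs (49.8%); 0 excluded by window overlap
head(res$events, 3)
#>         kind pos size supporting_pairs
#> 7   deletion 118    1               27
#> 10 insertion 121    1               13
#> 18  deletion 121    1               10
mean(amp$truth$edited)   # generator truth
#> [1] 0.506
```

End-to-end workflows with run manifests:
`run_cohort_workflow(list(seed = 1), "out/")` and
`run_amplicon_workflow(list(seed = 1), "out_amp/")` (configs may also be
YAML files).

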