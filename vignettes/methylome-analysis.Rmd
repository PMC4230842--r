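---
title: "Comparative methylome analysis with cometh"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative methylome analysis with cometh}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cometh)
```

## The analysis problem

Whole-genome bisulfite sequencing reports, for every cytosine, how many
reads covered it and how many of those reads were methylated. `cometh`
implements the downstream statistics for a comparative study design:
several related plant species, each sampled in two tissues (root, shoot)
under two treatments (control at 23°C, a 23-hour cold shift to 4°C), with
two bisulfite replicates and three RNA-seq replicates per combination.
From per-cytosine counts it calls methylated sites, segments each
methylome into methylated regions (MRs), tests positions and regions for
differential methylation (DMPs, DMRs), classifies cytosines aligned
across three genomes into conservation classes, and fits a factorial
negative-binomial model to expression counts so methylation changes can
be related to expression changes.

Every stage is exercised on synthetic data with known ground truth: the
package's simulators emit exactly the input formats the pipeline reads,
plus the generating truth, so calibration and recovery are measurable.

## Methylation calling

Bisulfite conversion is imperfect. Each library carries unmethylated
phage lambda DNA as a spike-in; the pooled fraction of apparently
methylated spike-in reads is the false methylation rate (FMR), the
sample's conversion-failure probability. `estimate_fmr()` reports the
pooled rate (and, optionally, per-coverage-bin rates for diagnostics;
the pooled value is used for testing, since nothing in the null model
conditions on coverage).

`call_methylated_sites()` tests each cytosine with coverage ≥ 3 against
the null that all its methylated reads arise from conversion failure:
an upper-tail binomial test at rate FMR. The test is one-sided because
conversion failure can only inflate apparent methylation. P-values are
Benjamini–Hochberg adjusted at a configurable level (default 0.05), and
a site must additionally reach a 20% methylation rate in at least one of
the four tissue-treatment combinations — the rate rule suppresses sites
that are statistically non-null only because coverage is very deep.

Two notes on calibration. First, binomial tail p-values at realistic
coverage are strongly discrete (at FMR ≈ 0.5% and coverage ≈ 20 most
null sites have zero methylated reads and p = 1), so the null p-value
distribution is *conservative*, not uniform: the meaningful property,
which the tests assert, is that the empirical CDF never rises above the
diagonal beyond sampling error. Second, replicates are merged before any
downstream analysis (`merge_replicates()`): sites where the two
replicates disagree (two-sided Fisher's exact test with the same
prefilter as DMP calling, BH-adjusted) are removed, remaining counts are
summed, and sites covered in a single replicate are retained — they
cannot be tested for disagreement, and dropping them would discard most
low-coverage data; their number is reported.

## Segmentation into methylated regions

Methylated regions are found with a two-state hidden Markov model over
consecutive covered cytosines: states U (unmethylated) and M
(methylated), and per state one beta-binomial emission distribution per
sequence context (CG, CHG, CHH) — six (α, β) pairs. Plant methylomes
need per-context emissions because CG, CHG and CHH levels differ
strongly even inside one methylated region; a single-distribution model
suits mammalian CG-only methylation but not this data.

The chain runs over cytosine index, not base pairs. To avoid decoding
regions across uncovered genome, the genome is first split wherever 50
or more adjacent base pairs lack a covered cytosine
(`split_segments()`); chromosome boundaries always split. Training is
genome-wide per sample (`train_hmm()`): Baum–Welch with log-space
forward–backward (emission likelihoods floored at 1e-300), and an M-step
that re-normalises expected transition counts and refits each (α, β) by
posterior-weighted maximum likelihood — method-of-moments start, Newton
refinement on the digamma-form score capped at 50 iterations, parameters
clamped to [1e-3, 1e6]. A candidate emission update is accepted only if
it does not lower the expected complete-data likelihood, so the EM trace
is non-decreasing by construction (generalised EM). Decoding is Viterbi
(`decode_mrs()`), the single most probable path; posterior decoding is
available behind a flag. Maximal runs of state M become regions, and
`trim_mr()` then removes boundary cytosines with a methylation rate
below 10% from both ends.

Replicates of each combination are merged before segmentation, so there
is one trained parameter set and one segmentation per tissue-treatment
combination. We train per combination rather than pooling combinations:
parameters are cheap to train, and per-combination training lets the
emission distributions absorb genuine tissue differences in methylation
level rather than forcing a shared compromise.

Initialisation defaults are weakly informative and well separated:
U-state emission means 0.05, M-state 0.7, precision α + β = 10,
transition diagonal 0.9, uniform start. They are configurable; on
well-separated data the EM is insensitive to them. Sites with zero
coverage never enter segments; covered sites below the calling coverage
floor participate in segmentation (the gap rule speaks of covered
positions) but cannot, on their own, satisfy rate-threshold decisions
such as trimming — a boundary site too shallow to demonstrate the
threshold rate is trimmed with its failing neighbours.

## Differential methylation

**Positions.** `call_dmps()` runs a two-sided Fisher's exact test on the
2×2 methylated/unmethylated read-count table at each site covered in
both samples, only for the four sanctioned comparisons that change one
factor (root vs shoot at each temperature; control vs cold in each
tissue), and only at sites whose rate reaches 20% in one of the two
samples — restricting tests is what keeps the multiple-testing burden
(BH within comparison) low.

**Regions.** Candidates are intervals of variable methylation state:
the union of the four combinations' MRs is flattened into disjoint
intervals, and an interval qualifies when at least one sample's MR
covers it, at least one sample's does not, and at least four cytosines
are covered in every sample (`select_dmr_candidates()`; the cytosine
floor is the package's explicit, configurable stand-in for the MR
pre-filtering step whose exact criteria are external to this analysis).
`test_dmr()` fits, per context present, a beta-binomial to each sample's
sites and to the pooled sites by maximum likelihood; the log-odds
statistic is the summed likelihood gain of the separate fits over the
joint fit, and twice it is referred to a chi-squared distribution with
2 degrees of freedom per context per extra group — parameter counting
for the likelihood-ratio analogue, with the conventional factor of two.
`group_and_confirm()` separates samples linked by significant pairwise
tests (p < 0.01) into groups by greedy single-linkage merging of
non-significant pairs — deterministic, and flagged when pairwise
significance is non-transitive — then sums counts within groups and
re-runs the test between combined groups; only the combined-group
(confirmation) p-value enters the FDR. Regions with a Storey q-value
below 0.01 are DMRs; `resolve_overlaps()` finally keeps, among mutually
overlapping DMRs, an exact maximum-weight non-overlapping subset where
the weight is the number of samples participating in significant
pairwise differences (ties: larger region, then leftmost).

`storey_fdr()` estimates the null proportion π0 on the λ-grid
0.05…0.95 with a cubic smoothing spline evaluated at λ = 0.95, clamped
into (0, 1]; with fewer than 100 p-values the estimate is too unstable
and the function falls back to π0 = 1, which reproduces BH exactly.
Site-level corrections use BH throughout; Storey's estimate is reserved
for the region level, where the candidate pre-selection makes a
substantial non-null fraction plausible and π0 < 1 buys real power.

## Cross-species conservation

Aligned cytosine triples enter the comparison only if their context
label agrees in all three species (`match_context()`): CG must be CG
everywhere, and degenerate contexts tolerate H-position substitutions —
which leave the label unchanged — while any substitution to G changes
the label (CHH→CHG, CHG→CG) and excludes the site as a context
transition. `classify_sites()` then labels each kept site that is
testable in all three species: methylated in all three (`conserved3`),
in exactly one (a lineage-specific gain), in exactly two (a
lineage-specific loss in the unmethylated species), or in none. Sites
untestable in any species are tallied separately rather than guessed: a
site must be callable in all three genomes before a gain or loss is
claimed. "Methylated in a species" means called in at least one of the
four tissue-treatment combinations, consistent with the calling rule.

Descriptive statistics follow the same conventions throughout:
`gain_density()` (gains/(gains+losses) in 10-kb windows, undefined
windows omitted), `gene_body_methylation()` (fraction of methylated CG
among testable CG between start and stop codon),
`feature_methylation_rate()` (mean per-site rate over all testable
sites of a context in a feature, zeros included, optionally normalised
to an outgroup), and `annotate_sites()`, which gives every site exactly
one label by the precedence TE > exon > intron > 5′UTR > 3′UTR >
upstream 1 kb > intergenic — transposon methylation is biologically
distinct and should not be absorbed into genic categories; the order is
an explicit, configurable choice. `ortholog_overlap_tests()` tests MR
or DMR sharing at 1:1:1 orthologs: pairwise with the hypergeometric
upper tail over the ortholog universe, and two/three-way against a
permutation null that shuffles each species' region-presence labels
across orthologs (10,000 permutations by default, maxima reported, and
an observed count above the permutation maximum flagged).

## Expression

`rpkm()` and `expressed_filter()` implement the standard quantification
(a gene is expressed at ≥ 3 RPKM in ≥ 3 of the 12 within-species
samples). The differential model is a negative-binomial GLM with log
link and library-size offset under `~ tissue * treatment` within
species (or `~ species * tissue * treatment` across), with per-gene
dispersions supplied. Instead of testing every factor level,
`fit_and_test()` assesses each factor and interaction *term*
simultaneously: a reduced model omitting the term's columns is fitted
and the deviance difference referred to chi-squared with the term's
degrees of freedom — the analysis-of-deviance analogue of a factorial
ANOVA, which keeps the number of tests at one per term. Gene-length
corrections are omitted: RPKM already carries length where it matters
descriptively, and length cancels from within-gene comparisons.

`estimate_dispersion()` maximises the Cox–Reid adjusted profile
likelihood per gene (means refitted once at the interim estimate), then
shrinks the log-dispersion toward a lowess trend on log mean expression,
weighting the gene's own maximiser by its residual degrees of freedom
against a prior weight of 10 pseudo-observations. The floor is 1e-6.
The calibration contract — type-I error near nominal for the deviance
tests, and median dispersion recovery within ±50% at 12 samples — is
what the test suite enforces; the estimator's internals are otherwise
ordinary empirical-Bayes practice.

`methylation_expression_correlation()` reports Spearman coefficients
(midrank ties) between a per-gene differential-methylation summary (DMP
direction, or DMR rate difference) and the matched comparison's log2
fold change, per feature class, with classes under 10 genes reported as
unavailable.

## What the simulators emulate — and what they do not

`simulate_genome()` draws i.i.d. sequence at 36% GC and catalogues every
cytosine's context on both strands. `simulate_methylome()` draws a
hidden U/M path from the Markov chain (restarting per chromosome),
per-site levels from the state- and context-specific betas, Poisson
coverage (mean 20, the study's average strand-specific depth) and
binomial methylated counts; conversion failure is additive false
methylation on the unmethylated fraction (observed rate
level + (1−level)·FMR, FMR default 0.005), spike-in sites are 1/1000 of
the catalogue with level 0, replicates share the hidden truth, and
injected DMRs flip the designated tissue to M-state levels inside the
region with no treatment effect. `simulate_alignment_map()` mutates
H positions with a configurable probability (one third of hits to G)
and emits its own class bookkeeping as the recovery oracle;
`simulate_expression()` draws NB counts under the factorial GLM.

These generators match the model assumptions of the pipeline, which is
precisely what makes recovery measurable — and means passing tests
demonstrate correctness of the implementation, not robustness to real
data. Real methylomes have autocorrelated coverage, context composition
that tracks repeat structure, partially methylated domains not well
described by two states, alignment error, and non-independent sites;
none of that is simulated. Test problem sizes (10–100 kb genomes, 10⁴
null regions, 2000 null genes, 500-gene dispersion panels) were chosen
as the smallest at which the asserted tolerances are comfortably
resolvable.

## Numerical choices and limitations

- All site coordinates are 1-based; all region intervals are 0-based
  half-open (BED convention). Converters are inverse bijections.
- Cytosines are strand-specific throughout; symmetric CG dyads are never
  collapsed.
- Beta-binomial fits: moment start, Newton with step halving, parameters
  clamped to [1e-3, 1e6]; boundary fits flagged. The region test's
  chi-squared reference is an approximation — its realised type-I error
  at nominal 0.05 runs near 0.08 with 10-site regions, which the
  acceptance checks bound at 0.10 — and the Storey-corrected
  confirmation step is what controls the reported DMR FDR.
- The DMR grouping rule is greedy and deterministic; with non-transitive
  pairwise significance several partitions are defensible and the chosen
  one is flagged in the output.
- NB GLM calibration is stated for supplied dispersions (the model the
  test implements); plugging in estimated dispersions adds the usual
  mild anti-conservatism at n = 12.
- `fisher_p()` reproduces `stats::fisher.test`'s two-sided
  point-probability rule including its 1e-7 relative tolerance for
  "as extreme".

## A worked example

```{r example, eval = FALSE}
library(cometh)

g <- simulate_genome(n_chrom = 1, lengths = 50000, seed = 1)
keys <- c(lapply(1:2, function(r) sample_key("crub", "root", "control23", r)),
          lapply(1:2, function(r) sample_key("crub", "shoot", "control23", r)))
sim <- simulate_methylome(g$catalogue, default_hmm_params(0.05, 0.85, 8, 0.97),
                          mean_cov = 20, fmr = 0.005, design = keys,
                          seed = 2)

root <- merge_replicates(sim$tables[[1]], sim$tables[[2]])
fmr <- estimate_fmr(root$spikein)$fmr
calls <- call_methylated_sites(root, fmr)
seg <- segment_methylome(root)
head(seg$mrs[, c("chrom", "start", "end", "n_cg", "rate")])
```
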