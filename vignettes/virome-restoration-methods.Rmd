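---
title: "Methods: virome triage, spike-in quantification and restoration statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: virome triage, spike-in quantification and restoration statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(viroflow)
```

viroflow implements the downstream analysis of faecal virome shotgun
sequencing for three-group intervention designs — an untreated control
group (`Ctr`), a chronically stressed group (`CtrStress`), and a stressed
group receiving a faecal virome transplant (`FVTStress`) — with the
central scientific question being which microbial features are *altered
by stress and restored by the transplant*. This vignette documents the
models, thresholds and numerical choices, and what the synthetic-data
validation does and does not establish.

## Viral contig triage

Assembled contigs (pooled across samples, minimum 3 kbp) are classified
as putatively viral by five independent evidence routes, any one of
which suffices:

1. **Nucleotide homology**: at least 85% of the contig length covered by
   the union of nucleotide database hits with at least 50% identity
   (hits pre-filtered to e ≤ 1e-10). Coverage is computed on merged
   query intervals, so overlapping hits from different databases combine.
2. **Protein homology**: at least 2 distinct ORFs with a protein hit
   (viral RefSeq at e ≤ 1e-10, or PHROGs/iPF HMMs at e ≤ 1e-5), and the
   hit ORFs making up at least 50% of the contig's ORF count. An ORF hit
   by several databases counts once.
3–4. **Stand-alone classifiers**: a positive VirSorter2 or DeepVirFinder
   call, consumed as boolean evidence (producer-side score thresholds
   are upstream of this package).
5. **Circularity**: a circular-contig call (VRCA).

Any rRNA gene hit vetoes the viral call, applied before provirus
refinement. Contigs flagged as proviral in the quality summary are
trimmed to the predicted viral region (`region_end − region_start + 1`,
1-based inclusive) and then re-filtered against the 3 kbp minimum; the
keep rule is inclusive (3000 bp is retained). All thresholds are
compared with a small absolute tolerance (1e-9 on the coverage fraction)
so that exact rational boundaries such as 850/1000 against 0.85 are
classified inclusively regardless of binary floating-point rounding.

For quantitative analysis a viral contig must additionally have
estimated completeness ≥ 50%, at least 1 gene classified viral, and
viral genes making up ≥ 10% of its gene count. A missing completeness
estimate is treated as *unknown* and fails the threshold — the
conservative reading; an absent quality record is never silently
interpreted as passing.

## Redundancy removal

Two contigs are redundant when they share ≥ 90% identity over ≥ 90% of
the shorter contig's length. Because the producing aligner reports
percent identity per HSP, the rule is evaluated as the merged-interval
coverage of the shorter contig by hits that each individually reach 90%
identity, not as a length-weighted mean identity. Removal is a greedy
pass in descending length (ties by ascending id, so equal-length pairs
keep the lexicographically smaller id): a contig is dropped iff it pairs
with a still-retained longer contig. This reproduces "the shortest of
each pair is removed" while guaranteeing a deterministic fixed point —
re-detection among retained contigs finds no qualifying pair, which the
tests assert directly.

## Quantification

Per-contig, per-sample mapped read counts arrive with a *breadth of
coverage* (fraction of positions with depth ≥ 1). Counts with breadth
strictly below 0.75 are set to zero — spurious mappings concentrated in
a small region of a contig should not count as presence. The filter is
idempotent and monotone in the threshold.

Relative abundance divides each count by contig length and by the
sample's total mapped reads, then rescales every sample to sum to 1
(total-sum scaling). The two normalisations differ only by a per-sample
constant, so applying both makes the relative scale well-defined (columns
sum to 1 exactly) without changing any downstream compositional result.

Absolute abundance anchors the relative scale to an exogenous spike:
`abs = rel / rel_spike × spike_amount`. The default spike amount is 1e6
units per sample, the protocol value for a 10 µl spike of 1e8 pfu/ml of
lactococcal phage Q33; because the per-ml versus per-sample unit is a
protocol detail, the amount is a parameter and the output unit is
carried opaquely as "spike units". A sample in which the spike has zero
relative abundance is flagged and its absolute values set to missing,
never silently zeroed.

## Compositional statistics

Count matrices are filtered (bacterial layer: total count across samples
≥ 5; phage layer: detected in ≥ 50% of samples — phages are so
heterogeneously distributed that features absent in about half the
samples mostly generate spurious associations). The "minimal count of 5"
is interpreted as the total across samples; a per-sample reading would
remove nearly everything in sparse virome data. Zeros are then replaced
by the 'const' rule — 0.65 × the smallest positive value in the matrix,
the convention of the compositional workflow family this package
follows; the multiplier is a parameter. The centred log-ratio transform
`clr(x)_ij = ln(x_ij / g_j)` (geometric mean per sample) follows, and
beta-diversity is the Euclidean distance between CLR vectors (Aitchison
distance).

Group differences in beta-diversity are tested by PERMANOVA
(`vegan::adonis2`), reporting `R² = SS_between / SS_total` from the
Gower-centred squared distances and a permutation p-value with the +1
correction, so p is never 0 and never below `1/(n_permutations + 1)`.
Labels are permuted freely (no strata): the designs analysed here are
single-factor and between-subjects at each timepoint. The tests verify
the R² against a brute-force double-loop oracle on small instances
(≤ 8 samples, 1e-10) and calibrate the null rejection rate on 500
simulated null datasets.

Alpha diversity is reported as observed Hill numbers of order q
(richness, exp-Shannon, inverse Simpson) on raw proportions, without
rarefaction or coverage standardisation — a documented divergence from
coverage-based estimators, acceptable here because the synthetic studies
hold library size constant.

## Restoration statistics

The headline per-feature statistic is a planned orthogonal contrast on
the three group means of CLR abundance (or log expression), weighing the
control and transplant groups against the stressed group:

* estimate `L = 0.5·m_Ctr − m_CtrStress + 0.5·m_FVT`,
* `SE = s_pooled · sqrt(Σ w²/n)`, `t = L/SE`, `df = N − 3`, two-sided p.

The weights (+0.5, −1, +0.5) are the symmetric averaging choice; any
positive rescaling leaves t and p unchanged (asserted by test). A
feature is *called* restored at contrast p < 0.05 and BH-FDR q < 0.2.
Note that a feature altered by stress but *not* restored also moves this
contrast (at half magnitude); the Tukey post hocs (Ctr vs Ctr Stress,
Ctr Stress vs FVT Stress, studentized-range adjusted with k = 3 and
df = N − 3 via `ptukey`) are what separate the two patterns, and both
are reported per feature. Post hocs are two-sided by default — the
reported figure-level statistics in this design family are two-sided —
with a one-sided switch that halves the adjusted p.

The cross-sectional model is fixed-effects: the design is
between-subjects at any single timepoint, so a subject-level random
effect has nothing to absorb there.

### Longitudinal variant

With repeated timepoints per animal, the model gains a random intercept
per subject (compound symmetry). For complete designs — every subject
observed once at every timepoint — the variance components have exact
closed forms from the split-plot decomposition: `MS_subject` estimates
`T·σ²_subject + σ²_residual` and the within-subject `MS_residual`
estimates `σ²_residual`, so the variance of a single observation is
estimated by `(MS_subject + (T−1)·MS_residual)/T`. The restoration
contrast is evaluated on the final-timepoint group means with
Satterthwaite degrees of freedom. This closed form was chosen over a
per-feature iterative mixed-model fit for two reasons: it reduces
*exactly* (machine precision) to the cross-sectional contrast when the
within-subject mean square vanishes or T = 1, which is the binding
correctness contract here; and it is fast enough to run calibration
studies of hundreds of replicates. On balanced data the result coincides
with an lme4/emmeans analysis of the same model — a unit test asserts
agreement of estimate, t and degrees of freedom against
`lmerTest::lmer` + `emmeans` on a balanced instance. The cost of the
closed form is the completeness requirement; designs with dropout would
need the iterative fit, which is out of scope.

A per-subject constant offset shifts final-timepoint group means and so
(correctly) shifts the between-subject contrast; what the random
intercept guarantees is that such offsets load on the subject variance
component, not the residual — both properties are under test.

### Supporting procedures

* **Outlier exclusion** (assay endpoints only, never sequencing counts):
  values beyond 2.5 SD from their group mean, single pass, at most 2 per
  test (largest deviations first). In groups of 3 the z-score bound
  `(n−1)/√n ≈ 1.15` makes exclusion impossible, which the tests assert.
* **Variance pre-filter** for transcript matrices: across-sample
  variance below the absolute cut-off 0.5 removes the feature.
* **BH-FDR** via the standard step-up (`p.adjust`), validated against a
  literal step-up oracle on 10,000 random vectors.
* **Hypergeometric enrichment** is the inclusive upper tail from
  `phyper`, validated against pmf summation.

## Association networks

Every (phage, bacterium) pair of CLR features is tested by Pearson
correlation across shared samples (two-sided p from the t transform,
df = n − 2), with BH adjustment across the full pair set and edges
retained at q < 0.1. No pre-selection of pairs is done — the FDR is
controlled over everything tested. Edges are annotated with the deepest
taxonomic rank (family > order > phylum) at which the phage's predicted
host matches the bacterium's taxonomy (case-folded, with a synonym table
for renamed phyla such as Firmicutes/Bacillota), and flagged when both
endpoints independently show a restoration effect at p < 0.05 (strict).
Correlations are computed on CLR abundances rather than model residuals
— the simpler, more reproducible choice where the source analysis is
ambiguous.

## Synthetic data: what it emulates, and what it does not

Two seeded generators make every stage testable without external data.

`simulate_evidence_bundle()` inverts the triage rules: each planted
viral contig receives evidence satisfying exactly one route, negatives
sit strictly below every threshold, and a configurable fraction of
positives sit exactly at a boundary (coverage 0.85, 2 of 4 ORFs,
completeness 50.0, viral-gene fraction 10%, trimmed length 3000 bp).
Additional contigs carry route evidence but are planted to be vetoed by
rRNA hits or by provirus trimming below 3 kbp. Closure — the triage
stage reproducing the planted truth with 100% concordance including
boundaries — is the module's acceptance oracle.

`simulate_count_study()` is a logistic-normal multinomial generator:
Gaussian CLR-scale abundances (baseline per feature, group shifts,
per-subject intercepts, residual noise) are exponentiated, one spike
feature is held at a constant absolute amount, and counts are drawn
multinomially with probability proportional to abundance × length.
Breadth is drawn from a high-breadth component (0.80–1.00) with a 5%
spurious low-breadth component (0.20–0.74) to exercise the filter.
`simulate_clr_study()` generates the Gaussian layer directly and is used
for statistical calibration, where the pooled SD must be exactly the
nominal one.

Default study conditions mirror the emulated design: group sizes
(10, 10, 9); stress effect 1.5 CLR units with random sign; restored
features reverting fully under transplant, stress-only features not;
subject SD 1.0 with within-subject residual SD 0.5 for longitudinal data
(between-animal variation exceeding within-animal temporal variation, as
is typical for faecal microbiota); library size 1e5 reads; spike at 1e6
units taking roughly 1/30 of the reads.

What passing tests establish: the decision logic is exactly faithful to
its rules at and around every boundary; the estimators are calibrated
(null p uniform, PERMANOVA rejection at nominal rate, FDR controlled)
and powered as the noncentral-t closed form predicts under the planted
conditions. What they do not establish: robustness to real-data
pathologies the generators deliberately omit — sequence-content biases,
assembly chimeras, overdispersion beyond the logistic-normal,
phylogenetic correlation among features, incomplete repeated-measures
designs, and batch effects (interplate recalibration is out of scope).

## Problem sizes and numerical conventions

The test and validation suites use: 1,000 random contigs (≤ 10 kbp,
≤ 50 hits) for the coverage oracle; 200-contig evidence bundles; 50
features × 29 samples × 1e5 reads for quantification closure (spike
recovery is summarised by median/mean relative error over entries with
expected reads ≥ 50, the scale at which multinomial noise approaches the
15% band); 500 null datasets × 199 permutations for PERMANOVA
calibration; 5,000 null features for contrast uniformity; 10 replicate
studies of 300 features/30 restored for sensitivity and power; 200
replicates for the longitudinal model; 100 replicates of 50 × 50 layers
for the network. All genomic intervals are 1-based inclusive
(`length = end − start + 1`); readers normalise reversed query intervals
at parse time; every dropped or zeroed record is counted and reported;
all tabular outputs are tab-separated UTF-8 with '.' decimal and a
header row, written at 15 significant digits so round-trips are exact to
1e-12.

## Known limitations

* The longitudinal model requires complete subject × timepoint data.
* Alpha diversity is observed (no coverage standardisation).
* Taxonomy concordance is exact string matching after case-folding and
  synonym substitution; it will miss unlisted renames.
* The spike-anchored absolute scale is only as accurate as the spike's
  own relative quantification; at low spike read counts the ratio
  estimator is noticeably noisy.
* Quantification assumes the upstream mapper reported one record per
  (contig, sample); duplicate records are rejected rather than summed.
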