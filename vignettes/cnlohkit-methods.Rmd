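---
title: "Methods: copy-neutral LOH, somatic tiers, copy number and expression in small tumor cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: copy-neutral LOH, somatic tiers, copy number and expression in small tumor cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and model

`cnlohkit` targets a specific and awkward analysis regime: small paired
tumor-normal cohorts (half a dozen samples) of genomically *stable* tumors,
where the interesting events are not sweeping aneuploidies but a low
mutation burden, a handful of focal gains, and — centrally — copy-neutral
loss of heterozygosity (CN-LOH): regions where germline-heterozygous sites
become effectively homozygous in the tumor while the total copy number
stays diploid. CN-LOH is invisible to copy-number analysis alone and to
naive somatic calling alone; it is the *joint* signature — high tumor
allele fractions at het sites plus a flat log2 ratio — that identifies it.
The pipeline therefore couples five analyses that are usually run in
isolation: two-tier somatic/LOH variant classification, coverage-conditioned
tumor mutation burden (TMB), B-allele-fraction LOH segmentation with
cross-sample intersection, aCGH segmentation with noise-adaptive status
calling, and rank-normalized differential expression.

## Two-tier variant classification

Each variant carries tumor and normal ref/alt read counts. The somatic
evidence statistic is the one-sided Fisher exact p on the 2x2 table
`[[tumor_alt, tumor_ref], [normal_alt, normal_ref]]`, i.e. the
hypergeometric upper tail of `tumor_alt` given the margins — the convention
of paired tumor-normal callers. Two tiers are called:

* **somatic-only** (tier 1): tumor depth >= 6, normal depth >= 8, tumor
  VAF >= 0.10, somatic p < 0.05, and normal VAF < 0.05. The normal-VAF
  ceiling operationalizes "no germline evidence"; 0.05 is this package's
  default and is configurable, as the concept has no canonical numeric
  value. The depth pair (6, 8) follows the common caller convention of a
  lower tumor minimum and a stricter normal minimum.
* **LOH-related** (tier 2): tumor VAF strictly above normal VAF, somatic
  p < 0.001, and coding location. This recovers germline-het sites swept
  to high VAF by an LOH event; they fail tier 1 (the normal is het) but
  are biologically informative. A variant satisfying both tiers is
  recorded as somatic-only.

Known polymorphisms (population AF >= 1%) are flagged rather than dropped;
a second flag marks variants that are possibly/probably damaging *or* have
no available prediction and are not polymorphisms — the follow-up set. No
multiple-testing correction is applied at the variant level: the tiers are
fixed operating points, not discovery thresholds.

TMB is the count of non-synonymous somatic-only calls (missense, stop
gain/loss, frameshift, in-frame indel, splice) inside the callable coding
region, divided by callable megabases, where callable means tumor depth
>= 6 and normal depth >= 8. Estimates over less than 0.1 callable Mb are
refused rather than returned. Group comparisons of TMB use an unpaired
t-test (Welch by default, pooled by flag); two zero-variance groups
degenerate to p = 1 (equal means) or p = 0 with a warning.

## LOH segmentation and the common region

No standard exists for calling LOH from exome allele fractions, so the
package defines an explicit, parameterized procedure. Informative sites
are germline hets: normal VAF in [0.3, 0.7] at normal depth >= 8. A site
carries LOH evidence when its tumor VAF deviates to either tail
(>= 0.75 or <= 0.25). Segments are maximal runs of informative sites that
start and end at evidence sites, tolerate at most 2 consecutive
non-evidence sites, break at gaps > 2 Mb, and must contain >= 10 sites
with an evidence fraction >= 0.8. The miss-run tolerance keeps a single
discordant site (sequencing error, subclonal site) from shattering an
11-Mb block, while the alternating-evidence worst case (fraction 0.5)
still reports nothing.

The cohort common region is found by a boundary sweep: the longest
interval covered by LOH segments of at least `min_samples` distinct
samples, then intersected with the contributing samples' segments — so the
reported region is contained in every contributing sample's LOH call. The
pipeline default `min_samples = n - 1` reflects the motivating use case,
where one sample of six is the expected outlier.

Integration with copy number is deliberately conservative: an LOH segment
is copy-neutral only if *every* overlapping copy-number segment has
|mean log2| < 0.3, and on mixed overlaps loss takes precedence over gain
over neutral. The 0.3 band sits well below the |1.0| aberration threshold
while tolerating probe-level noise. Tumor purity is assumed high (the
targeted tumors show VAFs near 0.9); no purity correction is applied in
analysis, though the simulator can attenuate VAFs to emulate impure
samples.

## aCGH segmentation and status calling

Profiles are segmented by circular binary segmentation: recursively, the
arc `(i, j]` maximizing the pooled-variance two-sample t statistic between
arc and complement is found exhaustively (ties to the leftmost arc), and
the split is accepted when its permutation p — from up to 1000
permutations of probe order within the segment — is below alpha = 0.01,
with both parts keeping >= 3 probes. Defaults mirror the canonical CBS
implementation's. A merge pass then joins adjacent segments whose means
differ by less than `2*sigma/sqrt(h)`, `h` the harmonic mean of their
probe counts.

Numerically, the search exploits an identity: for a fixed multiset of
values, `t^2 = (n-2) D / (SS_tot - D)` where `D` is the between-group sum
of squares of the split and `SS_tot` the total sum of squares, which is
permutation-invariant. Maximizing or thresholding t therefore reduces to
prefix sums of the (permuted) values, and the permutation loop can abort a
scan at the first arc reaching the observed statistic and stop entirely
once the exceedance count already exceeds `alpha * n_perm`. These are pure
re-expressions: decisions and p-values are identical to the direct
formula. Zero within-group variance with distinct means maps to t =
infinity, which makes noise-free piecewise-constant profiles reconstruct
exactly (an invariant in the test suite). All of this is deterministic
under a fixed seed, with permutations driven by R's RNG.

The profile's internal noise is the median absolute difference of
consecutive probes within chromosomes, scaled by `sqrt(2) * 0.6745` — a
derivative-based robust sigma that a step change barely perturbs. Status
calling adapts to it: gain/loss when |segment mean| exceeds
`max(0.2, 3*sigma)`. Separately, and *not* adaptively, segments are
flagged aberrant at |mean log2| > 1 and amplified at mean log2 > 2.3
(about five-fold, since `2^2.3 = 4.9`); recurrence analysis counts a gene
as sharing a gain when >= 1 bp of its interval overlaps a segment above
the aberrant threshold, and reports genes shared by >= 3 samples with the
mean over sharing samples only.

## Rank-normalized expression and GSEA

Cross-dataset comparisons (tumor cohort vs external normal tissue) are
dominated by batch effects, so expression values are reduced to in-sample
ranks: `(rank - 1)/(N - 1)`, average ties — invariant under any strictly
monotone per-sample distortion. The fold change reported per gene is the
log2 ratio of group means of these rank-normalized values (with
`eps = 1/(2N)` added only when a mean is exactly zero), which makes the
printed numbers directly interpretable as rank-position ratios.

The per-gene test is a pooled-variance two-sample t on the normalized
values. Two alternatives are provided, and the choice is worth explaining.
An exact rank-sum test at group sizes 6 vs 5 has a smallest achievable
two-sided p of `2/choose(11,5) = 0.0043`; after Benjamini-Hochberg over a
genome-scale matrix no gene can reach adjusted significance, so rank-sum
is structurally unusable here (it remains available for larger designs).
Welch's t is available too, but when one group saturates near a rank
extreme its variance collapses and the Satterthwaite df degrades to about
`n_other - 1`, costing real power at these sizes; after rank
normalization every sample shares the same marginal distribution, so the
pooled estimator is well calibrated and is the default. BH adjustment and
the significance rule |log2 FC| > 1 with padj < 0.05 follow.

Preranked GSEA uses the standard weighted running sum (hit increments
`|score|^p` normalized over the set, miss decrements `1/(N-k)`; ES is the
signed maximum deviation). The null permutes gene labels rather than
phenotypes — with 6 vs 5 samples there are too few phenotype permutations
to be useful. NES divides ES by the mean |null ES| of matching sign, and
FDR q follows the pooled positive/negative-null procedure. The pipeline's
ranking metric is signed `-log10(p)`.

# The synthetic cohort and what it does (not) show

The generator emits every input the pipeline reads — paired variant
tables, coverage BEDs, probe tables, an expression matrix with groups,
gene sets, gene annotation, a manifest — plus a machine-readable truth
set, deterministically (byte-identical) for a fixed seed. Defaults are the
study conditions the package is designed around:

| parameter | default | meaning |
|---|---|---|
| `n_samples` | 6 | tumor-normal pairs |
| `genome` | one 100-Mb chromosome "19" | analysis genome |
| `cnloh_region` | 373916-11465316 | planted telomeric ~11-Mb CN-LOH |
| `cnloh_fraction` | 5/6 | carriers of the CN-LOH block |
| `cnloh_tumor_vaf` | 0.95 | retained-allele VAF (residual normal reads) |
| `somatic_rate_per_mb` | 5.5 | Poisson rate over coding Mb |
| `somatic_vaf_inside/outside` | 0.88 / 0.45 | somatic VAF in/outside the block |
| `read_depth_tumor/normal` | 80 / 80 | Poisson-distributed site depths |
| `het_snp_density_per_mb` | 20 | cohort-shared germline het panel |
| `exon_width`, `exon_spacing` | 2 kb / 20 kb | coding model: 10 Mb callable |
| `probe_spacing_bp`, `probe_noise_sd` | 100 kb / 0.1 | aCGH array model |
| `gains` | log2 2.33 x3 carriers, 1.5 x3, 1.5 x2 | planted focal gains |
| `expr_n_genes`, `expr_n_de` | 2000 / 20 | expression matrix, planted DE |
| `expr_effect_size_sd` | 3 | DE shift, in between-gene SDs |
| `expr_group_sizes` | 6 vs 5 | tumor vs control groups |
| `purity` | 1.0 | attenuates tumor VAFs toward 0.5 when < 1 |

Design notes on choices that were genuinely open:

* **Shared het panel.** Het SNP positions are drawn once per cohort and
  shared across samples, emulating a common-polymorphism panel rather than
  private germline variation. This is what makes tier-2 recurrence
  reproduce the qualitative signature of a real CN-LOH region: the same
  panel genes recurrently "altered" in all carriers.
* **Haplotype orientation.** At each het site inside a carrier's CN-LOH
  block the retained allele is chosen at random (alleles are unphased), so
  tumor VAFs land near 0.95 or 0.05; the evidence rule is two-tailed for
  exactly this reason.
* **Mid-range DE baselines.** Planted DE genes draw their baseline from
  the middle of the log-expression distribution. This is a property of
  rank normalization, not a convenience: a gene already at the extreme of
  the baseline distribution *cannot* move further in rank, so a shift
  planted on it would emulate no observable regulation. Conversely this is
  a real limitation to remember in analysis — rank methods are blind to
  further up-regulation of already-top-ranked genes.
* **Effect size in between-gene SDs.** The planted shift is
  `3 * expr_baseline_sd` on the log scale, i.e. "strong" regulation that
  moves a mid-ranked gene to a rank extreme, mirroring marker genes whose
  rank-normalized means move e.g. from 0.95 to 0.50. A shift measured in
  within-gene noise SDs (0.25 log units) would move ranks by a few percent
  and be undetectable by *any* test after genome-wide correction at these
  group sizes.

What passing recovery tests show: the pipeline's statistics recover planted
events of realistic magnitude from binomial/Gaussian sampling noise at
realistic depths, deterministically and without parameter tuning. What
they do not show: robustness to features the generator does not emulate —
subclonal structure and low purity, GC/wave artifacts on arrays,
mapping-driven allelic bias, germline structural variation, batch effects
beyond monotone per-sample distortions, or realistic mutational signatures.
Conclusions about real data should lean on the parameter exposure (every
threshold above is an argument) rather than on the defaults being optimal.

# Problem sizes and determinism in the test suite

The unit suite runs the pipeline end to end on a reduced cohort (4
samples, 20-Mb genome) and keeps oracle comparisons exhaustive only where
that is cheap: every 2x2 Fisher table with margins <= 40, all-splits CBS
search on profiles up to 200 probes, all 3-of-10 GSEA sets, 100 random
BH vectors. The acceptance tests run 20 full-default cohorts (seeds 1-20)
and require the planted CN-LOH block recovered at Jaccard >= 0.9 in at
least 18, planted recurrent gains recovered exactly in all, and pooled TMB
within 3 standard errors of the planted Poisson rate. All stochastic
stages are seed-pinned and asserted bit-reproducible.

# Known limitations

* LOH calling assumes near-pure tumors; at purity well below ~0.8 the
  tumor VAF separation shrinks and the fixed 0.75 evidence threshold loses
  sensitivity. No purity/ploidy estimation is attempted.
* No allele-specific copy number: CN-LOH is inferred from the neutral-band
  overlap, not from major/minor allele counts.
* The CBS arc search is exhaustive (O(n^2) per scan); profiles far beyond
  ~10^4 probes per chromosome will be slow and would warrant the usual
  windowed-scan refinements.
* GSEA FDR uses the gene-permutation pooled-null convention; with few sets
  the q estimates are coarse.
* The VCF reader is a convenience for AD-style counts only; annotation
  fields are expected via the TSV dialect.
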