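---
title: "Methods: cfDNA fragmentomics and mutant-read integration for glioma liquid biopsies"
author: "gliofrag"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cfDNA fragmentomics and mutant-read integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gliofrag)
```

## The problem

Glioma sheds very little DNA into accessible body fluids. Two complementary
signals can nonetheless be recovered from liquid biopsies:

1. **Mutant-read integration.** Sequencing a patient-specific panel of
   hundreds to thousands of tumor-identified mutations at high depth and
   pooling the mutant and informative (error-suppressed, locus-covering)
   reads across all loci yields an integrated mutant allele fraction (IMAF)
   sensitive well below the per-locus detection limit.
2. **Fragmentomics.** Tumor-derived cfDNA fragments are shorter than
   background cfDNA, and urine cfDNA of glioma patients is globally more
   fragmented than that of healthy donors or patients with non-malignant CNS
   disease. Summaries of the fragment-length distribution from shallow WGS
   (sWGS) — 30-bp bin proportions and the amplitude of the ~10 bp
   nucleosomal oscillation — feed a supervised classifier without any need
   for tumor tissue.

The cohorts these analyses were developed on are controlled-access, so the
package pairs every analysis stage with a calibrated synthetic generator:
all statistical machinery is exercised end-to-end on data whose ground truth
is known.

## The synthetic size model

Fragment lengths are modelled on integer bp in [20, 500] as a two-component
mixture: a sub-nucleosomal component (discretised lognormal; median
`short_mu` = 70 bp, log-sd `short_sigma` = 0.35) and a mononucleosomal
component (discretised normal; `mono_mu` = 167 bp, `mono_sigma` = 20 bp —
the nucleosome-protected mode of cfDNA). The support extends beyond the
30–300 bp feature range so that length-range filters have something to
filter. Within the 50–140 bp window the mixture is multiplied by
$1 + a\cos\!\big(2\pi (s-\varphi)/T\big)$ and renormalised, injecting the
~10 bp periodicity; the period defaults to $T = 10.4$ bp and the phase to
$\varphi = 59.7$ bp, the least-squares fit of the crest grid to the
canonical averaged maxima positions (58, 69, 80, 92, 102, 112, 122, 134).
A single-period cosine cannot reproduce the slightly irregular ~10.9 bp
average spacing of those canonical positions exactly, so detected crests of
the synthetic model sit within about 1 bp of the cosine crest grid rather
than on the canonical list itself. Urine presets carry amplitude $a = 0.25$
(oscillations are most pronounced in urine); plasma and CSF presets carry
0.12/0.08.

**Calibration.** Each group preset (`healthy_urine` 137 bp, `cns_urine`
108 bp, `glioma_urine` 101 bp, and the mutant/non-mutant fluid presets
148/169, 160/169, 101/133 bp) is calibrated by bisection on the
short-component weight `w_short` only, holding all shapes fixed, until the
*exact pmf median* (no sampling) hits the target within 1 bp. This is
deterministic and is re-verified analytically in the test suite. The
other-CNS urine median is quoted as 108 bp in one place and 121 bp in
another in the source cohort's reporting; the preset defaults to 108 bp and
`calibrate_preset()` accepts any target, so both are reachable.

**Between-subject variability.** Within a simulated cohort each patient's
model jitters `w_short` by a truncated normal with sd 0.03. This value was
fixed a priori: it makes neighbouring groups (glioma 101 bp vs other-CNS
108 bp, a 7 bp gap) overlap to roughly the degree implied by the weak
rank-sum separation of those groups in real urine cohorts, while keeping
glioma vs healthy clearly separated. Samples default to 2×10^4 fragments.

**What the generator does not emulate.** All group differences are carried
by one latent weight, so between-group distributional distances are
compressed relative to real cohorts: the sup-norm between simulated group
median ECDFs is ~0.1, far below the ~0.48 measured between real glioma and
healthy urine. Real-data KS distances, detection-rate tables and cluster
purities are therefore *not* reproduction targets; passing tests demonstrate
the correctness and calibration of the machinery, not biological realism of
GC content, end motifs, capture bias against sub-100 bp fragments, or
copy-number structure (all deliberately out of scope).

## Fragment extraction

`extract_fragment_lengths()` counts each sequenced template once — only the
leftmost mate (positive template length, TLEN) contributes |TLEN| — after
dropping unpaired, unmapped, secondary, supplementary and duplicate records,
requiring the proper-pair flag, and applying a mapping-quality cutoff
(default MAPQ ≥ 30; pipelines say only "low mapping quality", so this is a
configurable choice). Down-sampling to a fixed fragment count (10^7 in the
sWGS protocol) is "when necessary": samples at or below the target pass
through unchanged. Whether the 10-million figure counts read records or
templates is ambiguous in the protocol wording; the package down-samples
*templates* (fragments), which is the quantity every downstream statistic
consumes.

## Size-profile statistics and the 10 features

Histogram heights are `count(x) / total fragments` — the denominator is the
whole sample even on a truncated grid, so heights are depth-invariant.
The nine bin proportions use inclusive printed bounds 30–60, 61–90, …,
271–300 (one source line prints "210–240"; the package treats that as a
typo for 211–240, consistent with the neighbouring bins), and they
partition P(30–300) exactly — an identity asserted in the tests. Sample
medians use the standard midpoint convention for even counts.

Local maxima/minima in the 50–140 bp window are positions strictly largest/
smallest within ±2 bp; ties are resolved to the leftmost plateau position,
and a constant stretch has no extrema (strictness). `OSC_10bp` is the sum
of heights at the eight canonical maxima minus the sum at the eight
canonical minima, using the *fixed* canonical positions by default — the
positions were averaged across samples once and then applied uniformly.
`average_positions()` re-derives positions from samples with clear peaks
(operationalised as ≥ 8 detected maxima in the window, a package choice)
when recomputation is wanted.

The two-sample KS distance is computed directly as the sup over pooled
observed values of $|F_a-F_b|$ (checked against an exhaustive oracle and
against `stats::ks.test`); the reported p-value is the asymptotic formula
and is informational only. Rank-sum comparisons delegate to
`stats::wilcox.test` (exact for small tie-free samples, tie-corrected
normal approximation otherwise).

## IMAF with blacklisting and outlier suppression

Loci showing signal (≥ 1 mutant read — "signal" is not pinned down in the
source protocols, this is the package's operationalisation) in > 10% of
control samples, or a mean control allele fraction > 1%, are blacklisted.
The IMAF of a sample is the pooled ratio $\sum_i m_i / \sum_i n_i$ — the
depth-weighted mean allele fraction — over loci that survive, in order:

1. the blacklist;
2. the per-locus cap AF < 0.25 (higher fractions in body fluids are
   implausible and usually mis-genotyped SNPs; the order of steps 1 and 2 is
   immaterial as the criteria are disjoint);
3. iterative binomial outlier suppression: each locus is scored with the
   exact upper tail $P(X \ge m_i \mid n_i, \mathrm{IMAF})$ and excluded when
   the Bonferroni-corrected p-value (multiplier = number of loci entering
   this stage) falls below 0.05, then IMAF is recomputed — to a fixpoint
   with at most 10 passes. The one-pass reading of the procedure is
   available via `max_iter = 1`; the fixpoint is the default because a
   single very large outlier can mask smaller ones. Zero-mutant loci can
   never be excluded (their tail probability is 1).

Detection uses a deliberately simple pooled one-sided exact binomial test of
$\sum m$ against the depth-weighted mean of the per-locus background error
rates (which are inputs, not estimated). It is labelled
`method = "pooled-binomial"` everywhere: it is *not* the likelihood-ratio
machinery of full INVAR, and its calls are not presented as reproductions
of the original per-patient detection table. Its type-I error is verified
by simulation (≤ 5% at tf = 0, up to binomial noise).

## Grouped repeated cross-validation

93-sample cohorts contain repeated patients (baseline + follow-up), so the
5-fold × 10-repeat scheme assigns *patients*, stratified by patient-level
class, to outer folds; all samples of a patient land on the same side of
every split. The phrasing "baseline and follow-up samples of the same
patient were randomly distributed in the training set or in the test set"
is interpreted as this co-assignment (it prevents leakage);
`cv_scheme(group_samples = FALSE)` gives the literal independent assignment
for comparison. Features are z-scored with training-fold statistics only.
Hyperparameters — unstated in the source protocol — use small fixed grids
tuned on grouped stratified inner 5-fold AUC: elastic-net mixing
α ∈ {0.2, 0.5, 0.8} with a 12-point λ grid (GLMEN), mtry ∈ {2, 3} at 300
trees (RF), radial-kernel cost ∈ {0.1, 1, 10} (SVM); plain logistic
regression has none. Threshold metrics use a fixed 0.5 cutoff (no threshold
is stated in the source). AUC is Mann–Whitney pair counting with half-credit
ties, verified against an exhaustive oracle. k-means (k = 2) uses
k-means++ seeding with 10 restarts over Lloyd iterations on z-scored
features (base R has no k-means++ initialiser, so the seeding is written
here). Every random draw derives from a master seed via a stable string
hash, so whole experiments are bit-reproducible.

## Problem sizes used in the shipped runs

The test suite and analysis scripts run at desk scale, chosen as the
smallest sizes at which each statistical check is decisive: 2×10^5 draws for
preset-median checks (sampled-median sd ≈ 0.2–0.3 bp, comfortably inside
the ±2 bp bands), 5,000 loci at depth 600 for IMAF recovery across
tf ∈ {10⁻⁴, 10⁻³, 10⁻²}, 500 replicates of 200-locus tables for the
false-detection rate, and 93-sample cohorts with 2×10^4 fragments per
sample for the classification experiments (50 CV iterations per family).

## Worked example

```{r example, eval = FALSE}
library(gliofrag)

# calibrated presets and a sample
healthy <- calibrate_preset("healthy_urine")
model_median(healthy$model)                       # 137
s <- sample_fragments(healthy, 2e5, seed = 7)
median_size(s)                                    # 137 +/- 2

# a synthetic cohort and the 10-feature classifier
cohort <- simulate_cohort(cohort_spec(list(
  list(preset = "healthy_urine", n = 26),
  list(preset = "cns_urine", n = 27),
  list(preset = "glioma_urine", n = 35, followups = 5)),
  master_seed = 1))
fm <- feature_matrix(cohort$samples, cohort$labels)
cv <- run_experiment(fm, scheme = cv_scheme(seed = 3))
sapply(cv, function(r) median(r$auc))             # ~0.8-0.9 per family

# IMAF on a synthetic locus table
tab <- simulate_locus_table(locus_sim_spec(5000, 600, 1e-3,
                                           error_rates = c(other = 1e-5),
                                           seed = 11))
compute_imaf(tab$loci)                            # IMAF ~1e-3
```

## Known limitations

* One latent weight per group compresses distributional distances; do not
  read simulated KS distances or cluster purities as forecasts for real
  cohorts.
* The cosine oscillation is strictly periodic; real crest spacing drifts.
* The detection rule is a simple pooled binomial test, intentionally weaker
  than a full likelihood-ratio integration over error classes and fragment
  sizes.
* Trinucleotide error rates are inputs; estimating them from raw sequencing
  is out of scope, as are UMI consensus building, alignment and variant
  calling themselves (their outputs are the package's inputs).
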