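# gliofrag

Fragmentomics and tumor-guided mutant-read integration for glioma liquid
biopsies (urine, plasma, CSF), with a calibrated synthetic cohort generator
so the whole pipeline runs and is tested without controlled-access data.

Glioma sheds minute amounts of DNA into body fluids. This package implements
the two analysis tracks used to recover that signal:

**1. Integrated mutant allele fraction (IMAF).** Given per-locus counts of
mutant reads $m_i$ and informative (error-suppressed, locus-covering) reads
$n_i$ over a patient-specific mutation panel, the tumor fraction estimate is
the pooled ratio

$$\mathrm{IMAF} = \frac{\sum_i m_i}{\sum_i n_i}$$

over loci that survive (i) control-based blacklisting (signal in > 10% of
control samples or mean control allele fraction > 1%), (ii) a per-locus cap
AF < 0.25, and (iii) iterative binomial outlier suppression: exclude loci
with Bonferroni-corrected exact tail probability
$P(X \ge m_i \mid n_i, \mathrm{IMAF}) \cdot L < 0.05$ and recompute to a
fixpoint. Detection is a pooled one-sided exact binomial test against the
depth-weighted mean background error rate (labelled `pooled-binomial`; a
deliberate simplification of full likelihood-based integration). Upstream
of IMAF, tissue variant calls are filtered (PHRED ≥ 30, ≥ 4 mutant reads
with both strands represented, 0 germline mutant reads at ≥ 10×) and
classified as shared / private / merged-only across tumor subparts.

**2. Fragmentation features from shallow WGS.** Fragment lengths are
extracted one-per-template from paired-end alignments (duplicates,
supplementary/secondary records and low-MAPQ reads removed). Each sample is
summarised by 10 features: the nine bin proportions P(30–60), P(61–90), …,
P(271–300) and the 10-bp oscillation amplitude

$$\mathrm{OSC_{10bp}} = \sum_{x \in \mathrm{maxima}} h(x) -
\sum_{x \in \mathrm{minima}} h(x),$$

with $h(x)$ the fraction of fragments of length $x$ and canonical
maxima/minima at 58, 69, 80, 92, 102, 112, 122, 134 / 62, 73, 84, 96, 106,
116, 126, 137 bp in the 50–140 bp window. Cancer vs control classification
uses grouped (patient-level), stratified 5-fold × 10-repeat
cross-validation — 50 test folds — over four model families (LR, RF, SVM,
elastic-net GLM), plus single-feature AUCs, PCA and k-means (k = 2).

The synthetic generator draws fragment lengths from a discrete
short-fragment + mononucleosomal mixture with cosine 10-bp modulation,
calibrated by bisection so each group preset's exact pmf median matches its
published cohort median (healthy urine 137 bp, other-CNS urine 108 bp,
glioma urine 101 bp; mutant/non-mutant: CSF 148/169, plasma 160/169, urine
101/133 bp), and simulates locus tables with known tumor fraction,
background error rates and per-read fragment sizes.

## Worked example

The numbered scripts under `analysis/` run the whole workflow; stage by
stage:

```sh
Rscript analysis/01_simulate_cohort.R     # 93-sample urine cohort
Rscript analysis/02_size_profiles.R       # medians, ECDFs, KS, P(30-60)
Rscript analysis/03_classification.R      # 10 features, 4 models, 50-fold CV
Rscript analysis/04_mutant_integration.R  # IMAF per fluid, size split
```

Stage 3 prints, for the simulated cohort (40 cancer / 53 control samples):

```
Grouped repeated-CV summary (50 iterations per family):
 family median_auc    auc_lo auc_hi median_accuracy
     LR  0.8768939 0.6883117      1       0.7894737
     RF  0.8961039 0.7142857      1       0.8333333
    SVM  0.9090909 0.7285714      1       0.7894737
  GLMEN  0.9000000 0.7142857      1       0.7836257
```

i.e. every family separates simulated glioma from control urine with median
AUC ≈ 0.88–0.91 while never letting a patient straddle a train/test
boundary. Stage 4 prints the IMAF recovery per fluid:

```
  fluid true_tf     imaf retained_loci excluded_loci detected detection_p
    csf 6.4e-03 6.34e-03          4999             1     TRUE    0.00e+00
 plasma 3.1e-05 4.30e-05          5000             0     TRUE    8.25e-41
  urine 4.7e-05 5.97e-05          4999             1     TRUE    2.10e-76
 mutant_median_bp nonmutant_median_bp
              147                 169
              156                 169
              105                 132
```

— the pooled estimator recovers tumor fractions spanning two orders of
magnitude at 5,000 loci × depth 600, and the mutant/non-mutant size split
reproduces the calibrated medians (CSF 148/169, urine 101/133 bp).

In R directly:

```r
library(gliofrag)
healthy <- calibrate_preset("healthy_urine")
model_median(healthy$model)
#> [1] 137
s <- sample_fragments(healthy, 2e5, seed = 7)
median_size(s)
#> [1] 136
feature_vector(s)[c("P30_60", "OSC_10bp")]
#>   P30_60 OSC_10bp 
#> 0.160885 0.013555
```

See `vignettes/glioma-fragmentomics-methods.Rmd` for the model, parameter
choices and limitations.

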