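---
title: "Methods: cryptic-exon stratification, ordinal stage prediction and screen scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cryptic-exon stratification, ordinal stage prediction and screen scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

This vignette documents the models, numerical choices and limitations
behind `driadce`. The package implements a transcriptome-based
precision-medicine workflow for Alzheimer's disease (AD): patients are
stratified by cryptic-exon (CE) expression as a proxy for TDP-43
pathology, and candidate gene sets are scored by how well they predict
Braak disease stage, relative to random gene sets of the same size. Two
companion analyses — interferon-stimulated-gene (ISG) enrichment and
pooled CRISPR rescue-screen scoring — round out the workflow. A synthetic
data generator supplies cohorts and screens with the statistical
structure every stage assumes, so the full pipeline is testable offline.

## 1. Cryptic-exon stratification

Loss of nuclear TDP-43 derepresses cryptic exons in STMN2 and UNC13A
pre-mRNA. Three transcripts serve as a transcriptomic proxy for TDP-43
pathology: STMN2-short (premature polyadenylation after exon 2a,
hg38 chr8:79,616,822–79,617,048), UNC13A-CE1
(chr19:17,642,414–17,642,541) and UNC13A-CE2
(chr19:17,642,414–17,642,591); both UNC13A CEs sit between canonical
exons 20 and 21. Coordinates are stored 1-based inclusive and converted
to BED's 0-based half-open convention only at serialisation
(`write_ce_bed()`), so the annotated numbers stay greppable in the code.

A CE is called **present** when its abundance strictly exceeds its
threshold: 1.3 TPM (STMN2-short), 0.09 (UNC13A-CE1), 0.08 (UNC13A-CE2).
Strict `>` is the documented default because the thresholds are defined
as exceedances; `call_ce_presence(strict = FALSE)` switches to `>=`. A
sample expressing **two or all three** CEs is predicted TDP-43
pathology-positive; one or none, negative. Missing abundances are
treated as absent with a warning rather than dropping the sample, since
a missing CE quantification is most often a zero.

### Threshold suggestion from abundance histograms

The fixed thresholds were defined as lying "above the lowest non-zero
peak" of the abundance histogram. `suggest_threshold()` operationalises
that verbal rule: non-zero abundances are binned on the log10 scale (50
equal-width bins by default), counts are smoothed with a zero-padded
3-bin moving average, and candidate peaks (strict local maxima, plateaus
resolved to their leftmost bin) are filtered in two ways that the verbal
description leaves open but that sparse histograms require:

* a **height floor** of `max(1.2, tallest smoothed bin / 3)` discards
  one- or two-count blips in sparse tails, which would otherwise be
  "first peaks";
* a **prominence merge**: adjacent candidate peaks whose intervening dip
  stays above half the lower peak are treated as sampling wiggles on the
  flank of a single mode and merged (keeping the taller). A genuine
  between-component valley in a zero-inflated mixture drops essentially
  to zero, so it always survives this merge.

The returned threshold is the abundance at the minimum-count bin between
the first two accepted peaks. With fewer than two accepted peaks the
distribution is treated as unimodal and the maximum non-zero value
× 1.01 is returned with a warning, so that every sample is called
absent — the conservative choice. Fewer than 20 non-zero values is an
error recommending the fixed defaults. On the default synthetic
conditions the suggested thresholds classify ≥ 95% of samples
identically to the planted expression indicator (tested).

## 2. Ordinal stage model and leave-pair-out evaluation

Braak stages 1–6 collapse to three ordered severity classes A (1–2),
B (3–4), C (5–6). Stage is predicted from a gene-set-restricted
expression matrix with a **cumulative-logit (proportional-odds) model
with an L2 penalty** on the gene weights:

$$ P(y \le k \mid x) = \mathrm{logistic}(\theta_k - x^\top w), \qquad
\min_{w,\theta} \; -\ell(w, \theta) + \tfrac{\lambda}{2}\lVert w \rVert^2 $$

The thresholds $\theta_1 \le \theta_2$ are unpenalised. The
cumulative-logit form is our chosen realisation of "ordinal ridge
regression"; an all-thresholds margin formulation would also fit that
name, so numeric agreement with other implementations is not guaranteed,
but ranking behaviour (all that the evaluation uses) is robust to this
choice. Features are standardised to training mean 0 / sd 1, recomputed
inside **every** cross-validation fold so no test-sample statistics leak
into training — the conservative choice where a global standardisation
would also be defensible.

The penalised negative log-likelihood is convex (the logistic CDF is
log-concave), so the fitter uses damped Newton iterations with analytic
gradient and Hessian, halving steps that would violate the threshold
ordering or increase the objective. Convergence requires gradient
max-norm ≤ 1e-8 or a Newton decrement below 1e-12 (the objective's
floating-point floor; the raw gradient can retain numeric dust of order
1e-8 at the optimum). Non-convergence is an error carrying the final
gradient norm. λ defaults to 1.0 on standardised features; no inner
tuning loop is performed, since the evaluation compares gene sets at a
fixed λ and any common value cancels in the comparison.

**Leave-pair-out cross-validation (LPOCV).** Every sample is paired with
its closest age match among samples of *other* stage classes; ties in
the age gap are broken uniformly at random from a seeded stream, and
duplicate unordered pairs collapse, giving between n/2 and n pairs. For
each pair, both members are withheld, the model is refitted, and the
pair is credited 1 if the later-stage member scores strictly higher, 0.5
on an exact tie (the model has no preference either way), 0 otherwise.
The mean credit estimates the AUC. Age matching removes the trivial
age–stage confound from the comparison. Folds that fail to fit are
skipped with a warning; more than 10% skipped folds is an error.

## 3. Gene-set efficacy against size-matched backgrounds

AUCs are not comparable across gene sets of different sizes, so each
set's AUC is referred to the empirical distribution of AUCs from random
gene sets of the **same effective size** (the size after intersecting
with the expression matrix), drawn uniformly without replacement from
the protein-coding feature universe. The empirical p-value is the
fraction of background sets with *strictly* higher AUC — ties do not
count against the set, following the definition of the statistic; an
optional (r+1)/(N+1) correction is available but off by default. The
background default is 1000 sets; tests and the bundled analyses reduce
it (the p-value's expectation is unchanged, only its resolution).
Within a stratum, the pair set depends only on the samples, so the drug
set and all its backgrounds are evaluated against identical pairs.
Benjamini–Hochberg correction is applied across the whole
(gene set × stratum) family of one invocation — the study-scale family
is one run of the analysis, and a per-stratum family would overstate
significance when both strata are reported together.

The stratified analysis (`run_driad_sp()`) evaluates each gene set
separately in the predicted TDP-43-positive and -negative strata,
mirroring the question "does this drug signature track disease
progression only in the TDP-43 subset?".

## 4. ISG enrichment

Differential expression between two groups is computed per gene on
log2(TPM + 1) as a mean difference with Welch's unequal-variance t-test
and BH adjustment. This is deliberately a transparent stand-in for
count-model DE protocols: it is well calibrated for the log-normal
synthetic data but does not model the mean–variance relation of real
RNA-seq counts, and results on real data would differ in the tails.
Genes with zero variance in both groups fall back to p = 1.

Genes are ranked by the signed significance metric
$-\mathrm{sign}(\mathrm{LFC}) \times \log_{10}(p)$ (p floored at 1e-300),
and set-level enrichment uses the classic weighted running-sum statistic
(weight exponent 1): hits increment proportionally to |metric|, misses
decrement by 1/(N − N_hit), and the enrichment score ES is the maximum
signed deviation. Ranking ties are broken by gene identifier for
determinism. The null distribution comes from random same-size gene sets
(gene permutation, as appropriate for a pre-ranked analysis); the
one-sided p for positive enrichment is (r + 1)/(n_perm + 1), which never
returns exactly zero — a deliberate asymmetry with the efficacy module,
whose "fraction of better backgrounds" definition is kept literal
because that is how the statistic is defined there. NES divides ES by
the mean |null ES| of matching sign.

## 5. CRISPR screen scoring

Counts are normalised to reads per million per column, replicates are
averaged on the RPM scale, and guide-level log2 fold changes use a
1-RPM pseudocount: LFC = log2(mean RPM_treatment + 1) − log2(mean
RPM_control + 1). Gene LFC is the arithmetic mean over the gene's
guides. A gene is an enrichment hit when its LFC rounded to one decimal
is ≥ 2.0 (depletion: ≤ −2.0).

**Decimal rounding matters here.** IEEE doubles store 1.95 as
1.9499999…, so binary round-to-nearest yields 1.9 and would misclassify
a borderline gene whose guide-average is exactly 1.95. `round_half_up()`
therefore renders the value as its 15-significant-digit decimal string
and rounds on the digit string, half away from zero — 1.95 → 2.0,
−1.9875 → −2.0 — and satisfies round(x) = −round(−x) by construction.
This is the module's sharpest correctness trap and is unit-tested
explicitly.

Gene-level significance uses the hypergeometric rank model: with N
ranked sgRNAs and a gene's m guides at ranks r₁ < … < r_m, each j whose
r_j lies within the top 10% of the list (the conventional rank-inclusion
window) contributes P(X ≥ j) for X hypergeometric with m successes in N
and r_j draws; the gene p is the minimum over admissible j, or 1 if no
guide makes the cut. The alternative count-model scorer with a
permutation null is a different, heavier procedure and is intentionally
out of scope; the hypergeometric model is implemented in full.
Differentiation-essential genes are scored with the same machinery using
the initial library as the control arm and the ascending ranking.

## 6. The synthetic data generator

`generate_cohort()` emulates the joint structure the downstream methods
assume, with defaults chosen once as the study conditions:

* **Cohort**: 300 samples, 2000 genes. Braak stages 1–6 roughly uniform
  (all six present for n ≥ 30); age ~ N(60 + 2·(stage−1), 8) clamped to
  [40, 100] (clamping, not resampling — the tail mass involved is a few
  percent); diagnosis AD with probability plogis(stage − 3), a weak
  stage–diagnosis coupling.
* **Latent TDP-43 status**: Bernoulli(0.37) among AD samples, never in
  controls — the observed positive fraction in CE-stratified AD cohorts.
* **CE abundances**: given latent status, each of the three CEs is
  expressed independently with probability 0.8 (positive) or 0.2
  (negative) — independence is justified by the absence of any observed
  linkage among the UNC13A CEs; expressed abundances are
  lognormal(log 5, 1) TPM; absent ones are exact zeros with probability
  0.8 and Uniform(0, 0.5 × threshold) sub-threshold noise otherwise, so
  histograms keep a non-trivial low peak for the valley finder. With
  these rates the marginal 0/1/2/3-CE distribution is qualitatively
  bimodal and the ≥2-rule recovers latent status at ~90%.
* **Expression**: per-gene baselines ~ N(3, 2) on log2; 20 stage genes
  shift by 0.5 log2-units per stage step; 50 ISGs shift by 1 log2-unit
  in latent-positive AD samples; residual noise N(0, 1);
  TPM = 2^(log2 value) with **no** per-sample renormalisation —
  downstream models standardise features, and renormalising would couple
  genes artificially. `stage_signal_scope = "ce_positive"` restricts the
  stage signal to latent-positive samples to emulate a
  stratum-specific drug signature.
* **Screen** (`generate_screen()`): 1000 genes × 4 sgRNAs + 1000
  control guides, negative-binomial counts (dispersion 0.2, i.e. NB
  size 5; dispersion 0 switches to Poisson) around per-sgRNA lognormal
  baselines of mean 500 reads shared across arms; 10 rescue genes × 8
  in the treatment arm; 8 differentiation-essential genes ÷ 8 in both
  post-differentiation arms.

All randomness flows from one master seed through independent child
streams per component (`child_seed()`), so adding a draw to one
component never perturbs another's stream, and identical seeds reproduce
outputs element-wise.

**What the generator does not emulate** — and hence what passing tests
do *not* establish about real data: RNA-seq count noise and
mean–variance coupling (expression is log-normal), library-size and
batch effects, correlated gene modules, transcript-to-gene collapsing,
dependence between the three CEs beyond the latent status, real Braak
label noise, and guide-efficiency heterogeneity in the screen. The tests
establish the *internal* correctness and calibration of the methods
under known structure, not their field performance.

## 7. Numerical choices and degenerate inputs

* Ordinal fit: threshold ordering enforced by the line search;
  single-class labels, negative λ and non-finite features are errors;
  constant features are retained with unit scale (their weight is
  shrunk to ~0 by the penalty).
* LPOCV needs ≥ 3 pairs; a stratum below that is skipped with an
  explicit report; empty gene-set ∩ matrix intersections are flagged
  untestable rather than silently dropped.
* Alignment of recovered weights with the planted direction is measured
  as the uncentred correlation (cosine); centring would make the measure
  depend on the arbitrary number of decoy features in the fit.
* Enrichment: all-zero metrics fall back to equal hit weights; p-values
  of exactly 0 are floored at 1e-300 with a warning.
* Problem sizes in the bundled analyses and tests (cohorts of 30–300,
  100 background sets, 200 uniformity replicates, screens of
  1000 genes) were chosen as the smallest sizes at which the
  statistical behaviour under test is unambiguous.

## 8. Known limitations

* The cumulative-logit realisation of ordinal ridge is one of several
  defensible forms; weight values are not directly comparable to
  margin-based implementations.
* The Welch DE stand-in is not a count model; on real counts a
  negative-binomial DE method should replace it upstream of the ranking
  metric, which is agnostic to the DE engine.
* The hypergeometric gene p ignores guide-rank correlation induced by
  shared gene effects below the inclusion window.
* Real MSBB-style single-end libraries under-detect UNC13A CEs; the
  package provides no library-type QC rule and assumes comparable CE
  sensitivity across samples.
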