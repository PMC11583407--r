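---
title: "Methods: cross-generation methylation array concordance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-generation methylation array concordance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossmeth)
```

## The problem

Illumina BeadChip arrays measure DNA methylation as beta values (the
methylated fraction of signal at a CpG, in [0, 1]). Successive array
generations — 450K-scale, EPICv1-scale, EPICv2-scale designs — drop, add,
and redesign probes, so a longitudinal cohort that switches arrays mid-study
confounds biological change with technical change. crossmeth quantifies that
technical layer: which probes exist on which arrays, which are reliable,
how much a probe's measured level shifts between generations, whether
association results and epigenetic-clock estimates transfer, and whether the
SNP fingerprint probes used to verify sample identity can be trusted across
generations.

The pipeline starts from beta matrices and per-array manifests. Raw
intensity processing (IDAT parsing, functional normalization) is upstream
of this package by design.

## Synthetic data as the test bed

Real multi-array cohorts of this kind are access-controlled, so every stage
is validated against `simulate_arrays()`, which generates data with known
ground truth under the study conditions the package targets: 30 donors
(balanced sexes, ages around 5 years), three array generations measuring
the same donors, two donors duplicated on every array as technical
replicates (mirroring chips whose spare positions are filled with
duplicates), 57 SNP fingerprint probes, and 21 of those corrupted on the
newest array.

Choices that matter:

* **Beta distribution.** Probe means follow the bimodal mixture arrays
  exhibit: 40% Beta(1, 10) (unmethylated), 40% Beta(10, 1) (methylated),
  20% Beta(2, 2) (intermediate). Person-to-person variation is logit-normal
  jitter (SD 0.4 on the logit scale) around the probe mean.
* **Measurement model.** measured = clip(true + array offset + noise, 0, 1),
  with technical noise SD 0.03 on the beta scale by default. Per-probe
  per-array offsets are N(0, 0.0148); that SD is chosen in closed form so
  the median absolute offset is about 0.01 — a calibration choice for the
  between-array bias magnitude, set once, not a fitted value. Constant
  per-array offsets can be injected instead for recovery experiments.
* **Clipping.** Because betas are bounded, clipping biases recovery at
  extreme probes; recovery tests therefore restrict to probes with true
  mean in [0.1, 0.9], where an offset of magnitude up to ~0.05 plus noise
  cannot reach a bound.
* **Sex CpGs.** A configurable set of shared CpGs carries an exact beta
  difference (default 0.05, females minus males) and no other
  between-person variation, so the noise-free regression recovers the
  injected effect exactly rather than the effect plus a jitter realization.
* **Age CpGs and toy clocks.** Two pools of shared CpGs are exact affine
  functions of age — one on the raw age scale, one on the transformed age
  scale used by anchored-age clocks. `generate_clock()` inverts the
  per-probe slopes analytically (weight `1/(k s_i)` per probe), so a toy
  clock reproduces donor age exactly on noise-free data with far fewer
  probes than samples; an ordinary least-squares fit could only do that by
  interpolation with at least as many probes as samples. Donor ages are
  drawn uniformly on [4.6, 5.5] years: wide enough for meaningful
  correlations of estimates, narrow enough to represent a single-visit
  pediatric cohort.
* **SNP probes.** Genotypes are Binomial(2, MAF) with MAF uniform on
  [0.2, 0.45]; expected betas sit at {0, 0.5, 1}. On the newest array the
  corrupted probes' manifest rows differ in probe sequence, color channel
  and/or next base, and their measured betas read the *opposite* allele
  (beta flipped to 1 − beta) — the failure a color-channel swap produces.
  This is the one place the generator deliberately models a mechanism
  rather than generic noise: corruption that is merely random per sample
  provably cannot defeat call-concordance matching (a newest-array sample
  still agrees with its own donor at all 36 clean probes, which no rival
  can overcome with 21 corrupted ones), whereas an allele flip reproduces
  the observed failure mode — newest-array samples clustering by array
  rather than by donor on raw SNP betas.
* **Determinism.** One integer seed drives a single RNG stream;
  `simulate_arrays()` is byte-reproducible for a fixed configuration.

What the generator does **not** emulate: probe-chemistry differences
(type I vs II dye behavior), cell-type composition, batch/position effects
beyond the array factor, and realistic linkage between SNPs. Tests passing
on this generator show the estimators recover what they claim under the
stated model; they do not certify behavior under chemistry-specific
artifacts the model omits.

## Probe harmonization

Manifests carry probe id, category (cg / rs / ch), design type, probe
sequence, color channel, next base, and 1-based coordinates (no liftover is
ever attempted; the build is whatever the manifest declares). Newer designs
carry several physical probes per CpG distinguished by an underscore suffix
(`cg00000029_TC11`); `probe_base_id()` strips the suffix because cross-array
joins must key on the locus, not the physical probe.
`collapse_replicate_probes()` reduces to one row per locus (mean by
default). The detection filter removes a probe when strictly more than 20%
of samples fail quality (detection p > 0.01 or bead count < 3) — strict
because the rule is phrased as "in more than 20% of samples"; a probe
failing in exactly 20% is kept.

`detect_snp_mismatches()` compares each rs probe on the newest array
against the older arrays' consensus on exactly three attributes: sequence,
color channel, next base. Probes absent from all older arrays, or whose
older arrays disagree among themselves, are *not comparable* rather than
bad — only a clean consensus can convict a probe.

## Reliability: ICC and IQR

Reliability uses the one-way random-effects intraclass correlation,
ICC(1) = (MSB − MSW) / (MSB + (k − 1) MSW), over donors measured k times.
One-way is the right model here because replicates are unordered
duplicates, not crossed raters. Negative estimates are reported, not
truncated: they are legitimate small-sample outcomes and truncation would
distort the empirical ICC distribution (the informative threshold of 0.5
is unaffected). Between-person spread is the interquartile range with
type-7 (linear-interpolation) quantiles — the convention is recorded
because different quantile types move the third decimal. A probe is
*informative* when ICC > 0.5 **and** IQR > 0.01, both strict. All
computations stay on the beta scale to match beta-scale thresholds; no
M-value transform is applied.

With only two replicated donors (the shared-replicate design), individual
ICCs are extremely noisy; that is faithful to the design being emulated and
is why distributional summaries, not single-probe ICCs, are the usable
output.

## Array-level bias

Per probe, a two-way fixed-effects additive ANOVA of beta on array + donor:
the donor factor absorbs repeated measures, and the array F statistic uses
the residual mean square with (a − 1)(n − 1) degrees of freedom. Donor is
deliberately a fixed factor — this mirrors the conventional
`aov(DNAm ~ array + SampleID)` formulation rather than a mixed model. The
balanced complete design is computed in closed form across all probes at
once; incomplete designs fall back to per-probe type-II sums of squares
with a warning. Pairwise contrasts are Tukey HSD: differences of array
marginal means with familywise p from the studentized range distribution
(Tukey–Kramer harmonic-mean sizes when unbalanced). FDR control is
Benjamini–Hochberg applied to the ANOVA p-values — the overall
between-array test, not the Tukey p-values. A probe's bias magnitude is
summarized as the maximum absolute pairwise difference, reported in
percent (beta × 100).

## Sample matching from SNP fingerprints

Betas at rs probes are called 0 / 1 / 2 copies with thresholds 0.25 / 0.75;
boundary values call heterozygous, the conservative choice. Matching uses
call concordance (fraction of co-called shared probes with equal calls) by
default because calls are robust to array-level intensity shifts — exactly
the failure mode under study. The raw-beta statistic (RMS difference) is
also provided because design corruption manifests there: with the 21
flipped probes included, newest-array samples are closer to each other than
to their own donors, the average-linkage dendrogram clusters by array, and
donor assignment breaks; excluding the flagged probes restores a perfect
assignment on both statistics. Assignment maps each newest-array sample to
the older-array donor of maximal concordance; ties across donors leave a
sample unmatched with a warning (ties within the same donor's replicate
positions are not ambiguous). The tree (distance 1 − concordance, average
linkage) can be exported as newick.

## EWAS concordance

Per array, each probe is regressed on the binary trait plus covariates by
ordinary least squares — one QR decomposition shared by all probes.
Empirical-Bayes variance moderation is intentionally not used: with the
sample sizes and thresholds in play, the concordance logic (overlap,
effect correlation, sign discordance) is unchanged by moderation, and
plain OLS keeps the estimator transparent; output metadata records
`"ols"`. The effect is the trait coefficient (second factor level minus
first; code the trait explicitly to fix the sign). Cross-array comparison
restricts to the common probe universe, recomputes BH q-values within it,
and reports Venn counts at q < 0.05 and p < 1e-8. The "stable across all
arrays" fraction uses the union of probes significant on at least one
array as denominator — the Venn-diagram framing; a per-array denominator
would give different numbers, so the convention is recorded in the report.
Effect comparison over a significant set reports Pearson r and
sign-discordant probes; zero effects are discordant with nothing and are
excluded from the count.

Because a constant per-probe array offset is pure intercept, it cannot
change effect estimates at all — the noise-free case is asserted exactly in
the tests. Array bias of the intercept kind can therefore never create
effect discordance; only probe-specific interactions with the trait could.

## Epigenetic clocks

A clock is intercept + signed weights over CpGs, optionally followed by an
output transform; the anchored-age transform maps the linear predictor x to
(1 + a)e^x − 1 below zero and (1 + a)x + a above, with anchor a = 20 years
by default. Missing-probe accounting normalizes |weights| to 100% and
reports the share carried by absent CpGs: absolute values, because weights
are signed and only |w| yields non-negative shares that sum to 100. (This
convention choice means signed-weight accountings of the same clock can
differ; the probe-count percentage is convention-free.) Imputation of
missing probes is explicit: training means when the clock ships them,
cohort means for per-sample gaps, zero, or dropping the term; the policy
used is recorded in the output. Cross-array comparison reports Pearson r
over shared donors and difference scores oriented earlier-generation minus
later.

## Numerical notes and limitations

* Degenerate inputs: an all-constant replicate table has an undefined ICC
  (returned `NA`); a zero residual mean square yields Tukey p of 1 (zero
  difference) or 0 (nonzero); BH is applied through the validating
  `adjust_fdr()` surface for user p-values, and directly for internal
  p-values that can legitimately reach 0 in noise-free simulations.
* The mQTL classifier is strict on both sides of the 1 Mb window: a pair at
  exactly 1 Mb is neither cis nor trans, and such ties are logged.
* Problem sizes in the shipped tests — a few hundred to a few thousand
  probes, 30 donors, 20 matching seeds, ~3,000 null probes for the type-I
  calibration band — are the package's chosen defaults for routine
  validation; all estimators are vectorized across probes and scale to
  full-array sizes linearly in probe count.
* Real published clock coefficient sets are not bundled; the engine reads
  any coefficient CSV. Principal-component clocks (estimates from PCA
  scores rather than raw betas) are out of scope.
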