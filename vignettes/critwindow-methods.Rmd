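---
title: "Methods: open/closed-state analysis of the social reward learning critical period"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: open/closed-state analysis of the social reward learning critical period}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(critwindow)
```

## The scientific problem

Social reward learning in mice is gated by a developmental critical period:
juvenile mice readily form a conditioned place preference for a bedding cue
paired with social housing, while adults do not.  Pharmacological treatments
(psychedelics among them) can transiently reinstate this learning in adults —
"reopen" the critical period.  Deciding whether a treated adult cohort is in
the **open** or **closed** state is therefore a statistical question: does the
cohort's normalized social preference deviate from the developmental
trajectory of untreated (closed-state) animals?

`critwindow` implements that decision pipeline end to end:

1. **Scoring** — convert zone-occupancy times from the social conditioned
   place preference (sCPP) assay into normalized (post/pre) and subtracted
   (post − pre) preference scores, with the standard pre-conditioning
   exclusion rule.
2. **Trajectory modelling** — fit the developmental timecourse of normalized
   preference with natural-spline regression (linear, B-spline and loess
   alternatives for model selection by LOOCV).
3. **State classification** — a nested-model mean-shift test of a new cohort
   against the fitted closed-state curve.
4. **Electrophysiology** — mEPSC event detection and per-cell summaries, to
   quantify the oxytocin-induced *frequency* (not amplitude) depression that
   accompanies the open state.
5. **Expression contrast** — a per-gene likelihood-ratio test of open-state
   versus closed-state conditions with a batch covariate and BH FDR control.
6. **Synthetic data** — seeded generators for all three modalities, with
   ground truth, used throughout the test suite.

## Preference scores and exclusion

A 30-min (1800 s) trial records the seconds spent in the social-assigned
bedding zone.  A score of 900 means half the session on each bedding; 1800
means the full session on the social cue.  With pre- and post-conditioning
zone times $T_{pre}$, $T_{post}$:

* normalized preference $= T_{post} / T_{pre}$,
* subtracted preference $= T_{post} - T_{pre}$ (seconds),
* pre-conditioning preference $= T_{pre} / (S/2)$ for session length $S$, so
  1 is unbiased and 0.5/1.5 correspond to 25%/75% occupancy.

Mice with a pre-conditioning preference above 1.5 or below 0.5 are excluded —
their baseline bedding bias leaves too little dynamic range for conditioning
to be read out.  The exclusion scale is the ratio to the neutral 900-s
occupancy: it is the only scale on which the 0.5/1.5 bounds bracket the
neutral value 1, and it is computable before conditioning (the normalized
post/pre ratio is not).  A mouse with zero pre-conditioning social-zone time
has an undefined normalized score; such records are automatically excluded by
the same rule (pre-preference 0 < 0.5) and never reach the ratio.

## The trajectory model

Each mouse contributes one point $(\text{age}, \text{normalized score})$.
The default model is a natural cubic spline in age — cubic between its knots,
with zero second derivative at the boundary knots and linear beyond them —
with one interior knot at P35 and boundary knots at the youngest observed age
and P98.  With $k$ interior knots the basis has $k+1$ columns plus the
intercept.  Alternatives (`model_form`): a straight line, a cubic B-spline
with the same interior knot, and loess (local linear regression with tricube
weights, span 0.75).

Fit quality is reported as RMSE ($\sqrt{\tfrac1n\sum e_i^2}$), $R^2$,
adjusted $R^2$, the overall regression F-test P value, and the leave-one-out
cross-validation RMSE.  For the linear-in-parameters forms the LOOCV error
uses the hat-matrix identity $e_{(i)} = e_i/(1-h_{ii})$, which is exactly the
explicit refit loop (the suite asserts agreement to $10^{-10}$); loess always
uses the explicit loop.  Perfectly saturated designs ($n \le p$) are refused
rather than silently interpolated, and singular designs are reported with the
offending columns.

**Knot choice.**  `select_knot()` offers a data-driven candidate: the
inflection of a loess smooth (degree 2), located by the sign change of the
numerical second derivative on a 512-point age grid.  Curvature blips below
1% of the curve's maximum curvature are ignored (they are numerical noise,
not inflections), and when a peaked smooth yields two inflections the one on
the declining flank — the transition from the juvenile elevation toward the
adult plateau — is returned.  A monotone-curvature smooth has no inflection
and is an error.  The default interior knot remains the configuration choice
P35.

## The open/closed state call

`classify_cohort()` pools the reference timecourse with the new cohort and
compares two nested least-squares models:

* **full**: spline basis in age + experiment indicator + cohort offset,
* **reduced**: the same without the cohort offset.

The mean-shift P value is the nested-model F test for the offset — exact
under Gaussian errors; a likelihood-ratio $\chi^2$ variant
($n\log(RSS_r/RSS_f)$, 1 df) is available and agrees closely at the sample
sizes involved (asserted in the suite).  The cohort is called **open** when
$P \le \alpha_{open} = 0.1$, the convention that comparisons with the spline
model are "not significant" at $P > 0.1$; the threshold is configurable.
Cohorts lying entirely outside the reference age range (± 7 days) are refused
— the spline's linear tails make extrapolated baselines untrustworthy.

The experiment indicator absorbs batch differences among reference
experiments.  An experiment label unique to the cohort would be perfectly
collinear with the cohort offset, so such labels are mapped to the
reference's modal experiment before fitting; cohorts sharing an experiment
with reference records keep their own label.

`binned_control_check()` supplies the companion sanity check: a two-tailed
two-sample t-test (Welch by default) of a control cohort against the
age-matched bin (default ± 7 days) of the reference data.

## Electrophysiology: mEPSC events

The open state is accompanied by restored oxytocin-induced long-term
depression in nucleus accumbens medium spiny neurons, visible as a decrease
in mEPSC *frequency* with amplitude untouched (a presynaptic locus).
`detect_events()` implements detection from the stated acquisition filters:

* baseline: running median, 50 ms window;
* candidates: contiguous regions of the baseline-subtracted, 0.5-ms
  moving-average-smoothed signal above 5 pA; regions separated by less than
  3 ms are merged (a decaying event can dip below threshold and re-cross on a
  noise bump), and regions containing multiple peaks separated by a trough
  below half the smaller peak are split into overlapping events;
* amplitude: raw baseline-subtracted maximum at the peak;
* rise time: 10–90% of the smoothed peak, measured from the last 10%
  crossing before the peak to the *first* 90% crossing after it (so late
  noise bumps on the decay plateau cannot stretch the measurement);
* filters: amplitude ≥ 5 pA and rise < 3 ms, both fixed by the acquisition
  convention.

Inward synaptic currents are stored as positive magnitudes; predominantly
negative-going traces are rectified at ingest.  `summarize_cell()` caps
analysis at the first 200 events per cell (the standard per-cell
acquisition); frequency is events per second of analysed duration — the full
trace when the cap is not reached, otherwise the time taken to collect the
200 events.  `condition_comparison()` runs one-way ANOVAs on per-cell
frequency and amplitude separately, excluding single-cell conditions with a
warning, with Holm–Šidák pairwise comparisons and the multivariate LRT
(`manova_lrt()`) available for the joint (frequency, amplitude) response.

## Expression contrast

The open-versus-closed contrast compares conditions in which the critical
period is open (LSD at 48 h and 2 weeks, ketamine at 48 h, MDMA at 48 h)
against conditions where it remains in or returns to the closed state
(saline and cocaine at both timepoints, ketamine at 2 weeks).  Time never
enters the design; batch does.  A treated-versus-untreated contrast (saline
against every drug, cocaine included) is also provided, conventionally read
at $q \le 0.15$ rather than 0.1.

Per gene, `gene_lrt()` fits Gaussian models on $\log(\text{TPM} + 0.5)$ —
full: intercept + batch + state; reduced: intercept + batch — and forms the
likelihood-ratio statistic $\Lambda = n\log(RSS_r/RSS_f)$.  **P-value
reference:** with a few dozen samples the asymptotic $\chi^2_1$ reference is
noticeably anticonservative (we measured a realized FDR of ~0.25 at a
nominal BH $q \le 0.1$ on synthetic data), so the default P value uses the
exact finite-sample null distribution of $\Lambda$ under the Gaussian model,
via its monotone transform $F = (n-p)(e^{\Lambda/n}-1) \sim F_{1,n-p}$.  The
asymptotic reference remains available (`null_dist = "chisq"`); the two
agree as $n$ grows.  A per-gene negative-binomial option (`method = "nb"`)
is provided for count-scale data.  Batch labels perfectly confounded with
state are an error (the effect is inestimable).  `ratio_to_saline()`
computes the per-condition expression ratios to the average saline baseline
used to display top-scoring genes.

## The synthetic-data generators

All generators take a single seed, restore the caller's RNG state, and are
bit-identical under identical arguments.

**Behaviour.**  The closed-state mean curve (`developmental_trajectory()`)
is itself a member of the default natural-spline family (interior knot P35,
boundary P21/P98), solved exactly to equal 1.4 at P21, 1.0 at P98, and to
have zero slope at P98 — hence identically 1.0 for adults.  Two design facts
motivated this.  First, within a single-interior-knot natural-spline family,
a flat adult plateau mathematically forces the juvenile limb to be monotone
declining: an interior peak is not representable, so "elevated juveniles"
enters as a weaning-age elevation with an inflection near P42 (consistent
with a declining sigmoid; a data-driven loess inflection lands in the same
region), not as a mid-juvenile bump.  Second, using the model's own family
makes the trajectory model *correctly specified* for synthetic data, so the
mean-shift test's null calibration can be verified exactly (the suite checks
the rejection rate at $\alpha = 0.1$ over 500 null cohorts and the
uniformity of null P values).  Real timecourses need not be spline-shaped:
with a misspecified mean the pooled residual variance absorbs lack of fit
and the test becomes conservative — a limitation to keep in mind, not a
failure mode the synthetic suite can exhibit.

Mouse-level variation is Gaussian on the normalized scale (s.d. 0.19, the
residual scale a trajectory fit of this kind reports), truncated to the
feasible ratio range [0, 2] (occupancy cannot exceed the session; the
truncated mass is below $10^{-3}$ at the defaults, leaving the mean at the
configured value to numerical precision).  Scores map back to zone times
holding the pre-conditioning time at its expected value (900 s), so zone
pairs sum to the session length and the post/pre ratio reproduces the drawn
score exactly.  A *mean* outside the feasible range is an error — clipping
would silently distort the planted effect.  Open-state treatments enter as
an additive shift on the normalized scale (`open_shift`), sized freely by
the caller; 0.2–0.4 spans the plausible range of reinstated preference.

**Electrophysiology.**  Event trains are homogeneous Poisson; each event is
a biexponential current (10–90% rise drawn around 1.5 ms, decay constant
5 ms — typical AMPA-receptor mEPSC kinetics; the decay is lengthened
automatically if a planted rise time exceeds what the kernel admits), scaled
to a truncated-normal amplitude (mean 15 pA, s.d. 2 pA) on Gaussian noise of
1.5 pA r.m.s. (a good whole-cell recording).  Default rate 1–2 Hz, in the
range reported for accumbens medium spiny neurons.  Oxytocin in an
open-state condition multiplies the event *rate* by `oxytocin_freq_ratio`
(default 0.5, matching the observed roughly halved frequency); amplitude
parameters are never touched, so the frequency/amplitude dissociation is
exact in the generator.  `generate_mepsc_summaries()` adds modest lognormal
between-cell variability (CV 0.2 on rate, a third of that on amplitude) for
condition-level simulations.

**Expression.**  Gene baselines are lognormal on the TPM-like scale;
gene-specific batch offsets (log2 s.d. 0.3) are drawn independently of state
labels; `n_state_genes` randomly chosen genes carry a ±`state_log2fc` shift
in open-state samples only, with identities recorded as ground truth;
residual noise is Gaussian on the log2 scale with s.d. 0.35 (~25% biological
CV, typical for brain-tissue replicates).  The default design is the nine
defined condition–timepoint pairs × 3 replicates (27 samples), with
replicate r of every condition in batch r, so batches cut across states and
are never confounded.

## Numerical choices and degenerate inputs

* Zero-variance two-group comparisons return $P = 1$ (equal constants) or
  $P = 0$ (distinct constants), never `NaN`.
* BH q-values come from the standard step-up procedure (`p.adjust`); the
  suite validates them against an independent step-up computation.
* Holm–Šidák adjustment: sorted ascending,
  $\tilde p_{(i)} = 1-(1-p_{(i)})^{m-i+1}$, cumulative maximum, capped at 1.
* The multivariate LRT statistic is $-n\log(|\hat\Sigma_f|/|\hat\Sigma_r|)$
  with a $\chi^2$ reference on (responses × parameters dropped) df; Wilks'
  $\Lambda$ is reported and cross-checked against the standard multivariate
  ANOVA decomposition.
* Loess predictions use direct surface evaluation so leave-one-out refits
  can predict at the data hull's edge.

## Problem sizes used by the test suite

The suite and the acceptance script simulate at sizes chosen to mirror the
study designs they emulate while remaining quick to run: reference
timecourses of 14 ages × 12 mice (168 points), cohorts of 15 mice (the
typical published cohort size), 500 null and 300 shifted cohorts for
calibration and power, 60-s traces at 10 kHz with ~60 events for detection,
2000-gene × 27-sample expression studies over 20 seeds, and 20-seed
condition comparisons of 8 cells per group (the figure-level n).

## Known limitations

* The mean-shift test's stated 95% power at a planted shift of
  $3\sigma/\sqrt{n}$ is unattainable for a two-sided test at
  $\alpha = 0.1$: even with an infinitely precise baseline the noncentrality
  is 3, giving $\Phi(3 - 1.645) \approx 0.91$, and a finite reference
  baseline lowers it further (simulations here land near 0.75–0.9 depending
  on the reference draw).  The implementation follows the two-sided
  nested-F design faithfully and reports the power it actually achieves.
* The Gaussian log-abundance LRT is a transparent stand-in for
  measurement-error-aware RNA-seq models; it does not model bootstrap
  quantification uncertainty, and the package does not attempt to reproduce
  any published gene list (raw reads are external).
* The event detector is defined from the stated acquisition filters (5 pA,
  <3 ms rise); the original acquisition software's exact algorithm is not
  public, so agreement is at the level of the filters, not the
  implementation.
* Synthetic sCPP data hold the pre-conditioning occupancy at its expectation;
  baseline bedding bias (and hence realistic exclusion rates) is not
  simulated — exclusion logic is exercised directly by the scoring tests.
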