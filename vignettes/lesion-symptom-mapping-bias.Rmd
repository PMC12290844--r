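---
title: "Dual frequentist/Bayesian lesion-symptom mapping and sampling-induced bias"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual frequentist/Bayesian lesion-symptom mapping and sampling-induced bias}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lsmbias)
```

## The problem

After a left-hemisphere stroke, patients may lose the ability to imitate
demonstrated hand postures, finger configurations, or both.  Whether hand
and finger imitation rely on dissociable cortical territory has been
debated for decades, and one methodological suspect is the *composition*
of the analysed samples: when patients whose deficit arises from a shared
mechanism are pooled with patients whose deficit is isolated to one body
part, the lesion-behaviour associations of the two groups blur into each
other.  This is the "partial injury problem": the association carried by
the smaller subgroup is watered down by the larger one, and regions truly
linked to one score can acquire spurious evidence under the other score.

`lsmbias` implements the full analysis machinery needed to study this:
voxelwise and regionwise lesion-symptom mapping run side by side with
frequentist and Bayes-factor inference, the behavioural sub-sampling
design, size-matched resampling controls, and a synthetic cohort
generator with known ground truth so that every claim about bias is
testable without patient data.

## Behavioural model and sub-samples

Each patient has a hand and a finger imitation score in 0--20 (10 items,
2 points for success at the first attempt, 1 at the second).  A score
strictly below 18 (hand) or 17 (finger) is pathological.  The four
deficit classes — none, isolated hand, isolated finger, shared — are
*always* derived from scores via `classify_deficit()`, never asserted by
construction, including inside the simulator.

Four analysis samples are formed by exclusion (`build_subsample()`): the
full sample; a "shared hand" sample without isolated hand deficits; a
"shared finger" sample without isolated finger deficits; and an
"isolated" sample without shared deficits.  With the default simulated
composition (40 none / 23 shared / 25 isolated hand / 8 isolated finger)
these have sizes 96, 71, 88 and 73.

## Statistical cores

**Frequentist.** `fit_univariate()` is an OLS fit of the score on a
single lesion predictor (binary voxel damage or continuous regional
lesion load) plus optional covariates (lesion size, weeks post stroke).
Two export conventions coexist deliberately, mirroring the software
lineages of the field: the voxelwise `z` is negative when damage predicts
worse performance, the regionwise `t` is positive in that case.  The
slope sign disambiguates, and `direction_label()` is invariant to the
convention.

**Bayesian.** `bayes_factor_univariate()` compares the model with the
lesion term to the nested model without it.  The default is the BIC
(Schwarz) approximation, `BF10 = exp((BIC0 - BIC1)/2)`, which is fast,
deterministic and strictly increasing in |t| at fixed n — the properties
that matter for ranking lesion-deficit evidence.  An optional
Jeffreys-Zellner-Siow method places a Cauchy prior (scale √2/2) on the
standardized slope and evaluates the one-dimensional g-integral by
adaptive quadrature around its mode; a dense-grid quadrature oracle in
the test suite pins it to relative error below 1e-6.  Evidence is
declared at BF10 > 20, i.e. a natural-log BF above `log(20)` = 2.9957
(2.99 at two decimals).  Both methods propagate constant predictors as
"untestable" missing values, never as zeros.

**Multiplicity.** Voxelwise maps are thresholded by Benjamini-Hochberg
FDR at q = 0.01, computed over tested voxels only (voxels damaged in at
least 5 patients).  Regionwise frequentist maps use maximum-statistic
permutation: one permutation set (default 50,000 draws, shared across
regions as max-statistic coherence requires) yields the null of the
maximum |t|, and `p_corrected = (1 + #\{max |t|* ≥ |t|\}) / (1 + n_perm)`.
With covariates, reduced-model residuals are permuted (Freedman-Lane).
An exhaustive-enumeration mode (n ≤ 8) exists so the Monte-Carlo engine
can be checked against brute force exactly.

## The synthetic cohort generator

The generator emulates the study conditions rather than any particular
brain: a 24×28×24 grid of 2 mm voxels (large enough to separate an
anterior "finger" territory from a posterior "hand" territory, small
enough for desk-scale permutation runs), with axis 2 running
posterior-to-anterior.  Lesions are grown by stochastic 6-connected
boundary accretion from a seed voxel, giving compact, irregular,
connected masks.  Two mechanisms for shared deficits are implemented
because the underlying science argues between them: a designated
`shared_area` carrying both effects, or `co_damage`, in which a shared
patient's mask is the union of two growths, one seeded in each isolated
area.  The union may be disconnected; we accepted that idealization in
exchange for the guaranteed audit property that both isolated areas carry
nonzero load.

Scores follow `clip(round(baseline_i + Σ effect_a · load_a + ε), 0, 20)`
with a per-patient latent baseline (mean 19, SD 0.8) shared between the
two tests — making the scores realistically correlated — and test noise
ε with SD 0.5.  Effects default to −10 points per unit load; protective
areas contribute with flipped sign.  Per-group lesion sizes (voxels) are
260 ± 80 (no deficit), 420 ± 160 (isolated), 500 ± 150 (shared-area
mechanism) or 800 ± 200 (co-damage, so one patient's lesion reaches both
areas); weeks post stroke are gamma-distributed per group with the
shared group tested earliest, so the time-post-stroke covariate is
exercised meaningfully.  Class targets are met by rejection sampling:
seed locations steer a patient toward the intended class, the realized
class is re-derived from the scores, and the draw is repeated until the
composition (default 40/23/25/8) is exact.

What the generator does *not* reproduce: vascular-territory lesion
shapes, hemispheric anatomy, and the full score dispersion of real
deficit groups — cut-off classification truncates the rejection-sampled
distributions, so simulated deficit groups have score SDs near 1.5
rather than the 3--4 seen clinically.  Passing tests therefore
demonstrate the *mechanics* of dilution and cross-task bias, not their
clinical effect sizes.

## The bias diagnostics

`compare_samples()` aligns per-unit logBF and t/z across sub-samples (all
tested units, not only supra-threshold ones, as scatter diagnostics
require).  On seeded cohorts the pipeline reproduces three phenomena:

* **Dilution** — evidence for the true hand and finger areas is strictly
  larger in the isolated sub-sample than in the full sample;
* **Cross-task positive bias** — the true hand area attracts more
  finger-score evidence in samples containing shared-deficit patients
  than in the isolated sub-sample;
* **Protective reversal** — a genuinely protective area reaches BF > 20
  with a positive slope and is labelled `"protective"` by
  `direction_label()`.

The protective validation deserves a note, because it shaped the design.
In a cut-off-classified cohort, a causal protective effect is doubly
masked in marginal regionwise regressions: rejection sampling truncates
exactly the high-protection patients out of the deficit classes, and
damage to the protective territory tags group membership (worse
performers), confounding the sign.  We therefore validate protection in
an impaired-baseline cohort (latent baseline 14 — a severely affected
chronic population) with lesions partly enriched in the protective
territory, where the effect is identifiable.  The emergent form of the
reversal — anterior damage predicting *better* hand scores in the full
sample, purely through sampling structure — also appears in the default
cohorts, but weakly at region level.

`resample_isolated_control()` implements the size-matched control design:
each of (by default) 10,000 draws keeps every patient not of the target
class plus exactly `keep` (default 8) random target-class patients.
`summarize_resamples()` tallies, per region, inclusion counts, how often
the region was "uncovered" (BF > 20 — the Bayesian rule defines
uncovering; frequentist flags are reported alongside), and the mean and
SD of BF over uncovered draws, with `"- (-)"` for never-uncovered regions
and an SD of 0 for a single uncovered draw.

## Numerical choices and degenerate inputs

* Re-binarization of reconstructed slice stacks uses ≥ 0.45 (a value
  exactly at the threshold becomes lesion).
* Slice-to-volume reconstruction assigns each output plane the nearest
  input slice (ties toward lower z), then smooths with an isotropic
  Gaussian (default SD 4 mm, half the 8 mm slice gap) with reflective
  boundaries, then re-binarizes.  Grids too small to smooth skip the
  kernel with a notice but still binarize.
* Region inclusion for regionwise analyses mirrors the voxel rule
  (≥ 5 patients with nonzero load); no printed criterion exists for the
  regionwise case, so the rule is exposed as `min_patients`.
* Only the lower overlap bound is enforced voxelwise; there is no upper
  cap on lesion frequency.
* Two-sided tests throughout; permutation p-values live in
  [1/(n_perm+1), 1]; empty parcels are dropped with a warning; constant
  scores are an error for a whole analysis but a constant predictor is an
  untestable unit within one.

## Problem sizes used in the checks

The shipped tests and the acceptance script run entirely on synthetic
data at sizes we consider adequate for their purpose: exhaustive
permutation oracles at n = 5--6; 10,000 replicates for the uniformity of
null p-values; 400 null datasets at n = 60 with 2,000 permutations for
the familywise-error check; 500 simulated patients for parameter
recovery; one 96-patient cohort per scenario for the bias phenomena; and
500 control resamples for the Table-2-style summary.  These sizes keep
binomial tolerances meaningful while completing in minutes on one CPU.
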