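---
title: "Synaptic endurance, ATP phases and immunofluorescence quantification: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synaptic endurance, ATP phases and immunofluorescence quantification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synendure)
```

# The measurements

`synendure` implements three quantitative read-outs of nerve-terminal
function under metabolic stress, together with a mechanistic synthetic-data
generator that makes every stage testable end to end without experimental
recordings.

## Endocytic block and synaptic endurance

Synaptophysin-pHluorin fluorescence rises when vesicles fuse (the sensor
unquenches at surface pH) and re-quenches as vesicles are retrieved and
re-acidified. After a stimulus round, healthy retrieval decays the signal
approximately single-exponentially with time constant $\tau$. The
**endocytic block** statistic of a round is the fraction of the exocytic
signal still present a fixed time after the peak:

$$\mathrm{EB} = 100 \times \frac{F(t_{peak} + 3\tau_{ref}) - F_{pre}}{F_{peak} - F_{pre}}\ \%$$

where $\tau_{ref}$ is fitted once per neuron from a dedicated reference
round delivered in 5 mM glucose, and $F_{pre}$ is the baseline immediately
before the round. For a perfect single-exponential retrieval
$\mathrm{EB} = 100\,e^{-3} \approx 5\%$; a complete arrest of endocytosis
gives 100%. Because EB is a ratio of baseline-subtracted values it is
invariant to any affine transform of the raw trace (camera gain and offset),
a property the test suite asserts on randomized fixtures.

**Synaptic endurance** is the number of repeated stimulus rounds (50 APs at
10 Hz, one round per minute, glucose-free bath) a neuron sustains before EB
first exceeds 50% (strict comparison). Neurons that never cross within the
observation horizon (30 rounds by default) are *censored* and contribute the
horizon value to group means — with the flag preserved so survival-style
summaries remain possible. This censoring convention is what makes group
means of endurance finite and comparable across conditions.

Decisions a reader should know about:

* $\tau_{ref}$ comes from a dedicated pre-experiment reference round in 5 mM
  glucose declared in the protocol; this makes $3\tau$ well defined per
  neuron even when later rounds decay incompletely.
* EB is computed against each round's own peak and immediately preceding
  baseline (not the first round's peak), so pool rundown across rounds does
  not masquerade as block.
* The probe value at $t_{peak}+3\tau_{ref}$ is a mean over a ±2-frame
  window; single-frame reads are noise-dominated.
* EB values above 100% (a post-stimulus rise) clamp to 100 with a warning;
  values below 0 clamp to 0 silently.

## Ratiometric ATP phases

Cytosolic ATP is reported as the frame-wise ratio of an intensiometric ATP
sensor to a spectrally separate expression reference. Expression level and
any bleaching shared by the two channels cancel in the ratio; frames where
the reference falls below a floor (3 × its estimated noise sd by default)
are masked rather than divided. ROI ratios are averaged per neuron and
normalized to the pre-stimulation baseline (= 100%). Around a long AP train
(600 APs at 10 Hz by default) the trace decomposes into **baseline** (100%
by construction), **drop** (100 minus the minimum within the train window
plus a 10 s grace period — the minimum typically falls near train end; a
train-end read-out is exposed as `drop_mode = "end"`), and **recovery** (the
mean over the final 60 s of the recording; the recordings end well after
stimulation, so this window is a post-activity plateau).

## Immunofluorescence quantification

Cell-body (or bouton) intensities are disk-ROI means, background-subtracted
against dedicated background ROIs, then normalized to the mean of the
corresponding culture batch per channel — making all downstream statistics
invariant to per-culture staining and acquisition gain (asserted as a
property test). Three analyses sit on these records:

* the glycogen vs. glycogen-synthase relation: OLS on culture-normalized
  intensities plus binned means (0.5-wide bins on the GS axis, left-closed,
  anchored at 0);
* the TH+/TH− ratio: per coverslip, the ratio of mean glycogen intensity of
  dopaminergic (TH-positive) to non-dopaminergic cell bodies, summarized as
  mean ± SEM across coverslips (within-coverslip gains cancel);
* treatment effects: treated intensities normalized to same-batch controls,
  reported as percent reduction with the SEM propagated from the normalized
  treated values only (the controls define the unit).

Background subtraction precedes culture normalization.

## Group statistics

Group comparisons use the Wilcoxon–Mann–Whitney rank test with mid-ranks for
ties. When both groups have at most 8 observations the p-value is exact,
obtained by full enumeration of all $\binom{n_1+n_2}{n_1}$ assignments of
the pooled mid-ranks — this stays exact under ties, where classical null
tables do not. Larger groups use the normal approximation with tie-corrected
variance and a continuity correction; every result records which method was
used. Two-sided tests are the default (configurable). Summaries print as
`mean ± SEM` with SEM $= s/\sqrt{n}$; censored endurance values enter
comparisons at the horizon, consistent with the group-mean convention. Stars
follow the usual convention (\*, \*\*, \*\*\*, \*\*\*\* at 0.05, 0.01,
0.001, 0.0001; `ns` otherwise).

# The synthetic-data generator

No raw recordings are distributed with this kind of experiment, so the
package ships a phenomenological nerve-terminal model whose outputs have the
statistical structure the analyses assume. Everything is dimensionless:
ATP relative to rest, glycogen relative to a full store, fluorescence
relative to the total sensor pool.

## The bioenergetic core

Per frame (forward Euler at the protocol's frame interval):

* **Demand** = resting drain (`atp_rest_cost`, 0.007 s⁻¹) + per-AP cost
  (`atp_cost_per_ap`, 5×10⁻⁴ per AP) + vesicle-retrieval cost
  (`recycle_cost` = 0.35 ATP units per pool unit retrieved, spread over the
  retrieval time course). Consumption tapers linearly below
  `consumption_knee` (0.5), a crude stand-in for metabolism slowing as
  substrate runs out, which keeps ATP from pinning at zero.
* **Supply** = glucose uptake (`glucose_uptake_gain` × bath mM) plus, when
  glucose is absent, glycogenolysis at `gp_activity × gp_rate × glycogen`
  (first-order in the remaining store); each glycogenolytic ATP unit costs
  `glycogen_per_atp` (0.032) store units.
* **Endocytic capacity** is a Hill function of ATP (midpoint 0.7,
  coefficient 6): retrieval collapses sharply once ATP falls through the
  midpoint, which reproduces the observed switch-like arrest with two
  interpretable knobs.

A deliberate modelling compromise: the resting drain is high relative to
the per-AP cost. This is what reconciles, inside one parameter set, a
*supply-rate-limited* arrest for partial glycogenolysis loss (half the
enzyme ⇒ inter-round recovery becomes slow and dips accumulate over a few
rounds) with a modest ATP drop in the untreated control during a 600-AP
train. The corollary — documented rather than hidden — is that with
glycogenolysis fully blocked in glucose-free saline, modelled resting ATP
collapses within the five-minute pre-incubation, which exaggerates the
pre-stimulus rundown relative to real neurons.

## Condition presets

Presets differ only in the interpretable fields:

| preset | gp_activity | effective store | glucose |
|---|---|---|---|
| `da_0gluc` (control) | 1 | 1 | 0 |
| `da_5gluc` | 1 | 1 | 5 mM |
| `da_gpi` (phosphorylase inhibitor) | 0 | 1 | 0 |
| `da_gpkd` (knockdown) | 0.5 | 1 | 0 |
| `da_sulpiride` (D2R antagonist) | 1 | 0.546 | 0 |
| `glut_0gluc` (hippocampal) | 0.5 | 0.95 | 0 |

The sulpiride preset reduces the store (through `d2r_tone = 0.546`, a 45.4%
reduction), not enzyme activity; inhibitor/knockdown presets reduce enzyme
activity, not the store — mirroring the distinct causal routes of the two
manipulations. The glutamatergic preset encodes a less engaged
glycogenolytic pathway and a slightly smaller usable reserve.

Defaults were calibrated once, before the test suite was frozen, against the
condition-level summary statistics reported for this class of experiment
(control endurance near 19 rounds with roughly a quarter of neurons censored
at 30; knockdown arrest within several rounds; inhibitor arrest within one
to two rounds; hippocampal neurons arresting around five to six rounds and
showing the deeper ATP drop). With 29 seeded neurons per condition the
generator yields control ≈ 20 rounds (6/29 censored), knockdown ≈ 6.5,
inhibitor = 1, sulpiride ≈ 5.7, hippocampal ≈ 4.8, and ATP drops ordered
inhibitor > knockdown ≈ hippocampal > control. Two magnitudes deliberately
deviate: the sulpiride arrest is slower than its experimental counterpart
(halving the store cannot reproduce a one-round arrest in this model), and
the inhibitor's raw ATP drop saturates deeper than observed. The analyses
assert orderings across conditions, not these magnitudes.

Per-neuron heterogeneity — needed for realistic spread and for censoring to
occur at all — is a single lognormal metabolic-efficiency factor (sdlog
`neuron_cv` = 0.5) scaling the glycogen-to-ATP yield.

## Fluorescence models

*pHluorin*: each train exocytoses `exo_pool_fraction_per_round` (0.15; the
per-round releasable fraction is not a published quantity and is treated as
a free parameter) of the still-releasable pool; the capacity fraction of the
exocytosed signal is retrieved exponentially (τ = 8 s) and the remainder
stays stranded on the surface, so block compounds across rounds. The NH4Cl
epoch sets fluorescence to the total-pool level. Raw units are
`offset + gain × (resting surface + signal)`, bleached multiplicatively and
with additive Gaussian noise of sd `noise_sd` (5%) × the first-round peak.
With `noise_sd = 0` and `bleach_rate = 0` every output is an exact closed
form of the parameters, which the unit tests exploit.

*ATP sensor*: the sensor channel follows ATP through a weakly saturating
binding curve `atp / (atp + sensor_kd)` with `sensor_kd = 3` on the
relative-ATP scale (the sensor operates below saturation at resting ATP);
the reference channel is constant-mean. Both share the per-ROI lognormal
expression amplitude and the bleaching term, with independent noise — so the
ratio stage has something real to cancel. Default 50 ROIs per neuron,
matching imaging practice of 40–60 varicosity ROIs.

*Immunofluorescence*: disk-shaped cell bodies over a noisy background.
GS expression is lognormal; the order-of-magnitude spread observed across a
mixed population is decomposed into a within-coverslip cell factor
(σ_log10 = 0.15) and a between-coverslip staining factor (σ_log10 = 0.48),
totalling σ_log10 ≈ 0.5. The decomposition matters: the per-coverslip
TH+/TH− ratio cancels the coverslip factor, so placing most of the spread
between coverslips keeps the ratio-of-means estimator well behaved at
realistic cell counts (28 cells per coverslip by default) while preserving
the population-wide spread. TH-positive cells express 1.7 × more GS, and
glycogen = slope × GS + noise — so the TH+/TH− glycogen ratio and the
linear glycogen–GS relation emerge from one mechanism (more synthase, more
storage). The sulpiride condition scales TH-positive glycogen (only) by
0.546.

# Numerical choices and degenerate inputs

* Decay fitting uses Levenberg–Marquardt least squares of
  $F = A e^{-(t-t_{peak})/\tau} + C$ on the post-peak segment, started from
  a log-linear regression; the offset $C$ absorbs any unretrieved fraction.
  Flat segments, non-convergence, and implausible τ (outside
  $[2\times10^{-4}, 50]$ × segment length) are errors carrying diagnostics,
  never silent numbers.
* Pixel membership in an ROI uses the pixel-center rule (centers at integer
  + 0.5, 0-based coordinates, x = column): unambiguous and checkable against
  a brute-force pixel loop, which the tests do.
* Background is the per-frame mean over all background ROIs (the simplest
  defensible reading of a single background-subtraction step); a
  `background = "none"` policy is explicit, never implicit.
* The responding-ROI criterion (mean rise during the first train > k × the
  baseline sd, k = 2 by default) is exposed as a parameter; a selection that
  rejects everything is an error, so downstream stages can never run on an
  empty set.
* The NH4Cl plateau is the median of the central 60% of the epoch, ignoring
  perfusion transients at the edges; a plateau not exceeding the baseline is
  a calibration error.
* All randomness flows from one integer seed through a deterministic
  splitmix-style fan-out (`derive_seed`), kept within 32-bit range; the same
  seed gives byte-identical outputs at every level, including pipeline
  report files.

# Problem sizes used in the shipped checks

The test suite and the reproduction script run entirely on synthetic data at
sizes chosen to estimate each quantity stably: 20 neurons per condition for
the ordering checks, 50 seeded neurons for τ and arrest-round recovery, 16
coverslips × 28 cells for the TH ratio, 138 cells for the regression, and
at least 200 randomized fixtures (n ≤ 7 per group) for the exact-test
equivalence. These are the package's own validation sizes; all entry points
accept larger cohorts.

# What passing tests do and do not show

The generator emulates stimulus-locked rises, incomplete re-acidification
under ATP depletion, pool-fraction calibration epochs, expression-ratio
cancellation, and condition-dependent intensity scalings — the features the
analysis stages rely on. It does not emulate motion or focus drift,
photon-counting (Poisson) noise statistics, PSF blur, segmentation error,
overlapping cells, or multi-exponential retrieval kinetics. Passing tests
therefore validate the *analysis logic and its invariances*, not robustness
to those real-data pathologies; ROI tables are taken as given (hand-drawn in
practice), and no drift correction or automatic bouton detection is
attempted. The rank test applies no multiple-testing correction, matching
the analysis convention it implements.
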