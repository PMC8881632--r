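---
title: "Methods: simulating and analysing affective representational similarity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing affective representational similarity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(affrsa)
```

This vignette is the package's own account of its models and the choices
behind them: what the synthetic study generator emulates and what it does
not, how each analysis stage is defined, which parameters matter, and what
the passing test suite does and does not establish about real data.

## The design being emulated

The pipeline targets a developmental movie-viewing design: 25 children and
20 adults passively view 24 film clips — 8 positive and 8 negative clips,
with each of 8 source films contributing exactly one of each, plus 8
neutral clips from distinct documentary sources — in one 510-volume run at
TR = 2 s. Clip durations span 19–46 s with a jittered 6–12 s interstimulus
interval, in one of three counterbalanced presentation orders. The
dependent measure is within-valence, inter-movie pattern similarity inside
three ROIs: amygdala (AMY), nucleus accumbens (NAcc) and ventromedial
prefrontal cortex (vmPFC).

`simulation_config()` holds these constants as defaults. Durations are
stimulus properties, so they are drawn once per study and shared across
orders; each order gets its own permutation and ISI jitter. Draws are
uniform over the stated ranges and are rejected and redrawn until every
order fits the run — uniformity over a stated range is the least
committed reading when only a range and a mean are reported, and
rejection keeps the published ranges intact while guaranteeing
feasibility, at the cost of a negligible downward bias in total
duration. A run that cannot hold the 24 clips even
at minimum durations errors immediately, naming the overflow.

The run length bookkeeping of the emulated study is ambiguous by a few
seconds (510 × 2 s = 1020 s versus a printed "17 min and 6 s", likely
discarded dummy scans); the simulator exposes `n_volumes` and takes no
position.

## The pattern model: planting similarity you can reason about

For each participant, ROI and clip the generator draws a voxel beta vector

$$ b = \sqrt{a}\, T_{v} + \sqrt{1-a}\, \varepsilon, $$

where $T_v$ is a unit-variance Gaussian template specific to that
participant × ROI × valence $v$, and $\varepsilon$ is unit-variance clip
noise. Two same-valence patterns then have expected Pearson correlation
exactly $a$, so the planted grid `similarity_grid()` is interpretable on
the same scale as the measured statistic. (The measured Spearman version
is attenuated by the usual ~0.95 factor for Gaussian data, and slightly
biased at small voxel counts; the calibration test pins the Pearson mean
to $a$ within 0.02 over 10,000 pairs.)

Two participant-level modifiers act on $a$: a shared offset with standard
deviation `participant_sd` (default 0.1), and for children an optional
linear trend in age in months (`child_age_slope`, default 0). The offset
is what gives the simulated cohort a realistic intraclass correlation —
with the default it lands near 0.07–0.09, matching the clustering real
record-level similarity tables show — and it is shared across all of a
participant's cells, so it cancels out of within-participant contrasts but
inflates the replicate-to-replicate variance of between-group contrasts,
exactly as real between-participant heterogeneity does.

The default grid plants the qualitative developmental pattern with cell
values chosen to mirror the magnitude of mean differences such studies
report (children ~0.03–0.12 above adults, the child advantage largest in
vmPFC, negative > positive > neutral within children, adults flat).
`recovery_grid()` carries the same qualitative ordering with every tested
gap widened to ≥ 4–5 replicate-to-replicate standard deviations of the
corresponding contrast; it exists because a parameter-recovery experiment
must plant effects the design has power to detect — with effects at the
printed magnitudes, a 95% replication bar measures power, not
correctness. (A group gap of 0.037 under participant heterogeneity of 0.1
flips sign in roughly one replicate in nine; no pipeline can "recover" it
19 times in 20.)

What the generator does **not** emulate: visual or auditory stimulus
content, attention and familiarity, spatial voxel correlation,
physiological noise spectra, or any age-related difference in
haemodynamics. Passing tests therefore demonstrate that the analysis
machinery is correct and calibrated under a known generative model — not
that the developmental findings themselves would replicate on new scans.

## BOLD simulation and the GLM stage

Each ROI voxel's timeseries is the sum over clips of the voxel's planted
beta times an HRF-convolved boxcar, plus slow drift and Gaussian noise
(`noise_sd`, default 1, in units of the unit-variance betas). The HRF is
the canonical double-gamma (response and undershoot delays 6 s and 16 s,
undershoot ratio 1/6, unit peak), sampled by 16× oversampling of the
boxcar; the identical construction feeds both the simulator and
`build_design()`, which is what makes noiseless recovery an exact linear
algebra identity rather than an approximation.

Drift is drawn from the discrete-cosine components with period longer
than the high-pass cutoff plus a linear ramp; `highpass()` projects out
the mean, a linear trend and exactly that cosine set (default cutoff
100 s, the common default for long-event designs). Filtering is applied
to data and design alike, so anything the filter removes cannot bias task
betas. Estimation is ordinary least squares per voxel (`fit_glm()`),
with no prewhitening: autocorrelation modelling changes efficiency, not
unbiasedness, and the downstream statistic uses only the point estimates.
The nuisance block is the standard one — white matter and CSF series, six
motion parameters, their first differences and one unit spike column per
flagged volume, so motion-corrupted volumes are regressed out rather than
deleted and the timeseries grid stays intact.

## Motion QC

The per-volume motion metric is thresholded at the boxplot upper fence,
Q75 + 1.5 × IQR, with quantiles by linear interpolation of order
statistics (the `type = 7` convention; declared because the fence value
depends on it, and verified against a brute-force interpolation oracle).
Flagging is strictly above the fence, so a constant series flags nothing.
Participants are excluded when more than 15% of volumes are flagged or
when any rotation series exceeds 1.5 — both strict, so a participant at
exactly the limit is kept. The exclusion limit for rotations is applied
on whatever scale the series are stored in; the convention that motivated
it mixes rotation units with millimetres, and the package stores the
series agnostically rather than resolving that ambiguity.

## ROI masks and alignment

All masks live on one common MNI-like grid (`volume_geometry`, 0-based
voxel indices, mm coordinates through the affine); per-subject nonlinear
warping is out of scope, and operating in a single common space is the
analysis-level equivalent. The vmPFC mask is a sphere of **diameter**
10 mm (taken literally; on a 4 mm grid that is 7–10 voxels depending on
where the centre falls between voxel centres) around MNI [2, 46, −8].
Membership compares the Euclidean distance from the mm centre to each
voxel centre against the radius, inclusive at a tie, and always includes
the voxel containing the centre so a zero diameter is well defined. AMY
and NAcc are thresholded probabilistic volumes at an inclusive 50% — the
common atlas convention when strictness is unstated. The package ships no
third-party atlas; `synthetic_prob_atlas()` builds clearly-labelled
synthetic probability blobs so the thresholding path is exercised with
package-generated data only.

`align_patterns()` extracts mask voxels in lexicographic index order, so
position *k* of every clip's vector is the same anatomical voxel;
non-finite voxels become missing for that clip only, and missingness is
then handled pairwise by the similarity statistic.

## The similarity statistic

`valid_pairs()` enumerates unordered same-valence pairs with distinct
source films; on the stated design this is exactly 28 per valence, and
the same-film exclusion is the reason (clips from one film share
characters, audio and style, which would masquerade as affective
similarity). `spearman_similarity()` ranks with midranks and computes the
Pearson correlation of ranks over the voxels non-missing in *both*
patterns; fewer than three shared voxels, or a constant rank vector,
yields a missing record with a warning — never a silent zero, which would
bias cell means toward null. Fisher's Z uses `atanh` after clamping at
1 − 10⁻⁷ so simulated correlations of exactly ±1 stay finite. A complete
(no-missing) participant × ROI matrix takes a vectorised path — rank once
per clip, one cross-product — that the tests pin to the per-pair
definition.

## Group inference

`mixed_anova()` fits the 3 × 2 × 3 design with two error strata via
`aov(z ~ age_group * roi * valence + Error(participant_id))`: the age
effect is tested against the between-participant residual (43 df at
N = 45) and all within-subject effects against the within residual
(11,340 − 45 − 16 = 11,279 df on the complete design). The factors are
balanced within participant, so sequential sums of squares coincide with
Type II here. Effect sizes are reported as partial ω² =
(SS − df·MS_err)/(SS_total + MS_participant), clamped at zero, with
MS_err from the effect's own stratum, and Cohen's *f* = √(ω²/(1−ω²));
these conventions are stated because published tables often list both
without formulas, and other ω² conventions differ in the denominator.

Record-level similarity values within a participant are not independent
— they share templates and clips — and the two-stratum ANOVA models only
the participant-level component of that dependence. This mirrors
standard practice for this analysis, and the calibration experiment
quantifies the consequence: under the null generator with *no*
representational structure (`similarity_grid(a = 0)`, `participant_sd =
0` — with nothing planted there is no similarity for participants to
vary in), the ROI × age interaction's rejection rate over 500 simulated
studies sits at 5–6% in our runs, i.e. the nominal size holds. With structure planted, shared
templates add a cell-level variance component the record-level tests do
not model, making them anticonservative; that is a property of the
analysis tradition being implemented, and it is why the recovery
experiment's planted effects are power-sized rather than threshold-sized.

`bonferroni_contrasts()` compares pooled record sets between two cell
collections (interaction contrasts pool the crossed cells, a
difference-of-differences up to a factor of two). The default test is
Welch's unpooled two-sample t with Satterthwaite df — matching the
per-contrast df in the low thousands that record-level post-hocs produce
— with a pooled-variance option for comparison; the Bonferroni family
size is the number of contrasts in the family (9 for the ROI × age cells,
3 for their interactions, 9 for valence × age, 1 for its interaction, 4
for valenced-vs-neutral) and is an explicit knob because reported tables
rarely state the family behind each adjusted p.

`age_multilevel()` restricts to children and fits
`z ~ age_months + (1 | participant)` with both variables standardised
(random intercepts, fixed slope), plus the null model without fixed
effects, whose between-participant variance fraction is the reported ICC.
Per-record responses are used rather than per-cell means — the model's
random intercept absorbs the participant-level dependence either way, and
records keep the residual df honest. Singular fits are flagged, not
zeroed.

`krippendorff_alpha()` is the nominal-data coincidence-matrix form,
1 − D_o/D_e over pairable values, with missing codes simply unpaired.
The simulated raters miscode a clip's valence with probability 0.03,
chosen so the expected chance-corrected agreement sits near the 0.91
that independent raters reached on the emulated stimulus set.

## Problem sizes and numerical choices

The test suite and acceptance script run the full 45-participant design
for count and df identities, reduced voxel counts (24 per ROI) for the
replicate-study experiments (100 recovery replicates, 500 null studies —
sizes at which a true 5% rate is estimated to ±1%), and a 5-participant
cohort with 6–10-voxel ROIs for the exact noiseless BOLD → GLM → RSA
identity (tolerance 10⁻⁶; observed error is at machine precision because
simulator and design share their regressor construction and the filter
annihilates the drift basis exactly). All randomness flows through
per-stage seeds derived from one base seed; identical seeds give
bit-identical schedules, patterns, timeseries and downstream tables.

## Known limitations

* Voxels are independent in the generator; real patterns are spatially
  smooth, which lowers the effective voxel count of an ROI.
* The record-level contrast tests inherit the anticonservatism discussed
  above whenever true structure is present.
* The rotation-exclusion unit ambiguity is preserved, not resolved.
* Neutral clips are assumed to come from 8 distinct sources; if sources
  were shared, neutral pair counts would drop below 28 and the design
  would no longer be balanced across valence categories.
* The multilevel model treats age linearly within the child range; any
  nonlinear maturation is out of scope.
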