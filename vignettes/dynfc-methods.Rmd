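---
title: "Trial-resolved dynamic connectivity during fear extinction: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trial-resolved dynamic connectivity during fear extinction: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynfc)
```

# The scientific problem

During fear extinction, a conditioned stimulus that previously predicted an
aversive outcome (CS+) is presented repeatedly without reinforcement, and
conditioned responding declines. The question this package addresses is how
coupling between large-scale brain systems changes *over the course* of that
learning, how those changes differ between healthy controls and patients with
anxiety disorders or PTSD, and how they relate to extinction-memory recall
the next day and to clinical severity. A single static connectivity matrix
averages away exactly the dynamics of interest; the pipeline therefore
estimates connectivity **per trial** and tests its early-to-late change.

The package implements the full chain: single-trial amplitude (beta-series)
estimation, jackknife trial-resolved connectivity, time-block summaries and
change scores, family-wise-error-controlled group inference on connectome
components (Network-Based Statistic, NBS), canonical-network summaries,
cross-phase association with recall signals, and canonical correlation
analysis (CCA) against clinical measures — plus a synthetic cohort generator
that plants all of these effects so every stage can be validated against
ground truth.

# Trial-resolved connectivity: the jackknife

A beta series is a trials × regions matrix of single-trial GLM amplitudes.
For an edge $(i,j)$ and trial $t$ of $T$, the leave-one-out correlation
$r_{(-t)}$ is the Pearson correlation of the two regions' beta series over
all trials except $t$. Removing a trial that carries strong coupling lowers
the remaining correlation, so after a Fisher transform the sign-flipped
value $-z_{(-t)}$ is high exactly when trial $t$ contributes strongly to the
edge. Two variants are exposed:

* `jackknife_zflip` (default): the flipped series is standardised per edge
  to mean 0, SD 1 across trials. Values are *relative within subject and
  edge*; this stabilises the scale across edges but discards amplitude
  differences between subjects (a consequence discussed under the
  generator below).
* `jackknife_pseudovalue`: classical pseudovalues
  $T z_{\text{all}} - (T-1) z_{(-t)}$ on the Fisher scale, unstandardised.

The leave-one-out pool is all trials of the phase (both CS types pooled);
matrices are reordered by CS type downstream. A per-CS-type pool is
available (`pool = "per_cs"`). Fisher transformation before the flip is on
by default and toggleable. Downstream block differences are invariant to
per-edge affine rescaling, so these toggles change units, not inference
signs.

Numerical choices: perfect correlations are capped at $|z| = 6$ so that
degenerate duplicated signals stay finite; leave-one-out subsamples with
zero variance produce a 0 entry and are counted in a quality flag rather
than emitting NaN; the diagonal is stored as 0 and never interpreted. The
fast implementation uses running sufficient statistics (sum, cross-product
downdates) and is tested to $10^{-10}$ against a naive loop that calls
`cor()` per leave-one-out subsample.

# Time-blocks, ΔFC, and differential change

Trials of each CS type, in presentation order, are divided evenly into 4
contiguous time-blocks (early to late learning) and averaged. The central
quantity is

$$\Delta FC = FC_{\text{block 4}} - FC_{\text{block 1}}$$

per edge and subject, vectorised over the upper triangle in row-major
$(i<j)$ order — one stated convention used everywhere so that edge vectors
from different stages can never misalign. *Differential change*,
$[\mathrm{CS+} - \mathrm{CS-}]_{\text{block 4}} - [\mathrm{CS+} -
\mathrm{CS-}]_{\text{block 1}}$, isolates cue-specific dynamics and equals
`deltaFC(CS+) − deltaFC(CS−)` edge-wise (tested as an identity). A
static-FC mode (one correlation matrix over all trials of a CS type) is
provided as the control analysis: it deliberately ignores when coupling
occurred.

Trial counts not divisible by the block count are an error by default;
`remainder = "truncate_late"` drops the last trials and is recorded in the
object.

# Group inference: edgewise GLM and the Network-Based Statistic

Per edge, ΔFC is regressed on [intercept, group indicator, age, sex]; the t
statistic on the group coefficient (df $= n_1+n_2-2-\#\text{covariates}$)
is thresholded directionally at the primary component-forming threshold
(default $p < 0.001$), connected components are formed over regions, and
each component's statistic is referred to a permutation null of the maximum
component statistic: group labels are exchanged across subjects (covariates
stay attached to their subjects), the GLM is refit, and the maximum is
recorded. Significance is read at $p_{FWE} < 0.05$. The permutation count
defaults to 5000 (the NBS literature's typical order; the add-one estimator
$(1+\#\{\text{null} \ge \text{obs}\})/(1+n_{perm})$ avoids zero p-values).
When the label-assignment space $\binom{n}{n_1}$ is no larger than the
requested permutation count, all assignments are enumerated exactly and the
p-value is the exact tail proportion — tested against an independent
enumeration oracle at 3-vs-3.

Two component statistics are available: **extent** (edge count, the
default, matching how component sizes are conventionally reported) and
**intensity** (summed |t|). The distinction matters for calibration
studies: at desk scale (60 regions, edge threshold 0.001) the null max
component size is a small integer with heavy ties, which makes the
permutation p-value conservative — family-wise error is still controlled,
but the realised rejection rate sits well below the nominal level. The
intensity statistic is continuous and tie-free; the package's calibration
experiments therefore measure the rejection rate with intensity and assert
non-inflation for extent. Permutation loops use the Frisch–Waugh shortcut
(the outcome matrix is residualised against the fixed covariate block once;
each permuted predictor costs one cross-product), which is algebraically
identical to refitting the full GLM.

**Component-forming threshold and recovery power.** The threshold trades
edge specificity against component sensitivity. For a planted 30-edge
component with edgewise Cohen's d = 0.8 at $n = 40$ vs $40$, the per-edge
power of a one-sided 0.001 threshold is 0.65 — no component-level procedure
can then reach 0.8 edge sensitivity. At threshold 0.01 the per-edge power
is 0.88, and the recovery benchmarks in this package use 0.01 for that
reason (chosen from this power calculation, not from the data). The
inference default remains 0.001.

After inference, components are summarised against an atlas table mapping
each region to one of 8 canonical networks (7 cortical systems plus a
subcortical network): the proportion of component edges per network pair
(denominator $|A||B|$, or $|A|(|A|-1)/2$ within a network), per-region
degrees (plain and |t|-weighted — both are emitted because "weighted
connection count" is ambiguous in common usage), component intersections,
and seed-label connection profiles (case-insensitive substring matching on
parcel labels, so multi-parcel families like the lateral-prefrontal label
group act as one seed). The shipped 432-region table is a synthetic
stand-in with the published parcellations' schema and granularity (400
cortical parcels across 7 systems + 32 subcortical regions); any table with
the same columns can be substituted.

# Cross-phase association

To relate learning-phase change to recall, the per-subject predictor is the
mean ΔFC over a fixed component. Region-level responses (recall activation
contrasts of extinguished vs unextinguished cues) are tested with OLS per
region plus age/sex, with family-wise error across regions controlled by a
max-|t| permutation null. The permutation scheme residualises the predictor
against the covariates and shuffles those residuals, holding the covariate
part fixed — this keeps the nuisance structure intact under the null. This
region-level max-statistic approach replaces voxel-level mapping
deliberately: it is self-contained, desk-scale, and statistically
interpretable, and voxelwise analysis is out of scope.

The same machinery runs per recall-phase edge with the continuous predictor
(cross-phase NBS), in separate positive and negative directions, since
control and patient groups can couple with opposite signs. Recall-phase
edge FC is computed as static beta-series correlation over the first 4
trials of each recall cue type, contrasted extinguished minus
unextinguished.

Correlations estimated in two disjoint groups are compared with the
independent-samples Fisher test
($z = (\operatorname{atanh} r_1 - \operatorname{atanh} r_2) /
\sqrt{1/(n_1-3) + 1/(n_2-3)}$, the default, because the group samples are
disjoint); Steiger's test for dependent overlapping correlations is
provided for within-sample comparisons and requires the inter-correlation
of the two non-shared variables.

# CCA against clinical measures

With far more edges than subjects, CCA is ill-posed; the X side is reduced
by principal components to rank $\min(\lfloor n/10 \rfloor, 30)$ by default
(logged, configurable) before the first canonical pair is computed against
the clinical matrix (4 anxiety/depression scales, or a single PTSD severity
scale — with one measure the canonical correlation reduces to a
regression's multiple R, which is tested). Canonical signs are arbitrary;
they are fixed mechanically: each principal component's sign makes its
largest-|loading| element positive, and the canonical pair is flipped so
the connectivity variate correlates non-negatively with the first principal
component. Loadings are reported on interpretable scales: each clinical
column against the clinical variate, and each network's mean ΔFC (over
component edges incident to it) against the connectivity variate.

Inference is by permutation of Y rows (10000 by default; the X reduction is
unchanged under the null), with the add-one estimator. Out-of-sample
validity uses 5-fold cross-validation: reduction and canonical weights are
fit on training folds, held-out subjects are projected, score pairs are
pooled across folds, and their correlation (`cv_r`) is referred to a
permutation null that reruns the entire cross-validation on shuffled Y.
Missing clinical values are dropped listwise with a logged count. Only the
first canonical pair is tested; higher pairs are descriptive. Optional
residualisation of both sides for age/sex exists and is off by default
(both choices are defensible; the default is the simpler model and is
logged).

# The synthetic cohort generator

The generator is the test bed: it emulates the study's statistical
structure with planted, recoverable effects.

* **Design**: two CS types × 16 extinction-learning trials each,
  interleaved (alternating by default; the order is configurable and
  recorded in BIDS-style events tables), 432 regions by default.
* **Planted component**: two 6-region cliques sharing one region — 30
  edges, 11 regions, connected. Cliques are used because equicorrelated
  blocks keep the per-trial correlation matrix positive definite up to
  $\rho \approx 0.55$, whereas correlation placed on the edges of an
  arbitrary graph need not be a valid correlation matrix at all. Configs
  whose correlation range breaks positive definiteness are rejected with a
  diagnostic.
* **Dynamics**: subject $i$ in group $g$ has latent slope
  $s_i \sim N(\mu_g, 0.1)$, truncated so every trial-wise correlation stays
  in the admissible range $[-0.15, 0.5]$. The CS+ planted correlation at
  within-type trial $m$ is $0.1 + s_i (m-1)/15$; CS− trials stay at
  baseline 0.1. Group means: controls $+0.30$ and trauma-exposed controls
  $+0.25$ (coupling rises across learning), anxiety $-0.05$ and PTSD
  $-0.10$ (flat to falling) — the qualitative group structure the analyses
  must recover. Everything off the planted subgraph is independent
  unit-variance noise (a background-correlation option is out of scope by
  design).
* **Ground-truth change proxy**: the quantity to which recall and clinical
  signals are linked is the subject's *realized* planted-component mean
  ΔFC, computed inside the generator from the drawn betas with the same
  jackknife/block machinery the analysis uses (deterministic given the
  draws). This choice matters: the default z-flip standardisation discards
  amplitude, so a subject's measured ΔFC correlates only weakly (~0.3) with
  the latent slope but perfectly with the realized change. Planting links
  on the realized change is also what "recall signal linearly linked to
  ΔFC" literally means.
* **Linked signals**: the recall activation table adds
  $\text{link}_g \times \text{proxy}$ at a designated recall region (link 1
  in controls, 0 in patient groups), with noise SD 0.2 — a proxy–recall
  correlation of ~0.7 in controls, a strong but not degenerate planted
  effect. An optional recall edge-FC table couples the planted edges
  positively in controls and negatively in the anxiety group (mirroring
  opposite-signed cross-phase coupling), noise SD 0.3. Clinical scores are
  $\text{mean}_k + w_k \times \text{proxy} + \varepsilon_k$ with negative
  weights — higher severity with lower connectivity change — and noise
  chosen so single-measure correlations sit around 0.5–0.6.
* **Determinism**: one integer seed; identical configs give bit-identical
  cohorts. The tree written by `writeCohort()` (events TSVs, full-precision
  beta tables, subject/clinical CSVs, ground-truth JSON) round-trips
  losslessly through `readCohort()`.

What the generator does **not** emulate: scanner physics, motion,
physiological noise, spatial autocorrelation, background (non-planted)
connectivity structure, skin-conductance responding, or realistic clinical
scale distributions (scores are Gaussian around plausible means). Passing
tests therefore demonstrate that the statistical machinery is correct and
calibrated under the planted model — not that the pipeline is robust to
acquisition artifacts, which is the preprocessing literature's territory.
An optional forward model (`simulateBoldFromBetas()`) convolves trial
events with the canonical double-gamma HRF and adds AR(1) noise to produce
4-D BOLD + events inputs for the least-squares-separate GLM path
(`estimateBetaSeries()`: per trial, that trial's regressor plus one pooled
regressor per condition plus polynomial drift of order 2), so the
beta-estimation stage can be validated by inversion.

A second, lighter generator (`simulateDeltaMatrix()`) draws ΔFC edge
vectors directly as unit-variance Gaussians with a mean shift (edgewise
Cohen's d) on planted edges for one group. It bypasses the trial level so
that null-calibration and recovery studies of the inference stage can run
at scale; note that the trial-level generator's defaults imply a much
smaller edgewise d (~0.3) than its component-level effect, because z-flip
units dilute per-edge amplitude.

# Problem sizes and validation experiments

The package validates itself with, among others: 50 random-instance oracle
equivalence checks for the jackknife (R ≤ 10, T ≤ 20); 200 null cohorts
(30 vs 30 subjects, 60 regions, 200 permutations each) for NBS
family-wise-error calibration; 25 planted-recovery replicates (d = 0.8,
40 vs 40); exact-enumeration agreement at 3 vs 3; a 60-vs-60 trial-level
cohort for cue- and group-specific dynamics; 25 cross-phase replicates at
the 77/91 group sizes; and 200 CCA calibration runs plus 20 planted-mode
cross-validation replicates (true canonical r = 0.6, n = 150). These sizes
were chosen as the smallest at which the asserted properties are
statistically decidable, and all statistical assertions use exact binomial
confidence intervals or pre-stated replicate margins.

# Interfaces and limitations

The package's interface is its R functions: `runPipeline()` orchestrates
cohort → trial FC → ΔFC → NBS → network maps → cross-phase → CCA from one
configuration (list or YAML) with per-stage seeds derived deterministically
from one top-level seed, and writes artifacts with md5 provenance. The
pipeline conditions downstream stages on a *significant* NBS component; if
none exists it falls back to the planted edge set (recorded in the report),
so synthetic studies remain interpretable either way.

Known limitations: time-block counts other than small divisors of the
trial count are unsupported by design (no interpolation); sliding-window
and state-based dynamic FC are out of scope; voxel-level analysis is out of
scope; the jackknife's z-flip units are relative within subject and edge,
so between-subject amplitude comparisons should use the pseudovalue
variant or component-level summaries; and the NBS extent statistic's
discreteness makes its realised error rate conservative at small graph
sizes (see above), which is a property of the statistic, not of the
implementation.
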