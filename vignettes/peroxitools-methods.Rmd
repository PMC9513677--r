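---
title: "Models and methods behind peroxitools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind peroxitools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peroxitools)
library(dplyr)
```

peroxitools collects the statistical machinery used to characterize a
peroxisomal proteome at several functional levels: stability of
receptor--peptide contacts in molecular-dynamics trajectories, a
range-based classifier for PTS1 cargo peptides, dissociation constants
from fluorescence-anisotropy titrations, normalization and clustering of
flow-injection metabolomics screens, and lipid class enrichment. This
vignette explains each model, its assumptions, the tunable parameters, and
the design choices made where the underlying protocol left the choice
open. Every input can be simulated with designed ground truth, so all
claims here are backed by the package's own tests.

## Hydrogen-bond occupancy from distance series

MD trajectories of receptor--peptide complexes are summarized per contact
as a time series of donor--acceptor distances (ps, nm). A frame is counted
as hydrogen bonded when the distance is at or below 0.35 nm — the boundary
is inclusive, and no angular criterion is applied. Directional judgments
(for instance, arginine side-chain N--H contacts whose geometry cannot
donate a hydrogen bond even within distance) are encoded as an explicit
exclusion list on the contact specification rather than as a geometric
term, keeping the detector a pure distance threshold.

Occupancy is the percentage of bonded frames inside an analysis window.
Windows are anchored at the end of each trajectory — `last90` keeps the
final 90 ns of a 100 ns run, discarding the first 10 ns as equilibration;
`last50` keeps the final 50 ns — and both boundaries are closed. Replicate
trajectories pool by frame-weighted mean, and the analyzed duration is the
sum of window lengths: two 100 ns runs under `last90` report a combined
180 ns. Comparing `last50` against `last90` pooled tables quantifies the
time dependence of each contact; the summary is flagged *minor* when the
largest per-contact delta stays below 5 percentage points (configurable).

Atom roles drive the aggregation rules. Backbone oxygens accept two or
more hydrogen bonds, so their two tracked contacts enter as an arithmetic
sum that may exceed 100%. The C-terminal carboxylate oxygens (OT1/OT2,
position -1 only) are analyzed individually. Backbone nitrogens donate a
single bond, so when several acceptors compete the per-frame minimum
distance is taken before occupancy scoring (`min_distance_merge()`).

Occupancies are reported at full precision; one decimal place is the
conventional display precision. The synthetic generator emits i.i.d.
Bernoulli frames by default — real trajectories are autocorrelated, and a
two-state Markov `persistence` parameter is available to emulate that, but
occupancy expectations are unaffected, so the default stays off and tests
reason with binomial error bars.

## PTS1 cargo classification

For each peptide (the C-terminal hexapeptide of a candidate protein), the
averaged hydrogen-bond stabilities at positions -1 and -3 — the two
positions whose backbone bonds are most stable across known cargos — are
compared against the envelope (min--max range) of a reference set of known
cargo peptides. A candidate passes a position when its stability reaches
the range minimum; it is called a binder when both positions pass.

Two deliberate choices:

* The default pass rule is one-sided (`>= min`). A candidate more stable
  than every known cargo should not fail the test; a strict
  `[min, max]` interval mode is available (`strict_interval = TRUE`) since
  the original protocol does not state which convention was used.
* Ties at exactly the range minimum pass, mirroring the inclusive 0.35 nm
  cutoff convention.

Which contacts enter each position average is configurable through the
contact-spec aggregation tags, because the exact accounting of the
reference analysis is not published in the main text; the default is the
one described above (position -1: the individually tracked carboxylate
contacts plus the backbone-N minimum-distance contact; position -3: the
summed backbone-O pair plus the backbone-N contact). The classifier is
self-consistent by construction (every reference cargo classifies as a
binder against its own envelope) and monotone (raising a stability never
turns a binder into a non-binder); both properties are tested.

## One-site anisotropy binding fits

Fluorescence anisotropy of a labelled peptide probe titrated with receptor
follows the one-site binding-saturation model

$$A(R) \;=\; A_\text{free} + (A_\text{bound} - A_\text{free})
\frac{R}{K_d + R},$$

with $R$ the receptor concentration. Free receptor is approximated by
total receptor: the probe is at ~10 nM against uM-scale $K_d$, so
depletion is negligible; a quadratic depletion-corrected model is
available behind `depletion_corrected = TRUE` for tighter binders.

`fit_one_site()` fits $K_d$, $A_\text{free}$ and $A_\text{bound}$ jointly
across all replicates and experiments by Levenberg--Marquardt least
squares, which preserves the error structure rather than averaging
replicates first (an `average_first` mode exists; for balanced designs the
two coincide). Starting values are derivative-free — plateaus from the
10th/90th anisotropy percentiles, $K_d$ from the concentration nearest
half-signal — with restarts from scaled $K_d$ values before declaring
non-convergence. Degenerate input with no dynamic range returns a flagged
non-converged object instead of an error. The fit is invariant to affine
rescaling of the anisotropy axis, and noiseless curves are recovered to
solver tolerance (both tested).

The simulated titration grid is log-spaced over 0.5--60 uM: the
published nM-scale titration ranges cannot produce saturation against
uM-scale dissociation constants (presumably a units typo), so the
simulation brackets half-saturation from both sides instead of guessing
the intended range. Normalization to fraction bound uses the fitted
plateaus: $(A - \hat A_\text{free}) / (\hat A_\text{bound} - \hat
A_\text{free})$.

```{r kd-example}
tc <- sim_titration(kd = 9.5, noise_sd = 2, seed = 1)
fit_one_site(tc)
```

## Flow-injection metabolomics normalization

The substrate is a samples-by-ions intensity matrix from an untargeted
flow-injection run, with per-sample metadata (strain, condition, OD600 at
harvest, injection order, total ion current). All corrections act on log2
intensities — mass-spectrometric noise is multiplicative — and the
pipeline order is: outlier filtering, injection-order drift correction,
OD600 correction, profile building.

**Outlier filtering.** Samples are discarded when OD600 or total ion
current deviates from the batch median by more than 3 MADs (per condition
batch; the multiplier is `k_mad`, the protocol states the criteria but no
thresholds). TIC is screened on the log scale — instrument failures are
multiplicative — and, when the injection order is known, against a running
median over injection order, so the ordinary acquisition drift does not
inflate the MAD and gross (10x) failures stand out against
injection-level noise. Robust screens have a small false-alarm rate by
construction (~one clean sample per few hundred at 3 MADs); the discard
log records every removal with its reason.

**Drift correction.** Per ion, a LOWESS curve (span 0.3, one robustifying
iteration; the span widens with a warning when the run is too small for
it) of log2 intensity on injection index is subtracted and the ion's
pre-correction median added back, so corrected intensities stay positive
and on the original scale.

**OD600 correction.** Per ion, log2 intensity is regressed linearly on
OD600 and each sample is mapped to the prediction at the reference density
(1.5, the target harvest density) plus its own residual. When this stage
follows the drift correction, the regression uses the injection-detrended
OD600 covariate: the drift smoother has already absorbed the share of the
OD signal that is smooth in injection order, and regressing on raw OD600
would subtract that share twice, re-introducing injection-order structure.
The pipeline wrapper enables this partitioning automatically; both
behaviours are unit-tested.

**Profiles, clustering, enrichment.** Replicates are averaged per strain
on the log scale and then each ion is z-scored across strains (averaging
precedes z-scoring, reading the protocol's "z-scored average profiles"
literally; a z-score-first mode is available for comparison).
Profiles are clustered by Ward's method on the Manhattan distance matrix,
cut at a fixed k (the reference analyses used 20 clusters for
loss-of-function and 18 for overexpression screens). Classical Ward
assumes squared Euclidean input; applying Ward's update to Manhattan
dissimilarities follows the reference protocol and is documented as a
deviation from the textbook assumption. Per cluster, the known annotated
genes within the cluster are tested for GO biological-process enrichment
by the upper-tail hypergeometric test; p-values are Benjamini--Hochberg
adjusted across terms within the cluster, and the term with the largest
enrichment factor (observed/expected rate ratio) among those with
adjusted p < 0.05 is selected, or none. The default background is all
annotated genes supplied for the run; whether the reference analysis used
a condition-specific background is unstated.

**Slope-based fold-changes.** For designs that sample cultures across
OD600 values (0 to ~1.5), the signal is the ordinary least-squares slope
of linear-scale intensity against OD600 per strain and ion; fold-change is
mutant slope over control slope. Ions whose control slope is
statistically indistinguishable from zero (|slope| <= 2 SE) are flagged
and excluded. Slopes are computed on raw linear intensities because the
drift and OD corrections target the fixed-density screen design, not the
time-course design.

## Lipid class enrichment

Lipids are quantified by single-point calibration against a co-measured
internal standard of known amount (intensity ratio times standard
amount). Per-lipid differential abundance between two groups uses a Welch
t-test on log2 amounts with BH adjustment at 0.05 — the underlying
protocol does not name its per-lipid test, so this standard
unequal-variance choice is labelled a reconstruction in the output.
Class-level enrichment of the significantly changing lipids uses the same
hypergeometric core as the GO enrichment (one implementation, shared),
comparing a class's share of significant lipids against its share of all
annotated lipids; directionality is the sign of the mean log2 fold-change
of the class's significant lipids. Lyso-phospholipids are distinct
classes from their parent phospholipids.

## The synthetic-data generators

Each generator produces one module's input with a designed, recorded
truth:

* `sim_distance_series()`: Bernoulli (optionally Markov) bonded/unbonded
  frames at a designed occupancy; two distance levels straddling the
  0.35 nm cutoff.
* `sim_titration()`: one-site model plus Gaussian noise, triplicate
  measurements in three independent experiments by default.
* `sim_metabolomics_plate()`: log2 intensities = ion baseline + drift +
  OD600 slope x OD + planted strain effect + noise. Drift is a smooth
  low-order curve (half-period sine plus linear ramp) chosen so the
  module's default smoother can represent it. OD600 is normal around the
  1.5 harvest target (SD 0.15). Outlier samples get either an overgrown
  culture (4x the target OD) or a 10x total ion current. The recorded TIC
  is the annotated-ion sum plus a dominant unannotated background sharing
  the drift/OD/failure structure, as in a real full-spectrum acquisition
  where annotated ions are a small fraction of the TIC — without it,
  single-metabolite biology on a dominant ion would masquerade as a TIC
  failure. Default nuisance magnitudes (drift amplitude 0.6 log2, noise SD
  0.25) are realistic for flow-injection screens and keep planted 10x
  failures >8 MADs from the clean population.
* `sim_od_course()`: the OD600 time-course design; per-ion control slopes
  with designed per-strain multipliers.
* `sim_lipid_table()`: one planted enriched class, all other lipids null.

The generators emulate the statistical structure the methods assume; they
do not emulate ion correlation structures, missingness, chemical noise,
or peak-annotation ambiguity of real spectra. Passing tests therefore
demonstrate correctness of the computations and recoverability under the
assumed model, not performance on raw instrument data.

## Problem sizes and numerical choices

The validation scenarios are sized so each check has the statistical
power its tolerance implies, while the whole suite runs in well under a
minute:

* occupancy oracles use 10^2--10^4-frame series (binomial SE well below
  the asserted bounds);
* dissociation-constant recovery uses 200 Monte-Carlo titrations of 108
  points each; the median is compared within 10% of truth;
* the metabolomics recovery plate uses 31 strains x 14 replicates (~410
  injections), giving a per-effect estimation SD of ~0.04 log2 against
  the 0.15 recovery bound and enough injections for the residual-drift
  Spearman check at 0.1;
* cluster recovery uses two groups of six strains with opposite planted
  signatures on half the ions (ARI compared against the planted labels);
  planted-effect recovery is measured on a separate sparse-effect plate
  because dense opposite signatures on most samples would inflate the
  per-effect estimation SD past the recovery bound regardless of the
  correction quality — the sparse design matches how mutant screens
  actually look (each mutant perturbs a few ions);
* hypergeometric p-values are verified against exhaustive subset
  enumeration for backgrounds up to N = 30 and against the combinatorial
  sum beyond;
* calibration of the enrichment test under label permutation is checked
  on the randomized probability integral transform, which is exactly
  uniform for a discrete test statistic, with a Kolmogorov--Smirnov test
  at alpha 0.01 summarized over three seeds.

Degenerate inputs are handled explicitly rather than by numerical
accident: empty analysis windows, all-excluded contact lists, zero
dynamic range titrations, constant-OD plates, single-strain profile
requests, zero-variance ions (flagged, profile set to zero), flat control
slopes (flagged, no fold-change), and empty significant sets (all class
p-values 1 with a note) each have a defined, tested behaviour.

## Known limitations

* The distance-only hydrogen-bond criterion cannot see angular geometry;
  wrongly oriented contacts must be excluded by hand via the contact
  table.
* The contact inventory shipped in examples is a documented
  reconstruction, not the original per-complex dataset; users supply
  their own contact specs and reference stabilities for real analyses.
* LOWESS spans, the 3-MAD multiplier, and cluster counts are sensible
  defaults, not optimized values; all are exposed as arguments.
* Ward linkage on Manhattan dissimilarities is a protocol-faithful but
  textbook-deviant combination; dendrogram heights should not be
  interpreted as variance decompositions.
* Per-lipid testing assumes approximate log-normality within groups and
  at least three samples per group.
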