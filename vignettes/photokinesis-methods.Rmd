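---
title: "Scoring and modeling light-evoked photokinesis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and modeling light-evoked photokinesis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(photokin)
```

# The behavioral assay and the photokinesis index

Larval *Astyanax mexicanus* are tracked individually in well plates
while the illumination alternates: a 30-minute dark acclimation, then
5-minute light/dark cycles (`make_schedule(1800, 300, 3, "on")`).
Surface morphs increase locomotion when the lights go off; cave morphs
when they come on. The analysis quantifies this with three steps:

1. `bin_activity()` converts the track into distance moved per 30-s
   bin. Bins are half-open `[t, t + 30)`, a step belongs to the bin
   containing its start time, and a trailing bin not fully covered by
   the track is dropped.
2. `extract_transition_deltas()` takes, at every light transition, the
   mean binned distance in one bin after minus one bin before
   (`window_bins` widens the window symmetrically), and averages these
   per transition type. Averaging the deltas first and forming the
   index afterwards is the package's fixed order of operations; the
   per-transition alternative would weight noisy single transitions
   more heavily and is deliberately not the default.
3. `photokinesis_index()` forms
   `PI = (d_onoff - d_offon) / (d_onoff + d_offon)`.

**Interpretation and range.** With both deltas non-negative — the fish
responds, if at all, with an activity *increase* at each kind of
transition — PI is confined to `[-1, 1]` and behaves like a preference
score. Nothing in the formula forces that situation: a fish with a
*sustained* elevation throughout the dark epochs loses activity at the
dark-to-light transition (`d_offon < 0`), and its PI exceeds +1. The
package reports the formula verbatim rather than clamping, because the
sign (and ordering between populations) carries the biology; the
`[-1, 1]` guarantee is asserted only where its precondition holds.

**Degenerate fish.** When the two deltas nearly cancel
(|sum| < `denom_epsilon`, default 1e-6 mm) the index is numerically
meaningless; such records are flagged `valid = FALSE` with a reason and
excluded from summaries rather than producing huge PI values. A
stationary larva is the canonical case.

**The acclimation boundary** (dark acclimation into the first light
epoch) is not part of the alternating cycles and is excluded from
off-to-on deltas by default (`skip_acclimation = FALSE` includes it).

**Jitter threshold.** Tracker centroids flicker even for a motionless
larva, and summing that flicker over a 30-s bin inflates distances.
Steps below `jitter_mm` are therefore zeroed before binning. The
default is 0.01 mm per step: at the assay's 25 fps, genuine larval
swimming (roughly 0.5-2.5 mm/s) produces steps of 0.02-0.1 mm, so the
threshold must sit *below* that band — a 0.1 mm/step filter, for
comparison, would erase essentially all true locomotion at this frame
rate. 0.01 mm/step corresponds to suppressing apparent speeds under
~0.25 mm/s.

# The synthetic locomotor model

No public raw tracking data exist for this assay, so the package ships
a generator whose outputs have the statistical structure the analysis
assumes. Instantaneous speed is

```
speed(t) = baseline
         + [state == trigger] * (sustained + transient * exp(-(t - t_entry)/tau))
         + Gaussian noise,   floored at 0
```

a baseline, a sustained elevation held while the triggering state
lasts, and a surge that decays (time constant `tau`, default 20 s) from
each entry into the triggering state. Both components are exposed
because the real assay does not quantify their ratio; the defaults
(`baseline 0.8 mm/s`, `sustained 0.15`, `transient 1.5`, `noise 0.6`)
are transient-dominant, which keeps population mean PI near the
interpretable range while still showing sustained elevation in binned
activity traces. With `sustained_gain = 0` and zero noise the index is
exactly +1 (surface-like) or -1 (cave-like) — the package's noiseless
calibration case.

Positions integrate speed as a correlated random walk inside a
circular well (radius 3.4 mm, a 96-well plate well). When a step would
leave the well the heading is redrawn — a "turn at the wall" — so every
per-frame displacement has length exactly `speed * dt`. This was chosen
over reflecting positions at the boundary because reflection shortens
the measured step at each bounce, which would make binned distances
drift below the closed-form expectation of the speed model; with the
turn-at-wall rule the Monte-Carlo mean of every bin matches
`sum(E[max(0, mu + sigma*Z)]) * dt` to within sampling error, and the
noiseless special cases are exact. The walk itself is a small C++
routine driven by R's RNG, so tracks are bit-reproducible under a seed.

# Hybrid crosses

Hybrid phenotypes use an additive model with `k` unlinked equal-effect
loci: the genetic value `g` is the fraction of surface alleles, so
parents are fixed (`g = 1` or `0`), F1 fish are exactly heterozygous
(`g = 0.5`), and F2 fish draw Binomial(2, 1/2) surface alleles per
locus, giving `Var(g) = 1/(8k)`. Per-fish environmental noise
(`env_sd`, default 0.05) is added to `g` before mapping to locomotor
parameters.

Because a parameter set contains a categorical trigger state,
"interpolating between cave and surface parameters" is defined on a
two-state representation: each fish carries sustained/transient gains
for the ON state and for the OFF state, weighted `g` (surface side) and
`1 - g` (cave side). Pure parents recover the single-trigger model
exactly; hybrids respond to both transitions with intermediate
strength, which is what makes F1 fish intermediate and F2 fish span the
grandparental range with inflated variance — the structure
`span_analysis()` quantifies.

`volume_pi_screen()` regresses per-region brain volumes on PI
(Pearson r, slope, intercept) and reports Benjamini-Hochberg q across
regions alongside raw p. The original region screen does not describe
multiple-testing control across the atlas; the package computes both
and defaults interpretation to q. Constant-volume regions are flagged
and excluded from the adjustment; fish missing either measurement are
dropped by an inner join with a logged count.

# Calcium trace tuning and clustering

The imaging protocol is one minute of darkness after laser onset, then
30-s alternating light/dark epochs, four minutes in total
(`make_schedule(60, 30, 3, "on")`). Since the upstream suite's raw
normalization is not specified, the package uses plain dF/F with the
baseline `f0` taken as the mean over the 1-minute dark lead-in
(configurable window). dF/F is invariant to multiplicative gain, so
detector settings cancel.

`compute_tuning()` averages dF/F within each post-acclimation epoch and
summarises ON- and OFF-epoch means; a neuron's preference is the larger
of the two unless they differ by less than the dead-band
(`dead_band = 0.05` dF/F), which prevents labeling noise-level
differences in untuned neurons.

`cluster_tuning()` applies Ward-linkage agglomerative clustering
(`hclust(method = "ward.D2")`) on Euclidean distances between
per-epoch tuning vectors and cuts the tree into exactly `max_clusters`
groups (default 5, the ceiling used by the original imaging analysis).
Linkage and distance are not stated upstream; Ward + Euclidean was
chosen because it is deterministic and variance-minimizing on exactly
the feature the analysis cares about. Clusters are renumbered by
descending size with ties broken by first occurrence, making labels
deterministic and permutation-invariant up to relabeling; the original
suite's internal cluster numbering (e.g. which groups end up as
"clusters 4 and 5") cannot be reproduced and is not attempted.

The trace generator convolves the preferred-state indicator with a
normalized exponential kernel (default `tau = 1.8 s`, nuclear
GCaMP6s-like; the source study does not state kinetics) so the response
saturates at the planted amplitude; the epoch mean of a saturating
response has the closed form `amp * (1 - tau/T * (1 - exp(-T/tau)))`,
which the tests check to 5%.

# Voxelwise activity mapping

`signed_map()` is a deliberately minimal stand-in for whole-brain
activity (pERK) mapping: per-voxel two-sided Mann-Whitney rank-sum
tests between two groups of registered volumes, BH control at
`q <= 0.05`, and a signed mask (+1 where group A's median is higher,
-1 where lower, 0 where not significant). Registration, deformation
fields and reference-brain construction are out of scope — volumes are
inputs. Optional isotropic Gaussian pre-smoothing (`smooth_sigma`, um)
is available because the original method smooths; it is off by default
and documented as an approximation.

p-values come from three regimes:

* total n <= 10: exhaustive enumeration of all group assignments
  (tie-safe via midranks);
* larger samples, voxel without ties: the exact Wilcoxon rank-sum null
  distribution. This matters for mass-univariate FDR: at n = 10 vs 10
  the normal approximation cannot produce two-sided p below ~2e-4,
  which is larger than the BH threshold a modest blob must clear on a
  32,000-voxel grid, and detection collapses; the exact distribution's
  floor is 2/choose(20,10) ~ 1e-5 and sensitivity is restored;
* tied voxels (or `approx = "normal"`): tie-corrected,
  continuity-corrected normal approximation.

`region_summary()` reports, per atlas label (label 0 = background),
the fraction of voxels significant in each direction; region-level
inference is intentionally left to the user.

# Problem sizes, tolerances and reproducibility

Default analysis scales used by the test-suite simulations: cohorts of
50-100 fish for behavioral sign recovery, 199 F2 fish for the
correlation screen (the study's F2 sample size), 48 neurons in five
planted clusters for recovery at `max_clusters = 5`, and 40x40x20
phantoms with 10 subjects per group for mapping. Null calibrations use
1000-2000 replicates for test size and a few hundred tables/phantoms
for FDR, which bounds Monte-Carlo error near 1% while keeping the full
suite around five minutes on one CPU.

Numerical conventions: PI denominators guarded at 1e-6 mm; ANOVA
degenerates (zero between-group variation, including all-constant
input) report F = 0, p = 1 rather than 0/0; constant groups in Welch
cells report p = 1 when means agree; correlation against a constant
vector is flagged rather than computed; BH is `p.adjust(method = "BH")`
and is cross-checked against a brute-force step-up in the tests.

Every generator draws from named substreams derived from one top-level
seed (`derive_seed()`), so adding fish to one cohort never perturbs
another, and `run_pipeline()` writes a manifest with the config hash,
seed and per-file hashes; identical configs give byte-identical
outputs.

# What the synthetic data do and do not show

The generators reproduce the *structure* the analysis relies on —
trigger-state-dependent activity, additive polygenic trait spread,
linear volume-behavior coupling, kernel-shaped tuned fluorescence,
blob-shaped group differences on a noise background — with independent
Gaussian noise throughout. They do not emulate circadian drift,
habituation across cycles, wall-hugging (thigmotaxis), correlated
tracker dropouts, registration error between brains, spatially
correlated imaging noise, or neuropil contamination. Passing tests
therefore certify the computations and their calibration under the
assumed noise model, not robustness of the biology to those real-data
pathologies.
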