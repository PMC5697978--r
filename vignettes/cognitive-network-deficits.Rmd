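---
title: "Detecting cognitive-network connectivity deficits with cognet"
author: "cognet authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting cognitive-network connectivity deficits with cognet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cognet)
```

## The problem

Cognitive impairment in demyelinating disease (and many other neurological
conditions) is thought to reflect disrupted communication between the
distributed brain regions that support a cognitive function, rather than
damage to any single region. Resting-state fMRI offers a task-free probe of
that communication: slow (< 0.1 Hz) BOLD fluctuations are temporally
correlated between functionally connected regions, and a weakened correlation
on a link between two regions is read as weakened functional connectivity.

`cognet` implements a per-patient, normative-band version of this analysis
over five predefined cognitive networks — default mode, attention, verbal
memory, memory and visuospatial working memory — together with two structural
companions: normalized volumetry with a thalamus asymmetry index, and a
single-case voxelwise comparison of skeletonized white-matter FA maps.
Because individual patients are compared against a control cohort (rather
than group means against group means), the output is a per-patient list of
abnormal links, which can then be aggregated.

## Networks, nodes and links

A network is a list of bilateral region names; every region contributes a
left and a right node, so *k* regions give *n = 2k* nodes and
*n(n−1)/2* unordered links:

```{r}
nets <- defaultNetworks()
data.frame(network = names(nets),
           regions = vapply(nets, function(n) length(n@regions), integer(1)),
           nodes = vapply(nets, nNodes, integer(1)),
           links = vapply(nets, linkCount, numeric(1)))
```

Two encoding decisions are worth spelling out. First, the default-mode
network is encoded with four bilateral regions (medial prefrontal cortex,
cingulate cortex as a single merged region, precuneus, lateral parietal
cortex): the five-region listing found in the source literature collapses to
four once the rostral anterior and posterior cingulate are treated as one
cingulate region, and only that reading matches the widely quoted 28-link
count for an 8-node DMN. Second, the attention network keeps its full
six-region listing (12 nodes, 66 links) even though published link tallies
for it assume a 10-node network; the discrepancy is documented here rather
than silently resolved, and no quantitative check in this package depends on
the attention link count. The fornix appears in the visuospatial network as
listed, although it is a white-matter structure.

Region names resolve to integer parcellation labels through an editable JSON
dictionary (`inst/extdata/networks.json`); any parcellation can be used by
supplying a different dictionary.

## Preprocessing

Two operations, applied in order, with fixed contracts:

* **Physiological regression** (`regressPhysio`): each voxel series is
  replaced by its least-squares residual against
  `[intercept, linear trend, cardiac, respiratory]`, the physiological
  traces being linearly interpolated to frame times. Residuals are orthogonal
  to every retained column to machine precision, and the operation is a
  projection (applying it twice equals applying it once). Numerically
  constant or redundant columns are dropped with a warning instead of
  producing a rank-deficient fit. The recorded traces are used directly as
  regressors — no cardiac-phase (RETROICOR-style) expansion — which exactly
  matches how the synthetic generator embeds its confounds.
* **Low-pass filtering** (`lowpass`): every voxel series is filtered below
  0.08 Hz (default) with a 4th-order Butterworth applied forward and
  backward, giving exactly zero phase shift. Two passes square the magnitude
  response, so the single-pass design cutoff is widened by the standard
  compensation factor `(sqrt(2)-1)^(-1/8) ≈ 1.116`; with that compensation
  the combined response keeps at least 90 % amplitude below 0.8 × cutoff and
  passes at most 10 % above 2 × cutoff at TR = 2 s, and DC survives exactly.
  The filter is applied voxelwise before extraction; since extraction is a
  mean (linear), filtering ROI-averaged signals instead would give identical
  node signals.

The forward–backward pass is implemented as a vectorized direct-form II
transposed recursion over a time × voxel matrix, with odd-reflection edge
padding and steady-state initial conditions — the same edge treatment as the
reference `filtfilt` implementations, applied to all voxels simultaneously.

Slice-timing correction, realignment, smoothing and coregistration are out of
scope: inputs are assumed aligned to the parcellation grid, and
`extractRoiSignals` refuses inputs whose affines disagree (tolerance 1e-4)
instead of resampling.

## The normative ±2 SD rule

For each link, the control cohort supplies a sample mean and SD (n − 1
denominator); a patient's correlation is *reduced* below mean − 2 SD and
*elevated* above mean + 2 SD. When control sex labels are available the band
is fitted per sex and each patient is compared against same-sex controls
(the default); with no labels all controls pool. Links with fewer than two
usable controls, or a NaN patient value, are *undefined* and excluded from
counts.

Under Gaussian link values and an infinitely large control cohort the rule
flags 2·Φ(−2) ≈ 4.55 % of null links two-sidedly; with 20 controls the rate
inflates somewhat (the acceptance suite asserts the band 3–9 %). No
multiple-testing correction is applied across links, deliberately: the
downstream statistic is the per-patient *count* of reduced links, not
link-wise inference.

The per-network deficit test is a one-sample two-sided t-test of per-patient
reduced-link counts against a null count. The null defaults to 0 — testing
that patients have any deficit at all — because that is the only reading
consistent with reporting small per-network means as significant; a
calibrated alternative (`null = "calibrated"`, expected false-positive count
Φ(−2)·L) is available and is the stricter question. Both are first-class and
neither is asserted as canonical. Inter-network structure is summarized by
Pearson correlations of per-patient counts between networks.

## Volumetry and asymmetry

Raw region volume is voxel count × |det(affine 3×3)|; normalized volume is
the fraction of total brain volume, defined as the sum over all labelled
segments — grey matter, white matter *and* CSF spaces — so GM + WM + CSF
fractions sum to 1 by construction. The asymmetry index of a paired
structure is AI = |V_L − V_R| / ((V_L + V_R)/2), in [0, 2]. The defining
formula is signed, but the magnitude is reported by default: group summaries
of asymmetry pool patients whose *smaller* side differs, and mean signed
values near zero would mask real asymmetry; the signed value remains
available (`signed = TRUE`). Group differences use Welch's t-test (groups of
10 and 20 should not be assumed equal-variance).

## FA single-case comparison

One patient against n controls is a single-case design: the default
statistic is the Crawford–Howell t, `(x − mean_c)/(sd_c·sqrt(1 + 1/n))` with
n − 1 df, which accounts for the patient being a single draw from the
control population. The naive form `(x − mean_c)/(sd_c/sqrt(n))` — treating
the patient value as if it were a group mean — is anti-conservative by a
factor `sqrt(n(1+1/n))` and is provided only as a flag. Voxels are analysed
when they lie on the common skeleton and the *control mean* FA is at least
0.2 (the conventional white-matter threshold); no cluster-level or TFCE
correction is applied, matching the voxelwise character of the analysis.
Registration to a standard FA template and skeletonization itself are out of
scope — inputs are pre-skeletonized maps on a common grid.

## The synthetic study generator

The generator is first-class, tested code: it produces every input the
pipeline consumes, with known planted structure, under a strict seeding
contract (identical seed + config → bit-identical outputs; per-subject
random streams derived from the master seed, so extending a cohort never
perturbs existing subjects).

Default study conditions: 20 controls (10 male, 10 female) and 10 patients
(9 female, 1 male); 150 volumes at TR = 2 s; per-subject GM/WM fractions
drawn from group-specific normals (controls 0.453 ± 0.011 / 0.281 ± 0.0168,
patients 0.435 ± 0.021 / 0.297 ± 0.048) and thalamus asymmetry magnitudes
from 0.089 ± 0.057 (controls) vs 0.188 ± 0.172 (patients), the affected side
random. These are the published group conditions the package emulates.

* **Label maps**: regions occupy contiguous blocks of the flattened grid;
  the brain voxel budget is apportioned to the subject's tissue fractions by
  largest-remainder rounding, and the thalamus pair is split so its integer
  voxel counts realize the planted asymmetry index (`splitPairedVoxels`,
  exact up to one-voxel quantization — the recovered AI differs from the
  planted value by at most ~4/total pair voxels).
* **BOLD**: regional latent signals are i.i.d. over time from a multivariate
  Gaussian with the planted correlation structure; every voxel of a region
  carries its region's latent plus independent Gaussian noise plus two
  sinusoidal confounds (cardiac 1.1 Hz, respiratory 0.3 Hz, random phase per
  subject). There is no hemodynamic convolution, drift or motion — the
  analysis consumes only second-order structure, and stationary Gaussian
  latents exercise it fully. The cardiac fundamental is deliberately not an
  integer multiple of 1/TR (1.1, not 1.0 Hz), so its alias at 0.1 Hz is
  visible in the sampled frames and the regression step has real work to do.
  The physiological trace is sampled at 25 Hz, high enough that linear
  interpolation back to frame times reproduces the embedded confound to ~1 %.
* **Planted connectivity**: the default plants r = 0.35 on every
  within-network link, and weakens 3 links per network to r = 0 in each
  patient. Pairwise targets over overlapping networks are generally not
  jointly realizable as a correlation matrix; `psdRepair` clips negative
  eigenvalues at zero and renormalizes to unit diagonal, and aborts if any
  entry moves beyond a tolerance (default 0.5 in the generator). 0.35 is the
  largest round default at which repair distortion of the five-network union
  stays below ~0.11; higher values are accepted but increasingly reshaped.
  The matrix square root is taken by eigendecomposition rather than
  Cholesky so that exactly singular targets (a planted r of 1) remain
  usable.
* **FA skeletons**: a fixed two-sheet skeleton geometry per grid; control
  values are N(0.5, 0.03) clamped to [0.2, 1]; patients carry a contiguous
  cubic patch (Chebyshev radius 2) in which FA is reduced by 0.15. The patch
  geometry is a generator convenience — nothing in the analysis assumes it —
  and `faLesionMask` recovers the planted patch for validation.

What the generator does *not* emulate — hemodynamics, motion, scanner drift,
EPI distortion, registration error, spatially correlated noise, realistic
anatomy — bounds what passing tests show: they validate the statistics and
the code, not robustness to real-data artefacts upstream of this pipeline's
contract.

## Orchestration and problem sizes

`runPipeline` composes the stages in memory and writes a deterministic
report bundle (summary JSON and long-format TSVs; NIfTI export of all
inputs and statistic overlays is optional via `writeImages`). Keeping the
stage hand-offs in memory rather than on disk avoids writing thirty 4D
volumes per run; every stage remains independently runnable on files through
the exported readers/writers and the thin CLI (`inst/scripts/cognet.R`).
Failures are re-raised with the failing stage's name.

The shipped demo scale — a 20 × 20 × 10 grid (about 2 600 brain voxels,
thalami of ~120 voxels each so AI quantization is ~0.017) with 30 subjects —
was chosen so a full study, including preprocessing of every voxel series,
runs in well under a minute while every statistical property of interest
(band calibration, planted-link recovery, asymmetry recovery, FA detection)
is measurable. The validation suites use 1 000 null subjects for band
calibration, 100 patients for sensitivity, 100 replicate cohorts for power,
and 50 null cases for the FA level — sizes at which the asserted bands have
comfortable Monte-Carlo margins.

## Known limitations

* Correlation targets after PSD repair are the *effective* planted values;
  recovery statements at high overlap refer to the repaired matrix.
* The ±2 SD band with 20 controls is anti-conservative relative to its
  Gaussian asymptote (flag rate ~6 % rather than 4.55 %); a t-quantile band
  would be exact but would not be the method implemented here.
* Volumetric asymmetry is quantized by voxel counts; planted AI below the
  quantization step of a small structure is unrecoverable.
* The attention-network link-count discrepancy in the source listing is
  carried, documented, not resolved.
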