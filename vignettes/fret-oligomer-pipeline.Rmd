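---
title: "Detecting and classifying protein oligomers from two-colour FRET data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and classifying protein oligomers from two-colour FRET data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oligofret)
```

# The measurement model

When a protein is split into two equimolar pools carrying a donor and an
acceptor fluorophore, co-assembly into an oligomer brings dyes within Förster
distance (< 10 nm) and energy transfer occurs. `oligofret` analyses the two
observable consequences: acceptor emission under donor excitation (the FRET
channel) and the per-event efficiency of transfer, which reports the packing
of the assembly — loosely packed oligomers populate a low-efficiency mode,
compact β-sheet-rich oligomers a higher one.

All analyses share the same per-observation arithmetic, whether an
observation is a summed confocal burst or a single voxel. Raw donor (`D`)
and acceptor (`A`) counts under donor excitation are corrected for
instrument autofluorescence (`A_D`, `A_A`, measured without fluorophores)
and for donor→acceptor cross-talk (`C`); acceptor→donor cross-talk is taken
as negligible:

$$I_D = D - A_D, \qquad I_A = A - A_A - C\,D$$

$$E = \frac{I_A}{I_A + I_D}, \qquad
  \text{size} = \frac{2\,(I_D + I_A/\gamma)}{I_\text{monomer}}$$

The gamma factor $\gamma$ absorbs the relative detection efficiencies and
quantum yields of the two dyes; only the donor dye is directly excited, so
total corrected brightness counts donor fluorophores and the factor 2
converts to monomers (every second monomer carries the donor). The size is
*apparent*: excitation is stochastic and molecules take varied paths through
the confocal volume.

**Assumptions.** Corrections are linear and channel-wise; direct excitation
of the acceptor by the donor laser is not modelled (no correction term for
it exists in the model above, and in-cell voxel efficiencies use the same
uncorrected-for-$\gamma$ ratio as burst efficiencies). Negative corrected
intensities — possible in dim observations once background is subtracted —
are *flagged and excluded*, never clamped: clamping at zero would pile
efficiency mass at 0 or 1 and bias the histograms. Exclusion counts are
carried on every result object.

# Tunable parameters

| Parameter | Default | Units | Why |
| --- | --- | --- | --- |
| event threshold | 10 | counts/bin/channel | a burst is real when a channel reaches this; coincidence requires both channels |
| histogram bin width | 0.05 | efficiency | standard binning for efficiency histograms; divides [0, 1] evenly |
| $\gamma$ | 1 | — | instrument-specific; override when measured |
| mask stringency `k` | 3 | blank SDs | direct-channel threshold `mean + k·sd` of a blank keeps the Gaussian false-positive rate near 0.1% |
| step penalty | `3·log n` | — | modified-BIC regime for scanned change points (below) |
| minimum plateau | 3 | frames | guards against single-frame noise excursions |
| coincidence radius | 2 | px | sub-pixel localization errors are ~0.2–0.3 px, so 2 px accepts true pairs without inflating chance overlap |
| bootstrap resamples | 9,999 | — | percentile CI of per-cell means |

# Burst analysis

A donor *event* is a maximal run of consecutive bins at or above threshold in
the donor channel; merging consecutive supra-threshold bins prevents a slow
transit from being counted twice. An event is *coincident* — i.e. an
oligomer carrying both dyes — when at least one of its bins also reaches
threshold in the acceptor channel. Event intensity is the run sum by
default; a peak (single-bin maximum) mode is provided since either
convention appears in practice. Runs touching the trace boundary are kept
but flagged.

One subtlety of run merging: the number of *events* is not monotone in the
threshold (raising it can split one long run into two), although the number
of supra-threshold *bins* is. The tests assert the per-bin form and the
event-level form in the single-bin regime where they coincide.

Monomer brightness `I_monomer` is the mean donor intensity of
*non-coincident* events — species carrying only donor dye. When a sample
contains no monomeric donor species the estimate is biased and the package
requires an explicit calibration value instead.

# Global two-Gaussian deconvolution

Efficiency histograms from every timepoint and treatment are fitted
*simultaneously* with two Gaussian components whose centers and widths are
shared across datasets while amplitudes remain per-dataset. Sharing the
shape guarantees the same two populations are identified everywhere and
pools their information; after fitting, components are ordered by center so
the higher-FRET (compact, "Type-B-like") component is always second. The
fraction converted for a dataset is the analytic area ratio
$a_2 w_2 / (a_1 w_1 + a_2 w_2)$, with a first-order (delta-method) standard
error from the fit covariance.

**Numerical choices.**

* *Least squares on counts, Levenberg–Marquardt.* Deterministic multi-start:
  centers are seeded from the two tallest well-separated modes of the pooled
  histogram plus a fixed 3×3 grid of center pairs; the best sum of squares
  wins and ties break by candidate order, so the fit is reproducible.
* *Poisson weighting by default.* Histogram bins are Poisson counts, so
  residuals are scaled by $1/\sqrt{\max(y, 1)}$. This is not cosmetic: with
  unweighted least squares the *global* optimum for a 10%-weight second
  component misallocates it into a broad tail term under the main peak
  (recovered fraction 0.38 for a true 0.10 on a 5,000-event simulation —
  and the fit converges there even when started at the true centers), while
  the weighted fit recovers 0.14. Unweighted fitting remains available as
  `weighting = "none"`.
* *Degeneracy.* Fits whose centers collapse within one bin width, or with a
  vanished component in every dataset, are flagged and refuse to report a
  fraction.
* *Bounds.* Centers in [0, 1], widths in [bin/2, 0.5], amplitudes ≥ 0.

`bootstrap_mean_ci()` provides the percentile bootstrap (default 9,999
resamples) used for per-cell summaries, where a handful of cells per
condition makes normal-theory intervals unreliable.

# In-cell voxel analysis

Three aligned channels are required: donor-excitation/donor-emission,
donor-excitation/acceptor-emission (FRET) and
acceptor-excitation/acceptor-emission. The direct channel is a
FRET-independent total-protein proxy, so masking is performed on it:
voxels with `direct > mean_blank + k·sd_blank` (default `k = 3`) enter the
analysis. Efficiency, corrected intensities and exclusions are computed per
masked voxel exactly as for bursts. Per-cell summaries (mean efficiency
over valid masked voxels, mean direct intensity, mean corrected FRET
intensity) take cells as *label masks* supplied by the user or the
generator — cell segmentation is deliberately out of scope. Voxel
efficiencies feed the same histogram/deconvolution route as burst
efficiencies.

# Photobleaching step counting

Each fluorophore bleaches in a single discrete event, so a spot's
intensity trace is a descending staircase whose step count estimates the
number of labelled monomers. The fit is piecewise-constant by greedy
change-point insertion: each insertion takes the split that maximally
reduces the residual sum of squares (minimum plateau 3 frames), the path is
followed while any split helps, and the returned model minimises the
penalised criterion $n\log(\mathrm{RSS}/n) + \lambda k$ along the path,
followed by a relocate-and-prune refinement. Choosing the criterion
*globally* along the insertion path matters: stopping at the first
non-improving insertion stalls on staircases with many comparable steps.

The default penalty is $\lambda = 3\log n$ rather than the classical BIC
$\log n$: a change point contributes a level *and* a location that is
scanned over every admissible frame, and the scan maximum of a spurious
split's RSS reduction itself grows like $2\log n\,\sigma^2$, so lighter
penalties admit false steps (the modified-BIC argument for change-point
problems). Only downward steps count as photobleaching; upward steps
(blinking or re-activation) are flagged and excluded. Counts at or above
the saturation cap (default 10) are reported as a censored "≥ cap"
category — larger oligomers bleach several fluorophores within a frame and
cannot be resolved by counting.

# Two-colour spot coincidence

Spots are detected per channel by a difference-of-Gaussians band-pass at
the PSF scale followed by local maxima above `median + k·MAD` of the
filtered image (default `k = 7`). The robust floor matters: in a sparse
spot field the plain standard deviation of the filtered image is dominated
by the spots themselves and would reject dim but genuine detections.
Sub-pixel positions come from a 3×3 intensity-weighted centroid. Spots
closer than roughly twice the PSF sigma merge into one detection — a limit
of any maxima rule, which is why the generator's default field density is
kept in the sparse regime single-aggregate imaging requires (~0.1 spots/µm²
at 100 nm pixels).

A channel-A spot is coincident when any channel-B spot lies within the
matching radius (one-to-many matches count once: aggregates, not
localizations, are the unit). Alongside the percentage, a 90°-rotation
control of channel B estimates chance coincidence, which for sparse fields
approaches the analytic $100\,n_B \pi r^2 / \text{area}$. The default
confidence interval is a *two-stage* percentile bootstrap — fields are
resampled, then per-spot coincidence indicators are resampled within each
drawn field. With the typical handful of fields, a field-level-only
bootstrap understates the uncertainty (it ignores the within-field binomial
noise of several hundred spots per field) and its nominal coverage is far
below 95%; the two-stage interval restores honest coverage. A
`mean ± 1.96·sd` mode is provided for comparability with reports whose
intervals can exceed 100%.

# The synthetic generators

The generators emulate the *statistical contract* of the analysis, not the
microscope — no diffusion physics, no 3-D PSF, no flow profile.

* **Burst streams.** Event arrivals are Poisson in time (pile-up allowed
  and recorded); each event draws a species, a true efficiency from a
  truncated normal, and photons as Poisson counts with donor mean
  $B(1-E)$ and acceptor mean $\gamma B E$; per-bin Poisson backgrounds use
  the same `A_D`, `A_A` constants the corrections subtract, and cross-talk
  is drawn as `Poisson(C × measured donor counts)` so the Eq.-style
  corrections are exactly unbiased against the generator. Donor
  fluorophores per event are `ceiling(size/2)`, matching the sizing
  convention. The `paper_mimic` preset fixes the two efficiency components
  at 0.24 and 0.48 with spread 0.08 and weights 60/40, size-6 oligomers at
  50 photons per monomer per event, `A_D = A_A = 2` counts/bin,
  `C = 0.05`, `γ = 1`, and 1 ms bins at an event rate giving 5,000 expected
  events per 600 s acquisition. The spread, weights, brightness and
  backgrounds are free simulation knobs fixed once at values typical for
  fast-flow single-molecule data; the component centers are the preset's
  defining feature.
* **In-cell stacks.** Aggregates are spherical cores of high efficiency
  with lower-efficiency rims (the stereotyped geometry of maturing
  aggregates: ordered center, loosely ordered shell); every voxel is
  Poisson-sampled and autofluorescence covers the field.
* **Bleach traces.** Geometric bleaching times, truncated so every
  fluorophore bleaches within the trace and separated by at least 5 frames:
  the generator emulates *resolvable* steps, because simultaneous bleaching
  is precisely the regime in which counting saturates.
* **Spot fields.** A set fraction of spots share coordinates across
  channels; the rest are uniform. Gaussian PSF rendering with
  gamma-distributed intensities and Poisson shot noise.

Fixed seeds give bit-identical outputs, and every dataset carries its
ground truth as a side channel that analysis code never reads.

**What passing tests do and do not show.** The generators realise exactly
the model the corrections assume — linear cross-talk, known backgrounds,
Gaussian-like efficiency components. Real data add focal drift,
non-uniform illumination, acceptor direct excitation, photophysics
(blinking beyond simple upward steps), and cell segmentation errors, none
of which are emulated; recovery on synthetic data validates the
implementation and the estimators' statistical behaviour, not robustness
to those effects.

# Problem sizes and determinism

The validation suite runs at desk scale: 5,000-event streams for center and
fraction recovery (recovery grids at nine mixing fractions), 200 simulated
six-step traces for step counting, five 1024² two-colour fields for
coincidence, and 64×64×8 voxel stacks for the in-cell route. All random
draws flow from explicit seeds; analyses themselves are deterministic given
their inputs (the mixture fit's multi-start is a fixed list).

# Known limitations

* Sizing assumes the 1:1 donor:acceptor labelling convention behind the
  factor 2; other stoichiometries need a rescaled `I_monomer`.
* `monomer_brightness()` is biased when no genuinely monomeric donor-only
  species is present; supply a calibration value then.
* The two-component mixture is fixed: no model selection across 1–3
  components is attempted.
* Step counting saturates around the cap and the fitter cannot separate
  steps closer than the minimum plateau.
* Spot detection merges sub-PSF pairs; at high field densities the
  coincidence percentage is biased low by partner merging.
* In-cell analysis trusts channel alignment and user-provided cell labels.
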