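---
title: "Models and methods behind hrdquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hrdquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrdquant)
```

# What the package models

Heterochromatin-retained proteins such as the KMT5C retention domain show
two kinetic signatures that ordinary FRAP summaries conflate: fast
*internal* mixing within a chromocenter and very slow *exchange* between
the chromocenter and the nucleoplasm. `hrdquant` implements the
quantification pipeline for both signatures (FRAP normalization and
fitting, inverse-FRAP efflux extrapolation, partition coefficients,
construct-panel clustering, motif and linker sequence features) and a
synthetic-data module that generates every input with known ground truth.
This vignette records the models, defaults, and the design decisions made
where several choices were defensible.

# The nucleus simulator

## Formalism

The simulator is a deterministic continuum scheme on a 2D pixel lattice
with two fluorescent fields per pixel: free `F` (diffusing at `D_free`,
no-flux at the elliptical nuclear envelope) and bound `B`. Binding sites
are laid out as a top-hat map: density `s_cc` inside circular
chromocenter foci, `s_np` (default 0) elsewhere in the nucleus. Exchange
is linear mass action with pseudo-first-order on-rate
`k_on = k_on_per_site * s(x)` and off-rate `k_off`. Each step is
Lie-split: an explicit 5-point diffusion step (stable for
`dt <= pixel_size^2 / (4 * max(D_free, D_bound))`; constructors reject
larger `dt` and default to 90% of the bound) followed by the *exact*
closed-form relaxation of the two-state exchange, so stiff binding rates
never constrain the time step. The symmetric stencil conserves total
fluorescence to floating-point roundoff — the test suite asserts relative
drift below 1e-12 — and fluorescence changes only at the bleach event,
which multiplies both fields inside the bleach region by `bleach_depth`
instantaneously (no bleach kinetics are modelled). Runs start from the
analytic steady state (uniform free concentration; `B = K(x) F`) and a
run-in loop verifies stationarity to 1e-6 per frame before bleaching.

## Why the bound field hops

With an immobile bound state and a single off-rate, both internal
remixing after a partial bleach and whole-compartment exchange are
governed by the same retarded diffusivity `D_free / (1 + K)`, where
`K = k_on s / k_off` is the bound:free ratio. An eigenmode estimate makes
the consequence explicit: the slowest internal mode of a disk of radius
`R` relaxes in about `R^2 (1 + K) / (14.7 D)`, while refilling the whole
disk through the nucleoplasm takes about `R^2 (1 + K) ln(d/R) / (4 D)`
(`d` the supply distance), so their ratio is a pure geometry factor of
order 10 — `K` cancels. We verified this numerically: no rate
combination, nor weak additional nucleoplasmic binding (which merely
installs a local fluorescence reservoir that *accelerates* the measured
exchange), pushed the separation beyond ~10-fold, far short of the two
orders of magnitude that retention requires.

The missing physics is transfer between binding sites without full
release — hopping or facilitated dissociation along the immobile
chromatin scaffold. The simulator therefore lets the bound field diffuse
with a small coefficient `D_bound`, with coupling confined to the site
region (a bound molecule can reach an adjacent site-bearing pixel but can
never cross site-free territory). Internal remixing is then set by
`D_bound` over the compartment scale, while escape still requires full
release and is paced by `k_off` times the escape probability
`~ 1 / (1 + k_on s R^2 / D_free)`. The two timescales become independent
knobs, which is precisely the observed phenomenology.

## Presets

Presets encode the three archetypes seen across heterochromatin proteins
(`sim_preset()`):

| preset       | `D_free` | `D_bound` | `k_on_per_site` | `k_off` | `s_cc` | realized phenotype |
|--------------|---------:|----------:|----------------:|--------:|-------:|--------------------|
| `retentive`  | 0.5      | 0.005     | 0.02            | 2e-4    | 100    | stripe remix ~20 s; efflux ~0.45 %/min; total-bleach recovery <1% at 100 s |
| `exchanging` | 0.5      | 0         | 0.05            | 1.0     | 100    | total-bleach recovery >90% at 100 s |
| `unbound`    | 0.5      | 0         | 0               | 1.0     | 0      | uniform concentration (PC ~ 1), half-recovery <1 s |

Units: µm²/s for diffusivities, 1/s for rates, sites/pixel for densities
at 0.1 µm/pixel. The retentive rates were placed by the closed-form
scaling above — `D_bound ~ R^2 * 14.7^-1 / t_internal` for a ~20–30 s
remix over a 1 µm focus, `k_off` set so the efflux extrapolation lands
below 1 %/min — and then verified by simulation; the defining property
of a preset is its phenotype, not a particular parameter value.
Chromocenter geometry (four foci of radius 1 µm in a 6 × 8.4 µm
ellipse at 0.1 µm/pixel) is a configurable default, not a
literature-derived constant: focus counts and sizes vary widely between
nuclei.

## Other simulator choices

* **Counterstain channel**: rendered from the ground-truth masks at fixed
  intensity ratios (chromatin dense in chromocenters), independent of the
  protein's partitioning — the stand-in for a Hoechst/DAPI channel.
* **Noise**: readout-only, mixed Poisson (scaled so `photons_at_np` sets
  the nucleoplasm SNR to `sqrt(photons_at_np)`) plus Gaussian read noise;
  field dynamics stay deterministic. Acquisition photobleaching is
  emulated as a global per-frame readout factor, which the scanning
  normalization removes exactly.
* **Expression series**: at a no-flux steady state the free concentration
  is spatially uniform, so the saturating mass-action steady state
  reduces to a scalar conservation equation solved exactly
  (`uniroot` to 1e-12 relative tolerance) rather than by time stepping;
  images are rendered from the resulting concentrations, and the
  time-dependent simulator is still used for the FRAP side of the
  saturation analysis with the on-rate linearized about the saturated
  occupancy.
* **Sequence generator**: motif instances are sampled from their
  grammars; wildcard and flank positions come from a reduced alphabet
  that cannot seed motifs; linker composition targets (NCPR, FCR,
  disorder-promoting fraction) are met by integer-count construction and
  rejected if infeasible (`|NCPR| <= FCR <= 1`). Candidate sequences are
  resampled until the scanner recovers exactly the planted architecture;
  the nested grammar family (every phi2/phi3 ends in a legal `V-x-L`
  phi1 core, and phi3 is a legal phi2) is tolerated as derived
  sub-motifs, not spurious hits.
* **Seeds**: every stochastic operation takes an explicit seed; the
  pipeline derives stage seeds from one master seed.

Passing tests on these synthetic data demonstrate correctness of the
*quantification* — formulas, fits, segmentation, clustering — under
controlled conditions. They do not certify performance on real
micrographs, which add focal drift, uneven illumination, 3D effects and
segmentation ambiguity that the generator deliberately omits.

# FRAP quantification

The normalization chain follows the standard protocol exactly:
background subtraction per frame; scanning-bleach correction
`NormI(t_n) = I(t_1)_nucleus / I(t_n)_nucleus * I(t_n)_ROI` anchored at
the **first post-bleach frame** (`anchor = "pre"` is available because
the anchoring convention differs between published protocols); relative
fluorescence as `NormI(t_n) / I(t_pre)` anchored at the **pre-bleach**
timepoint. Applied to a series with zero background and a constant
nuclear trace this chain is the identity up to the pre-bleach scale — a
property test asserts it.

The double-term exponential fit runs on post-bleach frames with time
re-zeroed at the bleach frame, bounds `a_i` in `[0, 1.5]` and `tau` in
`[1e-3, 1e4]` s, and 8 multi-starts on a log-spaced `tau` grid with the
lowest residual sum of squares winning; `tau1 <= tau2` by convention. If
no start converges, a single-exponential fallback (and, for step-like
records, a constant-plateau description) is returned flagged `degraded`.
On noiseless double-exponential curves the fit is exact (RSS < 1e-10,
parameters within 1%); under replicate-averaged noise (pointwise mean of
15 curves with 4% per-cell readout noise) parameters are recovered within
10%.

`recovery_at()` reports *fractional* recovery,
`(value - post-bleach minimum) / (1 - minimum)`, because raw relative
fluorescence is not comparable across constructs with different bleach
depths; the raw value is available via `type = "raw"` since either
reading of published recovery-at-time values is defensible.

`internal_equilibration_time()` measures the first time fractional
recovery exceeds a threshold (default 0.95) of the fitted plateau. The
0.95-of-plateau rule is this package's operationalization of "fully
remixed": kymograph-based readings of remixing are qualitative, and for
a single-exponential recovery the rule reproduces the closed-form
`3 tau` within the frame spacing.

`ifrap_efflux()` fits ordinary least squares to percent intensity versus
minutes (robust alternatives are out of scope), returns `ER_app` =
−slope, the complete-turnover extrapolation `100 / ER_app` (hours), and,
given an internal equilibration time, the equilibration ratio
(turnover in seconds / internal time in seconds). Apparent influx
(positive slope) yields rate 0 with a warning; a flat curve yields an
undefined turnover flagged `no_efflux`. The identities
`turnover * rate = 100` and `ratio = turnover / internal` hold exactly
by construction and are asserted in tests.

# Partitioning

Segmentation replaces interactive pixel classification with a
deterministic 3-class k-means on intensities, initialized at the
5th/50th/95th percentiles, plus removal of chromocenter components
smaller than 9 pixels; `mode = "counterstain"` segments the DNA channel
and transfers labels, for proteins with no chromocenter contrast. The
ground-truth-mask pathway isolates formula correctness from segmentation
quality; at nucleoplasm SNR ~ 10 the segmented and ground-truth PC agree
within 5% and per-pixel accuracy exceeds 95%.

`partition_coefficient()` applies
`PC = (mean_cc - mean_bg) / (mean_np - mean_bg)` per nucleus, with the
whole-nucleus mean over chromocenter plus nucleoplasm pixels. Cells whose
background-corrected nucleoplasm signal falls below 3 background standard
deviations are flagged (not silently dropped) so exploding ratios can be
excluded and counted. Since box plots of published panels display
medians, both mean and median PC are emitted by the binning and panel
summaries.

"Normalized intensity" in expression scatters is not uniquely defined;
`normalized_scatter()` divides background-corrected chromocenter and
nucleoplasm means by their construct-wise maxima and records that choice
in an attribute, with the `y = x` diagonal (PC = 1) as the reference.
Images are 2D; saturation-regime acquisitions at reduced laser power can
be harmonized with a per-batch intensity scale factor before computing
records.

# Panel analysis

`assemble_panel()` reduces cells to per-construct medians of PC and
fractional recovery at 5 s and 100 s (and the mobile fraction, which can
be added as a fourth clustering feature but is excluded by default, as
clustering published panels used the three displayed metrics).
`cluster_panel()` z-scores features, uses Euclidean distance with average
linkage (the common heatmap default; the distance and linkage are
arguments, since no single convention is canonical), cuts at `k`, and
relabels clusters by decreasing mean PC so labels are deterministic and
row-order invariant. `compare_pc()` runs Kruskal–Wallis across
constructs and pairwise Wilcoxon rank-sum tests; because many pairwise
comparisons are reported, Holm-adjusted p-values accompany the raw ones.

# Sequence features

Motif grammars are formalized as position-constraint templates; variable
gaps are expanded so *all* alternative spans are enumerated, overlapping
matches included, and `X` matches only wildcard positions. The primate
phi1 flank signature (threonine–histidine at −7/−6) is reported as an
annotation rather than a match constraint, since flanks are described
empirically, not as requirements. `call_hrd()` selects a
phi1→His-Cys→phi2 chain under the gap constraints (defaults 0 and 1
residues — the invariant spacings), then the nearest downstream phi3
within linker-length bounds; ambiguity resolves by minimal total span
then leftmost, and incomplete architectures are legal outputs.
Coordinates are 1-based inclusive everywhere.

Linker features treat histidine as uncharged (the convention of the
sequence-parameter literature), use the disorder-promoting set
`{A, R, G, Q, S, P, E, K}` (configurable), and assign conformational
classes by nearest FCR level in an editable reference table pairing the
five-member designed-linker series with functional lengths 13, 22.5,
34.3, 53.9 and 66.6 Å; the lengths are literature constants, the FCR
levels (0, 0.15, 0.30, 0.40, 0.50) are this package's calibration.
`alignment_identity()` counts invariant, gap-free columns over the full
aligned width — with the caveat that published domain boundaries and
residue counts can disagree by one; the function reports both the column
count and the invariant count so users can reconcile externally.

# Problem sizes and determinism

The shipped tests and the acceptance script run at desk scale: a 72 × 96
pixel nucleus (0.1 µm/pixel), 100–600 s simulated experiments at
dt = 4.5 ms, 45-cell Monte-Carlo estimator checks, 1000-sequence scanner
equivalence, and a 12-construct planted panel. These sizes were chosen so
the full suite completes in about a minute while leaving every
statistical margin comfortable. All randomness flows from explicit seeds;
re-running the pipeline with the same configuration reproduces identical
output hashes.

# Known limitations

* 2D only; 3D stacks are reduced by maximum projection with a warning.
* No photophysics (blinking, reversible bleaching), no bleach kinetics,
  no chromatin polymer motion, no liquid–liquid phase-separation
  energetics.
* The continuum scheme reports mean-field curves; per-molecule
  stochasticity enters only through readout noise.
* The double-exponential is an empirical summary, not a
  reaction–diffusion fit; its parameters should not be over-interpreted
  mechanistically.
* Real-image segmentation (drift, uneven illumination, touching nuclei)
  is out of scope; the intensity model assumes a cropped single nucleus.
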