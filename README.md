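# hrdquant

Quantification of protein retention in nuclear heterochromatin compartments
from live-cell fluorescence data, with a ground-truth synthetic-data module
so every stage is testable without microscope files.

## The scientific problem

Constitutive heterochromatin in mouse nuclei clusters into bright foci
(chromocenters). Some chromatin proteins — most strikingly the H4K20
methyltransferase KMT5C and its short heterochromatin retention domain
(HRD) — show a paradoxical mobility pattern there: after bleaching *part*
of a chromocenter, fluorescence remixes internally within tens of seconds,
yet a *fully* bleached chromocenter barely recovers over minutes, and
inverse FRAP shows the compartment loses well under a percent of its
content per minute. The protein is highly mobile inside the compartment
but effectively trapped in it. `hrdquant` provides the analysis toolkit
for quantifying this behavior and the sequence features that produce it:

* **FRAP / iFRAP quantification** (`background_correct()`,
  `normalize_scanning()`, `relative_fluorescence()`, `fit_frap()`,
  `recovery_at()`, `kymograph()`, `ifrap_efflux()`,
  `internal_equilibration_time()`). Normalization follows the standard
  two-step protocol: per-frame background subtraction, then frame-wise
  rescaling by the whole-nucleus trace anchored at the first post-bleach
  frame, then division by the pre-bleach value:

  `NormI(t_n) = I(t_1)_nucleus / I(t_n)_nucleus * I(t_n)_ROI`,
  `RelFluor(t_n) = NormI(t_n) / I(t_pre)`.

  Recovery curves are summarized by a double-term exponential,
  `F(t) = F0 + a1 (1 - e^(-t/tau1)) + a2 (1 - e^(-t/tau2))`, with the
  mobile fraction `(plateau - F0)/(1 - F0)`. Inverse-FRAP decays give the
  apparent efflux rate `ER_app` (%/min, ordinary least squares on percent
  vs minutes), the complete-turnover extrapolation `100 / ER_app`, and
  the equilibration ratio (turnover time / internal remixing time).

* **Partition coefficients** (`segment_nucleus()`,
  `partition_coefficient()`, `normalized_scatter()`,
  `saturation_bins()`). Per nucleus,
  `PC = (mean_cc - mean_bg) / (mean_np - mean_bg)` over 3-class
  intensity masks (chromocenter / nucleoplasm / background), with a
  DNA-counterstain fallback for proteins that do not partition, a
  normalized chromocenter-vs-nucleoplasm scatter, and expression-binned
  saturation summaries.

* **Construct panels** (`assemble_panel()`, `cluster_panel()`,
  `compare_pc()`): per-construct medians of PC and fractional recovery at
  5 s and 100 s, z-scored agglomerative clustering (Euclidean, average
  linkage), Kruskal–Wallis and pairwise Wilcoxon rank-sum tests with Holm
  adjustment.

* **Sequence features** (`scan_motifs()`, `call_hrd()`,
  `linker_features()`, `composition_matrix()`, `alignment_identity()`):
  scanning for the HP1 chromoshadow-ligand motif grammars
  (phi1 `[VI]-x-L`, His-Cys `H-x4-C-x3/4-C` with an amphibian variant,
  phi2 `L-x5/6-V-x-L`, phi3 `L-x5-V-x-L`, canonical `PxVxL`), calling the
  bipartite CR1–linker–CR2 architecture under its invariant spacings
  (0 and 1 residues), and disordered-linker charge metrics (NCPR, FCR,
  disorder-promoting fraction, window-1 charge profile, conformational
  class with reference functional lengths).

* **Synthetic data with ground truth** (`sim_params()`, `sim_preset()`,
  `simulate_frap()`, `make_nucleus_field()`, `make_expression_series()`,
  `make_hrd_sequence()`, `make_hrd_alignment()`): a continuum
  reaction–diffusion–binding simulator on a pixel lattice (free field
  diffusing at `D_free`; bound field exchanging at `k_on`/`k_off` and
  optionally hopping site-to-site at `D_bound` along the immobile
  chromatin scaffold), plus a motif-grammar sequence generator with
  constrained linker composition. Presets `"retentive"`, `"exchanging"`
  and `"unbound"` realize the canonical phenotypes.

## Worked example

Quantify internal mixing versus compartment exchange for the retentive
archetype:

```r
library(hrdquant)

params  <- sim_preset("retentive")
partial <- simulate_frap(params, bleach = "partial", stripe_width = 1,
                         t_end = 100, frame_interval = 0.5)
t_int   <- internal_equilibration_time(frap_curve(partial$series))
inverse <- simulate_frap(params, bleach = "inverse", t_end = 600,
                         frame_interval = 2)
tidy(ifrap_efflux(frap_curve(inverse$series), internal_time_s = t_int))
#> # A tibble: 1 x 5
#>   efflux_rate_pct_per_min turnover_time_h equilibration_ratio internal_time_s flag
#> 1                   0.445            3.75                659.            20.5 ok
```

A bleached stripe re-equilibrates inside the chromocenter in ~20 s, while
the compartment as a whole loses only 0.445 %/min — complete turnover
would take 3.75 h, an equilibration-rate separation of two to three
orders of magnitude, the hallmark of retention.

Partition quantification of a noisy synthetic nucleus with a planted
coefficient of 11.5 (nucleoplasm SNR ~ 10):

```r
f     <- make_nucleus_field(sim_params(seed = 1), pc_target = 11.5,
                            noise = list(photons_at_np = 100, read_sd = 1, seed = 2))
masks <- segment_nucleus(f$field)
partition_coefficient(f$field, masks, construct_id = "HRD", cell_id = "cell_01")
#> # A tibble: 1 x 9
#>   construct_id cell_id mean_cc mean_np mean_bg mean_nuclear    pc flag_low_contrast
#> 1 HRD          cell_01    502.    62.1    20.0         200.  11.4 FALSE
```

The recovered `pc` of 11.4 sits within 1% of the planted 11.5.

## Package shape

All user-facing functions take a data frame (or an object built from
one) first and return tibbles, so analyses chain with the pipe; fitted
objects support `tidy()`/`glance()` and `autoplot()`. The methods
vignette (`vignettes/hrdquant-methods.Rmd`) documents the model, its
parameters, and the design decisions behind the simulator and the
analysis defaults.
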