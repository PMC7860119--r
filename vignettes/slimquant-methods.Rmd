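---
title: "Quantifying single-molecule and confocal yeast imaging with slimquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying single-molecule and confocal yeast imaging with slimquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slimquant)
library(tibble)
library(dplyr)
```

## The measurement problem

Millisecond-exposure narrow-field ("Slimfield") fluorescence microscopy
resolves single fluorescent protein molecules in live yeast as
diffraction-limited foci of 250–300 nm full width at half maximum. Three
quantities are derived from such movies:

* **Stoichiometry** of a tracked focus — the number of tagged molecules it
  contains, `S = I0 / I1`, where `I0` is the focus's initial unbleached
  brightness and `I1` the brightness of one fluorophore.
* **Apparent microscopic diffusion coefficient** `D` — from the initial
  gradient of the mean square displacement (MSD) versus time lag, using the
  first five lags, with the fit constrained through `4 sigma^2` at zero lag
  (`sigma` = 40 nm localisation precision): for free 2-D diffusion with
  localisation noise, `MSD(tau) = 4 D tau + 4 sigma^2`.
* **Whole-cell copy number** — background- and autofluorescence-corrected
  integrated density over the cell, divided by `I1`.

Confocal/Airyscan stacks of the same cells are quantified separately:
punctate eisosomes (furrow-like Pil1/Lsp1-scaffolded plasma-membrane
domains) are segmented by intensity thresholding, cargo foci are classified
as colocalised with or distinct from eisosomes, and the contiguous
above-threshold GFP signal along the plasma membrane is measured in
micrometres. Around the imaging core sit small sequence and statistics
utilities: scanning promoters for the glucose-repressor (Mig1) consensus
motif (G/C)(C/T)GGGG, interactor-set overlaps, comparative-Ct (ddCt) qPCR
fold changes, and Holm–Šidák multiple-comparison t-tests.

No raw microscopy is distributed with the package. Instead, a first-class
synthetic-data generator produces Slimfield movies, stepwise-photobleaching
traces and two-channel confocal scenes with exact ground truth, so every
analysis stage is validated by parameter recovery.

## The synthetic-data generator

`sim_config()` collects the acquisition physics. Defaults mirror the study
conditions: 50 nm pixels, 5 ms frames, and a Gaussian point-spread function
of sigma 120 nm (FWHM ≈ 283 nm, inside the diffraction-limited 250–300 nm
band). The cell body is a filled ellipse — the simplest geometry that
supports membrane-versus-cytoplasm logic — with its boundary taken as the
membrane contour (the physical membrane width of 7 nm is far below one
pixel, so the contour is a curve).

`simulate_slimfield_movie()` renders each emitter as `S` fluorophores at a
common position. Each fluorophore bleaches irreversibly with an independent
geometric per-frame probability, and while unbleached contributes a
pixel-integrated Gaussian of total intensity `unitary_brightness`. Emitters
move by 2-D Brownian steps of per-axis variance `2 D dt`, reflected
(bounce-back) at the cell boundary so emitter number is conserved. The
camera model is Poisson shot noise on (signal + autofluorescence inside the
cell + uniform background) plus Gaussian read noise — the standard
EMCCD/sCMOS approximation. The movie is strictly 2-D: depth of field,
defocus and vectorial PSF effects are deliberately out of scope, so passing
tests demonstrate correctness of the estimators, not robustness to axial
blur in real data. Alternating-laser two-colour acquisition is represented
as independent single-channel movies.

```{r quick-scene}
cfg <- sim_config(n_frames = 10, image_shape = c(64, 64), bleach_rate = 0.02)
sc <- simulate_slimfield_movie(
  cfg, tibble(x_um = 1.6, y_um = 1.6, S = 4, D = 0.05), seed = 1)
head(sc$truth, 3)
```

`simulate_photobleach_trace()` produces the idealised stepwise trace (start
at `S * I1`, one `I1` drop per bleach event, Gaussian noise), and
`simulate_confocal_scene()` places red eisosome puncta on the membrane
contour with a guaranteed minimum separation and green cargo foci either
exactly at a punctum (colocalised) or at least an exclusion distance
(default 0.15 um) away from every punctum along the membrane. All
randomness flows through one seed argument; identical configuration and
seed give bit-identical output.

## Spot detection and tracking

`detect_spots()` finds candidate maxima on a difference-of-Gaussians
band-pass image, thresholded at 5 robust noise SDs, and refines each to
sub-pixel precision by iterative Gaussian masking (tolerance 0.01 px, max
50 iterations). Summed spot intensity is the background-corrected total
over a disc tied to the PSF scale (radius `ceiling(2.5 sigma_px)`), with
the local background taken as the median of the surrounding 2-px annulus.
Two analytic corrections keep photometry honest: the summed intensity is
divided by the Gaussian flux fraction inside the disc, and the
radial-moment width estimate is corrected for disc truncation before being
reported in nm. Spots whose corrected FWHM falls outside a configurable
acceptance band (default 100–500 nm, which passes the diffraction-limited
250–300 nm) are rejected.

`link_tracks()` assigns spots between frames by minimising the total
squared displacement over candidate pairs within the linking radius
(default 5 px), solved exactly with a Hungarian assignment implemented in
the package (no linear-assignment solver is available among the
dependencies); unmatched spots seed new tracks and a track survives
`max_gap` (default 1) missed frames. These defaults are declared choices —
the linking radius and gap policy of the original tracking software are
not published.

## Unitary-brightness calibration

`estimate_unitary_brightness()` commits to a three-stage procedure:

1. **Chung–Kennedy filtering** (window 10 frames, weighting exponent 10) —
   each point becomes a variance-weighted blend of its backward- and
   forward-window means, which suppresses noise while leaving step edges
   intact.
2. **Step detection** by a sliding two-sample Welch t-test (p < 0.01)
   between the windows before and after each point; local |t| maxima at
   least one window apart become change points, and segment means between
   change points are the brightness levels.
3. **Spectral spacing estimation** — all pairwise differences between the
   levels of each trace are pooled, and `I1` is the fundamental peak of the
   pairwise-difference distribution's spectral density, computed as the
   empirical characteristic-function power `|sum_d exp(2 pi i d / c)|^2`
   maximised over candidate spacings `c`; among near-maximal local optima
   the largest period wins so harmonics (`I1/2`, `I1/3`, …) cannot.
   Uncertainty is a bootstrap SE over traces.

A terminal-step fallback (mean size of the last step before the bleached
baseline) is available as `method = "terminal_step"`. On simulated traces
the spectral estimate is accurate within 1% up to noise of half `I1`
(tested), and the package keeps green and red channels as separate
calibrations. Calibration assumes photobleaching traces from foci whose
intensity is otherwise stationary — near-immobile foci, as in a dedicated
calibration acquisition. Traces of rapidly moving spots whose photometry
fluctuates through the measurement aperture degrade the level estimates,
and the pipeline warns of this indirectly through a large bootstrap
uncertainty.

## Quantification choices

* **Initial unbleached brightness** is operationalised as a
  single-exponential decay fit evaluated at the first frame (log-linear
  fit when the nonlinear fit degenerates, e.g. on noise-free data; mean of
  the first three frames as last resort, with the method recorded).
* **MSD** uses all overlapping displacement pairs per lag (higher counts,
  mildly correlated); a non-overlapping option exists
  (`overlapping = FALSE`). Tracks shorter than `n_lags + 1 = 6` frames are
  excluded from diffusion fitting.
* **The diffusion fit** is a zero-intercept least-squares slope of
  `msd - 4 sigma^2` against lag time over the first five lags, `D =
  slope / 4`; the fitted line therefore passes through `4 sigma^2` at zero
  lag exactly. Negative slopes are clipped to `D = 0` and flagged rather
  than dropped, keeping distributions complete. `sigma` defaults to
  0.04 um but is a parameter — it must reflect the actual localisation
  precision of the data being fitted, and the synthetic-data tests supply
  exactly the noise they inject.
* **Copy number** sums pixel counts over a measurement region in the
  first (least-bleached) frame and subtracts region-area multiples of the
  extracellular background and of the per-pixel autofluorescence measured
  on matched non-expressing (emitter-free) cells. The measurement region
  is the cell mask dilated by about 3 PSF sigma (8 px at defaults):
  membrane-proximal emitters' PSF tails would otherwise be clipped,
  biasing counts low by several percent — the equivalent of drawing a
  slightly generous ROI around the cell. On 20-cell simulations at the
  published per-cell abundances of the two AP180-family adaptors (~1000
  and ~400 molecules), the pipeline recovers the configured counts to
  well within 10% (see `scripts/acceptance.R`).
* **Membrane-proximal filtering** of foci keeps those within 3 px of the
  membrane contour by default.

## Confocal stage

`top_projection()` averages the five top-of-cell slices (0.18 um spacing)
by default; a per-pixel maximum mode is available and the mode used is
stamped in the output, because the source description of the projection
("average intensity of the maximum intensity projection") is ambiguous and
we decline to guess intent. `bleach_correct()` performs rank-preserving
histogram matching of every frame to frame one — idempotent and exactly
mean-restoring for multiplicative decay.

`segment_eisosomes()` binarises at the fixed, comparable-across-conditions
threshold 17 on the 16-bit 0–65,535 scale (inclusive `>=`) or at an
automatic Li minimum-cross-entropy threshold (iterated to a relative
tolerance so it transforms exactly covariantly under affine intensity
rescaling). Components are labelled with 8-connectivity (implemented in
the package; the available image library labels 4-connected) and a minimum
ROI size of 3 px rejects single-pixel noise. Eisosome counting uses these
still-image components; merged unresolved pairs are flagged by an area
outlier rule (area > 1.5x the median).

`classify_foci()` labels a focus colocalised when its nearest
other-channel focus lies within 100 nm (2 px) — the radius is a declared
parameter, as no numeric colocalisation criterion is published — and
separately reports exclusive mutual-proximity pairs (greedy by distance,
ties by lowest id). `contiguous_membrane_signal()` samples intensity along
the closed membrane contour at arc steps of at most 0.5 px with bilinear
interpolation, binarises at a threshold, and returns the arc length of
every maximal contiguous run, treating the contour as circular so runs may
wrap; a 90-degree bright arc on a 2 um ring measures pi um to within the
sampling step.

## Sequence and statistics utilities

`motif_scan()` matches the degenerate consensus (IUPAC `SYGGGG`) at every
position, reporting overlapping hits with 1-based start coordinates; `N`
never matches, and both-strand mode reports reverse-complement matches in
forward coordinates. Scanning defaults to the forward strand of the
supplied promoter window (strand policy is not published); the scanner
reports raw hits and leaves hit-count thresholds to the user, since the
published 106-gene target census is genome-version dependent.
`set_overlap()` performs exact set algebra on upper-cased, optionally
alias-mapped gene identifiers. `ddct_fold_change()` averages technical
replicates, forms `dCt` against the housekeeping reference, `ddCt` against
the control sample and `2^-ddCt`; statistics are meant to be run on Ct
values, not fold changes. `holm_sidak()` runs unpaired Welch t-tests and
the step-down Šidák adjustment (`1 - (1 - alpha)^(1/(m - i + 1))`); on a
simulated 10-comparison global null the family-wise error is controlled at
0.05 (tested with 10^4 replicates).

Supplementary interactor tables are not redistributable here, so
`inst/extdata/` ships *synthetic* stand-in lists (`synthetic_*.csv`,
labelled as such) constructed with plausible yeast gene names and exactly
the published overlap structure: 70 Mup1 interactors of which precisely
three are eisosome proteins (Lsp1, Slm1, Ygr130c), and 18 interactors
shared between Mup1 and Ygr130c.

```{r overlap}
mup1 <- read.csv(system.file("extdata", "synthetic_mup1_interactors.csv",
                             package = "slimquant"))$gene
eiso <- read.csv(system.file("extdata", "synthetic_eisosome_proteins.csv",
                             package = "slimquant"))$gene
set_overlap(mup1, eiso)
```

## Numerical conventions and degenerate inputs

Images are numeric matrices in camera counts, pixel (0,0) spanning
[0,1) x [0,1) with 0-based continuous spot coordinates mirrored in um.
Zero-variance frames detect zero spots (not an error); non-finite pixels
are an error. Empty trace lists, traces with no detectable steps, empty
cell masks, open membrane contours and unknown configuration keys all fail
loudly rather than defaulting. Negative corrected quantities floor at zero
with a flag (copy number, spot intensity, diffusion slope). Linking ties
are broken deterministically (lowest track id, then spot index), so runs
are reproducible given identical input order and seed.

## Problem sizes used in the tests

The shipped test-suite and acceptance checks simulate at sizes chosen to
give stable statistics while staying quick on a laptop: 20 cells per
copy-number condition (~1000 and ~400 molecules per cell, 160x160 px
scenes); 500 tracks per diffusion condition (D = 0.01, 0.05, 0.1 um^2/s,
100 frames at 5 ms, sigma = 40 nm); 50 photobleaching calibration traces
(S drawn from 5–15, I1 = 150 counts, noise SD 30) plus 10 traces per
stoichiometry level S = 2..20; 30-punctum confocal scenes on 256x256 px
fields; and 10^4 replicates for the family-wise-error simulation. Under
these conditions recovery errors are typically a few percent — far inside
the 10–15% acceptance bands — so the bands reflect tolerance to seed
variation, not looseness of the estimators.

## Known limitations

The simulator omits axial defocus, motion blur within an exposure,
fluorophore blinking and dark states, chromatic offsets and cross-channel
bleed-through (a mixing parameter exists but defaults to zero), so
estimator performance on real data will be bounded by those effects.
Step detection is a declared stand-in for the original unpublished
implementation and is validated only against synthetic truth. Cell
segmentation from brightfield, 3-D localisation, drift correction and
anomalous-diffusion modelling are out of scope.
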