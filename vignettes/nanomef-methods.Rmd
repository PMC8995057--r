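---
title: "Gap-distance morphometry and assay statistics with nanomef"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gap-distance morphometry and assay statistics with nanomef}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanomef)
```

## The problem

Metal-enhanced fluorescence (MEF) substrates made of silver nanostructures
grown on polystyrene amplify fluorophore emission when the metal morphology
is right: sparsely dispersed nanoparticles enhance weakly, crack-free
continuous films quench or reflect, and the semi-continuous nanoisland
morphology in between — irregular islands separated by gaps of tens of
nanometres — gives broad-spectral enhancement. `nanomef` provides the
computational side of characterizing such substrates and of validating the
enhanced fluoroimmunoassays (eFIA) built on them:

1. **morphometry** — from an SEM image to a gap-width distribution and its
   gamma-distribution summary, plus surface coverage and a
   continuity-regime label;
2. **enhancement analytics** — enhancement factors (EF) with background
   subtraction, condition-by-wavelength EF matrices, and a standardized
   PCA with Kaiser–Guttman retention;
3. **assay statistics** — saturating-exponential calibration, blank-based
   limit of detection (LOD), intra/inter-assay %CV, ROC with a
   Youden-optimal cutoff, and Bland–Altman method agreement;
4. **a synthetic-data generator** — stochastic island growth, SEM-style
   rendering, calibration and cohort simulators — so every stage is
   testable end to end without instrument data.

## The gap-distance model

The core statistic treats the *gap phase* (the space between islands) as
the physically active region: fluorophores sitting in gaps experience the
strongest near fields, and the local gap width determines whether a
protein-sized probe fits and how strongly it is enhanced.

The chain on a grayscale SEM field is:

1. **Binarization.** A global Otsu threshold maximizes the between-class
   variance of the intensity histogram; pixels above it are silver (1),
   below it gap (0). The implementation is the exact exhaustive argmax
   over histogram bins, ties resolved toward the lowest maximizing
   threshold, so it can be (and is) checked against a literal brute-force
   scan. The brighter phase is assumed to be silver — backscatter contrast
   of metal on polymer — with an `invert` flag for reversed contrast.
2. **Cleanup.** The classic `clean` then `majority` pair: silver pixels
   with no silver 8-neighbour are removed, then a pixel is silver iff at
   least 5 of the 9 pixels in its 3×3 neighbourhood are silver. Borders
   are zero-padded; a consequence worth knowing is that the four corner
   pixels of an all-silver field see only 4 of 9 silver pixels and flip —
   the package documents and tests this rather than special-casing it.
3. **Gap skeleton.** The gap phase is thinned to a unit-width medial line
   under 4-connectivity of the gaps (8-connectivity for silver — the
   standard dual pair). Thinning deletes only *simple* pixels (Yokoi
   connectivity number 1), in order of increasing distance to silver, so
   the Euler number (components minus holes) of the skeleton provably
   equals that of the full gap phase; curve end-pixels are preserved.
4. **Distance transform.** Exact Euclidean distance from every pixel
   center to the nearest silver pixel center.
5. **Gap distance.** At every interior skeleton pixel,
   `d = 2 × distance-to-silver`, i.e. the local gap width read at the
   medial line, convertible to nm via the pixel size. Skeleton pixels in
   the 1-px border frame are excluded: gaps cut by the field of view are
   truncated and would bias the sample.
6. **Gamma fit.** The pooled sample is summarized by a maximum-likelihood
   gamma fit (shape *k*, scale *θ*), initialized at the method-of-moments
   values `k₀ = mean²/var`, `θ₀ = var/mean`.

### The +1 px discretization offset

Distances are measured between pixel *centers*, not to the sub-pixel
phase boundary. On a stripe of geometric width *w* px the medial pixel is
`(w+1)/2` px from the nearest silver center, so the statistic reads
`w + 1` px. This is an intrinsic property of the center-to-center
convention, constant across widths, documented here and pinned by phantom
tests at widths {3, 5, 7, 9, 15} px. At 2 nm/px it amounts to +2 nm,
negligible against the tens-of-nm gaps of interest.

### Regime classification

`classify_regime()` operationalizes the qualitative continuity
progression: **continuous** when the largest 8-connected silver component
spans both image axes and the gap fraction is below 0.05; **discrete**
when no component spans either axis and the largest holds under 50% of
the silver area; **semi-continuous** otherwise. Both thresholds are
exposed as arguments; the defaults mark the points where a film is
practically crack-free and where structures stop being "dispersed
particles".

## The synthetic substrate generator

Real growth is seed-mediated: gold nanoparticle nucleation sites
electrostatically immobilized at a density set by the polycation
concentration, then autocatalytic silver reduction around them, with the
precursor budget setting how far growth proceeds. The generator mirrors
exactly that structure with the simplest stochastic model that reproduces
the discrete → semi-continuous → continuous progression:

* seed count ~ Poisson(`seed_density` × field area), positions uniform
  (`simulate_seed_field()`);
* silver starts as disks of `seed_radius` and accretes Eden-style: per
  sweep, each gap pixel 4-adjacent to silver converts with probability
  `attach_prob`; growth stops at `target_coverage`
  (`grow_islands()`);
* rendering adds Gaussian blur, Gaussian noise, and clipping (not
  rescaling — detector saturation) at 8 or 16 bit (`render_sem()`).

Parameter choices, made once:

* `pixel_size = 2` nm/px, so a 1000 × 750 px field corresponds to a
  2000 × 1500 nm SEM region — the scale at which such substrates are
  typically imaged and simulated.
* `seed_density = 150` µm⁻² by default. Seeding density is only
  qualitatively tied to polycation concentration in practice, so this is
  a free parameter; 150 µm⁻² puts tens of nucleation sites in the
  0.1–0.3 µm² fields used throughout the tests, matching the island
  counts visible in typical SEM fields of the semi-continuous regime.
* `seed_radius = 3` px = 6 nm, a citrate-gold-sized nucleation disk.
* `attach_prob = 0.5`: rough, tortuous growth fronts; 1.0 gives
  deterministic faceted (Manhattan-ball) growth, which the unit tests
  exploit as a closed-form case.
* Coverage is non-decreasing in `target_coverage` by construction (a
  lower-target mask is an earlier state of the same growth trajectory
  under a fixed seed), which the property tests assert.

What the generator does **not** emulate: diffusion-limited aggregation
realism, 3D island height (real islands are ~100 nm tall; everything here
is 2D projection), SEM beam/charging artifacts, and spatially correlated
detector noise. Tests passing on synthetic fields therefore validate the
*computational chain* — thresholding, topology, distances, fits — not the
instrument physics of real images.

## Enhancement analytics

The enhancement factor of a condition/channel is

$$EF = \frac{FI_{sample} - BKGD_{sample}}{FI_{ref} - BKGD_{ref}}$$

with the reference the plain polystyrene surface. EF is gain-invariant
(common rescaling of all four intensities cancels). A non-positive
numerator is reported as EF = 0 and, like any EF < 1, flagged as
quenching rather than dropped — short-wavelength fluorophores outside the
plasmon resonance genuinely quench, and that is signal, not noise.

The PCA of an EF matrix standardizes all variables (correlation-matrix
PCA): EF channels share units but differ by an order of magnitude across
wavelengths, and the ordinal synthesis covariates (seeding level,
precursor level, reducing-power score) are on arbitrary scales. With
standardized variables the eigenvalues sum to the variable count and the
Kaiser–Guttman rule reads "retain eigenvalues > 1"; ties at exactly 1 are
excluded. Because standardization is a deliberate choice here and
published biplots do not always state theirs, fractions of variance
explained are not comparable across studies and are not treated as
reproduction targets.

`spectral_overlap()` quantifies extinction/emission matching as
$\int \hat{E}F \, d\lambda / \int F \, d\lambda$ with the extinction
peak-normalized to 1, trapezoidal integration on the emission grid, and
zero outside the extinction support — a bounded [0, 1] summary of "how
much of this fluorophore's emission sits under the plasmon band".

## Assay statistics

* **Calibration** is the saturating exponential
  $S(c) = S_\infty - (S_\infty - S_0)e^{-kc}$ — the standard form for a
  sandwich assay approaching site saturation. Starting values come from
  the data (blank mean; top level + 5%; log-linearized slope), and the
  fit uses Levenberg–Marquardt least squares. On noiseless generated
  data the parameters recover to 1e-6 relative error.
* **LOD** follows the signal-domain convention: decision signal =
  blank mean + 3 × blank s.d. (signal-to-noise of 3), inverted through
  the closed form $c = -\ln[(S_\infty - S)/(S_\infty - S_0)]/k$.
  A decision signal at or beyond $S_\infty$ is an explicit
  "beyond dynamic range" error; a blank mean below the fitted asymptote
  is clamped to LOD = 0.
* **%CV**: intra-assay = within-run 100·s.d./mean averaged over runs;
  inter-assay = %CV of run means; sample (n−1) s.d. throughout.
* **ROC**: thresholds sweep the observed scores with the "score ≥
  threshold → positive" rule; AUC by trapezoid, which equals the
  Mann–Whitney pairwise concordance with ties counted ½ (asserted on
  random tied cohorts). The cutoff maximizes Youden's
  J = sensitivity + specificity − 1. "Optimal sensitivity and
  specificity" is ambiguous between Youden and closest-to-(0,1); Youden
  was chosen as the convention that maximizes the quantity clinicians
  report, and ties go to the lowest threshold so the operating point is
  the most sensitive among equals.
* **Agreement**: Pearson r plus Bland–Altman bias and 95% limits of
  agreement (bias ± 1.96 s.d. of differences). Two pairs suffice for a
  sample s.d., so n ≥ 2 is accepted; with a zero-variance series the
  correlation is undefined (`NA` with a warning) while the Bland–Altman
  quantities are still returned.

## Numerical and degenerate-input choices

* Constant images are a thresholding error (no two-class structure), an
  all-gap mask is a distance-transform error (no reference phase), an
  empty skeleton yields an empty sample with a warning, and gamma fitting
  refuses n < 10 or zero variance.
* All simulators draw from one RNG stream per call, seeded by a single
  integer `rng_seed` and restored afterwards, so runs are bit-reproducible
  and never disturb the caller's RNG.
* Component counting uses 4-connectivity labelling merged across diagonal
  touches for the 8-connectivity case; the Euler number uses the
  quad-count formula, cross-checked in tests against flood-fill
  components-minus-holes.

## Worked example

```{r example, eval = FALSE}
gp <- growth_params(field_size = c(192, 192), pixel_size = 2,
                    seed_density = 150, target_coverage = 0.55,
                    rng_seed = 7)
sub <- simulate_substrate(gp, render = render_params(noise_sd = 6,
                                                     blur_sigma = 0.8))
res <- analyze_gaps(sub$image, units = "nm")
res$regime$label     # "semi-continuous"
res$gamma            # gamma fit of the gap-width distribution in nm
```

The test suite and the acceptance script use fields between 64×64 and
256×256 px, 50–60 masks for topology sweeps, n = 1e5 draws for gamma
recovery, 200 cohorts for the AUC oracle and 1000 for the exchangeability
check — sizes at which every Monte-Carlo tolerance in the tests is
comfortably inside its sampling error.

## Known limitations

* 2D only: no island height, hence no correlation of gap statistics with
  the vertical dimension.
* No sub-pixel boundary localization; the +1 px offset above is the
  visible consequence.
* The regime thresholds are heuristics for simulated morphologies;
  on real SEM images with drift, charging, or contamination they should
  be inspected, not trusted blindly.
* The thinning is sequential and O(removed pixels); fields much beyond
  1000×750 px will be noticeably slower than the vectorized steps.
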