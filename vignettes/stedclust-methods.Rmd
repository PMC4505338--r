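---
title: "Quantifying membrane nanoclusters: models and methods in stedclust"
author: "stedclust authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying membrane nanoclusters: models and methods in stedclust}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stedclust)
```

# The problem

Tetraspanins (CD9, CD37, CD53, CD81, CD82) laterally organize membrane
proteins into tetraspanin-enriched microdomains on the plasma membrane of
immune cells. Dual-color STED microscopy of flat membrane sheets resolves
these domains as diffraction-limited nanoclusters (~100-170 nm FWHM) at
densities of roughly 0.5-5 clusters per square micrometre. Three
quantitative questions drive the analysis this package implements:

1. **Within one protein species**, are clusters randomly positioned on the
   membrane? This is tested against the analytic nearest-neighbor (NN) law
   of a homogeneous 2D Poisson process.
2. **Between two species**, are clusters co-localized, adjacent, or
   independent? This is tested with the 100 nm overlap criterion, per-sheet
   Pearson correlation, and Monte-Carlo "mock image" nulls with matched
   densities and size distributions but completely random placements.
3. **How many molecules does one cluster hold?** A stoichiometry chain
   combines quantitative immunoblotting, isotype-corrected flow cytometry,
   and a sphere-model cell surface area with the imaged cluster density.

Because no raw micrographs ship with the package, a synthetic membrane-sheet
generator with exact ground truth stands in for the microscope, and every
stage of the analysis is validated against it.

# The generative model

`syntheticSpec()` / `generateSheet()` simulate one sheet:

* **Placement.** Channel-1 centers are a homogeneous Poisson point process
  at density $\rho_1$ (clusters/um^2). Channel 2 is either an independent
  Poisson process, an exact copy of channel 1 (`co_centered`), or each
  channel-1 center displaced by a distance $\sim N(\mu_o, \sigma_o)$
  (truncated at 0 by resampling) at a uniform angle (`offset`). An optional
  hard-core minimum separation (sequential rejection) produces patterns in
  which every cluster is individually resolvable; its default is 0 so the
  default process is exactly Poisson.
* **Size and brightness.** Each cluster is an isotropic Gaussian of FWHM
  drawn from a truncated normal (default 110 +/- 35 nm) or from a supplied
  empirical sample. Each carries $1 + \mathrm{Poisson}(\mu - 1)$ labeled
  molecules (default mean 3.5) - the +1 reflects that a cluster with zero
  labels is unobservable. Integrated signal is molecules x
  `photonsPerMolecule`.
* **Optics and noise.** The PSF is Gaussian with 50 nm FWHM. Because the
  convolution of two Gaussians is Gaussian with
  $\sigma_\mathrm{eff} = \sqrt{\sigma_f^2 + \sigma_p^2}$, each spot is
  rendered directly at its convolved width - exact and fast. Pixels are
  20 nm; Poisson shot noise is added over a constant background.
* **Edges.** Centers are drawn in a guard margin of three cluster FWHM
  around the field and cropped, so boundary pixel intensities are unbiased;
  the ground truth lists in-field centers only.
* **Determinism.** One root seed; placement, per-channel noise and ensemble
  members use deterministically derived substreams, so a fixed seed
  reproduces images and truth bit-for-bit.

The generator emulates cluster statistics, not microscope physics: no
blinking or localization artifacts, no anisotropic PSF, no antibody-size
broadening, no drift, and a spatially flat background. Tests passing on
synthetic sheets therefore validate the *estimators* under the stated
statistical model; they cannot certify behavior under optical artifacts the
model omits.

The intensity model of mock images (Gaussian spots) is a package choice;
binary discs would be an equally defensible reading, but Gaussian spots are
the form consistent with FWHM-based sizing throughout.

# Cluster detection and measurement

`annotateClusters()` applies a background-relative threshold: background
median plus `offsetK` (default 3) robust SDs, with the scale estimated as
1.4826 x the median deviation of the pixels at or below the median, so
bright clusters cannot inflate it. Above-threshold pixels are grouped with
8-connectivity; components smaller than `minPixels` (default 4) are
discarded; each blob yields one intensity-weighted, background-subtracted
subpixel centroid. Overlapping clusters merge into one detection by design -
no watershed splitting is attempted, mirroring how nearby clusters coalesce
at limited resolution. Because the threshold is background-relative, all
detection and sizing results are invariant to a global intensity rescaling.

`measureFWHM()` sizes a cluster from two orthogonal axis-aligned profiles
through its peak pixel, interpolating the half-maximum crossings linearly
after background subtraction. One numerical subtlety matters: the raw
maximum pixel of a blob is the maximum of many noisy values and is biased
upward, which would place the half level too high and systematically shrink
dim, wide clusters. The apex is therefore estimated from the 3x3
neighborhood mean with an analytic Gaussian curvature correction, iterated
twice against the measured width. On noiseless rendered clusters the
measured FWHM matches $\sqrt{f^2 + p^2}$ within 3% across f = 80-180 nm
(p = 50 nm PSF); under shot noise at peak SNR >= 5 it stays within 5%.
A profile that never falls below half maximum inside the image is reported
as censored (NA, or an error with `strict = TRUE`).

`segmentMasks()` builds each cluster's region of interest as the connected
pixels above 50% of the background-subtracted peak (the FWHM contour,
consistent with the sizing rule). Circularity is $4\pi A / P^2$, clipped to
[0, 1], with the perimeter estimated from the traced Moore boundary chain
using the bias-corrected step weights 0.948 (straight) and 1.340
(diagonal); raw crack-length or chain-length perimeters would
under-estimate the circularity of discs by 30-40%.

# Spatial statistics

For clusters completely randomly distributed at density $\rho$, the NN
distance law is

$$ p(r)\,dr = 2 \pi \rho r e^{-\pi \rho r^2} dr, \qquad
   \mathbb{E}[r] = \frac{1}{2\sqrt{\rho}}, \qquad
   P(r \le d) = 1 - e^{-\pi \rho d^2}. $$

`nnDistances()` measures center-to-center NN distances with minus-sampling
edge correction: reference clusters within `borderMargin` (default 500 nm)
of the mask boundary are dropped, while all clusters remain candidate
neighbors. `fitRandomDistribution()` compares the distances with the law at
the density *independently determined from the image* - the density is
fixed, never fitted. It reports a one-sample Kolmogorov-Smirnov statistic;
the statistic is an extension over a visual curve comparison and is labeled
as such in its output. `overlapFraction()` implements the 100 nm overlap
criterion, and `pearsonPerSheet()` the per-sheet pixel Pearson correlation
over mask pixels, without any intensity thresholding.

Histogram bins default to 20 nm (one pixel) over 0-1000 nm. Distances are
in nm everywhere, densities in clusters/um^2; conversions are centralized.

# The mock-image null

`specFromObserved()` turns observed cluster maps into a null specification:
per-channel densities are means over sheets, the FWHM distribution is the
pooled empirical sample, and placements are completely random and
uncorrelated. Mock cluster counts are Poisson around the requested density
rather than frozen at the observed counts - the marginally more conservative
choice, and configurable through the generator. `buildMockEnsemble()`
(default 10 images) and `analyzeMockEnsemble()` push every mock through the
*identical* detection and NN path as the real data, so detection biases
(merging, edge effects) cancel between observed and null;
`compareToNull()` refuses truth-derived coordinates unless explicitly
flagged.

The comparison quantifies what would otherwise be a visual judgment:
the excess fraction of reference clusters within 100 nm (observed minus
pooled null, with the between-mock SD), a two-sample KS statistic with its
asymptotic p-value, and an ensemble-based empirical p-value from
leave-one-out KS statistics of the mocks. With $n$ mocks the empirical
p-value cannot fall below $1/(n+1)$ (0.091 at $n = 10$), so detecting
strong coupling at conventional thresholds relies on the asymptotic
two-sample p-value; both are reported.

# Stoichiometry

The chain multiplies independently measured factors:

| quantity | source | operation |
|---|---|---|
| copies/cell | quantitative immunoblot vs recombinant standard | `fitStandardCurve()`, `invertMass()`, `moleculesPerCell()` |
| surface fraction | isotype-corrected flow cytometry | `surfaceFraction()` |
| surface area | equatorial radii of swollen spherical cells | `cellSurfaceArea()` |
| clusters/cell | area x imaged cluster density | `moleculesPerCluster()` |

Numerical choices: copies per cell use the Avogadro route
(1 kDa = 1.66054e-9 pg per molecule) rather than any pre-tabulated
per-molecule mass; for CD53 (23.34 kDa, 1638 pg per 0.8e6 cells) this gives
~52,800 copies per cell, about 1% below the commonly quoted 53,185 - the
package computes, and documents, the Avogadro value. The surface area is
the mean of $4\pi r^2$ over cells, not $4\pi \bar r^2$, which differs for
dispersed radius samples (Jensen). The chain identity
(molecules/cluster x clusters/cell = copies/cell x fraction) is enforced by
the result class validity at machine precision.

```{r stoich}
moleculesPerCluster(moleculesPerCell = 53185, surfaceFractionPct = 30.12,
                    surfaceAreaUm2 = 1040, clusterDensity = 4.4)
```

# Problem sizes and verification

The test-suite and acceptance-script simulations use field sizes chosen so
that each check has the statistical resolution it needs while the whole
suite stays quick: 50 x 50 um Poisson fields (~11,000 clusters) for the
closed-form mean NN distance (agreement within 2%); 30 x 30 um dual-channel
fields (~3,300 reference clusters) for the overlap-under-independence check
(within 2 percentage points of $1-e^{-\pi\rho d^2}$); 20 x 20 um sheets
(~800 clusters) for detection fidelity (recall and precision >= 95%,
centroid error well under one pixel); 500 draws of n = 100 for KS
calibration (rejection at alpha = 0.05 stays near nominal); and 10-image
mock ensembles - the scale at which the null is actually used - for the
coupled-alternative power check.

Detection fidelity is scored on conditions under which clusters are
individually resolvable: hard-core separation of 450 nm (comfortably above
twice the largest 170 nm FWHM) and brightness giving every cluster peak
SNR >= 5. Outside those conditions nearby clusters merge into single
detections; that is documented estimator behavior, not failure, but it
makes raw recall an ill-posed score.

# Known limitations

* Merged clusters are reported once; abundance estimates at densities where
  a sizable fraction of neighbors falls below ~2x FWHM separation are
  biased low. The mock-null comparison cancels most of this bias because
  mocks pass through the same detector, but not all of it: mocks are placed
  at the *detected* density, to which merging losses then apply a second
  time, so at high densities (several clusters per um^2) the null overlap
  is slightly underestimated and the excess statistic is anti-conservative.
  Detected within-channel NN distributions likewise lose short distances to
  merging, so a strict KS test against the analytic Poisson law can reject
  at densities where truth-level patterns pass; interpret within-channel
  fits on dense channels with the detector in mind.
* The analytic NN law assumes homogeneity; membrane regions with strong
  density gradients would need an inhomogeneous null, which is out of
  scope.
* The minus-sampling margin trades sample size against edge bias; at the
  default 500 nm and densities >= 0.5/um^2 the residual bias on the mean NN
  distance is below 2%.
* Pearson correlation is computed on raw mask pixels; no Costes-style
  thresholding is attempted.
* The stoichiometry chain propagates point estimates; radii and
  standard-curve uncertainty can be bootstrapped externally, but the
  headline molecules-per-cluster value should be read as an order-of-
  magnitude estimate bounded above by ~10.
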