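# stedclust

Quantitative analysis of membrane-protein nanoclusters in dual-color
super-resolution (STED) images of plasma membrane sheets.

Tetraspanins such as CD53, CD37, CD81 and CD82 organize the plasma membrane
of immune cells into nanoscale protein domains. On STED images of membrane
sheets these domains appear as diffraction-limited spots of ~100-170 nm
FWHM at densities of 0.5-5 clusters/µm². `stedclust` implements the full
quantitative pipeline such a study needs, for microscopists and image
analysts who want the statistics to be testable rather than visual:

* **Synthetic sheets with ground truth** — a generative model (Poisson
  cluster placement, optionally co-centered or offset-coupled between
  channels; Gaussian clusters; 50 nm Gaussian PSF; Poisson shot noise) so
  every estimator can be validated without raw microscope data.
* **Cluster detection and measurement** — background-relative intensity
  threshold, 8-connected blob detection with subpixel centroids, FWHM
  sizing from interpolated half-maximum crossings, mask area and
  circularity (4πA/P²), and cluster densities.
* **Spatial statistics** — nearest-neighbor (NN) distance distributions
  with minus-sampling edge correction, tested against the analytic law for
  completely random clusters at density ρ,

  p(r) dr = 2πρr · exp(−πρr²) dr,  E[r] = 1/(2√ρ),

  with ρ fixed from the image, never fitted; the 100 nm overlap criterion;
  and per-sheet pixel Pearson correlation.
* **Monte-Carlo mock-image nulls** — ensembles of computer-generated images
  with the observed densities and size distributions but completely random,
  uncorrelated placements, pushed through the *identical* detection + NN
  path, with excess-overlap and Kolmogorov-Smirnov comparisons.
* **Stoichiometry** — the molecules-per-cluster chain: quantitative
  immunoblot standard curve → copies/cell → isotype-corrected surface
  fraction → sphere-model surface area → clusters/cell → molecules/cluster.

## Worked example

Estimate how many CD53 molecules one membrane cluster holds, from the
published B-cell inputs (53,185 copies/cell, 30.12% on the surface,
1,040 µm² surface area, 4.4 clusters/µm²):

```r
library(stedclust)
moleculesPerCluster(moleculesPerCell = 53185, surfaceFractionPct = 30.12,
                    surfaceAreaUm2 = 1040, clusterDensity = 4.4)
#> StoichiometryResult:
#>   molecules/cell     53,185
#>   surface fraction   30.12 %
#>   surface area       1,040 um^2
#>   cluster density    4.4 um^-2
#>   surface molecules  16,019
#>   clusters/cell      4,576
#>   molecules/cluster  3.5
```

So ~16,000 surface copies distribute over ~4,600 clusters: about 3.5
molecules per cluster, comfortably below 10.

Simulate a two-channel sheet with independent channels and run the whole
image pipeline, including a 10-image mock null:

```r
spec <- syntheticSpec(fieldUm = 20, density = c(CD53 = 1.0, MHCII = 1.0),
                      seed = 42)
gs <- generateSheet(spec)
gs$image
#> SheetImage 'synthetic-seed42': 2 channel(s) [CD53, MHCII], 1000 x 1000 px
#>   @ 20 nm, analyzed area 400 um^2

bundle <- runPipeline(gs$image, "MHCII", "CD53", nullImages = 10, seed = 42)
bundle$densities       # CD53 1.00, MHCII 0.96 clusters/um^2
bundle$overlapPct      # 3.7 % of MHCII clusters within 100 nm of CD53
bundle$pearson         # 0.002
bundle$nullComparison
#> NullComparison vs 10 mock image(s):
#>   overlap <= 100 nm: observed 3.725% vs null 3.267% (sd 0.985) -> excess 0.4581 points
#>   KS D = 0.02414, p = 0.993 (ensemble p = 1)
```

Independent channels show no excess proximity over the random null. The
same analysis on an offset-coupled sheet (`coupling = "offset"`,
`offsetMean = 150` nm — adjacent, mostly non-overlapping domains) is
unambiguous:

```r
#> NullComparison vs 10 mock image(s):
#>   overlap <= 100 nm: observed 12.85% vs null 3.033% (sd 0.681) -> excess 9.816 points
#>   KS D = 0.7852, p = <2e-16 (ensemble p = 0.0909)
```

Two reading notes: nearby clusters below the resolution scale merge into
single detections (documented behavior, no watershed splitting), which
slightly depletes short within-channel NN distances; and with 10 mock
images the ensemble-based empirical p-value cannot fall below 1/11 ≈ 0.09,
so strong coupling is read from the two-sample KS p-value.

A thin command-line wrapper with `simulate`, `detect`, `nn`, `coloc`,
`null`, `stoich` and `run` subcommands ships in `inst/cli/stedclust-cli.R`.

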