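# Shared fixtures built in code.

# Keep only clusters at least `margin` nm from the mask/field boundary, so
# detection scores are not confounded by clusters straddling the field edge.
interiorMap <- function(map, margin = 300) {
  map@clusters <- map@clusters[map@clusters$edge_nm >= margin, , drop = FALSE]
  map
}

# A ClusterMap built directly from coordinates on a rectangular field.
makeMap <- function(x, y, fieldNm = c(10000, 10000), channel = "ch1",
                    areaUm2 = prod(fieldNm) * 1e-6, source = "truth") {
  n <- length(x)
  df <- data.frame(x_nm = x, y_nm = y, peak = rep(NA_real_, n),
                   fwhm_nm = rep(NA_real_, n), area_um2 = rep(NA_real_, n),
                   circularity = rep(NA_real_, n),
                   edge_nm = pmin(x, y, fieldNm[1] - x, fieldNm[2] - y))
  new("ClusterMap", clusters = df, channel = channel, areaUm2 = areaUm2,
      imageId = "manual", fieldNm = fieldNm, source = source)
}

# Noiseless image with Gaussian spots at given centers (nm) on a constant
# background; the independent rendering oracle for detection/sizing tests.
makeSpotImage <- function(centers, sigma, amplitude = 1000, background = 10,
                          npx = 100, pitch = 20) {
  img <- matrix(background, npx, npx)
  xs <- (seq_len(npx) - 1) * pitch
  for (k in seq_len(nrow(centers))) {
    gx <- exp(-(xs - centers[k, 1])^2 / (2 * sigma[k]^2))
    gy <- exp(-(xs - centers[k, 2])^2 / (2 * sigma[k]^2))
    img <- img + amplitude * (gy %o% gx)
  }
  SheetImage(img, pixelPitch = pitch, imageId = "spots")
}

# Generator conditions under which every cluster is individually resolvable
# (hard-core separation well above twice the largest FWHM) and bright
# (peak SNR >= 5 even for single-molecule clusters).
resolvableSpec <- function(fieldUm = 20, density = 2, seed = 1,
                           fwhms = seq(80, 170, by = 10)) {
  syntheticSpec(fieldUm = fieldUm, density = c(ch1 = density, ch2 = density),
                fwhmSample = list(fwhms, fwhms), photonsPerMolecule = 8000,
                background = 20, minSeparation = 450, seed = seed)
}

# Inverse-CDF sampler of the analytic 2D Poisson nearest-neighbor law,
# rho in um^-2, result in nm: the independent oracle for calibration tests.
sampleAnalyticNN <- function(n, rho) {
  u <- stats::runif(n)
  sqrt(-log(1 - u) / (pi * rho * 1e-6))
}
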