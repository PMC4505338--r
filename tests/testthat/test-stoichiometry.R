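test_that("the standard curve fits, inverts, and scales correctly", {
  pts <- data.frame(mass_pg = c(100, 200, 400, 800), signal = c(100, 200, 400, 800) * 3 + 50)
  curve <- fitStandardCurve(pts)
  expect_equal(curve@slope, 3)
  expect_equal(curve@intercept, 50)
  expect_equal(curve@r2, 1)
  expect_equal(invertMass(curve, 3 * 567 + 50), 567)
  ## doubling all signals doubles the slope but leaves inferred mass fixed
  ## when the unknown's signal is doubled too
  curve2 <- fitStandardCurve(transform(pts, signal = 2 * signal))
  expect_equal(curve2@slope, 6)
  expect_equal(invertMass(curve2, 2 * (3 * 567 + 50)), 567)
  expect_error(invertMass(curve, 0), "negative")
  expect_error(fitStandardCurve(data.frame(mass_pg = c(1, 1, 1), signal = 1:3)),
               "degenerate")
  expect_error(fitStandardCurve(pts[1:2, ]), "3 points")
})

test_that("a noisy standard curve recovers the true slope within 2 SE", {
  set.seed(12)
  mass <- seq(100, 2000, length.out = 10)
  pts <- data.frame(mass_pg = mass, signal = 4 * mass + 80 + rnorm(10, 0, 150))
  curve <- fitStandardCurve(pts)
  expect_lt(abs(curve@slope - 4), 2 * curve@slopeSe)
})

test_that("molecules per cell follow from mass, cell count and molar mass", {
  ## Avogadro route: 23.34 kDa -> 23.34e3 g/mol / 6.022e23 -> pg per molecule
  perMolPg <- 23.34 * 1e3 / 6.02214076e23 * 1e12
  expect_equal(moleculesPerCell(1638, 0.8e6, 23.34), (1638 / 0.8e6) / perMolPg)
  ## ~1% below the printed 53,185 copies per cell (documented discrepancy)
  expect_lt(abs(moleculesPerCell(1638, 0.8e6, 23.34) / 53185 - 1), 0.015)
  expect_equal(moleculesPerCell(0, 1e6, 23.34), 0)
  expect_equal(moleculesPerCell(2 * 1638, 0.8e6, 23.34),
               2 * moleculesPerCell(1638, 0.8e6, 23.34))
  expect_error(moleculesPerCell(100, 0, 23.34))
})

test_that("surface fraction is the isotype-corrected MFI ratio", {
  expect_equal(surfaceFraction(500, 500, 20, 20), 100)
  expect_equal(surfaceFraction(20, 500, 20, 20), 0)
  ## forward-construct a known fraction, then invert
  expect_equal(surfaceFraction(620, 2030, 20, 38.3), 30.125, tolerance = 1e-4)
  expect_error(surfaceFraction(100, 50, 0, 60), "exceed")
})

test_that("cell surface area uses the sphere model averaged over cells", {
  expect_equal(cellSurfaceArea(1), 4 * pi)
  r1040 <- sqrt(1040 / (4 * pi))
  expect_equal(cellSurfaceArea(rep(r1040, 63)), 1040)
  ## Jensen: mean of 4 pi r^2 exceeds 4 pi (mean r)^2 for dispersed radii
  r <- c(7, 9, 11)
  expect_gt(cellSurfaceArea(r), 4 * pi * mean(r)^2)
  expect_error(cellSurfaceArea(c(9, -1)))
  expect_error(cellSurfaceArea(numeric(0)))
})

test_that("the stoichiometry chain reproduces its identities and scalings", {
  res <- moleculesPerCluster(53185, 30.12, 1040, 4.4)
  expect_equal(res@surfaceMolecules, 53185 * 0.3012)
  expect_equal(res@clustersPerCell, 4576)
  ## chain identity at machine precision
  expect_equal(res@moleculesPerCluster * res@clustersPerCell,
               res@moleculesPerCell * res@surfaceFractionPct / 100,
               tolerance = 1e-12)
  ## proportionality: halving density doubles molecules per cluster
  half <- moleculesPerCluster(53185, 30.12, 1040, 2.2)
  expect_equal(half@moleculesPerCluster, 2 * res@moleculesPerCluster)
  zero <- moleculesPerCluster(53185, 0, 1040, 4.4)
  expect_equal(zero@moleculesPerCluster, 0)
  expect_error(moleculesPerCluster(53185, 30, 0, 4.4))
})

test_that("the file-based chain runs end to end on the bundled example data", {
  ext <- system.file("extdata", package = "stedclust")
  curve <- fitStandardCurve(read.csv(file.path(ext, "synthetic_standard_curve.csv")))
  expect_gt(curve@r2, 0.99)
  mfi <- read.csv(file.path(ext, "synthetic_mfi.csv"))
  radii <- read.csv(file.path(ext, "synthetic_radii_um.csv"))$radius_um
  res <- stoichiometryChain(curve, lysateSignal = 12 * 1638 + 150,
                            nCells = 0.8e6, massKDa = 23.34,
                            surfaceMfi = mfi$surface, totalMfi = mfi$total,
                            surfaceIso = mfi$surface_iso, totalIso = mfi$total_iso,
                            radiiUm = radii, clusterDensity = 4.4)
  expect_gt(res@moleculesPerCluster, 2.5)
  expect_lt(res@moleculesPerCluster, 5)
  expect_lt(res@moleculesPerCluster, 10)
  path <- withr::local_tempfile(fileext = ".json")
  writeStoichiometry(res, path)
  js <- jsonlite::read_json(path)
  expect_equal(js$molecules_per_cluster, res@moleculesPerCluster)
  expect_equal(js$clusters_per_cell, res@clustersPerCell)
})
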