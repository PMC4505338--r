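test_that("edge exclusion erodes the mask by the requested margin", {
  img <- SheetImage(matrix(10, 500, 500), pixelPitch = 20)  # 10 x 10 um
  expect_identical(excludeEdges(img, 0), img)
  eroded <- excludeEdges(img, 500)
  expect_equal(analyzedArea(eroded), 81)  # (10 - 2 * 0.5)^2
  expect_error(excludeEdges(img, 6000), "empties")
  expect_error(excludeEdges(img, -1))
})

test_that("detection refuses degenerate thresholds", {
  flat <- SheetImage(matrix(7, 50, 50))
  expect_error(annotateClusters(flat, "ch1"), "flat")
  expect_error(annotateClusters(flat, "missing"), "not present")
})

test_that("well-separated bright clusters are all found with subpixel centroids", {
  gs <- generateSheet(resolvableSpec(fieldUm = 12, density = 1.2, seed = 3))
  map <- annotateClusters(gs$image, "ch1")
  tm <- truthToClusterMap(gs$truth, "ch1")
  sc <- matchClusters(interiorMap(tm), interiorMap(map), dmax = 60)
  expect_equal(sc$recall, 1)
  expect_gte(sc$precision, 0.95)
  expect_lt(sc$meanError, 20)
  expect_true(all(sc$matches$d <= 20))
})

test_that("two clusters below the PSF scale merge into one detection", {
  sigma <- 100 / (2 * sqrt(2 * log(2)))
  img <- makeSpotImage(centers = rbind(c(1000, 1000), c(1060, 1000)),
                       sigma = rep(sigma, 2), amplitude = 500)
  map <- annotateClusters(img, "ch1")
  expect_equal(nrow(clusters(map)), 1)
  ## merged centroid sits between the two true centers
  expect_gt(clusters(map)$x_nm, 1000)
  expect_lt(clusters(map)$x_nm, 1060)
})

test_that("FWHM of a noiseless Gaussian spot is recovered", {
  sigma <- 100 / (2 * sqrt(2 * log(2)))  # 42.47 nm -> FWHM 100 nm
  img <- makeSpotImage(centers = cbind(1000, 1000), sigma = sigma)
  map <- annotateClusters(img, "ch1")
  w <- measureFWHM(img, map)
  expect_equal(w, 100, tolerance = 0.02)
})

test_that("measured FWHM of rendered clusters follows sqrt(f^2 + p^2) within 3%", {
  for (f in seq(80, 180, by = 20)) {
    sp <- syntheticSpec(fieldUm = 6, density = c(ch1 = 0.6), fwhmSample = list(f),
                        minSeparation = 4 * f, photonsPerMolecule = 5e4,
                        background = 50, shotNoise = FALSE, seed = f)
    gs <- generateSheet(sp)
    map <- interiorMap(annotateClusters(gs$image, "ch1"), 2 * f)
    w <- measureFWHM(gs$image, map)
    expect_gt(length(w), 0)
    expect_lt(abs(mean(w, na.rm = TRUE) / sqrt(f^2 + 50^2) - 1), 0.03)
  }
})

test_that("a profile that never falls below half maximum is censored", {
  ## bright plateau running into the image border: the rightward profile
  ## never crosses half maximum inside the image
  m <- matrix(10, 100, 100)
  m[20:80, 50:100] <- 1000
  img <- SheetImage(m, pixelPitch = 20, imageId = "plateau")
  map <- makeMap(1480, 980, fieldNm = c(2000, 2000), channel = "ch1")
  expect_error(measureFWHM(img, map, strict = TRUE), "censored|half maximum")
  expect_true(is.na(measureFWHM(img, map)))
})

test_that("mask circularity separates discs, bars and merged clusters", {
  npx <- 60; pitch <- 20
  disc <- matrix(10, npx, npx)
  cx <- 30
  for (i in seq_len(npx)) for (j in seq_len(npx))
    if ((i - cx)^2 + (j - cx)^2 <= 10^2) disc[i, j] <- 500
  shp <- segmentMasks(SheetImage(disc, pitch), "ch1")
  expect_equal(nrow(shp), 1)
  expect_gte(shp$circularity, 0.95)
  expect_equal(shp$area_um2, sum(disc > 10) * pitch^2 * 1e-6)

  bar <- matrix(10, npx, npx)
  bar[30, 20:39] <- 500
  shpBar <- segmentMasks(SheetImage(bar, pitch), "ch1")
  expect_lt(shpBar$circularity, 0.4)

  ## two merged Gaussians: larger area, less circular than one alone
  sigma <- 160 / (2 * sqrt(2 * log(2)))
  one <- makeSpotImage(cbind(1000, 1000), sigma, amplitude = 800)
  two <- makeSpotImage(rbind(c(900, 1000), c(1100, 1000)), rep(sigma, 2),
                       amplitude = 800)
  s1 <- segmentMasks(one, "ch1")
  s2 <- segmentMasks(two, "ch1")
  expect_equal(nrow(s2), 1)
  expect_gte(s2$area_um2, 0.025)
  expect_lt(s2$circularity, s1$circularity)
})

test_that("cluster density is count over analyzed area", {
  m <- makeMap(runif(44, 1000, 9000), runif(44, 1000, 9000),
               areaUm2 = 10)
  expect_equal(clusterDensity(m), 4.4)
  empty <- makeMap(numeric(0), numeric(0), areaUm2 = 10)
  expect_equal(clusterDensity(empty), 0)
})

test_that("detection and sizing are invariant to a global intensity scale", {
  gs <- generateSheet(resolvableSpec(fieldUm = 8, density = 1.5, seed = 17))
  img <- gs$image
  scaled <- img
  scaled@channels <- lapply(img@channels, function(m) m * 5)
  m1 <- annotateClusters(img, "ch1")
  m2 <- annotateClusters(scaled, "ch1")
  expect_equal(nrow(clusters(m1)), nrow(clusters(m2)))
  expect_equal(clusters(m1)$x_nm, clusters(m2)$x_nm)
  expect_equal(clusterDensity(m1), clusterDensity(m2))
  expect_equal(measureFWHM(img, m1), measureFWHM(scaled, m2))
})

test_that("reported shapes satisfy their invariants", {
  gs <- generateSheet(resolvableSpec(fieldUm = 8, density = 1.5, seed = 23))
  shp <- segmentMasks(gs$image, "ch1")
  expect_true(all(shp$circularity >= 0 & shp$circularity <= 1))
  expect_true(all(shp$area_um2 > 0))
})
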