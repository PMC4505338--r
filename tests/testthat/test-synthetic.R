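test_that("zero density yields pure background and empty ground truth", {
  sp <- syntheticSpec(fieldUm = 3, density = c(ch1 = 0, ch2 = 0), seed = 4)
  gs <- generateSheet(sp)
  expect_equal(nrow(truthTable(gs$truth, 1)), 0)
  expect_equal(nrow(truthTable(gs$truth, 2)), 0)
  ## pure shot noise around the background level, no structure
  expect_lt(abs(mean(getChannel(gs$image, 1)) - 10), 0.5)
  expect_equal(nrow(clusters(annotateClusters(gs$image, "ch1"))), 0)
})

test_that("realized cluster counts follow the homogeneous Poisson law", {
  counts <- vapply(1:200, function(s) {
    sp <- syntheticSpec(fieldUm = 5, density = c(ch1 = 4.4), seed = s)
    nrow(truthTable(simulateTruth(sp), 1))
  }, numeric(1))
  lambda <- 4.4 * 25
  expect_lt(abs(mean(counts) - lambda), 3 * sqrt(lambda / 200))
  expect_gt(var(counts) / mean(counts), 0.8)
  expect_lt(var(counts) / mean(counts), 1.2)
})

test_that("a fixed seed reproduces image and ground truth bit-identically", {
  sp <- syntheticSpec(fieldUm = 5, density = c(ch1 = 2, ch2 = 2), seed = 11)
  a <- generateSheet(sp)
  b <- generateSheet(sp)
  expect_identical(a$image@channels, b$image@channels)
  expect_identical(a$truth@truth, b$truth@truth)
})

test_that("expected-count guard refuses runaway simulations", {
  sp <- syntheticSpec(fieldUm = 100, density = c(ch1 = 100), maxClusters = 1e4)
  expect_error(simulateTruth(sp), "cap")
})

test_that("spec validity rejects inconsistent parameters", {
  expect_error(syntheticSpec(density = c(ch1 = -1)), "densities")
  expect_error(syntheticSpec(pixelPitch = 0), "pixelPitch")
  expect_error(syntheticSpec(coupling = "offset", offsetMean = -5), "offsetMean")
  expect_error(syntheticSpec(fieldUm = c(-1, 2)), "fieldUm")
  expect_error(syntheticSpec(coupling = "sideways"), "coupling")
})

test_that("co-centered coupling puts a channel-1 center at distance 0 from every channel-2 center", {
  sp <- syntheticSpec(fieldUm = 8, density = c(ch1 = 2, ch2 = 2),
                      coupling = "co_centered", seed = 21)
  tr <- simulateTruth(sp)
  t1 <- truthTable(tr, 1); t2 <- truthTable(tr, 2)
  expect_gt(nrow(t2), 0)
  for (k in seq_len(nrow(t2))) {
    d <- sqrt((t1$x_nm - t2$x_nm[k])^2 + (t1$y_nm - t2$y_nm[k])^2)
    expect_equal(min(d), 0)
  }
})

test_that("offset coupling displaces channel 2 by the requested mean distance", {
  sp <- syntheticSpec(fieldUm = 25, density = c(ch1 = 2, ch2 = 2),
                      coupling = "offset", offsetMean = 150, offsetSd = 30,
                      seed = 31)
  pl <- stedclust:::.simulatePlacement(sp)
  ch1 <- pl$all[[1]]; ch2 <- pl$all[[2]]
  d <- sqrt((ch2$x_nm - ch1$x_nm[ch2$parent])^2 +
            (ch2$y_nm - ch1$y_nm[ch2$parent])^2)
  se <- sd(d) / sqrt(length(d))
  expect_lt(abs(mean(d) - 150), 2 * se + 1e-9)
})

test_that("truth nearest-neighbor distances: pair, scaling, degenerate input", {
  tr <- new("GroundTruth",
            truth = list(ch1 = data.frame(x_nm = c(500, 600), y_nm = c(500, 500),
                                          fwhm_nm = 100, molecules = 1L)),
            fieldNm = c(2000, 2000))
  expect_equal(truthNNDistances(tr, 1), c(100, 100))
  tr2 <- tr
  tr2@truth$ch1$x_nm <- tr2@truth$ch1$x_nm * 2
  tr2@truth$ch1$y_nm <- tr2@truth$ch1$y_nm * 2
  expect_equal(truthNNDistances(tr2, 1), c(200, 200))
  one <- new("GroundTruth",
             truth = list(ch1 = data.frame(x_nm = 500, y_nm = 500,
                                           fwhm_nm = 100, molecules = 1L)),
             fieldNm = c(2000, 2000))
  expect_warning(d <- truthNNDistances(one, 1), "fewer than 2")
  expect_length(d, 0)
})

test_that("Poisson truth reproduces the closed-form mean NN distance", {
  sp <- syntheticSpec(fieldUm = 40, density = c(ch1 = 4.4), seed = 5)
  d <- truthNNDistances(simulateTruth(sp), 1)
  expect_gt(length(d), 1000)
  expect_lt(abs(mean(d) / (1000 / (2 * sqrt(4.4))) - 1), 0.025)
})

test_that("independent-mode truth passes goodness of fit against the analytic null", {
  sp <- syntheticSpec(fieldUm = 35, density = c(ch1 = 3), seed = 8)
  tr <- simulateTruth(sp)
  map <- truthToClusterMap(tr, 1)
  nn <- nnDistances(map, sameSpecies = TRUE, borderMargin = 500)
  expect_gt(nn@nReference, 1000)
  fit <- fitRandomDistribution(nn)
  expect_gt(fit$ksP, 0.01)
})

test_that("sheets round-trip through TIFF, truth CSV and spec JSON", {
  sp <- syntheticSpec(fieldUm = 3, density = c(ch1 = 2, ch2 = 2), seed = 13)
  gs <- generateSheet(sp)
  dir <- withr::local_tempdir()
  paths <- writeSheet(gs$image, dir, "demo", truth = gs$truth, spec = sp)
  back <- readSheetTiff(paths[["image"]], pixelPitch = 20)
  expect_equal(length(back@channels), 2)
  expect_equal(back@channels$ch1, gs$image@channels$ch1)
  tt <- read.csv(paths[["truth"]])
  expect_equal(nrow(tt), sum(vapply(gs$truth@truth, nrow, numeric(1))))
  sj <- jsonlite::read_json(paths[["spec"]])
  expect_equal(sj$seed, 13)
  expect_equal(sj$coupling, "independent")
})
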