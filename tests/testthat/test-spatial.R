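test_that("nearest-neighbor distances: pairs, coincidence, and guards", {
  m <- makeMap(c(5000, 5100), c(5000, 5000))
  nn <- nnDistances(m, sameSpecies = TRUE)
  expect_equal(nn@distances, c(100, 100))
  ref <- makeMap(5000, 5000)
  tgt <- makeMap(c(5000, 8000), c(5000, 8000))
  expect_equal(nnDistances(ref, tgt)@distances, 0)
  expect_error(nnDistances(ref, makeMap(numeric(0), numeric(0))), "no clusters")
  near <- makeMap(c(100, 200), c(100, 200))
  expect_error(nnDistances(near, sameSpecies = TRUE, borderMargin = 500),
               "border margin")
  ## sameSpecies demands the same underlying map
  expect_error(nnDistances(ref, tgt, sameSpecies = TRUE), "same map")
})

test_that("nn distances are invariant under translation and rotation", {
  set.seed(42)
  x <- runif(40, 1000, 9000); y <- runif(40, 1000, 9000)
  base <- nnDistances(makeMap(x, y), sameSpecies = TRUE)@distances
  shifted <- nnDistances(makeMap(x + 700, y - 300, fieldNm = c(12000, 12000)),
                         sameSpecies = TRUE)@distances
  expect_equal(sort(base), sort(shifted))
  rot <- nnDistances(makeMap(y, 10000 - x), sameSpecies = TRUE)@distances
  expect_equal(sort(base), sort(rot))
})

test_that("the analytic NN law is a proper density with the known moments", {
  for (rho in c(0.5, 1, 4.4, 5)) {
    total <- integrate(function(r) analyticNNPdf(rho, r), 0, Inf,
                       rel.tol = 1e-9)$value
    expect_lt(abs(total - 1), 1e-6)
    meanNum <- integrate(function(r) r * analyticNNPdf(rho, r), 0, Inf,
                         rel.tol = 1e-9)$value
    expect_equal(meanNum, 1000 / (2 * sqrt(rho)), tolerance = 1e-6)
    medNum <- uniroot(function(r) analyticNNCdf(rho, r) - 0.5, c(1, 5000))$root
    expect_equal(medNum, 1000 * sqrt(log(2) / (pi * rho)), tolerance = 1e-4)
  }
  expect_equal(analyticNNPdf(4.4, 0), 0)
  expect_error(analyticNNPdf(-1, 10))
  expect_error(analyticNNPdf(4.4, -10))
})

test_that("the random-distribution fit accepts its own law and rejects clustering", {
  set.seed(7)
  good <- new("NNDistribution", distances = sampleAnalyticNN(400, 4.4),
              breaks = seq(0, 1000, 20), counts = integer(50),
              refChannel = "ch1", targetChannel = "ch1", rhoTarget = 4.4,
              nReference = 400L, source = "truth")
  good@counts <- stedclust:::.histCounts(good@distances, good@breaks)
  fit <- fitRandomDistribution(good)
  expect_gt(fit$ksP, 0.01)
  expect_equal(sum(fit$expectedCounts), 400, tolerance = 0.05)

  clustered <- good
  clustered@distances <- abs(rnorm(400, 0, 15))
  clustered@counts <- stedclust:::.histCounts(clustered@distances, good@breaks)
  expect_lt(fitRandomDistribution(clustered)$ksP, 1e-6)

  small <- good
  small@distances <- good@distances[1:10]
  small@nReference <- 10L
  small@counts <- stedclust:::.histCounts(small@distances, good@breaks)
  expect_error(fitRandomDistribution(small), "at least 20")
})

test_that("overlap fraction: limits and monotonicity", {
  d0 <- new("NNDistribution", distances = rep(0, 5), breaks = seq(0, 1000, 20),
            counts = integer(50), refChannel = "a", targetChannel = "b",
            rhoTarget = 1, nReference = 5L, source = "truth")
  expect_equal(overlapFraction(d0), 100)
  d1 <- d0; d1@distances <- 150; d1@nReference <- 1L
  expect_equal(overlapFraction(d1, 100), 0)
  set.seed(3)
  dm <- d0; dm@distances <- runif(200, 0, 400); dm@nReference <- 200L
  fracs <- vapply(seq(0, 500, 25), function(th) overlapFraction(dm, th), numeric(1))
  expect_true(all(diff(fracs) >= 0))
})

test_that("per-sheet Pearson correlation behaves at its limits", {
  set.seed(9)
  a <- matrix(rpois(300 * 300, 20), 300)
  b <- matrix(rpois(300 * 300, 20), 300)
  selfImg <- SheetImage(list(ch1 = a, ch2 = a))
  expect_equal(pearsonPerSheet(selfImg), 1)
  negImg <- SheetImage(list(ch1 = a, ch2 = -a))
  expect_equal(pearsonPerSheet(negImg), -1)
  indImg <- SheetImage(list(ch1 = a, ch2 = b))
  expect_lt(abs(pearsonPerSheet(indImg)), 0.1)
  flat <- SheetImage(list(ch1 = a, ch2 = matrix(5, 300, 300)))
  expect_error(pearsonPerSheet(flat), "zero-variance")
})

test_that("correlated rendering produces high Pearson, independent low", {
  spc <- syntheticSpec(fieldUm = 8, density = c(ch1 = 2, ch2 = 2),
                       coupling = "co_centered", photonsPerMolecule = 2000,
                       background = 15, seed = 10)
  rc <- pearsonPerSheet(generateSheet(spc)$image)
  spi <- syntheticSpec(fieldUm = 8, density = c(ch1 = 2, ch2 = 2),
                       coupling = "independent", photonsPerMolecule = 2000,
                       background = 15, seed = 10)
  ri <- pearsonPerSheet(generateSheet(spi)$image)
  expect_gt(rc, 0.5)
  expect_lt(abs(ri), 0.1)
})
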