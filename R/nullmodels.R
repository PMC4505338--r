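## Monte-Carlo mock-image null: regenerate images with the observed densities
## and size distributions but completely random, uncorrelated placements,
## push them through the identical detection + nearest-neighbor path, and
## compare the observed distance distribution with the pooled null.

#' Build a null-ensemble specification from observed cluster maps
#'
#' Densities are the per-channel means over sheets and the FWHM distribution
#' is the pooled empirical sample, so mock images match the data in density
#' and size while placements are completely random and uncorrelated.
#'
#' Measured cluster FWHMs are still convolved with the PSF; rendering mocks
#' from them directly would convolve a second time and systematically
#' oversize (and over-merge) mock clusters. With \code{deconvolvePsf = TRUE}
#' (default) the empirical sizes are deconvolved to
#' sqrt(max(f^2 - p^2, (p/2)^2)) before they enter the generator, so the
#' mock images reproduce the \emph{measured} size distribution after
#' re-convolution.
#'
#' @param maps list of \linkS4class{ClusterMap}s (one or more per channel;
#'   channels are distinguished by their \code{channel} label).
#' @param fieldUm mock field width/height, um.
#' @param nImages number of mock images (default 10).
#' @param pixelPitch,photonsPerMolecule,background,moleculesMean,psfFwhm
#'   rendering parameters forwarded to the generator.
#' @param seed integer root seed of the ensemble.
#' @param deconvolvePsf remove the PSF contribution from the empirical FWHM
#'   sample before rendering (see Details).
#' @return a \linkS4class{NullEnsembleSpec}.
#' @export
specFromObserved <- function(maps, fieldUm = c(20, 20), nImages = 10L,
                             pixelPitch = 20, photonsPerMolecule = 500,
                             background = 10, moleculesMean = 3.5,
                             psfFwhm = 50, seed = 1L, deconvolvePsf = TRUE) {
  if (is(maps, "ClusterMap")) maps <- list(maps)
  if (length(maps) == 0L) .stopf("need at least one ClusterMap")
  chans <- vapply(maps, function(m) m@channel, character(1))
  uch <- unique(chans)
  if (length(uch) > 2L) .stopf("at most two channels supported")
  density <- vapply(uch, function(ch)
    mean(vapply(maps[chans == ch], clusterDensity, numeric(1))), numeric(1))
  fwhmSample <- lapply(uch, function(ch) {
    f <- unlist(lapply(maps[chans == ch], function(m) m@clusters$fwhm_nm))
    f[!is.na(f) & f > 0]
  })
  names(density) <- uch
  if (deconvolvePsf)
    fwhmSample <- lapply(fwhmSample, function(f)
      sqrt(pmax(f^2 - psfFwhm^2, (psfFwhm / 2)^2)))
  spec <- syntheticSpec(fieldUm = fieldUm, pixelPitch = pixelPitch,
                        density = density, fwhmSample = fwhmSample,
                        moleculesMean = moleculesMean, psfFwhm = psfFwhm,
                        photonsPerMolecule = photonsPerMolecule,
                        background = background, coupling = "independent",
                        seed = seed)
  new("NullEnsembleSpec", spec = spec, nImages = as.integer(nImages))
}

#' Generate a mock-image ensemble
#'
#' Generates \code{nImages} independent realizations of the null
#' specification; per-image seeds are derived deterministically from the
#' ensemble seed, so a fixed seed reproduces the ensemble exactly.
#'
#' @param ensembleSpec a \linkS4class{NullEnsembleSpec}.
#' @return list of length \code{nImages}; each element is the
#'   \code{list(image, truth)} returned by \code{\link{generateSheet}}.
#' @export
buildMockEnsemble <- function(ensembleSpec) {
  stopifnot(is(ensembleSpec, "NullEnsembleSpec"))
  validObject(ensembleSpec)
  lapply(seq_len(ensembleSpec@nImages), function(i) {
    s <- ensembleSpec@spec
    s@seed <- .substream(ensembleSpec@spec@seed, 100L + i)
    out <- generateSheet(s)
    out$image@imageId <- sprintf("mock-%02d-seed%d", i, s@seed)
    out
  })
}

#' Nearest-neighbor analysis of a mock ensemble
#'
#' Pushes every mock image through the identical analysis path used for real
#' data: blob detection on both channels, then cross-channel
#' nearest-neighbor distances. Setting \code{detect = FALSE} skips detection
#' and uses ground-truth centers (tagged \code{source = "truth"}).
#'
#' @param ensemble output of \code{\link{buildMockEnsemble}}.
#' @param refChannel,targetChannel channel labels.
#' @param offsetK,minPixels detection parameters (must match the observed
#'   analysis).
#' @param borderMargin,breaks forwarded to \code{\link{nnDistances}}.
#' @param detect run detection (TRUE, default) or use ground truth.
#' @return list of \linkS4class{NNDistribution}, one per mock image.
#' @export
analyzeMockEnsemble <- function(ensemble, refChannel, targetChannel,
                                offsetK = 3, minPixels = 4L,
                                borderMargin = 500,
                                breaks = seq(0, 1000, by = 20),
                                detect = TRUE) {
  if (length(ensemble) == 0L) .stopf("empty mock ensemble")
  lapply(ensemble, function(mk) {
    if (detect) {
      ref <- annotateClusters(mk$image, refChannel, offsetK, minPixels)
      tgt <- annotateClusters(mk$image, targetChannel, offsetK, minPixels)
    } else {
      ref <- truthToClusterMap(mk$truth, refChannel, imageId = mk$image@imageId)
      tgt <- truthToClusterMap(mk$truth, targetChannel, imageId = mk$image@imageId)
    }
    nnDistances(ref, tgt, sameSpecies = FALSE, borderMargin = borderMargin,
                breaks = breaks)
  })
}

#' Compare an observed distance distribution with a mock-image null
#'
#' Pools the null distances over all mock images on the observed histogram
#' bins and reports (i) the excess overlap: observed minus null percentage of
#' reference clusters within \code{d} of a target cluster, with the
#' between-mock SD of the null percentage; (ii) a two-sample
#' Kolmogorov-Smirnov statistic of observed versus pooled null with its
#' asymptotic p-value; and (iii) an ensemble-based empirical p-value (each
#' mock's KS against the pool of the others; lower-bounded by
#' 1/(n_mock + 1)). The comparison refuses distributions derived from raw
#' ground-truth coordinates unless \code{allowTruth = TRUE}, so detection
#' biases cancel between observed and null by default.
#'
#' @param observed an \linkS4class{NNDistribution} from the real (or test)
#'   image.
#' @param nulls list of \linkS4class{NNDistribution} from
#'   \code{\link{analyzeMockEnsemble}}.
#' @param d overlap threshold, nm.
#' @param allowTruth permit truth-derived distributions.
#' @return a \linkS4class{NullComparison}.
#' @export
compareToNull <- function(observed, nulls, d = 100, allowTruth = FALSE) {
  stopifnot(is(observed, "NNDistribution"))
  if (length(nulls) == 0L) .stopf("empty null ensemble")
  srcs <- c(observed@source, vapply(nulls, function(x) x@source, character(1)))
  if (!allowTruth && any(srcs == "truth"))
    .stopf(paste("distributions derived from raw truth coordinates;",
                 "run the detection pipeline on mocks and observed data,",
                 "or set allowTruth = TRUE"))
  for (nl in nulls)
    if (!isTRUE(all.equal(nl@breaks, observed@breaks)))
      .stopf("histogram bin edges of null and observed distributions differ")
  pooled <- unlist(lapply(nulls, function(x) x@distances))
  if (length(pooled) == 0L) .stopf("null ensemble contains no distances")
  nullDist <- new("NNDistribution", distances = pooled,
                  breaks = observed@breaks,
                  counts = .histCounts(pooled, observed@breaks),
                  refChannel = observed@refChannel,
                  targetChannel = observed@targetChannel,
                  rhoTarget = mean(vapply(nulls, function(x) x@rhoTarget, numeric(1))),
                  nReference = length(pooled),
                  source = nulls[[1L]]@source)
  ovObs <- overlapFraction(observed, d)
  ovPerMock <- vapply(nulls, function(x) overlapFraction(x, d), numeric(1))
  ovNull <- 100 * mean(pooled <= d)
  ks <- suppressWarnings(stats::ks.test(observed@distances, pooled))
  ## ensemble-based empirical p: leave-one-out KS of each mock vs the rest
  nm <- length(nulls)
  ksNull <- vapply(seq_len(nm), function(i) {
    rest <- unlist(lapply(nulls[-i], function(x) x@distances))
    if (length(rest) == 0L || length(nulls[[i]]@distances) == 0L) return(NA_real_)
    unname(suppressWarnings(stats::ks.test(nulls[[i]]@distances, rest))$statistic)
  }, numeric(1))
  ksNull <- ksNull[!is.na(ksNull)]
  pEmp <- (1 + sum(ksNull >= unname(ks$statistic))) / (length(ksNull) + 1)
  new("NullComparison", observed = observed, null = nullDist,
      thresholdNm = d, overlapObs = ovObs, overlapNull = ovNull,
      overlapNullSd = stats::sd(ovPerMock), excessPct = ovObs - ovNull,
      ksStat = unname(ks$statistic), ksP = ks$p.value,
      pEmpirical = pEmp, nMock = as.integer(nm))
}
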