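## End-to-end analysis pipeline for one dual-channel sheet: detection ->
## sizing -> density -> within/cross-channel nearest neighbors -> overlap and
## Pearson -> analytic random fit -> mock-image null comparison.

.stage <- function(name, imageId, expr) {
  tryCatch(expr, error = function(e)
    .stopf("pipeline stage '%s' failed on '%s': %s", name, imageId,
           conditionMessage(e)))
}

#' Run the full sheet-analysis pipeline
#'
#' Runs the complete analysis the package implements on one dual-channel
#' sheet image: edge exclusion, blob detection on both channels, FWHM and
#' mask-shape measurements, cluster densities, within-channel
#' nearest-neighbor distributions with the analytic random fit,
#' cross-channel nearest neighbors with the overlap fraction and per-sheet
#' Pearson correlation, and a Monte-Carlo mock-image null comparison with
#' densities and size distributions matched to the detected maps. All
#' randomness (the mock ensemble) derives from \code{seed}; reruns with the
#' same inputs and seed are identical.
#'
#' @param image a \linkS4class{SheetImage} with two channels.
#' @param refChannel,targetChannel channel labels; the cross-channel analysis
#'   measures distances from \code{refChannel} clusters to their nearest
#'   \code{targetChannel} cluster.
#' @param edgeMargin sheet-edge exclusion margin, nm.
#' @param offsetK,minPixels detection parameters.
#' @param borderMargin minus-sampling margin for nearest neighbors, nm.
#' @param overlapD overlap threshold, nm.
#' @param breaks histogram bin edges, nm.
#' @param nullImages mock images in the null ensemble (0 skips the null
#'   comparison).
#' @param photonsPerMolecule,background,moleculesMean,psfFwhm rendering
#'   parameters for the mock images.
#' @param seed integer root seed for the mock ensemble.
#' @param outputDir optional directory; when given, cluster tables, distance
#'   tables and a JSON summary (with the resolved configuration, its hash
#'   and the seed) are written there.
#' @return a list bundle: \code{maps}, \code{densities}, \code{fwhm},
#'   \code{shapes}, \code{nnWithin}, \code{randomFit}, \code{nnCross},
#'   \code{overlapPct}, \code{pearson}, \code{nullComparison},
#'   \code{config}, \code{configHash}.
#' @export
runPipeline <- function(image, refChannel = 1L, targetChannel = 2L,
                        edgeMargin = 0, offsetK = 3, minPixels = 4L,
                        borderMargin = 500, overlapD = 100,
                        breaks = seq(0, 1000, by = 20), nullImages = 10L,
                        photonsPerMolecule = 500, background = 10,
                        moleculesMean = 3.5, psfFwhm = 50,
                        seed = 1L, outputDir = NULL) {
  stopifnot(is(image, "SheetImage"))
  cn <- channelNames(image)
  if (is.numeric(refChannel)) refChannel <- cn[refChannel]
  if (is.numeric(targetChannel)) targetChannel <- cn[targetChannel]
  for (ch in c(refChannel, targetChannel))
    if (is.na(ch) || !ch %in% cn)
      .stopf("configuration error: channel '%s' not present in image '%s'", ch, image@imageId)
  id <- image@imageId
  config <- list(imageId = id, refChannel = refChannel,
                 targetChannel = targetChannel, edgeMargin = edgeMargin,
                 offsetK = offsetK, minPixels = minPixels,
                 borderMargin = borderMargin, overlapD = overlapD,
                 breaks = range(breaks), binWidth = diff(breaks)[1L],
                 nullImages = nullImages, seed = as.integer(seed))
  hash <- .configHash(config)

  image <- .stage("exclude_edges", id, excludeEdges(image, edgeMargin))
  maps <- list()
  fwhm <- list()
  shapes <- list()
  for (ch in unique(c(refChannel, targetChannel))) {
    maps[[ch]] <- .stage("annotate_clusters", id,
                         annotateClusters(image, ch, offsetK, minPixels))
    fwhm[[ch]] <- .stage("measure_fwhm", id, measureFWHM(image, maps[[ch]]))
    maps[[ch]]@clusters$fwhm_nm <- fwhm[[ch]]
    shapes[[ch]] <- .stage("segment_masks", id,
                           segmentMasks(image, ch, offsetK, minPixels))
    if (nrow(shapes[[ch]]) == nrow(maps[[ch]]@clusters)) {
      maps[[ch]]@clusters$area_um2 <- shapes[[ch]]$area_um2
      maps[[ch]]@clusters$circularity <- shapes[[ch]]$circularity
    }
  }
  densities <- vapply(maps, clusterDensity, numeric(1))

  nnWithin <- list()
  randomFit <- list()
  for (ch in names(maps)) {
    nnWithin[[ch]] <- .stage("nn_within", id,
      nnDistances(maps[[ch]], sameSpecies = TRUE, borderMargin = borderMargin,
                  breaks = breaks))
    randomFit[[ch]] <- .stage("random_fit", id, tryCatch(
      fitRandomDistribution(nnWithin[[ch]]), error = function(e) NULL))
  }

  nnCross <- .stage("nn_cross", id,
    nnDistances(maps[[refChannel]], maps[[targetChannel]],
                sameSpecies = FALSE, borderMargin = borderMargin,
                breaks = breaks))
  overlapPct <- .stage("overlap", id, overlapFraction(nnCross, overlapD))
  pearson <- .stage("pearson", id,
                    pearsonPerSheet(image, refChannel, targetChannel))

  nullComparison <- NULL
  if (nullImages >= 1L) {
    fieldUm <- rev(dim(getChannel(image, refChannel))) * image@pixelPitch / 1000
    nes <- .stage("null_spec", id,
      specFromObserved(maps, fieldUm = fieldUm, nImages = nullImages,
                       pixelPitch = image@pixelPitch,
                       photonsPerMolecule = photonsPerMolecule,
                       background = background,
                       moleculesMean = moleculesMean, psfFwhm = psfFwhm,
                       seed = seed))
    ensemble <- .stage("mock_ensemble", id, buildMockEnsemble(nes))
    nullNN <- .stage("mock_analysis", id,
      analyzeMockEnsemble(ensemble, refChannel, targetChannel,
                          offsetK = offsetK, minPixels = minPixels,
                          borderMargin = borderMargin, breaks = breaks))
    nullComparison <- .stage("null_comparison", id,
      compareToNull(nnCross, nullNN, d = overlapD))
  }

  bundle <- list(maps = maps, densities = densities, fwhm = fwhm,
                 shapes = shapes, nnWithin = nnWithin, randomFit = randomFit,
                 nnCross = nnCross, overlapPct = overlapPct,
                 pearson = pearson, nullComparison = nullComparison,
                 config = config, configHash = hash)

  if (!is.null(outputDir)) {
    dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
    writeClusterCsv(maps, file.path(outputDir, paste0(id, "_clusters.csv")),
                    configHash = hash, seed = config$seed)
    dd <- data.frame(image_id = id, ref_channel = refChannel,
                     target_channel = targetChannel,
                     nn_nm = nnCross@distances, config_hash = hash,
                     seed = config$seed)
    utils::write.csv(dd, file.path(outputDir, paste0(id, "_nn_cross.csv")),
                     row.names = FALSE)
    summary <- list(
      image_id = id, config = config, config_hash = hash,
      analyzed_area_um2 = analyzedArea(image),
      densities_per_um2 = as.list(densities),
      mean_fwhm_nm = lapply(fwhm, function(f) mean(f, na.rm = TRUE)),
      overlap_pct = overlapPct, pearson_r = pearson,
      ks_random_fit = lapply(randomFit, function(f)
        if (is.null(f)) NULL else list(stat = f$ksStat, p = f$ksP)),
      null_comparison = if (is.null(nullComparison)) NULL else list(
        excess_pct = nullComparison@excessPct,
        overlap_null_pct = nullComparison@overlapNull,
        ks_stat = nullComparison@ksStat, ks_p = nullComparison@ksP,
        p_empirical = nullComparison@pEmpirical,
        n_mock = nullComparison@nMock))
    jsonlite::write_json(summary, file.path(outputDir, paste0(id, "_summary.json")),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  bundle
}

#' Match detected clusters to ground truth
#'
#' Greedy one-to-one matching of detected cluster centers to true centers by
#' increasing distance, with a maximum match radius. Used to score detection
#' recall, precision, and centroid error against the generator's ground
#' truth.
#'
#' @param truthMap,detectedMap \linkS4class{ClusterMap}s (typically
#'   \code{\link{truthToClusterMap}} output and a detected map).
#' @param dmax maximum match distance, nm (default 60).
#' @return list with \code{recall}, \code{precision}, \code{matches}
#'   (data.frame of index pairs and distances), \code{meanError} (mean
#'   centroid error of matches, nm).
#' @export
matchClusters <- function(truthMap, detectedMap, dmax = 60) {
  a <- as.matrix(truthMap@clusters[, c("x_nm", "y_nm")])
  b <- as.matrix(detectedMap@clusters[, c("x_nm", "y_nm")])
  m <- .greedyMatch(a, b, dmax)
  list(recall = if (nrow(a)) nrow(m) / nrow(a) else NA_real_,
       precision = if (nrow(b)) nrow(m) / nrow(b) else NA_real_,
       matches = m,
       meanError = if (nrow(m)) mean(m$d) else NA_real_)
}
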