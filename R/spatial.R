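## Nearest-neighbor distance distributions, the analytic 2D Poisson null,
## the 100 nm overlap statistic, and per-sheet Pearson correlation.

#' Nearest-neighbor distances between cluster maps
#'
#' For each reference cluster lying at least \code{borderMargin} from the
#' analyzable-region boundary, the Euclidean center-to-center distance to the
#' nearest target cluster. Neighbors may themselves lie inside the margin
#' (minus-sampling edge correction). With \code{sameSpecies = TRUE} the
#' reference and target are the same map and each cluster is excluded as its
#' own neighbor.
#'
#' @param reference,target \linkS4class{ClusterMap}s; identical for
#'   within-species analysis.
#' @param sameSpecies logical; exclude self-matches (requires
#'   \code{reference} and \code{target} to be the same map).
#' @param borderMargin minus-sampling margin, nm (default 500).
#' @param breaks histogram bin edges, nm (default 20 nm bins to 1000 nm).
#' @param rhoTarget target-channel density for the analytic null,
#'   clusters/um^2; defaults to the target map's own density
#'   (independently determined from the image).
#' @return an \linkS4class{NNDistribution}.
#' @export
nnDistances <- function(reference, target = reference, sameSpecies = FALSE,
                        borderMargin = 500, breaks = seq(0, 1000, by = 20),
                        rhoTarget = NULL) {
  stopifnot(is(reference, "ClusterMap"), is(target, "ClusterMap"))
  refTab <- reference@clusters
  tgtTab <- target@clusters
  if (nrow(tgtTab) < 1L) .stopf("target map has no clusters")
  if (sameSpecies) {
    if (!identical(refTab$x_nm, tgtTab$x_nm) || !identical(refTab$y_nm, tgtTab$y_nm))
      .stopf("sameSpecies = TRUE requires reference and target to be the same map")
    if (nrow(tgtTab) < 2L) .stopf("same-species analysis needs >= 2 clusters")
  }
  keep <- refTab$edge_nm >= borderMargin
  if (!any(keep))
    .stopf("all %d reference clusters lie within the %.0f nm border margin",
           nrow(refTab), borderMargin)
  ref <- as.matrix(refTab[keep, c("x_nm", "y_nm")])
  tgt <- as.matrix(tgtTab[, c("x_nm", "y_nm")])
  d <- if (sameSpecies) {
    full <- .nn1(tgt, tgt, excludeSelf = TRUE)
    full[keep]
  } else {
    .nn1(ref, tgt)
  }
  if (is.null(rhoTarget)) rhoTarget <- clusterDensity(target)
  src <- if (reference@source == "detected" && target@source == "detected")
    "detected" else "truth"
  new("NNDistribution", distances = d, breaks = breaks,
      counts = .histCounts(d, breaks),
      refChannel = reference@channel, targetChannel = target@channel,
      rhoTarget = rhoTarget, nReference = length(d), source = src)
}

#' Analytic nearest-neighbor law for a random (Poisson) cluster pattern
#'
#' For clusters completely randomly distributed at density rho, the
#' probability density of the distance r to the nearest neighbor is
#' \deqn{p(r) = 2 \pi \rho r \exp(-\pi \rho r^2)}
#' (rho converted from clusters/um^2 to clusters/nm^2 internally). The
#' corresponding CDF is \eqn{1 - \exp(-\pi \rho r^2)}; the mean of the law is
#' \eqn{1/(2\sqrt{\rho})} and its median \eqn{\sqrt{\ln 2 / (\pi \rho)}}.
#'
#' @param rho cluster density, clusters/um^2 (> 0).
#' @param r distance(s), nm (>= 0).
#' @return probability density per nm (\code{analyticNNPdf}) or cumulative
#'   probability (\code{analyticNNCdf}).
#' @export
analyticNNPdf <- function(rho, r) {
  if (any(rho <= 0)) .stopf("rho must be > 0")
  if (any(r < 0)) .stopf("r must be >= 0")
  rn <- rho * .NM2_TO_UM2
  2 * pi * rn * r * exp(-pi * rn * r^2)
}

#' @rdname analyticNNPdf
#' @export
analyticNNCdf <- function(rho, r) {
  if (any(rho < 0)) .stopf("rho must be >= 0")
  if (any(r < 0)) .stopf("r must be >= 0")
  rn <- rho * .NM2_TO_UM2
  1 - exp(-pi * rn * r^2)
}

#' Goodness of fit against the analytic random distribution
#'
#' Compares observed nearest-neighbor distances with the analytic law at the
#' density independently determined from the image (the density is fixed,
#' not fitted). Returns the expected histogram overlay and a one-sample
#' Kolmogorov-Smirnov test of the distances against the analytic CDF. The
#' KS statistic is an extension over a visual curve comparison and is
#' labeled as such in the report.
#'
#' @param dist an \linkS4class{NNDistribution} with \code{rhoTarget} set.
#' @param minN minimum number of reference clusters required (default 20).
#' @return list with \code{ksStat}, \code{ksP}, \code{rho}, \code{n},
#'   \code{breaks}, \code{observedCounts}, \code{expectedCounts}, and
#'   \code{method}.
#' @export
fitRandomDistribution <- function(dist, minN = 20L) {
  stopifnot(is(dist, "NNDistribution"))
  if (dist@rhoTarget <= 0) .stopf("rhoTarget must be positive (determined from the image)")
  if (dist@nReference < minN)
    .stopf("need at least %d reference clusters for a goodness-of-fit report (have %d)",
           minN, dist@nReference)
  rho <- dist@rhoTarget
  ks <- suppressWarnings(stats::ks.test(dist@distances,
                                        function(q) analyticNNCdf(rho, q)))
  br <- dist@breaks
  expProb <- diff(analyticNNCdf(rho, br))
  list(ksStat = unname(ks$statistic), ksP = ks$p.value, rho = rho,
       n = dist@nReference, breaks = br,
       observedCounts = dist@counts,
       expectedCounts = dist@nReference * expProb,
       method = "one-sample KS against fixed-density analytic 2D Poisson NN law (statistic is an extension over visual curve comparison)")
}

#' Fraction of overlapping clusters
#'
#' Percentage of reference clusters whose center lies within a threshold
#' distance of the nearest target cluster center (default 100 nm, the
#' criterion for clusters counted as at least partly overlapping).
#'
#' @param dist an \linkS4class{NNDistribution}.
#' @param d threshold distance, nm.
#' @return percentage in [0, 100].
#' @export
overlapFraction <- function(dist, d = 100) {
  stopifnot(is(dist, "NNDistribution"))
  if (dist@nReference < 1L) .stopf("no reference clusters")
  100 * mean(dist@distances <= d)
}

#' Per-sheet Pearson correlation of two channels
#'
#' Pearson correlation coefficient of the raw pixel intensities of two
#' channels over the analyzable mask pixels only (no intensity thresholding).
#'
#' @param image a \linkS4class{SheetImage}.
#' @param chA,chB channel names or indices.
#' @return correlation coefficient in [-1, 1].
#' @export
pearsonPerSheet <- function(image, chA = 1L, chB = 2L) {
  stopifnot(is(image, "SheetImage"))
  a <- getChannel(image, chA)[image@mask]
  b <- getChannel(image, chB)[image@mask]
  if (length(a) < 2L) .stopf("need at least 2 mask pixels")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    .stopf("zero-variance channel: Pearson correlation undefined")
  stats::cor(a, b)
}
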