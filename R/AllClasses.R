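#' @import methods
NULL

#' Dual-channel membrane-sheet image
#'
#' Container for one membrane sheet: one 2D photon-count grid per channel, a
#' shared pixel pitch (nm), and a logical mask marking the analyzable region
#' (the sheet minus its edges). Rows index y (downward), columns x
#' (rightward); the pixel at row i, column j spans a pitch x pitch cell whose
#' center is at ((j-1)*pitch, (i-1)*pitch) nm.
#'
#' @slot channels named list of numeric matrices (photon counts).
#' @slot pixelPitch pixel size in nm.
#' @slot mask logical matrix, TRUE where pixels are analyzable.
#' @slot imageId character identifier carried into all outputs.
#' @export
setClass("SheetImage",
  slots = c(channels = "list", pixelPitch = "numeric",
            mask = "matrix", imageId = "character"))

setValidity("SheetImage", function(object) {
  ch <- object@channels
  if (length(ch) < 1L) return("at least one channel required")
  if (is.null(names(ch)) || any(!nzchar(names(ch)))) return("channels must be named")
  dims <- vapply(ch, function(m) paste(dim(m), collapse = "x"), character(1))
  if (length(unique(dims)) != 1L) return("all channels must share dimensions")
  if (!all(dim(object@mask) == dim(ch[[1L]]))) return("mask dimensions must match channels")
  if (length(object@pixelPitch) != 1L || object@pixelPitch <= 0) return("pixelPitch must be a positive scalar (nm)")
  if (!any(object@mask)) return("mask must contain at least one analyzable pixel")
  TRUE
})

#' Construct a SheetImage
#'
#' @param channels named list of numeric matrices (photon counts), or a single
#'   matrix (named \code{"ch1"}).
#' @param pixelPitch pixel size in nm (default 20, the acquisition step size).
#' @param mask logical matrix of analyzable pixels; default all \code{TRUE}.
#' @param imageId identifier string.
#' @return a \linkS4class{SheetImage}.
#' @export
SheetImage <- function(channels, pixelPitch = 20, mask = NULL, imageId = "sheet") {
  if (is.matrix(channels)) channels <- list(ch1 = channels)
  if (is.null(names(channels))) names(channels) <- paste0("ch", seq_along(channels))
  if (is.null(mask)) mask <- matrix(TRUE, nrow(channels[[1L]]), ncol(channels[[1L]]))
  new("SheetImage", channels = channels, pixelPitch = pixelPitch,
      mask = mask, imageId = imageId)
}

#' Ground truth of a synthetic sheet
#'
#' Per-channel tables of true cluster centers (nm), FWHM (nm) and molecule
#' counts, plus the field extent. Only clusters inside the field are listed;
#' the generator additionally renders clusters in a guard margin so boundary
#' intensity is unbiased.
#'
#' @slot truth named list of data.frames with columns
#'   \code{x_nm, y_nm, fwhm_nm, molecules}.
#' @slot fieldNm numeric length-2, field width and height in nm.
#' @export
setClass("GroundTruth", slots = c(truth = "list", fieldNm = "numeric"))

setValidity("GroundTruth", function(object) {
  if (length(object@fieldNm) != 2L || any(object@fieldNm <= 0)) return("fieldNm must be two positive values")
  for (tab in object@truth) {
    need <- c("x_nm", "y_nm", "fwhm_nm", "molecules")
    if (!all(need %in% names(tab))) return("truth tables need x_nm, y_nm, fwhm_nm, molecules")
    if (nrow(tab)) {
      if (any(tab$molecules < 1)) return("molecule counts must be >= 1")
      if (any(tab$x_nm < 0 | tab$x_nm > object@fieldNm[1L] |
              tab$y_nm < 0 | tab$y_nm > object@fieldNm[2L]))
        return("all truth centers must lie inside the field")
    }
  }
  TRUE
})

#' Specification of a synthetic membrane sheet
#'
#' Parameters of the generative model: a homogeneous Poisson process of
#' cluster centers per channel, Gaussian clusters sized by FWHM, label counts
#' of 1 + Poisson(mu - 1) molecules, rendering through a Gaussian PSF, and
#' Poisson shot noise over a constant background. A second channel can be
#' independent, co-centered with the first, or displaced from it by a random
#' distance (offset coupling).
#'
#' @export
setClass("SyntheticSpec",
  slots = c(fieldUm = "numeric", pixelPitch = "numeric", density = "numeric",
            fwhmMean = "numeric", fwhmSd = "numeric", fwhmSample = "list",
            moleculesMean = "numeric", psfFwhm = "numeric",
            photonsPerMolecule = "numeric", background = "numeric",
            coupling = "character", offsetMean = "numeric", offsetSd = "numeric",
            minSeparation = "numeric", shotNoise = "logical",
            maxClusters = "numeric", seed = "integer"))

setValidity("SyntheticSpec", function(object) {
  if (length(object@fieldUm) != 2L || any(object@fieldUm <= 0)) return("fieldUm must be two positive extents (um)")
  if (object@pixelPitch <= 0) return("pixelPitch must be > 0")
  if (any(object@density < 0)) return("densities must be >= 0")
  if (length(object@density) > 2L) return("at most two channels are supported")
  if (any(object@fwhmMean <= 0) || any(object@fwhmSd < 0)) return("fwhmMean must be > 0 and fwhmSd >= 0")
  if (object@moleculesMean < 1) return("moleculesMean must be >= 1")
  if (object@psfFwhm <= 0) return("psfFwhm must be > 0")
  if (!object@coupling %in% c("independent", "co_centered", "offset"))
    return("coupling must be independent, co_centered or offset")
  if (object@coupling == "offset" && object@offsetMean < 0) return("offset coupling requires offsetMean >= 0")
  if (object@minSeparation < 0) return("minSeparation must be >= 0")
  if (object@background < 0 || object@photonsPerMolecule <= 0) return("background >= 0 and photonsPerMolecule > 0 required")
  TRUE
})

#' Construct a SyntheticSpec
#'
#' Defaults emulate the study conditions the analysis is built for: 20 nm
#' pixels, ~50 nm PSF FWHM, cluster FWHM around 110 +/- 35 nm, densities of a
#' few clusters per um^2, and on average 3.5 labeled molecules per cluster.
#'
#' @param fieldUm field width and height in um (scalar recycled).
#' @param pixelPitch pixel size, nm.
#' @param density per-channel cluster density, clusters/um^2 (length 1 or 2).
#' @param fwhmMean,fwhmSd per-channel cluster FWHM distribution, nm
#'   (truncated at 0; recycled across channels).
#' @param fwhmSample optional per-channel numeric vectors of empirical FWHMs
#'   (nm); when supplied these are resampled instead of the normal draw.
#' @param moleculesMean mean molecules per cluster (>= 1); counts are drawn
#'   as 1 + Poisson(mean - 1).
#' @param psfFwhm microscope PSF FWHM, nm.
#' @param photonsPerMolecule expected integrated photons contributed by one
#'   molecule.
#' @param background constant background level, photons/pixel.
#' @param coupling \code{"independent"}, \code{"co_centered"} or
#'   \code{"offset"} placement of channel 2 relative to channel 1.
#' @param offsetMean,offsetSd offset-coupling displacement distance, nm
#'   (normal, truncated at 0, uniform angle).
#' @param minSeparation optional hard-core minimum center separation, nm
#'   (0 = pure Poisson process).
#' @param shotNoise add Poisson shot noise (TRUE) or return noiseless
#'   expected counts.
#' @param maxClusters guard: error if the expected cluster count of any
#'   channel exceeds this.
#' @param seed integer root seed; placement and noise use derived substreams.
#' @return a \linkS4class{SyntheticSpec}.
#' @export
syntheticSpec <- function(fieldUm = c(20, 20), pixelPitch = 20,
                          density = c(ch1 = 4.4, ch2 = 4.4),
                          fwhmMean = 110, fwhmSd = 35, fwhmSample = list(),
                          moleculesMean = 3.5, psfFwhm = 50,
                          photonsPerMolecule = 500, background = 10,
                          coupling = "independent",
                          offsetMean = 150, offsetSd = 50,
                          minSeparation = 0, shotNoise = TRUE,
                          maxClusters = 2e5, seed = 1L) {
  if (length(fieldUm) == 1L) fieldUm <- rep(fieldUm, 2L)
  if (is.null(names(density))) names(density) <- paste0("ch", seq_along(density))
  nch <- length(density)
  fwhmMean <- rep_len(fwhmMean, nch)
  fwhmSd <- rep_len(fwhmSd, nch)
  new("SyntheticSpec", fieldUm = fieldUm, pixelPitch = pixelPitch,
      density = density, fwhmMean = fwhmMean, fwhmSd = fwhmSd,
      fwhmSample = fwhmSample, moleculesMean = moleculesMean,
      psfFwhm = psfFwhm, photonsPerMolecule = photonsPerMolecule,
      background = background, coupling = coupling,
      offsetMean = offsetMean, offsetSd = offsetSd,
      minSeparation = minSeparation, shotNoise = shotNoise,
      maxClusters = maxClusters, seed = as.integer(seed))
}

#' Annotated cluster map of one channel
#'
#' The result of blob detection on one channel (or of converting generator
#' ground truth): one row per cluster with subpixel center (nm), peak
#' intensity, optional FWHM / area / circularity, and the distance of the
#' center to the analyzable-region boundary (used for minus-sampling).
#'
#' @slot clusters data.frame, one row per cluster.
#' @slot channel channel label.
#' @slot areaUm2 analyzed area, um^2.
#' @slot imageId source image identifier.
#' @slot fieldNm image extent, nm (width, height).
#' @slot source \code{"detected"} or \code{"truth"}.
#' @export
setClass("ClusterMap",
  slots = c(clusters = "data.frame", channel = "character", areaUm2 = "numeric",
            imageId = "character", fieldNm = "numeric", source = "character"))

setValidity("ClusterMap", function(object) {
  if (object@areaUm2 <= 0) return("analyzed area must be > 0")
  need <- c("x_nm", "y_nm", "edge_nm")
  if (!all(need %in% names(object@clusters))) return("clusters needs x_nm, y_nm, edge_nm")
  if (!object@source %in% c("detected", "truth")) return("source must be 'detected' or 'truth'")
  cc <- object@clusters$circularity
  if (!is.null(cc) && any(!is.na(cc) & (cc < 0 | cc > 1))) return("circularity must lie in [0, 1]")
  TRUE
})

#' Nearest-neighbor distance distribution
#'
#' Center-to-center nearest-neighbor distances from each reference cluster
#' (at least \code{borderMargin} from the mask boundary) to the closest
#' target-channel cluster, with a fixed-bin histogram and the independently
#' determined target density used by the analytic random null.
#'
#' @slot distances numeric, nm (one per retained reference cluster).
#' @slot breaks,counts histogram on fixed bins (nm).
#' @slot refChannel,targetChannel channel labels.
#' @slot rhoTarget target-channel density, clusters/um^2.
#' @slot nReference number of reference clusters retained.
#' @slot source \code{"detected"} or \code{"truth"} provenance of the maps.
#' @export
setClass("NNDistribution",
  slots = c(distances = "numeric", breaks = "numeric", counts = "integer",
            refChannel = "character", targetChannel = "character",
            rhoTarget = "numeric", nReference = "integer", source = "character"))

setValidity("NNDistribution", function(object) {
  if (any(object@distances < 0)) return("distances must be >= 0")
  if (object@rhoTarget < 0) return("rhoTarget must be >= 0")
  if (sum(object@counts) > object@nReference) return("histogram counts cannot exceed n_reference")
  TRUE
})

#' Monte-Carlo mock-image ensemble specification
#'
#' Wraps a \linkS4class{SyntheticSpec} with independent (completely random,
#' uncorrelated) placement plus the number of mock images to generate. Built
#' from observed cluster maps so mock densities and size distributions match
#' the data.
#'
#' @slot spec the generating \linkS4class{SyntheticSpec} (coupling
#'   independent).
#' @slot nImages number of mock images.
#' @export
setClass("NullEnsembleSpec", slots = c(spec = "SyntheticSpec", nImages = "integer"))

setValidity("NullEnsembleSpec", function(object) {
  if (object@nImages < 1L) return("nImages must be >= 1")
  if (object@spec@coupling != "independent") return("null ensembles must use independent coupling")
  TRUE
})

#' Observed-versus-null comparison
#'
#' Quantitative comparison of an observed nearest-neighbor distribution with
#' the pooled distribution from a mock-image null ensemble: excess overlap
#' below the threshold distance, a two-sample Kolmogorov-Smirnov statistic
#' with its asymptotic p-value, and an ensemble-based empirical p-value
#' (lower-bounded by 1/(n_mock + 1)).
#'
#' @export
setClass("NullComparison",
  slots = c(observed = "NNDistribution", null = "NNDistribution",
            thresholdNm = "numeric", overlapObs = "numeric",
            overlapNull = "numeric", overlapNullSd = "numeric",
            excessPct = "numeric", ksStat = "numeric", ksP = "numeric",
            pEmpirical = "numeric", nMock = "integer"))

#' Densitometry standard curve
#'
#' Ordinary least-squares line through (recombinant protein mass, signal)
#' points, used to invert a lysate band signal to protein mass.
#'
#' @slot points data.frame with columns \code{mass_pg}, \code{signal}.
#' @slot slope,intercept,r2,slopeSe fit summaries.
#' @export
setClass("StandardCurve",
  slots = c(points = "data.frame", slope = "numeric", intercept = "numeric",
            r2 = "numeric", slopeSe = "numeric"))

setValidity("StandardCurve", function(object) {
  if (nrow(object@points) < 3L) return("a standard curve needs >= 3 points")
  if (object@slope <= 0) return("a valid standard curve has positive slope")
  TRUE
})

#' Molecules-per-cluster stoichiometry result
#'
#' The full estimation chain: copies per cell (quantitative immunoblot),
#' surface fraction (isotype-corrected flow cytometry), mean cell surface
#' area (sphere model), cluster density (imaging), and the derived surface
#' copies, clusters per cell and molecules per cluster.
#'
#' @export
setClass("StoichiometryResult",
  slots = c(moleculesPerCell = "numeric", surfaceFractionPct = "numeric",
            surfaceAreaUm2 = "numeric", clusterDensity = "numeric",
            surfaceMolecules = "numeric", clustersPerCell = "numeric",
            moleculesPerCluster = "numeric", notes = "character"))

setValidity("StoichiometryResult", function(object) {
  if (object@moleculesPerCell < 0) return("moleculesPerCell must be >= 0")
  ## chain identity must hold exactly
  lhs <- object@moleculesPerCluster * object@clustersPerCell
  rhs <- object@moleculesPerCell * object@surfaceFractionPct / 100
  if (is.finite(lhs) && abs(lhs - rhs) > 1e-6 * max(1, abs(rhs)))
    return("chain identity violated: molecules/cluster x clusters/cell != surface molecules")
  TRUE
})
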