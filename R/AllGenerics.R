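#' Accessors
#'
#' Small accessor generics for the core classes: channel names, a single
#' channel matrix, pixel pitch, the analyzable mask and area, cluster tables
#' and densities, and nearest-neighbor distances.
#'
#' @param x,object an object of the documented classes.
#' @param channel channel name or index.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))
#' @rdname accessors
#' @export
setMethod("channelNames", "SheetImage", function(x) names(x@channels))
#' @rdname accessors
#' @export
setMethod("channelNames", "GroundTruth", function(x) names(x@truth))

#' @rdname accessors
#' @export
setGeneric("getChannel", function(x, channel) standardGeneric("getChannel"))
#' @rdname accessors
#' @export
setMethod("getChannel", "SheetImage", function(x, channel) {
  if (is.numeric(channel)) channel <- names(x@channels)[channel]
  if (is.na(channel) || !channel %in% names(x@channels))
    .stopf("channel '%s' not present (channels: %s)", channel,
           paste(names(x@channels), collapse = ", "))
  x@channels[[channel]]
})

#' @rdname accessors
#' @export
setGeneric("pixelPitch", function(x) standardGeneric("pixelPitch"))
#' @rdname accessors
#' @export
setMethod("pixelPitch", "SheetImage", function(x) x@pixelPitch)

#' @rdname accessors
#' @export
setGeneric("sheetMask", function(x) standardGeneric("sheetMask"))
#' @rdname accessors
#' @export
setMethod("sheetMask", "SheetImage", function(x) x@mask)

#' @rdname accessors
#' @export
setGeneric("analyzedArea", function(x) standardGeneric("analyzedArea"))
#' @rdname accessors
#' @export
setMethod("analyzedArea", "SheetImage", function(x)
  sum(x@mask) * x@pixelPitch^2 * .NM2_TO_UM2)
#' @rdname accessors
#' @export
setMethod("analyzedArea", "ClusterMap", function(x) x@areaUm2)

#' @rdname accessors
#' @export
setGeneric("clusters", function(x) standardGeneric("clusters"))
#' @rdname accessors
#' @export
setMethod("clusters", "ClusterMap", function(x) x@clusters)

#' Cluster density of a map
#'
#' Number of clusters divided by the analyzed membrane area, clusters/um^2.
#'
#' @param x a \linkS4class{ClusterMap}.
#' @return density in clusters per um^2.
#' @export
setGeneric("clusterDensity", function(x) standardGeneric("clusterDensity"))
#' @rdname clusterDensity
#' @export
setMethod("clusterDensity", "ClusterMap", function(x) {
  if (x@areaUm2 <= 0) .stopf("analyzed area must be positive")
  nrow(x@clusters) / x@areaUm2
})

#' @rdname accessors
#' @export
setGeneric("nnDistancesOf", function(x) standardGeneric("nnDistancesOf"))
#' @rdname accessors
#' @export
setMethod("nnDistancesOf", "NNDistribution", function(x) x@distances)

#' @rdname accessors
#' @export
setGeneric("truthTable", function(x, channel) standardGeneric("truthTable"))
#' @rdname accessors
#' @export
setMethod("truthTable", "GroundTruth", function(x, channel) {
  if (is.numeric(channel)) channel <- names(x@truth)[channel]
  if (is.na(channel) || !channel %in% names(x@truth))
    .stopf("channel '%s' not present in ground truth", channel)
  x@truth[[channel]]
})

#' @rdname accessors
#' @export
setGeneric("fieldArea", function(x) standardGeneric("fieldArea"))
#' @rdname accessors
#' @export
setMethod("fieldArea", "GroundTruth", function(x) prod(x@fieldNm) * .NM2_TO_UM2)

setMethod("show", "SheetImage", function(object) {
  d <- dim(object@channels[[1L]])
  cat("SheetImage '", object@imageId, "': ", length(object@channels),
      " channel(s) [", paste(names(object@channels), collapse = ", "), "], ",
      d[2L], " x ", d[1L], " px @ ", object@pixelPitch, " nm, analyzed area ",
      signif(analyzedArea(object), 4), " um^2\n", sep = "")
})

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth over ", signif(fieldArea(object), 4), " um^2:\n", sep = "")
  for (ch in names(object@truth))
    cat("  ", ch, ": ", nrow(object@truth[[ch]]), " clusters\n", sep = "")
})

setMethod("show", "SyntheticSpec", function(object) {
  cat("SyntheticSpec: ", paste(object@fieldUm, collapse = " x "), " um field, ",
      length(object@density), " channel(s) at density ",
      paste(signif(object@density, 3), collapse = "/"), " um^-2, coupling=",
      object@coupling, ", seed=", object@seed, "\n", sep = "")
})

setMethod("show", "ClusterMap", function(object) {
  cat("ClusterMap [", object@source, "] '", object@imageId, "' channel ",
      object@channel, ": ", nrow(object@clusters), " clusters on ",
      signif(object@areaUm2, 4), " um^2 (density ",
      signif(clusterDensity(object), 3), " um^-2)\n", sep = "")
})

setMethod("show", "NNDistribution", function(object) {
  cat("NNDistribution ", object@refChannel, " -> ", object@targetChannel,
      " [", object@source, "]: n_ref=", object@nReference,
      ", rho_target=", signif(object@rhoTarget, 3), " um^-2, median ",
      signif(stats::median(object@distances), 4), " nm\n", sep = "")
})

setMethod("show", "NullComparison", function(object) {
  cat("NullComparison vs ", object@nMock, " mock image(s):\n",
      "  overlap <= ", object@thresholdNm, " nm: observed ",
      signif(object@overlapObs, 4), "% vs null ",
      signif(object@overlapNull, 4), "% (sd ",
      signif(object@overlapNullSd, 3), ") -> excess ",
      signif(object@excessPct, 4), " points\n",
      "  KS D = ", signif(object@ksStat, 4), ", p = ",
      format.pval(object@ksP, digits = 3), " (ensemble p = ",
      signif(object@pEmpirical, 3), ")\n", sep = "")
})

setMethod("show", "StandardCurve", function(object) {
  cat("StandardCurve: signal = ", signif(object@slope, 5), " * mass_pg + ",
      signif(object@intercept, 5), " (R^2 = ", signif(object@r2, 4), ", ",
      nrow(object@points), " points)\n", sep = "")
})

setMethod("show", "StoichiometryResult", function(object) {
  cat("StoichiometryResult:\n",
      "  molecules/cell     ", format(round(object@moleculesPerCell), big.mark = ","), "\n",
      "  surface fraction   ", signif(object@surfaceFractionPct, 4), " %\n",
      "  surface area       ", format(round(object@surfaceAreaUm2), big.mark = ","), " um^2\n",
      "  cluster density    ", signif(object@clusterDensity, 3), " um^-2\n",
      "  surface molecules  ", format(round(object@surfaceMolecules), big.mark = ","), "\n",
      "  clusters/cell      ", format(round(object@clustersPerCell), big.mark = ","), "\n",
      "  molecules/cluster  ", signif(object@moleculesPerCluster, 3), "\n", sep = "")
  if (length(object@notes) && nzchar(object@notes[1L]))
    cat("  note: ", paste(object@notes, collapse = "; "), "\n", sep = "")
})
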