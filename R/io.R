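## Raster and table I/O: 16-bit multi-page TIFF for images (one page per
## channel), CSV for cluster tables and distances, JSON sidecars for
## provenance.

#' Read a membrane-sheet image from TIFF
#'
#' Reads a multi-page (or single-page) grayscale TIFF as a
#' \linkS4class{SheetImage}, one channel per page. The mask defaults to
#' all-analyzable and can be replaced by a mask TIFF (non-zero = analyzable).
#'
#' @param path TIFF file path.
#' @param pixelPitch pixel size, nm.
#' @param channels optional channel names (default ch1, ch2, ...).
#' @param maskPath optional mask TIFF path.
#' @param imageId identifier; defaults to the file name.
#' @return a \linkS4class{SheetImage}.
#' @export
readSheetTiff <- function(path, pixelPitch = 20, channels = NULL,
                          maskPath = NULL, imageId = NULL) {
  if (!file.exists(path)) .stopf("cannot read image: no such file '%s'", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e) .stopf("failed to read TIFF '%s': %s", path, conditionMessage(e)))
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1L]
    matrix(as.numeric(p), nrow(p), ncol(p))
  })
  dims <- vapply(pages, function(p) paste(dim(p), collapse = "x"), character(1))
  if (length(unique(dims)) != 1L)
    .stopf("channel pages of '%s' have mismatched dimensions", path)
  if (is.null(channels)) channels <- paste0("ch", seq_along(pages))
  names(pages) <- channels
  mask <- NULL
  if (!is.null(maskPath)) {
    m <- tiff::readTIFF(maskPath, as.is = TRUE)
    if (length(dim(m)) == 3L) m <- m[, , 1L]
    mask <- m > 0
  }
  if (is.null(imageId)) imageId <- sub("\\.[^.]*$", "", basename(path))
  SheetImage(pages, pixelPitch = pixelPitch, mask = mask, imageId = imageId)
}

#' Write a synthetic sheet to disk
#'
#' Writes the image as a 16-bit multi-page TIFF (one page per channel,
#' counts clipped at 65535), the ground truth as a CSV
#' (channel, x_nm, y_nm, fwhm_nm, molecules), and a JSON sidecar echoing the
#' full generating specification and seed.
#'
#' @param image a \linkS4class{SheetImage}.
#' @param dir output directory (created if needed).
#' @param prefix file name prefix.
#' @param truth optional \linkS4class{GroundTruth}.
#' @param spec optional \linkS4class{SyntheticSpec} echoed to the sidecar.
#' @return named character vector of written paths, invisibly.
#' @export
writeSheet <- function(image, dir, prefix = image@imageId, truth = NULL,
                       spec = NULL) {
  stopifnot(is(image, "SheetImage"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tifPath <- file.path(dir, paste0(prefix, ".tif"))
  pages <- lapply(image@channels, function(m) pmin(pmax(round(m), 0), 65535) / 65535)
  tiff::writeTIFF(pages, tifPath, bits.per.sample = 16L)
  paths <- c(image = tifPath)
  if (!is.null(truth)) {
    tt <- do.call(rbind, lapply(names(truth@truth), function(ch) {
      tab <- truth@truth[[ch]]
      if (nrow(tab) == 0L) return(NULL)
      data.frame(channel = ch, x_nm = tab$x_nm, y_nm = tab$y_nm,
                 fwhm_nm = tab$fwhm_nm, molecules = tab$molecules)
    }))
    if (is.null(tt))
      tt <- data.frame(channel = character(0), x_nm = numeric(0),
                       y_nm = numeric(0), fwhm_nm = numeric(0),
                       molecules = integer(0))
    csvPath <- file.path(dir, paste0(prefix, "_truth.csv"))
    utils::write.csv(tt, csvPath, row.names = FALSE)
    paths <- c(paths, truth = csvPath)
  }
  if (!is.null(spec)) {
    sj <- list(fieldUm = spec@fieldUm, pixelPitch = spec@pixelPitch,
               density = as.list(spec@density), fwhmMean = spec@fwhmMean,
               fwhmSd = spec@fwhmSd, moleculesMean = spec@moleculesMean,
               psfFwhm = spec@psfFwhm,
               photonsPerMolecule = spec@photonsPerMolecule,
               background = spec@background, coupling = spec@coupling,
               offsetMean = spec@offsetMean, offsetSd = spec@offsetSd,
               minSeparation = spec@minSeparation, shotNoise = spec@shotNoise,
               seed = spec@seed)
    jsonPath <- file.path(dir, paste0(prefix, "_spec.json"))
    jsonlite::write_json(sj, jsonPath, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, spec = jsonPath)
  }
  invisible(paths)
}

#' Write a per-cluster table to CSV
#'
#' One row per cluster with image id, channel, subpixel center, FWHM, mask
#' area, circularity and peak intensity, plus provenance columns.
#'
#' @param maps list of \linkS4class{ClusterMap}s (or a single map).
#' @param path output CSV path.
#' @param configHash,seed provenance stamps carried on every row.
#' @return the path, invisibly.
#' @export
writeClusterCsv <- function(maps, path, configHash = "", seed = NA_integer_) {
  if (is(maps, "ClusterMap")) maps <- list(maps)
  rows <- do.call(rbind, lapply(maps, function(m) {
    tab <- m@clusters
    data.frame(image_id = m@imageId, channel = m@channel,
               x_nm = tab$x_nm, y_nm = tab$y_nm,
               fwhm_nm = if (is.null(tab$fwhm_nm)) NA_real_ else tab$fwhm_nm,
               area_um2 = if (is.null(tab$area_um2)) NA_real_ else tab$area_um2,
               circularity = if (is.null(tab$circularity)) NA_real_ else tab$circularity,
               peak = if (is.null(tab$peak)) NA_real_ else tab$peak,
               config_hash = configHash, seed = seed)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
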