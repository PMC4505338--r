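## Synthetic membrane-sheet generator: homogeneous Poisson cluster centers,
## Gaussian clusters sized by FWHM, Gaussian PSF, Poisson shot noise. Channel
## 2 is independent, co-centered or offset-coupled relative to channel 1.

## Draw cluster centers in a field padded by `pad` nm on every side so that
## clusters just outside the crop still contribute boundary intensity.
.placeChannel <- function(rho, fieldNm, pad, minSep, maxClusters) {
  wid <- fieldNm[1L] + 2 * pad
  hei <- fieldNm[2L] + 2 * pad
  lambda <- rho * wid * hei * .NM2_TO_UM2
  if (lambda > maxClusters)
    .stopf("expected cluster count %.0f exceeds the cap of %.0f; reduce density or field size",
           lambda, maxClusters)
  n <- stats::rpois(1L, lambda)
  if (n == 0L) return(cbind(x_nm = numeric(0), y_nm = numeric(0)))
  if (minSep <= 0) {
    return(cbind(x_nm = stats::runif(n, -pad, fieldNm[1L] + pad),
                 y_nm = stats::runif(n, -pad, fieldNm[2L] + pad)))
  }
  ## hard-core thinning: sequential proposals, reject closer than minSep
  xs <- numeric(n); ys <- numeric(n); kept <- 0L
  tries <- 0L
  while (kept < n && tries < 50L * n) {
    tries <- tries + 1L
    px <- stats::runif(1L, -pad, fieldNm[1L] + pad)
    py <- stats::runif(1L, -pad, fieldNm[2L] + pad)
    if (kept == 0L || min((xs[seq_len(kept)] - px)^2 + (ys[seq_len(kept)] - py)^2) >= minSep^2) {
      kept <- kept + 1L
      xs[kept] <- px; ys[kept] <- py
    }
  }
  cbind(x_nm = xs[seq_len(kept)], y_nm = ys[seq_len(kept)])
}

.drawFwhm <- function(n, mean, sd, sample) {
  if (length(sample))
    return(sample[sample.int(length(sample), n, replace = TRUE)])
  if (n == 0L) return(numeric(0))
  f <- stats::rnorm(n, mean, sd)
  while (any(f <= 0)) f[f <= 0] <- stats::rnorm(sum(f <= 0), mean, sd)
  f
}

.drawMolecules <- function(n, mu) 1L + stats::rpois(n, mu - 1)

## Full placement, including guard-margin clusters used only for rendering.
.simulatePlacement <- function(spec) {
  fieldNm <- spec@fieldUm * 1000
  pad <- 3 * max(spec@fwhmMean, spec@psfFwhm)
  nch <- length(spec@density)
  chn <- names(spec@density)
  set.seed(.substream(spec@seed, 1L))
  all <- vector("list", nch); names(all) <- chn
  parent <- NULL

  fs <- function(i) if (length(spec@fwhmSample) >= i) spec@fwhmSample[[i]] else numeric(0)

  xy1 <- .placeChannel(spec@density[1L], fieldNm, pad, spec@minSeparation, spec@maxClusters)
  all[[1L]] <- data.frame(x_nm = xy1[, 1L], y_nm = xy1[, 2L],
                          fwhm_nm = .drawFwhm(nrow(xy1), spec@fwhmMean[1L], spec@fwhmSd[1L], fs(1L)),
                          molecules = .drawMolecules(nrow(xy1), spec@moleculesMean))

  if (nch == 2L) {
    set.seed(.substream(spec@seed, 2L))
    n1 <- nrow(all[[1L]])
    if (spec@coupling == "independent") {
      xy2 <- .placeChannel(spec@density[2L], fieldNm, pad, spec@minSeparation, spec@maxClusters)
    } else if (spec@coupling == "co_centered") {
      xy2 <- as.matrix(all[[1L]][, c("x_nm", "y_nm")])
      parent <- seq_len(n1)
    } else {  # offset: displaced by |N(mean, sd)| at uniform angle
      d <- stats::rnorm(n1, spec@offsetMean, spec@offsetSd)
      while (any(d < 0)) d[d < 0] <- stats::rnorm(sum(d < 0), spec@offsetMean, spec@offsetSd)
      th <- stats::runif(n1, 0, 2 * pi)
      xy2 <- cbind(all[[1L]]$x_nm + d * cos(th), all[[1L]]$y_nm + d * sin(th))
      parent <- seq_len(n1)
    }
    all[[2L]] <- data.frame(x_nm = xy2[, 1L], y_nm = xy2[, 2L],
                            fwhm_nm = .drawFwhm(nrow(xy2), spec@fwhmMean[nch], spec@fwhmSd[nch], fs(2L)),
                            molecules = .drawMolecules(nrow(xy2), spec@moleculesMean))
    if (!is.null(parent)) all[[2L]]$parent <- parent
  }

  inField <- lapply(all, function(tab)
    tab[tab$x_nm >= 0 & tab$x_nm <= fieldNm[1L] &
        tab$y_nm >= 0 & tab$y_nm <= fieldNm[2L], , drop = FALSE])
  inField <- lapply(inField, function(tab) { rownames(tab) <- NULL; tab })
  list(all = all,
       truth = new("GroundTruth", truth = inField, fieldNm = fieldNm),
       fieldNm = fieldNm)
}

## Render one channel: each cluster is an isotropic Gaussian of its FWHM
## convolved with the Gaussian PSF. Because Gaussian (x) Gaussian is again
## Gaussian with sigma_eff = sqrt(sigma_cluster^2 + sigma_psf^2), the
## convolved spot is rendered directly (exact, no convolution pass). Total
## integrated signal is molecules x photonsPerMolecule.
.renderChannel <- function(tab, nx, ny, pitch, psfSigma, photonsPer) {
  img <- matrix(0, ny, nx)
  if (nrow(tab) == 0L) return(img)
  for (k in seq_len(nrow(tab))) {
    s <- sqrt((tab$fwhm_nm[k] * .FWHM_TO_SIGMA)^2 + psfSigma^2)
    xc <- tab$x_nm[k]; yc <- tab$y_nm[k]
    r <- 4 * s
    j0 <- max(1L, as.integer(floor((xc - r) / pitch)) + 1L)
    j1 <- min(nx, as.integer(ceiling((xc + r) / pitch)) + 1L)
    i0 <- max(1L, as.integer(floor((yc - r) / pitch)) + 1L)
    i1 <- min(ny, as.integer(ceiling((yc + r) / pitch)) + 1L)
    if (j0 > j1 || i0 > i1) next
    gx <- exp(-((seq(j0, j1) - 1) * pitch - xc)^2 / (2 * s^2))
    gy <- exp(-((seq(i0, i1) - 1) * pitch - yc)^2 / (2 * s^2))
    amp <- tab$molecules[k] * photonsPer * pitch^2 / (2 * pi * s^2)
    img[i0:i1, j0:j1] <- img[i0:i1, j0:j1] + amp * (gy %o% gx)
  }
  img
}

#' Simulate ground-truth cluster placements only
#'
#' Runs the placement model of \code{\link{generateSheet}} without rendering
#' an image: useful for large point-pattern simulations where only center
#' coordinates matter.
#'
#' @param spec a \linkS4class{SyntheticSpec}.
#' @return a \linkS4class{GroundTruth}.
#' @export
simulateTruth <- function(spec) .simulatePlacement(spec)$truth

#' Generate a synthetic membrane sheet
#'
#' Draws cluster centers as a homogeneous Poisson process per channel
#' (channel 2 optionally co-centered with, or offset from, channel 1),
#' renders every cluster as an isotropic Gaussian of its FWHM scaled by
#' molecule count, convolves with the Gaussian PSF, and adds Poisson shot
#' noise over a constant background. Centers are drawn in a guard margin of
#' three cluster FWHM around the field and cropped, so boundary intensity is
#' unbiased; the returned ground truth lists only in-field clusters.
#'
#' @param spec a \linkS4class{SyntheticSpec}.
#' @return list with elements \code{image} (\linkS4class{SheetImage}) and
#'   \code{truth} (\linkS4class{GroundTruth}).
#' @examples
#' sheet <- generateSheet(syntheticSpec(fieldUm = 5, density = c(ch1 = 2), seed = 7))
#' sheet$image
#' @export
generateSheet <- function(spec) {
  stopifnot(is(spec, "SyntheticSpec"))
  validObject(spec)
  pl <- .simulatePlacement(spec)
  pitch <- spec@pixelPitch
  nx <- as.integer(round(pl$fieldNm[1L] / pitch))
  ny <- as.integer(round(pl$fieldNm[2L] / pitch))
  if (nx < 1L || ny < 1L) .stopf("field size smaller than one pixel")
  psfSigma <- spec@psfFwhm * .FWHM_TO_SIGMA
  channels <- vector("list", length(pl$all))
  names(channels) <- names(pl$all)
  for (i in seq_along(pl$all)) {
    lam <- .renderChannel(pl$all[[i]], nx, ny, pitch, psfSigma,
                          spec@photonsPerMolecule) + spec@background
    if (spec@shotNoise) {
      set.seed(.substream(spec@seed, 10L + i))
      channels[[i]] <- matrix(stats::rpois(length(lam), lam), ny, nx)
    } else {
      channels[[i]] <- lam
    }
  }
  img <- SheetImage(channels, pixelPitch = pitch,
                    imageId = sprintf("synthetic-seed%d", spec@seed))
  list(image = img, truth = pl$truth)
}

#' Nearest-neighbor distances between ground-truth centers
#'
#' For every true center of a channel, the Euclidean distance to the nearest
#' other true center of the same channel. This is the noise-free oracle for
#' the image-based nearest-neighbor analysis.
#'
#' @param truth a \linkS4class{GroundTruth}.
#' @param channel channel name or index.
#' @return numeric vector of distances, nm. With fewer than two clusters an
#'   empty vector is returned with a warning.
#' @export
truthNNDistances <- function(truth, channel = 1L) {
  tab <- truthTable(truth, channel)
  if (nrow(tab) < 2L) {
    warning("fewer than 2 clusters in channel; returning empty distances")
    return(numeric(0))
  }
  xy <- as.matrix(tab[, c("x_nm", "y_nm")])
  .nn1(xy, xy, excludeSelf = TRUE)
}

#' Convert ground truth to a ClusterMap
#'
#' Builds a \linkS4class{ClusterMap} directly from generator ground truth
#' (bypassing detection). The boundary distance of each center is computed
#' against the rectangular field. Maps built this way are tagged
#' \code{source = "truth"} and are refused by \code{\link{compareToNull}}
#' unless explicitly allowed.
#'
#' @param truth a \linkS4class{GroundTruth}.
#' @param channel channel name or index.
#' @param imageId identifier carried into outputs.
#' @return a \linkS4class{ClusterMap}.
#' @export
truthToClusterMap <- function(truth, channel = 1L, imageId = "truth") {
  tab <- truthTable(truth, channel)
  if (is.numeric(channel)) channel <- channelNames(truth)[channel]
  w <- truth@fieldNm[1L]; h <- truth@fieldNm[2L]
  n <- nrow(tab)
  df <- data.frame(x_nm = tab$x_nm, y_nm = tab$y_nm,
                   peak = rep(NA_real_, n), fwhm_nm = tab$fwhm_nm,
                   area_um2 = rep(NA_real_, n), circularity = rep(NA_real_, n),
                   edge_nm = pmin(tab$x_nm, tab$y_nm, w - tab$x_nm, h - tab$y_nm))
  new("ClusterMap", clusters = df, channel = channel,
      areaUm2 = prod(truth@fieldNm) * .NM2_TO_UM2, imageId = imageId,
      fieldNm = truth@fieldNm, source = "truth")
}
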