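## Cluster detection: background-relative intensity threshold, 8-connected
## blob labeling, intensity-weighted centroids, FWHM sizing from orthogonal
## intensity profiles, and half-max mask area/circularity.

## Robust background statistics from the analyzable pixels: median, plus a
## MAD-type scale computed from the pixels at or below the median so bright
## clusters cannot inflate it.
.backgroundStats <- function(values) {
  med <- stats::median(values)
  lower <- values[values <= med]
  sigma <- 1.4826 * stats::median(med - lower)
  list(median = med, sigma = sigma)
}

## Threshold + label + size-filter shared by annotateClusters/segmentMasks.
.detectBlobs <- function(image, channel, offsetK, minPixels) {
  img <- getChannel(image, channel)
  mask <- image@mask
  bg <- .backgroundStats(img[mask])
  thr <- bg$median + offsetK * bg$sigma
  vals <- img[mask]
  if (max(vals) == min(vals))
    .stopf("degenerate threshold: channel '%s' is flat within the mask", channel)
  bw <- (img > thr) & mask
  if (all(bw[mask]))
    .stopf("degenerate threshold: every analyzable pixel is above threshold in channel '%s'", channel)
  lab <- .label8(bw)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= minPixels)
  list(img = img, mask = mask, bg = bg, threshold = thr, lab = lab, keep = keep)
}

#' Exclude sheet edges from analysis
#'
#' Erodes the analyzable mask by a margin: a pixel survives only if its
#' Euclidean distance to the nearest non-analyzable pixel (or image border)
#' exceeds the margin. The analyzed area is recomputed from the surviving
#' mask.
#'
#' @param image a \linkS4class{SheetImage}.
#' @param margin erosion margin, nm (>= 0; 0 leaves the mask unchanged).
#' @return a \linkS4class{SheetImage} with the eroded mask.
#' @export
excludeEdges <- function(image, margin) {
  stopifnot(is(image, "SheetImage"), margin >= 0)
  if (margin == 0) return(image)
  dist <- .maskDistanceNm(image@mask, image@pixelPitch)
  newMask <- image@mask & (dist > margin)
  if (!any(newMask))
    .stopf("excluding a %.0f nm margin empties the analyzable mask", margin)
  image@mask <- newMask
  image
}

#' Annotate clusters by threshold and blob detection
#'
#' Applies a background-relative intensity threshold (background median +
#' \code{offsetK} robust SDs, computed from analyzable pixels), groups
#' above-threshold pixels into 8-connected components, discards components
#' below a minimum pixel count, and returns one cluster per surviving blob
#' with its intensity-weighted (background-subtracted) subpixel centroid.
#' Overlapping blobs merge into a single detection; no watershed splitting is
#' attempted.
#'
#' @param image a \linkS4class{SheetImage}.
#' @param channel channel name or index.
#' @param offsetK threshold offset in robust background SDs (default 3).
#' @param minPixels minimum blob size in pixels (default 4).
#' @return a \linkS4class{ClusterMap}. The cluster table carries the peak
#'   pixel coordinates (internal columns \code{peak_row}, \code{peak_col})
#'   used by \code{\link{measureFWHM}}, and \code{edge_nm}, the distance of
#'   each centroid to the mask boundary.
#' @export
annotateClusters <- function(image, channel, offsetK = 3, minPixels = 4L) {
  stopifnot(is(image, "SheetImage"))
  det <- .detectBlobs(image, channel, offsetK, minPixels)
  if (is.numeric(channel)) channel <- channelNames(image)[channel]
  pitch <- image@pixelPitch
  edgeDist <- .maskDistanceNm(image@mask, pitch)
  n <- length(det$keep)
  out <- data.frame(x_nm = numeric(n), y_nm = numeric(n), peak = numeric(n),
                    fwhm_nm = rep(NA_real_, n), area_um2 = rep(NA_real_, n),
                    circularity = rep(NA_real_, n), edge_nm = numeric(n),
                    n_pixels = integer(n), peak_row = integer(n),
                    peak_col = integer(n))
  for (b in seq_len(n)) {
    px <- which(det$lab == det$keep[b], arr.ind = TRUE)
    vals <- det$img[px]
    w <- pmax(vals - det$bg$median, 0)
    if (sum(w) <= 0) w <- rep(1, length(vals))
    cx <- sum((px[, 2L] - 1) * w) / sum(w) * pitch
    cy <- sum((px[, 1L] - 1) * w) / sum(w) * pitch
    pk <- which.max(vals)
    ci <- pmin(pmax(as.integer(round(cy / pitch)) + 1L, 1L), nrow(det$img))
    cj <- pmin(pmax(as.integer(round(cx / pitch)) + 1L, 1L), ncol(det$img))
    out[b, ] <- list(cx, cy, vals[pk], NA_real_, NA_real_, NA_real_,
                     edgeDist[ci, cj], nrow(px), px[pk, 1L], px[pk, 2L])
  }
  fieldNm <- c(ncol(det$img), nrow(det$img)) * pitch
  new("ClusterMap", clusters = out, channel = channel,
      areaUm2 = analyzedArea(image), imageId = image@imageId,
      fieldNm = fieldNm, source = "detected")
}

## Half-max crossings of a 1D profile around a peak index, by linear
## interpolation after background subtraction. Returns width in index units
## or NA when the profile never falls below half max (censored).
.profileWidth <- function(prof, peakIdx, half) {
  n <- length(prof)
  right <- NA_real_
  for (j in seq(peakIdx + 1L, length.out = max(0L, n - peakIdx))) {
    if (is.na(prof[j])) break
    if (prof[j] < half) {
      ## crossing between j-1 and j, in 0-based index units
      right <- (j - 2) + (prof[j - 1L] - half) / (prof[j - 1L] - prof[j])
      break
    }
  }
  left <- NA_real_
  for (j in seq(peakIdx - 1L, by = -1L, length.out = max(0L, peakIdx - 1L))) {
    if (is.na(prof[j])) break
    if (prof[j] < half) {
      ## crossing between j and j+1, in 0-based index units
      left <- (j - 1) + (half - prof[j]) / (prof[j + 1L] - prof[j])
      break
    }
  }
  if (is.na(left) || is.na(right)) return(NA_real_)
  right - left
}

#' Measure cluster FWHM from intensity profiles
#'
#' For each cluster, two orthogonal (axis-aligned) intensity profiles are
#' extracted through the cluster's peak pixel; on each, the half-maximum
#' crossings of the background-subtracted profile are located by linear
#' interpolation, and the FWHM is the mean of the two widths. The peak
#' amplitude defining the half level is estimated from the 3x3 neighborhood
#' mean around the peak pixel with an analytic Gaussian curvature
#' correction (refined over the measured width), not from the raw maximum
#' pixel: the maximum of many noisy pixels is upward-biased, which would
#' systematically shrink the measured width of dim, wide clusters. The
#' measured size of a Gaussian cluster of FWHM f imaged through a Gaussian
#' PSF of FWHM p is sqrt(f^2 + p^2).
#'
#' @param image the \linkS4class{SheetImage} the map was detected on.
#' @param map a detected \linkS4class{ClusterMap} (or any map; peak pixels
#'   are located by hill-climbing from the center when absent).
#' @param strict if TRUE, a profile that never falls below half maximum
#'   inside the image (a censored size) is an error; otherwise it yields NA.
#' @return numeric vector of FWHM values in nm, one per cluster.
#' @export
measureFWHM <- function(image, map, strict = FALSE) {
  stopifnot(is(image, "SheetImage"), is(map, "ClusterMap"))
  img <- getChannel(image, map@channel)
  pitch <- image@pixelPitch
  bg <- .backgroundStats(img[image@mask])$median
  tab <- map@clusters
  out <- rep(NA_real_, nrow(tab))
  for (k in seq_len(nrow(tab))) {
    if (!is.null(tab$peak_row) && !is.na(tab$peak_row[k])) {
      pr <- tab$peak_row[k]; pc <- tab$peak_col[k]
    } else {
      ## hill-climb from the pixel nearest the center to the local maximum
      pr <- pmin(pmax(as.integer(round(tab$y_nm[k] / pitch)) + 1L, 1L), nrow(img))
      pc <- pmin(pmax(as.integer(round(tab$x_nm[k] / pitch)) + 1L, 1L), ncol(img))
      for (step in 1:100) {
        ri <- max(1L, pr - 1L):min(nrow(img), pr + 1L)
        cj <- max(1L, pc - 1L):min(ncol(img), pc + 1L)
        nb <- img[ri, cj, drop = FALSE]
        m <- which(nb == max(nb), arr.ind = TRUE)[1L, ]
        nr <- ri[m[1L]]; nc <- cj[m[2L]]
        if (nr == pr && nc == pc) break
        pr <- nr; pc <- nc
      }
    }
    ## apex amplitude from the 3x3 neighborhood mean; refine with the
    ## analytic curvature factor of a Gaussian of the measured width
    ri <- max(1L, pr - 1L):min(nrow(img), pr + 1L)
    cj <- max(1L, pc - 1L):min(ncol(img), pc + 1L)
    amp <- mean(img[ri, cj]) - bg
    if (amp <= 0 || img[pr, pc] <= bg) {
      if (strict) .stopf("cluster %d: peak not above local background", k)
      next
    }
    w <- NA_real_
    a <- amp
    for (iter in 1:3) {
      half <- bg + a / 2
      wx <- .profileWidth(img[pr, ], pc, half)
      wy <- .profileWidth(img[, pc], pr, half)
      if (is.na(wx) || is.na(wy)) {
        w <- NA_real_
        break
      }
      w <- mean(c(wx, wy)) * pitch
      sig <- w * .FWHM_TO_SIGMA
      corr <- (1 + 4 * exp(-pitch^2 / (2 * sig^2)) + 4 * exp(-pitch^2 / sig^2)) / 9
      a <- amp / corr
    }
    if (is.na(w)) {
      if (strict) .stopf("cluster %d: profile never falls below half maximum (censored size)", k)
      next
    }
    out[k] <- w
  }
  out
}

#' Area and circularity of cluster masks
#'
#' Detects blobs as in \code{\link{annotateClusters}}, then builds a local
#' region of interest per blob: the 8-connected set of pixels, containing the
#' blob peak, that lie at or above 50\% of the background-subtracted peak
#' (the FWHM contour). Area is pixel count x pitch^2; circularity is
#' 4 pi A / P^2 with the perimeter estimated from the traced boundary chain,
#' clipped to [0, 1].
#'
#' @inheritParams annotateClusters
#' @return data.frame with one row per blob: \code{area_um2},
#'   \code{circularity}, \code{n_pixels}.
#' @export
segmentMasks <- function(image, channel, offsetK = 3, minPixels = 4L) {
  stopifnot(is(image, "SheetImage"))
  det <- .detectBlobs(image, channel, offsetK, minPixels)
  if (length(det$keep) == 0L)
    .stopf("no blobs detected in channel '%s'", channel)
  pitch <- image@pixelPitch
  res <- data.frame(area_um2 = numeric(0), circularity = numeric(0),
                    n_pixels = integer(0))
  for (b in det$keep) {
    px <- which(det$lab == b, arr.ind = TRUE)
    pk <- px[which.max(det$img[px]), ]
    peakVal <- det$img[pk[1L], pk[2L]]
    tHalf <- det$bg$median + 0.5 * (peakVal - det$bg$median)
    ## local window around the blob, padded so the half-max contour fits
    pad <- 10L
    r0 <- max(1L, min(px[, 1L]) - pad); r1 <- min(nrow(det$img), max(px[, 1L]) + pad)
    c0 <- max(1L, min(px[, 2L]) - pad); c1 <- min(ncol(det$img), max(px[, 2L]) + pad)
    win <- det$img[r0:r1, c0:c1, drop = FALSE] >= tHalf
    labw <- .label8(win)
    sel <- labw == labw[pk[1L] - r0 + 1L, pk[2L] - c0 + 1L]
    npx <- sum(sel)
    perim <- .chainPerimeter(sel)
    area <- npx * pitch^2 * .NM2_TO_UM2
    circ <- if (perim > 0) min(4 * pi * npx / perim^2, 1) else 1
    res[nrow(res) + 1L, ] <- list(area, max(circ, 0), npx)
  }
  res
}
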