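# Internal helpers shared across modules. Unit convention: all coordinates and
# distances are nm, all densities are clusters per um^2, all areas um^2.

.NM2_TO_UM2 <- 1e-6
.FWHM_TO_SIGMA <- 1 / (2 * sqrt(2 * log(2)))  # 1/2.3548

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

## Deterministic substream seed derivation: one root seed per run, stage
## offsets keep placement / rendering / ensemble streams independent.
.substream <- function(seed, stage) {
  s <- (as.numeric(seed) %% 2147483647) * 48271 + as.numeric(stage) * 16807
  as.integer(s %% 2147483647)
}

## FNV-1a hash of a deparsed object; used only for provenance stamps.
.configHash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = " "))
  h <- 216613626
  for (b in bytes) h <- (bitwXor(h, b) * 16777619) %% 2147483648
  sprintf("%08x", h)
}

## Nearest-neighbor distances from each row of `ref` to rows of `tgt`
## (both n x 2 matrices, nm). Brute force in chunks: problem sizes here are
## a few thousand points, so this is fast and exact. `excludeSelf` assumes
## ref and tgt are the same ordered point set.
.nn1 <- function(ref, tgt, excludeSelf = FALSE, chunk = 512L) {
  n <- nrow(ref)
  m <- nrow(tgt)
  if (n == 0L) return(numeric(0))
  if (m == 0L || (excludeSelf && m < 2L)) .stopf("target point set too small for nearest-neighbor search")
  out <- numeric(n)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    k <- e - s + 1L
    dx <- outer(ref[s:e, 1L], tgt[, 1L], "-")
    dy <- outer(ref[s:e, 2L], tgt[, 2L], "-")
    d2 <- dx * dx + dy * dy
    if (excludeSelf) d2[cbind(seq_len(k), s:e)] <- Inf
    idx <- max.col(-d2, ties.method = "first")
    out[s:e] <- sqrt(d2[cbind(seq_len(k), idx)])
  }
  out
}

## Histogram counts on fixed breaks; values outside the range are dropped
## (the histogram is a view, the distances vector stays complete).
.histCounts <- function(x, breaks) {
  x <- x[x >= breaks[1L] & x <= breaks[length(breaks)]]
  if (length(x) == 0L) return(integer(length(breaks) - 1L))
  bin <- findInterval(x, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  tabulate(bin, nbins = length(breaks) - 1L)
}

## Euclidean distance (nm) of every mask pixel to the nearest non-analyzable
## pixel, treating the image border as non-analyzable.
.maskDistanceNm <- function(mask, pixelPitch) {
  padded <- matrix(0, nrow(mask) + 2L, ncol(mask) + 2L)
  padded[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- mask * 1
  dm <- EBImage::distmap(padded)
  matrix(as.numeric(dm), nrow(padded))[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] * pixelPitch
}

## 8-connected labeling: EBImage::bwlabel is 4-connected, so labels touching
## diagonally are merged with a union-find pass over the label adjacencies.
.label8 <- function(bw) {
  lab <- EBImage::bwlabel(bw * 1)
  lab <- matrix(as.integer(lab), nrow(bw))
  nl <- max(lab)
  if (nl < 2L) return(lab)
  a1 <- lab[-nrow(lab), -ncol(lab)]; b1 <- lab[-1L, -1L]
  a2 <- lab[-nrow(lab), -1L];        b2 <- lab[-1L, -ncol(lab)]
  p1 <- which(a1 > 0L & b1 > 0L & a1 != b1)
  p2 <- which(a2 > 0L & b2 > 0L & a2 != b2)
  pairs <- rbind(cbind(a1[p1], b1[p1]), cbind(a2[p2], b2[p2]))
  if (nrow(pairs) == 0L) return(lab)
  parent <- seq_len(nl)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_len(nrow(pairs))) {
    ra <- find(pairs[k, 1L]); rb <- find(pairs[k, 2L])
    if (ra != rb) parent[rb] <- ra
  }
  root <- vapply(seq_len(nl), find, integer(1L))
  relab <- match(root, unique(root))
  pos <- lab > 0L
  lab[pos] <- relab[lab[pos]]
  lab
}

## Perimeter of a single connected pixel component by Moore boundary tracing.
## Chain steps are weighted 0.948 (straight) / 1.340 (diagonal), the standard
## bias-corrected estimator for smooth outlines; result in pixel units.
.chainPerimeter <- function(mask) {
  npix <- sum(mask)
  if (npix == 0L) return(0)
  if (npix == 1L) return(4)
  m <- matrix(FALSE, nrow(mask) + 2L, ncol(mask) + 2L)
  m[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- mask
  ## clockwise Moore neighborhood starting W
  dr <- c(0L, -1L, -1L, -1L, 0L, 1L, 1L, 1L)
  dc <- c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)
  ## start at first foreground pixel in column-major order: W neighbor is bg
  start <- which(m)[1L]
  sr <- (start - 1L) %% nrow(m) + 1L
  sc <- (start - 1L) %/% nrow(m) + 1L
  cur_r <- sr; cur_c <- sc
  back <- 1L  # entered "from" the W neighbor
  straight <- 0L; diagonal <- 0L
  first_move <- NA_integer_
  steps <- 0L
  repeat {
    found <- FALSE
    for (t in 1:8) {
      d <- (back + t - 1L) %% 8L + 1L
      nr <- cur_r + dr[d]; nc <- cur_c + dc[d]
      if (m[nr, nc]) {
        if (abs(dr[d]) + abs(dc[d]) == 1L) straight <- straight + 1L else diagonal <- diagonal + 1L
        ## new backtrack: direction pointing from the new pixel to the last
        ## background pixel examined (the neighbor before d, seen from new px)
        pr <- cur_r + dr[(d - 2L) %% 8L + 1L]
        pc <- cur_c + dc[(d - 2L) %% 8L + 1L]
        rel <- which(dr == (pr - nr) & dc == (pc - nc))
        cur_r <- nr; cur_c <- nc; back <- rel
        if (is.na(first_move)) first_move <- d
        found <- TRUE
        break
      }
    }
    if (!found) break  # isolated pixel run
    steps <- steps + 1L
    if (cur_r == sr && cur_c == sc && steps > 1L) break
    if (steps > 8L * npix + 8L) break  # safety cap
  }
  0.948 * straight + 1.340 * diagonal
}

## Greedy one-to-one matching of two point sets by increasing distance.
.greedyMatch <- function(a, b, dmax) {
  if (nrow(a) == 0L || nrow(b) == 0L)
    return(data.frame(i = integer(0), j = integer(0), d = numeric(0)))
  dx <- outer(a[, 1L], b[, 1L], "-")
  dy <- outer(a[, 2L], b[, 2L], "-")
  d <- sqrt(dx * dx + dy * dy)
  cand <- which(d <= dmax, arr.ind = TRUE)
  if (nrow(cand) == 0L)
    return(data.frame(i = integer(0), j = integer(0), d = numeric(0)))
  ord <- order(d[cand])
  cand <- cand[ord, , drop = FALSE]
  usedA <- logical(nrow(a)); usedB <- logical(nrow(b))
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1L]; j <- cand[k, 2L]
    if (!usedA[i] && !usedB[j]) {
      usedA[i] <- TRUE; usedB[j] <- TRUE; keep[k] <- TRUE
    }
  }
  cand <- cand[keep, , drop = FALSE]
  data.frame(i = cand[, 1L], j = cand[, 2L], d = d[cand])
}
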