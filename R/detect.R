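#' @include AllClasses.R AllGenerics.R
NULL

#' Detection settings
#'
#' @param smoothSigma Gaussian pre-smoothing sd (px) applied to the sum of
#'   the encoding channels before segmentation.
#' @param k threshold in robust noise units: pixels brighter than
#'   `background + k * MAD` are foreground.
#' @param minContrast absolute floor (a.u.) on the threshold offset, so
#'   that noise-free (zero-MAD) images are still segmented sensibly and a
#'   constant image yields no detections.
#' @param minArea minimum connected-component area (px) kept.
#' @param minRadius minimum accepted bead radius (px).
#' @param circularityMin components less circular than this are dropped
#'   (merged clumps, debris).
#' @return list of settings for [detectBeads()].
#' @export
detectParams <- function(smoothSigma = 1, k = 8, minContrast = 50,
                         minArea = 12L, minRadius = 2, circularityMin = 0.7) {
  list(smoothSigma = smoothSigma, k = k, minContrast = minContrast,
       minArea = as.integer(minArea), minRadius = minRadius,
       circularityMin = circularityMin)
}

#' Detect beads in the encoding channels
#'
#' Segmentation-based detection: the two encoding channels are summed
#' (every bead carries both dyes), smoothed, and thresholded at
#' `background + k * MAD`; connected components become candidate beads.
#' Per component the center is refined to sub-pixel precision as the
#' intensity-weighted centroid, the radius is estimated from the area
#' enclosed by the half-maximum contour (the half-maximum of a blurred
#' disk edge sits at the true rim, so this estimate is unbiased), and a
#' circularity score (area over the circumscribed circle area) gates out
#' merged clumps. Components touching the image border are flagged
#' `edge = TRUE` and kept; downstream quantification rejects them.
#'
#' An empty or constant image yields zero detections, not an error.
#'
#' @param image a [ChipImage-class].
#' @param params settings from [detectParams()].
#' @return data.frame with one row per detection: `detection`, `row`,
#'   `col` (sub-pixel, 1-based), `radius_px`, `circularity`, `edge`,
#'   `area_px`.
#' @examples
#' cfg <- simConfig(beadsPerPopulation = 4, imageShape = c(400, 400),
#'                  seed = 7)
#' img <- renderChipImage(sampleBeadLayout(cfg), cfg)
#' detectBeads(img)
#' @export
detectBeads <- function(image, params = detectParams()) {
  stopifnot(is(image, "ChipImage"))
  S <- channel(image, "encode1") + channel(image, "encode2")
  H <- nrow(S); W <- ncol(S)
  empty <- data.frame(detection = integer(), row = numeric(), col = numeric(),
                      radius_px = numeric(), circularity = numeric(),
                      edge = logical(), area_px = integer())

  sm <- EBImage::imageData(EBImage::gblur(EBImage::Image(S),
                                          sigma = params$smoothSigma))
  bg <- stats::median(sm)
  noise <- stats::mad(sm)
  thr <- bg + max(params$k * noise, params$minContrast)
  mask <- sm > thr
  if (!any(mask)) return(empty)

  # watershed on the distance map splits touching beads whose threshold
  # skirts merge; tolerance suppresses spurious splits within one bead
  lab <- EBImage::imageData(EBImage::watershed(EBImage::distmap(mask),
                                               tolerance = 1.5, ext = 1))
  nlab <- max(lab)
  idx <- which(lab > 0L)
  l <- as.integer(lab[idx])
  ri <- ((idx - 1L) %% H) + 1L
  ci <- ((idx - 1L) %/% H) + 1L
  smv <- sm[idx]

  area <- tabulate(l, nbins = nlab)
  # intensity-weighted sub-pixel centroid
  w <- pmax(S[idx] - bg, 0)
  wsum <- rowsum(w, l)[, 1]
  wsum[wsum <= 0] <- NA_real_
  cy <- rowsum(w * ri, l)[, 1] / wsum
  cx <- rowsum(w * ci, l)[, 1] / wsum
  # Radius from iso-intensity contour areas. For a symmetrically blurred
  # rim the half-maximum contour sits at the true radius up to a curvature
  # term sigma^2/(2r); the edge scale sigma is estimated from the spread
  # between the 15% and 85% contours (at -/+ qnorm(0.85)*sigma for an erf
  # edge). The component peak is a high quantile of the flat-topped
  # interior.
  peak <- vapply(split(smv, l), stats::quantile, numeric(1),
                 probs = 0.9, names = FALSE)
  d2 <- (ri - cy[l])^2 + (ci - cx[l])^2
  relv <- (smv - bg) / pmax(peak[l] - bg, .Machine$double.eps)
  r50 <- sqrt(tabulate(l[relv >= 0.5], nbins = nlab) / pi)
  # second pass: the plateau level re-estimated from core pixels (well
  # inside the half-max contour, clear of the blurred rim); the initial
  # label-quantile peak sits a few percent low for small beads, which
  # would shift all contour radii outward
  core <- d2 <= (0.55 * r50[l])^2
  nCore <- tabulate(l[core], nbins = nlab)
  plateau <- ifelse(nCore >= 5, rowsum(smv * core, l)[, 1] / pmax(nCore, 1),
                    peak)
  relv <- (smv - bg) / pmax(plateau[l] - bg, .Machine$double.eps)
  r50 <- sqrt(tabulate(l[relv >= 0.5], nbins = nlab) / pi)
  r85 <- sqrt(tabulate(l[relv >= 0.85], nbins = nlab) / pi)
  r15 <- sqrt(tabulate(l[relv >= 0.15], nbins = nlab) / pi)
  sigmaEdge <- pmax(r15 - r85, 0) / (2 * stats::qnorm(0.85))
  radius <- r50 + sigmaEdge^2 / (2 * pmax(r50, 1))
  # circularity: area relative to the circumscribed circle
  rmax <- sqrt(vapply(split(d2, l), max, numeric(1)))
  circ <- pmin(1, area / (pi * (rmax + 0.5)^2))

  touches <- rowsum(as.numeric(ri == 1L | ri == H | ci == 1L | ci == W),
                    l)[, 1] > 0
  edge <- touches | cy - radius < 1.5 | cy + radius > H - 0.5 |
    cx - radius < 1.5 | cx + radius > W - 0.5

  # border-truncated components fail circularity by construction; they are
  # kept with the edge flag (downstream QC rejects them) rather than dropped
  keep <- which(area >= params$minArea & radius >= params$minRadius &
                (circ >= params$circularityMin | edge) & is.finite(cy))
  if (!length(keep)) return(empty)
  data.frame(detection = seq_along(keep), row = unname(cy[keep]),
             col = unname(cx[keep]), radius_px = unname(radius[keep]),
             circularity = unname(circ[keep]), edge = unname(edge[keep]),
             area_px = area[keep])
}

# Spatial-hash nearest neighbour: for each query point, index and distance
# of the nearest reference point (within cellSize of lookup range ~ 2 cells).
.nearestNeighbor <- function(qr, qc, rr, rc, cell) {
  ncr <- max(1L, as.integer(ceiling(max(rr, qr, 1) / cell)))
  ncc <- max(1L, as.integer(ceiling(max(rc, qc, 1) / cell)))
  grid <- vector("list", ncr * ncc)
  gi <- pmin(pmax(as.integer(ceiling(rr / cell)), 1L), ncr)
  gj <- pmin(pmax(as.integer(ceiling(rc / cell)), 1L), ncc)
  for (k in seq_along(rr)) {
    g <- gi[k] + (gj[k] - 1L) * ncr
    grid[[g]] <- c(grid[[g]], k)
  }
  n <- length(qr)
  nn <- integer(n); nd <- numeric(n)
  for (k in seq_len(n)) {
    ci <- pmin(pmax(as.integer(ceiling(qr[k] / cell)), 1L), ncr)
    cj <- pmin(pmax(as.integer(ceiling(qc[k] / cell)), 1L), ncc)
    ni <- max(1L, ci - 1L):min(ncr, ci + 1L)
    nj <- max(1L, cj - 1L):min(ncc, cj + 1L)
    nb <- unlist(grid[outer(ni, (nj - 1L) * ncr, "+")], use.names = FALSE)
    if (!length(nb)) { nn[k] <- NA_integer_; nd[k] <- Inf; next }
    d2 <- (rr[nb] - qr[k])^2 + (rc[nb] - qc[k])^2
    j <- which.min(d2)
    nn[k] <- nb[j]; nd[k] <- sqrt(d2[j])
  }
  list(index = nn, dist = nd)
}

#' Match detections to ground-truth beads
#'
#' Nearest-neighbour assignment of detections to truth beads within a
#' center-distance gate (one-to-one: if two detections claim the same
#' truth bead, the nearer one wins), used to score detection performance
#' on synthetic chips.
#'
#' @param detections data.frame from [detectBeads()].
#' @param truth data.frame from [sampleBeadLayout()].
#' @param maxDist maximum center distance (px) for a match.
#' @return list with `matches` (data.frame detection, bead, dist_px),
#'   `recall`, `precision`.
#' @export
matchDetections <- function(detections, truth, maxDist = 3) {
  emptyMatches <- data.frame(detection = integer(), bead = integer(),
                             dist_px = numeric())
  if (!nrow(detections) || !nrow(truth))
    return(list(matches = emptyMatches, recall = 0,
                precision = if (nrow(detections)) 0 else NA_real_))
  nn <- .nearestNeighbor(detections$row, detections$col,
                         truth$row, truth$col, cell = max(maxDist * 2, 8))
  cand <- data.frame(detection = detections$detection,
                     bead = truth$bead[nn$index], dist_px = nn$dist)
  cand <- cand[is.finite(cand$dist_px) & cand$dist_px <= maxDist, ,
               drop = FALSE]
  cand <- cand[order(cand$dist_px), , drop = FALSE]
  cand <- cand[!duplicated(cand$bead), , drop = FALSE]
  matches <- if (nrow(cand)) cand[order(cand$detection), , drop = FALSE]
             else emptyMatches
  rownames(matches) <- NULL
  list(matches = matches,
       recall = nrow(matches) / nrow(truth),
       precision = nrow(matches) / nrow(detections))
}
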