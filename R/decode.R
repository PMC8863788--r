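#' @include AllClasses.R detect.R
NULL

# Logical mask of all detection footprints (disks of factor*r), used to
# exclude bead pixels from far-field background estimates.
.beadMask <- function(H, W, detections, factor = 1.5, pad = 2) {
  mask <- matrix(FALSE, H, W)
  for (i in seq_len(nrow(detections))) {
    r <- detections$radius_px[i] * factor + pad
    r0 <- max(1L, floor(detections$row[i] - r))
    r1 <- min(H, ceiling(detections$row[i] + r))
    c0 <- max(1L, floor(detections$col[i] - r))
    c1 <- min(W, ceiling(detections$col[i] + r))
    if (r0 > r1 || c0 > c1) next
    dd <- outer(((r0:r1) - detections$row[i])^2,
                ((c0:c1) - detections$col[i])^2, "+")
    mask[r0:r1, c0:c1] <- mask[r0:r1, c0:c1] | (dd <= r^2)
  }
  mask
}

#' Measure per-bead encoding features
#'
#' For every non-edge detection, the mean of each encoding channel over the
#' inner disk (radius shrunk by `erosionFraction` to stay clear of the
#' blurred rim) is computed and corrected by a far-field background
#' estimate (the per-channel median over pixels not covered by any
#' detection footprint). The decoding features are the corrected channel
#' means, their ratio and the detected radius.
#'
#' Edge-flagged detections are not measured and carry QC code `"edge"`; a
#' non-positive corrected `enc2` makes the ratio undefined and the bead is
#' gated with `"ratio_undefined"`.
#'
#' @param image a [ChipImage-class].
#' @param detections data.frame from [detectBeads()].
#' @param erosionFraction fraction of the radius eroded from the
#'   measurement disk (default 0.3: the inner 70% of the radius is used).
#' @return data.frame: `detection`, `enc1`, `enc2` (background-corrected
#'   means), `ratio`, `log_ratio`, `radius_um`, `qc`.
#' @export
measureEncoding <- function(image, detections, erosionFraction = 0.3) {
  stopifnot(is(image, "ChipImage"))
  e1 <- channel(image, "encode1"); e2 <- channel(image, "encode2")
  H <- nrow(e1); W <- ncol(e1)
  n <- nrow(detections)
  out <- data.frame(detection = detections$detection,
                    enc1 = rep(NA_real_, n), enc2 = NA_real_,
                    ratio = NA_real_, log_ratio = NA_real_,
                    radius_um = detections$radius_px * image@pixelSize,
                    qc = rep("ok", n), stringsAsFactors = FALSE)
  if (!n) return(out)

  mask <- .beadMask(H, W, detections)
  bg1 <- stats::median(e1[!mask]); bg2 <- stats::median(e2[!mask])
  if (!is.finite(bg1)) { bg1 <- stats::median(e1); bg2 <- stats::median(e2) }

  for (i in seq_len(n)) {
    if (detections$edge[i]) { out$qc[i] <- "edge"; next }
    r <- detections$radius_px[i] * (1 - erosionFraction)
    r0 <- max(1L, floor(detections$row[i] - r))
    r1 <- min(H, ceiling(detections$row[i] + r))
    c0 <- max(1L, floor(detections$col[i] - r))
    c1 <- min(W, ceiling(detections$col[i] + r))
    dd <- outer(((r0:r1) - detections$row[i])^2,
                ((c0:c1) - detections$col[i])^2, "+")
    inner <- dd <= r^2
    if (!any(inner)) { out$qc[i] <- "ratio_undefined"; next }
    m1 <- mean(e1[r0:r1, c0:c1][inner]) - bg1
    m2 <- mean(e2[r0:r1, c0:c1][inner]) - bg2
    out$enc1[i] <- m1; out$enc2[i] <- m2
    if (m2 > 0 && m1 > 0) {
      out$ratio[i] <- m1 / m2
      out$log_ratio[i] <- log(m1 / m2)
    } else {
      out$qc[i] <- "ratio_undefined"
    }
  }
  attr(out, "background") <- c(encode1 = bg1, encode2 = bg2)
  out
}

#' Decode beads to populations
#'
#' Assigns each bead to the panel population minimising the standardised
#' Euclidean distance in (log encoding ratio, radius) feature space, each
#' dimension scaled by the panel's dispersion estimate for that
#' population. Beads whose minimal distance exceeds `maxDistance` (a
#' roughly 3-standard-deviation gate by default) are labelled
#' `"unclassified"`, as are beads with non-finite features. Exact distance
#' ties resolve to the first population in panel order and are flagged
#' `ambiguous`.
#'
#' @param features data.frame from [measureEncoding()] (columns
#'   `log_ratio`, `radius_um`).
#' @param panel a [ReferencePanel-class].
#' @param maxDistance gating threshold on the standardised distance.
#' @return data.frame: `population` (id or `"unclassified"`), `distance`
#'   (standardised distance to the assigned population, NA when
#'   unclassified for lack of features), `ambiguous`.
#' @export
decodePopulation <- function(features, panel, maxDistance = 3) {
  stopifnot(is(panel, "ReferencePanel"))
  cd <- panel@codes
  if (!nrow(cd)) stop("reference panel is empty")
  n <- nrow(features)
  out <- data.frame(population = rep("unclassified", n),
                    distance = rep(NA_real_, n),
                    ambiguous = rep(FALSE, n), stringsAsFactors = FALSE)
  if (!n) return(out)
  lrNom <- log(cd$enc1 / cd$enc2)
  radNom <- cd$diameter_um / 2
  ok <- is.finite(features$log_ratio) & is.finite(features$radius_um)
  for (i in which(ok)) {
    z <- sqrt(((features$log_ratio[i] - lrNom) / cd$sd_log_ratio)^2 +
              ((features$radius_um[i] - radNom) / cd$sd_radius_um)^2)
    j <- which.min(z)
    out$distance[i] <- z[j]
    if (z[j] <= maxDistance) {
      out$population[i] <- cd$population[j]
      out$ambiguous[i] <- sum(z == z[j]) > 1L
    }
  }
  out
}
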