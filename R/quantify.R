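#' @include AllClasses.R decode.R
NULL

#' Halo measurement settings
#'
#' Geometry and estimator settings for [measureHalo()]. Two estimators are
#' available. The default `"regression"` method fits, over a window
#' covering the rim and the surrounding background, the linear model
#' `pixel = background + amplitude * template` with the unit-amplitude
#' Gaussian ring template rendered at the detected center/radius (plus the
#' template's radius derivative as a nuisance regressor, which cancels the
#' first-order effect of sub-pixel center/radius estimation errors). The
#' `"annulus"` method is the classical ring statistic: trimmed mean over
#' the rim annulus `[r*(1-wIn), r*(1+wOut)]` minus the mean of the
#' background annulus `[r*(1+g1), r*(1+g2)]`, divided by the identical
#' statistic of the unit template (the division is skipped with
#' `calibrate = FALSE`, giving the plain background-subtracted ring mean).
#'
#' @param method `"regression"` (default) or `"annulus"`.
#' @param wIn,wOut inner/outer half-widths of the rim annulus as
#'   fractions of the radius (symmetric by default so the rim is sampled
#'   evenly on both sides).
#' @param g1,g2 background annulus bounds as fractions of the radius
#'   (annulus method).
#' @param trim trimming fraction of the ring mean (annulus method).
#'   Default 0: rank-based trimming of noisy pixels is inconsistent with
#'   trimming the noise-free template when the ring profile is not flat,
#'   which produces an amplitude-dependent bias; outlier protection is
#'   instead provided by the neighbour-footprint exclusion.
#' @param haloWidth assumed Gaussian radial sd of the halo (um), used for
#'   the unit template.
#' @param windowSigma half-width of the regression window around the rim,
#'   in units of `haloWidth`.
#' @param bgWidth width (px) of the far background band beyond the
#'   regression window that anchors the background level.
#' @param calibrate logical (annulus method); divide by the template
#'   factor (TRUE) or report the plain background-subtracted trimmed mean.
#' @param minBackgroundPixels below this count of usable background
#'   pixels the global image background is used instead and the bead is
#'   flagged `background_fallback`.
#' @return list of settings for [measureHalo()].
#' @export
annulusParams <- function(method = c("regression", "annulus"),
                          wIn = 0.25, wOut = 0.25, g1 = 0.6, g2 = 1.0,
                          trim = 0, haloWidth = 2, windowSigma = 3.5,
                          bgWidth = 4, calibrate = TRUE,
                          minBackgroundPixels = 20L) {
  method <- match.arg(method)
  stopifnot(wIn >= 0, wOut > 0, g2 > g1, g1 > wOut, trim >= 0, trim < 0.5,
            windowSigma > 1, bgWidth > 0)
  list(method = method, wIn = wIn, wOut = wOut, g1 = g1, g2 = g2,
       trim = trim, haloWidth = haloWidth, windowSigma = windowSigma,
       bgWidth = bgWidth, calibrate = calibrate,
       minBackgroundPixels = as.integer(minBackgroundPixels))
}

# Integer occupancy map: pixel -> detection id owning it (footprint
# factor*r + pad), 0 where free. Later claims do not overwrite earlier
# ones; beads are far apart so contention is rare.
.occupancyMap <- function(H, W, detections, factor = 1.3, pad = 1) {
  occ <- matrix(0L, H, W)
  for (i in seq_len(nrow(detections))) {
    r <- detections$radius_px[i] * factor + pad
    r0 <- max(1L, floor(detections$row[i] - r))
    r1 <- min(H, ceiling(detections$row[i] + r))
    c0 <- max(1L, floor(detections$col[i] - r))
    c1 <- min(W, ceiling(detections$col[i] + r))
    if (r0 > r1 || c0 > c1) next
    dd <- outer(((r0:r1) - detections$row[i])^2,
                ((c0:c1) - detections$col[i])^2, "+")
    blk <- occ[r0:r1, c0:c1]
    take <- dd <= r^2 & blk == 0L
    blk[take] <- detections$detection[i]
    occ[r0:r1, c0:c1] <- blk
  }
  occ
}

#' Measure the binding halo around each bead
#'
#' Estimates, per detection, the amplitude of the Gaussian rim halo in
#' the measurement channel together with the local background, using the
#' estimator selected in [annulusParams()] (template regression by
#' default, classical calibrated ring statistic as the alternative).
#' `halo_surface` estimates the halo ring amplitude on top of the local
#' background; negative values are retained so population means stay
#' unbiased near zero. Pixels inside another detection's exclusion
#' footprint (the bead plus ~3.5 sigma of its halo tail) are masked from
#' all statistics, bead by bead, so neighbouring halos do not leak in.
#'
#' Edge-flagged beads, and beads whose measurement window leaves the
#' image, are gated with QC code `"halo_edge"`. When the background is
#' (almost) fully occluded by neighbours, the global far-field background
#' is used instead and the bead is flagged `"background_fallback"`.
#'
#' @param image a [ChipImage-class].
#' @param detections data.frame from [detectBeads()].
#' @param annulus settings from [annulusParams()].
#' @return data.frame: `detection`, `ring_raw` (plain mean over the rim
#'   annulus), `local_background`, `calibration` (nominal template
#'   attenuation factor of the rim annulus), `halo_surface`, `qc`.
#' @export
measureHalo <- function(image, detections, annulus = annulusParams()) {
  stopifnot(is(image, "ChipImage"))
  me <- channel(image, "measure")
  H <- nrow(me); W <- ncol(me)
  n <- nrow(detections)
  out <- data.frame(detection = detections$detection,
                    ring_raw = rep(NA_real_, n),
                    local_background = NA_real_, calibration = NA_real_,
                    halo_surface = NA_real_, qc = rep("ok", n),
                    stringsAsFactors = FALSE)
  if (!n) return(out)

  sigma <- annulus$haloWidth / image@pixelSize
  regression <- annulus$method == "regression"
  # footprints cover the bead plus ~3.5 sigma of its halo tail so that
  # neighbouring halos never leak into background estimates
  exclRadius <- 1.05 * detections$radius_px + annulus$windowSigma * sigma + 1
  occ <- .occupancyMap(H, W, detections, factor = 1.05,
                       pad = annulus$windowSigma * sigma + 1)
  globalBg <- stats::median(me[occ == 0L])

  for (i in seq_len(n)) {
    r <- detections$radius_px[i]
    rOuter <- if (regression)
      r + annulus$windowSigma * sigma + annulus$bgWidth
    else r * (1 + annulus$g2)
    if (detections$edge[i] ||
        detections$row[i] - rOuter < 1 || detections$row[i] + rOuter > H ||
        detections$col[i] - rOuter < 1 || detections$col[i] + rOuter > W) {
      out$qc[i] <- "halo_edge"
      next
    }
    r0 <- floor(detections$row[i] - rOuter); r1 <- ceiling(detections$row[i] + rOuter)
    c0 <- floor(detections$col[i] - rOuter); c1 <- ceiling(detections$col[i] + rOuter)
    dd <- sqrt(outer(((r0:r1) - detections$row[i])^2,
                     ((c0:c1) - detections$col[i])^2, "+"))
    blk <- me[r0:r1, c0:c1]

    # mask pixels inside other beads' exclusion footprints (checked bead
    # by bead: footprints overlap, so a single owner map would let halo
    # tails slip through); templates use the same pixel sets, so masking
    # does not bias the estimates
    free <- matrix(TRUE, r1 - r0 + 1L, c1 - c0 + 1L)
    nearDist <- sqrt((detections$row - detections$row[i])^2 +
                     (detections$col - detections$col[i])^2)
    near <- which(nearDist < rOuter + exclRadius & seq_len(n) != i)
    for (j in near) {
      ddj <- outer(((r0:r1) - detections$row[j])^2,
                   ((c0:c1) - detections$col[j])^2, "+")
      free <- free & ddj > exclRadius[j]^2
    }

    tmpl <- exp(-(dd - r)^2 / (2 * sigma^2))
    ringFull <- dd >= r * (1 - annulus$wIn) & dd <= r * (1 + annulus$wOut)
    ring <- ringFull & free
    if (sum(ring) < max(10L, 0.2 * sum(ringFull))) ring <- ringFull
    out$ring_raw[i] <- mean(blk[ring])

    if (regression) {
      win <- dd >= max(0, r - annulus$windowSigma * sigma) &
        dd <= rOuter & free
      nWin <- sum(win)
      bgPx <- sum(win & tmpl < 0.05)
      y <- blk[win]; t <- tmpl[win]
      if (bgPx >= annulus$minBackgroundPixels && nWin >= 40L) {
        # y ~ alpha + A*t + B*dt/dr + C*d2t/dr2; the derivative regressors
        # absorb the first- and second-order template mismatch caused by
        # sub-pixel radius estimation error
        u <- (dd[win] - r) / sigma
        dt <- t * u / sigma
        d2t <- t * (u^2 - 1) / sigma^2
        X <- cbind(1, t, dt, d2t)
        cf <- tryCatch(qr.coef(qr(X), y), error = function(e) rep(NA_real_, 4))
        if (anyNA(cf)) cf <- c(qr.coef(qr(X[, 1:2]), y), 0, 0)
        out$local_background[i] <- cf[1]
        out$halo_surface[i] <- cf[2]
      } else {
        out$qc[i] <- "background_fallback"
        out$local_background[i] <- globalBg
        out$halo_surface[i] <- sum(t * (y - globalBg)) / sum(t^2)
      }
      out$calibration[i] <- 1
    } else {
      ringStat <- mean(blk[ring], trim = annulus$trim)
      fRing <- mean(tmpl[ring], trim = annulus$trim)
      usable <- dd >= r * (1 + annulus$g1) & dd <= r * (1 + annulus$g2) & free
      if (sum(usable) >= annulus$minBackgroundPixels) {
        # mean, not median: with the template correction the statistic is
        # linear in the pixel values; the skewed halo-tail distribution
        # under the annulus would bias a median upward
        lb <- mean(blk[usable])
        fBg <- mean(tmpl[usable])
      } else {
        lb <- globalBg      # far field: no own-halo contribution
        fBg <- 0
        out$qc[i] <- "background_fallback"
      }
      calib <- if (annulus$calibrate) fRing - fBg else 1
      out$calibration[i] <- calib
      out$local_background[i] <- lb
      out$halo_surface[i] <- (ringStat - lb) / calib
    }
  }
  attr(out, "globalBackground") <- globalBg
  out
}

#' Analyse one chip image end to end
#'
#' Runs detection, doublet gating, encoding measurement, population
#' decoding and halo quantification, returning one row per detected bead.
#' A bead's QC code is the first applicable of: `edge` / `halo_edge`,
#' `doublet` (nearest neighbour closer than `doubletGate` times the sum of
#' radii), `ratio_undefined`, `unclassified`, `background_fallback`; beads
#' with code `"ok"` enter population summaries.
#'
#' @param image a [ChipImage-class].
#' @param panel a [ReferencePanel-class].
#' @param detect settings from [detectParams()].
#' @param annulus settings from [annulusParams()].
#' @param maxDistance decoding gate, see [decodePopulation()].
#' @param erosionFraction see [measureEncoding()].
#' @param doubletGate neighbour-distance gate in units of summed radii.
#' @return data.frame of per-bead measurements with attribute
#'   `"background"` (far-field encoding background estimates).
#' @examples
#' cfg <- simConfig(beadsPerPopulation = 10, imageShape = c(640, 640),
#'                  seed = 3)
#' img <- renderChipImage(sampleBeadLayout(cfg), cfg)
#' beads <- analyzeChip(img, cfg@panel)
#' table(beads$population, beads$qc)
#' @export
analyzeChip <- function(image, panel, detect = detectParams(),
                        annulus = annulusParams(), maxDistance = 3,
                        erosionFraction = 0.3, doubletGate = 1.2) {
  det <- detectBeads(image, detect)
  if (!nrow(det)) {
    out <- data.frame(detection = integer(), row = numeric(), col = numeric(),
                      radius_px = numeric(), radius_um = numeric(),
                      circularity = numeric(), edge = logical(),
                      enc1 = numeric(), enc2 = numeric(), ratio = numeric(),
                      log_ratio = numeric(), population = character(),
                      distance = numeric(), ambiguous = logical(),
                      ring_raw = numeric(), local_background = numeric(),
                      halo_surface = numeric(), qc = character(),
                      stringsAsFactors = FALSE)
    return(out)
  }

  doublet <- rep(FALSE, nrow(det))
  if (nrow(det) > 1L) {
    for (i in seq_len(nrow(det))) {
      d <- sqrt((det$row - det$row[i])^2 + (det$col - det$col[i])^2)
      d[i] <- Inf
      j <- which.min(d)
      if (d[j] < doubletGate * (det$radius_px[i] + det$radius_px[j]))
        doublet[i] <- TRUE
    }
  }

  enc <- measureEncoding(image, det, erosionFraction)
  dec <- decodePopulation(enc, panel, maxDistance)
  halo <- measureHalo(image, det, annulus)

  qc <- rep("ok", nrow(det))
  qc[halo$qc == "background_fallback"] <- "background_fallback"
  qc[dec$population == "unclassified"] <- "unclassified"
  qc[enc$qc == "ratio_undefined"] <- "ratio_undefined"
  qc[doublet] <- "doublet"
  qc[det$edge | halo$qc == "halo_edge"] <- "edge"

  out <- data.frame(detection = det$detection, row = det$row, col = det$col,
                    radius_px = det$radius_px, radius_um = enc$radius_um,
                    circularity = det$circularity, edge = det$edge,
                    enc1 = enc$enc1, enc2 = enc$enc2, ratio = enc$ratio,
                    log_ratio = enc$log_ratio, population = dec$population,
                    distance = dec$distance, ambiguous = dec$ambiguous,
                    ring_raw = halo$ring_raw,
                    local_background = halo$local_background,
                    halo_surface = halo$halo_surface, qc = qc,
                    stringsAsFactors = FALSE)
  attr(out, "background") <- attr(enc, "background")
  attr(out, "globalBackground") <- attr(halo, "globalBackground")
  out
}

#' Summarise one population to its rMFI
#'
#' The referenced mean fluorescence intensity (rMFI) of a population is
#' the arithmetic mean of `halo_surface` over its QC-passing beads,
#' divided by `referenceScale` (default 1: the amplitude scale itself; the
#' encoding dyes serve only as the population code). Below `minBeads`
#' usable beads the summary is marked invalid rather than silently
#' reported.
#'
#' @param measurements data.frame from [analyzeChip()].
#' @param population population id.
#' @param referenceScale divisor defining the "referenced" scale.
#' @param minBeads minimum usable beads for a valid rMFI (default 10).
#' @return one-row data.frame: `population`, `n`, `rmfi`, `sd`, `valid`.
#' @export
summarizePopulation <- function(measurements, population,
                                referenceScale = 1, minBeads = 10L) {
  stopifnot(referenceScale > 0)
  sel <- measurements$population == population & measurements$qc == "ok" &
    is.finite(measurements$halo_surface)
  n <- sum(sel)
  v <- measurements$halo_surface[sel] / referenceScale
  data.frame(population = population, n = n,
             rmfi = if (n >= 1L) mean(v) else NA_real_,
             sd = if (n >= 2L) stats::sd(v) else NA_real_,
             valid = n >= minBeads, stringsAsFactors = FALSE)
}

#' Summarise a whole chip into per-population rMFI
#'
#' @param measurements data.frame from [analyzeChip()].
#' @param panel a [ReferencePanel-class].
#' @inheritParams summarizePopulation
#' @return data.frame with one row per panel population and attributes
#'   `"totalDetections"`, `"unclassified"`, `"qcFailed"` satisfying
#'   total = sum(n) + unclassified + qcFailed.
#' @export
summarizeChip <- function(measurements, panel, referenceScale = 1,
                          minBeads = 10L) {
  pops <- panel@codes$population
  out <- do.call(rbind, lapply(pops, function(p)
    summarizePopulation(measurements, p, referenceScale, minBeads)))
  rownames(out) <- NULL
  attr(out, "totalDetections") <- nrow(measurements)
  attr(out, "unclassified") <- sum(measurements$qc == "unclassified")
  attr(out, "qcFailed") <- nrow(measurements) - sum(out$n) -
    sum(measurements$qc == "unclassified")
  out
}

#' Per-population rMFI kinetic traces from a frame series
#'
#' Runs the full detect / decode / quantify pipeline independently on each
#' frame (beads are not tracked across frames; aggregation is at the
#' population level) and returns one (time, rMFI, n) trace per population.
#'
#' @param frames list of [ChipImage-class] sharing well id and shape.
#' @param panel a [ReferencePanel-class].
#' @param times frame times; default taken from the images (frame index
#'   when times are absent).
#' @param ... passed on to [analyzeChip()].
#' @inheritParams summarizePopulation
#' @return data.frame: `population`, `frame`, `time`, `n`, `rmfi`, `sd`,
#'   `valid`, ordered by population then time.
#' @export
rmfiTimeSeries <- function(frames, panel, times = NULL, referenceScale = 1,
                           minBeads = 10L, ...) {
  stopifnot(length(frames) >= 1L)
  shp <- imageShape(frames[[1]])
  well <- wellId(frames[[1]])
  for (f in frames) {
    if (!identical(imageShape(f), shp))
      stop("frames differ in shape")
    if (!identical(wellId(f), well))
      stop("frames belong to different wells")
  }
  if (is.null(times)) {
    times <- vapply(frames, frameTime, numeric(1))
    if (anyNA(times)) times <- seq_along(frames)
  }
  if (is.unsorted(times, strictly = TRUE))
    stop("frame times must be strictly increasing")
  out <- NULL
  for (k in seq_along(frames)) {
    meas <- analyzeChip(frames[[k]], panel, ...)
    s <- summarizeChip(meas, panel, referenceScale, minBeads)
    s$frame <- k
    s$time <- times[k]
    out <- rbind(out, s)
  }
  out <- out[order(out$population, out$time),
             c("population", "frame", "time", "n", "rmfi", "sd", "valid")]
  rownames(out) <- NULL
  out
}
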