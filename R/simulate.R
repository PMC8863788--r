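#' @include AllClasses.R simconfig.R
NULL

# Margin (px) keeping a bead's halo and background annulus inside the image.
.placementMargin <- function(config) {
  rmax <- max(config@panel@codes$diameter_um) / 2 / config@pixelSize
  ceiling(2.2 * rmax + 3 * config@haloWidth / config@pixelSize + 2)
}

#' Sample a random bead layout with ground truth
#'
#' Places `beadsPerPopulation` beads per panel population uniformly at
#' random, enforcing a minimum pairwise center distance by rejection
#' sampling on a spatial hash grid. Per-bead encoding intensities are drawn
#' around the population nominals with CV `encodingCV`; radii with CV
#' `radiusCV`. When `doubletFraction > 0`, that fraction of beads receives
#' a touching companion bead (flagged `doublet = TRUE`) to emulate clumps.
#'
#' Beads are kept far enough from the border that their halo and local
#' background annulus lie fully inside the image.
#'
#' @param config a [SimConfig-class].
#' @return data.frame with one row per bead: `bead`, `row`, `col`
#'   (sub-pixel center, 1-based), `radius_px`, `population`, `enc1`,
#'   `enc2`, `halo_amp`, `doublet`.
#' @examples
#' layout <- sampleBeadLayout(simConfig(beadsPerPopulation = 5,
#'                                      imageShape = c(512, 512)))
#' head(layout)
#' @export
sampleBeadLayout <- function(config) {
  validObject(config)
  cd <- config@panel@codes
  npop <- nrow(cd)
  nper <- config@beadsPerPopulation
  n <- npop * nper
  empty <- data.frame(bead = integer(), row = numeric(), col = numeric(),
                      radius_px = numeric(), population = character(),
                      enc1 = numeric(), enc2 = numeric(), halo_amp = numeric(),
                      doublet = logical(), stringsAsFactors = FALSE)
  if (n == 0L) return(empty)

  H <- config@imageShape[1]; W <- config@imageShape[2]
  margin <- .placementMargin(config)
  if (H - 2 * margin < 1 || W - 2 * margin < 1)
    stop("image too small for the configured bead sizes")
  dmin <- config@minCenterDistance / config@pixelSize

  withr::with_seed(config@seed, {
    popIdx <- rep(seq_len(npop), each = nper)
    radii <- (cd$diameter_um[popIdx] / 2 / config@pixelSize) *
      pmax(0.2, 1 + config@radiusCV * stats::rnorm(n))

    # spatial hash grid with cell size >= dmin: candidates need only be
    # checked against the 3x3 neighbourhood
    cell <- max(dmin, 1)
    ncr <- max(1L, as.integer(ceiling(H / cell)))
    ncc <- max(1L, as.integer(ceiling(W / cell)))
    grid <- vector("list", ncr * ncc)
    rows <- numeric(n); cols <- numeric(n)
    for (i in seq_len(n)) {
      placed <- FALSE
      for (att in seq_len(config@maxPlacementAttempts)) {
        rr <- stats::runif(1, margin, H - margin)
        cc <- stats::runif(1, margin, W - margin)
        ci <- as.integer(ceiling(rr / cell)); cj <- as.integer(ceiling(cc / cell))
        ni <- max(1L, ci - 1L):min(ncr, ci + 1L)
        nj <- max(1L, cj - 1L):min(ncc, cj + 1L)
        nb <- unlist(grid[outer(ni, (nj - 1L) * ncr, "+")], use.names = FALSE)
        if (!length(nb) ||
            all((rows[nb] - rr)^2 + (cols[nb] - cc)^2 >= dmin^2)) {
          rows[i] <- rr; cols[i] <- cc
          k <- ci + (cj - 1L) * ncr
          grid[[k]] <- c(grid[[k]], i)
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop(sprintf(paste("placement capacity exceeded: bead %d of %d could not",
                           "be placed at min distance %.3g um within %d attempts"),
                     i, n, config@minCenterDistance, config@maxPlacementAttempts))
    }

    enc1 <- cd$enc1[popIdx] * pmax(0.05, 1 + config@encodingCV * stats::rnorm(n))
    enc2 <- cd$enc2[popIdx] * pmax(0.05, 1 + config@encodingCV * stats::rnorm(n))
    amp <- unname(config@haloAmplitudes[cd$population[popIdx]])
    out <- data.frame(bead = seq_len(n), row = rows, col = cols,
                      radius_px = radii, population = cd$population[popIdx],
                      enc1 = enc1, enc2 = enc2, halo_amp = amp,
                      doublet = FALSE, stringsAsFactors = FALSE)

    if (config@doubletFraction > 0) {
      nd <- round(config@doubletFraction * n)
      if (nd > 0) {
        host <- sample.int(n, nd)
        cpop <- sample.int(npop, nd, replace = TRUE)
        crad <- (cd$diameter_um[cpop] / 2 / config@pixelSize) *
          pmax(0.2, 1 + config@radiusCV * stats::rnorm(nd))
        ang <- stats::runif(nd, 0, 2 * pi)
        sep <- 0.95 * (out$radius_px[host] + crad)
        crow <- pmin(pmax(out$row[host] + sep * sin(ang), margin), H - margin)
        ccol <- pmin(pmax(out$col[host] + sep * cos(ang), margin), W - margin)
        comp <- data.frame(bead = n + seq_len(nd), row = crow, col = ccol,
                           radius_px = crad, population = cd$population[cpop],
                           enc1 = cd$enc1[cpop] *
                             pmax(0.05, 1 + config@encodingCV * stats::rnorm(nd)),
                           enc2 = cd$enc2[cpop] *
                             pmax(0.05, 1 + config@encodingCV * stats::rnorm(nd)),
                           halo_amp = unname(config@haloAmplitudes[cd$population[cpop]]),
                           doublet = TRUE, stringsAsFactors = FALSE)
        out$doublet[host] <- TRUE
        out <- rbind(out, comp)
      }
    }
    out
  })
}

#' Render a bead layout into a chip image
#'
#' Encoding channels receive, per bead, a filled disk with a soft Gaussian
#' edge at the bead's true encoding intensities. The measurement channel
#' receives a radial ring centred at the bead radius with Gaussian radial
#' profile (amplitude = the bead's true halo amplitude, sd = `haloWidth`),
#' emulating surface-bound label imaged as a rim halo. Everything rides on
#' `backgroundLevel`. Optional Poisson shot noise (variance = mean) is
#' applied first, then additive Gaussian read noise; values are rounded and
#' clipped to the 16-bit range. Rendering is bit-identical for a fixed
#' layout, configuration and seed.
#'
#' @param layout data.frame from [sampleBeadLayout()] (or equivalent).
#' @param config a [SimConfig-class].
#' @param well well identifier stored in the image.
#' @param frame frame index (kinetic series).
#' @param time acquisition time in seconds (NA for single images).
#' @param seedOffset integer added to `config@seed` for the noise stream so
#'   different frames of one series get independent noise.
#' @return A [ChipImage-class].
#' @export
renderChipImage <- function(layout, config, well = "W01", frame = 1L,
                            time = NA_real_, seedOffset = 0L) {
  validObject(config)
  H <- config@imageShape[1]; W <- config@imageShape[2]
  if (nrow(layout)) {
    need <- c("row", "col", "radius_px", "enc1", "enc2", "halo_amp")
    if (!all(need %in% names(layout)))
      stop("layout must have columns: ", paste(need, collapse = ", "))
    out <- layout$row + layout$radius_px < 1 | layout$row - layout$radius_px > H |
           layout$col + layout$radius_px < 1 | layout$col - layout$radius_px > W
    if (any(out))
      stop(sprintf("%d bead(s) lie fully outside the image", sum(out)))
  }

  sigmaH <- config@haloWidth / config@pixelSize
  esoft <- config@edgeSoftness
  e1 <- matrix(config@backgroundLevel, H, W)
  e2 <- matrix(config@backgroundLevel, H, W)
  me <- matrix(config@backgroundLevel, H, W)
  rowv <- layout$row; colv <- layout$col; radv <- layout$radius_px
  en1 <- layout$enc1; en2 <- layout$enc2; hav <- layout$halo_amp
  for (i in seq_len(nrow(layout))) {
    hw <- ceiling(radv[i] + max(4 * esoft, 3.5 * sigmaH) + 1)
    r0 <- max(1L, floor(rowv[i] - hw)); r1 <- min(H, ceiling(rowv[i] + hw))
    c0 <- max(1L, floor(colv[i] - hw)); c1 <- min(W, ceiling(colv[i] + hw))
    if (r0 > r1 || c0 > c1) next
    dd <- sqrt(outer(((r0:r1) - rowv[i])^2, ((c0:c1) - colv[i])^2, "+")) -
      radv[i]
    # symmetric blurred rim: a hard sphere edge imaged through Gaussian
    # optics; the half-maximum contour sits exactly at the true radius
    disk <- stats::pnorm(-dd / esoft)
    ring <- exp(-dd^2 / (2 * sigmaH^2))
    e1[r0:r1, c0:c1] <- e1[r0:r1, c0:c1] + en1[i] * disk
    e2[r0:r1, c0:c1] <- e2[r0:r1, c0:c1] + en2[i] * disk
    me[r0:r1, c0:c1] <- me[r0:r1, c0:c1] + hav[i] * ring
  }
  img <- array(c(e1, e2, me), dim = c(H, W, 3L),
               dimnames = list(NULL, NULL, CHANNEL_NAMES))

  img <- withr::with_seed(config@seed + 1000003L + as.integer(seedOffset), {
    if (config@shotNoise)
      img[] <- stats::rpois(length(img), lambda = pmax(img, 0))
    if (config@readNoiseSD > 0)
      img[] <- img + stats::rnorm(length(img), sd = config@readNoiseSD)
    img
  })
  img[] <- pmin(pmax(round(img), 0), 65535)
  new("ChipImage", channels = img, pixelSize = config@pixelSize,
      well = as.character(well), frame = as.integer(frame),
      time = as.numeric(time))
}

#' Simulate a kinetic frame series of one well
#'
#' The bead layout (positions, radii, encoding) is fixed across frames --
#' beads have settled -- while each bead's halo amplitude follows
#' `amplitudeFun(t)` evaluated at the frame times, emulating real-time
#' binding signal development. Each frame gets an independent noise stream.
#'
#' @param config a [SimConfig-class]; its `haloAmplitudes` are ignored in
#'   favour of `amplitudeFun`.
#' @param times strictly increasing frame times (s).
#' @param amplitudeFun function(time) returning a named numeric of halo
#'   amplitudes per population.
#' @param well well identifier.
#' @return list with `frames` (list of [ChipImage-class]), `layout` (the
#'   shared truth layout) and `truth` (data.frame population, time,
#'   true_amplitude).
#' @export
simulateKineticSeries <- function(config, times, amplitudeFun, well = "W01") {
  stopifnot(length(times) >= 1L, !is.unsorted(times, strictly = TRUE))
  layout <- sampleBeadLayout(config)
  pops <- config@panel@codes$population
  frames <- vector("list", length(times))
  truth <- NULL
  for (k in seq_along(times)) {
    amp <- amplitudeFun(times[k])
    if (!all(pops %in% names(amp)))
      stop("amplitudeFun must name every panel population")
    lay <- layout
    lay$halo_amp <- unname(amp[lay$population])
    frames[[k]] <- renderChipImage(lay, config, well = well, frame = k,
                                   time = times[k], seedOffset = k)
    truth <- rbind(truth, data.frame(population = pops, time = times[k],
                                     true_amplitude = unname(amp[pops]),
                                     stringsAsFactors = FALSE))
  }
  list(frames = frames, layout = layout, truth = truth)
}

#' Dose-response amplitude model for the default synthetic screen
#'
#' Returns a function mapping a condition covariate (e.g. NaCl in mM) to
#' per-population true halo amplitudes. Target populations follow
#' monotone-decreasing binding curves -- the interferon-gamma target an
#' exponential decay, the others three-parameter log-logistic curves with
#' staggered midpoints -- mirroring suppression of electrostatically driven
#' aptamer binding by increasing ionic strength. Specificity-control
#' populations stay at a constant low amplitude.
#'
#' @param panel a [ReferencePanel-class] (default [defaultPanel()]).
#' @param targetAmplitude upper-asymptote amplitude for targets (a.u.).
#' @param controlAmplitude constant amplitude for non-targets (a.u.).
#' @return function(dose) -> named numeric of amplitudes per population.
#' @export
defaultScreenModel <- function(panel = defaultPanel(),
                               targetAmplitude = 800,
                               controlAmplitude = 150) {
  cd <- panel@codes
  pars <- list(IFNG = list(family = "EXD.2", e = 200),
               THRB = list(family = "LL.3", b = 2, e = 150),
               STRAV = list(family = "LL.3", b = 2.5, e = 250),
               PFLDH = list(family = "LL.3", b = 1.5, e = 350))
  function(dose) {
    amp <- stats::setNames(rep(controlAmplitude, nrow(cd)), cd$population)
    for (i in seq_len(nrow(cd))) {
      p <- pars[[cd$protein[i]]]
      if (is.null(p)) next
      amp[i] <- if (p$family == "EXD.2") {
        targetAmplitude * exp(-dose / p$e)
      } else {
        targetAmplitude / (1 + (dose / p$e)^p$b)
      }
    }
    amp
  }
}

#' Generate a full synthetic screen dataset
#'
#' One chip image per experiment design row, with the per-population true
#' halo amplitudes taken from `responseModel` evaluated at the row's dose
#' covariate. A sidecar truth table accompanies each image; when `outDir`
#' is given, images are written as multi-page TIFF and truth tables as CSV.
#'
#' @param design data.frame with columns `well`, `condition`, `dose` and
#'   optionally `aptamer`, `reference`.
#' @param config a [SimConfig-class]; each row uses seed
#'   `config@seed + row index` so wells differ but the set is reproducible.
#' @param responseModel function(dose) -> named amplitudes per population,
#'   e.g. [defaultScreenModel()]. Referencing a population absent from the
#'   panel is an error.
#' @param outDir optional output directory.
#' @return list with one element per design row: `image`, `truth` (the
#'   layout ground truth), `trueAmplitudes`, `design` (the row).
#' @export
generateScreenDataset <- function(design, config, responseModel, outDir = NULL) {
  stopifnot(all(c("well", "condition", "dose") %in% names(design)))
  pops <- config@panel@codes$population
  if (!is.null(outDir) && !dir.exists(outDir))
    dir.create(outDir, recursive = TRUE)
  out <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    amp <- responseModel(design$dose[i])
    if (!all(names(amp) %in% pops))
      stop("response model references unknown population(s): ",
           paste(setdiff(names(amp), pops), collapse = ", "))
    if (!all(pops %in% names(amp)))
      stop("response model must cover every panel population")
    cfg <- config
    cfg@haloAmplitudes <- amp[pops]
    cfg@seed <- config@seed + i
    layout <- sampleBeadLayout(cfg)
    img <- renderChipImage(layout, cfg, well = design$well[i])
    if (!is.null(outDir)) {
      base <- file.path(outDir, design$well[i])
      writeChipTiff(img, paste0(base, ".tif"))
      writeTruthTable(layout, paste0(base, "_truth.csv"))
    }
    out[[i]] <- list(image = img, truth = layout,
                     trueAmplitudes = amp[pops], design = design[i, ])
  }
  names(out) <- design$well
  out
}

#' Write / read a ground-truth bead table as CSV
#'
#' @param layout data.frame from [sampleBeadLayout()].
#' @param path file path.
#' @return `readTruthTable` returns the data.frame; `writeTruthTable`
#'   returns `path` invisibly.
#' @export
writeTruthTable <- function(layout, path) {
  utils::write.csv(layout, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTruthTable
#' @export
readTruthTable <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
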