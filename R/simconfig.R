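#' @include AllClasses.R panel.R
NULL

#' Construct a simulation configuration
#'
#' All arguments have defaults chosen to emulate a typical encoded-bead chip
#' well: roughly 500-1000 beads per population settle into a monolayer, two
#' bead size classes, population-specific blue/green encoding ratios with a
#' 5% dye coefficient of variation, and a Cy5-like surface halo in the
#' measurement channel riding on a flat background with shot and read noise.
#'
#' @param panel a [ReferencePanel-class]; default [defaultPanel()].
#' @param imageShape height, width in pixels.
#' @param pixelSize um per pixel.
#' @param beadsPerPopulation beads laid out per population (default 500,
#'   the low end of the typical 500-1000 beads loaded per population).
#' @param minCenterDistance minimum pairwise bead center distance (um);
#'   must be at least the largest bead diameter unless doublets are
#'   explicitly enabled.
#' @param haloAmplitudes named numeric of measurement-channel ring
#'   amplitudes (a.u.) per population; a scalar is recycled to all
#'   populations. Default: 800 a.u. on the four target populations, 150
#'   a.u. on specificity controls.
#' @param haloWidth radial Gaussian sd of the halo ring (um). The default
#'   of 2 um is the thin surface shell broadened by optical blur.
#' @param backgroundLevel additive background in all channels (a.u.).
#' @param encodingCV per-bead CV of the encoding intensities.
#' @param radiusCV per-bead CV of the bead radius.
#' @param readNoiseSD additive Gaussian read noise sd (a.u.).
#' @param shotNoise logical; Poisson shot noise with intensities treated as
#'   photon counts (variance = mean).
#' @param doubletFraction fraction of beads that receive a touching
#'   companion (default 0: no clumps).
#' @param edgeSoftness Gaussian softness of the bead disk edge (px).
#' @param maxPlacementAttempts rejection-sampling attempts allowed per bead
#'   before a capacity error is raised.
#' @param seed integer RNG seed; the full image stack is bit-reproducible
#'   for a fixed configuration and seed.
#' @return A validated [SimConfig-class].
#' @examples
#' cfg <- simConfig(beadsPerPopulation = 20, imageShape = c(512, 512))
#' cfg
#' @export
simConfig <- function(panel = defaultPanel(),
                      imageShape = c(3072L, 3072L),
                      pixelSize = 1,
                      beadsPerPopulation = 500L,
                      minCenterDistance = 20,
                      haloAmplitudes = NULL,
                      haloWidth = 2,
                      backgroundLevel = 100,
                      encodingCV = 0.05,
                      radiusCV = 0.02,
                      readNoiseSD = 10,
                      shotNoise = TRUE,
                      doubletFraction = 0,
                      edgeSoftness = 0.8,
                      maxPlacementAttempts = 200L,
                      seed = 1L) {
  pops <- panel@codes$population
  if (is.null(haloAmplitudes)) {
    targets <- c("IFNG", "THRB", "STRAV", "PFLDH")
    haloAmplitudes <- ifelse(panel@codes$protein %in% targets, 800, 150)
    names(haloAmplitudes) <- pops
  } else if (is.null(names(haloAmplitudes))) {
    haloAmplitudes <- stats::setNames(rep_len(haloAmplitudes, length(pops)), pops)
  }
  storage.mode(haloAmplitudes) <- "double"
  new("SimConfig",
      imageShape = as.integer(imageShape),
      pixelSize = as.numeric(pixelSize),
      panel = panel,
      beadsPerPopulation = as.integer(beadsPerPopulation),
      minCenterDistance = as.numeric(minCenterDistance),
      haloAmplitudes = haloAmplitudes,
      haloWidth = as.numeric(haloWidth),
      backgroundLevel = as.numeric(backgroundLevel),
      encodingCV = as.numeric(encodingCV),
      radiusCV = as.numeric(radiusCV),
      readNoiseSD = as.numeric(readNoiseSD),
      shotNoise = isTRUE(shotNoise),
      doubletFraction = as.numeric(doubletFraction),
      edgeSoftness = as.numeric(edgeSoftness),
      maxPlacementAttempts = as.integer(maxPlacementAttempts),
      seed = as.integer(seed))
}

#' Read a simulation configuration from YAML
#'
#' Accepts the scalar `simConfig()` arguments as top-level keys plus an
#' optional `panel` block (either a path to a panel CSV under key `csv`, or
#' the per-population vectors accepted by [referencePanel()]) and an
#' optional named `haloAmplitudes` mapping.
#'
#' @param path YAML file path.
#' @return A [SimConfig-class].
#' @export
readSimConfig <- function(path) {
  y <- yaml::read_yaml(path)
  panel <- if (is.null(y$panel)) {
    defaultPanel()
  } else if (!is.null(y$panel$csv)) {
    readPanel(y$panel$csv)
  } else {
    do.call(referencePanel, y$panel)
  }
  args <- y[setdiff(names(y), "panel")]
  if (!is.null(args$haloAmplitudes))
    args$haloAmplitudes <- unlist(args$haloAmplitudes)
  do.call(simConfig, c(list(panel = panel), args))
}
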