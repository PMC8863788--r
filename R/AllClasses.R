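#' @import methods
NULL

CHANNEL_NAMES <- c("encode1", "encode2", "measure")

#' QC flag vocabulary for bead measurements
#'
#' Fixed set of quality-control flags a bead can carry after analysis.
#' `"ok"` beads enter population summaries; all other flags exclude the bead
#' and are counted separately.
#'
#' @return Character vector of valid QC flags.
#' @export
qcFlags <- function() {
  c("ok", "edge", "low_circularity", "doublet", "ratio_undefined",
    "unclassified", "halo_edge", "background_fallback")
}

#' ReferencePanel: the dye/size code book of a bead mixture
#'
#' An S4 class describing the encoded microbead populations present in a
#' multiplex mixture: for each population its identifier, the coupled
#' protein, the nominal bead diameter and the nominal intensities of the two
#' encoding dyes, plus the feature dispersions used to gate decoding.
#'
#' Populations are decoded in the two-dimensional feature space
#' (log encoding ratio, bead radius); the dispersion columns
#' `sd_log_ratio` and `sd_radius_um` set the standardised-distance scale.
#'
#' @slot codes data.frame with columns `population`, `protein`,
#'   `diameter_um`, `enc1`, `enc2`, `sd_log_ratio`, `sd_radius_um`.
#' @export
setClass("ReferencePanel", representation(codes = "data.frame"))

setValidity("ReferencePanel", function(object) {
  cd <- object@codes
  need <- c("population", "protein", "diameter_um", "enc1", "enc2",
            "sd_log_ratio", "sd_radius_um")
  if (!all(need %in% names(cd)))
    return(paste("codes must have columns:", paste(need, collapse = ", ")))
  if (nrow(cd) < 1L) return("panel must contain at least one population")
  if (anyDuplicated(cd$population)) return("population ids must be unique")
  if (any(cd$diameter_um <= 0)) return("diameters must be positive")
  if (any(cd$enc1 <= 0) || any(cd$enc2 <= 0))
    return("nominal encoding intensities must be positive")
  if (any(cd$sd_log_ratio <= 0) || any(cd$sd_radius_um <= 0))
    return("feature dispersions must be positive")
  # decodability: no two populations may coincide in (log ratio, radius)
  # within their stated dispersions
  if (nrow(cd) > 1L) {
    lr <- log(cd$enc1 / cd$enc2)
    rad <- cd$diameter_um / 2
    for (i in seq_len(nrow(cd) - 1L)) {
      for (j in seq((i + 1L), nrow(cd))) {
        dz <- sqrt(((lr[i] - lr[j]) / max(cd$sd_log_ratio[i], cd$sd_log_ratio[j]))^2 +
                   ((rad[i] - rad[j]) / max(cd$sd_radius_um[i], cd$sd_radius_um[j]))^2)
        if (dz < 1)
          return(sprintf("populations '%s' and '%s' are not separable within their dispersions",
                         cd$population[i], cd$population[j]))
      }
    }
  }
  TRUE
})

#' SimConfig: parameters of the synthetic chip generator
#'
#' Captures everything needed to lay out and render one synthetic bead chip:
#' the raster geometry, the reference panel, bead counts and placement
#' constraints, the halo model for the measurement channel, and the noise
#' model. A fixed `seed` makes layout and rendering bit-reproducible.
#'
#' @slot imageShape integer(2), image height and width in pixels.
#' @slot pixelSize numeric, micrometres per pixel.
#' @slot panel ReferencePanel.
#' @slot beadsPerPopulation integer, beads laid out per population.
#' @slot minCenterDistance numeric, minimum pairwise center distance (um).
#' @slot haloAmplitudes named numeric, measurement-channel ring amplitude
#'   (a.u.) per population id.
#' @slot haloWidth numeric, Gaussian radial sd of the halo ring (um).
#' @slot backgroundLevel numeric, additive background in every channel (a.u.).
#' @slot encodingCV numeric in [0,1), coefficient of variation of per-bead
#'   encoding intensities around the population nominal.
#' @slot radiusCV numeric in [0,1), coefficient of variation of bead radii.
#' @slot readNoiseSD numeric, additive Gaussian read noise sd (a.u.).
#' @slot shotNoise logical, Poisson shot noise (intensities treated as
#'   photon counts).
#' @slot doubletFraction numeric in [0,1), fraction of beads given a
#'   touching companion bead.
#' @slot edgeSoftness numeric, Gaussian softness of the bead disk edge (px).
#' @slot maxPlacementAttempts integer, rejection-sampling budget per bead.
#' @slot seed integer RNG seed.
#' @export
setClass("SimConfig", representation(
  imageShape = "integer",
  pixelSize = "numeric",
  panel = "ReferencePanel",
  beadsPerPopulation = "integer",
  minCenterDistance = "numeric",
  haloAmplitudes = "numeric",
  haloWidth = "numeric",
  backgroundLevel = "numeric",
  encodingCV = "numeric",
  radiusCV = "numeric",
  readNoiseSD = "numeric",
  shotNoise = "logical",
  doubletFraction = "numeric",
  edgeSoftness = "numeric",
  maxPlacementAttempts = "integer",
  seed = "integer"
))

setValidity("SimConfig", function(object) {
  if (length(object@imageShape) != 2L || any(object@imageShape < 16L))
    return("imageShape must be two integers >= 16")
  if (object@pixelSize <= 0) return("pixelSize must be positive")
  if (object@beadsPerPopulation < 0L)
    return("beadsPerPopulation must be >= 0")
  if (any(object@haloAmplitudes < 0)) return("halo amplitudes must be >= 0")
  if (object@haloWidth <= 0) return("haloWidth must be positive")
  if (object@backgroundLevel < 0) return("backgroundLevel must be >= 0")
  if (object@encodingCV < 0 || object@encodingCV >= 1)
    return("encodingCV must be in [0, 1)")
  if (object@radiusCV < 0 || object@radiusCV >= 1)
    return("radiusCV must be in [0, 1)")
  if (object@readNoiseSD < 0) return("readNoiseSD must be >= 0")
  if (object@doubletFraction < 0 || object@doubletFraction >= 1)
    return("doubletFraction must be in [0, 1)")
  pops <- object@panel@codes$population
  if (!all(pops %in% names(object@haloAmplitudes)))
    return("haloAmplitudes must name every population in the panel")
  if (object@doubletFraction == 0 &&
      object@minCenterDistance < max(object@panel@codes$diameter_um))
    return("minCenterDistance must be >= the largest bead diameter when overlap is disabled")
  TRUE
})

#' ChipImage: one multi-channel well image
#'
#' Raster container for one imaged well at one time point: two encoding
#' channels (the internal blue/green population dyes) and one measurement
#' channel (the surface label whose rim halo reports binding). Pixel values
#' are 16-bit arbitrary units stored as numeric; coordinates are (row, col)
#' with pixel centers at integer positions, 1-based as usual in R.
#'
#' @slot channels numeric array height x width x 3, channel names
#'   `encode1`, `encode2`, `measure`.
#' @slot pixelSize numeric, micrometres per pixel.
#' @slot well character well identifier.
#' @slot frame integer frame index (kinetic series), 1 for a single image.
#' @slot time numeric acquisition time (s), NA when not a kinetic series.
#' @export
setClass("ChipImage", representation(
  channels = "array",
  pixelSize = "numeric",
  well = "character",
  frame = "integer",
  time = "numeric"
))

setValidity("ChipImage", function(object) {
  d <- dim(object@channels)
  if (length(d) != 3L || d[3] != 3L)
    return("channels must be a height x width x 3 array")
  nm <- dimnames(object@channels)[[3]]
  if (is.null(nm) || !identical(nm, CHANNEL_NAMES))
    return(sprintf("channel names must be %s", paste(CHANNEL_NAMES, collapse = ", ")))
  if (object@pixelSize <= 0) return("pixelSize must be positive")
  if (any(object@channels < 0, na.rm = TRUE))
    return("pixel values must be >= 0")
  TRUE
})

#' FittedModel: one fitted dose-response model
#'
#' Result of least-squares fitting of one candidate dose-response family.
#' Parameters follow the conventional naming: `b` slope, `c` lower
#' asymptote, `d` upper asymptote, `e` location (dose units), `f` asymmetry
#' (five-parameter log-logistic only). Fixed parameters (e.g. `c = 0` in
#' LL.3) are reported at their fixed values.
#'
#' @slot family character, model family code (e.g. "LL.3", "EXD.2").
#' @slot parameters named numeric, all parameters including fixed ones.
#' @slot free character, names of the freely estimated parameters.
#' @slot rss numeric, residual sum of squares on the original response scale.
#' @slot n integer, number of observations.
#' @slot aic numeric, n*log(RSS/n) + 2*(p+1) with p = length(free).
#' @slot ed50 numeric, dose at the response midpoint between the asymptotes.
#' @slot converged logical.
#' @slot message character, optimizer diagnostics.
#' @slot normalization numeric, response scale factor used for families with
#'   a fixed upper asymptote of 1 (LL.2, W1.2); 1 otherwise.
#' @export
setClass("FittedModel", representation(
  family = "character",
  parameters = "numeric",
  free = "character",
  rss = "numeric",
  n = "integer",
  aic = "numeric",
  ed50 = "numeric",
  converged = "logical",
  message = "character",
  normalization = "numeric"
))

setValidity("FittedModel", function(object) {
  if (length(object@rss) == 1L && !is.na(object@rss) && object@rss < 0)
    return("rss must be >= 0")
  if (!is.na(object@ed50) && object@ed50 <= 0)
    return("ed50 must be positive when defined")
  TRUE
})
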