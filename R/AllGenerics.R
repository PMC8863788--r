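#' @include AllClasses.R
NULL

#' Accessors for HaloScreen classes
#'
#' @param x a HaloScreen object.
#' @param name channel name, one of `"encode1"`, `"encode2"`, `"measure"`.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("channel", function(x, name) standardGeneric("channel"))

#' @rdname accessors
#' @export
setMethod("channel", "ChipImage", function(x, name) {
  name <- match.arg(name, CHANNEL_NAMES)
  x@channels[, , name]
})

#' @rdname accessors
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname accessors
#' @export
setMethod("pixelSize", "ChipImage", function(x) x@pixelSize)

#' @rdname accessors
#' @export
setMethod("pixelSize", "SimConfig", function(x) x@pixelSize)

#' @rdname accessors
#' @export
setGeneric("imageShape", function(x) standardGeneric("imageShape"))

#' @rdname accessors
#' @export
setMethod("imageShape", "ChipImage", function(x) dim(x@channels)[1:2])

#' @rdname accessors
#' @export
setGeneric("wellId", function(x) standardGeneric("wellId"))

#' @rdname accessors
#' @export
setMethod("wellId", "ChipImage", function(x) x@well)

#' @rdname accessors
#' @export
setGeneric("frameIndex", function(x) standardGeneric("frameIndex"))

#' @rdname accessors
#' @export
setMethod("frameIndex", "ChipImage", function(x) x@frame)

#' @rdname accessors
#' @export
setGeneric("frameTime", function(x) standardGeneric("frameTime"))

#' @rdname accessors
#' @export
setMethod("frameTime", "ChipImage", function(x) x@time)

#' @rdname accessors
#' @export
setGeneric("panelCodes", function(x) standardGeneric("panelCodes"))

#' @rdname accessors
#' @export
setMethod("panelCodes", "ReferencePanel", function(x) x@codes)

#' @rdname accessors
#' @export
setMethod("panelCodes", "SimConfig", function(x) x@panel@codes)

#' @rdname accessors
#' @export
setGeneric("populations", function(x) standardGeneric("populations"))

#' @rdname accessors
#' @export
setMethod("populations", "ReferencePanel", function(x) x@codes$population)

#' @rdname accessors
#' @export
setMethod("populations", "SimConfig", function(x) x@panel@codes$population)

#' @rdname accessors
#' @export
setGeneric("modelFamily", function(x) standardGeneric("modelFamily"))

#' @rdname accessors
#' @export
setMethod("modelFamily", "FittedModel", function(x) x@family)

#' @rdname accessors
#' @export
setGeneric("modelParameters", function(x) standardGeneric("modelParameters"))

#' @rdname accessors
#' @export
setMethod("modelParameters", "FittedModel", function(x) x@parameters)

#' @rdname accessors
#' @export
setGeneric("modelAIC", function(x) standardGeneric("modelAIC"))

#' @rdname accessors
#' @export
setMethod("modelAIC", "FittedModel", function(x) x@aic)

#' @rdname accessors
#' @export
setGeneric("isConverged", function(x) standardGeneric("isConverged"))

#' @rdname accessors
#' @export
setMethod("isConverged", "FittedModel", function(x) x@converged)

setMethod("show", "ReferencePanel", function(object) {
  cd <- object@codes
  cat(sprintf("ReferencePanel with %d population(s)\n", nrow(cd)))
  cat(sprintf("  diameters (um): %s\n",
              paste(sort(unique(cd$diameter_um)), collapse = ", ")))
  cat(sprintf("  encoding ratio range: %.3g .. %.3g\n",
              min(cd$enc1 / cd$enc2), max(cd$enc1 / cd$enc2)))
  invisible(NULL)
})

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig\n")
  cat(sprintf("  image: %d x %d px at %.3g um/px\n",
              object@imageShape[1], object@imageShape[2], object@pixelSize))
  cat(sprintf("  %d population(s) x %d bead(s); min center distance %.3g um\n",
              nrow(object@panel@codes), object@beadsPerPopulation,
              object@minCenterDistance))
  cat(sprintf("  halo width %.3g um, background %.3g a.u., encoding CV %.3g\n",
              object@haloWidth, object@backgroundLevel, object@encodingCV))
  cat(sprintf("  noise: shot=%s, read sd=%.3g; seed %d\n",
              object@shotNoise, object@readNoiseSD, object@seed))
  invisible(NULL)
})

setMethod("show", "ChipImage", function(object) {
  d <- dim(object@channels)
  cat(sprintf("ChipImage well '%s' frame %d: %d x %d px, 3 channels (%s)\n",
              object@well, object@frame, d[1], d[2],
              paste(CHANNEL_NAMES, collapse = ", ")))
  cat(sprintf("  pixel size %.3g um; measure channel range [%.4g, %.4g]\n",
              object@pixelSize, min(object@channels[, , 3]),
              max(object@channels[, , 3])))
  invisible(NULL)
})

setMethod("show", "FittedModel", function(object) {
  cat(sprintf("FittedModel %s (%s)\n", object@family,
              if (object@converged) "converged" else "NOT converged"))
  if (length(object@parameters)) {
    p <- paste(sprintf("%s=%.5g", names(object@parameters), object@parameters),
               collapse = ", ")
    cat("  parameters:", p, "\n")
  }
  cat(sprintf("  n=%d  RSS=%.6g  AIC=%.4f  ED50=%.6g\n",
              object@n, object@rss, object@aic, object@ed50))
  invisible(NULL)
})
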