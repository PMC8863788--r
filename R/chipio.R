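#' @include AllClasses.R
NULL

#' Write / read a chip image as multi-page 16-bit TIFF
#'
#' One TIFF page per channel, in the fixed order `encode1`, `encode2`,
#' `measure`. Pixel values are stored as 16-bit unsigned integers, so a
#' write/read round trip is lossless for rendered images. Well, frame and
#' pixel-size metadata are supplied on read because baseline TIFF carries
#' none.
#'
#' @param image a [ChipImage-class].
#' @param path TIFF file path.
#' @param pixelSize,well,frame,time metadata attached on read.
#' @return `writeChipTiff` returns `path` invisibly; `readChipTiff`
#'   returns a [ChipImage-class].
#' @export
writeChipTiff <- function(image, path) {
  stopifnot(is(image, "ChipImage"))
  pages <- lapply(CHANNEL_NAMES, function(ch)
    pmin(pmax(image@channels[, , ch], 0), 65535) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' @rdname writeChipTiff
#' @export
readChipTiff <- function(path, pixelSize = 1, well = "W01", frame = 1L,
                         time = NA_real_) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (length(pages) != 3L)
    stop("expected a 3-page TIFF (encode1, encode2, measure); got ",
         length(pages), " page(s)")
  d <- dim(pages[[1]])
  if (!all(vapply(pages, function(p) identical(dim(p), d), logical(1))))
    stop("TIFF pages differ in shape")
  img <- array(0, dim = c(d[1], d[2], 3L),
               dimnames = list(NULL, NULL, CHANNEL_NAMES))
  for (k in 1:3) img[, , k] <- pages[[k]]
  new("ChipImage", channels = img, pixelSize = as.numeric(pixelSize),
      well = as.character(well), frame = as.integer(frame),
      time = as.numeric(time))
}
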