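#' @include AllClasses.R
NULL

#' Construct a reference panel
#'
#' Builds a [ReferencePanel-class] from per-population vectors. The two
#' encoding dyes are read out as a ratio, so populations are separated in
#' (log ratio, bead radius) feature space; `sdLogRatio` and `sdRadius` are
#' the gating dispersions in those two dimensions. They should cover both
#' the manufacturing spread of the dyes (the encoding CV) and the
#' measurement error of the reader, which is why the defaults are somewhat
#' wider than a typical 5% dye CV alone would suggest.
#'
#' @param population character vector of unique population ids.
#' @param protein coupled protein name per population.
#' @param diameter nominal bead diameter (um).
#' @param enc1,enc2 nominal encoding intensities (a.u.).
#' @param sdLogRatio gating dispersion of log(enc1/enc2); default 0.1.
#' @param sdRadius gating dispersion of the bead radius (um); default 0.5.
#' @return A [ReferencePanel-class] object.
#' @seealso [defaultPanel()], [decodePopulation()]
#' @export
referencePanel <- function(population, protein, diameter, enc1, enc2,
                           sdLogRatio = 0.1, sdRadius = 0.5) {
  codes <- data.frame(
    population = as.character(population),
    protein = as.character(protein),
    diameter_um = as.numeric(diameter),
    enc1 = as.numeric(enc1),
    enc2 = as.numeric(enc2),
    sd_log_ratio = rep_len(as.numeric(sdLogRatio), length(population)),
    sd_radius_um = rep_len(as.numeric(sdRadius), length(population)),
    stringsAsFactors = FALSE
  )
  new("ReferencePanel", codes = codes)
}

#' Default 16-population demonstration panel
#'
#' Two bead size classes (10 and 15 um diameter) crossed with eight
#' encoding-ratio levels spaced 0.5 apart on the log scale. Four
#' populations carry the aptamer targets (interferon gamma, thrombin,
#' streptavidin, Plasmodium falciparum lactate dehydrogenase); the other
#' twelve carry non-target proteins and act as specificity controls.
#' Diameters and dye levels are simulator defaults, not vendor values.
#'
#' @param nPerSize number of ratio levels per size class (default 8).
#' @return A [ReferencePanel-class] with `2 * nPerSize` populations.
#' @export
defaultPanel <- function(nPerSize = 8L) {
  nPerSize <- as.integer(nPerSize)
  stopifnot(nPerSize >= 1L, nPerSize <= 12L)
  lev <- seq(-1.75, by = 0.5, length.out = nPerSize)
  targets <- c("IFNG", "THRB", "STRAV", "PFLDH")
  n <- 2L * nPerSize
  prot <- c(targets, sprintf("CTRL%02d", seq_len(max(0L, n - 4L))))[seq_len(n)]
  referencePanel(
    population = sprintf("P%02d", seq_len(n)),
    protein = prot,
    diameter = rep(c(10, 15), each = nPerSize),
    enc1 = round(1500 * exp(rep(lev, 2))),
    enc2 = rep(1500, n)
  )
}

#' Read / write a reference panel as CSV
#'
#' The CSV mirrors the `codes` table of [ReferencePanel-class]. Dispersion
#' columns are optional on read and filled with the [referencePanel()]
#' defaults when absent.
#'
#' @param path file path.
#' @param panel a [ReferencePanel-class].
#' @return `readPanel` returns a [ReferencePanel-class]; `writePanel`
#'   returns `path` invisibly.
#' @export
readPanel <- function(path) {
  cd <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("population", "protein", "diameter_um", "enc1", "enc2")
  if (!all(need %in% names(cd)))
    stop("panel CSV must have columns: ", paste(need, collapse = ", "))
  referencePanel(
    population = cd$population, protein = cd$protein,
    diameter = cd$diameter_um, enc1 = cd$enc1, enc2 = cd$enc2,
    sdLogRatio = if ("sd_log_ratio" %in% names(cd)) cd$sd_log_ratio else 0.1,
    sdRadius = if ("sd_radius_um" %in% names(cd)) cd$sd_radius_um else 0.5
  )
}

#' @rdname readPanel
#' @export
writePanel <- function(panel, path) {
  stopifnot(is(panel, "ReferencePanel"))
  utils::write.csv(panel@codes, path, row.names = FALSE)
  invisible(path)
}
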