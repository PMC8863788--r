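# Shared fixtures for the test suite, built in code. Expensive chips are
# cached per test run.

.fixtureCache <- new.env(parent = emptyenv())

# four-population mini panel: two sizes x two encoding ratios
miniPanel <- function() {
  referencePanel(
    population = c("A", "B", "C", "D"),
    protein = c("T1", "C1", "T2", "C2"),
    diameter = c(10, 10, 15, 15),
    enc1 = c(600, 3000, 600, 3000),
    enc2 = c(1500, 1500, 1500, 1500)
  )
}

miniConfig <- function(beads = 20L, shape = c(900L, 900L), seed = 101L, ...) {
  simConfig(panel = miniPanel(), beadsPerPopulation = beads,
            imageShape = shape,
            haloAmplitudes = c(A = 800, B = 150, C = 400, D = 0),
            seed = seed, ...)
}

# a rendered mini chip with its ground truth, cached
miniChip <- function() {
  if (is.null(.fixtureCache$miniChip)) {
    cfg <- miniConfig()
    lay <- sampleBeadLayout(cfg)
    img <- renderChipImage(lay, cfg)
    .fixtureCache$miniChip <- list(cfg = cfg, layout = lay, image = img)
  }
  .fixtureCache$miniChip
}

# analyzeChip output for the cached mini chip
miniMeasurements <- function() {
  if (is.null(.fixtureCache$miniMeas)) {
    ch <- miniChip()
    .fixtureCache$miniMeas <- analyzeChip(ch$image, ch$cfg@panel)
  }
  .fixtureCache$miniMeas
}

# standard NaCl dose grid used throughout the dose-response tests (mM)
naclDoses <- function(replicates = 3L) {
  rep(c(0, 25, 50, 100, 200, 400, 700, 1000), each = replicates)
}

# build a bare FittedModel for closed-form / prediction tests
mkFit <- function(family, parameters) {
  new("FittedModel", family = family, parameters = parameters,
      free = names(parameters), rss = 0, n = 8L, aic = 0,
      ed50 = NA_real_, converged = TRUE, message = "",
      normalization = 1)
}
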