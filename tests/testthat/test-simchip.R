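test_that("layout sampling respects counts, spacing and the empty case", {
  expect_identical(nrow(sampleBeadLayout(miniConfig(beads = 0L))), 0L)

  cfg <- simConfig(panel = miniPanel(),
                   beadsPerPopulation = 50L, imageShape = c(1200L, 1200L),
                   minCenterDistance = 20, seed = 5,
                   haloAmplitudes = c(A = 1, B = 1, C = 1, D = 1))
  lay <- sampleBeadLayout(cfg)
  expect_identical(nrow(lay), 200L)
  expect_identical(as.integer(table(lay$population)), rep(50L, 4))
  dmin <- min(dist(cbind(lay$row, lay$col)))
  expect_gte(dmin, 20)
  # centers inside bounds, radii positive
  expect_true(all(lay$row > 0 & lay$row <= 1200 & lay$col > 0 &
                  lay$col <= 1200))
  expect_true(all(lay$radius_px > 0))
})

test_that("per-bead encoding intensities follow the generator moments", {
  pan <- referencePanel("P", "X", 10, 2000, 2000)
  cfg <- simConfig(panel = pan, beadsPerPopulation = 1000L,
                   imageShape = c(3000L, 3000L), encodingCV = 0.05,
                   haloAmplitudes = c(P = 1), seed = 9)
  lay <- sampleBeadLayout(cfg)
  # sample mean within 3 * (nominal * cv / sqrt(n)) of the nominal
  band <- 3 * 2000 * 0.05 / sqrt(1000)
  expect_lt(abs(mean(lay$enc1) - 2000), band)
  expect_lt(abs(mean(lay$enc2) - 2000), band)
})

test_that("placement raises a capacity error when beads cannot fit", {
  cfg <- simConfig(panel = miniPanel(), beadsPerPopulation = 500L,
                   imageShape = c(256L, 256L), maxPlacementAttempts = 50L,
                   seed = 1)
  expect_error(sampleBeadLayout(cfg), "capacity")
})

test_that("simulation is bit-reproducible for a fixed seed", {
  cfg <- miniConfig(beads = 5L, shape = c(400L, 400L), seed = 77L)
  lay1 <- sampleBeadLayout(cfg); lay2 <- sampleBeadLayout(cfg)
  expect_identical(lay1, lay2)
  img1 <- renderChipImage(lay1, cfg); img2 <- renderChipImage(lay2, cfg)
  expect_identical(img1@channels, img2@channels)
})

test_that("noise-free rendering honours intensities, background and nulls", {
  cfg <- miniConfig(beads = 3L, shape = c(500L, 500L),
                    shotNoise = FALSE, readNoiseSD = 0, seed = 21L)
  lay <- sampleBeadLayout(cfg)
  img <- renderChipImage(lay, cfg)
  # encoding value at a bead center = that bead's intensity + background
  for (i in seq_len(nrow(lay))) {
    px <- img@channels[round(lay$row[i]), round(lay$col[i]), "encode1"]
    expect_lt(abs(px - (lay$enc1[i] + 100)) / (lay$enc1[i] + 100), 0.02)
  }
  # null binding: zero halo amplitude everywhere -> flat measure channel
  lay0 <- lay; lay0$halo_amp <- 0
  img0 <- renderChipImage(lay0, cfg)
  expect_true(all(img0@channels[, , "measure"] == 100))
  # 16-bit clipping
  expect_true(all(img@channels >= 0 & img@channels <= 65535))
})

test_that("rendering rejects beads fully outside the image", {
  cfg <- miniConfig(beads = 1L, shape = c(400L, 400L))
  lay <- sampleBeadLayout(cfg)
  lay$row[1] <- -50
  expect_error(renderChipImage(lay, cfg), "outside")
})

test_that("shot noise gives variance close to the mean on a flat region", {
  cfg <- simConfig(panel = miniPanel(), beadsPerPopulation = 0L,
                   imageShape = c(300L, 300L), backgroundLevel = 400,
                   haloAmplitudes = c(A = 0, B = 0, C = 0, D = 0),
                   shotNoise = TRUE, readNoiseSD = 0, seed = 3)
  img <- renderChipImage(sampleBeadLayout(cfg), cfg)
  px <- as.numeric(img@channels[, , "measure"])
  expect_lt(abs(var(px) / mean(px) - 1), 0.05)
})

test_that("doublet injection adds flagged companion beads", {
  cfg <- miniConfig(beads = 25L, shape = c(1000L, 1000L),
                    doubletFraction = 0.1, seed = 13L)
  lay <- sampleBeadLayout(cfg)
  # ground-truth conservation: primary records = beads per population sum
  expect_identical(sum(lay$bead <= 100L), 100L)
  expect_identical(nrow(lay), 100L + 10L)
  expect_identical(sum(lay$doublet[lay$bead > 100L]), 10L)
})

test_that("kinetic series shares the layout and ramps amplitudes", {
  cfg <- miniConfig(beads = 4L, shape = c(500L, 500L), seed = 31L)
  amp <- function(t) {
    a <- c(A = 100 + 100 * t, B = 50, C = 100 + 100 * t, D = 0)
    a
  }
  ks <- simulateKineticSeries(cfg, times = 1:5, amplitudeFun = amp)
  expect_length(ks$frames, 5L)
  aA <- ks$truth$true_amplitude[ks$truth$population == "A"]
  expect_true(all(diff(aA) > 0))
  expect_identical(vapply(ks$frames, frameIndex, integer(1)), 1:5)
})

test_that("screen generation writes one image and truth table per row", {
  design <- data.frame(well = c("W1", "W2", "W3"),
                       condition = c("0mM", "100mM", "400mM"),
                       dose = c(0, 100, 400))
  cfg <- miniConfig(beads = 3L, shape = c(500L, 500L))
  model <- function(dose) c(A = 400 / (1 + (dose / 150)^2), B = 50,
                            C = 300 * exp(-dose / 200), D = 10)
  out <- withr::with_tempdir({
    res <- generateScreenDataset(design, cfg, model, outDir = "screen")
    list(res = res, files = sort(list.files("screen")))
  })
  expect_length(out$res, 3L)
  expect_identical(out$files,
                   sort(c(paste0(design$well, ".tif"),
                          paste0(design$well, "_truth.csv"))))
  # per-row true amplitudes equal the model curve at the row's dose
  for (i in 1:3)
    expect_equal(out$res[[i]]$trueAmplitudes, model(design$dose[i])[c("A","B","C","D")])
  # unknown population in the model is an error
  badModel <- function(dose) c(A = 1, B = 1, C = 1, D = 1, ZZ = 5)
  expect_error(generateScreenDataset(design, cfg, badModel), "unknown")
})
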