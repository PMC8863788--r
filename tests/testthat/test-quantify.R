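test_that("noise-free halos recover amplitude and background exactly", {
  pan <- referencePanel("P", "X", 14, 2000, 1000)
  cfg <- simConfig(panel = pan, beadsPerPopulation = 5L,
                   imageShape = c(600L, 600L), shotNoise = FALSE,
                   readNoiseSD = 0, haloAmplitudes = c(P = 1000),
                   backgroundLevel = 100, seed = 17)
  lay <- sampleBeadLayout(cfg)
  img <- renderChipImage(lay, cfg)
  h <- measureHalo(img, detectBeads(img))
  expect_true(all(abs(h$halo_surface - 1000) / 1000 < 0.02))
  expect_true(all(abs(h$local_background - 100) / 100 < 0.02))

  # null binding
  cfg0 <- simConfig(panel = pan, beadsPerPopulation = 5L,
                    imageShape = c(600L, 600L), shotNoise = FALSE,
                    readNoiseSD = 0, haloAmplitudes = c(P = 0),
                    backgroundLevel = 100, seed = 17)
  img0 <- renderChipImage(sampleBeadLayout(cfg0), cfg0)
  h0 <- measureHalo(img0, detectBeads(img0))
  expect_true(all(abs(h0$halo_surface) < 5))
})

test_that("the halo estimator is unbiased under realistic noise", {
  ch <- miniChip()
  meas <- miniMeasurements()
  m <- matchDetections(meas, ch$layout)
  i <- match(m$matches$detection, meas$detection)
  j <- match(m$matches$bead, ch$layout$bead)
  ok <- meas$qc[i] == "ok"
  for (amp in c(800, 400, 150)) {
    sel <- ok & ch$layout$halo_amp[j] == amp
    v <- meas$halo_surface[i][sel]
    se <- sd(v) / sqrt(sum(sel))
    expect_lt(abs(mean(v) - amp), 4 * se)
  }
})

test_that("population summaries follow the stated arithmetic", {
  meas <- data.frame(detection = 1:4,
                     population = c("A", "A", "A", "A"),
                     halo_surface = c(10, 20, 30, 1000),
                     qc = c("ok", "ok", "ok", "doublet"),
                     stringsAsFactors = FALSE)
  s <- summarizePopulation(meas, "A", minBeads = 3L)
  expect_identical(s$n, 3L)
  expect_identical(s$rmfi, 20)
  expect_identical(s$sd, 10)
  expect_true(s$valid)
  # QC-failed bead excluded; dropping one more invalidates the summary
  s2 <- summarizePopulation(meas[-1, ], "A", minBeads = 3L)
  expect_identical(s2$n, 2L)
  expect_identical(s2$rmfi, 25)
  expect_false(s2$valid)
  # reference scale divides the statistic
  s3 <- summarizePopulation(meas, "A", referenceScale = 10, minBeads = 3L)
  expect_identical(s3$rmfi, 2)
})

test_that("halo surfaces are invariant to a constant measurement offset", {
  ch <- miniChip()
  meas <- miniMeasurements()
  imgOff <- ch$image
  imgOff@channels[, , "measure"] <- imgOff@channels[, , "measure"] + 500
  measOff <- analyzeChip(imgOff, ch$cfg@panel)
  s <- summarizeChip(meas, ch$cfg@panel)
  sOff <- summarizeChip(measOff, ch$cfg@panel)
  nz <- s$rmfi > 50
  expect_true(all(abs(sOff$rmfi[nz] - s$rmfi[nz]) / s$rmfi[nz] < 0.01))
})

test_that("rMFI is linear in the true halo amplitude", {
  cfg1 <- miniConfig(beads = 12L, shape = c(800L, 800L), seed = 91L)
  cfg2 <- miniConfig(beads = 12L, shape = c(800L, 800L), seed = 91L)
  cfg2@haloAmplitudes <- 2 * cfg1@haloAmplitudes
  s1 <- summarizeChip(analyzeChip(renderChipImage(sampleBeadLayout(cfg1), cfg1),
                                  cfg1@panel), cfg1@panel)
  s2 <- summarizeChip(analyzeChip(renderChipImage(sampleBeadLayout(cfg2), cfg2),
                                  cfg2@panel), cfg2@panel)
  nz <- s1$rmfi > 50
  expect_true(all(abs(s2$rmfi[nz] / s1$rmfi[nz] - 2) < 0.05))
})

test_that("kinetic traces track a ramped amplitude and reduce to one frame", {
  cfg <- miniConfig(beads = 12L, shape = c(800L, 800L), seed = 47L)
  amp <- function(t) c(A = 100 + 150 * t, B = 100 + 150 * t,
                       C = 100 + 150 * t, D = 100 + 150 * t)
  ks <- simulateKineticSeries(cfg, times = 1:5, amplitudeFun = amp)
  tr <- rmfiTimeSeries(ks$frames, cfg@panel)
  for (p in populations(cfg)) {
    v <- tr$rmfi[tr$population == p]
    expect_length(v, 5L)
    expect_true(all(diff(v) > 0))
  }
  # single frame reduces to the chip summary
  tr1 <- rmfiTimeSeries(ks$frames[1], cfg@panel)
  s1 <- summarizeChip(analyzeChip(ks$frames[[1]], cfg@panel), cfg@panel)
  expect_equal(tr1$rmfi, s1$rmfi[match(tr1$population, s1$population)])
})

test_that("constant-amplitude frames give a flat trace within noise", {
  cfg <- miniConfig(beads = 12L, shape = c(800L, 800L), seed = 53L)
  amp <- function(t) c(A = 500, B = 500, C = 500, D = 500)
  ks <- simulateKineticSeries(cfg, times = 1:3, amplitudeFun = amp)
  tr <- rmfiTimeSeries(ks$frames, cfg@panel)
  spread <- tapply(tr$rmfi, tr$population, function(v) diff(range(v)))
  expect_true(all(spread / 500 < 0.03))
})

test_that("frame series with incompatible shapes or wells are rejected", {
  cfg <- miniConfig(beads = 2L, shape = c(400L, 400L))
  cfgBig <- miniConfig(beads = 2L, shape = c(500L, 500L))
  f1 <- renderChipImage(sampleBeadLayout(cfg), cfg)
  f2 <- renderChipImage(sampleBeadLayout(cfgBig), cfgBig)
  expect_error(rmfiTimeSeries(list(f1, f2), cfg@panel), "shape")
})
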