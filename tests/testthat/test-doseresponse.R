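test_that("model equations satisfy their closed-form anchor points", {
  # LL.3 at x = e gives d/2 exactly
  expect_identical(drPredict("LL.3", c(b = 2, d = 100, e = 150), 150), 50)
  # EXD.2 intercept is d
  expect_identical(drPredict("EXD.2", c(d = 100, e = 200), 0), 100)
  # LL at x = 0 with positive slope is d, Weibull-2 starts at c
  expect_identical(drPredict("LL.4", c(b = 1, c = 10, d = 90, e = 50), 0), 90)
  expect_identical(drPredict("W2.3", c(b = 1.5, d = 90, e = 50), 0), 0)
  # monotone non-increasing over a dose grid for b > 0
  grid <- seq(0, 2000, by = 10)
  y <- drPredict("LL.3", c(b = 2, d = 100, e = 150), grid)
  expect_true(all(diff(y) <= 0))
  # domain error for non-positive location
  expect_error(drPredict("LL.3", c(b = 2, d = 100, e = -1), 10), "positive")
})

test_that("noise-free generating parameters are recovered to 0.1%", {
  cases <- list(
    list(family = "LL.3", p = c(b = 2, d = 100, e = 150)),
    list(family = "LL.4", p = c(b = 1.5, c = 20, d = 100, e = 200)),
    list(family = "W1.3", p = c(b = 1.2, d = 80, e = 180)),
    list(family = "EXD.2", p = c(d = 100, e = 200)),
    list(family = "EXD.3", p = c(c = 15, d = 100, e = 250))
  )
  doses <- naclDoses()
  for (cs in cases) {
    y <- drPredict(cs$family, cs$p, doses)
    fit <- fitDoseResponse(doses, y, cs$family)
    expect_true(isConverged(fit))
    est <- modelParameters(fit)[names(cs$p)]
    expect_true(all(abs(est - cs$p) / abs(cs$p) < 1e-3),
                info = cs$family)
    expect_lt(fit@rss, 1e-8 * sum(y^2))
  }
})

test_that("the returned fit is at least as good as the generating truth", {
  doses <- naclDoses()
  set.seed(31)
  for (rep in 1:5) {
    y <- drPredict("LL.3", c(b = 2, d = 100, e = 150), doses) *
      (1 + 0.05 * rnorm(length(doses)))
    fit <- fitDoseResponse(doses, y, "LL.3")
    rssTruth <- sum((y - drPredict("LL.3", c(b = 2, d = 100, e = 150),
                                   doses))^2)
    expect_lte(fit@rss, rssTruth + 1e-9)
  }
})

test_that("ED50 closed forms agree with numeric bisection", {
  cases <- list(
    mkFit("LL.3", c(b = 2, d = 100, e = 150)),
    mkFit("LL.4", c(b = -1.4, c = 10, d = 90, e = 80)),
    mkFit("LL.5", c(b = 2, c = 5, d = 100, e = 150, f = 1.7)),
    mkFit("W1.3", c(b = 1.5, d = 100, e = 180)),
    mkFit("W2.4", c(b = -2, c = 5, d = 95, e = 120)),
    mkFit("EXD.2", c(d = 100, e = 200)),
    mkFit("EXD.3", c(c = 10, d = 100, e = 300))
  )
  for (f in cases) {
    cf <- ed50(f)
    nm <- ed50Numeric(f)
    expect_lt(abs(cf - nm) / cf, 1e-6)
  }
  # the anchor values themselves
  expect_identical(ed50(mkFit("LL.3", c(b = 2, d = 100, e = 150))), 150)
  expect_equal(ed50(mkFit("EXD.2", c(d = 100, e = 200))), 200 * log(2))
})

test_that("ED50 is undefined for a flat response range", {
  f <- mkFit("LL.4", c(b = 1, c = 50, d = 50, e = 100))
  expect_error(ed50(f), "range")
  expect_error(ed50Numeric(f), "range")
})

test_that("AIC selection prefers the generating or an RSS-tied simpler model", {
  doses <- naclDoses()
  # exponential decay: richer families tie on RSS and lose on parameters
  y <- drPredict("EXD.2", c(d = 100, e = 200), doses)
  expect_identical(modelFamily(selectDoseResponse(doses, y)), "EXD.2")
  # a free lower asymptote is required when c != 0
  y4 <- drPredict("LL.4", c(b = 2, c = 20, d = 100, e = 150), doses)
  sel4 <- selectDoseResponse(doses, y4)
  expect_true("c" %in% sel4@free)
  expect_lt(abs(modelParameters(sel4)[["c"]] - 20), 0.1)
  # the AIC table covers all candidates
  expect_identical(attr(sel4, "aicTable")$family, drFamilies())
  expect_length(drFamilies(), 11L)
})

test_that("low-noise selection reproduces the generating curve", {
  doses <- naclDoses()
  truthPar <- c(b = 2, d = 100, e = 150)
  truthCurve <- drPredict("LL.3", truthPar, doses)
  set.seed(71)
  okCurve <- 0L
  nRuns <- 20L
  for (k in seq_len(nRuns)) {
    y <- truthCurve * (1 + 0.02 * rnorm(length(doses)))
    sel <- selectDoseResponse(doses, y)
    rmse <- sqrt(mean((predict(sel, doses) - truthCurve)^2))
    okCurve <- okCurve + (rmse < 0.05 * 100)
  }
  expect_gte(okCurve, round(0.9 * nRuns))
})

test_that("ED50 estimation error shrinks with replication", {
  truthPar <- c(b = 2, d = 100, e = 150)
  medianErr <- function(nrep, runs = 25L) {
    doses <- naclDoses(nrep)
    errs <- vapply(seq_len(runs), function(k) {
      y <- drPredict("LL.3", truthPar, doses) *
        (1 + 0.05 * rnorm(length(doses)))
      abs(fitDoseResponse(doses, y, "LL.3")@ed50 - 150) / 150
    }, numeric(1))
    median(errs)
  }
  set.seed(5)
  e2 <- medianErr(2L); e8 <- medianErr(8L); e32 <- medianErr(32L)
  expect_lt(e8, e2)
  expect_lt(e32, e8)
  expect_lt(e32, 0.02)
})

test_that("dose and response rescaling act on ED50 and RSS as expected", {
  doses <- naclDoses()
  set.seed(13)
  y <- drPredict("LL.3", c(b = 2, d = 100, e = 150), doses) *
    (1 + 0.03 * rnorm(length(doses)))
  f0 <- fitDoseResponse(doses, y, "LL.3")
  fx <- fitDoseResponse(doses * 3, y, "LL.3")
  expect_equal(fx@ed50, 3 * f0@ed50, tolerance = 1e-6)
  expect_equal(fx@rss, f0@rss, tolerance = 1e-6)
  fy <- fitDoseResponse(doses, y * 5, "LL.3")
  expect_equal(fy@ed50, f0@ed50, tolerance = 1e-6)
  expect_equal(fy@rss, 25 * f0@rss, tolerance = 1e-6)
  expect_equal(modelParameters(fy)[["d"]], 5 * modelParameters(f0)[["d"]],
               tolerance = 1e-6)
})

test_that("degenerate and underdetermined inputs are reported, not fitted", {
  doses <- naclDoses()
  flat <- fitDoseResponse(doses, rep(50, length(doses)), "LL.3")
  expect_false(isConverged(flat))
  expect_match(flat@message, "degenerate")
  few <- fitDoseResponse(rep(c(0, 100, 400), each = 2),
                         c(100, 99, 60, 61, 20, 21), "LL.4")
  expect_false(isConverged(few))
  expect_match(few@message, "distinct doses")
})
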