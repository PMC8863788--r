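test_that("percent change follows the signed arithmetic definition", {
  expect_identical(percentChange(200, 100), 100)
  expect_identical(percentChange(100, 100), 0)
  expect_identical(percentChange(20, 100), -80)
  expect_warning(pc <- percentChange(50, 0), "reference")
  expect_true(is.na(pc))
  # monotone in the test value for a fixed reference
  v <- percentChange(c(10, 20, 40, 80), 40)
  expect_true(all(diff(v) > 0))
})

test_that("specificity matrices report percent change against reference", {
  mkSummary <- function(rmfi) {
    data.frame(population = c("T", "C1", "C2"), n = 50L, rmfi = rmfi,
               sd = 1, valid = TRUE, stringsAsFactors = FALSE)
  }
  summaries <- list(ref = mkSummary(c(400, 100, 100)),
                    same = mkSummary(c(400, 100, 100)),
                    up = mkSummary(c(400, 200, 100)))
  tab <- buildScreenTable(summaries)
  m <- specificityMatrix(tab, "T", referenceCondition = "ref")
  expect_identical(dim(m), c(3L, 2L))
  expect_true(all(m["same", ] == 0))
  expect_identical(m["up", "C1"], 100)
  expect_identical(m["up", "C2"], 0)
  expect_identical(attr(m, "masked"), 0L)
  # invalid summaries propagate as masked cells, never zeros
  summaries$up$valid[3] <- FALSE
  tab2 <- buildScreenTable(summaries)
  m2 <- specificityMatrix(tab2, "T", referenceCondition = "ref")
  expect_true(is.na(m2["up", "C2"]))
  expect_identical(attr(m2, "masked"), 1L)
})

test_that("ANOVA matches a from-scratch sums-of-squares oracle", {
  values <- c(12.1, 11.8, 12.6, 13.0,   15.2, 14.8, 15.9, 15.1,
              11.9, 12.3, 12.0, 12.4)
  groups <- rep(c("ctrl", "high", "other"), each = 4)
  res <- compareToControl(values, groups, "ctrl")

  # independent oracle: one-way ANOVA from sums of squares by hand
  gm <- mean(values)
  groupMeans <- tapply(values, groups, mean)
  ns <- tapply(values, groups, length)
  ssb <- sum(ns * (groupMeans - gm)^2)
  ssw <- sum((values - groupMeans[groups])^2)
  dfb <- length(ns) - 1L
  dfw <- length(values) - length(ns)
  Fo <- (ssb / dfb) / (ssw / dfw)
  po <- stats::pf(Fo, dfb, dfw, lower.tail = FALSE)
  expect_lt(abs(res$F - Fo), 1e-10)
  expect_lt(abs(res$p - po), 1e-10)
  expect_identical(res$df, c(dfb, dfw))

  # pooled-variance t against the control, Bonferroni over 2 comparisons
  mse <- ssw / dfw
  tHigh <- (groupMeans[["high"]] - groupMeans[["ctrl"]]) /
    sqrt(mse * (1 / 4 + 1 / 4))
  pHigh <- 2 * stats::pt(-abs(tHigh), dfw)
  cmp <- res$comparisons
  expect_lt(abs(cmp$t[cmp$group == "high"] - tHigh), 1e-10)
  expect_lt(abs(cmp$p_adj[cmp$group == "high"] - min(1, 2 * pHigh)), 1e-10)
  expect_equal(cmp$percent_change[cmp$group == "high"],
               100 * (groupMeans[["high"]] / groupMeans[["ctrl"]] - 1))
})

test_that("identical groups give a null ANOVA and shifted groups power", {
  vals <- rep(c(5, 6, 7), times = 3)
  g <- rep(c("ctrl", "g1", "g2"), each = 3)
  res <- compareToControl(vals, g, "ctrl")
  expect_lt(res$F, 1e-12)
  expect_gt(res$p, 0.999)

  # a +5 within-group-SD shift is detected at p < 0.001
  set.seed(11)
  hits <- 0L
  for (k in 1:20) {
    v <- c(rnorm(6), rnorm(6, mean = 5), rnorm(6))
    gg <- rep(c("ctrl", "shift", "null"), each = 6)
    r <- compareToControl(v, gg, "ctrl")
    hits <- hits + (r$comparisons$p_adj[r$comparisons$group == "shift"] < 0.001)
  }
  expect_gte(hits, 19L)
})

test_that("degenerate all-constant groups are flagged", {
  w <- capture_warnings(
    res <- compareToControl(rep(c(1, 2), each = 3),
                            rep(c("ctrl", "x"), each = 3), "ctrl"))
  expect_true(any(grepl("variance", w)))
  expect_true(res$degenerate)
})

test_that("group size and structure requirements are enforced", {
  expect_error(compareToControl(1:4, rep("a", 4), "a"), "two groups")
  expect_error(compareToControl(c(1, 2, 3), c("a", "a", "b"), "a"),
               "replicates")
  expect_error(compareToControl(1:4, rep(c("a", "b"), 2), "zz"), "absent")
})

test_that("design tables are validated on read", {
  withr::with_tempfile("df", fileext = ".csv", {
    write.csv(data.frame(well = c("W1", "W2"), condition = c("a", "b"),
                         dose = c(0, 100), reference = c(TRUE, FALSE)),
              df, row.names = FALSE)
    d <- readDesign(df)
    expect_identical(nrow(d), 2L)
    write.csv(data.frame(well = c("W1", "W1"), condition = c("a", "b"),
                         dose = c(0, 100)), df, row.names = FALSE)
    expect_error(readDesign(df), "unique")
    write.csv(data.frame(well = c("W1", "W2"), condition = c("a", "b"),
                         dose = c(0, 100), reference = c(TRUE, TRUE)),
              df, row.names = FALSE)
    expect_error(readDesign(df), "reference")
  })
})
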