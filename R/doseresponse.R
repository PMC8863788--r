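#' @include AllClasses.R AllGenerics.R
NULL

# Family registry. Parameter convention: b slope, c lower asymptote,
# d upper asymptote, e location (dose units), f asymmetry (LL.5 only).
# `fixed` parameters are not estimated; families with d fixed at 1 are
# fitted on max-normalised responses (normalisation recorded on the fit).
.DR_FAMILIES <- list(
  LL.2 = list(free = c("b", "e"), fixed = c(c = 0, d = 1)),
  LL.3 = list(free = c("b", "d", "e"), fixed = c(c = 0)),
  LL.4 = list(free = c("b", "c", "d", "e"), fixed = numeric()),
  LL.5 = list(free = c("b", "c", "d", "e", "f"), fixed = numeric()),
  W1.2 = list(free = c("b", "e"), fixed = c(c = 0, d = 1)),
  W1.3 = list(free = c("b", "d", "e"), fixed = c(c = 0)),
  W1.4 = list(free = c("b", "c", "d", "e"), fixed = numeric()),
  W2.3 = list(free = c("b", "d", "e"), fixed = c(c = 0)),
  W2.4 = list(free = c("b", "c", "d", "e"), fixed = numeric()),
  EXD.2 = list(free = c("d", "e"), fixed = c(c = 0)),
  EXD.3 = list(free = c("c", "d", "e"), fixed = numeric())
)

#' The candidate dose-response model families
#'
#' Eleven nonlinear families are fitted by default: log-logistic with 2-5
#' free parameters (LL.2 to LL.5), type-1 and type-2 Weibull (W1.2-W1.4,
#' W2.3-W2.4) and exponential decay with 2 or 3 parameters (EXD.2,
#' EXD.3). LL.2 and W1.2 fix the lower asymptote at 0 and the upper at 1
#' and are therefore fitted to max-normalised responses.
#'
#' @return character vector of the 11 family codes, in default order.
#' @export
drFamilies <- function() names(.DR_FAMILIES)

.drSpec <- function(family) {
  spec <- .DR_FAMILIES[[family]]
  if (is.null(spec)) stop("unknown model family: ", family)
  spec
}

.fullParams <- function(family, parameters) {
  spec <- .drSpec(family)
  p <- c(b = NA_real_, c = 0, d = NA_real_, e = NA_real_, f = 1)
  p[names(spec$fixed)] <- spec$fixed
  p[names(parameters)] <- parameters
  p
}

#' Evaluate a dose-response model
#'
#' Model equations, with b slope, c lower and d upper asymptote, e
#' location and f asymmetry:
#' log-logistic `c + (d-c) / (1 + (x/e)^b)^f` (f = 1 except LL.5; defined
#' at x = 0, where the value is d for b > 0); Weibull-1
#' `c + (d-c) * exp(-(x/e)^b)`; Weibull-2 `c + (d-c) * (1 - exp(-(x/e)^b))`;
#' exponential decay `c + (d-c) * exp(-x/e)` (EXD.2: c = 0).
#'
#' @param family family code, see [drFamilies()].
#' @param parameters named numeric; fixed parameters of the family may be
#'   omitted.
#' @param x dose(s), >= 0.
#' @return predicted response(s).
#' @examples
#' drPredict("LL.3", c(b = 2, d = 100, e = 150), c(0, 150, 1000))
#' @export
drPredict <- function(family, parameters, x) {
  p <- .fullParams(family, parameters)
  if (!is.finite(p["e"]) || p["e"] <= 0)
    stop("location parameter e must be positive")
  if (any(x < 0)) stop("doses must be >= 0")
  b <- p["b"]; cc <- p["c"]; d <- p["d"]; e <- p["e"]; f <- p["f"]
  t <- x / e
  y <- switch(substr(family, 1, 2),
    LL = cc + (d - cc) / (1 + t^b)^f,
    W1 = cc + (d - cc) * exp(-(t^b)),
    W2 = cc + (d - cc) * (1 - exp(-(t^b))),
    EX = cc + (d - cc) * exp(-t),
    stop("unknown model family: ", family)
  )
  # x = 0 with b > 0: (x/e)^b = 0, so LL gives d, W1 gives d, W2 gives c
  if (any(x == 0)) {
    v0 <- switch(substr(family, 1, 2),
                 LL = if (b > 0) d else cc,
                 W1 = if (b > 0) d else cc,
                 W2 = if (b > 0) cc else d,
                 EX = d)
    y[x == 0] <- v0
  }
  unname(y)
}

#' @describeIn drPredict predict method for fitted models; evaluates the
#'   fitted family at `newdata` doses on the original response scale.
#' @param object a [FittedModel-class].
#' @param newdata doses to predict at.
#' @export
setMethod("predict", "FittedModel", function(object, newdata) {
  object@normalization *
    drPredict(object@family, object@parameters, newdata)
})

# Self-starter heuristics: d ~ max response, c ~ min response, e ~ dose
# whose mean response is nearest the half-range, b over a fixed grid.
.drStarts <- function(family, dose, response) {
  spec <- .drSpec(family)
  d0 <- max(response); c0 <- min(response)
  mid <- (d0 + c0) / 2
  agg <- tapply(response, dose, mean)
  ud <- as.numeric(names(agg))
  pos <- ud[ud > 0]
  e0 <- if (length(pos)) pos[which.min(abs(agg[ud > 0] - mid))]
        else max(dose, 1)
  if (e0 <= 0) e0 <- max(stats::median(pos), 1e-6)
  bGrid <- c(0.5, 1, 2, -0.5, -1, -2)
  starts <- list()
  if ("b" %in% spec$free) {
    for (b0 in bGrid) {
      s <- c(b = b0, c = c0, d = d0, e = e0, f = 1)
      starts[[length(starts) + 1L]] <- s[spec$free]
    }
  } else {
    for (mult in c(0.5, 1, 2)) {
      s <- c(c = c0, d = d0, e = e0 * mult)
      starts[[length(starts) + 1L]] <- s[spec$free]
    }
  }
  starts
}

.drBounds <- function(free) {
  lower <- c(b = -50, c = -Inf, d = -Inf, e = 1e-9, f = 0.05)
  upper <- c(b = 50, c = Inf, d = Inf, e = Inf, f = 20)
  list(lower = unname(lower[free]), upper = unname(upper[free]))
}

#' Fit one dose-response family by least squares
#'
#' Levenberg-Marquardt least squares from a fixed multi-start grid (no
#' stochastic restarts): d starts at the response maximum, c at the
#' minimum, e at the dose nearest the half-range, and the slope b is tried
#' over both signs and three magnitudes. The best start by RSS wins.
#' Families with a fixed upper asymptote of 1 (LL.2, W1.2) are fitted to
#' max-normalised responses; their RSS is reported on the original
#' response scale so AIC is comparable across families.
#'
#' `AIC = n * log(RSS/n) + 2 * (p + 1)` with p the number of estimated
#' parameters (+1 for the error variance); additive constants are
#' dropped. For the max-normalised families the normalisation factor is a
#' scale estimated from the data and is included in p. An RSS of
#' (numerically) zero is floored at `1e-12 * sum(y^2)` inside the AIC
#' only, so that noise-free fits of nested families tie on the floor and
#' the parameter penalty decides.
#'
#' Non-convergence and degenerate inputs (constant responses) are reported
#' on the returned object, never silently.
#'
#' @param dose numeric doses (>= 0; zero allowed).
#' @param response numeric responses, same length.
#' @param family family code, see [drFamilies()].
#' @param tol optimizer tolerance on the objective.
#' @return A [FittedModel-class].
#' @examples
#' x <- rep(c(0, 25, 50, 100, 200, 400, 700, 1000), each = 2)
#' y <- drPredict("LL.3", c(b = 2, d = 100, e = 150), x)
#' fitDoseResponse(x, y, "LL.3")
#' @export
fitDoseResponse <- function(dose, response, family, tol = 1e-10) {
  spec <- .drSpec(family)
  stopifnot(length(dose) == length(response), all(dose >= 0),
            all(is.finite(dose)), all(is.finite(response)))
  n <- length(dose)
  nFree <- length(spec$free)
  failFit <- function(msg) new("FittedModel", family = family,
    parameters = stats::setNames(rep(NA_real_, nFree), spec$free),
    free = spec$free, rss = NA_real_, n = as.integer(n), aic = Inf,
    ed50 = NA_real_, converged = FALSE, message = msg, normalization = 1)

  if (length(unique(dose)) < nFree + 1L)
    return(failFit(sprintf("needs at least %d distinct doses", nFree + 1L)))
  if (stats::sd(response) == 0)
    return(failFit("degenerate: all responses equal"))

  normalization <- 1
  y <- response
  if (identical(unname(spec$fixed["d"]), 1)) {
    normalization <- max(response)
    if (normalization <= 0)
      return(failFit("max-normalisation impossible: all responses <= 0"))
    y <- response / normalization
  }

  resid <- function(par) {
    names(par) <- spec$free
    r <- y - drPredict(family, par, dose)
    r[!is.finite(r)] <- 1e6
    r
  }
  bounds <- .drBounds(spec$free)
  best <- NULL
  for (start in .drStarts(family, dose, y)) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = start, fn = resid,
                         lower = bounds$lower, upper = bounds$upper,
                         control = minpack.lm::nls.lm.control(
                           ftol = tol, ptol = tol, maxiter = 500)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$deviance)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) return(failFit("no start converged"))

  par <- stats::setNames(as.numeric(best$par), spec$free)
  rss <- best$deviance * normalization^2
  rssEff <- max(rss, 1e-12 * sum(response^2), 1e-300)
  # the max-normalisation of fixed-d families estimates a response scale
  # from the data, so it counts as a free parameter in the AIC penalty
  nEff <- nFree + (normalization != 1)
  aic <- n * log(rssEff / n) + 2 * (nEff + 1)
  converged <- best$info %in% 1:4
  fit <- new("FittedModel", family = family,
             parameters = .fullParams(family, par)[
               union(names(spec$fixed), spec$free)][c("b", "c", "d", "e", "f")[
                 c("b", "c", "d", "e", "f") %in%
                   union(names(spec$fixed), spec$free)]],
             free = spec$free, rss = rss, n = as.integer(n), aic = aic,
             ed50 = NA_real_, converged = converged,
             message = best$message, normalization = normalization)
  fit@ed50 <- tryCatch(ed50(fit), error = function(e) NA_real_)
  fit
}

#' Fit all candidate families and select by AIC
#'
#' Fits every candidate, discards non-converged fits and returns the one
#' with the lowest AIC. AIC ties (within 1e-9) are broken by fewest free
#' parameters, then candidate order. The full AIC table is attached to
#' the result as attribute `"aicTable"` for reporting.
#'
#' @inheritParams fitDoseResponse
#' @param families candidate family codes; default the full set of 11.
#' @return the winning [FittedModel-class] with attribute `"aicTable"`.
#' @export
selectDoseResponse <- function(dose, response, families = drFamilies(),
                               tol = 1e-10) {
  stopifnot(length(families) >= 1L)
  fits <- lapply(families, function(f)
    fitDoseResponse(dose, response, f, tol = tol))
  tab <- data.frame(
    family = families,
    p = vapply(fits, function(f)
      length(f@free) + as.integer(f@normalization != 1), integer(1)),
    rss = vapply(fits, function(f) f@rss, numeric(1)),
    aic = vapply(fits, function(f) f@aic, numeric(1)),
    ed50 = vapply(fits, function(f) f@ed50, numeric(1)),
    converged = vapply(fits, function(f) f@converged, logical(1)),
    message = vapply(fits, function(f) f@message, character(1)),
    stringsAsFactors = FALSE)
  ok <- which(tab$converged & is.finite(tab$aic))
  if (!length(ok))
    stop("all candidate fits failed:\n",
         paste(sprintf("  %s: %s", tab$family, tab$message), collapse = "\n"))
  aicOk <- tab$aic[ok]
  bestAic <- min(aicOk)
  tied <- ok[aicOk <= bestAic + 1e-9]
  winner <- tied[order(tab$p[tied], match(tied, seq_along(fits)))][1]
  res <- fits[[winner]]
  attr(res, "aicTable") <- tab
  res
}

#' ED50 of a fitted model
#'
#' The dose at which the fitted response is halfway between the lower and
#' upper asymptotes. Closed forms: log-logistic families give `e`
#' (LL.5: `e * (2^(1/f) - 1)^(1/b)`); exponential decay gives
#' `e * log(2)`; Weibull-1 and Weibull-2 give `e * log(2)^(1/b)`.
#' [ed50Numeric()] solves the same midpoint equation by bisection on the
#' fitted curve and must agree with the closed form; it reports the
#' smallest crossing and warns when the fitted curve crosses the midpoint
#' more than once.
#'
#' @param fit a [FittedModel-class] (converged, with d != c).
#' @return ED50 in dose units.
#' @export
ed50 <- function(fit) {
  stopifnot(is(fit, "FittedModel"))
  p <- .fullParams(fit@family, fit@parameters)
  if (!is.finite(p["e"]) || p["e"] <= 0)
    stop("ED50 undefined: location parameter e not positive")
  if (!is.na(p["d"]) && !is.na(p["c"]) && p["d"] == p["c"])
    stop("ED50 undefined: response range d - c is zero")
  fam2 <- substr(fit@family, 1, 2)
  val <- switch(fam2,
    LL = if (fit@family == "LL.5") {
      p[["e"]] * (2^(1 / p[["f"]]) - 1)^(1 / p[["b"]])
    } else p[["e"]],
    EX = p[["e"]] * log(2),
    W1 = p[["e"]] * log(2)^(1 / p[["b"]]),
    W2 = p[["e"]] * log(2)^(1 / p[["b"]]),
    stop("unknown model family: ", fit@family))
  unname(val)
}

#' @rdname ed50
#' @param upper search upper bound for bracketing; defaults to expanding
#'   from the location parameter.
#' @param tolRel relative bisection tolerance.
#' @export
ed50Numeric <- function(fit, upper = NULL, tolRel = 1e-9) {
  stopifnot(is(fit, "FittedModel"))
  p <- .fullParams(fit@family, fit@parameters)
  cc <- p[["c"]]; d <- p[["d"]]
  if (d == cc) stop("ED50 undefined: response range d - c is zero")
  mid <- (cc + d) / 2
  g <- function(x) drPredict(fit@family, fit@parameters, x) - mid
  hi <- if (is.null(upper)) p[["e"]] else upper
  s0 <- sign(g(0))
  it <- 0L
  while (sign(g(hi)) == s0 && it < 60L) { hi <- hi * 2; it <- it + 1L }
  if (sign(g(hi)) == s0) stop("could not bracket the midpoint crossing")
  # scan for multiple crossings; report the smallest
  grid <- seq(0, hi, length.out = 1024L)
  sg <- sign(g(grid))
  cross <- which(diff(sg != s0) == 1L | (sg[-1] == 0 & sg[-length(sg)] == s0))
  if (length(cross) > 1L)
    warning("fitted curve crosses its midpoint more than once; ",
            "reporting the smallest crossing")
  lo <- grid[cross[1]]; hi <- grid[cross[1] + 1L]
  while ((hi - lo) > tolRel * max(hi, 1e-12)) {
    m <- (lo + hi) / 2
    if (sign(g(m)) == s0) lo <- m else hi <- m
  }
  (lo + hi) / 2
}
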