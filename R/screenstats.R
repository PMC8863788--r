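#' @include AllClasses.R
NULL

#' Percent change of a test rMFI versus a reference
#'
#' Signed percent change `100 * (test - reference) / reference`. A
#' non-positive reference makes the quantity undefined; such cells are
#' returned as NA (never silently zero).
#'
#' @param test test-condition rMFI value(s).
#' @param reference reference-condition rMFI (recycled).
#' @return numeric percent change(s); NA where the reference is not
#'   positive or either value is missing.
#' @examples
#' percentChange(200, 100)  # +100
#' percentChange(20, 100)   # -80
#' @export
percentChange <- function(test, reference) {
  out <- 100 * (test - reference) / reference
  bad <- !is.finite(reference) | reference <= 0
  if (any(bad, na.rm = TRUE)) {
    out[bad] <- NA_real_
    warning("percent change undefined for non-positive reference; NA returned")
  }
  out
}

#' Assemble a screen table from per-condition chip summaries
#'
#' Stacks per-population rMFI summaries of several conditions into one
#' long table ready for [specificityMatrix()] and export.
#'
#' @param summaries named list of [summarizeChip()] outputs, one per
#'   condition (names are the condition labels).
#' @param design optional data.frame with columns `condition` and
#'   `reference` (logical) marking the reference condition.
#' @return data.frame: `condition`, `population`, `n`, `rmfi`, `sd`,
#'   `valid`, plus `reference` when a design is given.
#' @export
buildScreenTable <- function(summaries, design = NULL) {
  stopifnot(length(summaries) >= 1L, !is.null(names(summaries)))
  out <- do.call(rbind, lapply(names(summaries), function(cond) {
    s <- summaries[[cond]]
    data.frame(condition = cond, s, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  if (!is.null(design)) {
    stopifnot(all(c("condition", "reference") %in% names(design)))
    out$reference <- design$reference[match(out$condition, design$condition)]
  }
  out
}

#' Specificity matrix: percent change of non-target populations
#'
#' For one aptamer, computes the percent change of every non-target
#' (specificity-control) population in every condition relative to the
#' reference condition, as plotted in screening heat maps. Invalid or
#' missing summaries propagate as NA (masked) cells, never as zeros. The
#' target population's percent changes are reported separately in the
#' `"target"` attribute.
#'
#' @param screenTable data.frame from [buildScreenTable()].
#' @param targetPopulation population id carrying the aptamer's target.
#' @param referenceCondition reference condition label; defaults to the
#'   condition flagged `reference` in the table.
#' @return matrix (conditions x non-target populations) of percent
#'   changes, with attributes `"target"` (named vector for the target
#'   population) and `"masked"` (count of masked cells).
#' @export
specificityMatrix <- function(screenTable, targetPopulation,
                              referenceCondition = NULL) {
  if (is.null(referenceCondition)) {
    if (!"reference" %in% names(screenTable))
      stop("no reference condition given and none flagged in the table")
    referenceCondition <- unique(screenTable$condition[screenTable$reference])
  }
  if (length(referenceCondition) != 1L)
    stop("exactly one reference condition is required")
  if (!referenceCondition %in% screenTable$condition)
    stop("reference condition '", referenceCondition, "' not in the table")

  pops <- unique(screenTable$population)
  conds <- unique(screenTable$condition)
  val <- function(cond, pop) {
    r <- screenTable[screenTable$condition == cond &
                     screenTable$population == pop, , drop = FALSE]
    if (nrow(r) != 1L || !isTRUE(r$valid) || !is.finite(r$rmfi)) NA_real_
    else r$rmfi
  }
  refVals <- vapply(pops, function(p) val(referenceCondition, p), numeric(1))
  pc <- matrix(NA_real_, length(conds), length(pops),
               dimnames = list(conds, pops))
  for (ci in seq_along(conds)) {
    for (pi in seq_along(pops)) {
      tv <- val(conds[ci], pops[pi]); rv <- refVals[pi]
      if (is.finite(tv) && is.finite(rv) && rv > 0)
        pc[ci, pi] <- 100 * (tv - rv) / rv
    }
  }
  if (!targetPopulation %in% pops)
    stop("target population '", targetPopulation, "' not in the table")
  ctrl <- setdiff(pops, targetPopulation)
  out <- pc[, ctrl, drop = FALSE]
  attr(out, "target") <- pc[, targetPopulation]
  attr(out, "masked") <- sum(!is.finite(out))
  out
}

#' One-way ANOVA with many-to-one comparisons against a control
#'
#' Classical one-way ANOVA over all groups, followed by two-sided
#' comparisons of every non-control group against the control using
#' pooled-variance t statistics (the residual mean square of the ANOVA)
#' with Bonferroni adjustment over the number of comparisons -- a simple,
#' conservative stand-in for Dunnett's many-to-one procedure; set
#' `adjust = "none"` for unadjusted p values. Mean differences and percent
#' changes versus the control are reported as effect sizes alongside the
#' p values.
#'
#' @param values numeric replicate measurements (e.g. rMFI per well).
#' @param groups group label per value.
#' @param control label of the control group.
#' @param adjust `"bonferroni"` (default) or `"none"`.
#' @return list with `F`, `df`, `p` (overall ANOVA), `comparisons`
#'   (data.frame group, n, mean, diff, percent_change, t, p_raw, p_adj)
#'   and `degenerate` (TRUE when every group has zero within-group
#'   variance).
#' @examples
#' v <- c(10, 11, 12, 20, 21, 22, 10, 12, 11)
#' g <- rep(c("ctrl", "high", "same"), each = 3)
#' compareToControl(v, g, "ctrl")
#' @export
compareToControl <- function(values, groups, control,
                             adjust = c("bonferroni", "none")) {
  adjust <- match.arg(adjust)
  groups <- as.character(groups)
  stopifnot(length(values) == length(groups))
  if (!control %in% groups) stop("control group '", control, "' absent")
  tab <- table(groups)
  if (length(tab) < 2L) stop("need at least two groups")
  if (any(tab < 2L))
    stop("every group needs >= 2 replicates for inference; got n = ",
         min(tab))

  g <- factor(groups, levels = c(control, setdiff(unique(groups), control)))
  fit <- stats::lm(values ~ g)
  an <- stats::anova(fit)
  mse <- an["Residuals", "Mean Sq"]
  dfres <- an["Residuals", "Df"]
  degenerate <- mse <= .Machine$double.eps * mean(values^2)
  if (degenerate)
    warning("zero within-group variance everywhere; p values unreliable")

  means <- tapply(values, g, mean)
  ns <- tapply(values, g, length)
  others <- levels(g)[-1]
  cmp <- do.call(rbind, lapply(others, function(lv) {
    se <- sqrt(mse * (1 / ns[[lv]] + 1 / ns[[control]]))
    tstat <- (means[[lv]] - means[[control]]) / se
    praw <- 2 * stats::pt(-abs(tstat), dfres)
    data.frame(group = lv, n = ns[[lv]], mean = means[[lv]],
               diff = means[[lv]] - means[[control]],
               percent_change = if (means[[control]] > 0)
                 100 * (means[[lv]] - means[[control]]) / means[[control]]
               else NA_real_,
               t = tstat, p_raw = praw, stringsAsFactors = FALSE)
  }))
  cmp$p_adj <- if (adjust == "bonferroni")
    stats::p.adjust(cmp$p_raw, "bonferroni") else cmp$p_raw
  rownames(cmp) <- NULL

  list(F = an["g", "F value"], df = c(an["g", "Df"], dfres),
       p = an["g", "Pr(>F)"], comparisons = cmp, degenerate = degenerate)
}

#' Read an experiment design table
#'
#' CSV with columns `well`, `condition`, `dose` (numeric covariate such as
#' NaCl mM) and optionally `aptamer` and `reference` (logical flag of the
#' reference condition; exactly one condition per aptamer family must be
#' flagged when present).
#'
#' @param path CSV file path.
#' @return data.frame.
#' @export
readDesign <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("well", "condition", "dose")
  if (!all(need %in% names(d)))
    stop("design CSV must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(d$well)) stop("well ids must be unique")
  if ("reference" %in% names(d)) {
    d$reference <- as.logical(d$reference)
    fam <- if ("aptamer" %in% names(d)) d$aptamer else rep("all", nrow(d))
    nref <- tapply(d$reference, fam, sum)
    if (any(nref != 1L))
      stop("exactly one reference condition is required per aptamer")
  }
  d
}
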