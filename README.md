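# HaloScreen

Simulation and analysis of multiplex aptamer binding screens on encoded
microbead chips.

## The problem

Multiplex bead assays pool microsphere populations, each carrying a
different capture protein and identified by its size and the ratio of two
internal encoding dyes. Fluorescently labelled aptamers that bind a bead's
surface protein decorate its rim and image as a **halo** in a separate
measurement channel. A screen reads one image (or a kinetic frame series)
per well, decodes every bead back to its population, quantifies the halos,
and reports the **referenced mean fluorescence intensity (rMFI)** per
population — then compares rMFI across buffer conditions, with non-target
populations in the same well serving as specificity controls. Typical
analyses include NaCl dose series condensed into ED50 values via nonlinear
model fits, percent-change specificity heat maps, ANOVA against control
conditions, and protein charge arguments (isoelectric points) explaining
non-specific electrostatic binding of the polyanionic aptamer DNA.

No raw images from such instruments are publicly deposited, so HaloScreen
pairs the analysis chain with a synthetic chip generator that provides full
ground truth, making every stage quantitatively testable.

## What is inside

| Stage | Functions |
|---|---|
| Synthetic chips with ground truth | `simConfig()`, `sampleBeadLayout()`, `renderChipImage()`, `simulateKineticSeries()`, `generateScreenDataset()` |
| Detection and decoding | `detectBeads()`, `measureEncoding()`, `decodePopulation()` |
| Halo quantification, rMFI | `measureHalo()`, `analyzeChip()`, `summarizeChip()`, `rmfiTimeSeries()` |
| Dose-response | `drPredict()`, `fitDoseResponse()`, `selectDoseResponse()` (11 candidate families, AIC), `ed50()` |
| Screening statistics | `percentChange()`, `specificityMatrix()`, `compareToControl()` |
| Protein characteristics | `netCharge()`, `isoelectricPoint()`, `molecularWeight()`, `proteinProperties()` |

The dose-response core fits log-logistic (LL.2–LL.5), Weibull (W1, W2) and
exponential-decay (EXD.2, EXD.3) models, e.g. the three-parameter
log-logistic

f(x) = d / (1 + (x/e)^b),

selects among the 11 candidates by AIC = n·ln(RSS/n) + 2(p+1), and reports
the half-maximal dose ED50 (= e for log-logistic, e·ln 2 for exponential
decay, e·(ln 2)^(1/b) for Weibull), cross-checked against numeric
bisection. Statistical comparisons use one-way ANOVA with pooled-variance
many-to-one t tests (Bonferroni-adjusted) against the control condition.

## Worked example

```r
library(HaloScreen)

panel <- referencePanel(
  population = c("IFNG", "THRB", "CTRL1", "CTRL2"),
  protein    = c("interferon-gamma", "thrombin", "GST", "HSA"),
  diameter   = c(10, 10, 15, 15),
  enc1       = c(600, 3000, 600, 3000),
  enc2       = c(1500, 1500, 1500, 1500))

cfg <- simConfig(panel, imageShape = c(1024, 1024), beadsPerPopulation = 50,
                 haloAmplitudes = c(IFNG = 800, THRB = 600,
                                    CTRL1 = 150, CTRL2 = 150),
                 seed = 42)
chip  <- renderChipImage(sampleBeadLayout(cfg), cfg)
beads <- analyzeChip(chip, panel)
summarizeChip(beads, panel)
#>   population  n     rmfi       sd valid
#> 1       IFNG 50 800.1234 3.538062  TRUE
#> 2       THRB 50 600.5535 3.294376  TRUE
#> 3      CTRL1 50 150.1292 1.849623  TRUE
#> 4      CTRL2 50 149.6855 2.045586  TRUE
```

The rMFI column recovers the programmed halo amplitudes (800, 600, 150,
150 a.u.) to a fraction of a percent; `n` counts QC-passing beads and
`valid` marks summaries with enough beads for reporting.

```r
doses <- rep(c(0, 25, 50, 100, 200, 400, 700, 1000), each = 3)  # NaCl mM
set.seed(7)
rmfi  <- drPredict("LL.3", c(b = 2, d = 800, e = 150), doses) *
           (1 + 0.05 * rnorm(length(doses)))
fit <- selectDoseResponse(doses, rmfi)
fit
#> FittedModel LL.3 (converged)
#>   parameters: b=2.213, c=0, d=783.61, e=167.03
#>   n=24  RSS=18592.3  AIC=167.6587  ED50=167.026
```

AIC selection recovers the generating log-logistic family and an ED50 of
167 mM against a programmed 150 mM at 5% measurement noise; the full
per-family AIC table is attached as `attr(fit, "aicTable")`.

## Command line

A thin wrapper over the same functions lives in
`inst/scripts/haloscreen-cli.R`:

```sh
Rscript haloscreen-cli.R simulate --config config.yaml --out DIR --seed 5
Rscript haloscreen-cli.R analyze  --image well.tif --panel panel.csv --out summary.csv
Rscript haloscreen-cli.R screen   --design design.csv --images DIR --panel panel.csv --out DIR
```

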