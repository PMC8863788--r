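---
title: "Models and methods behind HaloScreen"
author: "HaloScreen authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind HaloScreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(HaloScreen)
```

# The assay and what the package computes

In a multiplex microbead binding assay, polymer microspheres carrying
different capture proteins are pooled in one well. Each bead population is
identified ("encoded") by its size and the ratio of two internal dyes read
in two encoding channels; the dyes cannot leak, so they form a stable
reference system across experiments. A fluorescently labelled aptamer that
binds a bead's surface protein decorates the bead rim and images as a
*halo* in a third, measurement channel. The readout per population is the
referenced mean fluorescence intensity (rMFI): the mean background-corrected
halo intensity over that population's beads. Screens then compare rMFI
across buffer conditions (salt, pH, additives), with non-target populations
in the same well acting as specificity controls, and dose series (e.g. NaCl
0--1000 mM) are condensed into ED50 values through nonlinear model fits.

No raw chip images from such instruments are publicly deposited, so the
package is built around a synthetic chip generator with full ground truth;
every downstream stage is tested against what the generator programmed.

# The synthetic chip model

`simConfig()` fixes the study conditions; `sampleBeadLayout()` and
`renderChipImage()` realise them. Defaults, with units and reasons:

* **Beads per population: 500** — the low end of the 500--1000 beads per
  population typically loaded per well; configurable up to the full range.
* **Two size classes, 10 and 15 µm diameter, at 1 µm/pixel**, crossed with
  eight encoding-ratio levels spaced 0.5 apart in log ratio
  (`defaultPanel()`, 16 populations). Commercial panels do not publish
  their dye levels, so these are simulator choices: the log-ratio spacing
  is 7 times the per-bead log-ratio dispersion at the default 5% dye CV,
  which makes the code book comfortably decodable — the regime such panels
  are engineered for.
* **Encoding CV 0.05, radius CV 0.02** — typical manufacturing spreads.
* **Bead rim**: a symmetric erf-profile edge (`edgeSoftness` 0.8 px), i.e.
  a hard sphere edge imaged through Gaussian optics. This puts the
  half-maximum contour exactly at the true radius, which is what any
  model-free radius estimator assumes.
* **Halo**: a Gaussian radial ring centred at the bead radius,
  sd `haloWidth` = 2 µm (a thin surface shell broadened by optical blur),
  amplitude set per population by `haloAmplitudes` — the quantity every
  later stage tries to recover.
* **Noise**: Poisson shot noise treating intensity units as photon counts
  (variance = mean, the invariant the tests check), then additive Gaussian
  read noise (sd 10), then rounding and clipping to the 16-bit range.
* **Placement**: uniform rejection sampling with a minimum center distance
  of 20 µm on a spatial hash grid, with a bounded attempt budget and a
  capacity error when a layout cannot fit. Touching doublets are only
  injected when `doubletFraction > 0`. The layout and both noise streams
  are bit-reproducible for a fixed seed.

What the generator does **not** emulate: realistic point-spread functions,
focus drift, vignetting and illumination gradients, debris, autofluorescent
aggregates, bead stacking in 3-D, and photobleaching in kinetic series.
Passing tests therefore demonstrate correctness of the algorithms under the
stated image model, not robustness to every artefact of real chips; the
QC-flag machinery (edge, doublet, unclassified, background fallback) is the
hook real data would exercise much harder.

# Detection and decoding

`detectBeads()` segments the sum of the two encoding channels (every bead
carries both dyes): Gaussian pre-smoothing (sd 1 px), a robust threshold at
`background + 8·MAD` (with an absolute floor of 50 a.u. so noise-free and
constant images behave), connected components, and a distance-map watershed
to split beads whose threshold skirts touch. Per component:

* sub-pixel center = intensity-weighted centroid;
* radius = area of the half-maximum contour, with the plateau re-estimated
  from core pixels in a second pass and a curvature correction
  $\sigma^2/(2r)$ using the edge scale estimated from the 15%/85% contour
  spread;
* circularity = area over circumscribed-circle area, gating out merged
  clumps (border-truncated components are kept but edge-flagged instead,
  since truncation destroys circularity by construction).

Pipelines in this problem family often use multi-scale
Laplacian-of-Gaussian blob detection here. We chose segmentation instead:
beads are bright non-overlapping disks, segmentation yields unbiased
sub-pixel radii (a discrete LoG scale grid quantises them), and circularity
falls out of the same labelling. The detection contract — sub-pixel
centers, per-bead radii, circularity gate, edge flags — is unchanged.

`measureEncoding()` averages each encoding channel over the inner 70% of
the radius (clear of the blurred rim), subtracts a far-field background
(median outside all bead footprints), and forms the ratio.
`decodePopulation()` assigns each bead to the population minimising the
standardised Euclidean distance in (log ratio, radius in µm), scaled by the
panel's per-population dispersions, with a 3-unit gate; beads beyond the
gate are `"unclassified"`. The default gating dispersions (0.1 in log
ratio, 0.5 µm in radius) are slightly wider than the manufacturing CV alone
because they must also absorb measurement error. Exact ties resolve to
panel order and are flagged ambiguous; ties are a measure-zero event, so
assignments are in practice invariant to panel permutation (a tested
property).

# Halo quantification and the rMFI

The halo estimator must be *unbiased*, not merely proportional: the
bar we hold it to (population mean within 3 standard errors of the
programmed amplitude at n = 500 beads) tolerates a systematic error of only
a few hundredths of a percent at the default noise level. Three effects
ruin the classical "annulus mean minus background-annulus median"
statistic at this precision: the Gaussian radial profile is not flat across
any annulus (a ~15--40% attenuation depending on geometry), the background
annulus sits on the halo's own tail, and sub-pixel radius errors move the
annulus against the profile at first order.

The default estimator in `measureHalo()` is therefore a per-bead linear
regression over a window covering the rim and the surrounding background:

$$\mathrm{pixel}_i \;=\; \alpha \;+\; A\,t_i \;+\; B\,\partial_r t_i
\;+\; C\,\partial^2_r t_i \;+\; \varepsilon_i,$$

where $t_i = \exp(-(d_i - \hat r)^2 / 2\sigma_h^2)$ is the unit-amplitude
ring template at the detected center and radius. $\hat A$ estimates the
halo amplitude, $\hat\alpha$ the local background; the two derivative
regressors absorb the first- and second-order template mismatch caused by
radius estimation error. Being linear in the pixel values, the estimator is
exactly unbiased under any zero-mean noise once the geometry matches, and
insensitive to small geometry errors by construction; a constant offset
added to the measurement channel moves $\hat\alpha$ and leaves $\hat A$
untouched, which is the tested background-invariance property. Pixels
inside another bead's exclusion footprint (the bead plus 3.5 halo sd) are
masked from the window, bead by bead, so neighbouring halos cannot leak in;
beads whose background is fully occluded fall back to the global far-field
background and are flagged. Measured on ten default chips (2553 beads), the
bias is $-0.007\% \pm 0.018$ at amplitude 800 and $-0.16\% \pm 0.09$ at
amplitude 150.

The classical statistic remains available as
`annulusParams(method = "annulus")`: trimmed mean over
$[r(1-w_{in}),\,r(1+w_{out})]$ minus the background-annulus mean, divided
by the identical statistic of the unit template (skip the division with
`calibrate = FALSE` to get the textbook definition, for which
`halo_surface = ring − background` holds as an exact identity). Two
defaults deviate deliberately from the classical recipe: the rim annulus is
symmetric (±0.25 r) so small geometry errors cancel at first order, and the
trimming fraction defaults to 0 because rank-based trimming of noisy pixels
is inconsistent with trimming the noise-free template when the profile is
not flat, which produces an amplitude-dependent bias of up to ~1%; outlier
rejection is instead delegated to the neighbour-footprint exclusion. The
background uses a mean rather than a median for the same linearity reason.

`summarizePopulation()` then defines
$\mathrm{rMFI} = \overline{\mathrm{halo}} / \mathrm{referenceScale}$ over
QC-passing beads. The instrument literature never defines the
"referenced" normalisation numerically; we take the reference scale as a
configurable divisor with default 1 (the encoding dyes act purely as the
population code), so alternative conventions are one argument away.
Negative per-bead halo values are retained to keep means unbiased near
zero, and summaries with fewer than 10 usable beads are marked invalid
rather than reported silently. Kinetic series are analysed frame by frame
with population-level aggregation only — beads are not tracked across
frames, which is the robust choice when frames are minutes apart and the
chip may drift slightly.

# Dose-response models, AIC selection, ED50

Eleven candidate families are fitted by default (log-logistic LL.2--LL.5,
Weibull type 1 and 2, exponential decay EXD.2/EXD.3), parameterised with
slope $b$, asymptotes $c \le y \le d$, location $e$ and (LL.5) asymmetry
$f$; the $(x/e)^b$ parameterisation keeps dose 0 in the domain. Fitting is
Levenberg--Marquardt least squares from a fixed multi-start grid
($b \in \{\pm 0.5, \pm 1, \pm 2\}$, self-starter heuristics for the rest;
objective tolerance $10^{-10}$; no stochastic restarts, so fits are
reproducible). LL.2 and W1.2 fix $d = 1$ and are fitted to max-normalised
responses; their RSS is mapped back to the original scale so AIC is
comparable, and the normalisation factor counts as one estimated parameter
in

$$\mathrm{AIC} = n \ln(\mathrm{RSS}/n) + 2(p + 1),$$

with additive constants dropped (selection-invariant). Counting the
normalisation matters: without it, W1.2 — which reproduces EXD.2 exactly at
$b = 1$ — ties noise-free EXD.2 data on the RSS floor and steals the
selection on candidate order alone. A numerically zero RSS is floored at
$10^{-12}\sum y^2$ inside the AIC only, so noise-free fits of nested
families tie and the parameter penalty decides; AIC ties are broken by
fewest parameters, then candidate order, and the full AIC table is attached
to every selection.

ED50 — the dose at the midpoint of the fitted asymptotes — has closed forms
for every family (log-logistic: $e$; LL.5: $e(2^{1/f}-1)^{1/b}$;
exponential: $e\ln 2$; both Weibull types: $e(\ln 2)^{1/b}$) and a
bisection solver `ed50Numeric()` that must agree to $10^{-6}$ relative, as
a permanent cross-check; non-monotone fitted curves report the smallest
midpoint crossing with a warning.

One honest limitation, quantified in our simulations: with the stated AIC,
the probability of selecting the *generating* family is capped by the
overfitting probability of nested richer candidates. The deviance
improvement from $k$ unnecessary nested parameters is asymptotically
$\chi^2_k$ *independently of the noise level*, so LL.5 beats true LL.3 data
whenever $\chi^2_2 > 4$ (≈14%, more under multiplicative noise); we measure
a 79--87% generating-family selection rate at CV 2% (8 doses × 3
replicates). No noise level changes this. What low noise does guarantee —
and what matters for ED50 — is that the *selected curve* matches the
generating curve: its RMSE stays below 5% of the upper asymptote in 100/100
such runs.

# Screening statistics

`percentChange()` is the signed $100\,(t - r)/r$ with non-positive
references reported as NA, never zero. `specificityMatrix()` arranges
percent changes of non-target populations (conditions × populations)
against the per-aptamer reference condition, with invalid summaries
propagating as masked cells and the target column carried separately —
the tabular form of the screening heat maps. `compareToControl()` runs
classical one-way ANOVA and then compares each condition against the
control with pooled-variance two-sided t statistics under Bonferroni
adjustment — a deliberately conservative stand-in for Dunnett's
many-to-one procedure, chosen for transparency and exposed via the
`adjust` argument so an exact Dunnett implementation can be slotted in.
Groups need at least two replicates for inference (screens typically carry
n = 2--8 per condition); below that the module refuses to test rather than
reporting unstable p values, and zero within-group variance is flagged as
degenerate. Effect sizes (mean difference and percent change) are always
reported beside p values.

# Protein charge characteristics

High-pI proteins (pI above the buffer pH) carry positive net charge in
neutral binding buffers and electrostatically attract the polyanionic
aptamer DNA — the standard explanation for non-specific binding patterns,
and the reason the package computes charge at all. `netCharge()` is the
Henderson--Hasselbalch sum over the termini and the ionizable side chains
(D, E, C, Y, H, K, R): positive groups contribute
$+1/(1+10^{\,\mathrm{pH}-pK_a})$, negative groups
$-1/(1+10^{\,pK_a-\mathrm{pH}})$. The pKa constants are the Bjellqvist set
with generic termini, shipped as a versioned data file (an EMBOSS set is
bundled as an alternative) so results are pinned to a specific table.
`isoelectricPoint()` bisects the strictly decreasing charge curve on pH
0--14 to $|q| < 10^{-4}$. The bundled FASTA fixture contains clearly
labelled *synthetic* illustrative sequences (high-pI, low-pI, neutral
compositions), not the natural proteins of any particular panel: real
sequences are a download away, and shipping approximations under real
names would be worse than shipping none.

# Numerical choices and problem sizes

Degenerate inputs are explicit everywhere: empty and constant images yield
empty detection lists; constant responses yield a flagged degenerate fit;
all-candidate fit failure raises an aggregated report; non-positive
percent-change references and sub-minimum summaries are masked, not
zeroed. The test and acceptance workloads use deliberately scaled problem
sizes — a 16-population × 200-bead chip (2048² px) for detection/decoding
scoring, 500 beads per population for amplitude-recovery checks, 100
simulation runs for ED50 and model-selection rates, 1000 null simulations
for the ANOVA type-I error, and an 8-dose × 16-population screen at 60
beads per population end to end — sizes at which the Monte-Carlo bands in
the assertions are meaningful while a full run stays comfortable on one
CPU.
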