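---
title: "Models and methods behind oligoflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind oligoflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oligoflux)
library(dplyr)
```

oligoflux analyzes inhibitor screens against amyloid aggregation — the kind
of experiment in which a panel of designed single-domain antibodies is
incubated with aggregating alpha-synuclein and ranked by how strongly each
one suppresses the generation of toxic oligomeric species. This vignette
explains the models the package fits, the flux framework built on top of
them, the imaging and binding analyses, the synthetic-data generators the
test suite relies on, and the numerical and design choices that were
genuinely open.

## Kinetic model of seeded aggregation

Thioflavin-T (ThT) fluorescence reports the fibril mass of an aggregation
reaction. After normalization (baseline mapped to 0, end-point plateau to 1;
`normalize_trace()` uses the mean of the first 3 and last 5 samples by
default, a recipe chosen because plate-reader exports carry no stated one),
the package treats two seeding regimes differently.

**Highly seeded reactions** (around 15% preformed seeds) bypass nucleation:
fibrils simply elongate, so the early signal is linear,
$M(t) = M(0) + 2 k_+ P(0)\, m(0)\, t$. `fit_elongation()` puts an
ordinary least-squares line through the first six samples (one-minute
sampling) and reports the slope, the unresolved product
$2 k_+ P(0) m(0)$. Because $P(0)$ and $m(0)$ are shared across conditions of
one plate, the ratio of slopes to the control mean isolates the effect on
the elongation rate $k_+$ (`relative_elongation()`).

**Low-seeded reactions** (around 0.06% seeds) are dominated by secondary
nucleation — the autocatalytic birth of new aggregates on fibril surfaces —
and follow a generalized logistic (Richards) curve:

$$M(t) = \left(1 + a e^{-\kappa t}\right)^{-1/c},
\qquad \frac{dM}{dt} = \frac{\kappa}{c} M \left(1 - M^c\right).$$

Here $\kappa$ (per minute) is the effective rate of fibril amplification —
the quantity a secondary-nucleation inhibitor lowers — and $a$ encodes the
initial condition ($M(0) = (1+a)^{-1/c}$; weak primary nucleation or light
seeding means large $a$). The shape parameter $c$ is held fixed at 0.3, the
conventional value tying the curve to a secondary-nucleation reaction order
of 4 in monomer; it is never free unless the user unfixes it, because $a$
and $c$ are poorly identified jointly on single-plateau data. The primary
nucleation combination $\lambda$ is recorded as metadata through the
convention $a = c\kappa^2 / (2\lambda^2)$ and is not used downstream.

`fit_logistic()` estimates $(a, \kappa)$ by bounded nonlinear least squares
(`minpack.lm`), pooling residuals across technical replicates — the
replicates share one true curve, and pooling uses all points without
averaging away per-replicate noise structure (per-replicate fits remain
available for dispersion bars). Starting values come from the data
($\kappa$ from the maximum finite-difference slope divided by 0.25, $a$
from the initial signal); bounds are $a \in (0, 10^6]$,
$\kappa \in (0, 10]$ per minute. A trace that never reaches half of its
plateau, or an optimizer failure, is returned as a non-converged result
object rather than an error, because screens routinely contain wells where
the fit legitimately fails. The half-time is the root of $M(t) = 1/2$
(closed form $t_{1/2} = \log(a/(2^c - 1))/\kappa$, recovered by
`uniroot()` on the fitted curve).

## The oligomer flux

Oligomers are the transient species between monomers and fibrils: secondary
nucleation generates them, elongation consumes them into mature fibrils.
Under the linear polymerization law $dM/dt = r_+ P m$ (with
$r_+ = 2k_+ m_\mathrm{tot}$ the effective elongation rate and $m = 1 - M$
the free monomer), the fitted $M(t)$ implies a normalized fibril number

$$P(t) = \frac{dM/dt}{r_+ (1 - M)}
       = \frac{\kappa}{c\, r_+} \frac{M (1 - M^c)}{1 - M},$$

which rises from $P(0)$ to $\kappa / r_+$. The net flux of reactive
oligomers is its derivative, which reduces to a closed form in $M$ alone:

$$\phi(t) = \frac{dP}{dt}
  = \frac{\kappa^2}{c^2 r_+}\,
    \frac{M \left(1 - M^c\right)\left[1 - (1+c) M^c + c\, M^{1+c}\right]}
         {(1 - M)^2}.$$

The bracketed factor decreases monotonically from 1 at $M = 0$ to 0 at
$M = 1$, so $\phi \ge 0$ everywhere and vanishes at both ends of the
reaction: the flux is the characteristic bell over time. Three summaries
describe it (`flux_summary()`):

* $\phi_\mathrm{Peak}$ — the maximal rate of oligomer generation
  (`flux_peak_height()`);
* $\phi_\mathrm{Area}$ — the total oligomers generated,
  $\int_0^\infty \phi\, dt = \kappa / r_+ - P(0)$ in closed form
  (`flux_area()`);
* $\phi_\mathrm{Time}$ — when generation peaks (`flux_peak_time()`), found
  by bracketed root-finding of $d\phi/dt = 0$ on
  $[t_{1/2}/100,\; 5 t_{1/2}]$ (the peak always sits in the growth phase;
  an input whose peak falls outside the bracket — e.g. a reaction started
  beyond its inflection — raises a no-peak error rather than returning a
  boundary value).

Every closed form is guarded by an independent numerical oracle in the test
suite: trapezoidal quadrature for the area, dense-grid argmax/max for the
peak, and nested finite differences of $M(t)$ for the flux itself. All
three metrics are reported per condition relative to the control-replicate
mean (`normalize_flux_metrics()`; the peak-time normalization is a ratio,
like the other two, so all three relative metrics are dimensionless and the
control averages exactly 1). An ideal inhibitor drives the relative peak
and area below 1 while pushing the relative peak time above 1; because
$\phi_\mathrm{Peak} \propto \kappa^2$, $\phi_\mathrm{Area} \approx \kappa /
r_+$ and $\phi_\mathrm{Time} \propto 1/\kappa$ at fixed $a$ and $c$, any
reduction of $\kappa$ moves all three the right way, which the suite
asserts over a parameter sweep.

The default profile grid is $t \in [0, 5 t_{1/2}]$ with step
$t_{1/2}/1000$: it brackets the bell with bounded cost at any reaction
speed. The `r_plus` fed into the flux defaults to a single shared value
(inhibitors of secondary nucleation typically leave elongation untouched,
so the control's elongation rate is a sensible common choice); a
per-condition table is accepted when high-seed slopes exist per condition.
Since $\phi \propto 1/r_+$, a shared $r_+$ cancels exactly in the relative
metrics.

## Saturation binding and reference subtraction

Thermophoresis titrations are fitted with the two-parameter saturation
binding equation $Y = B_\mathrm{max} x / (K_d + x)$
(`fit_saturation()`), after optionally flooring the response at its lowest
observed value (`zero_floor()`), mirroring how such curves are presented. A
three-parameter variant with a free additive offset exists for synthetic
robustness checks. The two routes agree (within ~2% on $K_d$ at 1%
response noise) only when the titration's lowest concentration sits far
below $K_d$; when the curve does not reach baseline, the sample-minimum
floor still contains true signal and shifts $K_d$ by a few percent
independent of noise — the offset fit is then the safer route. As in
titration tables of weak binders, non-convergence is a reported value
(`converged = FALSE`), not an error. Biolayer-interferometry traces get the
standard correction (`bli_reference_subtract()`): reference sensor
subtracted, then the trace's own baseline-window mean, so association
starts near zero.

## Single-molecule pull-down imaging

Surface-captured aggregates appear as immobile diffraction-limited spots.
Averaging the 50-frame stack (`average_stack()`) raises SNR by
$\sqrt{50}$; `detect_spots()` then counts local maxima above a robust
threshold: image median plus `threshold_k` (default 5) times the MAD-based
robust s.d. Candidates are 3×3 local maxima with plateau ties resolved to
the smallest (row, col) in row-major order, and maxima closer than 3 px are
merged into the brighter one — the procedure is fully deterministic, which
matters for reproducible counting. At the default threshold a blank
512×512 noise field yields at most a couple of false maxima, while spots
with averaged-image SNR above ~7 are recovered essentially completely.
Pixel indices are 1-based; physical positions are
$(\mathrm{index} - 0.5) \times 105.4$ nm, the camera's pixel pitch.

## Morphometrics of super-resolved aggregates

Localization tables are grouped into aggregates by single-linkage
clustering cut at a 50 nm link radius (`cluster_localizations()`), with
clusters below 10 localizations discarded as background. For each
aggregate, `shape_metrics()` reports:

* **length** — the extent along the major covariance axis between the 1%
  and 99% projection quantiles. A plain maximum Feret diameter inflates by
  tens of percent under 20 nm localization noise (the extremes of hundreds
  of jittered points), while the trimmed extent stays within a few percent
  noiselessly and within ~20% at 20 nm precision.
* **area and perimeter** — from the convex hull of the localizations;
  **circularity** is $4\pi A / p^2$. Collinear clusters get area 0 and an
  undefined (NA) circularity.
* **eccentricity** — from the covariance (moment) ellipse, with a sampling
  debiasing step. The raw anisotropy $D^2 = (s_{xx} - s_{yy})^2 +
  4 s_{xy}^2$ of a finite sample overestimates the true anisotropy by its
  own sampling variance (eigenvalue repulsion): a perfectly circular
  aggregate sampled at 500–1000 localizations reads as ecc ≈ 0.3 from raw
  moments. The estimator subtracts the variance estimated from the data's
  fourth moments, $\widehat{V} = [\mathrm{var}(dx^2 - dy^2) +
  \mathrm{var}(2\,dx\,dy)]/n$, clamped at zero, before forming the
  eigenvalue ratio. The corrected estimator reports a median of 0 for
  isotropic shapes, leaves strongly elongated shapes essentially untouched,
  and is exactly rotation invariant. Its single-draw distribution on
  isotropic shapes is heavy-tailed, so distributional claims about
  eccentricity should use medians over aggregates rather than single
  values.

## What the synthetic data emulate — and what they do not

The generators produce every input the pipeline consumes, under the
conditions the analyses assume. `sim_tht_traces()` draws replicate ThT
curves from the generalized logistic model with i.i.d. Gaussian noise on
the normalized signal; the defaults (a = 50, kappa = 0.02 per minute,
c = 0.3, noise s.d. 0.02, three technical replicates, 1-minute sampling
over 2000 minutes) describe a low-seeded quiescent aggregation of 40 uM
monomer, with the plate-reader noise magnitude a calibration choice since
no instrument value is stated anywhere. `sim_binding_curve()` builds the
16-point 1:1.75 serial-dilution design. `sim_tirf_stack()` plants immobile
2-D Gaussian spots (PSF s.d. 1.5 px) over a camera offset with Gaussian
read noise. `sim_localizations()` scatters points uniformly along a rod or
over a disc and jitters them by the localization precision (default 20 nm,
1000 localizations).

Reproducibility follows one convention: every generator takes one integer
seed, and replicate $r$ draws under sub-stream seed + $r$, so a given
replicate is identical regardless of how many siblings are requested.

These generators are deliberately idealized. They do not model plate-to-well
gain variation, evaporation drift, or photobleaching in kinetic traces;
MST thermophoresis physics; PSF aberrations, pixelation noise or uneven
illumination in images; or fluorophore blinking, drift and multiple
localizations per emitter in the localization tables. Passing tests
therefore demonstrate that the estimators are correct and well calibrated
under their stated statistical assumptions — not that those assumptions
exhaust real instrument data.

## Statistical reporting

`anova_vs_control()` runs the omnibus one-way ANOVA and compares each
condition to the control with two-sided Welch t-tests, uncorrected for
multiplicity — the flag rides along in the result's metadata, and Dunnett's
many-to-one procedure is available via `method = "dunnett"`. Groups in
which every replicate is identical carry no variance estimate and raise a
degenerate-variance error. Star labels follow the four-tier convention
(* p < 0.1, ** p < 0.01, *** p < 0.001, **** p < 0.0001) with strict
comparisons, so boundary values fall to the weaker tier; a three-tier
convention without the weak single star is selectable.

## Problem sizes and worked scales

The suite and the acceptance script run everything at desk scale: kinetic
recovery uses 30–50 simulated three-replicate experiments of ~2000 points
each; flux oracles use 100 random parameter draws on grids of ~5000 points;
spot detection uses one planted 512×512 50-frame field plus 50 blank
fields; morphometrics use 31–201 aggregates of 500–1000 localizations.
These sizes were chosen so each check is statistically meaningful while the
whole pipeline re-runs in minutes on a single core.

## Known limitations

* The generalized logistic is an effective description; the package
  deliberately does not perform master-equation model competition or
  extract absolute microscopic rate constants ($k_+$, $k_2$ separately) —
  all rate comparisons are relative to the control.
* $\phi(t)$ inherits any misfit of $M(t)$; its closed forms are exact only
  for the fitted curve, not for the data.
* Spot counting assumes well-separated spots; fields much denser than a few
  hundred spots per 512×512 begin to lose counts to the 3 px merge radius.
* The eccentricity debiasing removes the leading sampling bias but not the
  blurring of true shape by localization precision; a rod thinner than the
  precision reads as a stadium of width set by the noise.
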