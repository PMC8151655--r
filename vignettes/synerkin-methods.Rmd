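---
title: "Models and methods behind synerkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind synerkin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synerkin)
library(dplyr)
```

`synerkin` turns raw plate-reader traces into three kinds of verdicts: an
enzyme-effector mechanism, a half-effect concentration (IC50/AC50), and a
drug-interaction class for two-agent mixtures. This vignette explains the
models each verdict rests on, the tunable parameters and their defaults,
what the synthetic-data generator does and does not emulate, and the
numerical choices that keep the pipeline stable.

## From traces to rates

A kinetic well is read every minute for a few minutes (default 3 min at
1-min intervals, matching common peroxidase and lipoxygenase protocols), so
a trace has only 4–8 points. `initial_rates()` estimates the initial
velocity as the OLS slope of absorbance versus time over the whole recorded
window. A two-point difference would use the same endpoints but discard the
interior reads; with so few points the regression slope is the natural
estimator of "change of absorption per minute" and comes with an R² that we
use as a quality flag. Traces with R² below `r2_threshold` (default 0.90)
are flagged, never silently dropped: at these trace lengths a single bad
read can sink R² while the slope remains usable, so the analyst decides.

Lipoxygenase activity is conventionally expressed in units of 0.001
absorbance increase per minute at 234 nm; `lox_units()` enforces the
wavelength because applying the conversion to a 470 nm trace would be a
silent unit error. Radical-scavenging (ABTS-type) assays are endpoint
reads, not traces: the decolorized absorbance after fixed incubation plays
the role of the rate, and the blank plays the role of the control.

## Enzyme kinetics and mechanism classification

Rates follow the Michaelis–Menten law $v = V_{max} S / (K_m + S)$.
`fit_michaelis_menten()` estimates the parameters by Levenberg–Marquardt
nonlinear least squares on the *untransformed* rates. The double-reciprocal
(Lineweaver–Burk) line is computed by `lineweaver_burk()` for display and
diagnostics only: the reciprocal transform massively inflates the influence
of the smallest rates, so it is never used for parameter reporting. On
noise-free data the two agree exactly, which the test suite asserts.

Fits use relative weights $1/v^2$. Plate-reader rate noise is
multiplicative — the scatter of a rate is roughly proportional to its
magnitude (a constant CV) — so weighting by the inverse squared signal makes
the residuals homoscedastic. This matters most for model *comparison*: with
unweighted least squares under CV-type noise, the deviance improvements of
an over-parameterized candidate are no longer $\chi^2$-calibrated, and in
simulation the 4-parameter mixed-inhibition model overtook the true
3-parameter competitive model in roughly one run in ten. With relative
weights the comparison is calibrated and the simpler true model wins.

`classify_mechanism()` fits six candidate global models across all effector
doses, sharing $K_m$ and $V_{max}$:

| candidate | dose law | parameters |
|---|---|---|
| none | — | 2 |
| competitive | $K_m \cdot (1 + I/K_i)$ | 3 |
| uncompetitive | $K_m, V_{max}$ both $/(1 + I/K_i)$ | 3 |
| noncompetitive | $V_{max} / (1 + I/K_i)$ | 3 |
| mixed | separate competitive and uncompetitive constants | 4 |
| activation | $V_{max} \cdot (1 + E_{max} A/(K_a + A))$ | 4 |

Selection is by AICc; models within 2 AICc of the best are treated as tied
and the tie goes to the fewer-parameter model, so an extra constant must
earn its keep. Mixed inhibition is included even when only uncompetitive
behaviour is expected, precisely so the classifier can be proven wrong.
Activation carries one extra guard: it is called only when the fitted rates
at every nonzero dose exceed the fitted control rates — the same criterion
one reads off a Lineweaver–Burk plot when the control line lies above all
effector lines. Effector constants are fitted on the log scale (they are
positive by definition), initialized from per-dose apparent-parameter
ratios: the apparent $V_{max}$ ratio senses the uncompetitive-type
constant, the apparent $K_m$ ratio the competitive-type constant.

Two numerical details. First, starting values: $V_{max,0}$ is the maximum
observed rate and $K_{m,0}$ the substrate concentration nearest half of it,
with five log-normally jittered restarts used only if the first attempt
fails. Second, on noise-free data the true model's residual sum of squares
is numerically zero and its AICc diverges to $-\infty$; the RSS is floored
at numerical precision so exact fits compare as ties and the
fewer-parameter rule decides deterministically.

## Median-effect dose–response

Effects are expressed as fractions: inhibition $f_a = 1 - v/v_0$,
scavenging $f_a = (A_{blank} - A)/A_{blank}$, activation
$f_a = \text{activation\%} / \text{plateau\%}$ (below). The median-effect
law
$$\frac{f_a}{1 - f_a} = \left(\frac{D}{D_m}\right)^m$$
is fitted by OLS of $\log_{10}(f_a/(1-f_a))$ on $\log_{10} D$ (base-10
logs throughout, the convention of the median-effect literature). The slope
is the sigmoidicity $m$; $D_m = 10^{-b_0/m}$ is the median-effect dose and
equals the IC50 identically under the $f_a$ definition. The equipotent
dose function is $D_x = D_m (x/(1-x))^{1/m}$, exactly inverted by
$f_a(D) = 1/(1 + (D_m/D)^m)$.

Fractions at exactly 0 or 1 have no logit and are excluded with a warning;
the remainder are clipped into `fa_bounds` (default 0.01–0.99) before the
transform. Clipping is a no-op when all points are interior, which the
tests assert. A fitted slope that is not positive means the data are not
monotone in dose; the fit is flagged invalid rather than silently
propagated. Fits are performed on per-replicate points, not dose means, and
all bootstrap resampling happens within dose.

Activation needs two conventions because activation percent,
$100(v/v_0 - 1)$, routinely exceeds 100 (a compound that doubles $V_{max}$
reaches 140% and more). The *operational* AC50 is the dose at which the
fitted dose–activation curve — the hyperbola
$\text{act\%} = P \cdot A/(K_a + A)$ of a nonessential activator — passes
through 50% activation relative to control: $A = 50 K_a / (P - 50)$,
defined only when the plateau $P$ exceeds 50%. For median-effect and
combination-index arithmetic, which require $f_a \in (0,1)$, the fraction
is plateau-normalized instead. Both are available; the operational AC50 is
what `estimate_ec50()` reports for activation assays.

## Fixed-ratio combination analysis

Two agents mixed at constant volume ratios (defaults 1:4, 4:1, 3:2, 2:3,
1:1) over a dose range form the classical fixed-ratio isobolographic
design. Each ratio's mixture is fitted with its own median-effect model on
*total* dose; the split into component doses happens afterwards. Volume
ratios are converted to dose fractions via per-component stock
concentrations (`stock_conc`): with equal stocks — the default, since
nothing in a volume ratio implies molarity matching — a 3:2 ratio is a
0.6/0.4 dose split, and unequal stocks are a configuration away.

At effect level $x$ (default 0.5, the IC50/AC50-centric choice; any level
or several can be requested) the combination index is
$$CI = \frac{d_1}{D_{x1}} + \frac{d_2}{D_{x2}} = \frac{1}{DRI_1} + \frac{1}{DRI_2},$$
with $d_i$ the component doses of the mixture achieving $x$ and $D_{xi}$
the single-agent equipotent doses. The two identities hold exactly by
construction and are asserted to $10^{-12}$ on every emitted row. Reported
per ratio, plus the across-ratio mean in `glance()`, since a single
published CI per pair may summarize either. Interaction labels follow the
refined band vocabulary (very strong synergism below 0.1 up to very strong
antagonism above 10, nearly additive on [0.90, 1.10]); the bands are
closed-open and monotone, so the label is a deterministic function of CI.
CI uncertainty is a nonparametric bootstrap SD (default B = 1000, seeded):
replicates are resampled within dose independently for the two single-agent
series and every mixture ratio, and the whole CI computation is repeated.

## The synthetic-data generator

The generator is the package's ground-truth instrument. Kinetic series are
exact mechanism-model evaluations on a substrate grid (default: 8
log-spaced points from 0.2 to 20 × $K_m$, 3 replicates) times a
multiplicative noise factor $1 + \varepsilon$, $\varepsilon \sim N(0, CV)$
truncated at −0.99 so rates stay positive — CV-style noise matches
plate-reader heteroscedasticity. Mixture designs are constructed by
inversion: for a target effect $x$ and ratio with dose fraction $p_1$, the
total dose is $\psi / (p_1/D_{x1} + (1-p_1)/D_{x2})$, which makes the
generated points satisfy $d_1/D_{x1} + d_2/D_{x2} = \psi$ *identically*, so
the pipeline's recovered CI has a known truth $\psi$ at every ratio and
effect level. Dose-effect series carry effects rather than rates, so noise
is applied to the surviving-activity fraction $1 - f_a$ — equivalent to
rate noise at a fixed control. When the two agents share the sigmoidicity
$m$, the constructed mixture is itself exactly median-effect in total dose
and noise-free recovery is exact to numerical precision; with unequal $m$
the mixture curve is only approximately log-linear, which is a property of
the fixed-ratio method itself, not of the implementation.

What the generator does *not* emulate: enzyme inactivation over time,
substrate depletion (traces are exactly linear apart from read noise),
inner-filter optical effects, plate-position or edge effects, and
non-Gaussian outliers. Passing recovery tests therefore demonstrate that
the estimators are correct and calibrated under the stated noise model, not
that any particular laboratory dataset satisfies that model.

## Problem sizes and reproducibility

Every stochastic function takes a `seed` and is bit-reproducible under it.
The test suite exercises Monte-Carlo calibration at sizes chosen to make
the relevant proportions statistically meaningful while staying
desk-sized: 200 seeds for median-bias checks of $K_m$ and of noisy CI
recovery, and 500 series per mechanism (at CV 5%, three doses, 8 × 3
points per dose) for classifier accuracy, where the ≥95% criterion has a
binomial standard error of about 1% at n = 500. Report CSVs written by
`run_pipeline()` carry a provenance header (package version, configuration
hash, seed), so a report is reproducible from its own first line.

## Known limitations

* Mechanism classification assumes rapid-equilibrium dose laws and a single
  effector; slow-binding or time-dependent inhibition is out of scope.
* The median-effect model is the only dose–response family offered (beyond
  the activation hyperbola); 4PL/5PL logistic alternatives are not fitted.
* Combination analysis covers two agents; three-drug mixtures and
  response-surface (Bliss, ZIP, HSA) scores are out of scope.
* The activation AC50 is undefined when the fitted plateau is below 50%
  activation; the package returns `NA` with a warning rather than
  extrapolating.
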