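# synerkin

Tidy analysis of microplate enzyme and radical-scavenging assays, from raw
kinetic absorbance traces to drug-interaction verdicts. `synerkin` is aimed
at researchers screening small molecules (for example dietary phenolic
acids) for enzyme activation or inhibition — thyroid peroxidase via guaiacol
oxidation at 470 nm, lipoxygenase via conjugated-diene formation at 234 nm,
ABTS radical scavenging — and for synergy or antagonism between pairs of
such compounds in fixed-ratio mixtures.

## What it computes

* **Initial rates.** Each well's absorbance-versus-time trace is reduced to
  an ordinary-least-squares slope (ΔAU/min), with R² quality flags and the
  234 nm lipoxygenase unit convention (1 unit = 0.001 ΔAU/min).
* **Enzyme kinetics and mechanism.** Michaelis–Menten parameters
  (v = V<sub>max</sub>·S / (K<sub>m</sub> + S)) are estimated by weighted
  nonlinear least squares; Lineweaver–Burk coordinates are provided for
  display. Across effector doses, six candidate global models — no effect,
  competitive (apparent K<sub>m</sub> scaled by 1 + I/K<sub>i</sub>),
  uncompetitive (apparent K<sub>m</sub> and V<sub>max</sub> both divided by
  1 + I/K<sub>i</sub>), noncompetitive, mixed, and hyperbolic activation
  (V<sub>max</sub> × (1 + E<sub>max</sub>·A/(K<sub>a</sub> + A))) — are
  compared by small-sample AICc to classify the mechanism.
* **Dose–response.** Effect fractions f<sub>a</sub> (inhibition %,
  scavenging %, activation % relative to control) are fitted with Chou's
  median-effect law f<sub>a</sub>/(1−f<sub>a</sub>) = (D/D<sub>m</sub>)<sup>m</sup>,
  giving IC50/AC50 (= D<sub>m</sub> for inhibition-type effects) with
  bootstrap uncertainties and the equipotent-dose function
  D<sub>x</sub> = D<sub>m</sub>·(x/(1−x))<sup>1/m</sup>.
* **Combination index.** For two agents mixed at fixed volume ratios
  (1:4, 4:1, 3:2, 2:3, 1:1), the Chou–Talalay index at effect level x is
  CI = d₁/D<sub>x1</sub> + d₂/D<sub>x2</sub> = 1/DRI₁ + 1/DRI₂: CI < 1
  synergy, CI = 1 Loewe additivity, CI > 1 antagonism, with refined labels
  (strong synergism, nearly additive, ...), dose-reduction indices,
  normalized isobologram coordinates and bootstrap SDs.
* **Synthetic data with known truth.** Generators for kinetic series, plate
  traces and fixed-ratio mixture designs with a controllable Loewe
  interaction index ψ, so every stage is testable by parameter recovery.

## Worked example

Classify a simulated uncompetitive lipoxygenase inhibitor and score a
synergistic mixture:

```r
library(synerkin)
library(dplyr)

# kinetic series: Km = 0.007 mM, Vmax = 1111 dAU/min, Ki = 0.009 mM, CV 5%
tr <- kinetic_truth(Km = 0.007, Vmax = 1111, mechanism = "uncompetitive",
                    Ki = 0.009, noise_cv = 0.05)
kin <- simulate_kinetic_series(tr, doses = c(0.005, 0.01, 0.02), seed = 42)
classify_mechanism(kin)
#> Effector mechanism: uncompetitive
#>   shared Km = 0.006652 mM, Vmax = 1078 dAU/min
#>   Ki = 0.009387 mM

# two agents (Dm = 0.10 and 0.69 mM) constructed to interact with psi = 0.24
truth <- mixture_truth(Dm1 = 0.10, Dm2 = 0.69, psi = 0.24, noise_cv = 0.05)
sim <- simulate_mixture_series(truth, seed = 42)
res <- combination_index(sim$mixtures,
                         filter(sim$agents, agent == 1),
                         filter(sim$agents, agent == 2),
                         B = 200, seed = 42)
select(as_tibble(res), ratio, ci, ci_sd, dri1, dri2, label)
#> # A tibble: 5 × 6
#>   ratio    ci   ci_sd  dri1  dri2 label
#>   <chr> <dbl>   <dbl> <dbl> <dbl> <chr>
#> 1 1:1   0.228 0.00801  5.05  33.3 strong synergism
#> 2 1:4   0.240 0.00722  6.68  11.0 strong synergism
#> 3 2:3   0.217 0.00667  5.66  24.9 strong synergism
#> 4 3:2   0.228 0.00776  4.83  47.8 strong synergism
#> 5 4:1   0.232 0.00847  4.47 118.  strong synergism
glance(res)
#> # A tibble: 1 × 5
#>       x mean_ci   sd_ci n_ratios label
#>   <dbl>   <dbl>   <dbl>    <int> <chr>
#> 1   0.5   0.229 0.00858        5 strong synergism
```

The recovered K<sub>i</sub> (0.0094 mM vs the 0.009 mM truth) and the
per-ratio CI values (0.22–0.24 vs ψ = 0.24) show the pipeline recovering
its generating parameters at realistic plate-reader noise; `autoplot(res)`
draws the dose-normalized isobologram with the additivity anti-diagonal.

Fitted objects follow broom conventions (`tidy()`, `glance()`) and each
result type has an `autoplot()` method. `run_pipeline()` orchestrates all
stages from trace CSVs to report CSVs with provenance headers, and
`inst/cli/synerkin.R` exposes the same stages as shell subcommands
(`simulate`, `rates`, `kinetics`, `dose`, `ci`).

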