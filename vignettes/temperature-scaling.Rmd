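---
title: "Modelling the temperature scaling of developmental timing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the temperature scaling of developmental timing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermodev)
```

## The model

A single reaction obeying Arrhenius kinetics has rate
$k(T) = A\,e^{-E_a/RT}$, with $R = 8.314\,\mathrm{J\,mol^{-1}K^{-1}}$,
$E_a$ the activation energy and $A$ the pre-exponential (frequency)
factor. In Arrhenius coordinates — $y = \ln k$ against $x = 1/T$ in
Kelvin$^{-1}$ — this is the straight line $y = \ln A - (E_a/R)\,x$.

Developmental intervals are not single reactions, but their rates
(defined as the reciprocal of the interval duration) can still be
regressed in these coordinates. The negative slope times $R$ is then an
*apparent* activation energy: a useful effective parameter describing
how strongly that interval's speed depends on temperature, not an
elementary energy barrier. Throughout the package, each per-embryo
interval observation is one regression point, carrying its own measured
temperature; per-temperature means ± standard errors are computed only
for display. This matches how replicate counts enter the reported
degrees of freedom, and avoids giving temperatures with more replicates
silently larger weight than their information content.

For a chain of $n$ sequential, irreversible first-order transitions the
expected total completion time is the sum of per-step times,

$$\tau(T) \;=\; \sum_{i=1}^{n} \frac{e^{+E_{a,i}/RT}}{A_i},
\qquad \ln k_{\mathrm{comp}}(T) = -\ln \tau(T).$$

The positive sign in the exponent follows from $\tau_i = 1/k_i$ applied
to the Arrhenius form of $k_i$; the package implements that
sign convention throughout and evaluates $\tau$ by log-sum-exp so that
activation energies up to 100 kJ/mol never overflow.

Writing $b_i = E_{a,i}/R$ and $w_i(x) = \tau_i(x)/\tau(x)$ for the
relative time spent in step $i$, the derivatives of the composite curve
have closed weighted-moment forms:

$$\frac{dy}{dx} = -\mathbb{E}_w[b], \qquad
  \frac{d^2y}{dx^2} = -\mathrm{Var}_w[b] \;\le\; 0 .$$

Two structural consequences drop out immediately. First, *concavity*:
any sequential chain is concave downward in the Arrhenius plot — rates
at both temperature extremes fall below the straight-line
extrapolation. Second, the *collapse identity*: steps sharing one
$E_a$ have zero variance and combine exactly into a single reaction
with $A_\mathrm{eff} = (\sum_i 1/A_i)^{-1}$, which is also the basis of
the reaction expansion: `expand_reaction()` splits a reaction into $m$
identical copies with $E_a' = E_a - R\,T_{\mathrm{ref}}\ln m$, making
the chain's relaxation time equal the original's exactly at
$T_{\mathrm{ref}}$ (and only there).

Curvature of the composite curve is quantified by the standard
plane-curve formula
$\kappa = |y''| / (1 + y'^2)^{3/2}$. Curvature is *not* invariant under
axis rescaling, so the package fixes the normative coordinates as
$x = 1/T$ in K$^{-1}$ and $y = \ln(\text{rate in min}^{-1})$; all
curvature values and the optimisation below are stated in that
convention. Derivatives are analytic (the moment identities above), and
the test suite cross-checks them against central finite differences
with a step of $10^{-6}$ K$^{-1}$, chosen to balance truncation error
$\mathcal{O}((bh)^2)$ against roundoff $\mathcal{O}(\varepsilon/h^2)$.

## Statistical machinery

**68% confidence intervals.** The half-width on $E_a$ is the Student-t
quantile at the fit's residual degrees of freedom times the slope
standard error (converted to kJ/mol). For the typical $n$ of tens of
embryos this is within a percent of ±1 standard error; the t convention
was chosen so that small-$n$ fits are not overconfident.

**Slope comparison (ANCOVA).** Whether two intervals share a slope is
tested by the extra-sum-of-squares F-test of the group × $1/T$
interaction: separate-slopes model against common-slope model.
Post-hoc power at level $\alpha$ uses the noncentral F distribution
with noncentrality $\lambda = F_{\mathrm{obs}} \cdot
\mathrm{df}_1$, the standard observed-power convention. The pipeline
reports raw pairwise p-values and, as a clearly labelled extension, a
Holm-adjusted column.

**Model selection.** Linear and quadratic fits in $x = 1/T$ are
compared with the Gaussian concentrated-likelihood BIC,
$\mathrm{BIC} = n\ln(\mathrm{RSS}/n) + k\ln n$ with $k = 2$ and $3$
parameters respectively (the profiled variance contributes equally to
both and cancels). The reported statistic is
$\Lambda = (\mathrm{BIC}_{\mathrm{lin}} -
\mathrm{BIC}_{\mathrm{quad}})/2$; $\Lambda > 0$ prefers the quadratic.
On exactly linear data the two RSS coincide and
$\Lambda = -\ln(n)/2$ — the penalty alone decides. Degenerate inputs
are resolved by a limiting rule: if only the quadratic interpolates
exactly, $\Lambda$ is set to a large sentinel (default $10^6$,
quadratic preferred); if both interpolate, the line is preferred.
Whether the published per-interval statistics were computed from
per-embryo points or per-temperature means is not documented anywhere
we could find; we use per-embryo points, consistent with the reported
replicate counts.

**Quadratic fits** default to *all* available temperatures, because the
departure from linearity lives at the extremes; a viable-regime
restriction is available as a configuration switch
(`quad_restrict_viable` in `analysis_config()`), with the fly default
14.3–30.1 °C and frog 12.2–28.5 °C. Linear fits default to the core
ranges 14.3–27 °C (fly) and 12.2–25.7 °C (frog); all ranges are
configuration, not code.

## Tunable parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `core_range` | 14.3–27 (fly), 12.2–25.7 (frog) | °C | linear-fit window |
| `viable_range` | 14.3–30.1 (fly), 12.2–28.5 (frog) | °C | optional quadratic/BIC window |
| `Ea_bounds` | 20–100 | kJ/mol | literature span of enzyme activation energies |
| `time_bounds_min` | 1/60–4320 | min | per-state time 1/k: 1 s to 3 days |
| `T_target_K` | 295.15 | K | temperature at which curvature is maximised |
| `n_starts` | 64 | — | multistart count for the optimisation |
| `lambda_cap` | 1e6 | — | BIC sentinel for an exactly interpolating quadratic |

The time bounds encode the judgement that no distinct embryonic state
resolves faster than a second, and none lasts longer than the roughly
three days of complete fly embryogenesis.

## The worst-case curvature optimisation

`optimize_worst_case()` maximises $\kappa$ at the target temperature
over two-reaction chains, parameterised as
$(E_{a,1}, E_{a,2}, \log t_1, \log t_2)$ with $t_i$ the per-reaction
time at the target, under box constraints on both. The optimiser is a
multi-start bounded quasi-Newton (L-BFGS-B) with an analytic gradient
derived from the same weighted-moment identities
($\partial m/\partial \log t_i = w_i(b_i - m)$,
$\partial v/\partial \log t_i = w_i[(b_i - m)^2 - v]$); 64 uniformly
sampled starts are the default, and constraint satisfaction at the
returned optimum is re-verified independently of the optimizer. The
interpretation of the $1/k$ bound as applying to each reaction's time
*at the target temperature* is normative here: the bound's published
description does not name a temperature.

Under these constraints the objective is monotone in each activation
energy toward the box bounds (the weights $w_i$ are free variables, so
$\partial \log\kappa / \partial E_{a,\mathrm{low}} < 0$ everywhere),
and the optimum therefore pins the activation energies to the bounds
themselves, with the time split interior. The optimised two-reaction
chain is then expanded to 1,000 reactions by splitting the lower-$E_a$
reaction into 999 identical copies via the collapse identity; the
expanded chain matches the parent's composite rate at the target
temperature to better than $10^{-9}$.

`random_network()` draws the comparison ensembles: $E_a$ uniform within
the same bounds and per-reaction times log-uniform within the time
bounds (log-uniform because the bounds span 5.4 decades and a linear
draw would concentrate all mass at the slow end), with $A_i$
back-solved so each reaction takes exactly its sampled time at the
reference temperature. A 1,000-reaction random chain leaves a residual
standard deviation below 0.01 around the best straight line over
14–28 °C — visually indistinguishable from Arrhenius behaviour.

## The synthetic-data generator

`timing_design()` + `generate_timelines()` emulate the structure of
scored time-lapse data: an ordered score sequence; per-interval true
Arrhenius parameters (optionally with a concave quadratic term $c_2$
in $1/T$); a temperature panel with a configurable number of replicate
embryos (defaults: 8 temperatures 14–28 °C, 5 replicates, matching a
realistic one-organism panel); multiplicative mean-one lognormal
duration noise of a given CV (default 5%, the scale of observed
replicate scatter for reproducible scores); optional per-temperature
clutch offsets (frog recordings at one temperature share a mother, fly
recordings do not — clutch effects default to off); optional
measured-temperature jitter emulating thermometer error; and a
viability window outside of which timelines are truncated after a
configurable number of leading scores, emulating death at temperature
extremes. Lognormal noise was chosen over additive Gaussian so that
durations stay positive and the CV is scale-free; the observed data
motivate a CV, not a specific noise law.

What the generator does *not* emulate: temperature-dependent noise
(scoring is harder at extremes), systematic concavity beyond the
supplied quadratic term, non-lognormal outliers from mis-scored
videos, and correlated errors between adjacent intervals sharing a
scored time point (in real tables, one mis-scored event perturbs the
two intervals it bounds in opposite directions). Passing recovery tests
on synthetic data therefore demonstrates the estimators are correct and
calibrated under the stated noise model, not that real scoring noise is
that model.

## Numerical and design choices

- Temperature conversion adds 273.15 exactly; $R = 8.314$
  J mol⁻¹ K⁻¹ is the package constant; $E_a$ is stored in kJ/mol and
  $A$ in min⁻¹ everywhere.
- CV screening uses the sample standard deviation ($n-1$), sensible at
  the replicate counts of 2–6 per temperature where the population
  formula would bias CVs low; temperatures with a single replicate are
  skipped rather than treated as zero-variance (a deliberate resolution
  of an ambiguity: with one embryo the CV is simply not identified).
- Score selection (`select_scores()`) is a greedy elimination: at each
  step the score whose adjacent-interval mean CV is largest is removed
  and adjacency is recomputed; ties keep the developmentally earlier
  score. Endpoint scores have a single adjacent interval, so a noisy
  terminal candidate can drag its neighbour's merit up — the tie rule
  resolves this deterministically but the greedy path is not a global
  optimum, which is acceptable for a screening heuristic.
- Negative or zero durations are scoring-order violations: excluded
  with a diagnostic, never clamped, because clamping would bias rates
  upward exactly where scoring is least reliable.
- Composite predictions feed each sub-interval fit's $(E_a, \ln A)$
  into the chain in min⁻¹ rate units; the tangent $E_a$ of the
  composite is invariant to the rate unit (a unit change shifts
  $\ln k$ by a constant and leaves the slope untouched).
- `tangent_align()` only ever shifts a curve vertically (the free
  constant when comparing shapes); slope disagreement is reported,
  never corrected.

## Problem sizes

The test-suite simulations use 200–500 replicate experiments for
coverage and recovery checks, 2,000 replicates for the ANCOVA type-I
error rate, 1,000 random 5-reaction networks for the concavity sweep,
and 10,000 random two-reaction competitors against the optimised
worst case; these sizes give Monte-Carlo standard errors comfortably
inside the asserted bands while keeping a full run in minutes on one
CPU.

## Known limitations

- The worst-case optimisation characterises two-parameter chains (then
  expanded); it does not search general $n$-reaction parameter spaces,
  branched or reversible topologies.
- Apparent $E_a$ from a composite process is an effective parameter;
  the package deliberately offers no mechanistic decomposition.
- Arrhenius variants with explicit heat-capacity terms (curved by
  construction) are out of scope.
- The CV screen and all fits treat embryos as independent given
  temperature; the clutch option in the generator exists precisely to
  probe how shared-mother correlation inflates apparent scatter, but
  the estimators themselves do not model it.
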