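---
title: "Kinetic modelling of sterol transport between plasma membrane and endo-lysosomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic modelling of sterol transport between plasma membrane and endo-lysosomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sterolkin)
```

## The biological problem

Mammalian cells move cholesterol continuously between the plasma membrane
(PM), recycling endosomes (REs) and late endosomes/lysosomes (LE/LYSs).
In Niemann-Pick type C2 disease, the luminal sterol-transfer protein NPC2
is missing, and sterol accumulates in LE/LYSs — specifically in their
intraluminal vesicles (ILVs), the precursors of secreted exosomes.
`sterolkin` implements a family of linear compartment models for the
trafficking of a fluorescent cholesterol analogue (DHE) through this
circuit, together with the analytic steady-state theory, a
two-pathway efflux model with a Weibull-delayed lysosomal export term,
global least-squares fitting of rate constants to fractional-fluorescence
time courses, and a synthetic-data generator for parameter-recovery
studies.

## The compartment models

The state is the sterol amount per compartment,
$n_1$ (PM), $n_2$ (REs), $n_3$ (limiting membrane of LE/LYSs, "LM") and
$n_4$ (ILVs), in arbitrary fluorescence units. Transport through the
PM → RE → LM circuit is modelled as unidirectional first-order steps with
rates $k_1, k_2$ and recycling $k_3$; LM and ILVs exchange bidirectionally
with rates $k_4$ and $k_{-4}$:

$$
\begin{aligned}
\dot n_1 &= -k_1 n_1 + k_3 n_3 \\
\dot n_2 &= k_1 n_1 - k_2 n_2 \\
\dot n_3 &= k_2 n_2 - (k_3 + k_4)\, n_3 + k_{-4} n_4 \\
\dot n_4 &= k_4 n_3 - k_{-4} n_4
\end{aligned}
$$

This is the `closed_four` variant; `closed_three` sets
$k_4 = k_{-4} = 0$ (adequate for NPC2-competent control cells, where
ILV/LM exchange is fast and the two pools behave as one). The
`open_four` variant adds a constant influx $v_0$ into the PM and a
first-order PM efflux $k_5$,
$\dot n_1 = v_0 - (k_1 + k_5) n_1 + k_3 n_3$, turning the cell into an
open system with a genuine steady state. A `reversible_two_branch`
comparison model (two independent reversible branches PM ↔ RE and
PM ↔ LE/LYS) is included only for model-selection demonstrations; its
exact published form is not available, and the four-rate parametrisation
used here is this package's interpretation.

Experimentally only the *sum* $n_3 + n_4$ is observable (the `LELY`
observable); the fitting layer therefore never fits LM and ILV curves
separately.

All rates are in min⁻¹ and all times are handled internally in minutes;
hour-valued inputs (efflux grids, Weibull time constants) are converted
at the interface.

## Analytic steady state of the open system

Setting the open-system right-hand side to zero gives, in closed form,

$$
n_3^\* = \frac{v_0 k_1}{k_3 k_5}, \qquad
n_1^\* = \frac{k_3}{k_1} n_3^\*, \qquad
n_2^\* = \frac{k_3}{k_2} n_3^\*, \qquad
n_4^\* = q_2\, n_3^\*,
$$

with the ILV/LM equilibrium constant $q_2 = k_4 / k_{-4}$. The
*fractional* distribution $(k_3/k_1 : k_3/k_2 : 1 : q_2)$ is independent
of $v_0$ and $k_5$, so the intracellular sterol fraction

$$
f_{\text{intra}} =
\frac{k_3/k_2 + 1 + q_2}{k_3/k_1 + k_3/k_2 + 1 + q_2}
$$

depends only on the transport rates. These expressions were derived here
by solving the linear system at steady state; the test suite verifies
them against an independent numerical `solve()` of the same system.
With the disease-cell rates the fraction is 0.3961, and it grows
hyperbolically with $q_2$ — intraluminal trapping alone explains the
endo-lysosomal sterol accumulation of NPC2-deficient cells:

```{r}
intracellular_fraction(dhe_params("disease"))
fraction_vs_q2(dhe_params("disease"), c(0, 0.2, 1, 2.15, 10))
```

The circuit transit time $1/k_1 + 1/k_2 + 1/k_3$ summarises how fast
sterol cycles between PM and endo-lysosomes: about 39 min with the
disease-cell rates and about 98 min for control cells — the circuit
itself is *not* slower in disease cells; the defect is confined to the
ILV ↔ LM exchange.

## Two-pathway efflux and the Weibull hazard

Sterol leaves the cell by two routes: pathway I, first-order efflux from
the PM (ectosome shedding and/or transfer to apoA1, rate $k_5$), and
pathway II, lysosomal exocytosis of ILVs as exosomes. Pathway II is
delayed and accelerating, described by the Weibull survival function
$S(t) = \exp(-(t/\tau)^\mu)$ with shape $\mu > 1$ (a compressed
exponential). Its hazard,

$$
k(t) = \mu\, k_6^{\mu}\, t^{\mu - 1}, \qquad k_6 = 1/\tau,
$$

enters the ILV balance as a time-dependent export coefficient:
$\dot n_4 = k_4 n_3 - k_{-4} n_4 - k(t)\, n_4$. The package applies this
drain to the ILV pool only — ILVs are the exosome precursors — while the
LM pool empties through it indirectly via $k_4$. The exact published
form of the efflux ODE system is in supplementary material not available
here; the equations implemented are a reconstruction from the narrative
and the model sketch, and are flagged as such.

Numerical conventions: $k(0) = 0$ for $\mu > 1$ (continuity), $k(t)
\equiv k_6$ for $\mu = 1$ (the model then collapses exactly to a
constant-rate export, which the tests verify against a matrix-exponential
solution), and $t = 0$ is a domain error for $\mu < 1$ where the hazard
diverges. `weibull_consistency_check()` integrates $\dot S = -k(t) S$
and confirms the hazard/survival pair is self-consistent to better than
1e-6.

Efflux simulations start, by default, from the open-system steady
fractions normalised to total 1, i.e. from the end of a long loading
period. (Whether the original analysis used steady-state or finite-time
loading fractions is not stated; steady-state fractions are this
package's choice.) The experimentally accessible readout is the LE/LYS
fraction $(n_3 + n_4)/\text{total}$, reported as `lely_fraction`. With
$k_6 = 0$ this fraction stays constant (within 2% over 200 h in the
reference scenario) even though total sterol declines — PM efflux alone
cannot deplete endo-lysosomes preferentially, which is the central
argument for pathway II. One published inconsistency is worth noting:
the narrative describes the simulated fraction as reaching a plateau
"after ca. 200 h, corresponding to 1,200 min" — the two numbers disagree
(200 h = 12,000 min); the simulation itself is the arbiter here, and with
$k_6 = 0.0015$ min⁻¹, $\mu = 2.577$ the plateau is reached on the
10,000–20,000 min scale. A second conflict concerns $k_6$ itself: one
passage states 0.01 s⁻¹ where the figure legends state 0.0015 min⁻¹; the
legend value in min⁻¹ is used throughout this package.

## Reference parameter values

`dhe_params()` carries the published global-fit estimates for DHE
transport in human fibroblasts (all min⁻¹):

| cell line | k1 | k2 | k3 | k4 | k-4 |
|---|---|---|---|---|---|
| disease (NPC2-deficient) | 0.03216 | 0.4331 | 0.1744 | 0.0084 | 0.0039 |
| control | 0.01204 | 0.2465 | 0.09351 | — | — |
| control_full (inferred) | 0.01204 | 0.2465 | 0.09351 | 0.01686 | 0.0843 |

Control-cell pulse-chase data determine only the three circuit rates
(the three-compartment model); `control_full` adds the ILV exchange
rates *inferred* from the steady-state comparison, corresponding to
$q_2 = 0.2$. `dhe_efflux_weibull()` provides the offset-Weibull efflux
parameters: $\tau = 135.14$ h, $\mu = 2.577$ for untreated disease cells
and $\tau = 86.96$ h, $\mu = 1.324$ after NPC2 add-back.

## Fitting

`global_fit()` minimises the pooled weighted least-squares objective over
all supplied datasets simultaneously (weights $1/\mathrm{sd}^2$ where
per-point uncertainties exist, uniform otherwise — the published data
carry no printed uncertainties, so uniform is the default), using
bounded Levenberg-Marquardt (`minpack.lm`). Each dataset's experiment
type implies its initial state: pulse-chase $(1,0,0,0)$, continuous
uptake $(0,0,0,0)$, efflux the steady fractions. Parameter standard
deviations come from the Jacobian-based covariance at the optimum;
the coefficient of variation is reported as sd/estimate. (The published
parameter table's CVs do not all equal sd/mean exactly as printed —
e.g. 0.0012/0.01204 = 0.0997 vs a printed 0.0970 — suggesting the
original software used a slightly different convention; sd/estimate is
used here and the discrepancy simply noted.) An optional multi-start
loop perturbs the guess by log-uniform factors in [0.2, 5] under a
recorded seed. AIC and BIC use the Gaussian least-squares forms
$n\ln(\mathrm{rss}/n) + 2p$ and $n\ln(\mathrm{rss}/n) + p\ln n$; the
original work names the criteria without formulas.

`fit_weibull_efflux()` fits the offset-weighted survival
$F(t) = f_\infty + (f_0 - f_\infty) e^{-(t/\tau)^\mu}$. On windows that
cover only part of the decay (96 h against $\tau = 135$ h), $\tau$,
$\mu$ and $f_\infty$ are mutually confounded and the least-squares
surface has local optima. The fitter therefore supports a deterministic
shape-regime multi-start ($\mu \in \{0.7, 1, 1.5, 2.5, 4\}$, lowest rss
wins), enabled by default when no starting guess is supplied. When a
caller does supply a guess, a single start from it is used — on noisy,
truncated windows the exhaustive search is *more* dispersed than a
Levenberg-Marquardt descent from a sensible start, because it chases
noise-fitting optima in the confounded directions.

Two identifiability caveats surfaced during development and are worth
knowing. First, a continuous-uptake curve alone constrains the transport
rates very weakly (a flat least-squares valley): the uptake protocol is
best used for steady-state comparison, or fitted with the known influx
and efflux pinned via the `fixed` argument. Second, uniformly sampled
pulse-chase grids with ~30 min spacing cannot resolve the fast RE
exchange ($1/k_2 \approx 2$ min), leaving the overall rate scale poorly
determined at realistic noise; the recovery studies in the test suite
therefore use log-spaced chase times (0–600 min, 12 points), which is
also how such experiments are designed in practice.

## The synthetic-data generator

The raw fluorescence data behind the published fits are not deposited,
so `generate_pulse_chase()`, `generate_continuous_uptake()` and
`generate_efflux()` produce datasets with the statistical structure the
analysis assumes: noise-free trajectories from the model plus additive
Gaussian measurement noise, clipped at zero (fractions cannot be
negative). Defaults: $\sigma = 0.02$ fraction units — chosen once so
that recovery CVs land in the 0.1–0.4 range of the published parameter
table — a pulse-chase grid of 0–120 min at 10 points and an efflux grid
of {0, 24, 48, 72, 96} h, mimicking the stated experimental spans (the
exact sampling times and replicate counts are not printed; these
defaults are stand-ins). Generation under a fixed seed is
bit-reproducible, and written CSVs carry a provenance comment (truth
parameters, seed, grid).

What the generator does *not* emulate: photobleaching, segmentation
error, cell-to-cell heterogeneity, albumin co-internalisation, or ACAT
esterification — the processes the original authors list as reasons the
model underestimates the measured intracellular fraction (0.3961
predicted vs 0.495 measured). Passing recovery tests therefore
demonstrate correctness of the estimation machinery under the assumed
noise model, not robustness to these real-data effects.

## Numerical choices

* Integration: `deSolve::lsoda` with `rtol = 1e-8`, `atol = 1e-10`.
  The rates span ~0.004–0.43 min⁻¹ (mild stiffness), but the Weibull
  hazard grows without bound, motivating an adaptive, stiff-capable
  solver. Constant-coefficient variants are verified against
  matrix-exponential solutions to 1e-7 in the tests.
* Solver undershoot below zero is clamped to 0 in the derived
  observables only; raw states are kept as solved.
* Parameter validation rejects negative rates outright rather than
  clipping — fitted rates are physical first-order constants.
* The $q_2$ sweep (`fraction_vs_q2()`) holds $k_{-4}$ fixed and varies
  $k_4$; the steady-state fraction depends on the two only through their
  ratio, so this choice reproduces the published sweep exactly.
* Fractions are printed to 4 decimals in summaries, matching the
  precision of the published values.
* Test problem sizes: recovery studies use 100 replicates (biphasic
  arm) plus 50 (single-phase arm) at 2% noise on the log-spaced grid;
  Weibull recovery uses 200 replicates at 1% noise on the 0–96 h grid.

## Known limitations

* No homeostatic feedback or de novo synthesis: efflux simulations
  deplete the cell entirely; they describe transient export kinetics
  only.
* ER, trans-Golgi and mitochondrial sterol pools are intentionally
  excluded (quantitatively minor for the analogue used).
* The ILV pool is parametrised indirectly (only $n_3 + n_4$ is
  observable), so $k_4$ and $k_{-4}$ carry the largest uncertainties —
  visible in their CVs both in the published table and in the
  package's own recovery studies.
* Well-mixed compartments are assumed; incomplete luminal mixing would
  produce stretched ($\mu < 1$), not compressed, export kinetics, which
  the efflux data exclude.
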