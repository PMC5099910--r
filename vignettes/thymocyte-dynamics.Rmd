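---
title: "Modeling thymocyte population dynamics with delayed compartments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling thymocyte population dynamics with delayed compartments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thymodyn)
```

## The model

T cells mature in the thymus through a conveyor of phenotypic stages:
bone-marrow (prenatally, fetal-liver) progenitors seed the CD4−CD8−
double-negative (DN) pool, DN cells differentiate into CD4+CD8+
double-positives (DP), and positive/negative selection yields the mature
CD4 and CD8 single-positive populations (SP4, SP8), which are exported to
the periphery. `thymodyn` models the cell counts of these four populations,
plus a bookkeeping pool `D` of apoptotic cells awaiting clearance by the
stroma, over the whole murine lifespan — from the first fetal progenitor
(~E10.5) to two years of age.

State variables are `N, P, SP4, SP8, D`, in units of $10^7$ cells (so "one
cell" is $10^{-7}$ units). The dynamics are

$$
\begin{aligned}
N' &= p_N(t)\,N - d_N N - s_N N + b(t) \\
P' &= p_P(t)\,P - d_P P - (s_4 + s_8)P + s_N\,N(t-\tau_N) \\
SP4' &= p_4(t)\,SP4 - d_4\,SP4 - s_{04}\,SP4 + s_4 P \\
SP8' &= p_8(t)\,SP8 - d_8\,SP8 - s_{08}\,SP8 + s_8 P \\
D' &= d_N N + d_P P + d_4\,SP4 + d_8\,SP8 - \delta D
\end{aligned}
$$

with transfer rates $s_\ast$, death rates $d_\ast$, export rates
$s_{04}, s_{08}$ (exported cells leave the system; only deaths feed `D`),
degradation rate $\delta$, and a discrete delay $\tau_N$ on the DN→DP
transfer: differentiation takes days, so the DP inflow at time $t$ reflects
the DN pool at $t - \tau_N$. By default the outflow term $-s_N N$ is
instantaneous (the conveyor reading: cells leave DN when they commit, and
arrive in DP after the maturation lag); a variant that lags the outflow
too is available via `delay_convention = "both_delayed"`.

**Decreasing proliferation.** The central modeling idea is that per-capita
proliferation decays exponentially with age,

$$ p_X(t) = c_X\, b_X\, e^{-b_X (t - t_\mathrm{ref})}, $$

which lets one model organism-level involution without density terms: the
thymus grows while proliferation outpaces loss and involutes inevitably as
it fades. Model class **M1** uses this law alone; class **M2** multiplies
it by a logistic density brake, $(1 - N/K_N)$ for the DN compartment and
$(1 - (P + SP4 + SP8)/K)$ for the others, with carrying capacities
$K_N, K$.

**Two stages.** Birth (19.5 days post-conception, dpc, in the modeled
strain) separates two physiological regimes, so every stage rate exists in
a prenatal and a postnatal version. Variant **V1** estimates both stages
freely; variant **V2** ties the postnatal proliferation amplitudes to the
prenatal values through
$c_\mathrm{post} = b_\mathrm{pre} c_\mathrm{pre} e^{b_\mathrm{pre} t_0}$,
removing three free parameters. Note that under the adopted proliferation
law with a postnatal decay clock restarting at birth (the default;
`postnatal_decay_clock = "absolute"` keeps a single clock), this formula
equals the prenatal amplitude re-expressed on an absolute clock and yields
exact rate continuity at birth only when the decay rates also agree; it is
applied verbatim as a parameter-tying device, not re-derived.

**Progenitor influx.** The DN source term is a three-parameter logistic,
$b(t) = b_0 / (1 + e^{-\beta (t - \tau_b)})$. The steepness $\beta$ is
never estimated: it is pinned by requiring the influx at thymopoiesis
onset $t_0$ to equal a single cell, $b(t_0) = 10^{-7}$, which has the
closed form $\beta = \log(b_0 \cdot 10^7 - 1)/(\tau_b - t_0)$ (the
implementation is cross-checked against a bisection root-finder in the
test suite). Initial conditions are an empty thymus at $t_0$ with zero
history; everything grows out of $b(t)$.

Free-parameter accounting follows from this structure: 18 rates per stage
(7 proliferation, 5 transfer/export, 4 death, $\delta$, $\tau_N$; +2
capacities under M2) plus the global $t_0, b_0, \tau_b$, minus the three
derived amplitudes under V2 — hence 39 (M1.V1), 36 (M1.V2), 43 (M2.V1),
40 (M2.V2).

## Numerics

The delay only enters through $N(t - \tau_N)$, so the system is integrated
by the **method of steps**: windows no longer than $\tau_N$, within which
the lagged term is a known function of the stored solution, making each
window a plain ODE solve. Windows are integrated by `deSolve` (`lsoda`,
`rtol = 1e-8`, `atol = 1e-12` by default) with a compiled right-hand side;
the lagged DN history is handed to the solver as a linearly interpolated
forcing built from the stored grid (0.01 d prenatally, 0.05 d postnatally
by default — far below any plausible $\tau_N$). A plain-R right-hand side
is exported (`rhs()`) and the two paths are cross-checked in the tests.
Birth is a hard window boundary: integration restarts there with the
postnatal parameters, so the rate jump never straddles a solver step;
the state itself is continuous.

Degenerate and pathological inputs: $\tau_N = 0$ collapses the lag onto
the current state (one window per segment); components in
$(-10^{-9}, 0)$ — solver noise around the invariant set — are clamped to
zero, while anything below $-10^{-9}$, or any non-finite state, aborts
with a diagnostic carrying the failure time (`thymodyn_blowup`). During
calibration such failures become an infinite objective rather than an
error.

**Accuracy is defined operationally**, not by matching a particular
solver: trajectories must agree with an independent brute-force Euler
integrator (explicit history buffer, fixed step $h = 10^{-3}$ d) to a
relative error below $10^{-3}$ over 40-day horizons. Two caveats shape
that comparison, both established by Euler self-convergence ($h = 10^{-3}$
vs $2.5\times10^{-4}$): a first-order method at this step is itself only
accurate to ~$10^{-3}$ when per-capita rates stay around 0.2/day — the
test instances are drawn accordingly — and its error transiently reaches
~$2\times10^{-3}$ in the steep early-growth tail where populations sit
orders of magnitude below their eventual size. The comparison norm
therefore measures each component relative to
$\max(|x|, 0.05 \max_t |x|)$: fully relative where a population is within
a factor 20 of its maximum, absolute against that scale below. Emergence
times (first crossing of a one-cell threshold, located by linear
interpolation on the stored grid) shift by less than $10^{-3}$ d under
grid refinement.

## Calibration

The mean-squared-error objective compares transformed observed counts with
transformed model predictions at each record's time and population.
Counts span four orders of magnitude across the lifespan, so the default
residual scale is $\log_{10}$ of counts in $10^7$-cell units, floored at
$10^{-8}$ (one-tenth of a cell) to keep empty compartments finite;
`linear` and `relative` scales are selectable. Models are scored by the
Gaussian least-squares AIC, $n \ln(\mathrm{MSE}) + 2k$, with $k$ the
free-parameter count above and $n$ the number of residuals — always
computed from the observation set, never assumed.

Optimization is a hybrid: differential evolution (rand/1/bin, $F = 0.7$,
$CR = 0.9$, reflection at the box bounds, population $\min(15d, 600)$)
with Nelder-Mead refinement of the incumbent every 20 generations and, at
termination, restarted refinements (a fresh simplex around the incumbent)
until no further improvement, up to three rounds. The initial population is sampled log-uniformly within the
box — rates span orders of magnitude, and a log prior seeds dynamically
tame candidates. At every evaluation $\beta$ is re-derived, V2 amplitudes
are recomputed, and the postnatal DP-throughput constraint
$s_N > d_P + s_4 + s_8$ (which keeps late-life DP above DN) is enforced by
death penalty. All randomness descends from one master seed through a
documented splitting map, so fits and bootstraps are bit-reproducible.

Uncertainty is quantified by a case-resampling bootstrap: replicates are
resampled with replacement within each (time, population) cell and the
model is refit `n_boot = 100` times (configurable), starting from the
incumbent of `n_prelim = 10` preliminary runs, with percentile 2.5/97.5%
intervals and per-parameter averages reported; the averages define the
central model used by the scenario analyses.

## The synthetic-data generator

Because the underlying census data are not redistributable, the package
generates its own: `study_design()` emulates a staged design — prenatal
sampling at E17.5/E18.5/E19.5, postnatal sampling at birth and every 5
days to day 50 plus day 80, four animals per point (a placeholder; actual
replicate counts per time point are rarely reported), all four live
populations plus the apoptotic pool. Noise is multiplicative lognormal
with unit mean (default CV 10%): counts are positive and span four orders
of magnitude, which rules out additive Gaussian noise, and
flow-cytometry-derived totals at the $10^6$–$10^8$ scale are effectively
continuous, so no Poisson discretization is applied.

`default_ground_truth()` returns the pinned reference parameterization. It
was calibrated once, by minimizing a weighted least-squares distance to
the documented developmental milestones — DN emergence just after
thymopoiesis onset (~E10.3), DP ~3.1 days later, SP4/SP8 ~0.9 days after
DP, a DN population peak near E16.5, the DN%/DP% composition crossing
~1.75 days before birth, ~$10^7$ cells at birth with DP already dominant,
postnatal expansion to ~$1.6\times10^8$ cells at 5–6 weeks with the adult
composition (DP ~80%, DN ~4%, SP4 ~10%, SP8 ~4%), and involution to ~$2
\times 10^7$ cells at one year — and then frozen. The progenitor-ablation
percentages were deliberately **excluded** from that calibration, so
scenario-level comparisons against them are out-of-sample validation of
the dynamics, not a fitting artifact. M2 variants reuse the set with
capacities placed above the M1 trajectory maxima (a mild late-growth
brake); V2 variants use prenatal decay rates chosen so the derived
postnatal amplitudes stay dynamically tame.

What passing tests on these synthetic data do show: the solver integrates
the delayed two-stage system correctly, the optimizer recovers
identifiable parameters at realistic noise, and the scenario engine
computes ablation impacts faithfully. What they cannot show: that this
particular parameterization is the biologically correct one — real
thymocyte counts carry litter effects, gating uncertainty and
strain-to-strain variation that lognormal replicate noise does not
emulate.

## Scenarios

`scenario_comparison()` solves the prenatal segment once and continues it
twice — postnatal influx held constant at the birth plateau $b_0$ versus
ablated to zero — so the two trajectories share a bit-identical prenatal
history. The impact table reports
$(\mathrm{with} - \mathrm{without})/\mathrm{with} \times 100\%$ per
population at six weeks, 3/6 months, 1 year, 18 months and 2 years after
birth. "Total thymocytes" counts live populations only by default (the
apoptotic pool is bookkeeping, not thymic cellularity); a switch includes
it. With the reference parameterization the ablated thymus tracks the
normal one closely for months — the DN pool present at birth sustains
downstream production — with the DN population affected first and most,
and all populations converging to ~100% impact in late life, when only
the influx-driven component survives.

```{r scenario, eval = FALSE}
spec <- default_ground_truth("M1", "V1")
cmp <- scenario_comparison(spec)
round(percentage_difference_table(cmp), 2)
milestone_report(cmp$with)
```

## Problem sizes and runtime choices

The packaged experiments are sized for interactive use: recovery tests
clamp all but 4–8 parameters, fit on designs truncated to the first
postnatal month where full lifespans are not needed, and use reduced
optimizer budgets (hundreds to ~1500 objective evaluations) with relaxed
solver control during fitting (`rtol = 1e-6`, history grids of 0.02-0.05 d
prenatally and 0.1-0.2 d postnatally). Recovery
experiments generate their observations at the same solver control used
in fitting; otherwise the noiseless objective floor measures solver
discretization rather than estimator quality, and that floor (~$2\times
10^{-5}$ on the log scale) is enough to bias weakly-sensitive death rates
by >10%. Bootstrap tests use small `n_boot` with restricted parameter
sets; full 100-replicate bootstraps of all 39 parameters are
overnight-scale computations run through `run_cli()`.

## Known limitations

* The dynamics are deterministic; demographic stochasticity at the
  one-cell scale (where the model starts) is not represented.
* A single discrete delay on DN→DP; the smaller DP→SP maturation lag is
  ignored by design.
* No peripheral T-cell compartment, no thymus transplantation or
  chimerism, no sex or strain structure.
* The density brake (M2) uses two capacities only — one for DN, one
  shared by DP/SP4/SP8 — mirroring the two-capacity structure of the
  model class it implements.
* Percentile bootstrap intervals are not bias-corrected; with strongly
  skewed resampling distributions BCa intervals would differ.
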