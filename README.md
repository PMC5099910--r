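# thymodyn

Delayed compartmental modeling of mouse thymocyte development, involution,
and the postnatal thymus's (in)dependence on bone-marrow progenitors.

## What it models, and for whom

T cells mature in the thymus along a conveyor of stages: progenitors seed
the CD4−CD8− double-negative pool (DN), which differentiates — after a
multi-day lag — into CD4+CD8+ double-positives (DP); selection then yields
the mature CD4 and CD8 single-positive populations (SP4, SP8) exported to
the periphery. `thymodyn` is for quantitative immunologists and systems
biologists who want to model the counts of these populations over the whole
murine lifespan — from the first fetal thymocyte (~E10.5) through the
postnatal peak to late-life involution — and to run in-silico experiments
such as cutting off the progenitor supply at birth.

The core is a five-equation delay-differential system for
`(N, P, SP4, SP8, D)` (the four live populations plus an apoptotic sink
collecting all dead cells, degraded at rate δ), in units of 10⁷ cells:

    N'   = p_N(t)·N   − d_N·N − s_N·N + b(t)
    P'   = p_P(t)·P   − d_P·P − (s_4+s_8)·P + s_N·N(t − τ_N)
    SP4' = p_4(t)·SP4 − d_4·SP4 − s_04·SP4 + s_4·P
    SP8' = p_8(t)·SP8 − d_8·SP8 − s_08·SP8 + s_8·P
    D'   = d_N·N + d_P·P + d_4·SP4 + d_8·SP8 − δ·D

Its distinguishing features:

* **Exponentially decreasing proliferation**, `p(t) = c·b·exp(−b(t−t_ref))`
  (model class M1), which captures age-driven involution without density
  terms; class M2 adds a logistic density brake with carrying capacities.
* **A birth switch**: prenatal and postnatal stages carry separate rate
  sets (variant V1), or postnatal proliferation amplitudes derived from
  prenatal ones via a continuity formula (variant V2, three fewer
  parameters). Free-parameter counts: 39 / 36 / 43 / 40 for
  M1.V1 / M1.V2 / M2.V1 / M2.V2.
* **Logistic progenitor influx** `b(t) = b0 / (1 + exp(−β(t−τ_b)))` whose
  steepness β is always derived so the influx at thymopoiesis onset t0
  equals exactly one cell.
* **A discrete DN→DP delay τ_N**, integrated by the method of steps
  (deSolve under the hood, compiled right-hand side).

Around the model: an MSE/AIC calibration engine (differential evolution
hybridized with Nelder-Mead, box constraints, a postnatal DP-throughput
constraint `s_N > d_P + s_4 + s_8`), a case-resampling bootstrap for
confidence intervals, progenitor-ablation scenario analysis, and a
synthetic-data generator emulating staged prenatal/postnatal cell-census
designs — so the whole pipeline is testable end to end without any
external data.

## Worked example

```r
library(thymodyn)

spec <- default_ground_truth("M1", "V1")   # pinned reference parameterization
cmp  <- scenario_comparison(spec)          # with vs without postnatal progenitors
milestone_report(cmp$with)
```

```
Developmental milestones (days post-conception):
  emergence: DN = 10.345, DP = 13.490, SP4 = 14.211, SP8 = 14.125
  delays: DN_to_DP = 3.144, DP_to_SP4 = 0.722, DP_to_SP8 = 0.636
  DN%=DP% crossing: 18.379
  total live peak: 16.254 (1e7 cells) at t = 57.65
```

The first DN thymocytes appear at E10.3 and the first DP about 3.1 days
later (the DN→DP delay), with SP4/SP8 following within a day; DP overtakes
DN as the dominant population about a day before birth (E19.5); the thymus
peaks at ~1.6×10⁸ cells around postnatal day 38 and involutes thereafter.

```r
round(percentage_difference_table(cmp), 2)
```

```
                 6 weeks 3 months 6 months 1 year 18 months 2 years
DN                 11.06    15.29    18.69  31.26     96.12  100.00
DP                  0.25     2.07    12.89  23.01     53.52   95.40
SP4                 0.12     0.76     9.06  21.45     44.07   91.97
SP8                 0.11     0.75     9.04  21.45     44.07   91.97
Total thymocytes    0.75     4.13    14.96  24.63     61.50   96.96
```

Each cell is `(with − without)/with × 100%` — the relative shortfall a
thymus deprived of progenitors at birth shows against a normally supplied
one. The signature result: for months the shortfall is minor (DP/SP4/SP8
under 1% at six weeks, total ~15% at six months) because the DN and DP
pools present at birth keep thymopoiesis running autonomously; only in late
life, when decreasing proliferation has exhausted the resident pools, does
the influx-fed component dominate and the difference approach 100%.

Calibration and uncertainty:

```r
design <- study_design(cv = 0.1)                        # staged census, 10% noise
obs    <- simulate_observations(spec, design, seed = 1)
fit    <- fit_model(obs, "M1", "V1", seed = 1)          # MSE + DE/Nelder-Mead
boot   <- bootstrap_fit(obs, "M1", "V1", n_boot = 100,  # percentile CIs
                        master_seed = 1)
```

A thin command-line pipeline wraps the same functions
(`inst/cli/thymodyn.R`): `synth`, `simulate`, `fit`, `bootstrap`,
`scenario`, `milestones`, each writing CSV/JSON artifacts plus a seeded,
versioned log.

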