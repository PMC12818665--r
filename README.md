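# cytotriad

Dynamics, stability and sensitivity analysis of the TNF-α / IL-6 / IL-10
cytokine network in acute post-stroke inflammation.

## The problem and who this is for

After an ischemic stroke, the pro-inflammatory cytokines TNF-α and IL-6
amplify each other through NF-κB-mediated cross-activation, while the
anti-inflammatory cytokine IL-10 — induced only after a transcriptional
delay, and only once pro-inflammatory signalling dominates — suppresses them
both. Whether a patient's inflammation resolves or persists depends on the
balance of these feedback loops. `cytotriad` implements a deterministic
three-variable ODE model of this triad for modellers and quantitative
immunologists who want to simulate therapeutic interventions (IL-10 boluses,
sustained TNF-α blockade, IL-10 knockout), map the model's steady-state and
bifurcation structure, and rank parameters by global sensitivity.

## The model

State variables are the concentrations (nM) of TNF-α (`C_T`), IL-6 (`C_6`)
and IL-10 (`C_10`); time is in hours:

```
dC_T/dt  = α_T  + k_T6 C_6 − β_T C_T − γ_T10 C_10 C_T
dC_6/dt  = α_6  + k_6T C_T − β_6 C_6 − γ_610 C_10 C_6
dC_10/dt = α_10 + (k_10T C_T + k_106 C_6) · h(C_T − C_6) · H(t − t_d) − β_10 C_10
```

where `h(d) = d^n / (K^n + d^n)` is a Hill gate on the clamped
pro-inflammatory excess `d = max(C_T − C_6, 0)` (cooperativity `n = 5`,
half-max `K = 0.3` nM) and `H(t − t_d)` is a Heaviside step delaying IL-10
induction until `t_d = 18` h. Default rate constants are the
literature-calibrated values returned by `cytokine_params()`.

The package provides:

- a breakpoint-aligned fixed-step RK4 integrator with intervention
  schedules (boluses, windowed parameter modulations) and scenario presets
  (`simulate_cytokines()`, `run_scenario()`);
- exhaustive steady-state enumeration by scalar reduction, analytic
  Jacobians in "exact" and "paper" modes, eigenvalue stability
  classification, and the closed-form (matrix-exponential) pre-delay linear
  solution (`enumerate_equilibria()`, `cytokine_jacobian()`,
  `solve_linear_subsystem()`);
- parameter sweeps with saddle-node (fold) detection, ascending/descending
  hysteresis protocols, and regression along equilibrium branches
  (`sweep_equilibria()`, `hysteresis_sweep()`, `branch_regression()`);
- variance-based global sensitivity analysis: Latin-hypercube/Saltelli
  sampling with Sobol first- and total-order indices (`lhs_sample()`,
  `sobol_indices()`).

Everything returns tibbles (or small S3 objects with `tidy()` / `glance()`
methods) and has a ggplot2 `autoplot()` method, so results pipe directly
into dplyr/ggplot workflows. A small CLI (`exec/cytotriad`) wraps the same
functions for shell use.

## Worked example

```r
library(cytotriad)

p  <- cytokine_params()                       # calibrated defaults
tr <- run_scenario("baseline", p, t_end = 72, dt = 0.01)
glance(tr)[, c("final_value_C_T", "final_value_C_6", "final_value_C_10")]
#>   final_value_C_T final_value_C_6 final_value_C_10
#> 1      0.01437893      0.01311694       0.01428571

enumerate_equilibria(p)
#> # A tibble: 1 × 9
#>      C_T    C_6   C_10 stability residual_norm  ...
#> 1 0.0144 0.0131 0.0143 stable         4.64e-14
```

The 72-hour baseline run relaxes onto the unique post-delay equilibrium
(≈ 0.0144 / 0.0131 / 0.0143 nM): with the default parameters the
pro-inflammatory excess never approaches the Hill threshold, so IL-10 stays
near its basal balance `α_10/β_10` and the system is monostable. Local
stability at the published reference state:

```r
cytokine_jacobian(p, c(C_T = 0.623, C_6 = 0.512, C_10 = 1.837), mode = "paper")
#> <jacobian_result> mode = paper , regime = post_delay
#>          [,1]     [,2]     [,3]
#> [1,] -1.98370  0.45000 -0.06230
#> [2,]  0.40000 -1.31022 -0.03072
#> [3,]  0.08318 -0.08318 -0.35000
#> eigenvalues: -2.186127+0i -1.107881+0i -0.349913+0i
```

All three eigenvalues are real and negative — a locally stable node with a
slowest mode of time constant `1/0.35 ≈ 2.9` h. Sweeping the IL-10
suppression efficacy `γ_T10` over 0.02–0.15 with the hysteresis protocol:

```r
glance(hysteresis_sweep(p, grid = seq(0.02, 0.15, length.out = 9),
                        t_settle = 200, dt = 0.05))
#>   parameter     max_gap n_grid all_settled
#> 1 gamma_T10 2.94903e-17      9        TRUE
```

The ascending and descending sweeps coincide to machine precision: under
the default parameter set the model is monostable across the whole range,
and the fold/hysteresis machinery is validated instead on analytic fixtures
(`generate_fixture("cubic_fold")`, `generate_fixture("ishigami")`). See the
methods vignette (`vignettes/cytokine-network-dynamics.Rmd`) for why, and
for every numerical choice.

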