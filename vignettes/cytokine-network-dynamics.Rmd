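---
title: "Methods: dynamics, stability and sensitivity of the post-stroke cytokine triad"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dynamics, stability and sensitivity of the post-stroke cytokine triad}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytotriad)
```

## The model and its assumptions

`cytotriad` models acute post-stroke neuroinflammation with three coupled
nonlinear ODEs for the concentrations (nM) of TNF-α (`C_T`), IL-6 (`C_6`)
and IL-10 (`C_10`):

$$
\begin{aligned}
\dot C_T &= \alpha_T + k_{T6} C_6 - \beta_T C_T - \gamma_{T10} C_{10} C_T\\
\dot C_6 &= \alpha_6 + k_{6T} C_T - \beta_6 C_6 - \gamma_{610} C_{10} C_6\\
\dot C_{10} &= \alpha_{10} + \left(k_{10T} C_T + k_{106} C_6\right)
  \, h(C_T - C_6)\, H(t - t_d) - \beta_{10} C_{10}
\end{aligned}
$$

The modelling assumptions are deliberately coarse: a single well-mixed
compartment (no infarct-core/penumbra gradients), first-order degradation
for all three species, receptor-level signalling (NF-κB, JAK-STAT, STAT3,
TNFR1/2) abstracted into effective rate constants, and deterministic
kinetics. Mutual TNF-α/IL-6 amplification is linear (`k_T6`, `k_6T`);
IL-10 suppression is bilinear in suppressor and target; IL-10 induction is
driven by the pooled pro-inflammatory signal `k_10T C_T + k_106 C_6`,
gated twice — cooperatively by a Hill function and temporally by a
Heaviside delay.

### The Hill gate and its clamp

`h(d) = d^n/(K^n + d^n)` is evaluated on the *clamped* pro-inflammatory
excess `d = max(C_T - C_6, 0)`. The gate is meant to encode activation by
pro-inflammatory *dominance*; without the clamp it would misbehave whenever
`C_6 > C_T` (spurious activation for even cooperativities, negative
production for odd ones — and the package treats `hill_n` as a continuous
real ≥ 1 so that sensitivity analysis can sample it over its screened range
2–8). The clamp makes the right-hand side well defined and continuous for
every admissible state and every `n`. The cost is a non-smooth point at
`d = 0`; the exact-mode Jacobian uses the one-sided derivative 0 there,
which is the correct two-sided derivative whenever `n > 1`.

The degenerate limit `K → 0` is excluded (`hill_K > 0` is a validation
invariant): the gate's derivative is singular there and no finite
parameterization of interest approaches it.

### The delay gate

`H(t - t_d)` switches IL-10 induction on at `t_d` (default 18 h). The
right-continuous convention `H(0) = 1` was chosen so that "induction active
from `t = t_d`" holds exactly at the switch node; nothing downstream
depends on the convention except the value of the RHS at the single instant
`t = t_d`. Inside the integrator the gate is resolved *per segment* (a
segment starting at `t_d` has the gate on), which agrees with the pointwise
convention at every grid node while keeping each integration segment
smooth — this is what preserves the integrator's order across the
discontinuity.

## Parameters

`cytokine_params()` returns the calibrated defaults; all are validated
(finite, nonnegative rates, strictly positive decay rates).

| field | meaning | default | units |
|---|---|---|---|
| `alpha_T`, `alpha_6`, `alpha_10` | basal production | 0.02, 0.01, 0.005 | nM·hr⁻¹ |
| `k_T6`, `k_6T` | cross-activation | 0.45, 0.40 | nM⁻¹·hr⁻¹ |
| `k_10T`, `k_106` | IL-10 induction drive | 0.15, 0.12 | nM⁻¹·hr⁻¹ |
| `gamma_T10`, `gamma_610` | IL-10 suppression | 0.10, 0.06 | nM⁻¹·hr⁻¹ |
| `beta_T`, `beta_6`, `beta_10` | decay | 1.8, 1.2, 0.35 | hr⁻¹ |
| `hill_n`, `hill_K` | induction gate shape | 5, 0.3 | —, nM |
| `t_delay` | induction delay | 18 | hr |

One documented ambiguity in the source material deserves note: the printed
form of the IL-10 equation carries the IL-6 induction rate on a TNF-α
concentration (`k_106 C_T`). The steady-state form of the same equation,
the parameter table ("IL-6-induced IL-10 production rate") and the
mechanism description all pair `k_106` with `C_6`, so the package
implements `k_10T C_T + k_106 C_6` and treats the other rendering as a
typographical slip.

## Integration

`simulate_cytokines()` uses the classical fixed-step fourth-order
Runge-Kutta scheme. Three design choices matter:

- **Breakpoint alignment.** The grid (`build_time_grid()`) is the union of
  per-segment uniform grids between consecutive breakpoints — the delay
  time, every bolus time, every modulation boundary. Each segment takes
  `ceil(length/dt)` equal steps, so the effective step never exceeds `dt`
  and every discontinuity sits exactly on a node. Integrating a smooth RHS
  within each segment preserves order 4; the suite verifies an empirical
  order in [3.9, 4.1] against a `dt = 1e-4` reference on the pre-delay
  segment, and agreement to better than `1e-8` (in practice ~`1e-15`) with
  the matrix-exponential closed form on the decoupled linear system.
- **Bolus semantics.** A bolus is an instantaneous state increment at an
  aligned node, applied *after* the node's state is recorded. The pre/post
  jump is therefore explicit in the output (the node at 24 h carries the
  pre-bolus value; the next node reflects the jump) and every RK4 step
  still integrates a smooth problem.
- **Modulations.** A `param_modulation(parameter, factor, start, end)`
  multiplies one parameter by `factor` while active; all active modulations
  apply multiplicatively. Activity is decided by the segment's left
  endpoint, which is exact because modulation boundaries are breakpoints.

Default `dt = 0.01` hr: the fastest default time scale is
`1/beta_T ≈ 0.56` hr, so `dt = 0.01` resolves it by a factor ~50 and the
convergence test justifies the choice a posteriori. States are clamped at
zero only for roundoff-scale negatives (|value| < 1e-9); anything more
negative raises an error telling the user to reduce `dt`, since the
continuous model is positivity-preserving (every species' production is
nonnegative when that species is zero — a property the suite asserts over
1000 random draws).

`run_scenario()` packages the four canonical experiments: baseline,
a 0.05 nM IL-10 bolus at 24 h, a 50% attenuation of basal TNF-α production
(`alpha_T × 0.5`) over the whole run, and IL-10 knockout
(`alpha_10 = k_10T = k_106 = 0`). "TNF-α expression attenuated by 50%" is
interpreted narrowly as scaling `alpha_T` only; users wanting a stronger
reading (e.g. scaling `k_T6` too) can express it directly with a
modulation schedule.

`summarize_trajectory()` reports per-species peaks (earliest node on ties)
and a resolution time: the earliest node after which TNF-α stays within a
5% band above its final value. The 5% default is a pragmatic, least
model-specific definition of "resolved"; it is a reporting convention, not
a model quantity.

## Equilibria and stability

For fixed `C_10` the TNF-α/IL-6 steady-state conditions are *linear*, with
the closed-form solution implemented in `solve_pro_subsystem()`
(denominator `D(C_10) = (\beta_T+\gamma_{T10}C_{10})(\beta_6+\gamma_{610}C_{10})
- k_{T6}k_{6T}`). Substituting into the IL-10 balance reduces equilibrium
finding to the roots of one scalar function of `C_10`. `enumerate_equilibria()`
scans `[0, C10_max]` on 10001 nodes, brackets sign changes, and bisects to
an interval width of 1e-12. `C10_max` defaults to twice the maximal
attainable IL-10 production over the `C_10 = 0` subsystem solution — an a
priori bound on any physical root — with a fallback cap when the subsystem
at zero is nonphysical (`D(0) ≤ 0`). Singular-`D` subintervals are excluded
and reported rather than silently skipped.

This scalar-reduction engine is exhaustive up to scan resolution and is
cross-checked in the suite against an independent million-point dense scan
(with `stats::uniroot` polishing) over 50 random parameter draws; every
reported equilibrium must re-satisfy the full RHS to `1e-10` sup-norm. Its
one blind spot is a root that touches zero without crossing — exactly a
fold point in parameter space, a measure-zero coincidence the sweep
machinery brackets from both sides instead.

`cytokine_jacobian()` implements two IL-10-row conventions. The **exact**
mode (default) applies the product rule to the induction term. The
**paper** mode reproduces a commonly quoted simplification that keeps only
the gate-derivative term with a pooled rate `(k_10T + k_106) h'(d)` and
forces antisymmetry `J_{32} = -J_{31}`; it is defined only for
`C_T > C_6` and is retained because the published eigenvalue analysis at
the reference state `(0.623, 0.512, 1.837)` with `gamma_T10 = 0.10` uses
it — the suite reproduces those eigenvalues `(-2.1886, -1.1052, -0.3502)`
to within 5e-3, and both modes satisfy the analytic trace identity
`tr J = -(\beta_T+\gamma_{T10}C_{10}) - (\beta_6+\gamma_{610}C_{10}) - \beta_{10}`
to machine precision. (That reference state is *not* itself an equilibrium
of the default parameter set — its RHS residual is order one — so the
package takes it purely as an evaluation point for the Jacobian
cross-check.) Stability is classified by eigenvalue real parts thresholded
at ±1e-9; classification stops at "marginal", with no center-manifold
analysis.

The pre-delay closed form `C(t) = e^{At}C_0 + A^{-1}(e^{At}-I)\alpha` is
evaluated with `Matrix::expm`. The RK4-vs-closed-form equivalence test
zeroes both suppression rates: the 2-D linear reduction drops the
`gamma · C_10` couplings, and with the default basal IL-10 balance
(`alpha_10/beta_10 ≈ 0.014` nM) those couplings shift trajectories by
~1e-3 — enough to mask the 1e-8 agreement the test is actually about.

## Bifurcation structure and hysteresis

`sweep_equilibria()` re-enumerates equilibria at every grid value of a
swept parameter (default: `gamma_T10` over 0.02–0.15 in 27 points — the
screened suppression range, with grid density chosen for desk-scale runs).
Folds are detected as changes in equilibrium count between adjacent grid
values and refined by bisection *on the parameter* to a width of 1e-4.
Count-change detection was chosen over pseudo-arclength continuation
because the scalar reduction makes exhaustive enumeration cheap and exact,
so there is nothing for continuation to add; the detector
(`find_fold_intervals()`) is generic and validated on the cubic normal
form `q + x - x^3`, whose folds sit analytically at `|q| = 2/(3\sqrt 3)`.

`hysteresis_sweep()` probes attractor selection dynamically: ascending and
descending passes over the grid, each point integrated to `t_settle`
(default 500 h — two orders of magnitude beyond the slowest default time
constant `1/beta_10 ≈ 2.9` h) from the previous attained state. Settling
is verified as a RHS sup-norm ≤ 1e-9; an unsettled point is retried once at
4× the horizon and flagged rather than failed, since near a fold the
approach slows critically and a warning is more informative than an error.

**A finding the package locks in as expected behaviour:** under the
default parameter set the post-delay equilibrium is unique across the
entire 0.02–0.15 suppression range — the steady pro-inflammatory excess
(`C_T - C_6 ≈ 0.001` nM) is far below the Hill threshold `K = 0.3` nM, so
the induction drive is ~1e-12 and the scalar residual is strictly
decreasing. The acceptance suite asserts exactly one equilibrium per grid
value, steady `C_T` variation below 1e-3 nM, and a hysteresis gap below
1e-6 nM. Bistability, fold points and genuine hysteresis therefore live in
*other* regions of parameter space (stronger induction drive, lower
thresholds); the fold and hysteresis machinery is validated on the
analytic cubic fixture instead, and `sweep_equilibria()` accepts any
parameter and grid for users exploring such regimes.
`branch_regression()` (OLS of steady `C_T` on the swept parameter,
`R² = 1 - SS_{res}/SS_{tot}`) serves the same exploratory role; on the
default sweep it reports a near-perfect but minuscule trend (slope
~ -1e-4 nM per unit `gamma_T10`).

## Global sensitivity analysis

The sampling scheme pairs two printed keywords — Latin hypercube sampling
and Sobol indices — that no single textbook estimator combines: plain LHS
supports only regression/correlation measures. The package's resolution is
a Saltelli design whose two base matrices are the halves of one
2k-dimensional Latin hypercube (`lhs::randomLHS`), completed with the
`AB_i` cross matrices: `n_base (k+2)` model runs. First-order indices use
the Saltelli estimator `mean(f_B (f_{AB_i} - f_A))/V`; total-order indices
the Jansen estimator `mean((f_A - f_{AB_i})^2)/(2V)`. Confidence
half-widths come from 200 bootstrap resamples of design rows. Everything
is deterministic given `seed`.

The estimator is benchmarked on the Ishigami function (`a = 7, b = 0.1`),
whose variance decomposition is known in closed form: at `n_base = 2^13`
the total indices land within 0.05 of `(0.5576, 0.4424, 0.2437)`, additive
test functions give `S1 ≈ ST` with `sum(S1) ≈ 1`, and a parameter the
output ignores gets `ST` within 0.03 of zero.

Model QOIs (`evaluate_qoi()`): `steady_state_CT` (default — equilibrium
TNF-α, the quantity that distinguishes pro-inflammatory from resolved
regimes), `final_CT_72h`, `peak_C10`, `auc_CT_0_72`, `resolution_time`
(coded 72 when unreached). Simulation-based QOIs use `dt = 0.02` to keep a
thirteen-thousand-run Saltelli design tractable; the default `n_base` is
1024. Screened ranges (`default_param_ranges()`) cover eleven parameters;
`hill_n` is sampled continuously over [2, 8]. Under the default QOIs and
these ranges the model's indices are dominated by whatever controls the
(nearly gate-free) linear balance; the package makes no claim of
reproducing any particular published index table, for the same
monostability reason documented above.

## Synthetic fixtures: what passing tests do and do not show

`generate_fixture()` produces the suite's analytic oracles: pure
exponential decay (integrator accuracy), a randomized stable 2-D linear
system (closed-form machinery), the cubic fold family (fold detection) and
Ishigami (Sobol estimation). These validate the *numerics* — order of
convergence, root exhaustiveness, estimator consistency. They do not
validate the *biology*: the model remains a three-species, well-mixed,
deterministic abstraction, and no fixture can substitute for clinical
cytokine time-series. Equally, the scenario tests (bolus suppresses
TNF-α/IL-6 node-wise; TNF-α inhibition lowers both TNF-α and downstream
IL-10) check directional, structural claims of the equations — not
quantitative agreement with patient data.

## Problem sizes and numerical tolerances

Chosen once, as desk-scale defaults: equilibrium scan 10001 points,
bisection widths 1e-12 (state) and 1e-4 (fold parameter), sweep grid 27
points, hysteresis settling residual 1e-9 at 500 h, RK4 default step 0.01
h, convergence test against a 1e-4 reference on a 10 h segment, brute-force
oracle 1e6 points over 50 random draws, Ishigami benchmark at
`n_base = 2^13`, positivity census 100 random draws × 72 h. Equilibrium
residual tolerance is 1e-10 sup-norm; trace identities are held to 1e-9 or
better.

## Known limitations

- No spatial structure, no stochasticity, no additional mediators (IL-1β,
  MCP-1, interferon-γ) or cellular actors; these are outside the model's
  scope by design.
- Fixed-step RK4 only — no adaptive error control. For stiff
  parameterizations far outside the screened ranges the negative-state
  guard will fire and ask for a smaller `dt` rather than adapt.
- The sharp Heaviside delay is a modelling idealization; distributed-delay
  formulations are not implemented.
- Fold detection reports count-change *intervals*, not codimension-1
  normal-form coefficients; marginal equilibria are reported as such
  without further classification.
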