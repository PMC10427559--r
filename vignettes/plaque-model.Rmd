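---
title: "A lipid-structured model of plaque macrophages: model, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A lipid-structured model of plaque macrophages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`plaquesim` simulates the macrophage population of an early atherosclerotic
plaque, structured by the ingested lipid load `a` of each cell. Lipid is
measured in units of the endogenous structural lipid of one cell, so the
minimum load is `a = 1`; time is measured in units of the reference
macrophage apoptosis timescale. The state consists of the live-cell density
`m(a, t)`, the apoptotic-cell density `p(a, t)` and the acellular necrotic
lipid pool `N(t)`. Writing `M`, `A_M` for the zeroth and first moments of
`m` (and `P`, `A_P` for `p`), the dimensionless system is

```
m_t + [lam/M + theta N] m_a = eta (m * p)(a) + 4 rho g_rho(2a-1) m(2a-1)
                              - [g_beta(a) + gamma g_gamma(a) + rho g_rho(a) + eta P] m
p_t = g_beta(a) m - [nu + eta M] p
N'  = nu A_P - theta M N
```

with the recruitment boundary condition
`[lam/M + theta N] m(1, t) = (A_M - M) / (kappa + A_M - M)`,
where `(m * p)(a)` is the efferocytosis convolution
`int_1^{a-1} m(a') p(a - a') da'` (zero for `a <= 2`: both cells carry at
least one unit of structural lipid).

The processes, term by term:

* **Lipid ingestion** advects every live cell to larger loads at the common
  speed `lam/M + theta N`: the net LDL-minus-HDL influx `lam` is shared
  across the population (quasi-steady consumption), and necrotic lipid is
  consumed by mass action at rate `theta` per cell.
* **Apoptosis** converts live into apoptotic cells at rate `g_beta(a)`
  (reference rate 1).
* **Emigration** removes live cells, and their lipid, at rate
  `gamma g_gamma(a)`.
* **Proliferation** at rate `rho g_rho(a)` removes the parent and creates
  two daughters, each carrying half the parent's ingested lipid plus one
  unit of newly synthesised structural lipid: daughters at `a` come from
  parents at `2a - 1`, which gives the nonlocal `4 rho g_rho(2a-1) m(2a-1)`
  source (a factor 2 for two daughters and a factor 2 from the coordinate
  stretch of the doubling map).
* **Efferocytosis**: each apoptotic cell is engulfed whole by a live cell
  at the mass-action rate `eta M`; the engulfing cell, drawn from the live
  distribution, jumps up by the dead cell's full load. This is the
  convolution source, the `eta P m` redistribution sink, and the `eta M p`
  loss in the `p` equation.
* **Secondary necrosis**: uncleared apoptotic cells lyse at constant
  per-cell rate `nu`, feeding their lipid into `N`.
* **Recruitment** brings in new cells at the minimum load `a = 1`, as a
  saturating (half-maximal at `kappa`) function of the accumulated lipid
  `A_M - M`, which proxies the inflammatory signalling of loaded cells.

Every term conserves cells and lipid consistently: integrating the `m` and
`p` equations (with and without the weight `a`) yields a closed set of
moment identities, and the total lipid `L = A_M + A_P + N` obeys the ledger
`dL/dt = F + lam + rho G_rho - gamma G_{gamma a}` (recruitment and influx
add lipid; emigration removes it; each division adds one unit of structural
lipid). These identities are enforced as tests against independently coded
oracles, not assumed.

The boundedness condition
`g_beta(a) + gamma g_gamma(a) - rho g_rho(a) > 0` for all `a` is required
for the population to remain bounded; `integrate_plaque()` refuses
configurations that violate it.

## Parameters

The dimensionless defaults of `model_parameters()` are `gamma = 0.2`,
`kappa = 25/6`, `rho = 0` or `0.5`, `nu = 1`, `lam = 0.1`, `theta = 0.6`,
`eta = 9.6`. They correspond, through `nondimensionalise()`, to the
dimensional estimates `beta = nu = 0.05/h` (apoptosis, post-apoptotic
lysis), `gamma = 0.01/h` (emigration), `alpha = 1e4 cells/h` (maximal
recruitment), `eta = 2.4e-6 /cell/h` (efferocytosis) and
`theta = 1.5e-7 /cell/h` (necrotic consumption), with
`rho = 0.025/h` for the proliferative case (a ~28 h doubling time).
With all modulations constant this parameterisation produces a small,
relatively benign reference plaque; the closed-form fixed point is
available in `lipid_independent_steady()`.

On `kappa`: the half-maximal recruitment constant is 25/6. We verified
against the closed moment system that this value — and not the rounded
`kappa = 5` — reproduces the reference steady states
(`M = 0.243`, `N = 4.03` without proliferation); `kappa = 5` would give
`M = 0.185`, `N = 5.23`.

## Lipid-dependent rate modulations

Two families modulate apoptosis, emigration or proliferation:

* **Saturating** (monotone): `g(a)` runs from 1 at `a = 1` to a limit
  `delta` with half-way value at `a_half` and Hill exponent `n`. Rising
  forms (`delta > 1`) model lipotoxic apoptosis; falling forms model
  reduced emigration or proliferation of foam cells.
* **Peaked** (non-monotone): `g(a) = eps + (1 - eps) h(a-1)/h(x*)` with
  `h(x) = x^k / (b^q + x^q)` and `x* = b (k/(q-k))^{1/q}`. It rises from a
  floor `eps` at `a = 1` to a peak of exactly 1 at `a = 1 + x*` and decays
  back to `eps`. This is the normalised form fixed by the properties we
  require of it — floor at the minimum load, unit peak, the peak location
  `1 + b` when `k = 1, q = 2` — and its steady-state predictions are
  validated against the published peaked-emigration values in the
  acceptance suite; the shape is used for emigration, where newly
  recruited cells are unlikely to leave before ingesting some lipid while
  heavily loaded cells are retained.

**Scaled scenarios.** To compare lipid-dependent against lipid-independent
kinetics at a matched net rate, a scaling constant multiplies the
modulation so that the steady-state population-averaged rate
`G = int g m da / M` equals 1 (accepted at `1 +/- 0.01`;
`calibrate_scaling()` finds the constant by warm-started secant iteration,
each trial being a full run to steady state). The scaling is applied with
behaviour-specific semantics, encoded once in `eval_modulation()`:
apoptosis and proliferation scale multiplicatively; for saturating
emigration the limit is divided by the scaling so the large-`a` emigration
rate is unchanged; for peaked modulations only the bump above the floor is
scaled, preserving both endpoints. The asymmetry matters because the model
is sensitive to the emigration rate of heavily loaded cells.

## Initial conditions (the stated world of the generator)

`initial_state()` seeds both densities with the same half-normal shape of
width `a_sigma`, anchored at `a = 1` — a young lesion whose cells have
ingested little lipid, with half as many dead cells as live ones
(`P0 = 0.5 M0`) and no necrotic core (`N = 0`). Requiring the initial
profile to satisfy the recruitment boundary condition fixes the initial
population `M0 = kappa lam sqrt(2 pi) / (a_sigma (a_sigma sqrt(2 pi) - 2 lam))`,
which needs `a_sigma > lam sqrt(2/pi)` (about 0.08 at the default `lam`).
`a_sigma` has no published value; we default to `a_sigma = 1` (the natural
lipid scale of a newly recruited cell) and verify in the test suite that
the steady states — the quantities of scientific interest — are unchanged
when `a_sigma` is halved or doubled, so the choice is immaterial for
everything the package reports at convergence. What the generator does
*not* emulate: established plaques (start from a saved state instead),
stochastic recruitment, or any spatial structure.

## Numerical method

The equations are solved by the method of lines on a truncated domain
`[1, a_max]`:

* **Grid**: nodes uniformly spaced at `h0 = 0.05` on `[1, a_fine = 15]`
  and geometrically coarsened to `a_max` (default 300; 1000 for
  lipid-dependent emigration, whose steady distributions are heavy-tailed).
  Trapezoidal weights make the grid double as the quadrature rule.
* **Advection**: conservative finite-volume upwinding (the speed is
  positive and the same at every `a`) with second-order MUSCL
  reconstruction and minmod limiting. The recruitment flux enters exactly
  as the inflow flux at `a = 1`, so total cell number balances to
  round-off and the boundary cell relaxes to `m(1) = F/speed` without an
  algebraic constraint. Outflow at `a_max` is free; the fraction of `M` in
  the last 5% of the domain is monitored against `tail_tol` and a run
  fails with advice to enlarge `a_max` if the truncation bites.
* **Nonlocal terms**: the efferocytosis convolution is evaluated by a
  precomputed trapezoid-plus-linear-interpolation quadrature plan (direct
  `O(n^2)`, built once per grid); the doubling-map proliferation source
  interpolates `m(2a - 1)` linearly and treats parents beyond `a_max` as
  absent. Both operators are verified against naive double-loop R
  implementations to 1e-12 on small grids, and against closed forms
  (shifted-exponential convolution; the doubling map's moment
  identities). Efferocytosis events whose combined load exceeds `a_max`
  generate no source; together with the advective outflow at `a_max` this
  truncation flux is logged with every trajectory (columns
  `conv_lipid_deficit` and `outflow_lipid`) so the lipid ledger can be
  closed exactly on the computational domain. The steady state amplifies
  lipid-moment imbalances by `1/gamma = 5` through the recruitment
  balance `A_M = (F + lam)/gamma`; at the default resolution the
  competing truncation and resolution biases leave the base-case moments
  within ~0.2-0.4% of the closed-form fixed point.
* **Time stepping**: explicit Heun (RK2) with its embedded Euler error
  estimate used to reject and adapt steps, always capped by the advective
  CFL bound `cfl * h_min / speed` (default `cfl = 0.6`, which keeps the
  limited scheme positivity-friendly). Densities are clipped to zero only
  below 1e-12 in magnitude; negativity beyond 1e-8 aborts the run.
  Values below 1e-290, and all denormals (via FTZ/DAZ on x86), are
  flushed to zero — the tails decay over hundreds of e-foldings and
  denormal arithmetic would otherwise dominate the run time without
  contributing anything above round-off.
* **Steady state**: declared when the relative rate of change of all five
  scalar summaries stays below `steady_tol = 1e-6` per unit time over a
  window of 20 time units, after a minimum time of 50. The transient
  regime is classified from the logged `M(t)`: at least four sign changes
  of `dM/dt` (above a noise floor of 1e-3 of the dynamic range) with a
  shrinking envelope is reported as a decaying oscillation.

Resolution: at the default `n = 1200` nodes the lipid-independent steady
states agree with the closed-form fixed point to about 0.2%; at the
reduced resolutions used in the test suite (500–700 nodes, `h0` up to
0.2) the error grows to 1–3%, which the tests account for explicitly.
Halving the resolution roughly quadruples the error, consistent with the
second-order design.

## Heavy emigration tails and domain truncation

When emigration declines with lipid load, the steady live-cell
distribution develops a tail far heavier than exponential: the
efferocytosis convolution keeps promoting cells to ever larger loads
(its source term grows relative to the sinks as `a` increases), and the
cells it produces are precisely those least likely to leave. On any
feasible truncated domain a small fraction of the population
(~1e-3 of `M` beyond 95% of an `a_max` of 1000–1500) sits in this tail,
and population-averaged quantities such as the steady emigration rate
`G_gamma` consequently depend on `a_max` at the level of a few percent.
This is a property of the model, not of the discretisation: the logged
summaries are time-stable long after convergence, and grid refinement at
fixed `a_max` changes `G_gamma` far less than moving `a_max` from 1000
to 1500 does. Results for lipid-dependent emigration should therefore
always be quoted together with the domain; the shipped scenarios use
`a_max = 1000` and the `tail_tol = 5e-3` guard (a threshold chosen above
the irreducible physical tail fraction but well below what a genuinely
truncated run produces).

## Transient regimes and the recruitment constant

The approach to steady state is classified from the logged `M(t)`. With
the default `kappa = 25/6` every shipped scenario settles monotonically
after the initial transient. When recruitment is made more sensitive to
accumulated lipid (larger `kappa`, e.g. `kappa = 5`) the severe
lipid-dependent apoptosis case (`a_half = 9`, `limit = 4`) instead
approaches its steady state through slow decaying oscillations —
repeated waves of recruitment, lipid accumulation, mass death and
necrotic-core consumption — converging only after `t ~ 1400`. The
classifier labels these regimes `"monotone_settling"` and
`"decaying_oscillation"` respectively; the oscillation test in the
acceptance suite exercises both.

## Degenerate inputs and edge cases

Population collapse (`M <= 0`) raises an error rather than NaN; `A_M < M`
beyond round-off is reported as state corruption; configurations violating
the boundedness condition are refused up front, including trial scalings
during calibration. The convolution is identically zero at or below
`a = 2`, and proliferation of parents beyond the domain edge is treated as
absent (their sink term still applies, which slightly underestimates
doubling for cells within a factor 2 of `a_max`; the tail guard keeps this
below tolerance).

## Known limitations

* Phagocytosis (`theta`) and efferocytosis (`eta`) are lipid-independent;
  only apoptosis, emigration and proliferation carry modulations.
* One modulation is lipid-dependent at a time in the shipped scenarios
  (the solver itself accepts any combination that satisfies boundedness).
* No spatial structure, no macrophage phenotype, no dimensional-time
  output beyond the conversion helper.
* The domain truncation interacts with slowly decaying emigration
  scenarios; these need `a_max = 1000` and still lose a tail fraction that
  is monitored rather than eliminated.
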