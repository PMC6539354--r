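---
title: "Dynamic network SBM-DEA: model, numerics, and design choices"
author: "dndea"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic network SBM-DEA: model, numerics, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dndea)
```

## The measurement problem

Classical DEA treats each decision-making unit (DMU) as a black box that
turns inputs into outputs in a single period. Many processes are not like
that: a city's economy produces GDP *and* pollution, the pollution becomes
an input burden on its health system, and capital stocks tie one year's
possibilities to the next. Ignoring that structure both overstates
efficiency (a unit can look fine on aggregate while one internal stage is
badly run) and misattributes it. The model implemented here evaluates a
panel of DMUs × periods × divisions jointly: divisions are linked within a
period by intermediate products ("links", consumed as inputs by the
receiving division), and consecutive periods are tied by good carry-overs
with an explicit continuity constraint.

## Model statement

For each DMU *o* the package solves one fractional program. Decision
variables are an intensity vector $\lambda_k^t \ge 0$ per (division,
period) — the convex weights defining o's benchmark on the frontier — and
nonnegative slacks for every variable: input excess $s^{t-}$, link excess
$s^{in,t}$, good-output shortfall $s^{good,t+}$, bad-output excess
$s^{bad,t-}$, and carry-over shortfall $s^{good(t,t+1)}$.

The objective is the non-oriented SBM ratio

$$\theta_o^* \;=\; \min\;
\frac{\sum_t W^t \sum_k W^k \Big[\,1-\tfrac{1}{m_k+linkin_k}\big(\sum_i
\tfrac{s_{iok}^{t-}}{x_{iok}^t}+\sum_l \tfrac{s_{o(kh)l}^{in\,t}}{z_{o(kh)l}^{in\,t}}\big)\Big]}
{\sum_t W^t \sum_k W^k \Big[\,1+\tfrac{1}{r_{1k}+r_{2k}+ngood_k}\big(\sum_r
\tfrac{s_{rok}^{good\,t+}}{y_{rok}^{good\,t}}+\sum_r
\tfrac{s_{rok}^{bad\,t-}}{y_{rok}^{bad\,t}}+\sum_{c}
\tfrac{s_{oc}^{good(t,t+1)}}{z_{oc}^{good(t,t+1)}}\big)\Big]}$$

subject to, for every $k,t$: $x_o^t = X^t\lambda_k^t + s^{t-}$,
$y_o^{good,t} = Y^{good,t}\lambda_k^t - s^{good,t+}$,
$y_o^{bad,t} = Y^{bad,t}\lambda_k^t + s^{bad,t-}$,
$z_o^{in,t} = Z^{in,t}\lambda_k^t + s^{in,t}$,
$z_o^{good(t,t+1)} = Z^{good(t,t+1)}\lambda_k^t - s^{good(t,t+1)}$,
$e'\lambda_k^t = 1$, and carry-over continuity
$\sum_j z_j^{good(t,t+1)}\lambda_{jk}^t =
 \sum_j z_j^{good(t,t+1)}\lambda_{jk}^{t+1}$ for $t = 1,\dots,T-1$.

Interpretation: the numerator discounts 1 by the average relative excess of
the cost-like quantities (inputs and incoming links), the denominator
inflates 1 by the average relative shortfall/excess of the benefit-like
quantities (good outputs, bad outputs, carry-overs). $\theta^*_o = 1$ if
and only if no feasible benchmark improves any variable — the unit is on
the efficient frontier.

Period, division, and division-period efficiencies are the same ratio
restricted to one period column, one division row, or one block:
$\partial_o^*(t)=\frac{\sum_k W^k N_k^t}{\sum_k W^k D_k^t}$,
$\varphi_o^*(k)=\frac{\sum_t W^t N_k^t}{\sum_t W^t D_k^t}$,
$\rho_o^*(k,t)=N_k^t / D_k^t$, where $N_k^t, D_k^t$ are the bracketed
numerator and denominator parts at the optimum.

### Conventions the implementation fixes

* **Single optimization per DMU.** The decomposition scores are read from
  the slacks that are optimal for the *overall* program. This keeps the
  exact identity $\theta^* = \sum_{t,k} W^tW^k N_k^t \,/\, \sum_{t,k}
  W^tW^k D_k^t$ (a weighted mediant, so $\theta^*$ always lies between the
  smallest and largest period score, and likewise over divisions). Passing
  `reoptimize = TRUE` to `dndea()` instead re-minimizes each slice's own
  ratio under the full constraint set; re-optimized scores can only be
  lower or equal, and the identity then no longer binds.
* **Weights.** $W^t$ and $W^k$ default to uniform and are normalized to
  sum to one. Any common rescaling cancels in the ratio (tested).
* **Links are inputs to the receiver.** A link variable constrains only the
  receiving division's intensity block and its slack enters the numerator.
  An optional within-period continuity constraint tying the source and
  target blocks (`link_continuity = TRUE`) is off by default, since only
  the receiving-side balance is part of the printed model.
* **Carry-over indexing.** The period-*t* value of a carry-over is the
  stock carried out of period *t*; the continuity constraint runs over
  $t = 1..T-1$, while the carry-over balance (and its slack, which counts
  as a good) exists in every period.
* **Returns to scale.** $e'\lambda = 1$ is hard-wired (variable returns to
  scale). No constant-returns switch is exposed.

## Linearization and numerics

The ratio of affine functions is converted to an LP by the Charnes–Cooper
transformation: scale all variables by $\tau > 0$, normalize the scaled
denominator to 1, minimize the scaled numerator, and homogenize every
constraint ($b \to b\,\tau$). A floor $\tau \ge 10^{-9}$ guards against
degenerate scaling; $(\lambda, s) = (\Lambda, S)/\tau$ recovers the
fractional solution with identical objective value.

Internally the LP is posed in **slack-ratio form**: the slack variables of
the program are $s/\text{observed}$, and each balance row is divided by
the evaluated unit's own value. With panel magnitudes spanning two decades
this keeps coefficients O(1). The solver is a dense two-phase primal
simplex written for this package: Dantzig pricing with a permanent switch
to Bland's rule after a stall (anti-cycling — DEA programs are heavily
degenerate), periodic refactorization of the tableau from the original
data to cap floating-point drift, and row/column equilibration of the
constraint matrix. If a solve still fails, it is retried once under
Bland's rule from the first iteration. Requested pivot tolerance is
$10^{-8}$; every accepted solution is re-verified against the raw panel
values with residual tolerance $10^{-6}$ (`verify_solution()`).

**Alternate optima.** SBM slacks are generally not unique at the optimum.
After the score is found, a second, fully linear pass maximizes the total
slack ratio subject to the original constraints and the attained
efficiency (the condition $N(s) \le \theta^* D(s)$ is linear in the
slacks). Reported slacks — and hence factor indices and report tables —
are therefore reproducible. $\theta^*$ itself is unaffected (tested to
$10^{-7}$).

**Zero values.** The objective divides by observed values, so validation
replaces an exact zero by $10^{-6}\times$ the variable's smallest positive
value across the panel, with a warning. Negative values are rejected.

## Factor indices

For each variable the frontier target is the observed value adjusted by
its optimal slack. Inputs and links: index $=(x-s)/x$; bad outputs:
$(y-s)/y$; good outputs and carry-overs: $y/(y+s)$. An index of 1 is
equivalent (up to tolerance) to a zero slack; a division-period block with
$\rho_o^*(k,t)=1$ has every index in that block equal to 1 (tested). Link
variables have no conventional published index; they are computed with the
input formula and tagged `link_in` so consumers can treat them as an
extension.

## The packaged two-stage configuration

`two_stage_spec()` wires the health-environment application: stage 1
*production* (inputs labor, energy consumption; good output GDP; carry-over
fixed assets), stage 2 *health treatment* (inputs health expenditure,
media reports; good output birth rate; bad outputs respiratory diseases,
mortality rate), links CO2 and AQI from stage 1 into stage 2. Derived
dimensions: stage 1 $m=2, r_1=1, r_2=0, linkin=0, ngood=1$; stage 2
$m=2, r_1=1, r_2=2, linkin=2, ngood=0$.

The fixed-assets carry-over attaches to the production stage by default —
capital stock is a production-side quantity and the variable table places
it there — but the attachment is genuinely ambiguous in the application
this mirrors, so `carryover_division = 2` moves it to the health stage
rather than hard-coding either reading. AQI is an index rather than a mass
flow; values are used as given, and unit conversions are the caller's
concern (units are metadata only).

## Synthetic data

Two generators make every part of the package testable without external
data; all draws come from one stream per integer seed, in documented
order, so panels are byte-reproducible.

**Planted frontier** (`generate_planted_frontier()`). Frontier units are
sampled, per division and period, on a common hyperplane with strictly
positive weights over cost coordinates (inputs, links, bad outputs) minus
benefit coordinates (good outputs, carry-overs). Every convex combination
of such units stays on the plane, and any point weakly dominating a plane
point would have to fall strictly below it — impossible within the hull.
Planted units therefore score exactly 1, *provably*, not just empirically.
Dominated units are convex combinations with every cost inflated by a
factor in `inflate_range` (default 1.05–1.6) and every benefit deflated by
`deflate_range` (default 0.6–0.95); the combination itself is a feasible
benchmark with strictly positive slack, so their scores are strictly below
1. The convex weights are returned as dominance certificates, letting
tests verify the construction by arithmetic alone. Setting both factor
ranges to 1 makes every unit an exact frontier combination — and hence
efficient. Each division needs at least one cost variable for the
construction; magnitudes span two decades (log-uniform) to exercise units
invariance realistically.

**Yearbook-like two-stage panel** (`generate_two_stage_panel()`, defaults
n = 31 units × 4 periods). City sizes are log-uniform over two decades;
labor, energy and GDP co-move through size; CO2 and AQI rise with energy
use; respiratory disease and mortality rise with the pollution links; the
fixed-asset path is AR(1)-smoothed across periods over a mild 3%/period
growth trend. The stage-specific log-normal noise SDs default to 0.15
(production) and 0.45 (health treatment): cross-unit dispersion of
stage-2 performance is deliberately planted to exceed stage 1's, mirroring
the stylized pattern that differences between units concentrate in the
treatment stage; the test suite asserts this variance ordering at the
defaults. What this generator does *not* emulate: real yearbook data have
measurement error correlated across variables, missing cells, reporting
revisions, and genuine policy shocks. Passing tests on synthetic panels
validates the *solver and its guarantees*, not any empirical claim about
real cities.

## Verification strategy

* **Closed-form toys.** A two-unit input-excess instance (score exactly
  0.5) and a bad-output instance (exactly 0.8), asserted to $10^{-6}$.
* **Exact brute-force oracle.** The objective is a ratio of affine
  functions, hence quasilinear: its minimum over the feasible polytope is
  attained at a vertex. For tiny instances (one division, n ≤ 3, T ≤ 2)
  the test suite enumerates *all* vertices of the feasible set in
  intensity space and evaluates the ratio at each — an exact, independent
  check that shares no code with the solver. The engine matches it within
  $2\times10^{-3}$ (observed: $\sim10^{-12}$) on 200 seeded random
  instances. A plain $10^{-3}$-step grid search over the intensity simplex
  is kept as a secondary single-period check; pure grid search was not
  adopted as the primary oracle because thin feasible regions in the
  dynamic case can fall between grid points.
* **Properties.** Units invariance (rescaling any variable's column leaves
  all scores unchanged to $10^{-8}$), monotonicity (worsening an input or
  bad output of a dominated unit cannot raise its score), score bounds,
  the mediant/bracketing identities, and planted-frontier recovery over
  repeated seeds.

Problem sizes in the default test run are kept modest by design — the
oracle domain is n ≤ 3, property panels use 3–5 units × 2 periods, and one
full 31 × 4 × 2 study run exercises the production-scale path end to end
(a few seconds; each unit's LP has ~290 variables and ~60 rows).

## Known limitations

* Only good carry-overs are implemented; bad, free and fixed carry-over
  categories are out of scope, as are orientation choices and constant
  returns to scale.
* Efficient units all score exactly 1; no super-efficiency ranking among
  them is provided.
* Scores are point estimates; no bootstrap or other inference is attached.
* The dense simplex targets the panel sizes above (tens of units, a few
  periods/divisions). Hundreds of units would call for a sparse LP
  backend.
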