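---
title: "Modeling leukemia cell dynamics: replicator games and the Leslie-Gower system"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling leukemia cell dynamics: replicator games and the Leslie-Gower system}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leukegame)
```

## The biological setting

Leukemia is a competition between two replicating cell populations in the
blood: healthy leukocytes (**leu**) and their malignant counterparts
(**c.leu**). `leukegame` models this competition at three levels of
description — a frequency-only evolutionary game, a density-based
predator-prey system, and a post-transplant coalition game — and provides
the shared stability machinery, simulation engine and scenario generator
needed to analyse all three.

## 1. The Hawk-Dove replicator model

On a fast time scale only the *composition* of the blood matters, not its
absolute size. Writing $x_1$ for the frequency of c.leu (the Hawks) and
$x_2 = 1 - x_1$ for leu (the Doves), the normalized contest game with
payoff constants $a, b > 0$ gives the one-dimensional replicator flow

$$\dot x_1 = (a x_1 - b x_2)\, x_1 x_2 .$$

`hawkdove_rhs()` implements this equation literally. It is worth being
explicit that this flow is the replicator dynamic of the *diagonal* game
$\mathrm{diag}(a, b)$ — a coordination structure — and not of the
zero-diagonal matrix built by `hawkdove_payoff_matrix()`; the two
formulations coexist in the literature on this model, so the package
keeps both: `replicator_rhs()` evolves any payoff matrix (including the
zero-diagonal normalized form and $n > 2$ strategies), while the
`hawkdove_*` operations implement the one-dimensional flow above, which
is the one whose fixed points and basins the stage analyses use.

The flow has exactly three stationary points: the monomorphic states
$x_1 = 0$ and $x_1 = 1$, and the interior mixed state $x^* = b/(a+b)$.
Linearising, both monomorphic points are stable (derivatives $-b$ and
$-a$) and the interior point is unstable — it is the separatrix between
the two basins of attraction. A claim sometimes attached to this model,
that the mixed equilibrium and both pure equilibria are simultaneously
asymptotically stable, is impossible in a one-dimensional flow; the
package reports the derivative-sign truth (`classify_fixed_point_1d()`),
under which the mixed point separates rather than attracts. The
risk-dominant strategy owns the larger basin: $x^* > 1/2$ exactly when
$b > a$, and `basin_sample()` recovers the fractions $b/(a+b)$ (all-leu
basin) and $a/(a+b)$ numerically.

```{r}
hawkdove_fixed_points(1, 3)
```

## 2. The Leslie-Gower predator-prey model

On a slower time scale absolute densities matter. With leu density $i(t)$
as prey and c.leu density $l(t)$ as predator,

$$\frac{di}{dt} = (r_1 - c_1 l - b i)\, i, \qquad
  \frac{dl}{dt} = \Big(r_2 - c_2 \frac{l}{i}\Big)\, l .$$

The Gower term $c_2 l / i$ ties the predator's carrying capacity to prey
abundance: as $i \to \infty$ the c.leu per-capita growth saturates at
$r_2$, and as $i \to 0$ it diverges to $-\infty$, so cancerous cells
cannot persist without healthy cells to prey on. Densities are in model
units of $10^9$ cells/liter — the convention under which the clinical
diagnostic range 30–200 $\times 10^9$ cells/liter maps to 30–200 and the
stage equilibria land at order 1–6, matching the phase-plane windows the
stage analyses use. Time is in days throughout (clinical observation
horizons of 40–80 days).

Parameters (all per day): $r_1, r_2$ intrinsic growth rates of leu and
c.leu; $c_1$ the conversion pressure of c.leu on leu; $c_2$ the Gower
coefficient; $b$ the effectiveness of c.leu at eliminating leu. The
auxiliary carrying capacity $k$ (default 100) and nutritional-value
constant $c$ (default 1) enter only the per-capita fitness forms
`leslie_fitness()` and the daily difference map `leslie_map_step()`
($i_{t+1} = i\,(1 + H_1)$, $l_{t+1} = l\,(1 + H_2)$); neither affects the
equilibrium or its stability, which is why the stage presets do not fix
them.

Setting both rates to zero gives the unique coexistence equilibrium

$$E = \left(\frac{r_1 c_2}{b c_2 + c_1 r_2},\;
            \frac{r_1 r_2}{b c_2 + c_1 r_2}\right),$$

whose Jacobian has the closed form implemented by `leslie_jacobian()`.
Two exact identities follow and are enforced as property tests: the
determinant (eigenvalue product) equals $r_1 r_2$ for *any* admissible
parameters, and the node-versus-focus inequality
$(\sqrt{r_1} - \sqrt{r_2})^2 \ge r_1 c_1 r_2 / (b c_2 + c_1 r_2)$ is
algebraically the sign of the discriminant $\tau^2 - 4\Delta$.

Three packaged disease-stage presets (`stage_scenario()`) drive the
analysis:

```{r}
for (stage in c("early", "acute", "chronic")) {
  rep <- leslie_stability_report(stage_scenario(stage))
  cat(sprintf("%-8s E = (%.4f, %.4f)  det = %.3f  label = %s\n", stage,
              rep$point[1], rep$point[2], rep$det, rep$label))
}
```

Since the trace $-(r_1 b c_2 + r_2 D)/D$ is negative and the determinant
$r_1 r_2$ positive for every admissible parameter set, the coexistence
equilibrium is *always* locally stable — a stable node when the criterion
holds (early prognosis) and a stable focus otherwise (acute). Stage
summaries of this model conventionally quote a positive "eigenvalue sum"
(0.638 acute, 0.3 chronic); that number is not the Jacobian trace but the
combination $(r_2 D - r_1 b c_2)/D$, which
`reported_trace_quantity()` computes so the conventional figure remains
reproducible alongside the true trace. Similarly, the equilibrium
coordinates are conventionally *truncated* to two decimals (4.9999
reported as 4.99); `truncate_decimals()` encodes that convention while
raw values stay at full precision.

The claimed global stability of $E$ is checked numerically rather than by
a Lyapunov construction: trajectories from a 10 by 10 grid of initial
conditions over $[0.6, 10]^2$ all settle within $10^{-3}$ of $E$ by
$t = 500$ days for the early-prognosis preset.

## 3. The HSC transplantation coalition game

After high-dose chemotherapy and a hematopoietic stem-cell (HSC)
transplant, three players interact: HSC, leu and c.leu. The HSC either
reinforce the immune system (favourable coalition with leu) or trigger a
graft-versus-host-like reaction (unfavourable coalition with c.leu). The
two coalition games reduce to coupled replicator equations on the unit
square,

$$\dot x_1 = x_1(1 - x_1)(a_1 - m x_2), \qquad
  \dot x_2 = x_2(1 - x_2)(b_1 - n x_1),$$

with $m = a_1 + a_2$, $n = b_1 + b_2$. The four corners are always fixed
points; the mixed point $(b_1/n,\, a_1/m)$ exists when both coordinates
lie strictly inside $(0,1)$. (The alternative ordering
$(a_1/m,\, b_1/n)$ that sometimes appears for this mixed point is not a
fixed point of the system above; the package implements the ordering
consistent with the equations.) At the mixed point the Jacobian is
antidiagonal, with eigenvalues $\pm\sqrt{J_{12} J_{21}}$: a saddle when
$a_1$ and $b_1$ share a sign, a center (closed orbits) when they differ
— provided the mixed point exists at all, which for opposite signs
requires $m$ and $n$ to be negative alongside.

The post-chemotherapy cell counts (`transplant_counts()`: $5.00 \times
10^8$ leu, $9.19 \times 10^6$ CD34+ cells/kg infused, $3.47 \times 10^4$
CD34+ cells/kg, residual c.leu $4.31 \times 10^{-1}$ and $1.42 \times
10^{-6}$, NK count $2.08 \times 10^{-7}$) parameterise two interaction
matrices shipped verbatim as `transplant_payoff_fixture()`. Their entries
are consistent with additive constructions from the counts (e.g.
$9.2247 \times 10^6 = 9.19 \times 10^6 + 3.47 \times 10^4$), but the
package does not enforce that reading; the matrices are data. Both have
negative determinants — real eigenvalues of opposite sign — so both
post-transplant regimes sit at a saddle:

```{r}
saddle_report(transplant_payoff_fixture("leu_vs_hsc_cleu"))$det
saddle_report(transplant_payoff_fixture("hsc_leu_vs_cleu"))$det
```

The NK count of $2.08 \times 10^{-7}$ cells is dimensionally implausible
(a fraction of a cell) and is stored verbatim without interpretation.
For the second fixture the published discriminant-style figure
83424.39498 equals $4\sqrt{|\det J^*|}$, not $\tau^2 - 4\det J^*$
(which is $1.7399 \times 10^9$ here since $\tau = 0$); the report exposes
the correctly computed discriminant and the conventional figure is left
unreproduced.

## Numerical choices

* **Integration.** `integrate_model()` wraps deSolve; the default is the
  adaptive Dormand-Prince RK4(5) pair at `abs_tol = rel_tol = 1e-9`, with
  fixed-step RK4 (`dt = 0.01` day) for convergence and reproducibility
  checks (the fourth-order error scaling is asserted on $\dot x = -x$).
* **Domain guards.** Adaptive steppers probe trial states outside the
  physical domain before rejecting a step, so the packaged vector fields
  are total: simplex fields clip to $[0,1]$ and renormalize, and the
  Leslie field floors the Gower ratio at $i = 10^{-9}$, which makes the
  predator derivative enormously negative near the singular axis and
  forces the step controller to retreat. The true singularity (vanishing
  prey with predators present) is enforced on the initial state and on
  every recorded trajectory row, raising an error with the offending
  time; `leslie_rhs()` itself remains strict.
* **Simplex drift.** Recorded replicator states are renormalized to unit
  sum whenever drift exceeds $10^{-12}$ (clip to $[0,1]$ first).
* **Tolerances.** Fixed-point residuals $10^{-9}$; derivative/sign
  degeneracy $10^{-12}$ (exposed as `tol` so boundary cases report
  `"degenerate"` instead of guessing); basin capture radius $10^{-2}$
  with a default settling horizon of 500 days.
* **Eigenvalue order.** `eigenvalues_2x2()` sorts by real part then
  imaginary part, so serialized reports are deterministic.

## The scenario generator

`random_scenario()` emulates the clinical variability the models are
meant to cover: each stage-preset rate is perturbed by an independent
Uniform(0.9, 1.1) factor (a ±10% parameter uncertainty, a choice the
clinical ranges do not pin down), the initial leu density is drawn
uniformly from the diagnostic range 30–200 (model units), the initial
c.leu burden is a Uniform(0.1, 1) fraction of it, and the horizon is a
whole number of days in [40, 80]. Draws are fully determined by the seed
and leave the global RNG untouched. What the generator does *not*
emulate: measurement noise, within-patient temporal parameter drift,
treatment effects (chemotherapy pharmacology is out of scope), or any
correlation structure between rates — so passing tests demonstrate
correctness of the dynamics and their analysis under the stated
parameter families, not fidelity to longitudinal patient data.

## Problem sizes used in the checks

Property suites run 1000 random parameter sets for the determinant
identity and the criterion/discriminant equivalence; brute-force
fixed-point scans use a $10^{-3}$ grid on $[0,1]$ (Hawk-Dove) and a
$200 \times 200$ grid on the unit square (coalition game); basin
fractions are estimated from 1001 initial conditions with a 300-day
horizon; global attraction uses a $10 \times 10$ grid of starts to
$t = 500$ days.

## Known limitations

* No parameter estimation or fitting to patient data; presets and the
  ±10% law are the only parameter sources.
* No bifurcation continuation, delay terms or stochastic dynamics.
* The three-player game is analysed only through the two coalition
  reductions; cooperative solution concepts (Shapley value, core) are
  out of scope, as is graft-versus-host pathophysiology.
* Figure styling of published phase portraits is not reproduced; the
  package emits quantitative trajectories and sampled vector fields
  (`phase_field()`) instead.
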