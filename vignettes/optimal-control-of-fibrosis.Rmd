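---
title: "Optimal control of TGF-beta in reaction-diffusion models of lung fibrosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optimal control of TGF-beta in reaction-diffusion models of lung fibrosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tgfctrl)
```

## The model

Idiopathic pulmonary fibrosis progresses when activated myofibroblasts
deposit excess extracellular matrix in the alveolar interstitium.
`tgfctrl` treats the lung tissue as the unit square and tracks two cell
densities on it: the myofibroblast density $m(x, y, t)$ and the
fibroblast density $f(x, y, t)$, both in g cm$^{-3}$, over a horizon of
days. Each obeys a homogenized reaction-diffusion equation

$$\frac{\partial m}{\partial t}
  - \frac{a}{\gamma} D_m \nabla^2 m
  = \Big(\lambda_{mfT}\,\frac{T}{K_{T} + T}
       + \lambda_{mfG}\,\frac{G_0}{K_G + G_0}\Big) f_0 - d_m\, m,$$

where $T$ is the TGF-beta concentration, $G_0$ the homeostatic PDGF
level, $f_0$ the homeostatic fibroblast density, and $d_m$ the
apoptosis rate. Homogenization replaces the alveolar microstructure by
an effective medium: a tissue volume fraction $\gamma = 127/343$ and an
isotropic effective diffusion coefficient $a = 0.11$, so every
molecular diffusivity $D$ acts as $(a/\gamma) D$. The fibroblast
equation has the same structure with a constant source
$\lambda_{Ef} E_0$ from the alveolar epithelium, a TGF-beta-driven
production term, and a total linear loss rate
$\alpha = \lambda_{mfG} G_0/(K_G + G_0) + \lambda_{TGFf} E/(E + K_E) +
\lambda_{\rho f} + d_f$ collecting transformation to myofibroblast,
TGF-beta production, matrix deposition and apoptosis. All constants
live in `myofibroblast_params()`, `fibroblast_params()` and
`homogenization_constants()`; every default is the tabulated
homeostatic value, in g, cm and day units, and overrides flow in
through a flat YAML config (`read_config()`). No unit conversion is
performed anywhere.

The control variable is TGF-beta through its Hill-saturated fraction

$$U = \frac{T}{K_{T} + T} \in [0, 1),$$

which makes the dynamics affine in the control,
$\dot m = A m + B U + b$, at the price of restricting physically
meaningful controls to $0 \le U < 1$ (`tgf_to_u()` / `u_to_tgf()` are
exact inverses on that range; $U \ge 1$ is a singularity and negative
$U$ has no physical concentration).

## Discretization

`build_grid(k)` places $k^2$ interior nodes on the unit square
($k = 6$ gives the 36-node layout, $k = 8$ the 64-node layout) and
`assemble_myofibroblast_system()` / `assemble_fibroblast_system()`
produce the state-space triple $(A, B, b)$. Two assemblies exist:

* **`neumann5`** (default): the five-point Laplacian with the mirror
  rule at the walls, scaled by the stencil weight
  $r = a D / (\gamma\, dx^2)$, minus the loss rate on the diagonal;
  $B = \theta I$ with $\theta = \lambda_{mfT} f_0$ (myofibroblast) or
  $\theta = \lambda_{fE} E/(E + K_E)$ (fibroblast); $b$ the constant
  source. The stencil weight formula is dimensionally forced: it is the
  unique reading under which discretizing $(a/\gamma) D \nabla^2$ with
  spacing $dx$ reproduces the printed symbol combination. With the
  loss removed the operator has (up to coefficient rounding at the
  $10^{-20}$ level) zero row sums, the discrete form of the no-flux
  boundary condition, so pure diffusion conserves mass.
* **`paper_literal`**: the block-tridiagonal variant in which the
  diagonal blocks repeat the one-dimensional stencil ($-2r$ diagonal),
  the coupling blocks carry $r$ on their sub-diagonal, $B$ has
  identity off-diagonal blocks, and $b$ carries boundary densities
  frozen at the homeostatic value — a Dirichlet idiom. It is retained
  verbatim for comparison because the published matrices have this
  form; the no-flux physics wins by default. The two assemblies
  coincide exactly when $D = 0$.

Time stepping is explicit Euler throughout (first order; the
convergence tests verify the error halves with the step). The guard
`cfl_max_step()` returns $2/(4r + \text{loss})$, the largest
non-expanding step; at the default parameters it is about 115 days, so
the standard step $dt = 0.1$ day has two orders of magnitude of
margin.

## The three control problems

**Unconstrained regulator** (`solve_lqr_model()`). Minimizing
$\tfrac12\int (m^\top m + U^\top U)\,dt$ subject to the affine dynamics
leads to the algebraic Riccati equation
$A^\top P + P A - P B B^\top P + I = 0$ and the feedback
$U = Km + \rho$ with $K = -B^\top P$. `solve_riccati()` computes $P$
from the stable invariant subspace of the Hamiltonian matrix
$\begin{pmatrix} A & -BB^\top \\ -I & -A^\top\end{pmatrix}$ and
enforces a residual below $10^{-8}(1 + \lVert P \rVert_F)$; $P$ is
symmetric positive definite here because $A$ is Hurwitz. A
`differential` mode integrates the matrix Riccati equation backward
from $P(t_f) = 0$ for finite-horizon studies; the terminal condition
is not dictated by the source formulation, so the stationary solve is
the default (matching the published use of a continuous
algebraic-Riccati solver) and the zero terminal condition is our
documented choice for the differential variant.

The constant source $b$ adds an affine offset $\rho$. The printed
recursion for the offset mixes shapes (a square matrix $\eta$ entering
a vector equation), so two realizations are provided and the scalar
case, where they coincide, anchors both: the default `adjoint` mode
uses the standard costate decomposition $\lambda = Pm + s$ with
$(A - BB^\top P)^\top s = -Pb$ and $\rho = -B^\top s$ — the unique
form consistent with the costate equation
$\dot\lambda = -m - A^\top\lambda$ — while `paper_eta` realizes the
printed square-matrix recursion $\eta(A - B^\top P B) = P$ with
$\rho = B^\top \eta b$.

Run end to end, the optimal fraction $U$ is negative at every step of
the default problem: the regulator demands a negative TGF-beta
concentration, which does not exist. The package records and flags
this (`feasible_flag`) rather than clamping silently; it is the
motivation for the constrained problem.

**Lower-bounded control** (`solve_constrained_model()`). The
constraint $T(t) \ge T(t_0)$ becomes $U(t) \ge U(t_0)$ and enters the
Hamiltonian with a KKT multiplier $\mu \ge 0$: where the unconstrained
feedback dips below the bound, $\mu > 0$ and the control sits exactly
at $U(t_0)$; elsewhere $\mu = 0$ and the feedback is untouched
(`kkt_branch()`). Branching is per node and per step — the pointwise
KKT condition — with a `global_branch` flag reproducing the
all-or-nothing reading in which one violation anywhere clamps the
whole horizon; under the default parameters the two coincide because
the bound binds everywhere, and the applied concentration is the
homeostatic $2.51 \times 10^{-12}$ g cm$^{-3}$ for all 300 days. The
multiplier's numeric value is never needed, only its sign, so it is
stored as a boolean. Restricting feasibility can only raise the cost;
the test suite verifies $J_{\text{constrained}} \ge
J_{\text{unconstrained}}$ over a seeded family of scalar systems.

**Coupled two-species control** (`solve_coupled_model()`). The joint
objective penalizes the state difference,
$\tfrac12\int (m - f)^\top(m - f) + U_m^\top U_m + U_f^\top U_f\,dt$,
with one lower-bounded control per species. The published derivation
decouples this into two independent Riccati/affine pairs with unit
state weights, and that derivation is the default synthesis. The
literal objective is available behind `strict_cross_term = TRUE`,
which regulates the stacked state $[m; f]$ against the indefinite
weight $\bigl(\begin{smallmatrix} I & -I \\ -I & I
\end{smallmatrix}\bigr)$ in a single Riccati solve; the default
reproduces the published scheme, the flag exposes the mathematically
faithful one. Two KKT multipliers give four sign cases (both free,
fibroblast clamped, myofibroblast clamped, both clamped). All four are
integrated and recorded — cheap at this scale — and
`select_admissible_case()` keeps the admissible run with the lowest
running cost, breaking ties toward the highest case number, which is
the published acceptance. Under the default kinetics the free cases
demand negative concentrations and only case 4 (both concentrations
constant at their initial values) is admissible. The value formula
$\bar J^* = \tfrac12(m_0^\top P_m m_0 - f_0^\top P_f f_0)$ is
implemented exactly as printed; its minus sign permits negative
values although the running integrand cannot be negative, so a
negative value is flagged in the run summary rather than hidden. The
myofibroblast equation of the coupled model keeps the fibroblast
density frozen at $f_0$ in its activation term, again as printed; a
`live_fibroblast` flag substitutes the simulated $f(t)$ for
exploration but is not the default.

## What the numbers do — and do not — reproduce

Three observations about the printed parameterization are recorded
rather than resolved, and the acceptance material reflects them:

* Both uncontrolled/clamped systems have strictly positive attracting
  states: $m \to (c_m + \theta_m U_0)/d_m \approx 3.5 \times 10^{-2}$
  and $f \to c_f/\alpha \approx 1.37$ g cm$^{-3}$. Published
  trajectory figures instead show both densities decaying to zero by
  240–290 and 50 days respectively. No assembly option in this package
  (including `paper_literal` + `paper_eta`) reproduces that decay from
  the printed equations, so vanish times are reported in the run
  summary (as `NA` when never reached) and are not asserted.
* The control authority $\theta_m \approx 5.7 \times 10^{-4}$ is of
  the same size as the source $c_m$, so even the correctly derived
  affine regulator settles at a strictly positive mean density.
* The fibroblast source $\lambda_{Ef} E_0 \approx 0.2$ g cm$^{-3}$
  day$^{-1}$ drives fibroblast growth, conflicting with decaying
  published fibroblast curves; $\lambda_{Ef}$ is tabulated in
  g cm$^{-3}$ while acting as a rate, and it is stored and used
  exactly as printed.

## Numerical choices

* Horizon $t_0 = 0$ to $t_f = 300$ days, $dt = 0.1$ day, 36 interior
  nodes by default; tests use 1-, 4- and 36-node instances, and
  convergence/fidelity studies use $dt = 10^{-3}$ on the well-mixed
  single node, where the first-order Euler error against the scalar
  closed form is about $2.3 \times 10^{-3}\,dt$ relative at
  $t = 100$ days.
* "Vanishing" is undefined in the source narrative; it is fixed here
  as the spatial mean density dropping to 1% of its initial value
  (`vanish_fraction`, configurable).
* The damage region enters as an optional tenfold elevation of the
  initial density inside a centred square (`damage_extent`, in cm);
  the mechanism by which damage enters the equations is otherwise
  unspecified, so it is disabled by default.
* Cost quadrature is the trapezoid rule on the stored time grid,
  matching the first-order integrator.
* The Hamiltonian-eigenvector Riccati solve requires exactly $n$
  stable eigenvalues; failure (never observed for these Hurwitz
  systems) aborts with a residual report rather than returning a
  doubtful $P$.
* Clamped controls report the initial concentration itself, not its
  floating-point Hill round trip, so "constant at
  $2.51 \times 10^{-12}$" holds to the last bit.

## What the synthetic instances do not cover

Test fixtures (`make_fixture()`) are deterministic small systems: the
tabulated scalar system, 4-node grids, a symmetric coupled pair and
seeded stable scalar draws. They exercise every code path but remain
linear, uniform-coefficient instances on tiny grids; they say nothing
about heterogeneous real tissue, patient-calibrated parameters, or
behaviour outside the Hill-saturated control range. Conclusions about
real lungs require the caveats above plus clinically estimated
constants.

## A worked example

```{r example, eval = FALSE}
st <- simulation_settings(tf = 300, dt = 0.1)   # 36 interior nodes
run <- solve_constrained_model(settings = st)
print(run)
time_to_fraction(run$trajectory, st$vanish_fraction)   # NA: never vanishes

out <- solve_coupled_model(settings = st)
out$selected$case                                      # 4
unique(as.vector(out$selected$control_m$TGF))          # 2.51e-12
```
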