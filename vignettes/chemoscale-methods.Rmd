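---
title: "Models and numerics in chemoscale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerics in chemoscale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemoscale)
```

chemoscale links three levels of description of chemotactic *E. coli*:
equilibrium receptor-cluster activity, single-cell excitation–adaptation
dynamics embedded in a run-and-tumble motility model, and the continuum
(Patlak–Keller–Segel, PKS) limit of a swimming population.  This vignette
is the package's account of each model, the parameter and numerical
choices that matter, and what the synthetic scenarios do and do not show
about real cells.

## The excitation–adaptation model

The fast/slow two-variable system

$$\frac{du_1}{d\tau} = \frac{f(S(\tau)) - u_1 - u_2}{\tau_e},\qquad
  \frac{du_2}{d\tau} = \frac{f(S(\tau)) - u_2}{\tau_a},$$

is the minimal caricature of chemotactic signal transduction: $u_1$ is
the response (kinase-activity excursion), $u_2$ the slow adaptation
variable, and $f$ (default identity, with $f(0)=0$) stands in for the
transduction steps.  Its two essential properties are **perfect
adaptation** — for any constant stimulus the steady state of $u_1$ is
exactly zero, restored on the timescale $\tau_a$ — and a **graded,
excitable** transient on the timescale $\tau_e \ll \tau_a$.

Two printed forms of this system circulate that differ in bracket
placement and in the step-response prefactor.  We adopt the reading in
which *both* right-hand sides are divided by their time constants, because
it is the only one for which the adapted steady state of $u_1$ is zero;
the closed-form unit-step response is then

$$u_1(t) = f(S_0)\,\frac{\tau_a}{\tau_a-\tau_e}\left(e^{-t/\tau_a} -
  e^{-t/\tau_e}\right),\qquad u_2(t) = f(S_0)(1 - e^{-t/\tau_a}),$$

whose initial slope $f(S_0)/\tau_e$ matches the ODE (a variant with
denominator $\tau_a+\tau_e$ does not; in the $\tau_e\ll\tau_a$ regime used
everywhere here the two differ by less than $2\tau_e/\tau_a$).
`analytic_step_response()` ships the ODE-consistent form and the test
suite holds it against the integrator to $10^{-10}$ relative.

**Integration.**  For piecewise-constant stimuli the linear system is
advanced with its exact matrix exponential per step (`exp_update`), so
the trajectory is exact at grid points; steps straddling a segment
boundary are split at the boundary.  Ramps use fixed-step RK4 at
$dt \ll \tau_e$.  The confluent case $\tau_a = \tau_e$ is refused in the
closed form and handled by the $t e^{-t/\tau}$ limit inside the
integrator.

A brief pulse of duration $\tau_e$ and amplitude $S_1$ drives $u_1$ up to
$(1 - e^{-1})S_1 \approx 2S_1/3$ (the `pulse_response_peak()` check);
with $\tau_e = 0.1$ s, $\tau_a = 10$ s a unit step peaks at $u_1 = 0.954$
near $t = 0.465$ s.

## Receptor-cluster activity

The core signalling unit is a trimer of receptor homodimers treated as a
two-state (active/inactive) switch.  At a fixed methylation label $m$ the
trimer occupies one of eight free-energy levels: active or inactive, with
0–3 ligands bound.  Successive bindings contribute
$-\log(3L/K_1)$, $-\log(3L^2/K_1K_2)$, $-\log(L^3/K_1K_2K_3)$ — the
3, 3, 1 degeneracies of a three-site binding polynomial, which the test
suite verifies by enumerating the $2^3$ site microstates.  Boltzmann's
law gives the trimer activity

$$p_{on} = \frac{1}{1 + e^{\Delta f^m}},\qquad
  \Delta f^m = E^m_{on} - E_{off} +
  \log\frac{P_{off}(L)}{P_{on}(L)},$$

with $P_x$ the state-$x$ binding polynomial.  A strongly coupled cluster
of $n$ trimers has free energy $n\,\Delta f^m$, and a mixed Tar/Tsr
cluster has $n_a \Delta f_a + n_s \Delta f_s$ (only pure-type trimers are
assumed; in single-ligand protocols the non-target type contributes its
ligand-free $\Delta f$ as a constant offset).  All binding polynomials
are evaluated in log space with a stable log-sum-exp, so activities stay
finite at arbitrarily large $L$.

**Attractant convention.**  Attractant binding deactivates the kinase,
so defaults bind the inactive state more tightly ($K_{d,off,i} <
K_{d,on,i}$) and dose–response curves decrease with $L$.

**Default parameters.**  The parameter values behind published
dose–response families are not reproduced here; `default_trimer_params()`
ships order-of-magnitude defaults obeying the qualitative constraints —
ligand-free activity ordered EEEE < QEQE < QQQQ across methylation
labels, sensitivity decreasing with methylation — and every value is
overridable.  No numerical identity with any published curve is claimed.
Methylation enters only as a fixed label selecting a parameter set, as in
adaptation-deficient (*cheRcheB*) mutants; methylation *kinetics* are out
of scope.

**Cooperativity.**  `fit_hill()` fits the four-parameter Hill function
(free plateaus, log-$L$ space, Levenberg–Marquardt with a deterministic
three-point multi-start seeded from the half-range grid point and the
steepest log-slope).  With the documented reference set ($K_{d,off} =
0.02$, $K_{d,on} = 0.5$, $\Delta E = -6\,k_BT$): a one-site two-state
unit fits $n_H = 1.000$ (the degree-(1,1) rational activity is exactly a
Hill curve of unit coefficient), a single trimer $n_H = 1.92$, and a
six-trimer cluster $n_H = 11.4$ — the low/moderate/high cooperativity
tiers, with class boundaries at 1.5 and 3 (configurable).

## Run-and-tumble agents

Each cell carries the internal pair $(y_1, y_2)$ driven by the local
signal through $G$ (default identity), advanced with the same exact
exponential update as the single-cell integrator.  The turning rate is

$$\lambda(y_1) = \lambda_0\left(1 - \frac{y_1}{\gamma_0 + |y_1|}\right)
  \in (0, 2\lambda_0),$$

so positive excitation (swimming up an attractant gradient) lengthens
runs.  Turns are instantaneous; the post-turn velocity is drawn uniformly
on the speed-$s_0$ sphere, independent of the incoming direction.  In
1-D a turn may therefore re-select the same direction: "runs" in
`run_statistics()` are turn-to-turn intervals, which are exponential with
mean $1/\lambda_0$, while direction-reversal intervals are twice as long.
A measured turning-angle distribution could be substituted for the
uniform kernel, but the uniform kernel is the model analysed here and is
the default.

**Scheme.**  Time-driven: per step of length $dt$, each cell updates
$(y_1,y_2)$, turns with probability $1 - e^{-\lambda dt}$, then advances
$x \leftarrow x + v\,dt$.  The step must satisfy $dt \le t_e/5$, which
both resolves excitation and keeps $\lambda\,dt \ll 1$; the residual
discretisation bias of the mean run interval, $dt/(1-e^{-\lambda dt}) -
1/\lambda \approx dt/2$, is 0.25% at the default $dt = 5$ ms.  For an
unstimulated walk the macroscopic diffusivity is $D = s_0^2/(N\lambda_0)$
(velocity autocorrelation $s_0^2 e^{-\lambda_0 t}$), estimated in
`run_statistics()` by an MSD regression past the ballistic crossover.

**Randomness.**  All draws are made vectorised across the whole
population from one seeded stream, one batch per time step.  There is no
per-cell iteration, so results cannot depend on cell ordering, and
identical seed + configuration reproduces trajectories bit for bit.

In 2-D an angular drift $d\theta = -\omega\,dt$ models the clockwise
swimming bias of cells near a surface; it is exact for non-turning cells,
which the test suite exploits.

## Chemical fields and pattern scenarios

`field_grid()` holds attractant $S$ (and optionally nutrient $F$) on a
regular lattice with periodic or no-flux boundaries:

$$\partial_t S = D_s \Delta S + \gamma \sum_i \delta(x - x_i) - \mu S,
 \qquad \partial_t F = D_f \Delta F - k \sum_i \delta(x - x_i).$$

The degradation term is first-order decay $-\mu S$ (a bare constant
source labelled a degradation rate would be inconsistent).  Cell delta
sources are spread by cloud-in-cell (bilinear) weights; sampling the
field at cell positions uses the same weights, making
deposit/interpolate an exact adjoint pair and conserving deposited mass
to the cell count exactly.  In the consumed-signal variant the $\gamma$
term is a sink on $S$ with $S(x,0) = 1$; a sink can overdraw a nearly
empty node, in which case the node is clamped at zero and the event
counted (`clamp_count`).

Diffusion uses Crank–Nicolson in 1-D and Peaceman–Rachford ADI in 2-D,
with the implicit operators factorised once per (grid, $dt$) via sparse
LU (`make_diffusion_ops()`); both conserve mass to solver round-off
because the discrete Laplacians have zero column sums.  The reaction is
applied pointwise per step with the exact integrating factor for the
decay + secretion pair, so pure decay is exact.  Agents and fields share
one $dt$ under first-order splitting.

**Scenarios** (`run_pattern_scenario()`) are desk-scale: domains of
0.6–4 mm, 400–1200 cells, a few simulated minutes.  Defaults were chosen
once so each scenario sits inside its characteristic regime:

* *liquid* (and *spiral*, which adds $\omega > 0$): 1200 cells on a
  $640\,\mu m$ periodic square, $D_s = 100\,\mu m^2/s$, $\gamma = 25$,
  $\mu = 0.02\,s^{-1}$.  Linear stability of the uniform lawn
  ($\sigma(k) = -D_n k^2 + \chi \gamma n_0 k^2/(\mu + D_s k^2)$) then
  makes the first few modes unstable with e-folding times of 5–10 s, so
  aggregation emerges from shot noise within the 200 s run; the
  binned-density variance grows several-fold while the $\gamma = 0$
  control stays flat.
* *swarm_ring*: adds a consumed nutrient layer and a central inoculum;
  the colony spreads radially at reduced scale.
* *adler* (consumed signal, 1-D): 400 cells consume a uniform signal
  ($\gamma = 0.004$ per cell) and ride the self-generated gradient; the
  population mean advances at an asymptotically constant speed
  ($R^2 > 0.99$ over the late half of the run).  Stronger consumption
  produces a faster band but also straggler drop-out and local
  signal exhaustion, which degrade the constant-speed regime.

These scenarios demonstrate mechanisms (instability onset, band
propagation, chirality), not quantitative colony geometry: real plates
involve growth, death and nutrient-dependent motility, none of which are
modelled, and the domains are two orders of magnitude smaller than
experiments.  Passing the pattern checks therefore says the coupled
solver reproduces the qualitative physics, nothing more.

## The continuum limit

Linearising the internal dynamics about the adapted state and closing the
moment hierarchy of the velocity-jump master equation in the
shallow-gradient regime yields the PKS equation

$$\partial_t n = \nabla\cdot\left(D_n \nabla n - \chi\, n \nabla S\right),
\qquad D_n = \frac{s_0^2}{N\lambda_0},\qquad
\chi = \frac{b\, s_0^2\, t_a}
        {N \lambda_0 (1 + \lambda_0 t_a)(1 + \lambda_0 t_e)},$$

with $b = |\partial\lambda/\partial y_1|_{y_1=0} = \lambda_0/\gamma_0$.
The chemotactic flux carries the density factor $n$; a flux independent
of $n$ would allow negative densities and is not a member of the PKS
family.  Signs are fixed by the physics: an attractant (runs lengthen
up-gradient) gives $\chi > 0$ and up-gradient drift, verified against the
closed-form drift speed $\chi \partial_x S$ to 1%.

**Discretisation.**  `solve_pks_1d()` is a conservative finite-volume
scheme whose face fluxes use Scharfetter–Gummel exponential fitting,
$F_{j+1/2} = (D/dx)\,[B(-P)n_j - B(P)n_{j+1}]$ with $P = u\,dx/D$ and
$B(z) = z/(e^z-1)$.  This reduces to central differencing for small cell
Péclet number and to upwinding for large, and — the reason it was chosen
over plain upwinding, whose numerical diffusion $u\,dx/2$ costs several
percent at practical resolution — its discrete zero-flux stationary state
is *exactly* $n \propto e^{\chi S/D_n}$ on any grid.  Explicit stepping
uses an automatic $dt$ under both stability limits; `method = "implicit"`
applies Crank–Nicolson to the full (linear, time-independent) transport
operator, which is unconditionally stable and shares the exact stationary
null vector.  No-flux boundaries conserve mass to round-off.

**Cross-scale check.**  `compare_agents_to_pks()` runs both descriptions
under matched parameters (a mismatch is an error) from a uniform initial
profile, and reports L1/max-norm discrepancies between the normalised
agent histogram and the PDE, plus the validity diagnostic
$s_0 |\nabla S|_{max} t_a$ — the signal change per adaptation time along
a run, which must be well below 1 for the closure to hold.  In the
reference comparison ($s_0 = 20\,\mu m/s$, $\lambda_0 = 1\,s^{-1}$,
$b = 4$, hence $\gamma_0 = 0.25$; $t_e = 0.1$ s, $t_a = 5$ s;
piecewise-linear signal peaked mid-domain on 4 mm; $10^4$ cells,
40 bins) the diagnostic is 0.05 and L1 stays below 0.1 at all matched
times, shrinking as cell count grows.  The adaptation times $t_e = 0.1$
s and $t_a = 5$ s of this fixture are package defaults, exposed in the
configuration.  A deliberately steep gradient drives the diagnostic
above 1 and the comparison flags it rather than hiding the disagreement.

## Problem sizes and reproducibility

The packaged scenarios and tests use: $10^2$–$10^4$ agents, grids up to
$200$ nodes (1-D) or $32^2$ (2-D), and runs of 100–600 simulated seconds
— sizes chosen so the full suite completes in minutes on one core while
keeping Monte-Carlo errors (e.g. $\sqrt{2/n_{cells}}$ on diffusivity
estimates) inside the stated tolerances.  Every stochastic entry point
takes an explicit seed; `run_scenario()` re-run with the same seed writes
byte-identical summaries.

## Known limitations

* No methylation kinetics, phosphorylation cascade or CheY dynamics —
  the receptor model is equilibrium-only, the cell model is the
  two-variable caricature.
* No cell growth, death, division or mechanical interaction; patterns at
  desk scale are qualitative analogues, not fits.
* The continuum module is 1-D; steep-gradient regimes need higher-order
  moment closures that are intentionally out of scope (the comparison
  diagnostic reports, but does not repair, their absence).
* Mixed clusters assume pure-type trimers and single-ligand protocols;
  whether the inactive-state energy is methylation-independent for both
  receptor types is taken as a simplifying assumption.
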