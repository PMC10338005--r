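---
title: "Buoyancy-modulated solute dispersion in an oscillating wavy channel: model and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Buoyancy-modulated solute dispersion in an oscillating wavy channel: model and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wavechannel)
```

## The physical problem

A slender two-dimensional channel, bounded by a flat wall at $y = 0$ and a
wavy wall at $y = H(x) = 1 + \beta\cos 2\pi x$, stands vertically with $x$
measured downward from the upper end in units of the wall wavelength. An
oscillating pressure difference between the two open ends drives a pulsatile
flow. This configuration is a canonical model for cerebrospinal-fluid motion
in the spinal subarachnoid space, where the wavelength mimics the
inter-vertebral spacing, and for the dispersion of an intrathecally injected
drug whose density differs slightly from that of the carrier fluid
(hyperbaric/hypobaric anaesthetics).

Four dimensionless groups control the reduced model:

* $\alpha$ — the Womersley number, $\sqrt{\omega h_0^2/\nu}$: the ratio of
  the transverse viscous time to the oscillation time. Cardiac-driven spinal
  flow has $\alpha \approx 3$–$6$; the presets use 4 and 16.
* $\beta$ — relative amplitude of the wall undulation, $0 \le \beta < 1$.
* $Ri$ — the Richardson number comparing the effective gravitational
  acceleration $g\,(\rho-\rho_s)/\rho$ with the convective acceleration
  $u_c^2/\lambda$. Positive for a solute lighter than the fluid. Order unity
  in drug-dispersion applications.
* $\sigma$ — the reduced Schmidt number $\varepsilon^2 \nu/\kappa$, an
  order-unity grouping expressing that molecular diffusivities of drugs are
  a factor $\sim\varepsilon^2$ smaller than the kinematic viscosity.

The stroke-length ratio $\varepsilon$ (stroke length over wavelength,
$\approx 0.02$–$0.05$) is the small parameter of the underlying asymptotics.
It never appears in the reduced equations — solve once, rescale at will —
and is carried only as metadata to convert the slow time $\tau =
\varepsilon^2 t$ into oscillation counts (`cycles_from_tau()`).

## Model structure

The velocity field is built in three layers, each available as a package
object.

**Oscillatory base flow** (`oscillatory_flow()`). At leading order the flow
is harmonic, $u_0 = \mathrm{Re}(i e^{it} U)$, with a Womersley profile in
the local gap:
$$U = \frac{dP}{dx}\,G, \qquad
G = 1 - \frac{\cosh[\Lambda(2y/H-1)]}{\cosh\Lambda}, \qquad
\Lambda^2 = \tfrac{i}{4}\,\alpha^2 H^2 ,$$
where the branch with $\mathrm{Re}\,\Lambda > 0$ is taken. The complex
pressure gradient follows from requiring a constant complex flow rate $Q$
and unit end-to-end pressure drop per cell,
$$Q = \Big[\int_0^1 \frac{dx}{H\,(1 - \Lambda^{-1}\tanh\Lambda)}\Big]^{-1},$$
independent of the number of cells. The transverse component $V$ follows
from continuity using the closed-form wall-to-$y$ integral of $G$.
The branch of $\Lambda$ deserves a note: only $\Lambda^2$ enters the
profile, but conjugating $\Lambda^2$ conjugates $U$ and $V$ and thereby
*flips the sign of the Stokes drift* below. The implementation therefore
pins the branch by the momentum-balance residual
$-U + dP/dx - (i/\alpha^2)\,\partial_{yy}U = 0$, which the test suite
verifies to $10^{-12}$; the combined-drift peak value below confirms it
independently.

**Buoyancy-free mean drift** (`mean_drift()`). The time-averaged convective
acceleration of the oscillatory flow,
$F = \tfrac12\mathrm{Re}[\partial_x(U\bar U) + \partial_y(V\bar U)]$,
forces a steady Eulerian *steady-streaming* velocity $u_{SS}$, obtained by
integrating the averaged momentum balance across the gap with no-slip walls
and the zero-net-flux closure
$dp_{SS}/dx = -6H^{-3}\int_0^H F\,y(H-y)\,dy$. The mean *Lagrangian* drift
adds the Stokes drift
$u_{SD} = \tfrac12\mathrm{Im}[\partial_x(U\bar U) + \partial_y(V\bar U)]$,
$v_{SD} = \tfrac12\mathrm{Im}[\partial_x(U\bar V) + \partial_y(V\bar V)]$.
Both carry zero net section flux, so in the absence of buoyancy each
wavelength cell is a closed recirculation region: a solute deposited in one
cell cannot leave it.

**Buoyancy-induced mean flow** (`buoyancy_flow()`). A solute column of
concentration $c$ drives a mean flow with the same transverse structure,
with forcing $Ri\,c$ and a non-local pressure closure (equal end
pressures over the whole $n$-cell channel):
$$\frac{1}{Ri}\frac{\partial p_B}{\partial x}
 = \frac{6}{H^3}\left[\frac{\int_0^n H^{-3} m\,dx}{n\int_0^1 H^{-3}dx} - m\right],
 \qquad m(x) = \int_0^H c\,y(H-y)\,dy ,$$
yielding a generally nonzero "chimney" draft
$Q_B = -\alpha^2 Ri\,\big[\int_0^n H^{-3}m\,dx\big]\big/\big[2n\int_0^1H^{-3}dx\big]$.
With $x$ pointing downward, a light solute ($Ri>0$) gives $Q_B<0$: an
upward draft. For a flat channel and uniform concentration $c^*$ this
reduces to the closed forms $u_B = -\alpha^2 Ri\,c^* y(1-y)/2$ and
$Q_B = -\alpha^2 Ri\,c^*/12$, which the tests verify against an independent
two-point boundary-value solve.

**Averaged transport** (`run_transport()`). On the slow time scale the
concentration obeys a nonlinear integro-differential equation: it is
advected by the full mean Lagrangian velocity (steady streaming + Stokes
drift + buoyancy flow, the latter a functional of $c$ itself) and diffuses
across the gap only,
$$\frac{\partial c}{\partial\tau}
 + (u_{SD}+u_{SS}+u_B)\frac{\partial c}{\partial x}
 + (v_{SD}+v_{SS}+v_B)\frac{\partial c}{\partial y}
 = \frac{1}{\alpha^2\sigma}\frac{\partial^2 c}{\partial y^2},$$
with no-flux walls. Longitudinal diffusion and Taylor dispersion are absent
from the model (they are asymptotically negligible in the regime of
interest). Integrating across the gap yields the conservation law
$\partial_\tau C + \partial_x\phi = 0$ with $C=\int_0^H c\,dy$ and
$\phi = \int_0^H(u_{SD}+u_{SS}+u_B)c\,dy$; total solute is conserved
whenever the end fluxes vanish — the central correctness contract of the
solver.

The standard initial condition is a truncated-Gaussian bolus
$c_i = \min\{1, \tfrac32\exp[-16((x-x_0)/\delta)^2]\}$, a saturated band of
width $\delta$ centred at $x_0$ (`initial_bolus()`, defaults $x_0 = 1.75$,
$\delta = 0.2$ in a three-cell channel).

## Numerical method

All fields live on closed uniform tensor grids in $(x, \eta)$ with
$\eta = y/H(x)$, which maps the wavy gap onto a rectangle so boundary
conditions sit on grid nodes; metric terms follow from the chain rule, the
transverse contravariant velocity being $w = (v - u\,\eta H')/H$.
Cell-periodic fields (base flow, steady streaming, Stokes drift) are
computed on one cell and tiled.

* **Quadrature**: composite trapezoid everywhere, matching the integral
  closures; the streaming and buoyancy pressure closures are assembled from
  the *same* trapezoid sums that appear in the discrete section flux, so the
  zero-net-flux theorems and the two-way flow-rate identity hold to
  round-off on every grid (they converge to the analytic closures at second
  order).
* **Differentiation**: fourth-order central differences, periodic in $x$ on
  the cell, one-sided five-point closures at non-periodic boundaries.
* **Advection**: three-point second-order upwind stencils selected by the
  local velocity sign, first-order fallback at the first interior node;
  zero-gradient end condition in $x$ (the scenarios keep the solute away
  from the ends; end fluxes are monitored and a warning fires beyond
  $10^{-6}M$ per unit $\tau$).
* **Transverse diffusion**: fourth-order compact (tridiagonal) scheme.
  The Neumann walls are closed by even reflection. A fully one-sided
  fourth-order wall stencil was implemented and measured as well: it is
  pointwise more accurate on generic data but injects an $O(\Delta\eta^3)$
  spurious wall flux that accumulated to a $\sim 10^{-3}$ relative solute
  loss over $\tau = 8$; the reflection closure's defect is proportional to
  the wall gradient, which the no-flux physics drives to zero, keeping the
  budget at $\sim 10^{-5}$. Conservation was judged the binding contract.
* **Time stepping**: three-stage third-order TVD (strong-stability
  preserving) Runge–Kutta, the buoyancy velocity recomputed from the stage
  concentration at every stage. Step size
  $d\tau = \mathrm{CFL}\,\min(\Delta x/\max|u|,\ \Delta\eta/\max|w|,\
  \tfrac12\alpha^2\sigma(H_{\min}\Delta\eta)^2)$ with $\mathrm{CFL}=0.4$.
* **No clipping**: upwind over/undershoots are monitored (warning beyond
  $[-0.05, 1.05]$), never suppressed — silent clipping would mask
  conservation errors.
* **Determinism**: no randomness anywhere; reruns are bit-identical.

Measured orders on manufactured solutions: diffusion $4.0$, advection
$2.0$, time integration $3.0$ (see `test-transport.R` and the acceptance
suite).

The limiting solver `low_sigma_transport()` integrates the
rapid-transverse-mixing form $\partial_\tau(Hc) + \partial_x(Q_B c) = 0$,
with $Q_B$ evaluated from the instantaneous gap-uniform concentration, in
conservative finite-volume form with second-order upwind-biased interface
states. At $\sigma = 0.05$ the full solver agrees with it to a few per cent
in $L^1$ after $\tau = 1$.

## Peak diagnostics and reference values

`flow_diagnostics()` computes $\psi(x,y)=\int_0^y u\,dy'$ (so $\psi = 0$ on
the flat wall, and on both walls for zero-flux fields) and the slender-flow
vorticity $\Omega = -\partial u/\partial y$. `drift_peaks()` evaluates peak
magnitudes on a ladder of grids refined by factors of two until the peaks
change by less than 0.1%. At $\beta = 0.4$ the converged model values are

```{r peaks, eval = FALSE}
drift_peaks(channel_params(alpha = 4, beta = 0.4))
#>   field      psi_peak omega_peak nx_cell neta converged
#>   streaming    0.0114       1.45     192  193 TRUE
#>   lagrangian   0.0235       1.99     192  193 TRUE
```

with $(|\psi|_{\max}, |\Omega|_{\max}) = (0.0114, 1.448)$ for steady
streaming and $(0.0235, 1.990)$ for the combined drift at $\alpha = 4$, and
$(0.1692, 40.79)$ / $(0.1484, 40.80)$ at $\alpha = 16$. The Stokes drift is
comparable to the streaming at $\alpha = 4$ and relatively much weaker at
$\alpha = 16$.

## Scenario presets and the study conditions

The presets encode the canonical scenarios: a three-cell channel
($n = 3$, aspect ratio small, stroke length $\varepsilon = 0.02$ as
metadata), bolus at $x_0 = 1.75$, $\delta = 0.2$:

* `"neutral-bolus"` — $\beta=0.2$, $\alpha=4$, $\sigma=1$, $Ri=0$,
  $\tau \le 8$ ($t \le 20000$, about 3200 cycles at $\varepsilon=0.02$).
  The bolus stirs and homogenises within the deposition cell; adjacent-cell
  presence is numerical leakage only and stays below 1%.
* `"light-bolus"` — same with $Ri=1$: the buoyant draft connects the cells
  and carries the solute monotonically upward.
* `"meanflow-alpha4"`, `"meanflow-alpha16"` — one-cell, $\beta=0.4$
  mean-drift studies behind the peak table above.

Default transport resolution is $200\times101$ per the stated
finite-difference design. The long-horizon checks in the test and
acceptance suites run at $64\times33$ (and $64\times25$ for the stiff
$\sigma=0.05$ case): at those sizes the $\tau=8$ scenarios complete in
about a minute each while the measured conservation drift
($1.3\times10^{-5}$ for the neutral scenario) and cell leakage (0.04%)
sit comfortably inside the contracts; both tighten further under
refinement.

## What the generator emulates — and what it does not

The scenarios are synthetic model problems: an idealised planar channel
with a single sinusoidal wall, an integer number of identical cells, and a
solute released away from the ends. They exercise every mechanism of the
reduced model (closed Lagrangian cells, buoyant draft, diffusion-limited
versus material transport), but they do not represent the annular,
eccentric, anatomy-specific geometry of a real spinal canal, elastic wall
motion, longitudinal or Taylor diffusion, fine anatomical obstructions
(trabeculae), or the oscillatory concentration fluctuations that ride on
the mean. Passing tests therefore validate the reduced model and its
discretisation — not clinical predictions.

## Known limitations and open choices

* The $x$-end condition (zero gradient) is a pragmatic closure; the model
  scenarios never exercise the ends, and end fluxes are logged.
* Peak extraction searches one cell; for cell-periodic fields a longer
  channel adds nothing.
* The quasi-steady buoyancy solve is a pure function of the instantaneous
  concentration; dynamic buoyancy corrections and stratification feedback
  on the oscillatory flow are outside the model hierarchy.
* Very large $\alpha$ ($\gtrsim 600$) would overflow the direct `cosh`
  evaluation; the implementation targets the physical range
  $\alpha \lesssim 20$ and errors out beyond it.
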