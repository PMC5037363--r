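---
title: "Fronts, fingering and noise in an auto-chemotactic epithelium: methods"
author: "chemofront"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fronts, fingering and noise in an auto-chemotactic epithelium: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemofront)
```

## The model

An epithelial monolayer advances over a solid substrate into a bath of water
and nutrients. Three ingredients drive and shape the front:

* **Auto-chemotaxis.** Cells at the leading edge produce a morphogen that
  diffuses (diffusivity $D_e$ on both sides of the front) and is taken up by
  the tissue with a characteristic time $\tau_e$. The cells respond to the
  self-generated gradient with a migration coefficient $\lambda_0$.
* **Pressure-limited proliferation.** Cells divide at a rate proportional to
  the deficit of the local pressure below the homeostatic pressure
  ($K_p$ per unit pressure).
* **Substrate friction.** On the substrate the motion is friction-dominated
  and the coarse-grained cell velocity obeys a Darcy law,
  $\mathbf v = -K_e \nabla p$.

Using $\tau_e$ as time unit, the diffusion length $\sqrt{D_e\tau_e}$ as length
unit, $P_0 = D_e/K_e$ as pressure unit and the interface concentration scale
$c_i$ as concentration unit, the control parameters collapse to

* $\Lambda = \lambda_0 c_i / D_e$ — chemotactic migration constant,
* $\alpha^2 = K_p D_e / K_e$ — proliferation coefficient,
* $N_0$ — morphogen production rate of the border row of cells,
* $\sigma$ — capillary (surface-tension) parameter,
* $P_i$ — interface pressure relative to the homeostatic pressure
  (negative for advancing proliferative fronts).

In dimensionless form the morphogen obeys a diffusion–consumption equation in
the tissue and a pure diffusion equation in the water. At the front the
concentration jumps by one unit (the production is localized at the border)
and the normal-flux jump equals $N_0 v_n$ — sources attached to the moving
front. These two conditions are fixed, up to normalization, by the interface
amplitude of the steady profile, $C_0 = r_e U (1+N_0)$. The pressure satisfies
the bulk balance $\Delta(P + \Lambda C_e) - \alpha^2 P = 0$: the chemotactic
flux acts as a source distribution that lowers the pressure near the
morphogen-rich front and pulls the tissue forward. At the interface, mechanical
equilibrium imposes the Laplace condition $P = P_i + \sigma\kappa$ and the
front moves with the pressure-driven Darcy velocity, $v_n = -\partial_n P$;
the chemotactic component of the cell flux is accommodated by the thin density
boundary layer at the edge and does not advect the interface directly.

## Steady front and the implicit velocity relation

In the co-moving frame ($Y = y - Ut$, epithelium at $Y<0$) the morphogen is a
single exponential on each side, with decay rates
$r_e = (\sqrt{U^2+4}-U)/2$ and $r_w = U$, and the elimination of the pressure
yields the implicit velocity relation

$$
U \;=\; -\alpha P_i \;+\;
\Lambda (1+N_0)\,\frac{r_e^3\,U}{\alpha + r_e}.
$$

Two limits organize the physics: without chemotaxis the front is purely
proliferative, $U = -\alpha P_i$; without proliferation a chemotaxis-only
front exists when $S = \Lambda(1+N_0) > 1$, with
$U = \sqrt S - 1/\sqrt S$. `front_velocity()` scans a log-spaced bracket and
polishes roots with `uniroot()`; the smallest positive root is returned and
all roots are available on request, since uniqueness of the advancing branch
is assumed rather than proven. The resonance $\alpha = r_e$ of the pressure
profile is handled with the $Y e^{\alpha Y}$ particular solution; the implicit
relation itself is continuous across it.

The tests verify this relation against an independent finite-difference
boundary-value solution of the same steady equations (Thomas-algorithm
tridiagonal solves, three-level Richardson extrapolation in the grid step), at
five parameter sets, to $10^{-6}$ in $U$.

## Linear stability and the fingering threshold

A sinusoidal perturbation $\zeta = Ut + \varepsilon e^{ikx+\Omega t}$ of the
front perturbs the fields with $\Omega$-dependent decay rates
$l_e$, $l_w$ (concentrations) and $\chi = \sqrt{k^2+\alpha^2}$ (pressure,
$\Omega$-independent because the Darcy balance is quasi-static). Eliminating
the amplitudes against the four linearized interface conditions gives a single
scalar residual whose root in $\Omega$ is the growth rate
(`dispersion_residual()`, `growth_rate()`). Only the real branch continuously
connected to the translational Goldstone mode $\Omega(0)=0$ is followed; the
interface algebra also possesses a second, fast real root far above it, which
is not connected to the physical mode at $k\to 0$ and is excluded by the
branch selection (the test suite's independent discretization of the
linearized system exhibits the same two branches, which is why its physical
eigenvalue is identified by isolation around the continuation branch).

Proliferation and surface tension are stabilizing and chemotaxis is
destabilizing; above a critical $\Lambda_0(U)$ a band of unstable wavenumbers
opens. The onset of a steady fingering pattern is the double zero
$\Omega(k_0) = \partial_k\Omega(k_0) = 0$, located by a damped 2-D Newton
iteration in $(\Lambda, k)$ with Richardson-extrapolated central differences
(`find_threshold()`). Multiple Newton starts guard against the possibility of
a pair of marginal points; when several are found, the smallest $\Lambda_0$ is
the physical boundary. At the reference speed $U = 7$ (with
$\alpha = N_0 = 1$, $\sigma = 10^{-3}$, the defaults throughout) the selected
point is

```{r threshold}
find_threshold(7)
```

and the coupled solve at prescribed interface pressure recovers the
operating point:

```{r coupled}
threshold_for_interface_pressure(-6.76)
```

A threshold point carries two derived scales used downstream: the curvature
$\xi_0^2 = -\tfrac12 \partial_k^2\Omega$ at $(k_0,\Lambda_0)$ and the gap
rate $\Lambda_0\,\partial\Omega/\partial\Lambda$, i.e. the growth rate gained
per unit relative gap $\mu = (\Lambda-\Lambda_0)/\Lambda_0$.

## The weakly nonlinear layer

Near threshold the dispersion relation is approximated by a quadratic maximum
tied to the Goldstone zero,

$$
\Omega(k) \approx \Big(\frac{k}{k_0}\Big)^{\!2}
\big[\mu\, \Omega_\mu - \xi_0^2 (k-k_0)^2\big],
$$

with $\Omega_\mu$ the gap rate (`linear_symbol()`). Galilean invariance
($x \to x - vt$, $u \to u + v$) fixes the only admissible quadratic
nonlinearity of the interface-velocity deviation $u$, giving the
Kuramoto–Sivashinsky-type front equation
$\partial_t u = L u + \tfrac12 \partial_x(u^2)$; the unknown coefficient of
the quadratic term is absorbed into the scale of $u$. `evolve_front()`
integrates it pseudo-spectrally with an ETDRK4 exponential integrator and
2/3-rule dealiasing, in rescaled coordinates where $k_0 \mapsto 1$. The
spatial mean of $u$ is conserved exactly (the symbol vanishes at $k=0$ and
the flux-form nonlinearity has zero mean), and Galilean equivariance holds to
spectral accuracy.

The multiscale expansion about threshold couples the pattern amplitude $A$
(carrier $k_0$) to the real mean-velocity mode $B$ (carrier $k \approx 0$),
which is marginal by Galilean invariance. In the scaled variables
($X = \varepsilon x$, $T = \varepsilon^2 t$, $\mu = \varepsilon^2$) the
equations implemented by `evolve_amplitudes()` are

$$
A_T = \mu A + 4 A_{XX} - |A|^2 A + B\,(iA + A_X), \qquad
B_T = 37\, B_{XX} + 36\, \partial_X |A|^2 .
$$

The advection terms $B(iA + A_X)$ are the slow-variable image of the pattern
being carried by the velocity shift $B$. The two numerical coefficients are
pinned by the long-wavelength stability coefficients: linearizing
about the plane wave $A = A_0 e^{iqX}$, $B = 0$
($|A_0|^2 = 1 - 4q^2$, existence band $q^2 < 1/4$) and eliminating the fast
amplitude mode yields $\eta^2 + c_1 p^2 \eta + c_2 p^2 = 0$ with

$$
c_1 = \frac{41 + 144q - 52q^2}{1 - 4q^2}, \qquad
c_2 = -288\,q\,(q+1),
$$

and this matching determines the mean-field diffusivity (37) and coupling
(36) uniquely — including the $-52q^2$ term, which provides a strong internal
consistency check of the reconstruction. The regimes follow from the roots
(`growth_roots()`, `stability_coefficients()`): exponential growth for
$q > 0$ (forbidden band), damped oscillations for $q_h < q < 0$, and a Hopf
bifurcation at the negative root of the $c_1$ numerator,

```{r hopf}
hopf_point()
```

with oscillation frequency $\omega_h p = \sqrt{c_2(q_h)}\, p$, linear in the
perturbation wavenumber (`hopf_frequency()`). The quadratic is the
long-wavelength limit; `growth_roots(..., method = "matrix")` keeps the exact
$3\times 3$ linearization, whose eigenvalues the numerically linearized
integrator reproduces to $10^{-4}$ in the tests.

## Noise below threshold

Below threshold ($\mu < 0$) each interface Fourier mode relaxes at
$\Gamma(\lambda) = \xi_0^2(\lambda - k_0)^2 - \mu\,\Omega_\mu > 0$ — the
quadratic approximation of $-\Omega$ around the selected wavenumber — and
biochemical noise turns it into an Ornstein–Uhlenbeck process. Its stationary
variance is the structure function

$$
S(\lambda) = \frac{C_0(\lambda)}{2\Gamma(\lambda)},
$$

maximal at $\lambda = k_0$ and divergent as $1/|\mu|$ when the threshold is
approached: the pattern wavelength is selected by noise before the
deterministic instability exists. `langevin_mode()` uses the exact OU
transition density (mean $e^{-\Gamma\,\mathrm dt}$, variance
$C_0(1-e^{-2\Gamma\,\mathrm dt})/2\Gamma$), so Monte-Carlo estimates carry no
time-step bias; `structure_function_empirical()` averages per-realization
stationary variances and reports Monte-Carlo standard errors. Note that the
quadratic $\Gamma$ is a local approximation: the full front equation also has
soft Goldstone modes at $\lambda \to 0$ whose position variance accumulates
diffusively (the translational wandering of the mean front), so the
peak-at-$k_0$ statement is about the pattern band, not the $\lambda \to 0$
limit.

Noise sources live in the boundary conditions: the concentration jump
($\eta^{(3)}$), the production rate $N_0 \to N_0 + \eta^{(4)}$ and the
chemotactic constant $\Lambda \to \Lambda + \eta^{(5)}$. The latter two also
shake the bifurcation gap itself. The gap responds through the chemotactic
forcing $S = \Lambda(1+N_0)$ of the velocity relation and, for $\eta^{(5)}$,
additionally through the direct role of $\Lambda$ as bifurcation parameter,
so the effective multiplicative noise is
$\eta_1 = -(s_4\eta^{(4)} + s_5\eta^{(5)})$ with

$$
s_4 = \frac{\partial \ln S}{\partial N_0} = \frac{1}{1+N_0}, \qquad
s_5 = \frac{\partial \ln S}{\partial \Lambda} + \frac{1}{\Lambda}
    = \frac{2}{\Lambda},
$$

evaluated on the steady branch (`multiplicative_sensitivities()`; the
operating point $\alpha = N_0 = 1$, $\Lambda = 7.65$, $U = 7$ gives
$0.5$ and $0.26$). Because both expressions are relative sensitivities they
require $\Lambda > 0$; off the chemotactic branch the operation refuses to
answer rather than extrapolate. The transfer coefficients $E_3, E_4, E_5$ of
the additive construction are computed as implicit linear responses of the
dispersion residual, $E_j = -(\partial F/\partial\eta_j)/(\partial F/\partial\Omega)$,
which is their defining property (`noise_mapping()`).

Multiplicative gap noise of strength $C_1$ renormalizes the mean threshold,
$\mu \to \mu + C_1$ (`novikov_shift()`). The stochastic-calculus convention
behind this mean shift is not something we assert: the test suite integrates
the $k_0$ mode with a Stratonovich (Heun) scheme, with the noise intensity
expressed in gap units, and verifies numerically that the ensemble mean grows
at the shifted rate — noise-induced instability with $\mu < 0$ — rather than
assuming the Itô or Stratonovich drift by fiat. `sde_evolve_front()` adds
white-in-space additive noise (per-cell variance $C_0/\Delta x$ per unit
time, so results converge for smooth spectra) and scalar Itô gap noise to the
ETD front integrator; with all intensities zero it reproduces the
deterministic path bit for bit.

## Numerical choices and degenerate inputs

* Root solving in $\Omega$: geometric bracket expansion around a continuation
  guess, bounded below by the branch point of $l_w$, then `uniroot()` at
  $10^{-13}$; flagged `NA` when no real root exists on the branch.
* Threshold Newton: steps clipped at 2 per iteration, $10^{-8}$ acceptance on
  both $|\Omega|$ and $|\partial_k\Omega|$; inverse solves
  (`threshold_for_interface_pressure()`, `threshold_velocity_for_k0()`)
  bracket by scanning the speed range and skip speeds without a marginal
  point.
* ETDRK4 coefficient tables use the complex-contour mean (32 points) to avoid
  cancellation at small $|hL|$.
* Degenerate parameters: $\alpha = \Lambda = 0$ gives a uniform pressure and
  no advancing front; $\alpha = 0$ alone switches to the closed-form
  chemotaxis-only speed; $\alpha = r_e$ uses the resonant pressure profile.
* Blow-up guards abort simulations when $\|u\|_\infty$ exceeds a configurable
  bound, since quadratically nonlinear front equations can escape in finite
  time for large data.

## What the simulated conditions do and do not show

The synthetic runs in the tests use the reference conditions of the model's
figures: $\alpha = N_0 = 1$, $\sigma = 10^{-3}$, speeds of order
$U \sim 5$–$10$, gaps $|\mu| \le 0.2$, and noise intensities small enough for
the linearized below-threshold theory to apply. Dimensional anchors use
$D_e = 0.3\,\mu\mathrm{m}^2/\mathrm{s}$ and $\tau_e = 45$ min, for which a
dimensionless speed $U = 10$ is about $0.1\,\mu$m/s and the selected
wavenumber $k_0 = 7.2$ is a wavelength of about $25\,\mu$m. Problem sizes are
chosen for sharp statistics at desk scale: 128–512 collocation modes,
ensembles of 200 realizations, and finite-difference oracles with
$10^3$–$10^4$ nodes.

Passing these tests shows that the implementation solves the stated
free-boundary, amplitude and Langevin problems correctly; it does not show
that a real epithelium obeys them. In particular the model has a constant
tissue thickness away from the edge, a sharp interface with the density
boundary layer reduced to effective jump conditions, no mechanotaxis or
leader-cell heterogeneity, white-in-time noise only, and no treatment of the
fully developed fingering regime far above threshold (the amplitude equations
are asymptotic in $\sqrt\mu$). The second, fast root of the interface algebra
(see above) lies outside the physical branch the model describes; its status
would require resolving the interfacial boundary layer, which the sharp
interface description deliberately coarse-grains.

## Reproducing the headline numbers

`scripts/acceptance.R` recomputes, from the installed package alone: the Hopf
detuning; the coupled operating point at $P_i = -6.76$; the critical
$\Lambda_0$ at $U = 7$; the multiplicative sensitivities; and the speed at
which $k_0 = 7.2$. See the README for the exact invocation.
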