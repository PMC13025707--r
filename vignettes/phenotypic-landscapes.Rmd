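---
title: "Phenotypic landscapes from Bayesian sensing: model, numerics, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotypic landscapes from Bayesian sensing: model, numerics, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenoscape)
```

## The model

The package describes a one-dimensional coarse-grained phenotype $X$ of a cell
that adapts to a one-dimensional environmental variable $Y$ by Bayesian
updating, while also replicating and diffusing in phenotype space. Under a
strict timescale separation (the environment acts as a static observation
during one adaptive update), the averaged Bayesian update produces an
effective adaptation force. For jointly Gaussian $(X, Y)$ with correlation
$\rho$, everything is controlled by the *dependence ratio*

$$r(X, Y) = \frac{P(X, Y)}{P(X)\,P(Y)},$$

whose standardized closed form is implemented exactly in
`dependence_ratio()`. Two complementary expansions reduce $r - 1$, averaged
over the true environmental distribution, to a quadratic polynomial in $X$:

* **Weak coupling (case I, $|\rho| \ll 1$).** The Mehler–Hermite (Gaussian
  Lancaster) expansion truncated at second order,
  $\rho z_X z_Y + \tfrac{\rho^2}{2}(z_X^2 - 1)(z_Y^2 - 1)$, averaged over the
  true environment, gives `case1_polynomial()`. Its error against the exact
  ratio is $O(\rho^3)$; the test suite verifies the eight-fold error growth
  per doubling of $\rho$ against `dependence_ratio()` as the oracle.
* **Homeostatic operation (case II, $z_X \to 0$).** Expanding around the
  expected phenotypic state, valid for any $|\rho| < 1$, gives
  `case2_polynomial()` built from the constants $A$, $B$, and the Gaussian
  prefactor $r_0$ of `case2_base_constants()`. $r_0$ equals the exact
  dependence ratio at $z_X = 0$, which pins down its prefactor
  $(1-\rho^2)^{-1/2}$ unambiguously.

The polynomial coefficients combine with a locally Taylor-expanded
proliferation profile $\mu(X) - \bar\mu = \mu'(X - \bar X) +
\tfrac12 \mu''(X - \bar X)^2$ into the effective cubic-force coefficients
(`effective_coefficients()`):

$$\alpha = \frac{c_1}{\tau} + \mu' - \mu''\bar X, \qquad
  \beta = \frac{c_0}{\tau} - \mu'\bar X + \tfrac12 \mu''\bar X^2, \qquad
  \gamma = \frac{c_2}{\tau} + \tfrac12 \mu'',$$

so that the deterministic phenotype dynamics follow
$\dot X = K(X) = \tfrac{\gamma}{3}X^3 + \tfrac{\alpha}{2}X^2 + \beta X$.
Two structural consequences are worth noting (both are tested): linear
proliferation ($\mu'' = 0$) tilts the landscape through $\alpha$ and $\beta$
but can never change the saturation term $\gamma$, and curvature shifts
$\gamma$ by exactly $\mu''/2$. The Gaussian mutual information
$I(X;Y) = -\tfrac12\ln(1-\rho^2)$ (`mutual_information()`) makes $\rho$ an
information-theoretic control parameter.

### The two case-I constant terms

Direct substitution of the standardized phenotype into the truncated
expansion yields a constant term
$-\rho\bar z_Y S_X + \tfrac{\rho^2}{2}(\bar z_Y^2 - 1)(S_X^2 - 1)$, whereas
the closed-form coefficient set used as the default carries
$+\rho\bar z_Y S_X + \tfrac{\rho^2}{2}(\bar z_Y^2 - 1)(1 + S_X^2)$. The
linear and quadratic coefficients agree between the two derivations; only
the constant differs. Because the two cannot be reconciled, both are
exposed: `case1_polynomial(s, variant = "printed")` (default) and
`variant = "expansion"`. The constant term only enters $\beta$, so the
choice matters most near regime boundaries at small $|\rho|$. Similarly, in
case II the coefficient set of the canonical recombination
($\tilde B = A r_0/\sigma_X - 2 B S_X r_0 / \sigma_X$) is used throughout;
the perfect-sensing special forms of $\tilde A$ and $\tilde C$ are recovered
exactly at $\bar z_Y = 0$ and are asserted in the tests.

## Landscape analysis

The force is the gradient of the bare potential
$\Phi(x) = -(\tfrac{\gamma}{12}x^4 + \tfrac{\alpha}{6}x^3 +
\tfrac{\beta}{2}x^2)$, $\Phi(0)=0$. Fixed points are $x = 0$ and, when
$\Delta = 9\alpha^2 - 48\gamma\beta > 0$ and $\gamma \ne 0$,
$X_\pm = (-3\alpha \pm \sqrt\Delta)/(4\gamma)$; stability is the sign of
$K'(x) = \gamma x^2 + \alpha x + \beta$. Five canonical regimes exhaust the
cubic family: *fixation* (single deep well), *switch* (two wells),
*relaxation* (finite well, outer barriers), *critical switch* (vanishing
barrier), and *explosion* (runaway). Classification uses the exact sign
table first and falls back to fixed-point topology for sign patterns
outside it, so every coefficient triple receives exactly one label.

**Tolerance policy.** All criticality checks are relative to the coefficient
scale $s = \max(|\alpha|, |\beta|, |\gamma|, 1)$ with default
`tol = 1e-9`: $|\gamma| \le \text{tol}\cdot s$ or
$|\Delta| \le \text{tol}\cdot s^2$ labels the landscape critical, and a
fixed point with $|K'| \le \text{tol}\cdot s$ is marginal and also forces
the critical label. One can show $K'(X_\pm) =
\sqrt\Delta(\sqrt\Delta/3 \mp \alpha)/(8\gamma)$, so marginal slopes occur
only when $\Delta \approx 0$ or $\beta \approx 0$; the vectorized
phase-diagram classifier therefore tests $|\beta| \le \text{tol}\cdot s$
explicitly and matches the scalar path cell-for-cell. Degenerate inputs are
defined, not rejected: the all-zero triple reports the single marginal root
at 0 and the critical label.

### Barrier depth: exact closed form

The potential difference between the two non-origin extrema has an exact
closed form. With $u + v = -3\alpha/(2\gamma)$, $uv = 3\beta/\gamma$ and
$u - v = \sqrt\Delta/(2|\gamma|)$ for the roots $u, v$ of
$\tfrac{\gamma}{3}x^2 + \tfrac{\alpha}{2}x + \beta$, expanding
$\Phi(u)-\Phi(v)$ in the symmetric functions gives

$$|\Phi(X_+) - \Phi(X_-)| \;=\; \frac{|\alpha|\,\Delta^{3/2}}{192\,|\gamma|^3},$$

which is what `barrier_depth()` returns. A simpler expression without the
$|\alpha|/|\gamma|$ factor circulates for this quantity, but it is
dimensionally inconsistent (it carries units of potential per length) and
coincides with the exact form only when $|\alpha| = |\gamma|$ — which
happens to hold for all five canonical example triples, e.g. the switch
triple $(-1, 2, -1)$ where both give $105^{3/2}/192 \approx 5.60381$. The
test suite verifies the identity against numerically evaluated potential
differences over 1000 random draws at $10^{-8}$ relative tolerance. In the
bistable regime both outer extrema are wells, so the quantity measures
well-to-well asymmetry rather than a well-to-saddle barrier;
`phenoscape()` flags this case in its report
(`barrier_is_well_asymmetry`).

### Stationary density and the diffusion convention

The stationary law of the Langevin dynamics is
$P_{ss}(x) = Z^{-1} e^{-\Phi(x)/D}$ with
$Z = \int e^{-\Phi/D} dx$. The package keeps $1/D$ out of the potential:
$\Phi$ is *bare*, and $D$ enters only through the Boltzmann factor. This is
the unique convention under which the drift $K$, the noise amplitude
$\sqrt{2D\,dt}$ used by the simulator, and the stationary density are
mutually consistent (a formulation that embeds $1/D$ inside the potential
and divides by $D$ again in $Z$ would double-count it). $D = 1$ is the
default everywhere. Normalizability requires $\gamma < 0$, or $\gamma = 0$
with $\beta < 0$; anything else raises an explicit non-normalizable error,
mirroring the runaway regime. Truncation bounds are widened automatically
until the integrand falls below $10^{-12}$ of its maximum at both ends, and
$Z$ is computed by adaptive quadrature; the returned grid density
integrates to 1 within $10^{-6}$ by the trapezoidal rule.

## Stochastic and PDE dynamics

**Langevin simulator.** Explicit Euler–Maruyama was chosen over higher-order
schemes for transparency; the default `dt = 1e-3` makes the discretization
bias of the OU stationary variance $D/(1 - dt/2) - D \approx 5\times10^{-4}$,
far below sampling error at the ensemble sizes used. The generator is fully
seeded (`set.seed` on entry), so ensembles are bit-reproducible. Explosion
handling is an absorbing threshold `x_max` (default $10^3$) with the first
crossing time recorded and the path stored as `NA` afterwards, so exploded
segments can never leak into statistics. The noise convention takes $D$ as
the diffusion coefficient with increment amplitude $\sqrt{2D\,dt}$; the
noise standard deviation is not an independent parameter.

**Gradient-form Fokker–Planck solver.** `solve_gradient_fpe()` solves the
probability-conserving form $\partial_t P = -\partial_x(KP) + D\partial_x^2 P$
with no-flux boundaries by a finite-volume scheme whose interface fluxes are
exponentially fitted (Scharfetter–Gummel/Chang–Cooper type): the flux between
cells $i$ and $i+1$ is proportional to
$e^{(\Phi_{i+1}-\Phi_i)/2D} p_{i+1} - e^{(\Phi_i-\Phi_{i+1})/2D} p_i$. Two
properties follow by construction and are asserted in tests: the discrete
stationary state is *exactly* $\propto e^{-\Phi/D}$ at the nodes, and column
sums of the generator vanish, so implicit-Euler stepping conserves mass to
solver precision. Because the implicit scheme is unconditionally stable, no
diffusion CFL limit applies; the solver instead refuses a time step when
$dt \cdot \max|K'|$ exceeds 2 — an accuracy bound on the drift stiffness —
and suggests a usable `dt`.

**Replicator solver.** `solve_replicator_rde()` integrates the literal
reaction form $\partial_t P = (\gamma x^2 + \alpha x + \beta)P -
v(x)\partial_x P + D\partial_x^2 P$, in which $P$ is an unnormalized
population density and the reference mean proliferation rate is fixed, so
mass genuinely grows or decays and its trajectory is reported rather than
renormalized (the self-consistent time-dependent mean-rate variant is out of
scope). The phenotypic drift $v$ defaults to zero, upwinded when supplied.
The reaction and gradient forms are *not* mathematically equivalent; the
test suite demonstrates their long-time profiles differ on the switch
landscape. All closed-form results of the landscape analysis belong to the
gradient form, which is therefore the default elsewhere.

## Phase diagrams

`sweep_phase_plane()` classifies a $(\bar z_Y, S_X)$ grid at fixed $\rho$,
$\sigma_X = 1$, $\tau = 1$ and zero proliferation by default, with area
fractions by uniform cell counting; critical boundary cells are reported
separately and never merged into neighbors. Grid ranges are a package
choice: $\bar z_Y \in [0, 3]$, $S_X \in [0, 5]$ at $201 \times 201$
(fully configurable and recorded in the output metadata).

**Why case I is the sweep default.** The homeostatic (case II) coefficients
are all damped by the Gaussian prefactor
$r_0 \propto e^{-\rho^2 \bar z_Y^2/(2(1-\rho^2))}$, which collapses toward
zero at large bias and large $|\rho|$; there the constant term approaches
$r_0 - 1 \to -1$, so $\beta < 0$ and the far field of the diagram is
classified as relaxation rather than explosion. As a result the case-II
explosive area is *not* monotone in $\rho$ over this plane. The
weak-coupling polynomial, by contrast, reproduces the expected qualitative
reorganization — the explosive fraction shrinks monotonically as $\rho$
falls from 0.9 to 0.3, and negative $\rho$ suppresses both the explosive
and the bistable regions (a robustness–plasticity trade-off) — and is
therefore the default (`case = "I"`), with case II selectable for
sensitivity analysis. Formally the weak-coupling premise is strained at
$\rho = 0.9$; the sweep treats the polynomial as a parametric family of
landscapes rather than a controlled approximation there.

## Scope of the synthetic dynamics

The Langevin/PDE machinery generates all data the package is validated
against; nothing is fitted to measurements. The generator emulates a single
well-mixed phenotypic coordinate with constant diffusion, Gaussian sensing
statistics and a frozen environment. It does not emulate state-dependent
noise $D(X)$, non-Gaussian or multimodal sensing, cell–cell interactions,
spatial structure, or a time-evolving population mean phenotype — so
passing tests certify internal consistency of the model and its numerics,
not agreement with any particular single-cell dataset.

## Problem sizes and tolerances used in validation

The test suite checks the OU stationary variance with 200 trajectories to
$t = 50$ at `dt = 1e-3` (3% tolerance); stationary-law agreement on the
fixation landscape with 100 trajectories to $t = 200$ (total-variation
distance below 0.05 against the analytic law, and below $10^{-3}$ in $L^1$
for the PDE steady state at $t = 50$ on 301 cells); explosion statistics
with 200 trajectories to $t = 10$; and phase-diagram properties on
$101 \times 101$ grids. These sizes keep every stochastic check several
standard errors inside its tolerance while remaining quick to run.

## Configuration and interfaces

Scenario files are YAML (the standard R configuration dialect), validated
with field-level messages and strict unknown-key rejection; exactly one
coefficient source (direct triple, sensing block, or a fixture name) must
be supplied. Reports serialize to pretty-printed JSON with the full resolved
parameter set and seed embedded; grids and trajectories to CSV (with a JSON
metadata sidecar or comment header). A thin command-line wrapper
(`inst/cli/phenoscape.R`) exposes `classify`, `landscape`, `simulate`,
`phase`, `fixtures` and `config` subcommands over the exported functions;
usage errors exit 2, domain errors exit 1. Plotting (base graphics, fixed
regime color table with explosion red and switch green) is optional and
never load-bearing: all checks operate on serialized numbers.

## Known limitations

One-dimensional phenotype and environment only; constant diffusion; the
quadratic truncation of both adaptation expansions (landscapes beyond the
cubic-force family are out of scope); fixed reference proliferation rate
(no self-consistent renormalization); no estimation of $\rho$, $\bar z_Y$
or $S_X$ from data; no escape-rate (Kramers) machinery on top of the
barrier analysis.
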