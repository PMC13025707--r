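# phenoscape

Phenotypic landscapes from Bayesian cellular sensing and proliferation.

Cells can be viewed as Bayesian decision-makers: they combine noisy
microenvironmental observations with an internal state to update a
coarse-grained phenotype `X`, while also replicating and diffusing in
phenotype space. For jointly Gaussian intrinsic/extrinsic states, the
averaged Bayesian update plus a locally expanded proliferation profile
`μ(X)` produce an effective cubic phenotypic force

    dX/dt = K(X) = (γ/3) X³ + (α/2) X² + β X + ξ(t),

whose coefficients are explicit functions of the intrinsic–extrinsic
correlation `ρ` (equivalently the mutual information
`I(X;Y) = −½ ln(1 − ρ²)`), the sensing bias `z̄_Y`, the phenotypic
signal-to-noise ratio `S_X = μ_X/σ_X`, the relaxation time `τ`, and the
proliferation derivatives `μ′`, `μ″`. The associated potential
`Φ(x) = −(γx⁴/12 + αx³/6 + βx²/2)` admits exactly five qualitative
regimes — phenotypic fixation, switch (bistable decision-making), critical
switch, relaxation, and explosion (runaway, cancer-like) — determined by
the signs of `(α, β, γ)` and the discriminant `Δ = 9α² − 48γβ`.

The package is aimed at researchers in stochastic cell-fate dynamics and
quantitative cancer biology. It provides:

- **Coefficients**: exact Gaussian dependence ratio, its second-order
  Mehler–Hermite truncation, the weak-coupling (case I) and homeostatic
  (case II) adaptation polynomials, proliferation coupling, and mutual
  information.
- **Landscape analysis** (`phenoscape()`): fixed points and stabilities,
  regime classification, the exact barrier closed form
  `|α| Δ^{3/2} / (192 |γ|³)`, and the analytic stationary density
  `∝ exp(−Φ/D)`, wrapped in a classed object with `print`, `summary`,
  `coef`, `plot` and `simulate` methods.
- **Dynamics**: a seeded Euler–Maruyama Langevin simulator with explosion
  detection, an exponentially fitted finite-volume Fokker–Planck solver
  (gradient form, mass-conserving), and a replicator
  (reaction–advection–diffusion) solver for unnormalized population
  densities.
- **Phase diagrams**: classification sweeps of the (`z̄_Y`, `S_X`) plane at
  fixed `ρ` with per-regime area fractions.
- **Interfaces**: YAML scenario configs, JSON/CSV serialization with
  embedded provenance, a fixture catalog of canonical parameter sets, and a
  thin command-line wrapper.

## Worked example

A cell operating near homeostasis (case II) with moderate coupling
`ρ = 0.5`, sensing bias `z̄_Y = 0.5`, SNR `S_X = 0.25`, `σ_X = 0.35`:

```r
library(phenoscape)
s <- sensing_params(rho = 0.5, zbar_Y = 0.5, S_X = 0.25, sigma_X = 0.35, tau = 1)
m <- phenoscape(sensing = s, case = "II")
summary(m)
#> Phenotypic landscape analysis
#>
#> Sensing parameters:
#>   rho = 0.5   zbar_Y = 0.5   S_X = 0.25   sigma_X = 0.35   tau = 1   (mu_X = 0.0875)
#> Proliferation profile: mu' = 0, mu'' = 0, X_bar = 0, mu_bar = 0
#>   adaptation polynomial: case II;  mutual information I(X;Y) = 0.143841 nats
#> Cubic force coefficients: alpha = 1.16471, beta = 0.195067, gamma = -0.627878 (Delta = 18.088)
#> Regime: phenotypic_switch (matched by table2_signs)
#>
#> Fixed points:
#>    location      slope stable marginal
#>  -0.3021515 -0.2141749   TRUE    FALSE
#>   0.0000000  0.1950674  FALSE    FALSE
#>   3.0846515 -2.1865025   TRUE    FALSE
#>
#> Barrier depth |Phi(X+) - Phi(X-)| = 1.88529  [both outer extrema stable: value is well-to-well asymmetry]
#> Stationary density normalizable: yes (D = 1)
```

These sensing statistics place the cell in the bistable decision-making
regime: two stable phenotypes (at `x ≈ −0.30` and `x ≈ 3.08`) separated by
an unstable homeostatic point, with a confining landscape (`γ < 0`) whose
well-to-well potential asymmetry is 1.89. `simulate(m, nsim = 100,
t_end = 50)` then samples trajectories hopping between the two wells, and
`plot(m)` draws the double-well potential.

Sweeping the sensing plane at a differentiated-cell correlation:

```r
g <- sweep_phase_plane(0.3, n_zy = 101, n_sx = 101)
g
#> Phase grid (case I): rho = 0.3, sigma_X = 1, tau = 1, 101 x 101 cells
#> Area fractions:
#> phenotypic_relaxation     phenotypic_switch  phenotypic_explosion
#>                0.1011                0.2960                0.5623
#>   phenotypic_fixation
#>                0.0406
```

At low correlation roughly a third of the plane supports homeostatic or
bistable (healthy, differentiated) landscapes; repeating at `ρ = 0.9`
shows the explosive fraction growing — and at `ρ = −0.3` both the explosive
and bistable fractions collapse, the robustness–plasticity trade-off.

A command-line wrapper is installed with the package:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "phenoscape.R", package = "phenoscape"))') \
  classify --fixture regimes/switch
```

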