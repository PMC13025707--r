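# shared helpers for the test suite

canonical_triples <- list(
  phenotypic_relaxation = c(1, -2, 1),
  phenotypic_switch     = c(-1, 2, -1),
  critical_switch       = c(1.5, 2, 0),
  phenotypic_explosion  = c(0.5, 2, 0.5),
  phenotypic_fixation   = c(-1, -2, -1))

trapz_num <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)

# analytic Boltzmann density normalized by trapezoid on an arbitrary grid
analytic_density_on <- function(grid, c, D = 1) {
  phi <- bare_potential(grid, c)
  w <- exp(-(phi - min(phi)) / D)
  w / trapz_num(grid, w)
}

# brute-force fixed points: sign changes of K on a dense grid
scan_fixed_points <- function(c, lim = 50, step = 1e-3) {
  x <- seq(-lim, lim, by = step)
  k <- cubic_force(x, c)
  s <- sign(k)
  idx <- which(s[-1] * s[-length(s)] < 0)
  roots <- (x[idx] + x[idx + 1]) / 2
  exact <- x[k == 0]
  sort(c(roots, exact))
}
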