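#' Effective cubic phenotypic force
#'
#' Deterministic drift of the phenotype,
#' \eqn{K(x) = \frac{\gamma}{3}x^3 + \frac{\alpha}{2}x^2 + \beta x + c}.
#'
#' @param x phenotype value(s).
#' @param c a \code{\link{cubic_coefficients}} object (or numeric triple).
#' @return \eqn{K(x)}, vectorized over \code{x}.
#' @export
cubic_force <- function(x, c) {
  c <- as_cubic(c)
  c$gamma * x^3 / 3 + c$alpha * x^2 / 2 + c$beta * x + c$c_const
}

#' Bare effective potential
#'
#' Potential \eqn{\Phi(x)} with \eqn{K(x) = -\Phi'(x)} and \eqn{\Phi(0) = 0}:
#' \deqn{\Phi(x) = -\left(\frac{\gamma}{12}x^4 + \frac{\alpha}{6}x^3 + \frac{\beta}{2}x^2\right) - c\,x.}
#' The diffusion constant does not enter \eqn{\Phi}; the stationary density is
#' \eqn{\propto \exp(-\Phi(x)/D)} (see \code{\link{stationary_density}}).
#'
#' @inheritParams cubic_force
#' @return \eqn{\Phi(x)}, vectorized over \code{x}.
#' @export
bare_potential <- function(x, c) {
  c <- as_cubic(c)
  -(c$gamma * x^4 / 12 + c$alpha * x^3 / 6 + c$beta * x^2 / 2) - c$c_const * x
}

landscape_scale <- function(c) max(abs(c$alpha), abs(c$beta), abs(c$gamma), 1)

#' Fixed points of the cubic force
#'
#' Roots of \eqn{K(x) = 0} for the conservative force (\code{c_const = 0}):
#' always \eqn{x = 0}; additionally
#' \eqn{X_\pm = (-3\alpha \pm \sqrt\Delta)/(4\gamma)} when \eqn{\gamma \neq 0}
#' and \eqn{\Delta = 9\alpha^2 - 48\gamma\beta > 0}, or the single root
#' \eqn{-2\beta/\alpha} when \eqn{\gamma = 0, \alpha \neq 0}. Each point is
#' annotated with the slope \eqn{K'(x) = \gamma x^2 + \alpha x + \beta} and a
#' stability flag (stable iff \eqn{K' < 0}); points with
#' \eqn{|K'| \le} \code{tol} times the coefficient scale are flagged marginal.
#'
#' @param c a \code{\link{cubic_coefficients}} object with \code{c_const = 0}.
#' @param tol relative tolerance for marginal slopes (default \code{1e-9}).
#' @return A data frame with columns \code{location}, \code{slope},
#'   \code{stable}, \code{marginal}, sorted by location.
#' @examples
#' fixed_points(cubic_coefficients(-1, 2, -1))$location  # -3.312, 0, 1.812
#' @export
fixed_points <- function(c, tol = 1e-9) {
  c <- as_cubic(c)
  if (c$c_const != 0)
    stop("fixed_points is defined for the conservative force (c_const = 0)")
  sc <- landscape_scale(c)
  roots <- 0
  if (c$gamma != 0 && c$delta > 0) {
    roots <- c(roots, (-3 * c$alpha + c(-1, 1) * sqrt(c$delta)) / (4 * c$gamma))
  } else if (c$gamma == 0 && c$alpha != 0) {
    roots <- c(roots, -2 * c$beta / c$alpha)
  }
  roots <- sort(unique(roots))
  slope <- c$gamma * roots^2 + c$alpha * roots + c$beta
  data.frame(location = roots, slope = slope,
             stable = slope < 0,
             marginal = abs(slope) <= tol * sc)
}

regime_levels <- c("phenotypic_relaxation", "phenotypic_switch", "critical_switch",
                   "phenotypic_explosion", "phenotypic_fixation", "other")

# vectorized regime classifier over coefficient arrays; returns a list of
# character vectors (name, matched_by). The scalar classify_regime() and the
# phase-diagram sweep both call this, so per-cell labels match the standalone
# pipeline exactly.
classify_core <- function(alpha, beta, gamma, tol = 1e-9) {
  sc <- pmax(abs(alpha), abs(beta), abs(gamma), 1)
  delta <- 9 * alpha^2 - 48 * gamma * beta
  name <- rep("other", length(alpha))
  matched <- rep("topology_fallback", length(alpha))

  # a marginal fixed-point slope forces the critical label; non-origin slopes
  # are K'(X+-) = sqrt(D)(sqrt(D)/3 -+ alpha)/(8 gamma), which vanish only when
  # Delta ~ 0 or beta ~ 0, and the origin slope is beta itself
  crit <- abs(gamma) <= tol * sc | abs(delta) <= tol * sc^2 | abs(beta) <= tol * sc

  t2 <- !crit
  sel <- t2 & delta > 0 & beta < 0 & gamma > 0
  name[sel] <- "phenotypic_relaxation"; matched[sel] <- "table2_signs"
  sel <- t2 & delta > 0 & beta > 0 & gamma < 0
  name[sel] <- "phenotypic_switch"; matched[sel] <- "table2_signs"
  sel <- t2 & delta < 0 & beta > 0 & alpha > 0 & gamma > 0
  name[sel] <- "phenotypic_explosion"; matched[sel] <- "table2_signs"
  sel <- t2 & delta < 0 & beta < 0 & alpha < 0 & gamma < 0
  name[sel] <- "phenotypic_fixation"; matched[sel] <- "table2_signs"

  # topological fallback for sign patterns outside the canonical table rows
  for (i in which(!crit & name == "other")) {
    g <- gamma[i]; a <- alpha[i]; b <- beta[i]; d <- delta[i]
    r <- 0
    if (g != 0 && d > 0) r <- c(r, (-3 * a + c(-1, 1) * sqrt(d)) / (4 * g))
    sl <- g * r^2 + a * r + b
    nst <- sum(sl < 0)
    name[i] <- if (g < 0 && nst == 1) "phenotypic_fixation"
      else if (g < 0 && nst == 2 && sum(sl > 0) == 1) "phenotypic_switch"
      else if (g > 0 && nst >= 1) "phenotypic_relaxation"
      else if (g > 0) "phenotypic_explosion"
      else "other"
  }
  name[crit] <- "critical_switch"; matched[crit] <- "table2_signs"
  list(name = name, matched_by = matched)
}

#' Classify the phenotypic landscape regime
#'
#' Assigns one of the canonical landscape regimes from the sign structure of
#' \eqn{(\alpha, \beta, \gamma, \Delta)}:
#' \itemize{
#'   \item \emph{phenotypic_relaxation}: \eqn{\Delta>0, \beta<0, \gamma>0} -
#'     finite well at the origin with two outer barriers;
#'   \item \emph{phenotypic_switch}: \eqn{\Delta>0, \beta>0, \gamma<0} -
#'     two stable wells separated by an unstable origin;
#'   \item \emph{critical_switch}: \eqn{\gamma \approx 0} or
#'     \eqn{\Delta \approx 0} (vanishing barrier), or any marginal fixed point;
#'   \item \emph{phenotypic_explosion}: \eqn{\Delta<0, \beta>0, \alpha>0, \gamma>0} -
#'     runaway, no confining minimum;
#'   \item \emph{phenotypic_fixation}: \eqn{\Delta<0, \beta<0, \alpha<0, \gamma<0} -
#'     single deep global well.
#' }
#' Sign patterns outside these rows are resolved by the topology of the fixed
#' points (counts of stable/unstable roots and the sign of \eqn{\gamma});
#' such labels carry \code{matched_by = "topology_fallback"}.
#'
#' @param c a \code{\link{cubic_coefficients}} object.
#' @param tol relative tolerance for the critical boundary, applied to the
#'   coefficient scale \code{max(|alpha|, |beta|, |gamma|, 1)}.
#' @return An object of class \code{"regime_label"}: list with \code{name}
#'   and \code{matched_by}.
#' @examples
#' classify_regime(cubic_coefficients(-1, 2, -1))$name  # "phenotypic_switch"
#' @export
classify_regime <- function(c, tol = 1e-9) {
  c <- as_cubic(c)
  stopifnot(is.numeric(tol), tol > 0)
  k <- classify_core(c$alpha, c$beta, c$gamma, tol)
  structure(list(name = k$name, matched_by = k$matched_by),
            class = "regime_label")
}

#' @export
print.regime_label <- function(x, ...) {
  cat(sprintf("Regime: %s (matched by %s)\n", x$name, x$matched_by))
  invisible(x)
}

#' Landscape barrier depth
#'
#' Closed-form potential difference between the two non-origin extrema of the
#' bare potential,
#' \deqn{\Delta U = |\Phi(X_+) - \Phi(X_-)| = \frac{|\alpha|\,\Delta^{3/2}}{192\,|\gamma|^3},
#'   \qquad \Delta = 9\alpha^2 - 48\gamma\beta,}
#' defined when \eqn{\Delta > 0} and \eqn{\gamma \neq 0}. The identity is
#' exact (see the methods vignette for the derivation); when
#' \eqn{|\alpha| = |\gamma|} -- as in all canonical example triples -- it
#' reduces to \eqn{\Delta^{3/2}/(192\gamma^2)}. In the bistable switch regime both
#' \eqn{X_\pm} are stable wells, so the formula then measures well-to-well
#' asymmetry rather than a well-to-saddle barrier; \code{\link{phenoscape}}
#' flags this case.
#'
#' @param c a \code{\link{cubic_coefficients}} object with
#'   \code{delta > 0}, \code{gamma != 0}, \code{c_const = 0}.
#' @return The barrier depth in bare-potential units.
#' @examples
#' barrier_depth(cubic_coefficients(-1, 2, -1))  # 105^1.5/192 = 5.6038
#' @export
barrier_depth <- function(c) {
  c <- as_cubic(c)
  if (c$c_const != 0)
    stop("barrier_depth is defined for the conservative force (c_const = 0)")
  if (!(c$delta > 0) || c$gamma == 0)
    stop("barrier depth undefined: requires delta > 0 and gamma != 0")
  abs(c$alpha) * c$delta^1.5 / (192 * abs(c$gamma)^3)
}

# trapezoidal integral
trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)

#' Analytic stationary phenotype density
#'
#' Boltzmann-form stationary law of the phenotypic Langevin dynamics,
#' \deqn{P_{ss}(x) = \frac{1}{Z} e^{-\Phi(x)/D}, \qquad Z = \int e^{-\Phi(x)/D}\,dx,}
#' with \eqn{\Phi} the bare potential of \code{\link{bare_potential}}. Defined
#' only for confining landscapes: \eqn{\gamma < 0}, or \eqn{\gamma = 0} with
#' \eqn{\beta < 0}. Truncation bounds are auto-widened until the integrand at
#' both ends is below \code{1e-12} of its maximum.
#'
#' @param c a \code{\link{cubic_coefficients}} object (conservative).
#' @param D diffusion constant, strictly positive.
#' @param bounds optional numeric \code{c(lo, hi)} truncation interval.
#' @param n number of grid points, at least 101 (default 2001).
#' @return An object of class \code{"stationary_density"}: list with
#'   \code{grid}, \code{density}, \code{Z}, \code{D}, \code{bounds},
#'   \code{coefficients}.
#' @export
stationary_density <- function(c, D = 1, bounds = NULL, n = 2001) {
  c <- as_cubic(c)
  stopifnot(is.numeric(D), length(D) == 1L, D > 0, n >= 101)
  if (!(c$gamma < 0 || (c$gamma == 0 && c$beta < 0)))
    stop("non-normalizable landscape: stationary density requires gamma < 0, or gamma = 0 with beta < 0 (runaway regime otherwise)")
  phi <- function(x) bare_potential(x, c)
  # locate the potential minimum over a generous interval, then widen the
  # truncation window until the tails are negligible
  probe <- seq(-50, 50, length.out = 4001)
  pmin_x <- probe[which.min(phi(probe))]
  phimin <- stats::optimize(phi, interval = pmin_x + c(-1, 1))$objective
  phimin <- min(phimin, phi(0))
  if (is.null(bounds)) bounds <- pmin_x + c(-1, 1)
  stopifnot(length(bounds) == 2L, bounds[1] < bounds[2])
  tail_ok <- function(b) all(exp(-(phi(b) - phimin) / D) < 1e-12)
  for (i in 1:200) {
    if (tail_ok(bounds)) break
    w <- diff(bounds)
    if (exp(-(phi(bounds[1]) - phimin) / D) >= 1e-12) bounds[1] <- bounds[1] - 0.25 * w
    if (exp(-(phi(bounds[2]) - phimin) / D) >= 1e-12) bounds[2] <- bounds[2] + 0.25 * w
  }
  grid <- seq(bounds[1], bounds[2], length.out = n)
  w <- exp(-(phi(grid) - phimin) / D)
  Z0 <- stats::integrate(function(x) exp(-(phi(x) - phimin) / D),
                         bounds[1], bounds[2], rel.tol = 1e-10,
                         subdivisions = 500L)$value
  structure(list(grid = grid, density = w / Z0,
                 Z = Z0 * exp(-phimin / D), D = D, bounds = bounds,
                 coefficients = c),
            class = "stationary_density")
}

#' @export
print.stationary_density <- function(x, ...) {
  cat(sprintf("Stationary phenotype density on [%.3g, %.3g] (%d points), D = %g\n",
              x$bounds[1], x$bounds[2], length(x$grid), x$D))
  cat(sprintf("  trapezoidal mass = %.8f\n", trapz(x$grid, x$density)))
  invisible(x)
}

#' @export
as.data.frame.stationary_density <- function(x, ...) {
  data.frame(x = x$grid, density = x$density)
}
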