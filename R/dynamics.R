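#' Simulate the overdamped phenotypic Langevin dynamics
#'
#' Euler-Maruyama integration of
#' \eqn{dX/dt = K(X) + \xi(t)} with \eqn{K} the cubic force and white noise
#' of intensity \eqn{\sqrt{2D}}, i.e. the update
#' \eqn{x \leftarrow x + K(x)\,dt + \sqrt{2 D\, dt}\; g}, \eqn{g \sim N(0,1)}.
#' This noise convention makes \eqn{\exp(-\Phi/D)/Z} the stationary law on
#' confining landscapes. Trajectories crossing \eqn{|x| > x_{max}} are marked
#' exploded at the first crossing and frozen (stored as \code{NA} thereafter),
#' mirroring runaway phenotypic amplification.
#'
#' @param c a \code{\link{cubic_coefficients}} object (or numeric triple).
#' @param D diffusion constant, non-negative.
#' @param x0 initial condition: scalar or one value per trajectory.
#' @param dt time step (default \code{1e-3}).
#' @param t_end final time, must exceed \code{dt}.
#' @param n_traj number of trajectories.
#' @param seed integer seed; identical seed and parameters give identical
#'   ensembles bit-for-bit.
#' @param x_max absorbing explosion threshold (default \code{1e3}).
#' @param thin record every \code{thin}-th step (default 1); statistics are
#'   unaffected beyond sampling resolution.
#' @return An object of class \code{"trajectory_ensemble"}: recorded
#'   \code{times} (starting at 0), \code{paths} (time x trajectory matrix,
#'   \code{NA} after explosion), \code{exploded}, \code{explosion_time},
#'   and the full parameter set.
#' @examples
#' e <- simulate_langevin(cubic_coefficients(0, -1, 0), D = 1, t_end = 1,
#'                        n_traj = 3, seed = 42)
#' dim(e$paths)
#' @export
simulate_langevin <- function(c, D = 1, x0 = 0, dt = 1e-3, t_end = 10,
                              n_traj = 1, seed = 1, x_max = 1e3, thin = 1L) {
  c <- as_cubic(c)
  stopifnot(is.numeric(D), length(D) == 1L, D >= 0,
            is.numeric(dt), length(dt) == 1L,
            is.numeric(t_end), length(t_end) == 1L,
            n_traj >= 1, thin >= 1)
  if (dt <= 0) stop("dt must be > 0")
  if (t_end <= dt) stop("t_end must exceed dt")
  if (any(abs(x0) >= x_max)) stop("x_max must exceed |x0|")
  thin <- as.integer(thin)
  n_steps <- as.integer(round(t_end / dt))
  n_rec <- n_steps %/% thin
  x <- rep_len(as.numeric(x0), n_traj)
  paths <- matrix(NA_real_, nrow = n_rec + 1L, ncol = n_traj)
  paths[1L, ] <- x
  exploded <- rep(FALSE, n_traj)
  explosion_time <- rep(NA_real_, n_traj)
  g3 <- c$gamma / 3; a2 <- c$alpha / 2; b <- c$beta; cc <- c$c_const
  amp <- sqrt(2 * D * dt)
  set.seed(as.integer(seed))
  k <- 1L
  for (i in seq_len(n_steps)) {
    g <- stats::rnorm(n_traj)
    act <- !exploded
    if (any(act)) {
      xa <- x[act]
      xa <- xa + (g3 * xa^3 + a2 * xa^2 + b * xa + cc) * dt + amp * g[act]
      if (any(is.nan(xa)))
        stop("numerical overflow (NaN) in trajectory update: reduce dt or x_max")
      x[act] <- xa
      hit <- act & abs(x) > x_max & !exploded
      if (any(hit)) {
        exploded[hit] <- TRUE
        explosion_time[hit] <- i * dt
        x[hit] <- NA_real_
      }
    }
    if (i %% thin == 0L) {
      k <- k + 1L
      paths[k, ] <- x
    }
  }
  structure(list(times = c(0, seq_len(n_rec) * thin * dt), paths = paths,
                 exploded = exploded, explosion_time = explosion_time,
                 dt = dt, t_end = t_end, n_traj = as.integer(n_traj),
                 D = D, seed = as.integer(seed), x0 = x0, x_max = x_max,
                 thin = thin, coefficients = c),
            class = "trajectory_ensemble")
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  cat(sprintf("Langevin trajectory ensemble: %d trajectories, t_end = %g, dt = %g, D = %g, seed = %d\n",
              x$n_traj, x$t_end, x$dt, x$D, x$seed))
  cat(sprintf("  exploded: %d/%d (threshold |x| > %g)\n",
              sum(x$exploded), x$n_traj, x$x_max))
  invisible(x)
}

#' @export
as.data.frame.trajectory_ensemble <- function(x, ...) {
  n_rec <- length(x$times)
  df <- data.frame(trajectory = rep(seq_len(x$n_traj), each = n_rec),
                   time = rep(x$times, times = x$n_traj),
                   x = as.vector(x$paths))
  df[!is.na(df$x), , drop = FALSE]
}

#' Empirical phenotype density from a trajectory ensemble
#'
#' Normalized histogram of the pooled post-burn-in, non-exploded samples.
#'
#' @param e a \code{"trajectory_ensemble"}.
#' @param burn_in discard samples at times \code{<= burn_in}.
#' @param bins number of histogram bins.
#' @return An object of class \code{"empirical_density"} with \code{breaks},
#'   \code{mids}, \code{density} (integrating to 1) and \code{n_samples}.
#' @export
empirical_density <- function(e, burn_in = 0, bins = 50L) {
  stopifnot(inherits(e, "trajectory_ensemble"), bins >= 2)
  if (burn_in >= e$t_end) stop("burn_in must be < t_end")
  s <- as.vector(e$paths[e$times > burn_in, , drop = FALSE])
  s <- s[!is.na(s)]
  if (length(s) == 0L)
    stop("no samples: all trajectories exploded before the burn-in horizon")
  h <- graphics::hist(s, breaks = seq(min(s), max(s), length.out = bins + 1L),
                      plot = FALSE)
  structure(list(breaks = h$breaks, mids = h$mids, density = h$density,
                 n_samples = length(s)),
            class = "empirical_density")
}

#' @export
print.empirical_density <- function(x, ...) {
  cat(sprintf("Empirical density: %d samples in %d bins on [%.3g, %.3g]\n",
              x$n_samples, length(x$mids), min(x$breaks), max(x$breaks)))
  invisible(x)
}

# reference density evaluated as a function of x, zero outside its support
ref_density_fun <- function(ref) {
  if (inherits(ref, "stationary_density")) {
    f <- stats::approxfun(ref$grid, ref$density, yleft = 0, yright = 0)
  } else if (inherits(ref, "density_evolution")) {
    p <- ref$densities[nrow(ref$densities), ]
    p <- p / trapz(ref$grid, p)
    f <- stats::approxfun(ref$grid, p, yleft = 0, yright = 0)
  } else if (is.list(ref) && !is.null(ref$grid) && !is.null(ref$density)) {
    f <- stats::approxfun(ref$grid, ref$density, yleft = 0, yright = 0)
  } else stop("unsupported reference density object")
  f
}

#' Total-variation distance between an empirical and a reference density
#'
#' Bins the reference density (an analytic \code{\link{stationary_density}},
#' the final profile of a \code{"density_evolution"}, or any list with
#' \code{grid}/\code{density}) onto the histogram bins of the empirical
#' density, and returns
#' \eqn{\frac12 \sum_b |p^{emp}_b - p^{ref}_b| + \frac12 m_{out}}, where
#' \eqn{m_{out}} is the reference mass outside the histogram support.
#'
#' @param emp an \code{"empirical_density"}.
#' @param ref the reference density object.
#' @return The total-variation distance in \eqn{[0, 1]}.
#' @export
tv_distance <- function(emp, ref) {
  stopifnot(inherits(emp, "empirical_density"))
  f <- ref_density_fun(ref)
  nb <- length(emp$mids)
  widths <- diff(emp$breaks)
  p_emp <- emp$density * widths
  p_ref <- vapply(seq_len(nb), function(i) {
    xs <- seq(emp$breaks[i], emp$breaks[i + 1L], length.out = 21L)
    trapz(xs, f(xs))
  }, numeric(1))
  0.5 * sum(abs(p_emp - p_ref)) + 0.5 * max(0, 1 - sum(p_ref))
}

# shared scaffolding for the finite-volume PDE solvers: cell-centered grid,
# implicit Euler with a precomputed dense resolvent
pde_grid <- function(bounds, n) {
  dx <- diff(bounds) / n
  list(x = bounds[1] + (seq_len(n) - 0.5) * dx, dx = dx)
}

pde_p0 <- function(p0, x, dx) {
  p <- if (is.null(p0)) rep(1, length(x))
       else if (is.function(p0)) p0(x)
       else as.numeric(p0)
  if (length(p) != length(x)) stop("p0 must have one value per grid cell")
  if (any(p < 0)) stop("p0 must be non-negative")
  p / (sum(p) * dx)
}

pde_save_index <- function(t_end, dt, save_times) {
  if (is.null(save_times)) save_times <- seq(0, t_end, length.out = 26L)
  save_times <- sort(unique(pmin(pmax(save_times, 0), t_end)))
  idx <- unique(as.integer(round(save_times / dt)))
  list(idx = idx, times = idx * dt)
}

#' Solve the probability-conserving (gradient-form) Fokker-Planck equation
#'
#' Solves \eqn{\partial_t P = -\partial_x (K(x) P) + D \partial_x^2 P} with
#' no-flux boundaries on a truncated interval, using an exponentially fitted
#' finite-volume discretization (the discrete stationary state is exactly
#' \eqn{\propto e^{-\Phi(x)/D}} at the nodes) and implicit Euler time
#' stepping. Mass is conserved to solver precision by construction.
#'
#' @param c a \code{\link{cubic_coefficients}} object.
#' @param D diffusion constant, strictly positive.
#' @param bounds interval \code{c(lo, hi)}; auto-sized from the potential
#'   (tails below \code{1e-12} of the mode) when \code{NULL}, which requires
#'   a confining landscape.
#' @param n number of finite-volume cells (at least 201, default 301).
#' @param dt time step (implicit, unconditionally stable; refused when the
#'   drift stiffness \code{dt * max|K'|} is too large to be accurate).
#' @param t_end final time.
#' @param p0 initial density: \code{NULL} (uniform), a function of x, or a
#'   vector of cell values; normalized to unit mass.
#' @param save_times times at which to record the profile (default 26 evenly
#'   spaced including 0 and \code{t_end}).
#' @return An object of class \code{"density_evolution"} with \code{grid},
#'   \code{times}, \code{densities} (time x grid), \code{mass} and
#'   \code{conserving = TRUE}.
#' @export
solve_gradient_fpe <- function(c, D = 1, bounds = NULL, n = 301L, dt = 0.005,
                               t_end = 50, p0 = NULL, save_times = NULL) {
  c <- as_cubic(c)
  stopifnot(D > 0, n >= 201, dt > 0, t_end > 0)
  if (is.null(bounds)) {
    if (!(c$gamma < 0 || (c$gamma == 0 && c$beta < 0)))
      stop("non-confining landscape: supply explicit bounds")
    sdens <- stationary_density(c, D = D, n = 101)
    bounds <- sdens$bounds
  }
  stopifnot(length(bounds) == 2L, bounds[1] < bounds[2])
  g <- pde_grid(bounds, n)
  x <- g$x; dx <- g$dx
  kp_max <- max(abs(c$gamma * x^2 + c$alpha * x + c$beta))
  if (dt * kp_max > 2)
    stop(sprintf("dt too large for the drift stiffness (dt*max|K'| = %.3g): use dt <= %.3g",
                 dt * kp_max, 1 / kp_max))
  n_steps <- as.integer(ceiling(t_end / dt))
  dt <- t_end / n_steps
  phi <- bare_potential(x, c)
  dphi <- diff(phi) / (2 * D)     # half potential steps between neighbors
  r <- D / dx^2
  lo_gain <- r * exp(dphi)        # gain of cell i from cell i+1
  hi_gain <- r * exp(-dphi)       # gain of cell i+1 from cell i
  L <- matrix(0, n, n)
  L[cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L)] <- lo_gain
  L[cbind(seq_len(n - 1L) + 1L, seq_len(n - 1L))] <- hi_gain
  diag(L) <- -(c(hi_gain, 0) + c(0, lo_gain))
  Ainv <- solve(diag(n) - dt * L)
  p <- pde_p0(p0, x, dx)
  sv <- pde_save_index(t_end, dt, save_times)
  dens <- matrix(NA_real_, length(sv$idx), n)
  k <- 0L
  if (0L %in% sv$idx) { k <- 1L; dens[1L, ] <- p }
  for (i in seq_len(n_steps)) {
    p <- drop(Ainv %*% p)
    if (i %in% sv$idx) { k <- k + 1L; dens[k, ] <- p }
  }
  structure(list(grid = x, dx = dx, times = sv$times, densities = dens,
                 mass = rowSums(dens) * dx, conserving = TRUE,
                 coefficients = c, D = D, bounds = bounds, dt = dt),
            class = "density_evolution")
}

#' Solve the replicator (reaction-advection-diffusion) density equation
#'
#' Literal reaction form of the population-density dynamics,
#' \deqn{\partial_t P = (\gamma x^2 + \alpha x + \beta) P - v(x) \partial_x P + D \partial_x^2 P,}
#' in which \eqn{P} is an unnormalized population density and the reaction
#' term implements frequency-dependent selection around a fixed reference
#' proliferation rate; total mass is \emph{not} conserved and its trajectory
#' is reported. Zero-gradient boundaries; upwinded advection (the drift
#' \eqn{v} defaults to zero); implicit Euler stepping.
#'
#' @inheritParams solve_gradient_fpe
#' @param v drift function of x, or \code{NULL} for zero drift.
#' @param bounds interval \code{c(lo, hi)} (default \code{c(-10, 10)}).
#' @return A \code{"density_evolution"} with \code{conserving = FALSE}; the
#'   initial profile is normalized to unit mass, \code{mass} tracks growth
#'   or decay.
#' @export
solve_replicator_rde <- function(c, v = NULL, D = 1, bounds = c(-10, 10),
                                 n = 301L, dt = 0.005, t_end = 10,
                                 p0 = NULL, save_times = NULL) {
  c <- as_cubic(c)
  stopifnot(D > 0, n >= 201, dt > 0, t_end > 0,
            length(bounds) == 2L, bounds[1] < bounds[2])
  g <- pde_grid(bounds, n)
  x <- g$x; dx <- g$dx
  reaction <- c$gamma * x^2 + c$alpha * x + c$beta
  if (dt * max(abs(reaction)) > 2)
    stop(sprintf("dt too large for the reaction stiffness: use dt <= %.3g",
                 1 / max(abs(reaction))))
  n_steps <- as.integer(ceiling(t_end / dt))
  dt <- t_end / n_steps
  vv <- if (is.null(v)) rep(0, n) else { stopifnot(is.function(v)); v(x) }
  r <- D / dx^2
  L <- matrix(0, n, n)
  up <- rep(r, n - 1L); dn <- rep(r, n - 1L)
  L[cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L)] <- up
  L[cbind(seq_len(n - 1L) + 1L, seq_len(n - 1L))] <- dn
  diag(L) <- -(c(dn, 0) + c(0, up))     # zero-gradient diffusion stencil
  # upwinded advection -v dP/dx
  for (i in seq_len(n)) {
    if (vv[i] > 0 && i > 1L) {
      L[i, i] <- L[i, i] - vv[i] / dx; L[i, i - 1L] <- L[i, i - 1L] + vv[i] / dx
    } else if (vv[i] < 0 && i < n) {
      L[i, i] <- L[i, i] + vv[i] / dx; L[i, i + 1L] <- L[i, i + 1L] - vv[i] / dx
    }
  }
  diag(L) <- diag(L) + reaction
  Ainv <- solve(diag(n) - dt * L)
  p <- pde_p0(p0, x, dx)
  sv <- pde_save_index(t_end, dt, save_times)
  dens <- matrix(NA_real_, length(sv$idx), n)
  k <- 0L
  if (0L %in% sv$idx) { k <- 1L; dens[1L, ] <- p }
  for (i in seq_len(n_steps)) {
    p <- drop(Ainv %*% p)
    if (i %in% sv$idx) { k <- k + 1L; dens[k, ] <- p }
  }
  structure(list(grid = x, dx = dx, times = sv$times, densities = dens,
                 mass = rowSums(dens) * dx, conserving = FALSE,
                 coefficients = c, D = D, bounds = bounds, dt = dt),
            class = "density_evolution")
}

#' @export
print.density_evolution <- function(x, ...) {
  cat(sprintf("%s density evolution: %d cells on [%.3g, %.3g], %d saved times to t = %g\n",
              if (x$conserving) "Probability-conserving" else "Replicator (unnormalized)",
              length(x$grid), x$bounds[1], x$bounds[2], length(x$times),
              max(x$times)))
  cat(sprintf("  final mass = %.6g\n", x$mass[length(x$mass)]))
  invisible(x)
}

#' @export
as.data.frame.density_evolution <- function(x, ...) {
  data.frame(time = rep(x$times, each = length(x$grid)),
             x = rep(x$grid, times = length(x$times)),
             density = as.vector(t(x$densities)))
}
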