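#' Sweep the sensing-bias by signal-to-noise phase plane
#'
#' Classifies every point of a (sensing bias \eqn{\bar z_Y}) x (phenotypic
#' SNR \eqn{S_X}) grid at fixed correlation \eqn{\rho}: each cell is mapped
#' through the chosen adaptation polynomial and the proliferation profile to
#' effective cubic-force coefficients and then to a regime label, exactly as
#' the standalone landscape pipeline would. Per-regime area fractions use
#' uniform cell counting; tolerance-classified critical boundary cells are
#' counted under \code{critical_switch} and never merged into neighbors.
#'
#' The default adaptation polynomial is the weak-coupling one
#' (\code{case = "I"}); see the methods vignette for why this choice, rather
#' than the homeostatic expansion, reproduces the qualitative reorganization
#' of the diagrams as \eqn{\rho} varies.
#'
#' @param rho correlation, \code{abs(rho) < 1}.
#' @param sigma_X phenotypic standard deviation (default 1).
#' @param tau adaptation relaxation time (default 1).
#' @param proliferation a \code{\link{proliferation_params}} object (default
#'   zero profile, matching figure-style sweeps).
#' @param case adaptation polynomial: \code{"I"} (default) or \code{"II"}.
#' @param zy_range,sx_range axis ranges \code{c(lo, hi)}; defaults
#'   \eqn{\bar z_Y \in [0, 3]}, \eqn{S_X \in [0, 5]}.
#' @param n_zy,n_sx grid resolution per axis (default 201, minimum 2).
#' @param tol critical-boundary tolerance passed to the classifier.
#' @return An object of class \code{"phase_grid"}: axes, label matrix
#'   (\code{n_zy} rows x \code{n_sx} columns), per-regime \code{fractions},
#'   and the full parameter set.
#' @examples
#' g <- sweep_phase_plane(0.3, n_zy = 41, n_sx = 41)
#' g$fractions
#' @export
sweep_phase_plane <- function(rho, sigma_X = 1, tau = 1,
                              proliferation = proliferation_params(),
                              case = c("I", "II"),
                              zy_range = c(0, 3), sx_range = c(0, 5),
                              n_zy = 201L, n_sx = 201L, tol = 1e-9) {
  case <- match.arg(case)
  stopifnot(is.numeric(rho), length(rho) == 1L, is.finite(rho),
            inherits(proliferation, "proliferation_params"),
            sigma_X > 0, tau > 0, n_zy >= 2, n_sx >= 2,
            length(zy_range) == 2L, length(sx_range) == 2L,
            all(is.finite(c(zy_range, sx_range))))
  if (abs(rho) >= 1) stop("abs(rho) must be < 1")
  zy_axis <- seq(zy_range[1], zy_range[2], length.out = n_zy)
  sx_axis <- seq(sx_range[1], sx_range[2], length.out = n_sx)
  zy <- rep(zy_axis, times = n_sx)
  sx <- rep(sx_axis, each = n_zy)
  k <- if (case == "I") case1_coefs_vec(rho, zy, sx, sigma_X)
       else case2_coefs_vec(rho, zy, sx, sigma_X)
  p <- proliferation
  alpha <- k$c1 / tau + p$mu_prime - p$mu_double_prime * p$X_bar
  beta  <- k$c0 / tau - p$mu_prime * p$X_bar + 0.5 * p$mu_double_prime * p$X_bar^2
  gamma <- k$c2 / tau + 0.5 * p$mu_double_prime
  lab <- classify_core(alpha, beta, gamma, tol)$name
  labels <- matrix(lab, nrow = n_zy, ncol = n_sx,
                   dimnames = list(NULL, NULL))
  fr <- table(factor(lab, levels = regime_levels))
  structure(list(rho = rho, sigma_X = sigma_X, tau = tau,
                 proliferation = proliferation, case = case,
                 zy_axis = zy_axis, sx_axis = sx_axis, labels = labels,
                 fractions = stats::setNames(as.numeric(fr) / length(lab),
                                             regime_levels),
                 tol = tol),
            class = "phase_grid")
}

#' Per-regime area fractions of a phase grid
#'
#' Recomputes the uniform-cell-count fraction of each regime from the label
#' matrix; sums to 1 exactly.
#'
#' @param g a \code{"phase_grid"}.
#' @return Named numeric vector over all regime labels.
#' @export
area_fractions <- function(g) {
  stopifnot(inherits(g, "phase_grid"))
  if (length(g$labels) == 0L) stop("empty phase grid")
  fr <- table(factor(as.vector(g$labels), levels = regime_levels))
  stats::setNames(as.numeric(fr) / length(g$labels), regime_levels)
}

#' Regime area fraction as a function of correlation
#'
#' Repeats \code{\link{sweep_phase_plane}} over a vector of correlations with
#' an identical grid specification and extracts one regime's area fraction,
#' e.g. to quantify how the explosive region shrinks as the intrinsic-
#' extrinsic correlation (mutual information) decreases.
#'
#' @param rhos vector of correlations, each with \code{abs(rho) < 1}.
#' @param regime regime name (one of the classifier labels).
#' @param ... passed on to \code{\link{sweep_phase_plane}}.
#' @return Named numeric vector of fractions, one per correlation.
#' @export
regime_fraction_vs_rho <- function(rhos, regime = "phenotypic_explosion", ...) {
  stopifnot(is.numeric(rhos), length(rhos) >= 1L)
  regime <- match.arg(regime, regime_levels)
  stats::setNames(vapply(rhos,
                         function(r) sweep_phase_plane(r, ...)$fractions[[regime]],
                         numeric(1)), rhos)
}

#' @export
print.phase_grid <- function(x, ...) {
  cat(sprintf("Phase grid (case %s): rho = %g, sigma_X = %g, tau = %g, %d x %d cells\n",
              x$case, x$rho, x$sigma_X, x$tau,
              length(x$zy_axis), length(x$sx_axis)))
  cat("Area fractions:\n")
  print(round(x$fractions[x$fractions > 0], 4))
  invisible(x)
}

#' @export
as.data.frame.phase_grid <- function(x, ...) {
  data.frame(zbar_Y = rep(x$zy_axis, times = length(x$sx_axis)),
             S_X = rep(x$sx_axis, each = length(x$zy_axis)),
             label = as.vector(x$labels))
}

# fixed color language: explosion red, switch green
phase_colors <- c(phenotypic_relaxation = "skyblue",
                  phenotypic_switch = "forestgreen",
                  critical_switch = "grey70",
                  phenotypic_explosion = "firebrick",
                  phenotypic_fixation = "gold",
                  other = "white")

#' Plot a phase diagram
#'
#' Raster image of the regime labels over the (\eqn{\bar z_Y}, \eqn{S_X})
#' plane with the fixed color table (explosion red, switch green, fixation
#' gold, relaxation blue, critical grey).
#'
#' @param x a \code{"phase_grid"}.
#' @param legend draw a regime legend (default TRUE).
#' @param ... passed to \code{image}.
#' @export
plot.phase_grid <- function(x, legend = TRUE, ...) {
  z <- matrix(match(as.vector(x$labels), regime_levels),
              nrow = nrow(x$labels))
  graphics::image(x$zy_axis, x$sx_axis, z, zlim = c(1, length(regime_levels)),
                  col = unname(phase_colors), xlab = "sensing bias",
                  ylab = "signal-to-noise ratio", ...)
  if (legend) {
    present <- regime_levels[regime_levels %in% x$labels]
    graphics::legend("topright", legend = present,
                     fill = unname(phase_colors[present]), cex = 0.7, bg = "white")
  }
  invisible(x)
}
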