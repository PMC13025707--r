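#' Analyze a Bayesian phenotypic landscape
#'
#' Central constructor of the package. Either supply the effective cubic-force
#' coefficients directly, or supply sensing (and optionally proliferation)
#' parameters, in which case the chosen adaptation polynomial (weak-coupling
#' case \code{"I"} or homeostatic case \code{"II"}) is combined with the
#' proliferation profile into effective coefficients. The returned object
#' bundles the deterministic analysis of the landscape: fixed points with
#' stabilities, the regime label, the barrier depth (when defined) and the
#' normalizability of the stationary law.
#'
#' @param coefficients a \code{\link{cubic_coefficients}} object (or numeric
#'   triple); mutually exclusive with \code{sensing}.
#' @param sensing a \code{\link{sensing_params}} object; mutually exclusive
#'   with \code{coefficients}.
#' @param proliferation a \code{\link{proliferation_params}} object, used only
#'   with \code{sensing}.
#' @param case adaptation polynomial used with \code{sensing}: \code{"II"}
#'   (homeostatic limit, default) or \code{"I"} (weak coupling).
#' @param D diffusion constant, strictly positive (default 1).
#' @param tol relative tolerance for marginal fixed points and the critical
#'   regime boundary.
#' @return An object of class \code{"phenoscape"} with fields
#'   \code{coefficients}, \code{fixed_points} (data frame), \code{regime},
#'   \code{barrier_depth} (\code{NA} when undefined), \code{barrier_is_well_asymmetry}
#'   (flag: both outer extrema stable, so the closed form measures well-to-well
#'   asymmetry), \code{normalizable}, \code{D}, and, when derived from sensing,
#'   \code{sensing}, \code{proliferation}, \code{case},
#'   \code{mutual_information}.
#' @examples
#' m <- phenoscape(cubic_coefficients(-1, 2, -1))
#' m$regime$name        # "phenotypic_switch"
#' coef(m)
#' @export
phenoscape <- function(coefficients = NULL, sensing = NULL,
                       proliferation = proliferation_params(),
                       case = c("II", "I"), D = 1, tol = 1e-9) {
  case <- match.arg(case)
  stopifnot(is.numeric(D), length(D) == 1L, is.finite(D))
  if (D <= 0) stop("D must be > 0")
  if (is.null(coefficients) == is.null(sensing))
    stop("supply exactly one of 'coefficients' or 'sensing'")
  mi <- NULL
  if (!is.null(sensing)) {
    stopifnot(inherits(sensing, "sensing_params"))
    q <- if (case == "I") case1_polynomial(sensing) else case2_polynomial(sensing)
    coefficients <- effective_coefficients(q, proliferation, sensing$tau)
    mi <- mutual_information(sensing$rho)
  } else {
    coefficients <- as_cubic(coefficients)
  }
  fp <- fixed_points(coefficients, tol = tol)
  regime <- classify_regime(coefficients, tol = tol)
  bd <- NA_real_
  asym <- FALSE
  if (coefficients$delta > 0 && coefficients$gamma != 0) {
    bd <- barrier_depth(coefficients)
    outer <- fp[fp$location != 0, , drop = FALSE]
    asym <- nrow(outer) == 2L && all(outer$stable)
  }
  normalizable <- coefficients$gamma < 0 ||
    (coefficients$gamma == 0 && coefficients$beta < 0)
  structure(list(coefficients = coefficients, fixed_points = fp,
                 regime = regime, barrier_depth = bd,
                 barrier_is_well_asymmetry = asym,
                 normalizable = normalizable, D = D, tol = tol,
                 sensing = sensing,
                 proliferation = if (!is.null(sensing)) proliferation else NULL,
                 case = if (!is.null(sensing)) case else NULL,
                 mutual_information = mi),
            class = "phenoscape")
}

#' @export
print.phenoscape <- function(x, ...) {
  cat("Phenotypic landscape\n")
  print(x$coefficients)
  print(x$regime)
  invisible(x)
}

#' @export
summary.phenoscape <- function(object, ...) {
  structure(object, class = c("summary.phenoscape", "phenoscape"))
}

#' @export
print.summary.phenoscape <- function(x, ...) {
  cat("Phenotypic landscape analysis\n\n")
  if (!is.null(x$sensing)) {
    print(x$sensing)
    print(x$proliferation)
    cat(sprintf("  adaptation polynomial: case %s;  mutual information I(X;Y) = %.6g nats\n",
                x$case, x$mutual_information))
  }
  print(x$coefficients)
  print(x$regime)
  cat("\nFixed points:\n")
  print(x$fixed_points, row.names = FALSE)
  if (!is.na(x$barrier_depth)) {
    cat(sprintf("\nBarrier depth |Phi(X+) - Phi(X-)| = %.6g%s\n",
                x$barrier_depth,
                if (isTRUE(x$barrier_is_well_asymmetry))
                  "  [both outer extrema stable: value is well-to-well asymmetry]" else ""))
  } else {
    cat("\nBarrier depth: undefined (Delta <= 0 or gamma = 0)\n")
  }
  cat(sprintf("Stationary density normalizable: %s (D = %g)\n",
              if (x$normalizable) "yes" else "no (runaway landscape)", x$D))
  invisible(x)
}

#' @export
coef.phenoscape <- function(object, ...) {
  with(object$coefficients, c(alpha = alpha, beta = beta, gamma = gamma))
}

#' Plot a phenotypic landscape
#'
#' Draws the bare potential with fixed points marked (filled for stable,
#' open for unstable), and optionally the analytic stationary density.
#'
#' @param x a \code{\link{phenoscape}} object.
#' @param which \code{"potential"} (default) or \code{"density"}.
#' @param xlim phenotype range; auto-chosen from the fixed points if missing.
#' @param ... passed to \code{plot}.
#' @export
plot.phenoscape <- function(x, which = c("potential", "density"),
                            xlim = NULL, ...) {
  which <- match.arg(which)
  if (which == "density") {
    if (!x$normalizable)
      stop("non-normalizable landscape: no stationary density to plot")
    sd <- stationary_density(x$coefficients, D = x$D)
    graphics::plot(sd$grid, sd$density, type = "l", xlab = "phenotype x",
                   ylab = "stationary density", ...)
    return(invisible(x))
  }
  if (is.null(xlim)) {
    r <- range(x$fixed_points$location)
    w <- max(diff(r), 1)
    xlim <- c(r[1] - 0.6 * w, r[2] + 0.6 * w)
  }
  xs <- seq(xlim[1], xlim[2], length.out = 512)
  graphics::plot(xs, bare_potential(xs, x$coefficients), type = "l",
                 xlab = "phenotype x", ylab = "effective potential", ...)
  fp <- x$fixed_points
  graphics::points(fp$location, bare_potential(fp$location, x$coefficients),
                   pch = ifelse(fp$stable, 19, 1), col = ifelse(fp$stable, "darkgreen", "red"))
  invisible(x)
}

#' Simulate phenotype trajectories from a landscape
#'
#' \code{simulate} method dispatching to \code{\link{simulate_langevin}} with
#' the landscape's coefficients and diffusion constant.
#'
#' @param object a \code{\link{phenoscape}} object.
#' @param nsim number of trajectories.
#' @param seed integer seed for the noise generator.
#' @param ... further arguments to \code{\link{simulate_langevin}}
#'   (\code{x0}, \code{dt}, \code{t_end}, \code{x_max}, \code{thin}).
#' @return A \code{"trajectory_ensemble"} object.
#' @export
simulate.phenoscape <- function(object, nsim = 1, seed = 1, ...) {
  simulate_langevin(object$coefficients, D = object$D, n_traj = nsim,
                    seed = seed, ...)
}
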