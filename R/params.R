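#' Sensing parameters of the Bayesian adaptation model
#'
#' Bundles the information-theoretic inputs of the model: the
#' intrinsic-extrinsic correlation \eqn{\rho}, the standardized sensing bias
#' \eqn{\bar z_Y} (mismatch between the true environmental mean and the
#' cell-perceived one), the phenotypic signal-to-noise ratio
#' \eqn{S_X = \mu_X/\sigma_X}, the phenotypic standard deviation
#' \eqn{\sigma_X}, and the adaptation relaxation time \eqn{\tau}.
#' The phenotype mean \eqn{\mu_X = S_X \sigma_X} is derived and stored.
#'
#' @param rho correlation between intrinsic and extrinsic states; must satisfy
#'   \code{abs(rho) < 1}.
#' @param zbar_Y sensing bias (standardized, dimensionless).
#' @param S_X phenotypic signal-to-noise ratio, non-negative.
#' @param sigma_X phenotypic standard deviation, strictly positive.
#' @param tau adaptation relaxation time, strictly positive.
#' @return An object of class \code{"sensing_params"}.
#' @examples
#' s <- sensing_params(rho = 0.5, zbar_Y = 0.5, S_X = 0.25, sigma_X = 0.35)
#' s$mu_X  # 0.0875
#' @export
sensing_params <- function(rho, zbar_Y = 0, S_X = 1, sigma_X = 1, tau = 1) {
  stopifnot(is.numeric(rho), length(rho) == 1L, is.finite(rho),
            is.numeric(zbar_Y), length(zbar_Y) == 1L, is.finite(zbar_Y),
            is.numeric(S_X), length(S_X) == 1L, is.finite(S_X),
            is.numeric(sigma_X), length(sigma_X) == 1L, is.finite(sigma_X),
            is.numeric(tau), length(tau) == 1L, is.finite(tau))
  if (abs(rho) >= 1)
    stop("abs(rho) must be < 1: perfect (or super-unit) correlation is outside the Gaussian model domain")
  if (S_X < 0) stop("S_X must be >= 0")
  if (sigma_X <= 0) stop("sigma_X must be > 0")
  if (tau <= 0) stop("tau must be > 0")
  structure(list(rho = rho, zbar_Y = zbar_Y, S_X = S_X,
                 sigma_X = sigma_X, tau = tau, mu_X = S_X * sigma_X),
            class = "sensing_params")
}

#' @export
print.sensing_params <- function(x, ...) {
  cat("Sensing parameters:\n")
  cat(sprintf("  rho = %g   zbar_Y = %g   S_X = %g   sigma_X = %g   tau = %g   (mu_X = %g)\n",
              x$rho, x$zbar_Y, x$S_X, x$sigma_X, x$tau, x$mu_X))
  invisible(x)
}

#' Proliferation profile parameters
#'
#' Local Taylor expansion of the phenotype-dependent proliferation rate
#' \eqn{\mu(X)} around a fixed reference phenotype \eqn{\bar X}:
#' \eqn{\mu(X) - \bar\mu = \mu'(X - \bar X) + \tfrac12 \mu''(X - \bar X)^2}.
#' The reference average rate \eqn{\bar\mu} is bookkeeping only: it never
#' enters the effective force coefficients.
#'
#' @param mu_prime first derivative of the proliferation rate at the
#'   reference phenotype (1/time per phenotype unit).
#' @param mu_double_prime second derivative (1/time per phenotype unit^2).
#' @param X_bar reference phenotype (phenotype units).
#' @param mu_bar fixed reference average proliferation rate (1/time).
#' @return An object of class \code{"proliferation_params"}.
#' @export
proliferation_params <- function(mu_prime = 0, mu_double_prime = 0,
                                 X_bar = 0, mu_bar = 0) {
  vals <- c(mu_prime, mu_double_prime, X_bar, mu_bar)
  stopifnot(is.numeric(vals), length(vals) == 4L, all(is.finite(vals)))
  structure(list(mu_prime = mu_prime, mu_double_prime = mu_double_prime,
                 X_bar = X_bar, mu_bar = mu_bar),
            class = "proliferation_params")
}

#' @export
print.proliferation_params <- function(x, ...) {
  cat(sprintf("Proliferation profile: mu' = %g, mu'' = %g, X_bar = %g, mu_bar = %g\n",
              x$mu_prime, x$mu_double_prime, x$X_bar, x$mu_bar))
  invisible(x)
}

#' Effective cubic-force coefficients
#'
#' Container for the coefficient triple \eqn{(\alpha, \beta, \gamma)} of the
#' effective phenotypic force
#' \eqn{K(X) = \frac{\gamma}{3}X^3 + \frac{\alpha}{2}X^2 + \beta X + c},
#' together with the derived discriminant
#' \eqn{\Delta = 9\alpha^2 - 48\gamma\beta} that controls the existence of
#' non-origin fixed points.
#'
#' @param alpha quadratic-force coefficient (asymmetry/bias term).
#' @param beta linear-force coefficient (local stability of the origin).
#' @param gamma cubic-force coefficient (large-amplitude saturation).
#' @param c_const optional constant force offset, default 0.
#' @return An object of class \code{"cubic_coefficients"} with fields
#'   \code{alpha}, \code{beta}, \code{gamma}, \code{c_const}, \code{delta}.
#' @examples
#' cubic_coefficients(-1, 2, -1)$delta  # 105
#' @export
cubic_coefficients <- function(alpha, beta, gamma, c_const = 0) {
  vals <- c(alpha, beta, gamma, c_const)
  stopifnot(is.numeric(vals), length(vals) == 4L, all(is.finite(vals)))
  structure(list(alpha = alpha, beta = beta, gamma = gamma,
                 c_const = c_const,
                 delta = 9 * alpha^2 - 48 * gamma * beta),
            class = "cubic_coefficients")
}

#' @export
print.cubic_coefficients <- function(x, ...) {
  cat(sprintf("Cubic force coefficients: alpha = %g, beta = %g, gamma = %g (Delta = %g)\n",
              x$alpha, x$beta, x$gamma, x$delta))
  if (x$c_const != 0) cat(sprintf("  constant force offset c = %g\n", x$c_const))
  invisible(x)
}

# coerce a cubic_coefficients or length-3/4 numeric into cubic_coefficients
as_cubic <- function(c) {
  if (inherits(c, "cubic_coefficients")) return(c)
  if (is.numeric(c) && length(c) %in% c(3L, 4L))
    return(cubic_coefficients(c[[1L]], c[[2L]], c[[3L]],
                              if (length(c) == 4L) c[[4L]] else 0))
  stop("expected a 'cubic_coefficients' object or a numeric vector (alpha, beta, gamma[, c_const])")
}
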