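#' Gaussian mutual information from the correlation coefficient
#'
#' For jointly Gaussian intrinsic and extrinsic states with correlation
#' \eqn{\rho}, the mutual information is
#' \eqn{I(X;Y) = -\frac12 \log(1 - \rho^2)} (in nats). It is the
#' information-theoretic control parameter of the landscape: large \eqn{|\rho|}
#' means tight environmental tracking, small \eqn{|\rho|} a decoupled,
#' internally stabilized phenotype.
#'
#' @param rho correlation coefficient, \code{abs(rho) < 1}. Vectorized.
#' @return Mutual information in nats; non-negative, even in \code{rho}.
#' @examples
#' mutual_information(0.3)  # 0.04715534
#' @export
mutual_information <- function(rho) {
  stopifnot(is.numeric(rho), all(is.finite(rho)))
  if (any(abs(rho) >= 1))
    stop("abs(rho) must be < 1: mutual information diverges at perfect correlation")
  -0.5 * log1p(-rho^2)
}

#' Exact bivariate-Gaussian dependence ratio
#'
#' The dependence ratio \eqn{r(X,Y) = P(X,Y) / (P(X) P(Y))} for a
#' standardized bivariate Gaussian with correlation \eqn{\rho}, evaluated at
#' standardized coordinates \eqn{(z_x, z_y)}:
#' \deqn{r = (1-\rho^2)^{-1/2} \exp\!\left(-\frac{\rho^2(z_x^2+z_y^2) - 2\rho z_x z_y}{2(1-\rho^2)}\right).}
#' This is the exact quantity whose weak-correlation expansion produces the
#' adaptation force; it serves as the oracle for \code{\link{mehler_truncation}}.
#'
#' @param z_x,z_y standardized intrinsic and extrinsic coordinates. Vectorized.
#' @param rho correlation, \code{abs(rho) < 1}.
#' @return The strictly positive dependence ratio.
#' @export
dependence_ratio <- function(z_x, z_y, rho) {
  stopifnot(is.numeric(z_x), is.numeric(z_y), is.numeric(rho),
            all(is.finite(z_x)), all(is.finite(z_y)), all(is.finite(rho)))
  if (any(abs(rho) >= 1))
    stop("abs(rho) must be < 1")
  (1 - rho^2)^(-0.5) *
    exp(-(rho^2 * (z_x^2 + z_y^2) - 2 * rho * z_x * z_y) / (2 * (1 - rho^2)))
}

#' Second-order Mehler-Hermite truncation of the dependence ratio
#'
#' Truncation of the Gaussian Lancaster (Mehler-Hermite) expansion of
#' \eqn{r(X,Y) - 1} at second order in \eqn{\rho}:
#' \deqn{\rho z_x z_y + \frac{\rho^2}{2}(z_x^2 - 1)(z_y^2 - 1),}
#' accurate to \eqn{O(\rho^3)} and intended for the weak-coupling regime
#' \eqn{|\rho| \ll 1}.
#'
#' @inheritParams dependence_ratio
#' @return The truncated expansion of \code{dependence_ratio(...) - 1}.
#' @export
mehler_truncation <- function(z_x, z_y, rho) {
  stopifnot(is.numeric(z_x), is.numeric(z_y), is.numeric(rho))
  rho * z_x * z_y + (rho^2 / 2) * (z_x^2 - 1) * (z_y^2 - 1)
}

# vectorized internal kernels; the scalar user-facing functions and the
# phase-diagram sweep both go through these, so composition is exact.
case1_coefs_vec <- function(rho, zy, sx, sigma) {
  list(c0 = rho * zy * sx + rho^2 * (zy^2 - 1) / 2 * (1 + sx^2),
       c1 = rho * zy / sigma - rho^2 * (zy^2 - 1) * sx / sigma,
       c2 = rho^2 * (zy^2 - 1) / (2 * sigma^2))
}

# constant term from the direct expansion of the averaged dependence ratio
# (differs from the printed closed form only in the constant term)
case1_c0_expansion_vec <- function(rho, zy, sx) {
  -rho * zy * sx + rho^2 * (zy^2 - 1) / 2 * (sx^2 - 1)
}

case2_base_vec <- function(rho, zy) {
  om <- 1 - rho^2
  r0 <- om^(-0.5) * exp(-rho^2 * zy^2 / (2 * om))
  list(A = rho * zy / om,
       B = rho^2 * (zy^2 - om^2) / (2 * om^2),
       r0 = r0,
       r_tilde = r0 - 1)
}

case2_coefs_vec <- function(rho, zy, sx, sigma) {
  b <- case2_base_vec(rho, zy)
  list(c0 = b$r_tilde + b$A * sx * b$r0 + b$B * sx^2 * b$r0,
       c1 = b$A * b$r0 / sigma - 2 * b$B * sx * b$r0 / sigma,
       c2 = b$B * b$r0 / sigma^2)
}

new_quadratic_fitness <- function(c0, c1, c2, case_tag) {
  structure(list(c0 = c0, c1 = c1, c2 = c2, case_tag = case_tag),
            class = "quadratic_fitness")
}

#' @export
print.quadratic_fitness <- function(x, ...) {
  cat(sprintf("Quadratic adaptation polynomial (%s): c0 = %g, c1 = %g, c2 = %g\n",
              x$case_tag, x$c0, x$c1, x$c2))
  invisible(x)
}

#' Weak-coupling (case-I) adaptation polynomial
#'
#' Adaptation force polynomial \eqn{h(X) = c_0 + c_1 X + c_2 X^2} in the
#' weak-coupling limit \eqn{|\rho| \ll 1}, obtained from the second-order
#' Mehler-Hermite expansion of the dependence ratio averaged over the true
#' environmental distribution:
#' \deqn{c_0 = \rho \bar z_Y S_X + \tfrac{\rho^2(\bar z_Y^2-1)}{2}(1 + S_X^2),\quad
#'       c_1 = \frac{\rho \bar z_Y}{\sigma_X} - \frac{\rho^2(\bar z_Y^2-1) S_X}{\sigma_X},\quad
#'       c_2 = \frac{\rho^2(\bar z_Y^2-1)}{2\sigma_X^2}.}
#'
#' The default \code{variant = "printed"} uses the closed-form coefficients
#' above. \code{variant = "expansion"} instead derives the constant term by
#' direct substitution of the standardized phenotype into the truncated
#' expansion, which yields
#' \eqn{c_0 = -\rho \bar z_Y S_X + \tfrac{\rho^2(\bar z_Y^2-1)}{2}(S_X^2 - 1)};
#' the linear and quadratic terms agree between the two variants. Both are
#' exposed because the two derivations genuinely disagree on the constant
#' term; see the methods vignette.
#'
#' @param s a \code{\link{sensing_params}} object.
#' @param variant \code{"printed"} (default) or \code{"expansion"}.
#' @return A \code{"quadratic_fitness"} object with \code{case_tag = "case_I"}.
#' @export
case1_polynomial <- function(s, variant = c("printed", "expansion")) {
  stopifnot(inherits(s, "sensing_params"))
  variant <- match.arg(variant)
  k <- case1_coefs_vec(s$rho, s$zbar_Y, s$S_X, s$sigma_X)
  if (variant == "expansion")
    k$c0 <- case1_c0_expansion_vec(s$rho, s$zbar_Y, s$S_X)
  new_quadratic_fitness(k$c0, k$c1, k$c2, "case_I")
}

#' Homeostatic-limit (case-II) base constants
#'
#' Constants of the expansion of the dependence ratio around the expected
#' phenotypic state (\eqn{z_X \to 0}), valid for any \eqn{|\rho| < 1}:
#' \deqn{A = \frac{\rho \bar z_Y}{1-\rho^2}, \qquad
#'       B = \frac{\rho^2\,(\bar z_Y^2 - (1-\rho^2)^2)}{2(1-\rho^2)^2},}
#' with Gaussian prefactor
#' \eqn{r_0 = (1-\rho^2)^{-1/2} \exp(-\rho^2 \bar z_Y^2 / (2(1-\rho^2)))}
#' and \eqn{\tilde r = r_0 - 1}. Note \eqn{r_0} equals the exact dependence
#' ratio evaluated at \eqn{z_x = 0}.
#'
#' @param s a \code{\link{sensing_params}} object.
#' @return An object of class \code{"case2_base"} with fields \code{A},
#'   \code{B}, \code{r0}, \code{r_tilde}.
#' @export
case2_base_constants <- function(s) {
  stopifnot(inherits(s, "sensing_params"))
  b <- case2_base_vec(s$rho, s$zbar_Y)
  structure(b, class = "case2_base")
}

#' Homeostatic-limit (case-II) adaptation polynomial
#'
#' Adaptation polynomial
#' \eqn{\tilde h(X) = (\tilde r + \tilde A) + \tilde B X + \tilde C X^2}
#' around the expected phenotypic state, with
#' \deqn{\tilde A = A S_X r_0 + B S_X^2 r_0, \qquad
#'       \tilde B = \frac{A r_0}{\sigma_X} - \frac{2 B S_X r_0}{\sigma_X}, \qquad
#'       \tilde C = \frac{B r_0}{\sigma_X^2},}
#' using the constants of \code{\link{case2_base_constants}}. At perfect
#' sensing (\eqn{\bar z_Y = 0}) this reduces to
#' \eqn{\tilde A = -\tfrac{\rho^2}{2} S_X^2 r_0 < 0} and
#' \eqn{\tilde C = -\tfrac{\rho^2}{2\sigma_X^2} r_0 < 0}.
#'
#' @param s a \code{\link{sensing_params}} object.
#' @return A \code{"quadratic_fitness"} object with \code{case_tag = "case_II"};
#'   \code{c0} houses \eqn{\tilde r + \tilde A}.
#' @export
case2_polynomial <- function(s) {
  stopifnot(inherits(s, "sensing_params"))
  k <- case2_coefs_vec(s$rho, s$zbar_Y, s$S_X, s$sigma_X)
  new_quadratic_fitness(k$c0, k$c1, k$c2, "case_II")
}

#' Combine adaptation and proliferation into effective force coefficients
#'
#' The effective fitness is \eqn{h_{\rm eff}(X) = h(X)/\tau + \mu(X) - \bar\mu},
#' giving the cubic-force coefficients
#' \deqn{\alpha = c_1/\tau + \mu' - \mu'' \bar X, \qquad
#'       \beta = c_0/\tau - \mu' \bar X + \tfrac12 \mu'' \bar X^2, \qquad
#'       \gamma = c_2/\tau + \tfrac12 \mu'',}
#' with the same combination rule for both adaptation cases. Linear
#' proliferation (\eqn{\mu'' = 0}) only tilts the landscape (it cannot change
#' \eqn{\gamma}), while curvature \eqn{\mu''} reshapes the large-amplitude
#' confinement.
#'
#' @param q a \code{"quadratic_fitness"} object (either case).
#' @param p a \code{\link{proliferation_params}} object; defaults to the
#'   all-zero profile.
#' @param tau adaptation relaxation time, strictly positive.
#' @return A \code{\link{cubic_coefficients}} object.
#' @export
effective_coefficients <- function(q, p = proliferation_params(), tau = 1) {
  stopifnot(inherits(q, "quadratic_fitness"), inherits(p, "proliferation_params"),
            is.numeric(tau), length(tau) == 1L, is.finite(tau))
  if (tau <= 0) stop("tau must be > 0")
  cubic_coefficients(
    alpha = q$c1 / tau + p$mu_prime - p$mu_double_prime * p$X_bar,
    beta  = q$c0 / tau - p$mu_prime * p$X_bar + 0.5 * p$mu_double_prime * p$X_bar^2,
    gamma = q$c2 / tau + 0.5 * p$mu_double_prime)
}

#' Adaptation-only effective coefficients
#'
#' Convenience composition: the effective coefficients with a zero
#' proliferation profile, i.e. \eqn{\alpha_{\rm adapt} = c_1/\tau},
#' \eqn{\beta_{\rm adapt} = c_0/\tau}, \eqn{\gamma_{\rm adapt} = c_2/\tau},
#' where \eqn{(c_0, c_1, c_2)} is the chosen case polynomial and \eqn{\tau}
#' is taken from \code{s}.
#'
#' @param s a \code{\link{sensing_params}} object.
#' @param case \code{"I"} (weak coupling) or \code{"II"} (homeostatic limit).
#' @return A \code{\link{cubic_coefficients}} object.
#' @export
adaptation_only_coefficients <- function(s, case = c("II", "I")) {
  case <- match.arg(case)
  q <- if (case == "I") case1_polynomial(s) else case2_polynomial(s)
  effective_coefficients(q, proliferation_params(), s$tau)
}
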