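#' Catalog of canonical parameter sets
#'
#' Built-in bundles covering the canonical landscape examples and scenario
#' settings used throughout the package:
#' \itemize{
#'   \item \code{regimes/*}: the five canonical cubic-force triples
#'     (relaxation \code{(1, -2, 1)}, switch \code{(-1, 2, -1)}, critical
#'     \code{(1.5, 2, 0)}, explosion \code{(0.5, 2, 0.5)}, fixation
#'     \code{(-1, -2, -1)}).
#'   \item \code{potentials/weak-coupling}: weak-coupling potential scenario
#'     (\code{tau = 0.01, S_X = 0.5, rho = 0.0015, sigma_X = 0.01}; the
#'     sensing bias is the swept variable).
#'   \item \code{potentials/homeostatic}: homeostatic-limit potential scenario
#'     (\code{tau = 1, S_X = 0.25, zbar_Y = 0.5, sigma_X = 0.35}; the
#'     correlation is the swept variable).
#'   \item \code{phase/rho-*}: phase-diagram scenarios at
#'     \code{sigma_X = 1, tau = 1} for \code{rho} in 0.9, 0.8, 0.65, 0.3 and
#'     the negative counterparts -0.3, -0.65.
#' }
#'
#' @return Named list of parameter bundles; \code{regimes/*} entries are
#'   \code{\link{cubic_coefficients}}, scenario entries are plain lists.
#' @examples
#' names(fixture_catalog())
#' fixture("regimes/switch")
#' @export
fixture_catalog <- function() {
  phase_entry <- function(rho) list(rho = rho, sigma_X = 1, tau = 1)
  list(
    "regimes/relaxation" = cubic_coefficients(1, -2, 1),
    "regimes/switch"     = cubic_coefficients(-1, 2, -1),
    "regimes/critical"   = cubic_coefficients(1.5, 2, 0),
    "regimes/explosion"  = cubic_coefficients(0.5, 2, 0.5),
    "regimes/fixation"   = cubic_coefficients(-1, -2, -1),
    "potentials/weak-coupling" = list(tau = 0.01, S_X = 0.5, rho = 0.0015,
                                      sigma_X = 0.01, case = "I",
                                      varies = "zbar_Y"),
    "potentials/homeostatic"   = list(tau = 1, S_X = 0.25, zbar_Y = 0.5,
                                      sigma_X = 0.35, case = "II",
                                      varies = "rho"),
    "phase/rho-0.9"  = phase_entry(0.9),
    "phase/rho-0.8"  = phase_entry(0.8),
    "phase/rho-0.65" = phase_entry(0.65),
    "phase/rho-0.3"  = phase_entry(0.3),
    "phase/rho--0.3" = phase_entry(-0.3),
    "phase/rho--0.65" = phase_entry(-0.65)
  )
}

#' @rdname fixture_catalog
#' @param name catalog entry name.
#' @export
fixture <- function(name) {
  cat <- fixture_catalog()
  if (!name %in% names(cat))
    stop(sprintf("unknown fixture '%s'; available: %s", name,
                 paste(names(cat), collapse = ", ")))
  cat[[name]]
}
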