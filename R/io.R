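# serialization, configuration and the command-line surface

#' Serialize a landscape analysis to JSON
#'
#' Pretty-printed JSON with stable key ordering, embedding the full resolved
#' parameter set so every report is self-describing.
#'
#' @param m a \code{\link{phenoscape}} object.
#' @return A JSON string (class \code{json}).
#' @export
landscape_json <- function(m) {
  stopifnot(inherits(m, "phenoscape"))
  co <- m$coefficients
  rep <- list(
    coefficients = list(alpha = co$alpha, beta = co$beta, gamma = co$gamma,
                        c_const = co$c_const, delta = co$delta),
    regime = list(name = m$regime$name, matched_by = m$regime$matched_by),
    fixed_points = m$fixed_points,
    barrier_depth = if (is.na(m$barrier_depth)) NULL else m$barrier_depth,
    barrier_is_well_asymmetry = m$barrier_is_well_asymmetry,
    normalizable = m$normalizable,
    D = m$D)
  if (!is.null(m$sensing)) {
    rep$sensing <- unclass(m$sensing)
    rep$proliferation <- unclass(m$proliferation)
    rep$case <- m$case
    rep$mutual_information <- m$mutual_information
  }
  jsonlite::toJSON(rep, pretty = TRUE, auto_unbox = TRUE, digits = NA,
                   null = "null")
}

#' Write a phase grid to CSV with a JSON metadata sidecar
#'
#' The CSV holds one row per grid cell (\code{zbar_Y, S_X, label}); the
#' sidecar records the resolved parameters and the per-regime area fractions.
#'
#' @param g a \code{"phase_grid"}.
#' @param csv_path output CSV path.
#' @param meta_path output JSON path, or \code{NULL} to skip.
#' @return \code{csv_path}, invisibly.
#' @export
write_phase_grid <- function(g, csv_path, meta_path = NULL) {
  stopifnot(inherits(g, "phase_grid"))
  utils::write.csv(as.data.frame(g), csv_path, row.names = FALSE)
  if (!is.null(meta_path)) {
    meta <- list(rho = g$rho, sigma_X = g$sigma_X, tau = g$tau,
                 case = g$case, proliferation = unclass(g$proliferation),
                 zy_range = range(g$zy_axis), sx_range = range(g$sx_axis),
                 n_zy = length(g$zy_axis), n_sx = length(g$sx_axis),
                 tol = g$tol, fractions = as.list(g$fractions))
    writeLines(jsonlite::toJSON(meta, pretty = TRUE, auto_unbox = TRUE,
                                digits = NA), meta_path)
  }
  invisible(csv_path)
}

#' Write a trajectory ensemble to long-format CSV
#'
#' Columns \code{trajectory, time, x}; a leading \code{#}-comment line embeds
#' the resolved parameters and seed as JSON for provenance.
#'
#' @param e a \code{"trajectory_ensemble"}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_trajectories <- function(e, path) {
  stopifnot(inherits(e, "trajectory_ensemble"))
  co <- e$coefficients
  meta <- jsonlite::toJSON(list(alpha = co$alpha, beta = co$beta,
                                gamma = co$gamma, c_const = co$c_const,
                                D = e$D, dt = e$dt, t_end = e$t_end,
                                n_traj = e$n_traj, seed = e$seed,
                                x0 = e$x0, x_max = e$x_max, thin = e$thin),
                           auto_unbox = TRUE, digits = NA)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", meta), con)
  utils::write.csv(as.data.frame(e), con, row.names = FALSE)
  invisible(path)
}

#' Write a density (stationary or evolving) to CSV
#'
#' Stationary densities serialize as two columns (\code{x, density}); density
#' evolutions as long format (\code{time, x, density}).
#'
#' @param d a \code{"stationary_density"} or \code{"density_evolution"}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_density <- function(d, path) {
  stopifnot(inherits(d, "stationary_density") || inherits(d, "density_evolution"))
  utils::write.csv(as.data.frame(d), path, row.names = FALSE)
  invisible(path)
}

config_schema <- list(
  mode = NA,
  fixture = NA,
  coefficients = c("alpha", "beta", "gamma", "c_const"),
  sensing = c("rho", "zbar_Y", "S_X", "sigma_X", "tau"),
  proliferation = c("mu_prime", "mu_double_prime", "X_bar", "mu_bar"),
  case = NA,
  dynamics = c("D", "dt", "t_end", "n_traj", "seed", "x_max", "x0", "thin",
               "burn_in", "bins"),
  phase = c("rho", "zy_range", "sx_range", "n_zy", "n_sx", "tol"),
  output = c("json", "csv", "meta", "png"))

#' Load and validate a scenario configuration file
#'
#' YAML configuration with a \code{mode} (\code{classify}, \code{landscape},
#' \code{simulate} or \code{phase}), exactly one coefficient source (a
#' \code{coefficients} or \code{sensing} block, or a \code{fixture} name),
#' and optional \code{proliferation}, \code{dynamics}, \code{phase} and
#' \code{output} blocks. Unknown keys are rejected with field-level messages;
#' defaults are filled for everything omitted.
#'
#' @param path path to a YAML file.
#' @return A validated list of class \code{"scenario_config"}.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config must be a YAML mapping")
  bad <- setdiff(names(cfg), names(config_schema))
  if (length(bad))
    stop(sprintf("unknown config key(s): %s", paste(bad, collapse = ", ")))
  for (blk in names(cfg)) {
    allowed <- config_schema[[blk]]
    if (length(allowed) > 1L || !is.na(allowed[1])) {
      bad <- setdiff(names(cfg[[blk]]), allowed)
      if (length(bad))
        stop(sprintf("unknown key(s) in '%s': %s", blk, paste(bad, collapse = ", ")))
    }
  }
  if (is.null(cfg$mode)) stop("config field 'mode' is required")
  cfg$mode <- match.arg(cfg$mode, c("classify", "landscape", "simulate", "phase"))
  n_src <- (!is.null(cfg$coefficients)) + (!is.null(cfg$sensing)) +
    (!is.null(cfg$fixture))
  if (cfg$mode != "phase" && n_src != 1L)
    stop("supply exactly one of 'coefficients', 'sensing' or 'fixture'")
  if (cfg$mode == "phase" && is.null(cfg$phase$rho))
    stop("phase mode requires 'phase: rho'")
  defaults <- list(case = "II",
                   dynamics = list(D = 1, dt = 1e-3, t_end = 10, n_traj = 1,
                                   seed = 1, x_max = 1e3, x0 = 0, thin = 1,
                                   burn_in = 0, bins = 50),
                   phase = list(zy_range = c(0, 3), sx_range = c(0, 5),
                                n_zy = 201, n_sx = 201, tol = 1e-9),
                   proliferation = list(mu_prime = 0, mu_double_prime = 0,
                                        X_bar = 0, mu_bar = 0))
  for (blk in names(defaults)) {
    if (is.list(defaults[[blk]])) {
      for (k in names(defaults[[blk]]))
        if (is.null(cfg[[blk]][[k]])) cfg[[blk]][[k]] <- defaults[[blk]][[k]]
    } else if (is.null(cfg[[blk]])) cfg[[blk]] <- defaults[[blk]]
  }
  structure(cfg, class = "scenario_config")
}

cli_usage <- function() {
  paste(
    "usage: phenoscape <subcommand> [flags]",
    "",
    "subcommands:",
    "  classify  --alpha A --beta B --gamma G | --fixture NAME   [--tol T] [--out FILE]",
    "  landscape --alpha A --beta B --gamma G | --fixture NAME   [--D D] [--out FILE] [--density-csv FILE]",
    "  simulate  --alpha ... | --fixture NAME  [--seed S --dt DT --t-end T --n-traj N --D D --x0 X --x-max M --thin K] --out FILE",
    "  phase     --rho R [--case I|II] [--n N] [--out FILE] [--meta FILE]",
    "  fixtures",
    "  config    --file FILE",
    sep = "\n")
}

parse_flags <- function(args) {
  flags <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[[i]]
    if (!startsWith(a, "--"))
      stop(sprintf("unexpected argument '%s'", a))
    if (i == length(args)) stop(sprintf("flag '%s' needs a value", a))
    flags[[sub("^--", "", a)]] <- args[[i + 1L]]
    i <- i + 2L
  }
  flags
}

flag_num <- function(flags, name, default = NULL) {
  if (is.null(flags[[name]])) return(default)
  v <- suppressWarnings(as.numeric(flags[[name]]))
  if (is.na(v)) stop(sprintf("flag '--%s' must be numeric", name))
  v
}

cli_coefficients <- function(flags) {
  if (!is.null(flags$fixture)) {
    fx <- fixture(flags$fixture)
    if (!inherits(fx, "cubic_coefficients"))
      stop(sprintf("fixture '%s' is not a coefficient triple", flags$fixture))
    return(fx)
  }
  a <- flag_num(flags, "alpha"); b <- flag_num(flags, "beta")
  g <- flag_num(flags, "gamma")
  if (is.null(a) || is.null(b) || is.null(g))
    stop("supply --alpha, --beta and --gamma (or --fixture)")
  cubic_coefficients(a, b, g, flag_num(flags, "c-const", 0))
}

cli_emit <- function(txt, out) {
  if (is.null(out)) cat(txt, "\n", sep = "") else writeLines(txt, out)
}

#' Run the command-line interface
#'
#' Thin dispatcher behind the \code{inst/cli/phenoscape.R} script. Usage
#' errors return status 2; computational errors (e.g. requesting the
#' stationary density of a runaway landscape) return status 1 with the domain
#' message on standard error; success returns 0.
#'
#' @param argv character vector of command-line arguments.
#' @return Integer exit status, invisibly.
#' @export
run_cli <- function(argv = character()) {
  if (length(argv) == 0L || argv[[1]] %in% c("-h", "--help", "help")) {
    cat(cli_usage(), "\n")
    return(invisible(if (length(argv) == 0L) 2L else 0L))
  }
  sub <- argv[[1]]
  if (!sub %in% c("classify", "landscape", "simulate", "phase", "fixtures", "config")) {
    message(sprintf("unknown subcommand '%s'", sub))
    message(cli_usage())
    return(invisible(2L))
  }
  flags <- tryCatch(parse_flags(argv[-1]), error = function(e) e)
  if (inherits(flags, "error")) {
    message(conditionMessage(flags)); message(cli_usage())
    return(invisible(2L))
  }
  status <- tryCatch({
    switch(sub,
      fixtures = {
        cat(paste(names(fixture_catalog()), collapse = "\n"), "\n", sep = "")
      },
      classify = {
        m <- phenoscape(cli_coefficients(flags),
                        tol = flag_num(flags, "tol", 1e-9))
        cli_emit(as.character(landscape_json(m)), flags$out)
      },
      landscape = {
        m <- phenoscape(cli_coefficients(flags), D = flag_num(flags, "D", 1),
                        tol = flag_num(flags, "tol", 1e-9))
        cli_emit(as.character(landscape_json(m)), flags$out)
        if (!is.null(flags[["density-csv"]])) {
          if (!m$normalizable)
            stop("non-normalizable landscape: no stationary density (runaway regime)")
          write_density(stationary_density(m$coefficients, D = m$D),
                        flags[["density-csv"]])
        }
      },
      simulate = {
        e <- simulate_langevin(cli_coefficients(flags),
                               D = flag_num(flags, "D", 1),
                               x0 = flag_num(flags, "x0", 0),
                               dt = flag_num(flags, "dt", 1e-3),
                               t_end = flag_num(flags, "t-end", 10),
                               n_traj = flag_num(flags, "n-traj", 1),
                               seed = flag_num(flags, "seed", 1),
                               x_max = flag_num(flags, "x-max", 1e3),
                               thin = flag_num(flags, "thin", 1))
        if (is.null(flags$out)) stop("simulate requires --out FILE")
        write_trajectories(e, flags$out)
        message(sprintf("wrote %s (%d trajectories, seed %d)", flags$out,
                        e$n_traj, e$seed))
      },
      phase = {
        rho <- flag_num(flags, "rho")
        if (is.null(rho)) stop("phase requires --rho")
        n <- as.integer(flag_num(flags, "n", 201))
        case <- if (is.null(flags$case)) "I" else flags$case
        g <- sweep_phase_plane(rho, case = match.arg(case, c("I", "II")),
                               n_zy = n, n_sx = n)
        if (!is.null(flags$out)) {
          write_phase_grid(g, flags$out, flags$meta)
          message(sprintf("wrote %s", flags$out))
        } else print(g)
      },
      config = {
        if (is.null(flags$file)) stop("config requires --file FILE")
        cfg <- load_config(flags$file)
        run_scenario(cfg)
      })
    0L
  }, error = function(e) {
    message(conditionMessage(e))
    1L
  })
  invisible(status)
}

# execute a validated scenario configuration
run_scenario <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  coef_from_cfg <- function() {
    if (!is.null(cfg$fixture)) {
      fx <- fixture(cfg$fixture)
      if (!inherits(fx, "cubic_coefficients"))
        stop("fixture is not a coefficient triple")
      return(fx)
    }
    if (!is.null(cfg$coefficients)) {
      co <- cfg$coefficients
      return(cubic_coefficients(co$alpha, co$beta, co$gamma,
                                if (is.null(co$c_const)) 0 else co$c_const))
    }
    s <- do.call(sensing_params, cfg$sensing)
    p <- do.call(proliferation_params, cfg$proliferation)
    q <- if (cfg$case == "I") case1_polynomial(s) else case2_polynomial(s)
    effective_coefficients(q, p, s$tau)
  }
  dyn <- cfg$dynamics
  switch(cfg$mode,
    classify = ,
    landscape = {
      m <- phenoscape(coef_from_cfg(), D = dyn$D)
      out <- cfg$output$json
      cli_emit(as.character(landscape_json(m)), out)
    },
    simulate = {
      e <- simulate_langevin(coef_from_cfg(), D = dyn$D, x0 = dyn$x0,
                             dt = dyn$dt, t_end = dyn$t_end,
                             n_traj = dyn$n_traj, seed = dyn$seed,
                             x_max = dyn$x_max, thin = dyn$thin)
      if (is.null(cfg$output$csv)) stop("simulate mode requires 'output: csv'")
      write_trajectories(e, cfg$output$csv)
    },
    phase = {
      ph <- cfg$phase
      g <- sweep_phase_plane(ph$rho, case = cfg$case,
                             proliferation = do.call(proliferation_params,
                                                     cfg$proliferation),
                             zy_range = ph$zy_range, sx_range = ph$sx_range,
                             n_zy = ph$n_zy, n_sx = ph$n_sx, tol = ph$tol)
      if (!is.null(cfg$output$csv))
        write_phase_grid(g, cfg$output$csv, cfg$output$meta)
      else print(g)
    })
  invisible(NULL)
}
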