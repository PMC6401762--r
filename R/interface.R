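# Configuration ingestion, figure-parameter fixtures and result
# serialization for both engines. Configs are YAML with an explicit
# engine key ("ehd" or "iftp") and per-quantity units; everything is
# normalized to the internal (nm, kBT, e, s) system on load.

.fixture_db <- function() list(
  fig2 = list(
    engine = "ehd",
    note = paste("Pressure-voltage trapping in a solid-state pore:",
                 "dV = -100 mV, rho_b = 1.6 M, Lp = 180 nm (615 bp),",
                 "d = 5 nm, Lm = 200 nm, sigma_m = 0.13 e/nm^2,",
                 "sigma_p = 0.4 e/nm^2; a = 1 nm assumed (ds-DNA radius)."),
    params = list(a = 1, d = 5, Lm = 200, Lp = 180, sigma_p = 0.4,
                  sigma_m = 0.13, dV = -0.1, dP = atm_to_pa(2),
                  rho_b = 1.6),
    assumed = c(a = "not printed for this setup; ds-DNA radius 1 nm used")),
  fig6 = list(
    engine = "ehd",
    note = paste("ss-DNA in an alpha-Hemolysin pore: Lm = 5 nm, Lp = 10 nm,",
                 "d = 8.5 A, a = 5 A, tau = 0.29 e/A, neutral wall,",
                 "dV = 120 mV; image-charge barrier setup."),
    params = list(a = 0.5, d = 0.85, Lm = 5, Lp = 10,
                  sigma_p = 2.9 / pi, sigma_m = 0, dV = 0.12, dP = 0,
                  rho_b = 0.04),
    barrier = "image"),
  fig7 = list(
    engine = "ehd",
    note = paste("Voltage dependence of alpha-Hemolysin capture rates;",
                 "same pore as fig6, voltage scanned at fixed salt."),
    params = list(a = 0.5, d = 0.85, Lm = 5, Lp = 10,
                  sigma_p = 2.9 / pi, sigma_m = 0, dV = 0.15, dP = 0,
                  rho_b = 0.1),
    barrier = "image"),
  fig9a = list(
    engine = "iftp",
    note = "Pore-driven waiting times: N0 = 128, f = 5, eta_p = 3.5 (3D).",
    params = list(N0 = 128, f = 5, eta_p = 3.5, A_nu = 1.15, nu = 0.588,
                  gamma_prime = 0.69, mode = "pore-driven")),
  fig9b = list(
    engine = "iftp",
    note = "End-pulled waiting times: N0 = 100, f = 100, eta_p = 3 (3D).",
    params = list(N0 = 100, f = 100, eta_p = 3, A_nu = 1.15, nu = 0.588,
                  gamma_prime = 0.69, mode = "end-pulled")),
  fig10a = list(
    engine = "iftp",
    note = paste("Pore-driven scaling sweep: f = 5, A_nu = 1.15,",
                 "eta_p in {1, 5, 10}."),
    params = list(f = 5, eta_p = c(1, 5, 10), A_nu = 1.15, nu = 0.588,
                  gamma_prime = 0.69, mode = "pore-driven")),
  fig10b = list(
    engine = "iftp",
    note = paste("End-pulled scaling sweep: f = 100,",
                 "eta_p in {1.5, 10, 20}."),
    params = list(f = 100, eta_p = c(1.5, 10, 20), A_nu = 1.15, nu = 0.588,
                  gamma_prime = 0.69, mode = "end-pulled"))
)

#' Packaged parameter sets
#'
#' `list_fixtures()` enumerates the bundled parameter sets (named after the
#' figures of the study they reproduce) and `fixture(name)` returns one,
#' with electrohydrodynamic sets already assembled into a [pore_system()].
#'
#' @param name fixture name, e.g. `"fig6"`.
#' @return `list_fixtures()`: data frame with `name`, `engine`, `note`;
#'   `fixture()`: a list with `engine`, `note`, `params` and, for ehd
#'   fixtures, a ready `system`.
#' @export
fixture <- function(name) {
  db <- .fixture_db()
  if (!name %in% names(db))
    stop_domain("fixture: unknown fixture '%s' (see list_fixtures())", name)
  fx <- db[[name]]
  fx$name <- name
  if (fx$engine == "ehd") {
    p <- fx$params
    fx$system <- pore_system(a = p$a, d = p$d, Lm = p$Lm, Lp = p$Lp,
                             sigma_p = p$sigma_p, sigma_m = p$sigma_m,
                             dV = p$dV, dP = p$dP,
                             electrolyte = electrolyte(p$rho_b))
  }
  fx
}

#' @rdname fixture
#' @export
list_fixtures <- function() {
  db <- .fixture_db()
  data.frame(name = names(db),
             engine = vapply(db, `[[`, "", "engine"),
             note = vapply(db, `[[`, "", "note"),
             row.names = NULL)
}

# ---- config files ----------------------------------------------------------

.len_units <- c(nm = 1, angstrom = 0.1, A = 0.1)
.volt_units <- c(V = 1, mV = 1e-3)
.pres_units <- c(Pa = 1, atm = 101325)
.conc_units <- c(M = 1, mM = 1e-3)

.take_unit <- function(x, table, what, key) {
  if (is.list(x)) {
    if (is.null(x$value) || is.null(x$units))
      stop_domain("load_config: '%s' needs 'value' and 'units'", key)
    if (!x$units %in% names(table))
      stop_domain("load_config: unknown %s unit '%s' for '%s'",
                  what, x$units, key)
    x$value * table[[x$units]]
  } else as.numeric(x)
}

.ehd_keys <- c("a", "d", "Lm", "Lp", "sigma_p", "sigma_m", "dV", "dP",
               "rho_b", "barrier")
.iftp_keys <- c("N0", "f", "eta_p", "nu", "gamma_prime", "A_nu", "mode",
                "chain", "entropic", "noise", "dt")

#' Load and validate a run configuration
#'
#' Reads a YAML run configuration with keys `engine` (`"ehd"` or
#' `"iftp"`), a matching `params` block (each physical quantity either a
#' bare number in internal units or a `{value, units}` pair; supported
#' units nm/angstrom, V/mV, Pa/atm, M/mM), an optional `fixture` name whose
#' values serve as defaults, an optional `scan` block (`param`, `values`),
#' `seed`, and `output` (directory). Unknown keys are rejected naming the
#' offender.
#'
#' @param path path to the YAML file.
#' @return validated config of class `run_config` with normalized units.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known_top <- c("engine", "params", "fixture", "scan", "seed", "output",
                 "log_level")
  extra <- setdiff(names(raw), known_top)
  if (length(extra))
    stop_domain("load_config: unknown key(s): %s", paste(extra, collapse = ", "))
  if (is.null(raw$engine) || !raw$engine %in% c("ehd", "iftp"))
    stop_domain("load_config: 'engine' must be \"ehd\" or \"iftp\"")
  params <- list()
  if (!is.null(raw$fixture)) params <- fixture(raw$fixture)$params
  keys <- if (raw$engine == "ehd") .ehd_keys else .iftp_keys
  user <- raw$params
  extra <- setdiff(names(user), keys)
  if (length(extra))
    stop_domain("load_config: unknown %s parameter(s): %s", raw$engine,
                paste(extra, collapse = ", "))
  for (k in names(user)) {
    params[[k]] <- switch(k,
      a = , d = , Lm = , Lp = .take_unit(user[[k]], .len_units, "length", k),
      dV = .take_unit(user[[k]], .volt_units, "voltage", k),
      dP = .take_unit(user[[k]], .pres_units, "pressure", k),
      rho_b = .take_unit(user[[k]], .conc_units, "concentration", k),
      user[[k]])
  }
  cfg <- list(engine = raw$engine, params = params, scan = raw$scan,
              seed = raw$seed, output = raw$output,
              log_level = if (is.null(raw$log_level)) "info" else raw$log_level)
  class(cfg) <- "run_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  p <- cfg$params
  if (cfg$engine == "ehd") {
    for (k in c("a", "d", "Lm", "Lp", "sigma_p", "sigma_m"))
      if (is.null(p[[k]]))
        stop_domain("config: missing required parameter '%s'", k)
    if (p$a >= p$d)
      stop_domain("config: invariant violated for 'a': need a < d")
    pore_system(a = p$a, d = p$d, Lm = p$Lm, Lp = p$Lp, sigma_p = p$sigma_p,
                sigma_m = p$sigma_m, dV = p$dV %||% 0, dP = p$dP %||% 0,
                electrolyte = electrolyte(p$rho_b %||% 0.1))
  } else {
    for (k in c("N0", "f", "eta_p"))
      if (is.null(p[[k]]))
        stop_domain("config: missing required parameter '%s'", k)
    if (isTRUE(p$noise) && is.null(cfg$seed))
      stop_domain("config: engine iftp with noise on requires a seed")
  }
  invisible(cfg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a configuration
#'
#' Dispatches a validated [load_config()] object to the matching engine and
#' writes deterministic outputs: a `result.json` with the scalar results
#' and provenance (resolved config, package version, seed) and profile or
#' sweep CSV files. Identical config and seed give identical files.
#'
#' @param cfg a `run_config`.
#' @param dir output directory (created if needed); defaults to the
#'   config's `output` or a temporary directory.
#' @return (invisibly) a list with the computed results and the paths of
#'   the written files.
#' @export
run_config <- function(cfg, dir = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  dir <- dir %||% cfg$output %||% tempfile("nanotransloc-run-")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- cfg$params
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  files <- character()
  if (cfg$engine == "ehd") {
    make_sys <- function(pp) pore_system(
      a = pp$a, d = pp$d, Lm = pp$Lm, Lp = pp$Lp, sigma_p = pp$sigma_p,
      sigma_m = pp$sigma_m, dV = pp$dV %||% 0, dP = pp$dP %||% 0,
      electrolyte = electrolyte(pp$rho_b %||% 0.1))
    barrier <- p$barrier %||% "mf"
    if (!is.null(cfg$scan)) {
      rows <- lapply(cfg$scan$values, function(v) {
        pp <- p; pp[[cfg$scan$param]] <- v
        tr <- translocation(make_sys(pp), barrier = barrier)
        data.frame(param = cfg$scan$param, value = v, Rc_nm_per_s = tr$Rc,
                   tau_s = tr$tau$tau, vp_mean_nm_per_s = tr$vp_mean)
      })
      sweep <- do.call(rbind, rows)
      files["sweep"] <- file.path(dir, "sweep.csv")
      utils::write.csv(sweep, files["sweep"], row.names = FALSE)
      result <- list(scan = cfg$scan, n = nrow(sweep))
    } else {
      tr <- translocation(make_sys(p), barrier = barrier)
      files["profile"] <- file.path(dir, "profile.csv")
      utils::write.csv(tr$profile$profile, files["profile"], row.names = FALSE)
      result <- list(Rc_nm_per_s = tr$Rc, tau_s = tr$tau$tau,
                     tau1_s = tr$tau$tau1, tau2_s = tr$tau$tau2,
                     tau3_s = tr$tau$tau3, vp_mean_nm_per_s = tr$vp_mean,
                     N_pore = tr$N)
    }
  } else {
    par <- iftp_params(N0 = p$N0, f = p$f, eta_p = p$eta_p,
                       nu = p$nu %||% 0.588,
                       gamma_prime = p$gamma_prime %||% 0.69,
                       A_nu = p$A_nu %||% 1.15,
                       mode = p$mode %||% "pore-driven",
                       chain = p$chain %||% "flexible",
                       entropic = isTRUE(p$entropic),
                       noise = isTRUE(p$noise),
                       dt = p$dt %||% 1e-3, seed = cfg$seed)
    res <- iftp_solve(par)
    files["trajectory"] <- file.path(dir, "trajectory.csv")
    utils::write.csv(res$trajectory, files["trajectory"], row.names = FALSE)
    wt <- waiting_time(res)
    files["waiting_time"] <- file.path(dir, "waiting_time.csv")
    utils::write.csv(wt, files["waiting_time"], row.names = FALSE)
    result <- list(tau = res$tau, tau_tp = res$tau_tp, tau_pp = res$tau_pp)
  }
  files["result"] <- file.path(dir, "result.json")
  jsonlite::write_json(
    list(result = result,
         provenance = list(engine = cfg$engine, params = p, seed = cfg$seed,
                           package = "nanotransloc",
                           version = as.character(utils::packageVersion("nanotransloc")))),
    files["result"], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(result = result, files = files))
}
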