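# Flat typed key-value configuration. Keys follow the user-parameter table
# of the solver (H, L, Ls, Q, c0, D, bmax, kon, koff, Nx, Ny, Ns) plus
# numerical controls. All physical values are SI. Unknown keys are rejected.

config_error <- function(msg) {
  stop(errorCondition(msg, class = c("bs_config_error", "error")))
}

# key -> type ("num", "int", "str"); required keys have no default
CONFIG_SPEC <- list(
  L = list(type = "num"), H = list(type = "num"), Ls = list(type = "num"),
  Q = list(type = "num"), c0 = list(type = "num"), D = list(type = "num"),
  bmax = list(type = "num"), kon = list(type = "num"), koff = list(type = "num"),
  Nx = list(type = "int"), Ny = list(type = "int"), Ns = list(type = "int"),
  rho = list(type = "num"), mu = list(type = "num"),
  dt = list(type = "num"), t_end = list(type = "num"),
  sensor_offset = list(type = "num", default = 0),
  grading_ratio = list(type = "num", default = 1),
  depth_W = list(type = "num", default = 1),
  t_washout = list(type = "num", default = NA_real_),
  output_every = list(type = "int", default = 50L),
  inlet_profile = list(type = "str", default = "uniform"),
  c_init = list(type = "num", default = 0),
  concentration_source = list(type = "str", default = "local"),
  flow_tol = list(type = "num", default = 1e-9),
  flow_max_iter = list(type = "int", default = 50L),
  mass_tol = list(type = "num", default = 1e-8),
  couple_tol = list(type = "num", default = 1e-10),
  couple_max_iter = list(type = "int", default = 10L)
)

#' Build a simulation configuration
#'
#' Validates the full parameter set of a binding-cycle run (geometry, fluid,
#' transport, kinetics, mesh and numerical controls). Runs are fully
#' deterministic: there is no random state anywhere in the solver.
#'
#' @param ... named values; see the configuration key table in
#'   [read_config()]. Required: `L`, `H`, `Ls`, `Q`, `c0`, `D`, `bmax`,
#'   `kon`, `koff`, `Nx`, `Ny`, `Ns`, `rho`, `mu`, `dt`, `t_end`.
#' @return a `bs_config` object (named list).
#' @export
simulation_config <- function(...) {
  vals <- list(...)
  unknown <- setdiff(names(vals), names(CONFIG_SPEC))
  if (length(unknown))
    config_error(paste0("unknown configuration key(s): ",
                        paste(unknown, collapse = ", ")))
  cfg <- list()
  for (key in names(CONFIG_SPEC)) {
    sp <- CONFIG_SPEC[[key]]
    if (!is.null(vals[[key]])) {
      v <- vals[[key]]
      if (sp$type %in% c("num", "int")) {
        if (!is.numeric(v) || length(v) != 1L || (!is.na(v) && !is.finite(v)))
          config_error(sprintf("key '%s' must be a single finite number", key))
        if (sp$type == "int") {
          if (!is.na(v) && abs(v - round(v)) > 0)
            config_error(sprintf("key '%s' must be an integer", key))
          v <- as.integer(v)
        }
      } else if (!is.character(v) || length(v) != 1L) {
        config_error(sprintf("key '%s' must be a single string", key))
      }
      cfg[[key]] <- v
    } else if (!is.null(sp$default) || "default" %in% names(sp)) {
      cfg[[key]] <- sp$default
    } else {
      config_error(sprintf("missing required configuration key '%s'", key))
    }
  }
  ok <- tryCatch({
    geometry_from_config(cfg)
    fluid_properties(cfg$rho, cfg$mu)
    transport_params(cfg$D, cfg$c0)
    surface_kinetics_params(cfg$kon, cfg$koff, cfg$bmax,
                            cfg$concentration_source)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) config_error(conditionMessage(ok))
  if (!(cfg$dt > 0) || !(cfg$t_end > 0))
    config_error("dt and t_end must be positive")
  if (!is.na(cfg$t_washout) &&
      (cfg$t_washout <= 0 || cfg$t_washout > cfg$t_end))
    config_error("t_washout must lie in (0, t_end]")
  if (!(cfg$Q >= 0)) config_error("flow rate Q must be non-negative")
  if (!(cfg$depth_W > 0)) config_error("depth_W must be positive")
  if (!cfg$inlet_profile %in% c("uniform", "parabolic"))
    config_error("inlet_profile must be 'uniform' or 'parabolic'")
  structure(cfg, class = "bs_config")
}

geometry_from_config <- function(cfg) {
  geometry_config(L = cfg$L, H = cfg$H, Ls = cfg$Ls,
                  sensor_offset = cfg$sensor_offset,
                  Nx = cfg$Nx, Ny = cfg$Ny, Ns = cfg$Ns,
                  grading_ratio = cfg$grading_ratio)
}

#' Read a configuration file
#'
#' Flat `key = value` text format, one pair per line; `#` starts a comment;
#' blank lines are ignored. Keys:
#'
#' | key | meaning | unit |
#' |---|---|---|
#' | `L`, `H` | channel length, height | m |
#' | `Ls`, `sensor_offset` | sensor length, inlet-to-sensor distance | m |
#' | `Q` | flow rate | m^3 s^-1 |
#' | `c0` | inlet concentration | mol m^-3 |
#' | `D` | diffusion coefficient | m^2 s^-1 |
#' | `bmax` | binding-site density | mol m^-2 |
#' | `kon`, `koff` | adsorption / dissociation rate | m^3 mol^-1 s^-1, s^-1 |
#' | `Nx`, `Ny`, `Ns` | node counts (x, y, sensor) | - |
#' | `rho`, `mu` | fluid density, viscosity | kg m^-3, Pa s |
#' | `dt`, `t_end`, `t_washout` | step, duration, wash-out switch | s |
#' | `depth_W` | out-of-plane depth for Q -> u0 | m |
#' | `grading_ratio`, `inlet_profile`, `c_init`, `concentration_source`, `output_every` | numerical controls | - |
#' | `flow_tol`, `flow_max_iter`, `mass_tol`, `couple_tol`, `couple_max_iter` | tolerances and caps | - |
#'
#' Unknown keys, missing required keys, type errors and violated invariants
#' raise a `bs_config_error` naming the key.
#'
#' @param path file path.
#' @return a `bs_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) config_error(paste0("no such config file: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  vals <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*=\\s*(.*)$", ln))[[1]]
    if (length(m) != 3L)
      config_error(paste0("malformed config line: '", ln, "'"))
    key <- m[2]; raw <- trimws(m[3])
    sp <- CONFIG_SPEC[[key]]
    if (is.null(sp))
      config_error(paste0("unknown configuration key: ", key))
    if (sp$type == "str") {
      vals[[key]] <- raw
    } else {
      if (identical(raw, "none") && identical(key, "t_washout")) {
        vals[[key]] <- NA_real_
      } else {
        v <- suppressWarnings(as.numeric(raw))
        if (is.na(v))
          config_error(sprintf("key '%s': cannot parse '%s' as a number",
                               key, raw))
        vals[[key]] <- v
      }
    }
  }
  do.call(simulation_config, vals)
}

#' Write a configuration file
#'
#' Serializes with full (17 significant digit) precision so that a
#' write-then-read round trip reproduces every value bit-exactly.
#' @param cfg a `bs_config`; `path` output file.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "bs_config"))
  fmt <- function(v) {
    if (is.character(v)) v
    else if (is.na(v)) "none"
    else if (is.integer(v)) as.character(v)
    else sprintf("%.17g", v)
  }
  lines <- vapply(names(cfg), function(k) paste(k, "=", fmt(cfg[[k]])),
                  character(1))
  writeLines(lines, path)
  invisible(path)
}
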