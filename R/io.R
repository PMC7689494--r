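#' @importFrom jsonlite read_json write_json
#' @importFrom yaml read_yaml
NULL

scenario_defaults <- function() {
  list(
    model = "sdkr",
    experiment = "simulate",
    params = list(phi = 0.9, eps = 0.95, L = 1, cleavage = 1, eps_R = 1,
                  cost_basis = "per_copy"),
    suppression = list(mode = "none", dominance = "dominant", rate = 0,
                       migration = 0.02),
    release = list(ratio = NULL, frequency = NULL, genotype = NULL),
    horizon = 1000,
    threshold = list(tol = 0.002, level = 0.95, max_freq = 0.99),
    grid = list(axes = NULL, metric = "equilibrium_load_target"),
    output = list(path = NULL)
  )
}

# recursively overlay user values onto defaults, rejecting unknown keys
merge_config <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown configuration key", if (length(unknown) > 1) "s", ": ",
         paste0(path, unknown, collapse = ", "), call. = FALSE)
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))
        && k != "axes") {
      defaults[[k]] <- merge_config(defaults[[k]], user[[k]],
                                    paste0(path, k, "."))
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

# accept "from:to:step" strings or numeric vectors for grid axes
parse_axis <- function(x, name) {
  if (is.character(x) && length(x) == 1L) {
    parts <- suppressWarnings(as.numeric(strsplit(x, ":", fixed = TRUE)[[1]]))
    if (length(parts) != 3L || anyNA(parts))
      stop("axis `", name, "` must be numeric or \"from:to:step\"",
           call. = FALSE)
    x <- seq(parts[1], parts[2], by = parts[3])
  }
  x <- as.numeric(x)
  if (!length(x) || anyNA(x) || any(x < 0 | x > 1))
    stop("axis `", name, "` values must lie in [0, 1]", call. = FALSE)
  x
}

#' Validate a scenario configuration
#'
#' Fills defaults, checks every parameter against its admissible range and
#' rejects unknown keys.  The result is the canonical configuration object
#' used by [run_scenario()] and echoed into every output file.
#'
#' @param user named list of configuration values (possibly nested), as
#'   parsed from YAML/JSON or assembled from CLI flags.
#' @return validated configuration, class `scenario_config`.
#' @export
validate_scenario <- function(user = list()) {
  cfg <- merge_config(scenario_defaults(), user)
  if (!cfg$model %in% c("sdkr", "nhej", "ddkr"))
    stop("unknown model name: ", cfg$model, call. = FALSE)
  if (!cfg$experiment %in% c("simulate", "threshold", "scan", "two_deme"))
    stop("unknown experiment type: ", cfg$experiment, call. = FALSE)
  for (k in c("phi", "eps", "L", "cleavage", "eps_R")) {
    v <- cfg$params[[k]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop("parameter `params.", k, "` must be a single number in [0, 1]",
           call. = FALSE)
  }
  if (!cfg$params$cost_basis %in% c("per_copy", "per_construct"))
    stop("params.cost_basis must be per_copy or per_construct", call. = FALSE)
  if (!cfg$suppression$mode %in% c("none", "sex_conversion",
                                   "female_lethality"))
    stop("unknown suppression.mode: ", cfg$suppression$mode, call. = FALSE)
  if (!cfg$suppression$dominance %in% c("dominant", "recessive"))
    stop("unknown suppression.dominance: ", cfg$suppression$dominance,
         call. = FALSE)
  check_prob(cfg$suppression$rate, "suppression.rate")
  check_prob(cfg$suppression$migration, "suppression.migration")
  if (is.null(cfg$release$ratio) && is.null(cfg$release$frequency))
    cfg$release$ratio <- 2  # default: a 2:1 release
  if (!is.null(cfg$release$frequency)) {
    if (cfg$release$frequency < 0 || cfg$release$frequency >= 1)
      stop("release.frequency must be in [0, 1)", call. = FALSE)
  } else if (cfg$release$ratio < 0) {
    stop("release.ratio must be >= 0", call. = FALSE)
  }
  if (!is.numeric(cfg$horizon) || cfg$horizon < 1)
    stop("horizon must be >= 1", call. = FALSE)
  cfg$horizon <- as.integer(cfg$horizon)
  if (!is.null(cfg$grid$axes)) {
    if (is.null(names(cfg$grid$axes)) || any(names(cfg$grid$axes) == ""))
      stop("grid.axes must be a named list", call. = FALSE)
    ok_axes <- c("phi", "eps", "L", "cleavage", "eps_R", "rate")
    bad <- setdiff(names(cfg$grid$axes), ok_axes)
    if (length(bad))
      stop("unknown grid axis: ", paste(bad, collapse = ", "),
           " (allowed: ", paste(ok_axes, collapse = ", "), ")", call. = FALSE)
    cfg$grid$axes <- mapply(parse_axis, cfg$grid$axes, names(cfg$grid$axes),
                            SIMPLIFY = FALSE)
  }
  structure(cfg, class = "scenario_config")
}

#' Load a scenario configuration file
#'
#' Reads a YAML or JSON configuration (chosen by file extension, `.json`
#' for JSON, anything else parsed as YAML), validates it with
#' [validate_scenario()] and records provenance (file MD5 hash and package
#' version) as attributes.
#'
#' @param path configuration file path.
#' @return validated `scenario_config` with attributes `md5` and `version`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                        simplifyMatrix = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  cfg <- validate_scenario(raw)
  attr(cfg, "md5") <- unname(tools::md5sum(path))
  attr(cfg, "version") <- as.character(utils::packageVersion("sdkr"))
  cfg
}

#' Preset scenario configurations
#'
#' Named, ready-to-run scenario configurations for the standard analyses:
#' `fig3a`/`fig3b`/`fig3c` (killer-rescue, split-drive and SDKR sample
#' trajectories), `fig4a`-`fig4e` (SDKR introduction thresholds and their
#' dependence on homing rate, fitness and lethal penetrance), `fig5` (NHEJ
#' resistance-allele equilibria and persistence), `fig6` (two-deme
#' suppression load maps, dominant sex conversion by default), `fig7`
#' (DDKR thresholds) and `fig8` (DDKR threshold curves for comparison
#' against `fig4b`).  Use `preset_config()` with no argument to list names.
#'
#' @param name preset name, or `NULL` to return the available names.
#' @return a `scenario_config`, or a character vector of names.
#' @export
preset_config <- function(name = NULL) {
  presets <- list(
    fig3a = list(model = "sdkr", experiment = "simulate", horizon = 100,
                 params = list(phi = 0, eps = 0.95, L = 1),
                 release = list(frequency = 0.5)),
    fig3b = list(model = "sdkr", experiment = "simulate", horizon = 100,
                 params = list(phi = 0.9, eps = 0.95, L = 0),
                 release = list(frequency = 0.5)),
    fig3c = list(model = "sdkr", experiment = "simulate", horizon = 100,
                 params = list(phi = 0.9, eps = 0.95, L = 1),
                 release = list(frequency = 0.5)),
    fig4a = list(model = "sdkr", experiment = "threshold",
                 params = list(phi = 0.9, eps = 0.85, L = 1)),
    fig4b = list(model = "sdkr", experiment = "scan",
                 params = list(L = 1),
                 grid = list(axes = list(phi = c(0.5, 0.6, 0.7, 0.8, 0.9, 1),
                                         eps = "0.7:1:0.05"),
                             metric = "threshold")),
    fig4c = list(model = "sdkr", experiment = "scan",
                 params = list(L = 1),
                 grid = list(axes = list(phi = "0:1:0.05",
                                         eps = "0.7:1:0.05"),
                             metric = "threshold")),
    fig4d = list(model = "sdkr", experiment = "scan",
                 params = list(phi = 0.9),
                 grid = list(axes = list(L = "0:1:0.05",
                                         eps = "0.7:1:0.05"),
                             metric = "threshold")),
    fig4e = list(model = "sdkr", experiment = "scan",
                 grid = list(axes = list(phi = "0:1:0.1",
                                         eps = "0.7:1:0.05",
                                         L = c(0.5, 0.75, 1)),
                             metric = "threshold")),
    fig5 = list(model = "nhej", experiment = "scan", horizon = 2000,
                params = list(eps = 0.95, L = 1, cleavage = 0.95, eps_R = 1),
                release = list(frequency = 0.75),
                grid = list(axes = list(phi = "0.5:1:0.05",
                                        eps = "0.7:1:0.05"),
                            metric = c("equilibrium_R", "persistence"))),
    fig6 = list(model = "sdkr", experiment = "scan", horizon = 1000,
                params = list(eps = 0.95, L = 1),
                suppression = list(mode = "sex_conversion",
                                   dominance = "dominant", migration = 0.02),
                release = list(frequency = 0.75),
                grid = list(axes = list(phi = "0:1:0.05",
                                        rate = "0:1:0.05"),
                            metric = c("equilibrium_load_target",
                                       "equilibrium_load_nontarget"))),
    fig7 = list(model = "ddkr", experiment = "scan",
                params = list(L = 1),
                grid = list(axes = list(phi = c(0.5, 0.6, 0.7, 0.8, 0.9, 1),
                                        eps = "0.7:1:0.05"),
                            metric = "threshold")),
    fig8 = list(model = "ddkr", experiment = "scan",
                params = list(L = 1),
                grid = list(axes = list(phi = c(0.5, 0.75, 1),
                                        eps = "0.7:1:0.05"),
                            metric = "threshold"))
  )
  if (is.null(name)) return(names(presets))
  if (!name %in% names(presets))
    stop("unknown preset: ", name, " (available: ",
         paste(names(presets), collapse = ", "), ")", call. = FALSE)
  cfg <- validate_scenario(presets[[name]])
  attr(cfg, "preset") <- name
  attr(cfg, "version") <- as.character(utils::packageVersion("sdkr"))
  cfg
}

config_model <- function(cfg, override = list()) {
  p <- utils::modifyList(cfg$params, override[names(override) != "rate"])
  sup <- cfg$suppression
  if ("rate" %in% names(override)) sup$rate <- override$rate
  params <- drive_params(phi = p$phi, eps = p$eps, L = p$L,
                         cleavage = p$cleavage, eps_R = p$eps_R,
                         cost_basis = p$cost_basis)
  drive_model(cfg$model, params,
              suppression_params(sup$mode, sup$dominance, sup$rate,
                                 sup$migration))
}

config_release <- function(cfg) {
  release_spec(ratio = cfg$release$ratio,
               frequency = cfg$release$frequency,
               genotype = cfg$release$genotype)
}

#' Run a scenario configuration
#'
#' Dispatches on the configuration's `experiment` field: `simulate` returns
#' a [simulate_drive()] trajectory, `threshold` a [find_threshold()] result,
#' `scan` a [scan_grid()] result (grid axes override the base parameters
#' cell by cell; the axis named `rate` scans the suppression effect rate),
#' and `two_deme` a [simulate_two_deme()] trajectory.
#'
#' @param cfg a `scenario_config` from [validate_scenario()],
#'   [load_config()] or [preset_config()].
#' @return the experiment result, with the configuration attached as
#'   attribute `config`.
#' @export
run_scenario <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  result <- switch(cfg$experiment,
    simulate = simulate_drive(config_model(cfg), config_release(cfg),
                              cfg$horizon),
    threshold = find_threshold(config_model(cfg),
                               tol = cfg$threshold$tol,
                               horizon = cfg$horizon,
                               level = cfg$threshold$level,
                               max_freq = cfg$threshold$max_freq),
    scan = {
      axes <- cfg$grid$axes
      if (is.null(axes)) stop("scan experiment needs grid.axes", call. = FALSE)
      family <- function(...) config_model(cfg, list(...))
      scan_grid(family, axes, metric = cfg$grid$metric,
                release = config_release(cfg), horizon = cfg$horizon,
                migration = cfg$suppression$migration,
                threshold_tol = cfg$threshold$tol,
                threshold_level = cfg$threshold$level)
    },
    two_deme = simulate_two_deme(config_model(cfg), config_release(cfg),
                                 cfg$horizon,
                                 m = cfg$suppression$migration))
  attr(result, "config") <- cfg
  result
}

config_echo <- function(cfg) {
  if (is.null(cfg)) return(NULL)
  out <- unclass(cfg)
  attrs <- attributes(cfg)
  out$provenance <- list(md5 = attrs$md5, preset = attrs$preset,
                         version = attrs$version)
  out
}

#' Write an experiment result to disk
#'
#' Trajectories (single- or two-deme) are written as CSV with one row per
#' generation and a stable column order; threshold results and grid scans
#' are written as JSON carrying the result, the resolved configuration and
#' the package version.  Both formats round-trip losslessly (to numerical
#' precision) via [read_trajectory()] and [read_summary()].
#'
#' @param result a `drive_trajectory`, `two_deme_trajectory`,
#'   `threshold_result` or `grid_scan`.
#' @param path output file path.
#' @param cfg optional `scenario_config` to embed (defaults to the
#'   result's `config` attribute, if present).
#' @return `path`, invisibly.
#' @export
write_outputs <- function(result, path, cfg = attr(result, "config")) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  if (inherits(result, "drive_trajectory") ||
      inherits(result, "two_deme_trajectory")) {
    utils::write.csv(as.data.frame(result), path, row.names = FALSE)
  } else if (inherits(result, "threshold_result")) {
    payload <- c(unclass(result),
                 list(config = config_echo(cfg),
                      version = as.character(utils::packageVersion("sdkr"))))
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  } else if (inherits(result, "grid_scan")) {
    payload <- list(axes = result$axes, metric = result$metric,
                    cells = result$grid,
                    config = config_echo(cfg),
                    version = as.character(utils::packageVersion("sdkr")))
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  } else {
    stop("don't know how to serialize an object of class ",
         paste(class(result), collapse = "/"), call. = FALSE)
  }
  invisible(path)
}

#' Read back a trajectory CSV
#'
#' @param path CSV written by [write_outputs()].
#' @return data frame with the trajectory columns.
#' @export
read_trajectory <- function(path) {
  utils::read.csv(path, check.names = FALSE)
}

#' Read back a JSON summary (threshold or grid scan)
#'
#' @param path JSON written by [write_outputs()].
#' @return list mirroring the written payload; grid-scan cells are returned
#'   as a data frame.
#' @export
read_summary <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
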