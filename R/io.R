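#' Default run configuration
#'
#' The nested configuration consumed by the command-line interface and by
#' [config_objects()].  Defaults reproduce the symmetric reference
#' configuration end to end.
#'
#' @return A nested list with blocks `model`, `environment`, `simulation`,
#'   `analysis` and `output`.
#' @export
default_run_config <- function() {
  s <- sim_settings()
  list(
    model = unclass(symmetric_parameters()),
    environment = list(n_steps = 101L, factor = 1),
    simulation = list(
      step_duration = s$step_duration,
      immigration_interval = s$immigration_interval,
      immigration_amount = s$immigration_amount,
      initial_state = as.list(s$initial_state),
      rtol = s$rtol,
      atol = as.list(stats::setNames(s$atol, .state_fields)),
      steady_state_residual_tol = s$steady_state_residual_tol,
      early_exit = s$early_exit),
    analysis = list(metric = "log10", no_tipping_floor = 0.5),
    output = list(dir = "."))
}

#' Validate and complete a run configuration
#'
#' Unknown keys raise an error naming the key; keys absent from the user
#' configuration are filled from [default_run_config()]; required keys set
#' to null raise an error naming the key.
#'
#' @param config A nested list (as from [load_run_config()]), possibly
#'   partial.
#' @return The completed configuration.
#' @export
validate_run_config <- function(config) {
  defaults <- default_run_config()
  check <- function(user, def, path) {
    if (!is.list(user)) stop("configuration block '", path,
                             "' must be a mapping", call. = FALSE)
    bad <- setdiff(names(user), names(def))
    if (length(bad))
      stop("unknown configuration key: ", path, ".", bad[1L], call. = FALSE)
    for (nm in names(def)) {
      here <- paste0(path, ".", nm)
      if (nm %in% names(user)) {
        if (is.null(user[[nm]]))
          stop("configuration key is null: ", here, call. = FALSE)
        if (is.list(def[[nm]])) {
          def[[nm]] <- check(user[[nm]], def[[nm]], here)
        } else {
          def[[nm]] <- user[[nm]]
        }
      }
    }
    def
  }
  bad <- setdiff(names(config), names(defaults))
  if (length(bad))
    stop("unknown configuration block: ", bad[1L], call. = FALSE)
  out <- defaults
  for (blk in names(config)) {
    if (is.null(config[[blk]]))
      stop("configuration key is null: ", blk, call. = FALSE)
    out[[blk]] <- check(config[[blk]], defaults[[blk]], blk)
  }
  out
}

#' Read / write a run configuration (YAML)
#'
#' @param path File path.
#' @param config A configuration list.
#' @return `load_run_config()` returns the validated, completed
#'   configuration; `save_run_config()` returns `path` invisibly.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path))
    stop("configuration file not found: ", path, call. = FALSE)
  validate_run_config(yaml::read_yaml(path))
}

#' @rdname load_run_config
#' @export
save_run_config <- function(config, path) {
  yaml::write_yaml(validate_run_config(config), path,
                   precision = 15L)
  invisible(path)
}

#' Turn a configuration into model objects
#'
#' @param config A completed configuration (see [validate_run_config()]).
#' @return A list with elements `params` (`symtip_params`), `settings`
#'   (`symtip_settings`), `n_steps`, `factor`, `metric`,
#'   `no_tipping_floor` and `out_dir`.
#' @export
config_objects <- function(config) {
  config <- validate_run_config(config)
  sim <- config$simulation
  st <- unlist(sim$initial_state)
  list(
    params = do.call(model_parameters, config$model),
    settings = sim_settings(
      step_duration = sim$step_duration,
      immigration_interval = sim$immigration_interval,
      immigration_amount = sim$immigration_amount,
      initial_state = system_state(st[["N_CB"]], st[["N_SB"]], st[["O"]],
                                   st[["S"]], st[["P"]]),
      rtol = sim$rtol,
      atol = unlist(sim$atol)[.state_fields],
      steady_state_residual_tol = sim$steady_state_residual_tol,
      early_exit = isTRUE(sim$early_exit)),
    n_steps = config$environment$n_steps,
    factor = config$environment$factor,
    metric = config$analysis$metric,
    no_tipping_floor = config$analysis$no_tipping_floor,
    out_dir = config$output$dir)
}

#' Export the stable states of a hysteresis experiment as CSV
#'
#' One row per direction and gradient step, columns `direction`,
#' `step`, `a_O`, `a_S`, `N_CB`, `N_SB`, `O`, `S`, `P`, `residual`.
#'
#' @param hyst A `symtip_hysteresis` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_states_csv <- function(hyst, path) {
  stopifnot(inherits(hyst, "symtip_hysteresis"))
  up <- cbind(direction = "toward_oxic", as.data.frame(hyst$toward_oxic))
  dn <- cbind(direction = "toward_anoxic",
              as.data.frame(hyst$toward_anoxic))
  utils::write.csv(rbind(up, dn), path, row.names = FALSE)
  invisible(path)
}

#' Read stable states written by [write_states_csv()]
#'
#' @param path CSV file path.
#' @return A list with `toward_oxic` and `toward_anoxic` data frames.
#' @export
read_states_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("direction", "step", "a_O", "a_S", .state_fields)
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("states file is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  split(df[names(df) != "direction"], df$direction)
}

.report_as_list <- function(report) {
  tp <- function(t) list(
    detected = t$detected, transition = t$transition,
    location_a_O = t$location_a_O,
    location_log10_a_O = t$location_log10_a_O,
    magnitude_O = t$magnitude_O, magnitude_S = t$magnitude_S,
    total_magnitude = t$total_magnitude, tie = t$tie)
  list(metric = report$metric, factor = report$factor,
       tp_anoxic_to_oxic = tp(report$tp_anoxic_to_oxic),
       tp_oxic_to_anoxic = tp(report$tp_oxic_to_anoxic),
       total_anoxic_to_oxic = report$total_anoxic_to_oxic,
       total_oxic_to_anoxic = report$total_oxic_to_anoxic,
       magnitude_asymmetry = report$magnitude_asymmetry,
       bistability_width = report$bistability_width,
       location_shift_up = report$location_shift_up,
       location_shift_down = report$location_shift_down)
}

#' Write a symmetry report as JSON
#'
#' @param report A `symmetry_report`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "symmetry_report"))
  jsonlite::write_json(.report_as_list(report), path, auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  invisible(path)
}

#' Write a reproducibility manifest
#'
#' Records the complete resolved configuration, the command that produced
#' the outputs, and the package version.
#'
#' @param config The resolved configuration list.
#' @param command Character description of the command run.
#' @param path Output file path.
#' @param extra Optional named list of additional entries.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(config, command, path, extra = list()) {
  manifest <- c(list(
    package = "symtip",
    version = as.character(utils::packageVersion("symtip")),
    command = command,
    config = config), extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}
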