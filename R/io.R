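#' Load a run configuration from a YAML file
#'
#' The configuration schema has four optional top-level keys:
#' `sequence` (a builtin condition label such as `"seq_1_1"` or
#' `"1,1"`), `model` (overrides for [model_spec()] arguments),
#' `settings` (overrides for [simulation_settings()] arguments) and
#' `seed` (integer). An empty file yields the reference defaults
#' (`lambda = 0.2`, `dt = 0.01`, `threshold = 1.1`, all `A = 1`,
#' `B = 1`). Unknown keys at any level are rejected, with the offending
#' field path in the message.
#'
#' @param path readable YAML file.
#' @return A [sequence_config()] with a `seed` field.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  config_from_list(raw)
}

# build a sequence_config from a nested list (parsed YAML)
config_from_list <- function(raw) {
  known_top <- c("sequence", "model", "settings", "seed", "name",
                 "schedule_mode", "onset", "stim_duration")
  .reject_unknown(raw, known_top, "")
  model_args <- raw$model %||% list()
  .reject_unknown(model_args,
                  names(formals(model_spec)), "model.")
  settings_args <- raw$settings %||% list()
  .reject_unknown(settings_args,
                  names(formals(simulation_settings)), "settings.")
  for (nm in c("p", "omega", "amplitude"))
    if (!is.null(model_args[[nm]])) model_args[[nm]] <- unlist(model_args[[nm]])

  if (!is.null(raw$sequence)) {
    nm <- gsub("[(), ]+", "_", tolower(raw$sequence))
    nm <- sub("^_|_$", "", nm)
    if (!startsWith(nm, "seq_")) nm <- paste0("seq_", nm)
    base <- builtin_sequences()[[nm]]
    if (is.null(base)) stop("unknown builtin sequence: ", raw$sequence)
    if (length(model_args)) {
      g <- base$model$gates; b <- base$model$coupling
      amp <- vapply(base$model$drives, `[[`, numeric(1), "amplitude")
      defaults <- list(a_at = g$a_at, a_pt = g$a_pt, b_at = b$b_at,
                       b_pt = b$b_pt, amplitude = amp)
      base$model <- do.call(model_spec,
                            utils::modifyList(defaults, model_args))
    }
    cfg <- base
  } else {
    cfg <- sequence_config(
      name = raw$name %||% "custom",
      model = do.call(model_spec, model_args),
      schedule_mode = raw$schedule_mode %||% "single")
  }
  if (length(settings_args))
    cfg$settings <- do.call(simulation_settings, settings_args)
  if (!is.null(raw$onset)) cfg$onset <- raw$onset
  if (!is.null(raw$stim_duration)) cfg$stim_duration <- raw$stim_duration
  cfg$seed <- as.integer(raw$seed %||% 1L)
  cfg
}

.reject_unknown <- function(x, known, prefix) {
  if (!length(x)) return(invisible())
  bad <- setdiff(names(x), known)
  if (length(bad))
    stop("unknown configuration field(s): ",
         paste0(prefix, bad, collapse = ", "))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save a run configuration to YAML
#'
#' Writes the fields needed to rebuild the configuration with
#' [load_config()]; `load_config(save_config(cfg, f))` reproduces `cfg`.
#'
#' @param config a [sequence_config()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "sequence_config"))
  m <- config$model
  amp <- lapply(m$drives, `[[`, "amplitude")
  p <- lapply(m$units, `[[`, "p")
  omega <- lapply(m$drives, `[[`, "frequency")
  out <- list(
    name = config$name,
    schedule_mode = config$schedule_mode,
    onset = config$onset,
    stim_duration = if (is.finite(config$stim_duration))
      config$stim_duration else NULL,
    seed = config$seed %||% 1L,
    model = list(lambda = m$units$target$lambda,
                 p = p, omega = omega, amplitude = amp,
                 a_at = m$gates$a_at, a_pt = m$gates$a_pt,
                 b_at = m$coupling$b_at, b_pt = m$coupling$b_pt,
                 gate_shape = m$gate_shape),
    settings = unclass(config$settings))
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Write a simulation result or scenario report to disk
#'
#' CSV output has a fixed column order
#' (`time,stimulus,target,nontarget,speed,direction` for trajectories;
#' `unit,rms,n_harmonics,variability,rt` for reports) and is accompanied
#' by a JSON sidecar (`<path>.json`) embedding the generating
#' configuration and seed, so every artifact can be regenerated.
#' JSON output embeds data and configuration in a single file.
#'
#' @param x a `"simulation_result"` or `"scenario_report"`.
#' @param path output file.
#' @param format `"csv"` (default) or `"json"`.
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path, format = c("csv", "json")) {
  format <- match.arg(format)
  cfg <- attr(x, "config")
  meta <- list(package_version = as.character(utils::packageVersion("dualosc")),
               seed = cfg$seed %||% NA_integer_,
               config = if (!is.null(cfg)) .config_as_list(cfg))
  df <- as.data.frame(x)
  if (format == "csv") {
    utils::write.csv(df, path, row.names = FALSE)
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
  } else {
    jsonlite::write_json(c(meta, list(data = df)), path, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
  }
  invisible(path)
}

.config_as_list <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  save_config(config, tmp)
  yaml::read_yaml(tmp)
}

#' Read back a trajectory CSV written by [write_results()]
#' @param path CSV file.
#' @return data.frame with the trajectory columns.
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.csv(path)
}
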