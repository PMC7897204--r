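#' Validate a pipeline run configuration
#'
#' Checks a configuration list (or JSON file) against the schema of the
#' requested stage and raises a single aggregated error listing every
#' violation. Unknown fields are reported as well, so typos fail loudly.
#'
#' @param config Named list, or path to a JSON file holding one.
#' @param stage One of `"detect"`, `"titrate"`, `"simulate"`, `"library"`.
#' @return The validated config (invisibly usable), with defaults filled in
#'   and a `config_hash` field added for provenance.
#' @export
validate_config <- function(config,
                            stage = c("detect", "titrate", "simulate",
                                      "library")) {
  stage <- match.arg(stage)
  if (is.character(config) && length(config) == 1L) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) {
    stop("config must be a named list or a path to a JSON file",
         call. = FALSE)
  }
  schema <- switch(
    stage,
    detect = list(required = c("peaks", "pH"),
                  optional = c("dialect", "tol_h", "tol_c", "swap_axes",
                               "dss_offset_H", "out", "min_uniqueness",
                               "field_MHz")),
    titrate = list(required = c("titration"),
                   optional = c("n_sites", "n_boot", "seed", "out")),
    simulate = list(required = c("sequence", "seed"),
                    optional = c("modifications", "pH", "noise_H", "noise_C",
                                 "volume_cv", "out", "truth_out", "dialect")),
    library = list(required = c("out"), optional = c("full"))
  )
  problems <- character()
  missing_f <- setdiff(schema$required, names(config))
  if (length(missing_f)) {
    problems <- c(problems, paste0("missing required field(s): ",
                                   paste(missing_f, collapse = ", ")))
  }
  unknown <- setdiff(names(config),
                     c(schema$required, schema$optional, "config_hash"))
  if (length(unknown)) {
    problems <- c(problems, paste0("unknown field(s): ",
                                   paste(unknown, collapse = ", ")))
  }
  if (!is.null(config$pH) && (config$pH < 0 || config$pH > 14)) {
    problems <- c(problems, "pH must lie in [0, 14]")
  }
  if (length(problems)) {
    stop("invalid ", stage, " config: ", paste(problems, collapse = "; "),
         call. = FALSE)
  }
  defaults <- switch(
    stage,
    detect = list(dialect = "sparky", tol_h = 0.05, tol_c = 0.5,
                  swap_axes = FALSE, dss_offset_H = 0, min_uniqueness = 1,
                  field_MHz = 600),
    titrate = list(n_sites = "auto", n_boot = 500L, seed = 1L),
    simulate = list(modifications = list(), pH = 7.4, noise_H = 0.01,
                    noise_C = 0.1, volume_cv = 0.05, dialect = "csv"),
    library = list(full = TRUE)
  )
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  config$config_hash <- rlang::hash(config[sort(setdiff(names(config),
                                                        "config_hash"))])
  config
}

#' Run the detection stage from a configuration
#'
#' Reads the peak list, applies DSS referencing (offset from the config,
#' default 0), runs [detect_modifications()], and embeds the full
#' configuration, its hash and the library version in the report. Writes the
#' report to `config$out` when set.
#'
#' @param config See [validate_config()] (`stage = "detect"`).
#' @return A `detection_report` with a `parameters$config` entry.
#' @export
run_detect <- function(config) {
  config <- validate_config(config, "detect")
  pl <- read_peaklist(config$peaks, dialect = config$dialect, pH = config$pH,
                      field_MHz = config$field_MHz,
                      swap_axes = isTRUE(config$swap_axes))
  pl <- rereference(pl, referencing_spec(config$dss_offset_H))
  report <- detect_modifications(pl, tolH = config$tol_h, tolC = config$tol_c,
                                 min_uniqueness = config$min_uniqueness)
  report$parameters$config <- config
  if (!is.null(config$out)) write_report(report, config$out, "json")
  report
}

#' Run titration fitting from a configuration
#'
#' Reads a titration CSV (columns `pH`, `shift_ppm`, `variant`, `atom`,
#' optional `series`), fits each series with [fit_titration()], and writes
#' one JSON report per series when `config$out` is a directory (or a single
#' report when only one series is present and `out` ends in `.json`).
#'
#' @param config See [validate_config()] (`stage = "titrate"`).
#' @return Named list of `titration_fit` objects, one per series.
#' @export
run_titrate <- function(config) {
  config <- validate_config(config, "titrate")
  df <- utils::read.csv(config$titration, stringsAsFactors = FALSE)
  need <- c("pH", "shift_ppm", "variant", "atom")
  if (!all(need %in% names(df))) {
    stop("titration CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  key <- if (!is.null(df$series)) df$series else paste(df$variant, df$atom)
  fits <- lapply(split(df, key), function(d) {
    ser <- titration_series(d$pH, d$shift_ppm, variant = d$variant[[1L]],
                            atom = d$atom[[1L]])
    fit_titration(ser, n_sites = config$n_sites, seed = config$seed,
                  n_boot = config$n_boot)
  })
  if (!is.null(config$out)) {
    if (grepl("\\.json$", config$out) && length(fits) == 1L) {
      write_report(fits[[1L]], config$out, "json")
    } else {
      dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
      for (nm in names(fits)) {
        write_report(fits[[nm]],
                     file.path(config$out,
                               paste0(gsub("[^A-Za-z0-9_.-]", "_", nm),
                                      ".json")), "json")
      }
    }
  }
  fits
}

#' Run the simulator from a configuration
#'
#' Generates a synthetic peak list via [simulate_peaklist()], writes it in
#' the requested dialect, and writes the ground truth alongside as JSON.
#'
#' @param config See [validate_config()] (`stage = "simulate"`).
#' @return The simulation result (list with `peaklist`, `truth`), invisibly.
#' @export
run_simulate <- function(config) {
  config <- validate_config(config, "simulate")
  spec <- simulation_spec(config$sequence,
                          modifications = as.list(config$modifications),
                          pH = config$pH, noise_H = config$noise_H,
                          noise_C = config$noise_C,
                          volume_cv = config$volume_cv, seed = config$seed)
  sim <- simulate_peaklist(spec)
  if (!is.null(config$out)) {
    write_peaklist(sim$peaklist, config$out, dialect = config$dialect)
    truth_out <- if (!is.null(config$truth_out)) {
      config$truth_out
    } else {
      paste0(config$out, ".truth.json")
    }
    jsonlite::write_json(list(config = config, truth = sim$truth), truth_out,
                         digits = NA, auto_unbox = TRUE)
  }
  invisible(sim)
}

#' Export the packaged library from a configuration
#'
#' @param config See [validate_config()] (`stage = "library"`).
#' @return The export path, invisibly.
#' @export
run_library <- function(config) {
  config <- validate_config(config, "library")
  export_library(rc_library(), config$out, full = isTRUE(config$full))
}
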