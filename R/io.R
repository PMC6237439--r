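# File formats: tidy observation tables (CSV), experiment manifests
# (JSON) and parameter documents (YAML or JSON, flat keys).

#' Write a study to a tidy observation table plus manifest
#'
#' Observations go to an RFC-4180 CSV with columns `experiment_id`,
#' `time_h`, `variable`, `replicate`, `value`, `excluded`; the experiment
#' structure (strains, initial design, inoculum) goes to a JSON manifest
#' next to it.
#'
#' @param experiments Named list of [fermentation_experiment()]s.
#' @param obs_path Path of the CSV file.
#' @param manifest_path Path of the JSON manifest (default: `obs_path`
#'   with extension `.manifest.json`).
#' @return Invisibly, the two paths.
#' @export
write_observations <- function(experiments, obs_path,
                               manifest_path = NULL) {
  if (is.null(manifest_path)) {
    manifest_path <- sub("\\.csv$", "", obs_path)
    manifest_path <- paste0(manifest_path, ".manifest.json")
  }
  tabs <- lapply(experiments, function(e) {
    cbind(experiment_id = e$id,
          e$observations[, c("time_h", "variable", "replicate", "value",
                             "excluded")])
  })
  tab <- do.call(rbind, tabs)
  rownames(tab) <- NULL
  # full double precision so values survive the text round trip bit-exactly
  tab$value <- sprintf("%.17g", tab$value)
  utils::write.csv(tab, obs_path, row.names = FALSE, quote = TRUE)
  manifest <- lapply(experiments, function(e) {
    list(strains = as.list(e$strains), initial = as.list(e$initial),
         inoculum = as.list(e$inoculum))
  })
  names(manifest) <- vapply(experiments, `[[`, "", "id")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(c(obs_path, manifest_path))
}

#' Read a study from a tidy observation table plus manifest
#'
#' Validates the schema strictly: the header must be present, variable
#' names must come from [observation_variables()] (violations are reported
#' with the list of valid names), and negative values or times are
#' rejected with the offending row number.
#'
#' @param obs_path CSV written by [write_observations()] (or compatible).
#' @param manifest_path JSON manifest (default derived from `obs_path`).
#' @return Named list of [fermentation_experiment()]s.
#' @export
read_observations <- function(obs_path, manifest_path = NULL) {
  if (is.null(manifest_path)) {
    manifest_path <- paste0(sub("\\.csv$", "", obs_path), ".manifest.json")
  }
  if (!file.exists(obs_path)) stop("no such file: ", obs_path, call. = FALSE)
  tab <- utils::read.csv(obs_path, stringsAsFactors = FALSE)
  needed <- c("experiment_id", "time_h", "variable", "replicate", "value")
  if (!all(needed %in% names(tab))) {
    stop("observation table must have columns ",
         paste(needed, collapse = ", "), call. = FALSE)
  }
  bad_var <- which(!tab$variable %in% observation_variables())
  if (length(bad_var) > 0) {
    stop("row ", bad_var[1], ": unknown variable '", tab$variable[bad_var[1]],
         "'; valid names are: ",
         paste(observation_variables(), collapse = ", "), call. = FALSE)
  }
  bad_val <- which(!is.finite(tab$value) | tab$value < 0)
  if (length(bad_val) > 0) {
    stop("row ", bad_val[1], ", column value: negative or non-numeric",
         call. = FALSE)
  }
  bad_t <- which(!is.finite(tab$time_h) | tab$time_h < 0)
  if (length(bad_t) > 0) {
    stop("row ", bad_t[1], ", column time_h: negative or non-numeric",
         call. = FALSE)
  }
  if (is.null(tab$excluded)) tab$excluded <- FALSE
  manifest <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  ids <- unique(tab$experiment_id)
  missing <- setdiff(ids, names(manifest))
  if (length(missing) > 0) {
    stop("experiment(s) absent from manifest: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- lapply(ids, function(id) {
    m <- manifest[[id]]
    fermentation_experiment(
      id = id, strains = unlist(m$strains),
      initial = unlist(m$initial), inoculum = unlist(m$inoculum),
      observations = tab[tab$experiment_id == id,
                         c("time_h", "variable", "replicate", "value",
                           "excluded")])
  })
  names(out) <- ids
  out
}

#' Read / write a parameter document
#'
#' Flat key/value documents (`mu.RI: 0.55`, `K.RI.fructose: 8`, ...) in
#' YAML or JSON, chosen by file extension. The schema is strict: unknown
#' or missing keys are rejected by [model_parameters()].
#'
#' @param path File path ending in `.yaml`, `.yml` or `.json`.
#' @return `read_params`: a [model_parameters()] object.
#' @export
read_params <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  vals <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("parameter file must be .yaml, .yml or .json", call. = FALSE)
  }
  model_parameters(vals)
}

#' @rdname read_params
#' @param params A [model_parameters()] object.
#' @export
write_params <- function(params, path) {
  if (!inherits(params, "model_parameters")) params <- model_parameters(params)
  vals <- as.list(unclass(params))
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(vals, path)
  } else if (grepl("\\.json$", path)) {
    jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    stop("parameter file must be .yaml, .yml or .json", call. = FALSE)
  }
  invisible(path)
}

#' Write a run manifest
#'
#' Records command, arguments, seed, package version and timestamp so that
#' any numeric output can be reproduced from its manifest.
#'
#' @param path Output JSON path.
#' @param command Subcommand or function name.
#' @param args Named list of arguments worth recording.
#' @param seed Integer seed (or NA).
#' @return Invisibly, the path.
#' @export
write_run_manifest <- function(path, command, args = list(), seed = NA) {
  jsonlite::write_json(
    list(command = command, args = args, seed = seed,
         package = "syngut",
         version = as.character(utils::packageVersion("syngut")),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
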