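# The fermentation-experiment container shared by the fitting, balance and
# synthetic-data code.

#' Valid observation variable names
#'
#' Strain abundances `X_RI`, `X_FP`, `X_BH` and measurable metabolite
#' concentrations `S_<metabolite>`. The unknown compound is a modeled but
#' unobservable state and is deliberately absent.
#'
#' @return Character vector of valid variable names.
#' @export
observation_variables <- function() {
  c(paste0("X_", strain_ids()),
    paste0("S_", setdiff(observed_metabolites(), "unknown")))
}

#' Construct a fermentation experiment
#'
#' A batch-fermentation record: which strains were inoculated, the initial
#' substrate design, and the observed time series with technical-replicate
#' structure. Rows may carry an `excluded` flag (set by
#' [exclude_decline()]) so that declining-phase samples can be kept in the
#' record but dropped from objective functions.
#'
#' @param id Experiment identifier, e.g. `"FP_BH_1"`.
#' @param strains Character subset of `c("RI","FP","BH")` present.
#' @param initial Named numeric of initial metabolite concentrations (mM),
#'   names among [model_metabolites()]; typically fructose 50 plus acetate
#'   and/or formate at 50.
#' @param inoculum Named numeric of initial abundances (10^8 counts/mL) for
#'   the strains present.
#' @param observations data.frame with columns `time_h`, `variable`,
#'   `replicate`, `value` and optionally `excluded` (logical) and
#'   `exclude_reason` (character).
#' @param truth Optional list with the generating ground truth (parameters,
#'   Q0, noiseless trajectory) attached by the synthetic-data generator.
#' @return Object of class `fermentation_experiment`.
#' @export
fermentation_experiment <- function(id, strains, initial, inoculum,
                                    observations, truth = NULL) {
  stopifnot(is.character(id), length(id) == 1)
  if (!all(strains %in% strain_ids()) || length(strains) == 0) {
    stop("strains must be a non-empty subset of RI, FP, BH", call. = FALSE)
  }
  if (!all(names(initial) %in% model_metabolites())) {
    stop("unknown metabolite in initial design", call. = FALSE)
  }
  if (!all(names(inoculum) %in% strains)) {
    stop("inoculum names must match the strains present", call. = FALSE)
  }
  obs <- as.data.frame(observations)
  needed <- c("time_h", "variable", "replicate", "value")
  if (!all(needed %in% names(obs))) {
    stop("observations need columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(obs$variable), observation_variables())
  if (length(bad) > 0) {
    stop("unknown observation variable(s): ", paste(bad, collapse = ", "),
         "; valid names are: ",
         paste(observation_variables(), collapse = ", "), call. = FALSE)
  }
  if (any(obs$time_h < 0)) stop("negative sample time", call. = FALSE)
  if (any(obs$value < 0)) stop("negative observation value", call. = FALSE)
  if (is.null(obs$excluded)) obs$excluded <- FALSE
  if (is.null(obs$exclude_reason)) obs$exclude_reason <- NA_character_
  obs <- obs[order(obs$variable, obs$time_h, obs$replicate), , drop = FALSE]
  rownames(obs) <- NULL
  structure(list(id = id, strains = strains, initial = initial,
                 inoculum = inoculum, observations = obs, truth = truth),
            class = "fermentation_experiment")
}

#' @export
print.fermentation_experiment <- function(x, ...) {
  cat("Fermentation experiment ", x$id, " [",
      paste(x$strains, collapse = "/"), "]\n", sep = "")
  cat("  initial (mM): ",
      paste(sprintf("%s=%g", names(x$initial), x$initial), collapse = ", "),
      "\n  samples: ", length(unique(x$observations$time_h)),
      " times x ", max(x$observations$replicate), " replicates, ",
      sum(x$observations$excluded), " excluded rows\n", sep = "")
  invisible(x)
}

# Per-time replicate means for one variable; optionally included rows only.
replicate_means <- function(exp, variable, included_only = FALSE) {
  obs <- exp$observations
  obs <- obs[obs$variable == variable, , drop = FALSE]
  if (included_only) obs <- obs[!obs$excluded, , drop = FALSE]
  if (nrow(obs) == 0) {
    return(data.frame(time_h = numeric(0), mean = numeric(0)))
  }
  agg <- stats::aggregate(value ~ time_h, data = obs, FUN = mean)
  names(agg) <- c("time_h", "mean")
  agg[order(agg$time_h), , drop = FALSE]
}

#' Map an experiment to a model initial state
#'
#' @param exp A [fermentation_experiment()].
#' @param Q0 Named numeric of initial lag variables per strain present
#'   (default 1 for each).
#' @param unknown0 Initial concentration of the unknown compound (mM);
#'   30 mM by convention whenever FP is present (it is required for FP
#'   growth and never measured).
#' @return Named initial state vector.
#' @export
experiment_initial_state <- function(exp, Q0 = NULL, unknown0 = 30) {
  X <- stats::setNames(numeric(length(exp$strains)), exp$strains)
  X[names(exp$inoculum)] <- exp$inoculum
  S <- exp$initial[names(exp$initial) %in% model_metabolites()]
  if ("FP" %in% exp$strains && !"unknown" %in% names(S)) {
    S <- c(S, unknown = unknown0)
  }
  if (is.null(Q0)) Q0 <- stats::setNames(rep(1, length(exp$strains)),
                                         exp$strains)
  initial_state(X = X, S = S, Q0 = Q0)
}
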