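# Seeded generator of synthetic batch-fermentation experiments: simulate a
# ground-truth trajectory under known kinetics, sample it on the standard
# fermentation sampling grid, append a declining tail to the counts after
# stationary onset, and corrupt with technical-replicate noise. Every
# pipeline stage can then be tested against known truth without access to
# the original fermentation deposit.

#' Standard fermentation sampling grid
#'
#' Samples at 10 min and 2, 3, 5, 6, 7, 9, 10, 11, 13, 14, 15, 17, 18, 24,
#' 30 and 48 h after inoculation, as in the batch fermentations the
#' generator emulates.
#'
#' @return Numeric vector of sampling times (h).
#' @export
sampling_times <- function() {
  c(1 / 6, 2, 3, 5, 6, 7, 9, 10, 11, 13, 14, 15, 17, 18, 24, 30, 48)
}

#' Reference kinetic parameter set for testing
#'
#' A fixed, versioned parameter set with realistic magnitudes for the
#' three-strain community: growth rates around 0.5/h, half-saturation
#' constants of a few to ~15 mM against a 50 mM fructose dose, and yields
#' sized so that (a) RI and FP deplete 50 mM fructose well within 48 h in
#' monoculture, (b) BH consumes formate, and (c) tri-culture dominance
#' flips across lag-phase and initial-abundance grids. It is the ground
#' truth for all recovery tests; it is not a fit to any measured data.
#'
#' @return A [model_parameters()] object.
#' @export
fixture_params <- function() {
  model_parameters(c(
    mu.RI = 0.35, K.RI.fructose = 8, K.RI.acetate = 30, omega.RI = 0.3,
    nu.RI.fructose = 6, nu.RI.acetate = 2,
    alpha.RI.formate = 0.9, alpha.RI.butyrate = 7, alpha.RI.H2 = 9,
    alpha.RI.CO2 = 10,
    mu.FP = 0.55, K.FP.unknown = 5, K.FP.fructose = 8, K.FP.acetate = 30,
    omega.FP = 0.6, nu.FP.fructose = 5, nu.FP.acetate = 1.5,
    nu.FP.unknown = 2.5,
    alpha.FP.formate = 2.2, alpha.FP.butyrate = 3, alpha.FP.CO2 = 2,
    mu.BH = 0.32, K.BH.fructose = 15, K.BH.formate = 10, omega.BH = 1.2,
    nu.BH.fructose = 5, nu.BH.formate = 8,
    alpha.BH.acetate = 3, alpha.BH.H2 = 2, alpha.BH.CO2 = 2))
}

#' Noise model for synthetic observations
#'
#' Technical-replicate scatter: multiplicative mean-one log-normal noise on
#' counts (qPCR-like), additive Gaussian noise floored at zero on
#' concentrations (HPLC/GC-like), and an exponential declining tail
#' appended to counts after stationary onset. The decline is deliberately
#' absent from the kinetic model (death is assumed negligible there); it
#' is added to the data so that decline detection and exclusion have
#' something to act on.
#'
#' @param cv_abundance Coefficient of variation of count noise (default 0.1).
#' @param sd_metabolite Gaussian sd of concentration noise in mM (default 0.5).
#' @param replicates Technical replicates per sample (default 3).
#' @param decline_rate Exponential decay rate of counts after stationary
#'   onset (1/h, default 0.05; 0 disables the tail).
#' @param seed Integer seed fixing all randomness.
#' @return List of class `noise_config`.
#' @export
noise_config <- function(cv_abundance = 0.1, sd_metabolite = 0.5,
                         replicates = 3, decline_rate = 0.05, seed = 1L) {
  stopifnot(cv_abundance >= 0, sd_metabolite >= 0, replicates >= 1,
            decline_rate >= 0)
  structure(list(cv_abundance = cv_abundance, sd_metabolite = sd_metabolite,
                 replicates = as.integer(replicates),
                 decline_rate = decline_rate, seed = as.integer(seed)),
            class = "noise_config")
}

#' Describe a fermentation design
#'
#' @param name Experiment identifier.
#' @param strains Strains inoculated.
#' @param initial Named numeric initial concentrations (mM); fructose
#'   defaults to 50 mM, acetate/formate added per design.
#' @param inoculum Named numeric initial abundances (10^8 counts/mL).
#' @param lags Named numeric lag phases (h) per strain present.
#' @param times Sampling grid (default [sampling_times()]).
#' @return List of class `experiment_design`.
#' @export
experiment_design <- function(name, strains, initial = c(fructose = 50),
                              inoculum, lags = NULL,
                              times = sampling_times()) {
  stopifnot(all(strains %in% strain_ids()))
  if (is.null(lags)) lags <- stats::setNames(rep(0, length(strains)), strains)
  stopifnot(all(names(lags) %in% strains),
            all(names(inoculum) %in% strains))
  structure(list(name = name, strains = strains, initial = initial,
                 inoculum = inoculum, lags = lags, times = times),
            class = "experiment_design")
}

# Ground-truth trajectory for a design under given parameters.
design_truth <- function(params, design, dt = 0.05) {
  p <- unclass(params)
  mu <- p[paste0("mu.", design$strains)]
  Q0 <- Q0_from_lag(design$lags[design$strains], mu)
  names(Q0) <- design$strains
  init <- experiment_initial_state(
    fermentation_experiment(design$name, design$strains, design$initial,
                            design$inoculum,
                            data.frame(time_h = 0, variable = "S_fructose",
                                       replicate = 1L, value = 0)),
    Q0 = Q0)
  t_end <- max(design$times)
  times <- sort(unique(c(seq(0, t_end, by = dt), design$times)))
  list(trajectory = simulate_community(params, init, times), Q0 = Q0,
       init = init)
}

#' Generate one synthetic fermentation experiment
#'
#' Simulates the ground truth under `params`, samples it at the design's
#' sampling times, appends the declining tail to counts and applies
#' replicate noise. The generating truth (parameters, initial lag
#' variables, noiseless trajectory) is stored in the result's `truth`
#' field for recovery tests. The unknown compound is never emitted as an
#' observation.
#'
#' @param params A [model_parameters()] object (ground truth).
#' @param design An [experiment_design()].
#' @param noise A [noise_config()].
#' @return A [fermentation_experiment()] with `truth` attached.
#' @export
generate_experiment <- function(params, design, noise = noise_config()) {
  tr <- design_truth(params, design)
  traj <- tr$trajectory
  at <- function(v, t) stats::approx(traj$time, traj[[v]], xout = t)$y
  vars <- c(paste0("X_", design$strains),
            "S_fructose", "S_formate", "S_acetate", "S_butyrate",
            "S_H2", "S_CO2")
  times <- design$times

  # Stationary onset per strain: first time its abundance reaches 99.5% of
  # the final value; later counts decay exponentially (decline tail).
  onset <- vapply(design$strains, function(s) {
    x <- traj[[paste0("X_", s)]]
    traj$time[which(x >= 0.995 * x[length(x)])[1]]
  }, numeric(1))

  set.seed(noise$seed)
  rows <- list()
  for (v in vars) {
    truth_v <- vapply(times, function(t) at(v, t), numeric(1))
    if (startsWith(v, "X_")) {
      s <- sub("^X_", "", v)
      tail_fac <- ifelse(times > onset[[s]],
                         exp(-noise$decline_rate * (times - onset[[s]])), 1)
      truth_v <- truth_v * tail_fac
    }
    for (r in seq_len(noise$replicates)) {
      val <- if (startsWith(v, "X_")) {
        if (noise$cv_abundance > 0) {
          sdlog <- sqrt(log(1 + noise$cv_abundance^2))
          truth_v * stats::rlnorm(length(truth_v), -sdlog^2 / 2, sdlog)
        } else truth_v
      } else {
        pmax(truth_v + stats::rnorm(length(truth_v), 0,
                                    noise$sd_metabolite), 0)
      }
      rows[[length(rows) + 1]] <- data.frame(
        time_h = times, variable = v, replicate = r, value = val,
        stringsAsFactors = FALSE)
    }
  }
  obs <- do.call(rbind, rows)
  fermentation_experiment(
    id = design$name, strains = design$strains, initial = design$initial,
    inoculum = design$inoculum, observations = obs,
    truth = list(params = params, Q0 = tr$Q0, lags = design$lags,
                 trajectory = traj, design = design))
}

#' Designs of the full synthetic study
#'
#' The mono/bi/tri design matrix mirroring a systematic batch-fermentation
#' campaign: RI and FP monocultures with initial acetate, a BH monoculture
#' with initial formate, the RI/FP, RI/BH and FP/BH bi-cultures with
#' initial acetate, RI/BH and FP/BH bi-cultures without acetate, and six
#' tri-cultures with varied inoculum proportions chosen so that both
#' RI-dominant and FP-dominant outcomes occur under [fixture_params()].
#' All co-substrates are dosed at 50 mM, like fructose.
#'
#' @return Named list of [experiment_design()] objects.
#' @export
study_designs <- function() {
  fru <- c(fructose = 50)
  fru_ace <- c(fructose = 50, acetate = 50)
  fru_for <- c(fructose = 50, formate = 50)
  tri_inocula <- list(
    TRI_1 = c(RI = 0.60, FP = 0.01, BH = 0.20),
    TRI_2 = c(RI = 0.50, FP = 0.02, BH = 0.20),
    TRI_3 = c(RI = 0.30, FP = 0.08, BH = 0.20),
    TRI_4 = c(RI = 0.12, FP = 0.20, BH = 0.20),
    TRI_5 = c(RI = 0.05, FP = 0.30, BH = 0.20),
    TRI_6 = c(RI = 0.02, FP = 0.45, BH = 0.20))
  designs <- list(
    RI_1 = experiment_design("RI_1", "RI", fru_ace, c(RI = 0.06),
                             c(RI = 1.0)),
    RI_2 = experiment_design("RI_2", "RI", fru_ace, c(RI = 0.08),
                             c(RI = 1.5)),
    FP_1 = experiment_design("FP_1", "FP", fru_ace, c(FP = 0.05),
                             c(FP = 0.5)),
    FP_2 = experiment_design("FP_2", "FP", fru_ace, c(FP = 0.07),
                             c(FP = 1.0)),
    BH_1 = experiment_design("BH_1", "BH", fru_for, c(BH = 0.05),
                             c(BH = 0.8)),
    RI_FP_1 = experiment_design("RI_FP_1", c("RI", "FP"), fru_ace,
                                c(RI = 0.05, FP = 0.04),
                                c(RI = 0.8, FP = 0.5)),
    RI_BH_1 = experiment_design("RI_BH_1", c("RI", "BH"), fru_ace,
                                c(RI = 0.05, BH = 0.04),
                                c(RI = 1.0, BH = 0.8)),
    RI_BH_2 = experiment_design("RI_BH_2", c("RI", "BH"), fru,
                                c(RI = 0.05, BH = 0.04),
                                c(RI = 1.0, BH = 0.8)),
    FP_BH_1 = experiment_design("FP_BH_1", c("FP", "BH"), fru_ace,
                                c(FP = 0.04, BH = 0.04),
                                c(FP = 0.5, BH = 0.8)),
    FP_BH_2 = experiment_design("FP_BH_2", c("FP", "BH"), fru_ace,
                                c(FP = 0.06, BH = 0.05),
                                c(FP = 0.8, BH = 1.0)),
    FP_BH_3 = experiment_design("FP_BH_3", c("FP", "BH"), fru,
                                c(FP = 0.04, BH = 0.04),
                                c(FP = 0.5, BH = 0.8)))
  tris <- lapply(names(tri_inocula), function(nm) {
    experiment_design(nm, strain_ids(), fru, tri_inocula[[nm]],
                      c(RI = 0.33, FP = 0.08, BH = 0.1))
  })
  names(tris) <- names(tri_inocula)
  c(designs, tris)
}

#' Generate the full synthetic study
#'
#' @param params Ground-truth [model_parameters()] (default
#'   [fixture_params()]).
#' @param noise A [noise_config()]; each experiment receives a seed derived
#'   deterministically from `noise$seed`, so the whole study is
#'   reproducible from one integer.
#' @param designs Named list of designs (default [study_designs()]).
#' @return Named list of [fermentation_experiment()] objects.
#' @export
generate_study <- function(params = fixture_params(), noise = noise_config(),
                           designs = study_designs()) {
  out <- vector("list", length(designs))
  names(out) <- names(designs)
  for (i in seq_along(designs)) {
    n_i <- noise
    n_i$seed <- noise$seed + i
    out[[i]] <- generate_experiment(params, designs[[i]], n_i)
  }
  out
}
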