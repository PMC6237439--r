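# Shared test fixtures and independent oracles.

# A small, well-conditioned parameter set for hand checks (round numbers,
# distinct from the fixture set so tests do not depend on fixture tuning).
toy_params <- function() {
  model_parameters(c(
    mu.RI = 0.5, K.RI.fructose = 10, K.RI.acetate = 5, omega.RI = 0.4,
    nu.RI.fructose = 5, nu.RI.acetate = 2,
    alpha.RI.formate = 1, alpha.RI.butyrate = 6, alpha.RI.H2 = 8,
    alpha.RI.CO2 = 9,
    mu.FP = 0.6, K.FP.unknown = 4, K.FP.fructose = 8, K.FP.acetate = 6,
    omega.FP = 0.5, nu.FP.fructose = 4, nu.FP.acetate = 1,
    nu.FP.unknown = 2,
    alpha.FP.formate = 2, alpha.FP.butyrate = 3, alpha.FP.CO2 = 2,
    mu.BH = 0.45, K.BH.fructose = 12, K.BH.formate = 9, omega.BH = 1.1,
    nu.BH.fructose = 4, nu.BH.formate = 6,
    alpha.BH.acetate = 3, alpha.BH.H2 = 2, alpha.BH.CO2 = 2))
}

# A generic mixed state with all compartments populated.
toy_state <- function() {
  initial_state(X = c(RI = 1.2, FP = 0.7, BH = 0.4),
                S = c(fructose = 30, formate = 4, acetate = 12,
                      butyrate = 5, unknown = 20, H2 = 3, CO2 = 6),
                Q0 = c(RI = 0.5, FP = 2, BH = 1))
}

# Brute-force fixed-step explicit Euler integrator over the model RHS;
# deliberately naive, used as the integration oracle.
euler_simulate <- function(params, init, t_end, dt = 1e-3,
                           keep = seq(0, t_end, by = 1)) {
  y <- as.numeric(init)
  p <- unclass(params)
  n <- round(t_end / dt)
  keep_idx <- round(keep / dt)
  out <- matrix(NA_real_, nrow = length(keep), ncol = length(y))
  k <- 1
  if (keep_idx[1] == 0) { out[1, ] <- y; k <- 2 }
  for (i in seq_len(n)) {
    y <- y + dt * syngut:::rhs_core(y, p)
    if (k <= length(keep_idx) && i == keep_idx[k]) {
      out[k, ] <- y
      k <- k + 1
    }
  }
  colnames(out) <- state_names()
  cbind(time = keep, as.data.frame(out))
}

# Noise-free study generator used by recovery tests.
noiseless <- function(seed = 1) {
  noise_config(cv_abundance = 0, sd_metabolite = 0, replicates = 1,
               decline_rate = 0, seed = seed)
}

# All parameter keys belonging to one strain.
free_keys_for_test <- function(strain) {
  grep(paste0("\\.", strain, "(\\.|$)"), parameter_names(), value = TRUE)
}

# Deterministic multiplicative perturbation of a parameter set, emulating
# a rough manual initial estimate for the optimizer.
perturb_params <- function(params, factor = 1.3) {
  p <- unclass(params)
  # alternate up/down so the start is biased in both directions
  f <- rep(c(factor, 1 / factor), length.out = length(p))
  model_parameters(stats::setNames(p * f, names(p)))
}
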