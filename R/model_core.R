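# Core model definitions: strains, metabolites, kinetic parameters and the
# right-hand side of the community ODE system.

#' Strain identifiers
#'
#' The community consists of three human gut isolates: *Roseburia
#' intestinalis* L1-82 (`"RI"`), *Faecalibacterium prausnitzii* A2-165
#' (`"FP"`) and *Blautia hydrogenotrophica* S5a33 (`"BH"`). All per-strain
#' quantities in the package are indexed by these three codes, in this
#' fixed order.
#'
#' @return Character vector `c("RI", "FP", "BH")`.
#' @export
strain_ids <- function() c("RI", "FP", "BH")

#' Modeled and observed metabolites
#'
#' Seven metabolites carry differential equations: fructose (the energy
#' source), formate, acetate, butyrate, the unknown compound (an
#' unidentified co-factor required by FP, never measured), hydrogen gas and
#' carbon dioxide. The observation layer additionally admits lactate and
#' ethanol, which are measured in fermentations but not modeled.
#'
#' @return Character vector of metabolite names.
#' @export
model_metabolites <- function() {
  c("fructose", "formate", "acetate", "butyrate", "unknown", "H2", "CO2")
}

#' @rdname model_metabolites
#' @export
observed_metabolites <- function() {
  c("fructose", "formate", "acetate", "butyrate", "lactate", "ethanol",
    "H2", "CO2")
}

#' Names of the 13 state variables
#'
#' Strain abundances `X_i` (10^8 counts/mL), lag-phase variables `Q_i`
#' (dimensionless) and metabolite concentrations `S_s` (mM), in the
#' canonical order used by all state vectors in the package.
#'
#' @return Character vector of length 13.
#' @export
state_names <- function() {
  c("X_RI", "X_FP", "X_BH", "Q_RI", "Q_FP", "Q_BH",
    paste0("S_", model_metabolites()))
}

# Index helpers into the canonical state vector (computed once).
.state_idx <- local({
  nm <- c("X_RI", "X_FP", "X_BH", "Q_RI", "Q_FP", "Q_BH",
          "S_fructose", "S_formate", "S_acetate", "S_butyrate",
          "S_unknown", "S_H2", "S_CO2")
  stats::setNames(seq_along(nm), nm)
})

#' Full set of kinetic parameter names
#'
#' The flat key scheme is `<symbol>.<strain>[.<metabolite>]`: maximal
#' specific growth rates `mu.<i>` (1/h), half-saturation constants
#' `K.<i>.<s>` (mM), the dimensionless facultative-substrate weight
#' `omega.<i>`, consumption yields `nu.<i>.<s>` and production yields
#' `alpha.<i>.<s>` (both mM per 10^8 counts/mL).
#'
#' Which substrates each strain consumes and produces is fixed by the
#' model: RI consumes fructose (obligatory) and acetate (facultative) and
#' produces formate, butyrate, H2 and CO2; FP consumes the unknown
#' compound and fructose (both obligatory) and acetate (facultative) and
#' produces formate, butyrate and CO2; BH consumes fructose and formate
#' (additively, formate weighted by `omega.BH`) and produces acetate, H2
#' and CO2.
#'
#' @return Character vector of the 30 parameter keys.
#' @export
parameter_names <- function() {
  c("mu.RI", "K.RI.fructose", "K.RI.acetate", "omega.RI",
    "nu.RI.fructose", "nu.RI.acetate",
    "alpha.RI.formate", "alpha.RI.butyrate", "alpha.RI.H2", "alpha.RI.CO2",
    "mu.FP", "K.FP.unknown", "K.FP.fructose", "K.FP.acetate", "omega.FP",
    "nu.FP.fructose", "nu.FP.acetate", "nu.FP.unknown",
    "alpha.FP.formate", "alpha.FP.butyrate", "alpha.FP.CO2",
    "mu.BH", "K.BH.fructose", "K.BH.formate", "omega.BH",
    "nu.BH.fructose", "nu.BH.formate",
    "alpha.BH.acetate", "alpha.BH.H2", "alpha.BH.CO2")
}

#' Construct and validate a model parameter set
#'
#' @param x Named numeric vector or named list containing exactly the keys
#'   of [parameter_names()] (order irrelevant).
#' @return Object of class `model_parameters`: a named numeric vector in
#'   canonical key order.
#' @details All parameters must be finite and non-negative; half-saturation
#'   constants `K.*` and growth rates `mu.*` must be strictly positive.
#'   Unknown or missing keys are rejected.
#' @export
model_parameters <- function(x) {
  if (is.list(x)) x <- unlist(x)
  if (is.null(names(x)) || !is.numeric(x)) {
    stop("parameters must be a named numeric vector or list", call. = FALSE)
  }
  wanted <- parameter_names()
  unknown <- setdiff(names(x), wanted)
  if (length(unknown) > 0) {
    stop("unknown parameter key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  missing <- setdiff(wanted, names(x))
  if (length(missing) > 0) {
    stop("missing parameter key(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  p <- as.numeric(x[wanted])
  names(p) <- wanted
  if (any(!is.finite(p))) stop("non-finite parameter value", call. = FALSE)
  if (any(p < 0)) {
    stop("negative parameter value: ",
         paste(wanted[p < 0], collapse = ", "), call. = FALSE)
  }
  strict <- grepl("^(K|mu)\\.", wanted)
  if (any(p[strict] <= 0)) {
    stop("K and mu parameters must be strictly positive", call. = FALSE)
  }
  structure(p, class = "model_parameters")
}

#' @export
print.model_parameters <- function(x, ...) {
  cat("Community model parameters (", length(x), " values)\n", sep = "")
  for (s in strain_ids()) {
    keys <- grep(paste0("\\.", s, "(\\.|$)"), names(x), value = TRUE)
    cat(" ", s, ": ", paste(sprintf("%s=%.4g", keys, unclass(x)[keys]),
                            collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Build an initial system state
#'
#' @param X Named numeric of initial strain abundances (10^8 counts/mL);
#'   names among `RI`, `FP`, `BH`; omitted strains start at 0.
#' @param S Named numeric of initial metabolite concentrations (mM); names
#'   among [model_metabolites()]; omitted metabolites start at 0.
#' @param Q0 Named numeric of initial lag variables (dimensionless, > 0);
#'   omitted strains default to 1 (no lag: the growth weight starts at 0.5).
#' @return Named numeric state vector of length 13 in [state_names()] order.
#' @export
initial_state <- function(X = c(RI = 0, FP = 0, BH = 0), S = c(fructose = 50),
                          Q0 = c(RI = 1, FP = 1, BH = 1)) {
  st <- stats::setNames(numeric(13), state_names())
  st[c("Q_RI", "Q_FP", "Q_BH")] <- 1
  if (length(X)) {
    stopifnot(all(names(X) %in% strain_ids()))
    st[paste0("X_", names(X))] <- X
  }
  if (length(S)) {
    stopifnot(all(names(S) %in% model_metabolites()))
    st[paste0("S_", names(S))] <- S
  }
  if (length(Q0)) {
    stopifnot(all(names(Q0) %in% strain_ids()))
    st[paste0("Q_", names(Q0))] <- Q0
  }
  validate_state(st)
  st
}

#' @keywords internal
validate_state <- function(state) {
  if (length(state) != 13 || !identical(names(state), state_names())) {
    stop("state must be a named vector of the 13 canonical state variables",
         call. = FALSE)
  }
  if (any(!is.finite(state))) stop("non-finite state value", call. = FALSE)
  if (any(state[1:3] < 0)) stop("negative abundance", call. = FALSE)
  if (any(state[4:6] <= 0)) stop("lag variables Q must be > 0", call. = FALSE)
  if (any(state[7:13] < 0)) stop("negative concentration", call. = FALSE)
  invisible(state)
}

#' Lag-phase weighting function
#'
#' The growth rate of each strain is damped by `Gamma(Q) = Q / (1 + Q)`,
#' where the auxiliary variable Q grows exponentially at the strain's
#' maximal growth rate. Gamma rises from near 0 (deep lag) towards 1, and
#' the lag-phase duration is defined as the time at which Gamma reaches
#' 0.5, i.e. Q = 1.
#'
#' @param Q Non-negative numeric (vectorized).
#' @return `Q / (1 + Q)`, in `[0, 1)`.
#' @export
lag_weight <- function(Q) {
  if (any(!is.finite(Q)) || any(Q < 0)) {
    stop("Q must be finite and non-negative", call. = FALSE)
  }
  Q / (1 + Q)
}

# Monod saturation term with a guard against tiny negative excursions the
# adaptive solver can produce; the model is only defined for S >= 0.
monod <- function(S, K) {
  S <- pmax(S, 0)
  S / (K + S)
}

#' Per-strain specific growth rate
#'
#' Evaluates the growth function Phi_i at a given state. Fructose is an
#' obligatory substrate for RI and FP (multiplicative Monod factor), and FP
#' additionally requires the unknown compound; acetate enhances RI and FP
#' growth facultatively through `1 + omega * Monod(acetate)`. BH grows
#' additively on fructose and formate, the formate term weighted by
#' `omega.BH`, so BH grows on formate alone. All growth functions carry the
#' lag weight [lag_weight()].
#'
#' @param strain One of `"RI"`, `"FP"`, `"BH"`.
#' @param state Named state vector (see [initial_state()]).
#' @param params A [model_parameters()] object.
#' @return Specific growth rate (1/h), non-negative.
#' @export
growth_rate <- function(strain, state, params) {
  strain <- match.arg(strain, strain_ids())
  p <- unclass(params)
  g <- lag_weight(state[[paste0("Q_", strain)]])
  fru <- state[["S_fructose"]]
  ace <- state[["S_acetate"]]
  switch(strain,
    RI = g * p[["mu.RI"]] * monod(fru, p[["K.RI.fructose"]]) *
      (1 + p[["omega.RI"]] * monod(ace, p[["K.RI.acetate"]])),
    FP = g * p[["mu.FP"]] * monod(state[["S_unknown"]], p[["K.FP.unknown"]]) *
      monod(fru, p[["K.FP.fructose"]]) *
      (1 + p[["omega.FP"]] * monod(ace, p[["K.FP.acetate"]])),
    BH = g * p[["mu.BH"]] * (monod(fru, p[["K.BH.fructose"]]) +
      p[["omega.BH"]] * monod(state[["S_formate"]], p[["K.BH.formate"]]))
  )
}

#' Acetate-linked partial growth rate for RI or FP
#'
#' Acetate consumption is not proportional to the full growth rate: it is
#' driven by the auxiliary rate Phi_i_acetate, the product of the lag
#' weight, mu, the facultative weight omega, the strain's obligatory Monod
#' factor(s) and the acetate Monod factor. It vanishes when acetate is
#' absent or when the strain cannot grow at all.
#'
#' @inheritParams growth_rate
#' @return Partial rate (1/h).
#' @export
acetate_uptake_rate <- function(strain, state, params) {
  if (!strain %in% c("RI", "FP")) {
    stop("acetate uptake is defined for RI and FP only", call. = FALSE)
  }
  p <- unclass(params)
  g <- lag_weight(state[[paste0("Q_", strain)]])
  fru <- state[["S_fructose"]]
  ace <- state[["S_acetate"]]
  if (strain == "RI") {
    g * p[["mu.RI"]] * p[["omega.RI"]] * monod(fru, p[["K.RI.fructose"]]) *
      monod(ace, p[["K.RI.acetate"]])
  } else {
    g * p[["mu.FP"]] * p[["omega.FP"]] *
      monod(state[["S_unknown"]], p[["K.FP.unknown"]]) *
      monod(fru, p[["K.FP.fructose"]]) * monod(ace, p[["K.FP.acetate"]])
  }
}

#' Partial growth rates of BH on fructose and on formate
#'
#' BH's additive growth function splits into a fructose part and a
#' formate part (the latter carrying the weight `omega.BH`); substrate
#' consumption by BH is driven by the respective part, not by the total
#' growth rate. Their sum equals [growth_rate()] for BH.
#'
#' @inheritParams growth_rate
#' @return Named numeric `c(fructose = , formate = )` (1/h).
#' @export
bh_partial_rates <- function(state, params) {
  p <- unclass(params)
  g <- lag_weight(state[["Q_BH"]])
  c(fructose = g * p[["mu.BH"]] *
      monod(state[["S_fructose"]], p[["K.BH.fructose"]]),
    formate = g * p[["mu.BH"]] * p[["omega.BH"]] *
      monod(state[["S_formate"]], p[["K.BH.formate"]]))
}

# Positional right-hand side used by the integrator and the fitting code:
# `state` must be in canonical order; no name lookups for speed.
rhs_core <- function(state, p) {
  X_RI <- state[1L]; X_FP <- state[2L]; X_BH <- state[3L]
  g_RI <- state[4L] / (1 + state[4L])
  g_FP <- state[5L] / (1 + state[5L])
  g_BH <- state[6L] / (1 + state[6L])
  fru <- max(state[7L], 0); fo <- max(state[8L], 0)
  ace <- max(state[9L], 0); unk <- max(state[11L], 0)

  m_fru_RI <- fru / (p[["K.RI.fructose"]] + fru)
  m_ace_RI <- ace / (p[["K.RI.acetate"]] + ace)
  m_unk_FP <- unk / (p[["K.FP.unknown"]] + unk)
  m_fru_FP <- fru / (p[["K.FP.fructose"]] + fru)
  m_ace_FP <- ace / (p[["K.FP.acetate"]] + ace)
  m_fru_BH <- fru / (p[["K.BH.fructose"]] + fru)
  m_fo_BH  <- fo / (p[["K.BH.formate"]] + fo)

  phi_RI <- g_RI * p[["mu.RI"]] * m_fru_RI * (1 + p[["omega.RI"]] * m_ace_RI)
  phi_FP <- g_FP * p[["mu.FP"]] * m_unk_FP * m_fru_FP *
    (1 + p[["omega.FP"]] * m_ace_FP)
  phi_BH_fru <- g_BH * p[["mu.BH"]] * m_fru_BH
  phi_BH_fo <- g_BH * p[["mu.BH"]] * p[["omega.BH"]] * m_fo_BH
  phi_BH <- phi_BH_fru + phi_BH_fo
  phi_RI_ace <- g_RI * p[["mu.RI"]] * p[["omega.RI"]] * m_fru_RI * m_ace_RI
  phi_FP_ace <- g_FP * p[["mu.FP"]] * p[["omega.FP"]] * m_unk_FP * m_fru_FP *
    m_ace_FP

  gRI_X <- phi_RI * X_RI; gFP_X <- phi_FP * X_FP; gBH_X <- phi_BH * X_BH

  c(gRI_X, gFP_X, gBH_X,
    p[["mu.RI"]] * state[4L], p[["mu.FP"]] * state[5L],
    p[["mu.BH"]] * state[6L],
    -p[["nu.RI.fructose"]] * gRI_X - p[["nu.FP.fructose"]] * gFP_X -
      p[["nu.BH.fructose"]] * phi_BH_fru * X_BH,
    p[["alpha.RI.formate"]] * gRI_X + p[["alpha.FP.formate"]] * gFP_X -
      p[["nu.BH.formate"]] * phi_BH_fo * X_BH,
    -p[["nu.RI.acetate"]] * phi_RI_ace * X_RI -
      p[["nu.FP.acetate"]] * phi_FP_ace * X_FP +
      p[["alpha.BH.acetate"]] * gBH_X,
    p[["alpha.RI.butyrate"]] * gRI_X + p[["alpha.FP.butyrate"]] * gFP_X,
    -p[["nu.FP.unknown"]] * gFP_X,
    p[["alpha.RI.H2"]] * gRI_X + p[["alpha.BH.H2"]] * gBH_X,
    p[["alpha.RI.CO2"]] * gRI_X + p[["alpha.FP.CO2"]] * gFP_X +
      p[["alpha.BH.CO2"]] * gBH_X)
}

#' Right-hand side of the community ODE system
#'
#' Time derivative of the 13-dimensional state: `dX_i/dt = Phi_i X_i`,
#' `dQ_i/dt = mu_i Q_i` (exponential growth of the lag variable), and the
#' seven metabolite equations with consumption yields `nu` and production
#' yields `alpha`. Acetate consumption is driven by the auxiliary rates
#' [acetate_uptake_rate()]; BH's fructose and formate consumption by the
#' respective [bh_partial_rates()]. H2 is produced by RI and BH, CO2 by all
#' three strains; both gasses are booked cumulatively in mM of the liquid
#' volume with no outgassing or consumption term. Butyrate is only
#' produced, the unknown compound only consumed.
#'
#' Monod terms clip negative concentrations to zero so that adaptive
#' solvers stepping marginally below zero never see undefined kinetics.
#'
#' @param state Named state vector in [state_names()] order.
#' @param params A [model_parameters()] object.
#' @return Named numeric vector of derivatives, same layout as `state`.
#' @export
ode_rhs <- function(state, params) {
  if (!identical(names(state), state_names())) {
    state <- state[state_names()]
    if (any(is.na(state))) stop("state is missing variables", call. = FALSE)
  }
  stats::setNames(rhs_core(as.numeric(state), unclass(params)), state_names())
}
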