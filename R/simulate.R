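# Integration of the community ODE system and trajectory summaries.

#' Simulate the community over a time grid
#'
#' Integrates the 13-state ODE system with an adaptive, stiffness-switching
#' solver (deSolve's `lsoda`). Monod terms with small half-saturation
#' constants make the system moderately stiff near substrate exhaustion,
#' hence the tight default tolerances.
#'
#' @param params A [model_parameters()] object.
#' @param init Initial state from [initial_state()].
#' @param times Numeric time grid in hours, starting at 0, strictly
#'   increasing. Default: 0 to 48 h in 0.25 h steps.
#' @param rtol,atol Relative and absolute solver tolerances.
#' @param method deSolve integration method (default `"lsoda"`).
#' @param compiled Use the compiled C right-hand side (default TRUE; the
#'   interpreted [ode_rhs()] path is retained for cross-checks).
#' @return A `community_trajectory`: a data.frame with a `time` column and
#'   the 13 state variables, carrying the parameters, initial state and
#'   solver settings as attributes.
#' @export
simulate_community <- function(params, init, times = seq(0, 48, by = 0.25),
                               rtol = 1e-8, atol = 1e-10, method = "lsoda",
                               compiled = TRUE) {
  if (!inherits(params, "model_parameters")) params <- model_parameters(params)
  validate_state(init)
  if (times[1] != 0 || is.unsorted(times, strictly = TRUE)) {
    stop("times must start at 0 and be strictly increasing", call. = FALSE)
  }
  p <- unclass(params)
  out <- if (compiled) {
    deSolve::ode(y = init, times = times, func = "community_derivs",
                 parms = p, dllname = "syngut",
                 initfunc = "community_init", method = method,
                 rtol = rtol, atol = atol)
  } else {
    deriv <- function(t, y, parms) list(rhs_core(y, parms))
    deSolve::ode(y = init, times = times, func = deriv, parms = p,
                 method = method, rtol = rtol, atol = atol)
  }
  if (nrow(out) < length(times)) {
    stop(sprintf(
      "integration failed after t = %.4g h (step-size underflow or divergence)",
      out[nrow(out), "time"]), call. = FALSE)
  }
  traj <- as.data.frame(out)
  names(traj)[1] <- "time"
  structure(traj,
            params = params, init = init,
            solver = list(method = method, rtol = rtol, atol = atol),
            class = c("community_trajectory", "data.frame"))
}

#' @export
print.community_trajectory <- function(x, ...) {
  cat("Community trajectory: ", nrow(x), " time points, t = ",
      min(x$time), "-", max(x$time), " h\n", sep = "")
  ep <- x[nrow(x), c("X_RI", "X_FP", "X_BH")]
  cat(sprintf("  final abundances (10^8 counts/mL): RI %.3g, FP %.3g, BH %.3g\n",
              ep[[1]], ep[[2]], ep[[3]]))
  invisible(x)
}

#' Reshape a trajectory to long (tidy) format
#'
#' @param traj A `community_trajectory`.
#' @return data.frame with columns `time_h`, `variable`, `value`.
#' @export
trajectory_long <- function(traj) {
  vars <- setdiff(names(traj), "time")
  data.frame(
    time_h = rep(traj$time, times = length(vars)),
    variable = rep(vars, each = nrow(traj)),
    value = unlist(lapply(vars, function(v) traj[[v]]), use.names = FALSE),
    stringsAsFactors = FALSE)
}

#' Convert between lag-phase duration and initial lag variable
#'
#' The lag variable grows as `Q(t) = Q(0) exp(mu t)`, and the lag phase is
#' the time at which the growth weight [lag_weight()] reaches 0.5 (Q = 1):
#' `lag = -ln(Q(0)) / mu`. A `Q0 > 1` gives a negative lag (growth starts
#' above half speed).
#'
#' @param Q0 Initial lag variable, > 0.
#' @param mu Maximal specific growth rate (1/h), > 0.
#' @return `lag_from_Q0`: lag phase in hours; `Q0_from_lag`: the initial
#'   lag variable `exp(-mu * lag)`.
#' @export
lag_from_Q0 <- function(Q0, mu) {
  if (any(Q0 <= 0)) stop("Q0 must be > 0", call. = FALSE)
  if (any(mu <= 0)) stop("mu must be > 0", call. = FALSE)
  -log(Q0) / mu
}

#' @rdname lag_from_Q0
#' @param lag Lag phase in hours (may be negative).
#' @export
Q0_from_lag <- function(lag, mu) {
  if (any(mu <= 0)) stop("mu must be > 0", call. = FALSE)
  exp(-mu * lag)
}

#' End-point summary of a trajectory
#'
#' Linearly interpolates the state at `t_e`, reports per-strain end-point
#' abundances, the FP/RI abundance ratio and the dominance ordering
#' (descending end-point abundance; exact ties broken by the fixed strain
#' order RI, FP, BH and flagged).
#'
#' @param traj A `community_trajectory`.
#' @param t_e End-point time (h), within the trajectory span (default: the
#'   last time point).
#' @return List of class `endpoint_summary` with elements `t_e`, `X`
#'   (named abundances), `ratio_FP_RI`, `dominance` (strain ids, most
#'   abundant first) and `tie` (logical).
#' @export
endpoint_summary <- function(traj, t_e = max(traj$time)) {
  if (t_e < min(traj$time) || t_e > max(traj$time)) {
    stop("t_e outside the trajectory span", call. = FALSE)
  }
  X <- vapply(c("X_RI", "X_FP", "X_BH"), function(v) {
    stats::approx(traj$time, traj[[v]], xout = t_e)$y
  }, numeric(1))
  names(X) <- strain_ids()
  ratio <- X[["FP"]] / X[["RI"]]
  ord <- order(-X)  # stable: ties keep RI < FP < BH order
  tie <- anyDuplicated(X) > 0
  structure(list(t_e = t_e, X = X, ratio_FP_RI = ratio,
                 dominance = strain_ids()[ord], tie = tie),
            class = "endpoint_summary")
}

#' @export
print.endpoint_summary <- function(x, ...) {
  cat(sprintf("End point at t = %g h: RI %.3g, FP %.3g, BH %.3g (10^8 counts/mL)\n",
              x$t_e, x$X[["RI"]], x$X[["FP"]], x$X[["BH"]]))
  cat(sprintf("  FP/RI ratio %.3g; dominance %s%s\n", x$ratio_FP_RI,
              paste(x$dominance, collapse = " > "),
              if (x$tie) " (tie)" else ""))
  invisible(x)
}
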