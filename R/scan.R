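# Dominance scans: grids of simulations over lag phases or initial
# abundances of RI and FP, summarized as the log10 end-point FP/RI ratio.

scan_run <- function(params, init, t_e, rtol, atol) {
  times <- sort(unique(c(seq(0, t_e, length.out = 97), t_e)))
  traj <- simulate_community(params, init, times, rtol = rtol, atol = atol)
  endpoint_summary(traj, t_e)
}

build_grid <- function(params, x_axis, y_axis, make_init, t_e, rtol, atol) {
  nx <- length(x_axis$values); ny <- length(y_axis$values)
  ratio <- matrix(NA_real_, nrow = ny, ncol = nx,
                  dimnames = list(signif(y_axis$values, 6),
                                  signif(x_axis$values, 6)))
  cells <- vector("list", nx * ny)
  failed <- matrix(FALSE, nrow = ny, ncol = nx)
  for (j in seq_len(nx)) {
    for (i in seq_len(ny)) {
      cell <- tryCatch(
        scan_run(params, make_init(x_axis$values[j], y_axis$values[i]),
                 t_e, rtol, atol),
        error = function(e) NULL)
      k <- (j - 1) * ny + i
      if (is.null(cell)) {
        failed[i, j] <- TRUE
      } else {
        cells[[k]] <- cell
        # log10 ratio; zero end-point abundances become +/-Inf sentinels.
        ratio[i, j] <- log10(cell$X[["FP"]]) - log10(cell$X[["RI"]])
      }
    }
  }
  list(ratio = ratio, cells = cells, failed = failed)
}

#' Scan end-point dominance over RI and FP lag phases
#'
#' Simulates the tri-culture once per grid cell with the lag phases of RI
#' (x axis) and FP (y axis) varied and everything else fixed, and records
#' the log10 end-point abundance ratio FP/RI. Default fixed conditions:
#' initial abundances 0.58, 0.04 and 0.21 (10^8 counts/mL) for RI, FP and
#' BH -- the observed tri-culture averages -- and a 48 h end point, the
#' fermentation duration. Cells whose simulation fails are flagged and the
#' scan continues; cells are independent, so the result does not depend on
#' evaluation order.
#'
#' @param params A [model_parameters()] object.
#' @param base_init Named initial abundances for RI, FP, BH.
#' @param lag_RI_values,lag_FP_values Lag-phase grid values (h).
#' @param lag_BH Fixed BH lag phase (h, default 0.1).
#' @param t_e End-point time (h, default 48).
#' @param S0 Initial metabolite concentrations (default 50 mM fructose plus
#'   30 mM of the unknown compound).
#' @param rtol,atol Solver tolerances.
#' @return Object of class `scan_grid`: axes, the log10-ratio matrix (rows
#'   = y axis), per-cell [endpoint_summary()]s, failure flags and the
#'   fixed conditions.
#' @export
scan_lag <- function(params, base_init = c(RI = 0.58, FP = 0.04, BH = 0.21),
                     lag_RI_values = seq(0, 8, length.out = 25),
                     lag_FP_values = seq(0, 8, length.out = 25),
                     lag_BH = 0.1, t_e = 48,
                     S0 = c(fructose = 50, unknown = 30),
                     rtol = 1e-8, atol = 1e-10) {
  p <- unclass(params)
  make_init <- function(lag_RI, lag_FP) {
    initial_state(
      X = base_init, S = S0,
      Q0 = c(RI = Q0_from_lag(lag_RI, p[["mu.RI"]]),
             FP = Q0_from_lag(lag_FP, p[["mu.FP"]]),
             BH = Q0_from_lag(lag_BH, p[["mu.BH"]])))
  }
  g <- build_grid(params,
                  x_axis = list(variable = "lag_RI", values = lag_RI_values,
                                scale = "linear"),
                  y_axis = list(variable = "lag_FP", values = lag_FP_values,
                                scale = "linear"),
                  make_init, t_e, rtol, atol)
  structure(list(mode = "lag",
                 x_axis = list(variable = "lag_RI", values = lag_RI_values,
                               scale = "linear"),
                 y_axis = list(variable = "lag_FP", values = lag_FP_values,
                               scale = "linear"),
                 log10_ratio_FP_RI = g$ratio, cells = g$cells,
                 failed = g$failed,
                 fixed = list(base_init = base_init, lag_BH = lag_BH,
                              S0 = S0, t_e = t_e, params = params)),
            class = "scan_grid")
}

#' Scan end-point dominance over RI and FP initial abundances
#'
#' As [scan_lag()], but varying the initial abundances of RI (x axis) and
#' FP (y axis) on log-spaced grids with the lag phases fixed (defaults
#' 0.33, 0.08 and 0.1 h for RI, FP and BH -- the estimated tri-culture
#' averages).
#'
#' @param params A [model_parameters()] object.
#' @param lags Named lag phases (h) for RI, FP, BH.
#' @param init_RI_values,init_FP_values Initial-abundance grids (10^8
#'   counts/mL), positive; log-spaced by default.
#' @param init_BH Fixed BH inoculum (default 0.21).
#' @param t_e End-point time (h, default 48).
#' @inheritParams scan_lag
#' @return A `scan_grid` (see [scan_lag()]).
#' @export
scan_init <- function(params, lags = c(RI = 0.33, FP = 0.08, BH = 0.1),
                      init_RI_values = 10^seq(-3, 0, length.out = 25),
                      init_FP_values = 10^seq(-3, 0, length.out = 25),
                      init_BH = 0.21, t_e = 48,
                      S0 = c(fructose = 50, unknown = 30),
                      rtol = 1e-8, atol = 1e-10) {
  if (any(init_RI_values <= 0) || any(init_FP_values <= 0)) {
    stop("initial-abundance axes must be positive", call. = FALSE)
  }
  p <- unclass(params)
  Q0 <- c(RI = Q0_from_lag(lags[["RI"]], p[["mu.RI"]]),
          FP = Q0_from_lag(lags[["FP"]], p[["mu.FP"]]),
          BH = Q0_from_lag(lags[["BH"]], p[["mu.BH"]]))
  make_init <- function(x_RI, x_FP) {
    initial_state(X = c(RI = x_RI, FP = x_FP, BH = init_BH), S = S0, Q0 = Q0)
  }
  g <- build_grid(params,
                  x_axis = list(variable = "init_RI",
                                values = init_RI_values, scale = "log"),
                  y_axis = list(variable = "init_FP",
                                values = init_FP_values, scale = "log"),
                  make_init, t_e, rtol, atol)
  structure(list(mode = "init",
                 x_axis = list(variable = "init_RI",
                               values = init_RI_values, scale = "log"),
                 y_axis = list(variable = "init_FP",
                               values = init_FP_values, scale = "log"),
                 log10_ratio_FP_RI = g$ratio, cells = g$cells,
                 failed = g$failed,
                 fixed = list(lags = lags, init_BH = init_BH, S0 = S0,
                              t_e = t_e, params = params)),
            class = "scan_grid")
}

#' @export
print.scan_grid <- function(x, ...) {
  r <- x$log10_ratio_FP_RI
  cat("Dominance scan (", x$mode, " mode): ", nrow(r), "x", ncol(r),
      " cells, ", sum(x$failed), " failed\n", sep = "")
  fin <- r[is.finite(r)]
  cat(sprintf("  log10(FP/RI) range %.2f to %.2f; FP dominant in %d cells, RI in %d\n",
              min(fin), max(fin), sum(fin > 0), sum(fin < 0)))
  invisible(x)
}

#' Long-format view of a scan grid
#'
#' @param grid A `scan_grid`.
#' @return data.frame with the two axis variables, `log10_ratio_FP_RI`,
#'   `dominant` and `failed`.
#' @export
scan_long <- function(grid) {
  xv <- grid$x_axis$values; yv <- grid$y_axis$values
  ny <- length(yv)
  out <- expand.grid(y = yv, x = xv, KEEP.OUT.ATTRS = FALSE)
  names(out) <- c(grid$y_axis$variable, grid$x_axis$variable)
  out$log10_ratio_FP_RI <- as.vector(grid$log10_ratio_FP_RI)
  out$dominant <- vapply(seq_len(nrow(out)), function(k) {
    cell <- grid$cells[[k]]
    if (is.null(cell)) NA_character_ else classify_dominance(cell)$label
  }, "")
  out$failed <- as.vector(grid$failed)
  out[, c(2, 1, 3, 4, 5)]
}

#' Classify dominance of an end point
#'
#' FP dominates when the end-point FP/RI abundance ratio exceeds 1, RI
#' when it is below 1; an exact tie is labelled `"tie"`. When an observed
#' dominance label is supplied, an agreement flag is added.
#'
#' @param summary An [endpoint_summary()].
#' @param observed Optional observed dominance, `"RI"` or `"FP"`.
#' @return List with `label` (`"FP"`, `"RI"` or `"tie"`), `ratio`, and
#'   `agreement` (logical, NA without an observation).
#' @export
classify_dominance <- function(summary, observed = NULL) {
  r <- summary$ratio_FP_RI
  label <- if (r == 1) "tie" else if (r > 1) "FP" else "RI"
  agreement <- NA
  if (!is.null(observed)) {
    observed <- match.arg(observed, c("RI", "FP"))
    agreement <- identical(label, observed)
  }
  list(label = label, ratio = r, agreement = agreement)
}
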