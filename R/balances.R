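# Fermentation mass balances: net metabolite deltas, carbon recovery and
# the classical oxidation/reduction ("available hydrogen") balance.

#' Stoichiometry tables for fermentation balances
#'
#' Carbon atoms per molecule and O/R values in the classical fermentation
#' balance convention: each product is scored by its oxidation state
#' relative to the carbohydrate substrate, so CO2 counts +2, formate +1,
#' acetate/lactate/fructose 0, butyrate and ethanol -2, and H2 -1.
#'
#' @return List with named numeric vectors `carbon` and `or_value`.
#' @export
stoichiometry_tables <- function() {
  list(
    carbon = c(fructose = 6, butyrate = 4, lactate = 3, acetate = 2,
               ethanol = 2, formate = 1, CO2 = 1, H2 = 0),
    or_value = c(CO2 = 2, formate = 1, acetate = 0, lactate = 0,
                 fructose = 0, butyrate = -2, ethanol = -2, H2 = -1))
}

#' Net metabolite changes over a fermentation
#'
#' Final minus first sample of each metabolite's replicate-mean series:
#' consumption is negative, production positive. Transients (for example a
#' formate peak that is later consumed) are invisible to the net delta by
#' construction.
#'
#' @param exp A [fermentation_experiment()].
#' @return Named numeric vector of deltas (mM) per observed metabolite;
#'   metabolites with fewer than 2 time points are omitted with a warning.
#' @export
net_deltas <- function(exp) {
  mets <- unique(sub("^S_", "",
                     grep("^S_", exp$observations$variable, value = TRUE)))
  out <- numeric(0)
  for (m in mets) {
    series <- replicate_means(exp, paste0("S_", m))
    if (nrow(series) < 2) {
      warning("metabolite ", m, " has fewer than 2 time points; omitted",
              call. = FALSE)
      next
    }
    out[m] <- series$mean[nrow(series)] - series$mean[1]
  }
  out
}

#' Carbon recovery of a fermentation
#'
#' The percentage of carbon in consumed substrates recovered in measured
#' products: `100 * sum(produced delta x C) / sum(|consumed delta| x C)`.
#' Biomass carbon and the unknown compound are excluded. A recovery near
#' 100% indicates a closed balance; values well below 100% indicate carbon
#' sinks not captured by the measured products (e.g. growth on unmeasured
#' medium components).
#'
#' @param deltas Named numeric deltas (mM) as from [net_deltas()];
#'   consumption negative.
#' @param tables Stoichiometry tables (default [stoichiometry_tables()]).
#' @return Carbon recovery in percent.
#' @export
carbon_recovery <- function(deltas, tables = stoichiometry_tables()) {
  known <- intersect(names(deltas), names(tables$carbon))
  miss <- setdiff(names(deltas), names(tables$carbon))
  if (length(miss) > 0) {
    stop("no carbon entry for metabolite(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  d <- deltas[known]
  cc <- tables$carbon[known]
  consumed <- sum(abs(d[d < 0]) * cc[d < 0])
  produced <- sum(d[d > 0] * cc[d > 0])
  if (consumed <= 0) {
    stop("no carbon-bearing substrate consumed; carbon recovery undefined",
         call. = FALSE)
  }
  100 * produced / consumed
}

#' Oxidation/reduction balance of a fermentation
#'
#' Ratio of oxidized-product equivalents (produced CO2 at +2, net formate
#' at +1 -- consumed formate enters the oxidized sum negatively) to
#' reduced-product equivalents (produced butyrate and ethanol at 2, H2 at
#' 1). A ratio near 1 indicates redox closure of the fermentation.
#'
#' @inheritParams carbon_recovery
#' @return Dimensionless O/R ratio.
#' @export
or_balance <- function(deltas, tables = stoichiometry_tables()) {
  known <- intersect(names(deltas), names(tables$or_value))
  miss <- setdiff(names(deltas), names(tables$or_value))
  if (length(miss) > 0) {
    stop("no O/R entry for metabolite(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  d <- deltas[known]
  v <- tables$or_value[known]
  oxidized <- sum(d[v > 0] * v[v > 0])
  reduced <- sum(-d[v < 0 & d > 0] * v[v < 0 & d > 0])
  if (reduced <= 0) {
    stop("no reduced equivalents produced; O/R balance undefined",
         call. = FALSE)
  }
  oxidized / reduced
}

#' Full balance report for an experiment
#'
#' @param exp A [fermentation_experiment()].
#' @param tables Stoichiometry tables (default [stoichiometry_tables()]).
#' @return List of class `balance_report` with `deltas`,
#'   `carbon_recovery` (percent), `or_balance` (NA when undefined) and the
#'   tables used. Because recovery is a ratio, recovery computed on
#'   replicate-mean deltas is not in general the mean of per-replicate
#'   recoveries.
#' @export
balance_report <- function(exp, tables = stoichiometry_tables()) {
  deltas <- net_deltas(exp)
  cr <- carbon_recovery(deltas, tables)
  orb <- tryCatch(or_balance(deltas, tables), error = function(e) NA_real_)
  structure(list(id = exp$id, deltas = deltas, carbon_recovery = cr,
                 or_balance = orb, tables = tables),
            class = "balance_report")
}

#' @export
print.balance_report <- function(x, ...) {
  cat("Balance report for ", x$id, "\n", sep = "")
  cat("  deltas (mM): ",
      paste(sprintf("%s %+0.1f", names(x$deltas), x$deltas),
            collapse = ", "), "\n", sep = "")
  cat(sprintf("  carbon recovery: %.1f%%; O/R balance: %s\n",
              x$carbon_recovery,
              if (is.na(x$or_balance)) "undefined"
              else sprintf("%.2f", x$or_balance)))
  invisible(x)
}

#' Reference net metabolite changes of the community fermentations
#'
#' Published replicate-mean net consumption (negative) and production
#' (positive) of metabolites, in mM, for the mono-, bi- and tri-culture
#' batch fermentations of the three-strain community. These serve as fixed
#' anchors for the balance arithmetic: recomputing carbon recovery and O/R
#' balance from them reproduces the reported balance columns.
#'
#' @return data.frame with columns `culture`, `n_replicates`, `co_substrate`
#'   and one column per metabolite delta.
#' @export
balance_anchors <- function() {
  path <- system.file("extdata", "balance_anchors.csv", package = "syngut")
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Deltas vector for one anchor row
#'
#' @param culture Value of the `culture` column of [balance_anchors()].
#' @return Named numeric deltas (mM) suitable for [carbon_recovery()].
#' @export
anchor_deltas <- function(culture) {
  tab <- balance_anchors()
  row <- tab[tab$culture == culture, , drop = FALSE]
  if (nrow(row) != 1) {
    stop("unknown culture '", culture, "'; available: ",
         paste(tab$culture, collapse = ", "), call. = FALSE)
  }
  mets <- setdiff(names(row), c("culture", "n_replicates", "co_substrate"))
  d <- as.numeric(row[1, mets])
  names(d) <- mets
  d[!is.na(d)]
}
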