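test_that("lag weight is Q/(1+Q), bounded and monotone", {
  expect_identical(lag_weight(1), 0.5)
  expect_identical(lag_weight(0), 0)
  expect_identical(lag_weight(3), 0.75)
  q <- seq(0, 50, by = 0.5)
  g <- lag_weight(q)
  expect_true(all(g >= 0 & g < 1))
  expect_true(all(diff(g) > 0))
  expect_error(lag_weight(-0.1), "non-negative")
})

test_that("parameter schema is strict", {
  p <- toy_params()
  expect_s3_class(p, "model_parameters")
  expect_error(model_parameters(c(unclass(p), bogus.key = 1)), "unknown")
  expect_error(model_parameters(unclass(p)[-1]), "missing")
  bad <- unclass(p); bad[["K.RI.fructose"]] <- 0
  expect_error(model_parameters(bad), "strictly positive")
  bad2 <- unclass(p); bad2[["nu.RI.fructose"]] <- -1
  expect_error(model_parameters(bad2), "negative")
})

test_that("growth rates honor obligatory and facultative substrates", {
  p <- toy_params()
  pp <- unclass(p)
  base <- toy_state()

  # RI: no fructose -> no growth, regardless of acetate
  st <- base; st[["S_fructose"]] <- 0
  expect_identical(growth_rate("RI", st, p), 0)
  expect_identical(growth_rate("FP", st, p), 0)
  # FP additionally requires the unknown compound
  st2 <- base; st2[["S_unknown"]] <- 0
  expect_identical(growth_rate("FP", st2, p), 0)
  expect_gt(growth_rate("RI", st2, p), 0)
  # BH grows on formate alone
  st3 <- base; st3[["S_fructose"]] <- 0
  expect_gt(growth_rate("BH", st3, p), 0)
  st4 <- st3; st4[["S_formate"]] <- 0
  expect_identical(growth_rate("BH", st4, p), 0)

  # saturation limits with Gamma ~ 1
  sat <- initial_state(X = c(RI = 1), S = c(fructose = 1e9),
                       Q0 = c(RI = 1e12, FP = 1e12, BH = 1e12))
  expect_equal(growth_rate("RI", sat, p), pp[["mu.RI"]], tolerance = 1e-6)
  half <- sat; half[["S_fructose"]] <- pp[["K.RI.fructose"]]
  expect_equal(growth_rate("RI", half, p), pp[["mu.RI"]] / 2,
               tolerance = 1e-6)
  bh_for <- initial_state(S = c(formate = 1e9),
                          Q0 = c(RI = 1, FP = 1, BH = 1e12))
  expect_equal(growth_rate("BH", bh_for, p),
               pp[["mu.BH"]] * pp[["omega.BH"]], tolerance = 1e-6)

  # upper bounds mu * (1 + omega)
  for (s in strain_ids()) {
    expect_lte(growth_rate(s, base, p),
               pp[[paste0("mu.", s)]] * (1 + pp[[paste0("omega.", s)]]))
  }
})

test_that("acetate uptake rate vanishes without acetate or the obligatory substrate", {
  p <- toy_params()
  pp <- unclass(p)
  st <- toy_state()
  st_no_ace <- st; st_no_ace[["S_acetate"]] <- 0
  expect_identical(acetate_uptake_rate("RI", st_no_ace, p), 0)
  st_no_fru <- st; st_no_fru[["S_fructose"]] <- 0
  expect_identical(acetate_uptake_rate("RI", st_no_fru, p), 0)
  expect_identical(acetate_uptake_rate("FP", st_no_fru, p), 0)
  sat <- initial_state(X = c(RI = 1), S = c(fructose = 1e9, acetate = 1e9),
                       Q0 = c(RI = 1e12, FP = 1, BH = 1))
  expect_equal(acetate_uptake_rate("RI", sat, p),
               pp[["mu.RI"]] * pp[["omega.RI"]], tolerance = 1e-6)
  expect_error(acetate_uptake_rate("BH", st, p), "RI and FP")
})

test_that("BH partial rates sum to the BH growth rate on random states", {
  p <- toy_params()
  set.seed(42)
  for (i in 1:25) {
    st <- initial_state(
      X = c(RI = runif(1, 0, 5), FP = runif(1, 0, 5), BH = runif(1, 0, 5)),
      S = stats::setNames(runif(7, 0, 60), model_metabolites()),
      Q0 = stats::setNames(runif(3, 0.01, 5), strain_ids()))
    pr <- bh_partial_rates(st, p)
    expect_equal(unname(pr[["fructose"]] + pr[["formate"]]),
                 growth_rate("BH", st, p), tolerance = 1e-12)
  }
  st0 <- toy_state(); st0[["S_formate"]] <- 0
  expect_identical(bh_partial_rates(st0, p)[["formate"]], 0)
  st0[["S_fructose"]] <- 0
  expect_identical(unname(bh_partial_rates(st0, p)), c(0, 0))
})

test_that("ode_rhs matches a term-by-term hand evaluation", {
  p <- unclass(toy_params())
  st <- toy_state()
  # independent arithmetic: every printed equation written out explicitly
  gRI <- 0.5 / 1.5; gFP <- 2 / 3; gBH <- 0.5
  mf_RI <- 30 / (10 + 30); ma_RI <- 12 / (5 + 12)
  mu_u <- 20 / (4 + 20); mf_FP <- 30 / (8 + 30); ma_FP <- 12 / (6 + 12)
  mf_BH <- 30 / (12 + 30); mfo_BH <- 4 / (9 + 4)
  phiRI <- gRI * 0.5 * mf_RI * (1 + 0.4 * ma_RI)
  phiFP <- gFP * 0.6 * mu_u * mf_FP * (1 + 0.5 * ma_FP)
  phiBH_f <- gBH * 0.45 * mf_BH
  phiBH_fo <- gBH * 0.45 * 1.1 * mfo_BH
  phiBH <- phiBH_f + phiBH_fo
  phiRI_a <- gRI * 0.5 * 0.4 * mf_RI * ma_RI
  phiFP_a <- gFP * 0.6 * 0.5 * mu_u * mf_FP * ma_FP
  expected <- c(
    X_RI = phiRI * 1.2, X_FP = phiFP * 0.7, X_BH = phiBH * 0.4,
    Q_RI = 0.5 * 0.5, Q_FP = 0.6 * 2, Q_BH = 0.45 * 1,
    S_fructose = -5 * phiRI * 1.2 - 4 * phiFP * 0.7 - 4 * phiBH_f * 0.4,
    S_formate = 1 * phiRI * 1.2 + 2 * phiFP * 0.7 - 6 * phiBH_fo * 0.4,
    S_acetate = -2 * phiRI_a * 1.2 - 1 * phiFP_a * 0.7 + 3 * phiBH * 0.4,
    S_butyrate = 6 * phiRI * 1.2 + 3 * phiFP * 0.7,
    S_unknown = -2 * phiFP * 0.7,
    S_H2 = 8 * phiRI * 1.2 + 2 * phiBH * 0.4,
    S_CO2 = 9 * phiRI * 1.2 + 2 * phiFP * 0.7 + 2 * phiBH * 0.4)
  expect_equal(ode_rhs(st, toy_params()), expected, tolerance = 1e-12)
})

test_that("ode_rhs degenerate cases: no biomass, zero yields, sign structure", {
  p <- toy_params()
  st <- toy_state()
  st0 <- st; st0[c("X_RI", "X_FP", "X_BH")] <- 0
  d0 <- ode_rhs(st0, p)
  expect_true(all(d0[grep("^S_", names(d0))] == 0))
  expect_true(all(d0[c("X_RI", "X_FP", "X_BH")] == 0))
  expect_true(all(d0[c("Q_RI", "Q_FP", "Q_BH")] > 0))

  pz <- unclass(p)
  pz[grep("^(nu|alpha)\\.", names(pz))] <- 0
  dz <- ode_rhs(st, model_parameters(pz))
  expect_true(all(dz[grep("^S_", names(dz))] == 0))
  expect_true(all(dz[c("X_RI", "X_FP", "X_BH")] > 0))

  # fixed signs: butyrate never consumed, unknown never produced
  set.seed(7)
  for (i in 1:20) {
    sti <- initial_state(
      X = c(RI = runif(1, 0, 5), FP = runif(1, 0, 5), BH = runif(1, 0, 5)),
      S = stats::setNames(runif(7, 0, 50), model_metabolites()),
      Q0 = stats::setNames(runif(3, 0.1, 3), strain_ids()))
    d <- ode_rhs(sti, p)
    expect_gte(d[["S_butyrate"]], 0)
    expect_lte(d[["S_unknown"]], 0)
    expect_true(all(d[c("X_RI", "X_FP", "X_BH")] >= 0))
  }
})

test_that("negative substrate excursions are clipped, not fatal", {
  p <- toy_params()
  st <- toy_state()
  st_neg <- unclass(st)
  st_neg[["S_fructose"]] <- -1e-9
  d <- syngut:::rhs_core(as.numeric(st_neg), unclass(p))
  expect_true(all(is.finite(d)))
})
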