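make_mono_obs <- function(times, counts, variable = "X_RI") {
  data.frame(time_h = times, variable = variable, replicate = 1L,
             value = counts)
}

test_that("decline exclusion flags post-peak samples below 90% of peak", {
  obs <- make_mono_obs(1:5, c(1, 5, 9, 8.0, 4))
  e <- fermentation_experiment("d", "RI", c(fructose = 50), c(RI = 1), obs)
  out <- exclude_decline(e)$observations
  # peak 9 at t=3; 8.0 < 8.1 and 4 < 8.1 are declining
  expect_identical(out$excluded[order(out$time_h)],
                   c(FALSE, FALSE, FALSE, TRUE, TRUE))
  expect_match(out$exclude_reason[out$time_h == 4], "decline")

  # monotone series: nothing excluded
  e2 <- fermentation_experiment("m", "RI", c(fructose = 50), c(RI = 1),
                                make_mono_obs(1:5, c(1, 2, 4, 7, 9)))
  expect_false(any(exclude_decline(e2)$observations$excluded))

  # post-peak plateau above 90% of peak is not decline
  e3 <- fermentation_experiment("p", "RI", c(fructose = 50), c(RI = 1),
                                make_mono_obs(1:5, c(1, 5, 10, 9.5, 9.2)))
  expect_false(any(exclude_decline(e3)$observations$excluded))

  # metabolites are retained unless explicitly dropped
  obs4 <- rbind(make_mono_obs(1:5, c(1, 5, 9, 8, 4)),
                make_mono_obs(1:5, c(50, 40, 20, 10, 5), "S_fructose"))
  e4 <- fermentation_experiment("mm", "RI", c(fructose = 50), c(RI = 1), obs4)
  out4 <- exclude_decline(e4)$observations
  expect_false(any(out4$excluded[out4$variable == "S_fructose"]))
  out5 <- exclude_decline(e4, drop_metabolites = TRUE)$observations
  expect_true(all(out5$excluded[out5$variable == "S_fructose" &
                                  out5$time_h %in% 4:5]))
})

test_that("normalized RMSE matches hand arithmetic and its invariances", {
  # single variable, max 10, residuals +1 and -1 at two times -> 0.1
  obs <- make_mono_obs(c(1, 2), c(10, 4))
  e <- fermentation_experiment("h", "RI", c(fructose = 50), c(RI = 1), obs)
  traj <- structure(data.frame(time = c(0, 1, 2), X_RI = c(0, 11, 3)),
                    class = c("community_trajectory", "data.frame"))
  expect_equal(normalized_rmse(traj, e), 0.1)

  # scaling data and model of one variable by 10 leaves it unchanged
  e10 <- fermentation_experiment("h10", "RI", c(fructose = 50), c(RI = 1),
                                 make_mono_obs(c(1, 2), c(100, 40)))
  traj10 <- structure(data.frame(time = c(0, 1, 2), X_RI = c(0, 110, 30)),
                      class = c("community_trajectory", "data.frame"))
  expect_equal(normalized_rmse(traj10, e10), 0.1)

  # exact model -> 0
  e0 <- fermentation_experiment("z", "RI", c(fructose = 50), c(RI = 1),
                                make_mono_obs(c(1, 2), c(11, 3)))
  expect_equal(normalized_rmse(traj, e0), 0)

  # an all-zero variable is skipped with a warning
  obs_z <- rbind(make_mono_obs(c(1, 2), c(10, 4)),
                 make_mono_obs(c(1, 2), c(0, 0), "S_H2"))
  ez <- fermentation_experiment("w", "RI", c(fructose = 50), c(RI = 1), obs_z)
  trajz <- structure(
    data.frame(time = c(0, 1, 2), X_RI = c(0, 11, 3), S_H2 = c(0, 0, 0)),
    class = c("community_trajectory", "data.frame"))
  expect_warning(v <- normalized_rmse(trajz, ez), "all-zero")
  expect_equal(v, 0.1)

  # excluded rows do not contribute
  obs_ex <- make_mono_obs(c(1, 2), c(10, 4))
  obs_ex$excluded <- c(FALSE, TRUE)
  eex <- fermentation_experiment("x", "RI", c(fructose = 50), c(RI = 1),
                                 obs_ex)
  expect_equal(normalized_rmse(traj, eex), 0.1)  # single residual 1/10
})

test_that("an empty free mask returns the initial point with its objective", {
  study <- generate_study(fixture_params(), noiseless(5),
                          designs = study_designs()["RI_1"])
  fit <- fit_parameters(study, character(0), fixture_params(),
                        Q0_init = list(RI_1 = study$RI_1$truth$Q0))
  expect_identical(unclass(fit$params), unclass(fixture_params()))
  expect_lt(fit$objective, 1e-5)
  expect_identical(fit$free, character(0))
})

test_that("a low-dimensional noise-free fit recovers mu and K", {
  truth <- fixture_params()
  study <- generate_study(truth, noiseless(5),
                          designs = study_designs()["RI_1"])
  init <- unclass(truth)
  init[["mu.RI"]] <- init[["mu.RI"]] * 1.4
  init[["K.RI.fructose"]] <- init[["K.RI.fructose"]] * 0.6
  fit <- fit_parameters(study, c("mu.RI", "K.RI.fructose"),
                        model_parameters(init),
                        Q0_init = list(RI_1 = study$RI_1$truth$Q0),
                        control = list(maxit = 400, restarts = 2))
  expect_lt(abs(unclass(fit$params)[["mu.RI"]] /
                  unclass(truth)[["mu.RI"]] - 1), 0.05)
  expect_lt(abs(unclass(fit$params)[["K.RI.fructose"]] /
                  unclass(truth)[["K.RI.fructose"]] - 1), 0.20)
  expect_lte(fit$objective, fit$trace[1])
})

test_that("enlarging the restart budget never worsens the result", {
  truth <- fixture_params()
  study <- generate_study(truth, noiseless(6),
                          designs = study_designs()["FP_1"])
  init <- unclass(truth)
  init[["mu.FP"]] <- init[["mu.FP"]] * 1.3
  init[["nu.FP.fructose"]] <- init[["nu.FP.fructose"]] * 0.8
  init <- model_parameters(init)
  free <- c("mu.FP", "nu.FP.fructose", "Q0.FP_1.FP")
  f1 <- suppressWarnings(fit_parameters(study, free, init,
                       control = list(maxit = 60, restarts = 1)))
  f2 <- suppressWarnings(fit_parameters(study, free, init,
                       control = list(maxit = 60, restarts = 3)))
  expect_lte(f2$objective, f1$objective)
  # determinism: identical inputs give identical results
  f1b <- suppressWarnings(fit_parameters(study, free, init,
                        control = list(maxit = 60, restarts = 1)))
  expect_identical(f1$objective, f1b$objective)
  expect_identical(unclass(f1$params), unclass(f1b$params))
})

test_that("a non-finite objective at the start names the experiment", {
  study <- generate_study(fixture_params(), noiseless(7),
                          designs = study_designs()["RI_1"])
  bad <- unclass(fixture_params())
  bad[["mu.RI"]] <- 1e8   # Q explodes; integration fails at the start
  suppressWarnings(expect_error(
    fit_parameters(study, "K.RI.fructose", model_parameters(bad)),
    "RI_1"))
})

test_that("Q0 estimation recovers lags and flags degenerate data", {
  truth <- fixture_params()
  # design lag 1.98 h -> Q0 = exp(-0.35 * 1.98) = 0.50
  des <- experiment_design("q", "RI", c(fructose = 50, acetate = 50),
                           c(RI = 0.06), c(RI = 1.98))
  e <- generate_experiment(truth, des, noiseless(3))
  est <- estimate_Q0(e, "RI", truth)
  expect_lt(abs(est$Q0 / 0.5 - 1), 0.25)
  expect_false(est$at_bound)

  # no lag (Q0 = 5 > 1, negative lag) -> estimate above 1
  des2 <- experiment_design("q2", "RI", c(fructose = 50, acetate = 50),
                            c(RI = 0.06),
                            c(RI = lag_from_Q0(5, 0.35)))
  e2 <- generate_experiment(truth, des2, noiseless(3))
  est2 <- estimate_Q0(e2, "RI", truth)
  expect_gt(est2$Q0, 1)
  expect_lt(est2$lag, 0)

  # constant counts carry no lag signal: bound hit with a warning
  e3 <- fermentation_experiment(
    "q3", "RI", c(fructose = 50), c(RI = 1),
    make_mono_obs(c(1, 5, 10, 20), rep(1, 4)))
  expect_warning(est3 <- estimate_Q0(e3, "RI", truth), "bound")
  expect_true(est3$at_bound)

  expect_error(estimate_Q0(
    fermentation_experiment("q4", "RI", c(fructose = 50), c(RI = 1),
                            make_mono_obs(c(1, 2), c(1, 2))),
    "RI", truth), "at least 3")
})

test_that("the monoculture protocol fits each strain on its own cultures", {
  truth <- fixture_params()
  study <- generate_study(truth, noiseless(8),
                          designs = study_designs()[c("RI_1", "FP_1", "BH_1")])
  study <- lapply(study, exclude_decline)
  init <- perturb_params(truth, 1.1)
  fit <- suppressWarnings(
    parameterization1(study, init, control = list(maxit = 150, restarts = 0)))
  expect_named(fit$stages, c("RI", "FP", "BH"))
  expect_lte(fit$objective, mean(vapply(
    study, function(e) {
      f <- suppressWarnings(fit_parameters(list(e), character(0), init))
      f$objective
    }, numeric(1))))
  expect_error(parameterization1(study["RI_1"], init), "no monoculture")
})

test_that("the model fits its own dynamics far better than biphasic growth", {
  truth <- fixture_params()
  # (a) data generated by the model itself
  good <- generate_study(truth, noiseless(9),
                         designs = study_designs()["BH_1"])$BH_1
  # (b) biphasic data: 10 h of growth on hidden medium components with no
  # formate/fructose consumption, then the Monod dynamics kick in
  bi <- good
  o <- bi$observations
  t_sw <- 10
  early <- o$time_h <= t_sw
  xbh <- o$variable == "X_BH"
  x0 <- 0.05
  o$value[xbh & early] <- x0 * exp(0.25 * o$time_h[xbh & early])
  for (v in c("S_fructose", "S_formate")) {
    sel <- o$variable == v & early
    o$value[sel] <- o$value[o$variable == v & o$time_h == min(o$time_h)][1]
  }
  bi$observations <- o
  init <- perturb_params(truth, 1.1)
  free <- c(free_keys_for_test("BH"), "Q0.BH_1.BH")
  ctrl <- list(maxit = 600, restarts = 1)
  f_good <- suppressWarnings(
    fit_parameters(list(BH_1 = good), free, init, control = ctrl))
  f_bi <- suppressWarnings(
    fit_parameters(list(BH_1 = bi), free, init, control = ctrl))
  expect_lt(f_good$objective * 3, f_bi$objective)
})

test_that("the staged protocol runs, permutes with a warning, and predicts held-out designs", {
  truth <- fixture_params()
  study <- generate_study(truth, noiseless(10),
    designs = study_designs()[c("FP_1", "FP_2", "FP_BH_1", "FP_BH_2",
                                "RI_BH_1", "RI_BH_2")])
  study <- lapply(study, exclude_decline)
  init <- perturb_params(truth, 1.05)
  ctrl <- list(maxit = 120, restarts = 0)
  fit <- suppressWarnings(parameterization2(study, init, control = ctrl))
  expect_named(fit$stages, c("FP_monocultures", "BH_yields", "BH_kinetics",
                             "RI_biculture"))
  # held-out no-acetate bi-culture predicted without refitting
  held <- study$RI_BH_2
  pred <- fit_parameters(list(RI_BH_2 = held), character(0), fit$params,
                         Q0_init = list(RI_BH_2 = held$truth$Q0))
  expect_lt(pred$objective, 0.5)

  expect_warning(
    suppressMessages(parameterization2(study, init, control = ctrl,
                                       stage_order = c(2, 1, 3, 4))),
    "deviates")
  expect_error(parameterization2(study, init, stage_order = c(1, 1, 2, 3)),
               "permutation")
  expect_error(parameterization2(study["FP_1"], init), "staged protocol")
})
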