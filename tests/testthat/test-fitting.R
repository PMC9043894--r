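test_that("r_squared follows 1 - SS_res/SS_tot about the mean", {
  obs <- c(3, 1, 4, 1, 5, 9)
  expect_equal(r_squared(obs, obs), 1.0)
  expect_equal(r_squared(obs, rep(mean(obs), 6)), 0.0)
  # frozen hand computation on a fixed 6-point toy pair:
  # pred = obs + c(1,-1,0,2,-2,1); SS_res = 11, SS_tot = 269/6
  pred <- obs + c(1, -1, 0, 2, -2, 1)
  expect_equal(r_squared(obs, pred), 1 - 11 / (269 / 6),
               tolerance = 1e-12)
  expect_error(r_squared(rep(2, 5), rep(2, 5)), "zero variance")
  expect_error(r_squared(1:3, 1:4), "equal length")
})

test_that("initial_guess lands near truth and flags degenerate data", {
  d <- noiseless_table(15.92, 362.61, 0.2072)
  g <- initial_guess(d, "plateau")
  expect_true(g$Y0 > 15.92 / 3 && g$Y0 < 15.92 * 3)
  expect_true(g$a > 362.61 / 3 && g$a < 362.61 * 3)
  expect_true(g$b > 0.2072 / 3 && g$b < 0.2072 * 3)
  expect_false(attr(g, "degenerate"))

  const <- data.frame(t = default_schedule(), y = 7)
  gc <- initial_guess(const, "plateau")
  expect_equal(gc$Y0, 7)
  expect_equal(gc$a, 1e-6)
  expect_true(attr(gc, "degenerate"))

  expect_error(initial_guess(data.frame(t = c(0, 1), y = c(5, 3)),
                             "first_order"), "insufficient")
})

test_that("fit_model recovers noiseless truths exactly and is invariant
           to row order", {
  # first-order truth
  d_fo <- noiseless_table(0, 370.36, 0.1199)
  f <- fit_model(d_fo, "first_order")
  expect_true(f$converged)
  expect_equal(f$params$a, 370.36, tolerance = 1e-6)
  expect_equal(f$params$b, 0.1199, tolerance = 1e-6)
  expect_equal(f$r_squared, 1.0, tolerance = 1e-9)
  expect_equal(f$dt50_days, log(2) / f$params$b)

  # plateau truth (sterilized-soil parameters)
  d_pl <- noiseless_table(48.82, 302.95, 0.0827)
  fp <- fit_model(d_pl, "plateau")
  expect_equal(fp$params$Y0, 48.82, tolerance = 1e-6)
  expect_equal(fp$params$a, 302.95, tolerance = 1e-6)
  expect_equal(fp$params$b, 0.0827, tolerance = 1e-6)
  expect_equal(fp$r_squared, 1.0, tolerance = 1e-9)

  set.seed(4)
  shuffled <- d_pl[sample(nrow(d_pl)), ]
  fs <- fit_model(shuffled, "plateau")
  expect_equal(fs$params$b, fp$params$b, tolerance = 1e-9)
  expect_identical(fs$fingerprint, fp$fingerprint)

  # degenerate data are flagged, not fitted
  dz <- data.frame(t = default_schedule(), y = 5)
  fz <- fit_model(dz, "plateau")
  expect_false(fz$converged)
  expect_match(fz$note, "degenerate")
})

test_that("fitted SS matches an independent grid-search oracle on a toy
           dataset", {
  p <- plateau_params(2, 8, 0.5)
  t <- c(0, 1, 2, 4, 8)
  set.seed(21)
  y <- eval_plateau(p, t) + c(0.3, -0.2, 0.1, -0.3, 0.2)
  fit <- fit_model(data.frame(t = t, y = y), "plateau")
  oracle <- grid_search_plateau(t, y, c(0, 5), c(4, 12), c(0.05, 1.5))
  # optimizer must do at least as well as the grid's attainable precision
  expect_lte(fit$ss_res, oracle$ss + 1e-6)
  expect_equal(fit$params$Y0, oracle$par[1], tolerance = 5e-3)
  expect_equal(fit$params$b, oracle$par[3], tolerance = 5e-3)
})

test_that("regression p-value behaves like its F construction", {
  # perfect fit underflows
  f <- fit_model(noiseless_table(0, 370.36, 0.1199), "first_order")
  expect_lt(f$p_value, 1e-16)

  # strong-signal simulation: p < 1e-4 in virtually all runs
  ps <- vapply(1:50, function(s) {
    fit_model(sim_one(15.92, 362.61, 0.2072, seed = s),
              "first_order")$p_value
  }, 0)
  expect_gte(mean(ps < 1e-4), 0.99)
})

test_that("regression F test is valid (not anti-conservative) under a
           pure-noise null", {
  # The model is bounded monotone-decreasing, so on trendless noise it
  # often collapses to a flat curve: the test is conservative, and the
  # null rejection rate must not exceed the nominal band.
  sched <- default_schedule()
  set.seed(99)
  ps <- vapply(1:400, function(i) {
    d <- data.frame(t = sched, y = rnorm(18, 100, 10))
    fit_model(d, "first_order", n_starts = 2L)$p_value
  }, 0)
  expect_lte(mean(ps < 0.05), 0.07)
  expect_gte(median(ps), 0.3) # p values pile up high, never low
})

test_that("compare_models applies nesting and the parsimony tie-break", {
  # plateau truth with a large residual plateau -> plateau preferred
  d <- sim_one(83.58, 266.69, 0.0976, seed = 10, noise_cv = 0.05)
  fo <- fit_model(d, "first_order")
  pl <- fit_model(d, "plateau")
  cm <- compare_models(fo, pl)
  expect_identical(cm$preferred, "plateau")
  expect_equal(cm$delta_r2, cm$r2_plateau - cm$r2_first_order)

  # noiseless first-order truth: the nested models coincide
  dz <- noiseless_table(0, 300, 0.1)
  cm0 <- compare_models(fit_model(dz, "first_order"),
                        fit_model(dz, "plateau"))
  expect_equal(cm0$delta_r2, 0, tolerance = 1e-9)
  expect_identical(cm0$preferred, "first_order")

  # mismatched data are rejected
  d2 <- sim_one(83.58, 266.69, 0.0976, seed = 11, noise_cv = 0.05)
  expect_error(compare_models(fit_model(d2, "first_order"), pl),
               "identical data")
  expect_error(compare_models(pl, pl), "first-order and a plateau")
})

test_that("nesting invariant: plateau R2 >= first-order R2 on simulated
           data", {
  for (s in 1:20) {
    set.seed(s)
    d <- sim_one(runif(1, 0, 100), runif(1, 150, 400),
                 runif(1, 0.03, 0.3), seed = s)
    fo <- fit_model(d, "first_order")
    pl <- fit_model(d, "plateau")
    expect_lte(pl$ss_res, fo$ss_res + 1e-9 * fo$ss_tot)
  }
})

test_that("fits are scale-equivariant", {
  d <- sim_one(48.82, 302.95, 0.0827, seed = 5, noise_cv = 0.05)
  f1 <- fit_model(d, "plateau")
  d2 <- d
  d2$concentration_ng_per_g <- d2$concentration_ng_per_g * 3.7
  f2 <- fit_model(d2, "plateau")
  expect_equal(f2$params$Y0, 3.7 * f1$params$Y0, tolerance = 1e-4)
  expect_equal(f2$params$a, 3.7 * f1$params$a, tolerance = 1e-4)
  expect_equal(f2$params$b, f1$params$b, tolerance = 1e-4)
  expect_equal(f2$r_squared, f1$r_squared, tolerance = 1e-6)
  expect_equal(f2$p_value, f1$p_value, tolerance = 1e-4)
})

test_that("per-time-point means option reduces n_obs and near-zero Y0 is
           snapped to the boundary", {
  d <- sim_one(0, 300, 0.12, seed = 2, noise_cv = 0.05)
  fm <- fit_model(d, "plateau", use_means = TRUE)
  expect_equal(fm$n_obs, 18)
  fr <- fit_model(d, "plateau")
  expect_equal(fr$n_obs, 54)

  dz <- noiseless_table(0, 300, 0.1)
  fz <- fit_model(dz, "plateau")
  expect_identical(fz$params$Y0, 0)
  expect_match(fz$note, "coincide")
})
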