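# Build a long measurement table for arbitrary toy designs.
toy_table <- function(Y, grp, times = seq_len(ncol(Y))) {
  n <- nrow(Y); k <- ncol(Y)
  data.frame(condition_id = rep(paste0("g", grp), each = k),
             soil_site = rep(paste0("g", grp), each = k),
             temperature_C = 25, water_content_pct = 33,
             sterilized = FALSE,
             replicate = rep(stats::ave(seq_len(n), grp,
                                        FUN = seq_along), each = k),
             time_days = rep(times, n),
             concentration_ng_per_g = as.vector(t(Y)))
}

test_that("split-plot SS, df and F match a brute-force cell-mean
           oracle on a toy 2-group x 3-time x 2-subject design", {
  Y <- rbind(c(10, 7, 4), c(12, 8, 7),   # group 1
             c(20, 15, 9), c(18, 13, 11)) # group 2
  grp <- c(1, 1, 2, 2)
  tab <- toy_table(Y, grp)
  a <- rm_anova(tab, between = "soil_site", max_poly_order = 2)

  oracle <- brute_split_plot(
    y = as.vector(t(Y)), grp = rep(grp, each = 3),
    subj = rep(1:4, each = 3), time = rep(1:3, 4))

  bt <- a$between
  expect_equal(bt$ss[bt$effect == "soil_site"], oracle$grp[["ss"]])
  expect_equal(bt$df[bt$effect == "soil_site"], oracle$grp[["df"]])
  expect_equal(bt$F[bt$effect == "soil_site"], oracle$grp[["F"]])
  expect_equal(bt$ss[bt$effect == "Residuals"],
               oracle$subj_within[["ss"]])

  wt <- a$within
  expect_equal(wt$ss[wt$effect == "time"], oracle$time[["ss"]])
  expect_equal(wt$F[wt$effect == "time"], oracle$time[["F"]])
  expect_equal(wt$ss[wt$effect == "soil_site:time"],
               oracle$grp_time[["ss"]])
  expect_equal(wt$F[wt$effect == "soil_site:time"],
               oracle$grp_time[["F"]])
  expect_equal(wt$ss[wt$effect == "Residuals"], oracle$residual[["ss"]])
  expect_equal(wt$df[wt$effect == "Residuals"], oracle$residual[["df"]])
})

test_that("within-subject SS partition sums to the total within-subject
           SS and SS are non-negative", {
  sim <- simulate_dataset(simulation_config(
    truth = default_truth_set(sites = c("Gongzhuling", "Jinan"),
                              include_sterilized = FALSE), seed = 8))
  a <- rm_anova(sim, between = c("soil_site", "temperature_C",
                                 "water_content_pct"))
  ser <- btdecay:::as_subject_series(sim)
  total_within <- sum(sweep(ser$Y, 1, rowMeans(ser$Y))^2)
  expect_equal(sum(a$within$ss), total_within,
               tolerance = 1e-8)
  expect_true(all(a$within$ss >= 0))
  expect_true(all(a$between$ss >= 0))
  expect_true(a$gg_epsilon >= 1 / (a$n_time_levels - 1) &&
                a$gg_epsilon <= 1)
})

test_that("between-subject stratum equals a factorial ANOVA of
           time-averaged responses (scaled by k)", {
  sim <- simulate_dataset(simulation_config(
    truth = default_truth_set(sites = "Gongzhuling",
                              include_sterilized = FALSE), seed = 12))
  a <- rm_anova(sim, between = c("temperature_C", "water_content_pct"))
  ser <- btdecay:::as_subject_series(sim)
  d <- data.frame(m = rowMeans(ser$Y),
                  temp = factor(ser$meta$temperature_C),
                  wat = factor(ser$meta$water_content_pct))
  ref <- as.data.frame(stats::anova(stats::aov(m ~ temp * wat, d)))
  k <- a$n_time_levels
  expect_equal(a$between$ss[a$between$effect == "temperature_C"],
               k * ref["temp", "Sum Sq"])
  expect_equal(a$between$F[a$between$effect == "temperature_C"],
               ref["temp", "F value"])
  expect_equal(a$between$p[a$between$effect == "temperature_C"],
               ref["temp", "Pr(>F)"])
  expect_equal(
    a$between$ss[a$between$effect == "temperature_C:water_content_pct"],
    k * ref["temp:wat", "Sum Sq"])
})

test_that("GG epsilon is 1 for exactly compound-symmetric within-cell
           covariance", {
  # 4 subjects x 3 times, deviations with orthonormal mean-zero columns:
  # sample covariance = I/3 (compound symmetric), so epsilon must be 1.
  H <- cbind(c(1, -1, 0, 0) / sqrt(2),
             c(1, 1, -2, 0) / sqrt(6),
             c(1, 1, 1, -3) / sqrt(12))
  Y <- matrix(50, 4, 3) + H
  eps <- btdecay:::.gg_epsilon(Y, factor(rep(1, 4)))
  expect_equal(eps, 1, tolerance = 1e-6)
})

test_that("constant responses give zero effect SS", {
  Y <- matrix(5, nrow = 4, ncol = 3)
  tab <- toy_table(Y, c(1, 1, 2, 2))
  a <- rm_anova(tab, between = "soil_site", max_poly_order = 2)
  expect_equal(sum(a$within$ss), 0)
  expect_equal(sum(a$between$ss), 0)
  expect_true(is.na(a$gg_epsilon))
})

test_that("permuting subject labels within cells leaves the table
           unchanged", {
  set.seed(31)
  Y <- matrix(rnorm(8 * 5, 100, 10), 8, 5)
  grp <- rep(1:2, each = 4)
  a1 <- rm_anova(toy_table(Y, grp), between = "soil_site",
                 max_poly_order = 3)
  perm <- c(4, 2, 1, 3, 7, 8, 5, 6) # permutes subjects within groups
  a2 <- rm_anova(toy_table(Y[perm, ], grp), between = "soil_site",
                 max_poly_order = 3)
  expect_equal(a1$between$ss, a2$between$ss)
  expect_equal(a1$within$F, a2$within$F)
  expect_equal(a1$gg_epsilon, a2$gg_epsilon)
  expect_equal(a1$contrasts$F, a2$contrasts$F)
})

test_that("incomplete series are excluded with a warning and empty
           designs error", {
  sim <- simulate_dataset(simulation_config(
    truth = default_truth_set(sites = "Gongzhuling",
                              include_sterilized = FALSE), seed = 2))
  broken <- sim[!(sim$condition_id == "Gongzhuling_T15_W20" &
                    sim$replicate == 1 & sim$time_days == 0), ]
  expect_warning(a <- rm_anova(broken,
                               between = c("temperature_C",
                                           "water_content_pct")),
                 "incomplete")
  expect_equal(a$n_subjects, 26)
  one_subj <- sim[sim$replicate == 1, ]
  expect_error(rm_anova(one_subj, between = c("temperature_C",
                                              "water_content_pct")),
               ">= 2 subjects")
})

test_that("polynomial contrasts decompose the time trend", {
  k <- 6
  C <- stats::contr.poly(k)
  # construction: orthonormal columns
  expect_equal(crossprod(C), diag(k - 1), tolerance = 1e-12,
               ignore_attr = TRUE)

  # exactly linear-in-rank responses: linear contrast captures all time
  # SS, higher orders are null
  n <- 6
  Y <- outer(rep(1, n), seq_len(k) * 2) +
    matrix(rep(rnorm(n, 0, 1), k), n, k) # subject shifts only
  tab <- toy_table(Y, rep(1:2, each = 3))
  ct <- polynomial_time_contrasts(tab, between = "soil_site",
                                  max_order = 3)
  a <- rm_anova(tab, between = "soil_site", max_poly_order = 3)
  ss_time <- a$within$ss[a$within$effect == "time"]
  expect_equal(ct$ss[ct$label == "linear"], ss_time, tolerance = 1e-8)
  expect_equal(ct$ss[ct$label == "quadratic"], 0, tolerance = 1e-8)
  expect_equal(ct$ss[ct$label == "cubic"], 0, tolerance = 1e-8)

  expect_error(polynomial_time_contrasts(tab, between = "soil_site",
                                         max_order = 6),
               "below the number of time levels")
})

test_that("plateau-shaped mean curves yield significant low-order
           contrasts in most simulations", {
  # reference-site design: 9 conditions x 3 replicates, CV 10%
  hits <- vapply(1:30, function(s) {
    sim <- simulate_dataset(simulation_config(
      truth = default_truth_set(sites = "Gongzhuling",
                                include_sterilized = FALSE),
      seed = 4000 + s))
    ct <- polynomial_time_contrasts(
      sim, between = c("temperature_C", "water_content_pct"),
      max_order = 3)
    all(ct$p < 0.01)
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("metric-spaced contrasts differ from rank-spaced ones but
           keep orthonormality", {
  sim <- sim_one(20, 300, 0.15, seed = 3)
  cr <- polynomial_time_contrasts(sim, between = character(0),
                                  max_order = 2, metric_time = FALSE)
  cm <- polynomial_time_contrasts(sim, between = character(0),
                                  max_order = 2, metric_time = TRUE)
  expect_false(isTRUE(all.equal(cr$F, cm$F)))
  C <- stats::contr.poly(18, scores = default_schedule())
  expect_equal(crossprod(C), diag(17), tolerance = 1e-10,
               ignore_attr = TRUE)
})
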