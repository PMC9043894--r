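# Shared fixtures and independent oracles, all built in code.

# Printed first-order (b, DT50) pairs and plateau parameter sets from the
# published per-condition tables (reference site, plus the sterilized /
# unsterilized pair).
table2_first_order <- data.frame(
  condition = c("15C_20", "15C_33", "15C_50", "25C_20", "25C_33",
                "25C_50", "35C_20", "35C_33", "35C_50"),
  a = c(336.25, 346.22, 319.48, 370.36, 351.53, 310.77, 375.38, 372.06,
        347.45),
  b = c(0.046, 0.0661, 0.0378, 0.1199, 0.1146, 0.0747, 0.1861, 0.201,
        0.0742),
  dt50_printed = c(15.1, 10.5, 18.3, 5.8, 6.1, 9.3, 3.7, 3.5, 9.3),
  dt50_digits = 1)

table3_first_order <- data.frame(
  condition = c("sterilized", "nonsterilized"),
  a = c(346.34, 347.45),
  b = c(0.059, 0.0742),
  dt50_printed = c(11.75, 9.34),
  dt50_digits = 2)

table2_plateau <- data.frame(
  condition = c("15C_20", "15C_33", "15C_50", "25C_20", "25C_33",
                "25C_50", "35C_20", "35C_33", "35C_50"),
  Y0 = c(83.58, 74.37, 87.33, 22.09, 44.53, 51.36, 15.92, 11.92, 4.58),
  a = c(266.69, 286.73, 246.25, 352.16, 319.43, 274.35, 362.61, 362.25,
        343.26),
  b = c(0.0976, 0.1291, 0.0873, 0.1399, 0.1739, 0.1369, 0.2072, 0.2168,
        0.0762))

# Noiseless measurement table from one plateau truth on a schedule.
noiseless_table <- function(Y0, a, b, schedule = default_schedule(),
                            replicates = 3, cid = "cond1") {
  p <- plateau_params(Y0 = Y0, a = a, b = b)
  data.frame(condition_id = cid,
             soil_site = "SiteA", temperature_C = 25,
             water_content_pct = 33, sterilized = FALSE,
             replicate = rep(seq_len(replicates), each = length(schedule)),
             time_days = rep(schedule, replicates),
             concentration_ng_per_g = rep(eval_plateau(p, schedule),
                                          replicates))
}

# One simulated table for a single condition with arbitrary truth.
sim_one <- function(Y0, a, b, seed, noise_cv = 0.10, noise_floor_sd = 2,
                    replicates = 3) {
  truth <- data.frame(condition_id = "c1", soil_site = "S",
                      temperature_C = 25, water_content_pct = 33,
                      sterilized = FALSE, Y0 = Y0, a = a, b = b)
  simulate_dataset(simulation_config(
    truth = truth, replicates = replicates, noise_cv = noise_cv,
    noise_floor_sd = noise_floor_sd, seed = seed))
}

# Independent multi-stage grid-search minimizer of the plateau-model SS,
# refined down to a final resolution of 1e-3 on every parameter.
grid_search_plateau <- function(t, y, Y0_range, a_range, b_range,
                                final_res = 1e-3) {
  best <- c(mean(Y0_range), mean(a_range), mean(b_range))
  widths <- c(diff(Y0_range), diff(a_range), diff(b_range)) / 2
  repeat {
    g <- expand.grid(
      Y0 = pmax(0, seq(best[1] - widths[1], best[1] + widths[1],
                       length.out = 21)),
      a = pmax(1e-9, seq(best[2] - widths[2], best[2] + widths[2],
                         length.out = 21)),
      b = pmax(1e-6, seq(best[3] - widths[3], best[3] + widths[3],
                         length.out = 21)))
    ss <- vapply(seq_len(nrow(g)), function(i)
      sum((y - (g$Y0[i] + g$a[i] * exp(-g$b[i] * t)))^2), 0)
    best <- as.numeric(g[which.min(ss), ])
    if (all(widths / 10 < final_res / 2)) break
    widths <- widths / 10
  }
  list(par = best, ss = min(ss))
}

# Brute-force split-plot sums of squares by cell-mean arithmetic, for a
# single between factor 'grp'. Independent of the package's ANOVA path.
brute_split_plot <- function(y, grp, subj, time) {
  grp <- factor(grp); subj <- factor(subj); time <- factor(time)
  k <- nlevels(time); n <- nlevels(subj); g <- nlevels(grp)
  grand <- mean(y)
  m_subj <- tapply(y, subj, mean)
  m_grp <- as.vector(tapply(y, grp, mean))
  m_time <- as.vector(tapply(y, time, mean))
  m_gt <- matrix(tapply(y, list(grp, time), mean), g, k)
  grp_of_subj <- tapply(as.integer(grp), subj, function(v) v[1])
  n_per_grp <- table(grp_of_subj)

  ss_grp <- k * sum(n_per_grp * (m_grp - grand)^2)
  ss_subj_within <- k * sum((m_subj - m_grp[grp_of_subj])^2)
  ss_time <- n * sum((m_time - grand)^2)
  ss_gt <- sum(rep(n_per_grp, k) *
                 (t(t(m_gt) - m_time) - (m_grp - grand))^2)
  ss_tot <- sum((y - grand)^2)
  ss_res <- ss_tot - ss_grp - ss_subj_within - ss_time - ss_gt

  df_grp <- g - 1; df_subj <- n - g
  df_time <- k - 1; df_gt <- (g - 1) * (k - 1)
  df_res <- df_subj * df_time
  list(
    grp = c(ss = ss_grp, df = df_grp,
            F = (ss_grp / df_grp) / (ss_subj_within / df_subj)),
    subj_within = c(ss = ss_subj_within, df = df_subj),
    time = c(ss = ss_time, df = df_time,
             F = (ss_time / df_time) / (ss_res / df_res)),
    grp_time = c(ss = ss_gt, df = df_gt,
                 F = (ss_gt / df_gt) / (ss_res / df_res)),
    residual = c(ss = ss_res, df = df_res))
}
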