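#' Default sampling schedule
#'
#' The 18-point destructive-sampling schedule used by the incubation
#' design: 0, 4, 8, 12, 16, 20, 24 hours then 1.5, 2, 3, 4, 7, 11, 16, 21,
#' 32, 64 and 96 days. Times are returned in days; the hour-denominated
#' points are exact fractions of a day (4 h = 1/6 d) so that round trips
#' through text formats do not perturb fits.
#'
#' @return Numeric vector of 18 strictly increasing times in days,
#'   starting at 0.
#' @export
default_schedule <- function() {
  c(c(0, 4, 8, 12, 16, 20, 24) / 24,
    1.5, 2, 3, 4, 7, 11, 16, 21, 32, 64, 96)
}

# Gongzhuling plateau-model parameters by temperature x water content,
# plus the sterilized/nonsterilized pair at 35C/50%.
.gzl_truths <- data.frame(
  temperature_C     = rep(c(15, 25, 35), each = 3),
  water_content_pct = rep(c(20, 33, 50), times = 3),
  Y0 = c(83.58, 74.37, 87.33, 22.09, 44.53, 51.36, 15.92, 11.92, 4.58),
  a  = c(266.69, 286.73, 246.25, 352.16, 319.43, 274.35, 362.61, 362.25,
         343.26),
  b  = c(0.0976, 0.1291, 0.0873, 0.1399, 0.1739, 0.1369, 0.2072, 0.2168,
         0.0762)
)

.sterilized_truth <- c(Y0 = 48.82, a = 302.95, b = 0.0827)

# Site scaling factors calibrated to the printed per-site mean DT50 and
# mean Y0 (Gongzhuling 9.1 d / 43.9 ng/g as reference). Non-reference
# sites are synthetic stand-ins, not measured parameter sets.
.site_factors <- data.frame(
  soil_site = c("Gongzhuling", "Jinan", "Beijing", "Zhengzhou"),
  b_factor  = 9.1 / c(9.1, 6.6, 10.1, 13.3),
  Y0_factor = c(43.9, 50.2, 38.6, 47.8) / 43.9
)

condition_id <- function(soil_site, temperature_C, water_content_pct,
                         sterilized) {
  paste0(soil_site, "_T", temperature_C, "_W", water_content_pct,
         ifelse(sterilized, "_sterilized", ""))
}

#' Default ground-truth parameter set
#'
#' Plateau-model parameters for every condition of the factorial design:
#' the nine Gongzhuling temperature-by-water cells carry measured fitted
#' parameters, as does the sterilized Gongzhuling 35 degC / 50% condition.
#' The other three sites have no published per-cell parameters, so their
#' truths are synthetic stand-ins built by scaling the Gongzhuling decay
#' rate `b` by the ratio of printed per-site mean DT50 values and the
#' plateau `Y0` by the ratio of printed per-site mean Y0 values.
#'
#' @param sites Character vector of soil sites to include. Default: all
#'   four.
#' @param include_sterilized Include the sterilized 35 degC / 50%
#'   Gongzhuling condition (one extra row).
#' @return A data frame with one row per condition: `condition_id`,
#'   `soil_site`, `temperature_C`, `water_content_pct`, `sterilized`,
#'   and the plateau truth `Y0`, `a`, `b`.
#' @examples
#' tr <- default_truth_set()
#' nrow(tr) # 36 factorial conditions + 1 sterilized
#' @export
default_truth_set <- function(sites = c("Gongzhuling", "Jinan", "Beijing",
                                        "Zhengzhou"),
                              include_sterilized = TRUE) {
  stopifnot(all(sites %in% .site_factors$soil_site))
  rows <- lapply(sites, function(site) {
    f <- .site_factors[.site_factors$soil_site == site, ]
    d <- .gzl_truths
    d$soil_site <- site
    d$Y0 <- d$Y0 * f$Y0_factor
    d$b <- d$b * f$b_factor
    d$sterilized <- FALSE
    d
  })
  out <- do.call(rbind, rows)
  if (include_sterilized && "Gongzhuling" %in% sites) {
    st <- data.frame(temperature_C = 35, water_content_pct = 50,
                     Y0 = .sterilized_truth[["Y0"]],
                     a = .sterilized_truth[["a"]],
                     b = .sterilized_truth[["b"]],
                     soil_site = "Gongzhuling", sterilized = TRUE)
    out <- rbind(out, st)
  }
  out$condition_id <- condition_id(out$soil_site, out$temperature_C,
                                   out$water_content_pct, out$sterilized)
  rownames(out) <- NULL
  out[, c("condition_id", "soil_site", "temperature_C",
          "water_content_pct", "sterilized", "Y0", "a", "b")]
}

#' Simulation configuration
#'
#' Bundles everything `simulate_dataset()` needs: the per-condition truth
#' parameters, the sampling schedule, the replicate count, the noise model
#' and the master seed. The noise model is truncated additive Gaussian
#' with proportional standard deviation `noise_cv * mu(t)` and a floor
#' `noise_floor_sd`, emulating the proportional error of ELISA
#' quantification while keeping near-plateau late points from having
#' near-zero variance.
#'
#' @param truth Data frame as returned by [default_truth_set()].
#' @param schedule Sampling times in days; strictly increasing, first 0.
#' @param replicates Replicates per condition and time point (default 3).
#' @param noise_cv Coefficient of variation of measurement noise
#'   (default 0.10).
#' @param noise_floor_sd Minimum noise SD in ng/g (default 2.0).
#' @param seed Master integer seed.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(truth = default_truth_set(),
                              schedule = default_schedule(),
                              replicates = 3L,
                              noise_cv = 0.10,
                              noise_floor_sd = 2.0,
                              seed = 1L) {
  stopifnot(is.data.frame(truth),
            all(c("condition_id", "Y0", "a", "b") %in% names(truth)),
            !anyDuplicated(truth$condition_id))
  if (length(schedule) < 2 || any(diff(schedule) <= 0) || schedule[1] != 0)
    stop("schedule must be strictly increasing and start at 0",
         call. = FALSE)
  if (replicates < 1) stop("replicates must be >= 1", call. = FALSE)
  if (noise_cv < 0 || noise_floor_sd < 0)
    stop("noise parameters must be >= 0", call. = FALSE)
  structure(list(truth = truth, schedule = as.numeric(schedule),
                 replicates = as.integer(replicates),
                 noise_cv = noise_cv, noise_floor_sd = noise_floor_sd,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# Deterministic 31-bit string hash (polynomial rolling hash). Used to
# derive per-(condition, replicate) child seeds so that adding conditions
# never reshuffles the noise of existing ones.
.string_hash <- function(s) {
  h <- 0
  for (v in utf8ToInt(s)) h <- (h * 131 + v) %% 2147483629
  h
}

child_seed <- function(master_seed, cond_id, replicate) {
  (as.numeric(master_seed) +
     .string_hash(paste0(cond_id, "#", replicate))) %% 2147483629
}

#' Simulate a measurement table
#'
#' Draws, for every condition, replicate and scheduled time, a
#' concentration `max(0, mu(t) + e)` where `mu(t)` is the plateau-model
#' truth curve and `e ~ N(0, sd(t))` with
#' `sd(t) = max(noise_floor_sd, noise_cv * mu(t))`. Identical
#' configurations (including the seed) give bit-identical tables; each
#' (condition, replicate) pair has its own deterministic child seed.
#'
#' @param config A [simulation_config()].
#' @return A long-format `measurement_table` data frame with columns
#'   `condition_id`, `soil_site`, `temperature_C`, `water_content_pct`,
#'   `sterilized`, `replicate`, `time_days`, `concentration_ng_per_g`;
#'   the configuration is attached as attribute `"config"`.
#' @examples
#' cfg <- simulation_config(seed = 42)
#' sim <- simulate_dataset(cfg)
#' nrow(sim) # 37 conditions x 3 replicates x 18 times
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)

  tr <- config$truth
  sched <- config$schedule
  nt <- length(sched)
  rows <- vector("list", nrow(tr) * config$replicates)
  k <- 0L
  for (i in seq_len(nrow(tr))) {
    p <- plateau_params(tr$Y0[i], tr$a[i], tr$b[i])
    mu <- eval_plateau(p, sched)
    sdv <- pmax(config$noise_floor_sd, config$noise_cv * mu)
    for (r in seq_len(config$replicates)) {
      set.seed(child_seed(config$seed, tr$condition_id[i], r))
      e <- if (all(sdv == 0)) rep(0, nt) else stats::rnorm(nt, 0, sdv)
      k <- k + 1L
      rows[[k]] <- data.frame(
        condition_id = tr$condition_id[i],
        soil_site = tr$soil_site[i],
        temperature_C = tr$temperature_C[i],
        water_content_pct = tr$water_content_pct[i],
        sterilized = tr$sterilized[i],
        replicate = r,
        time_days = sched,
        concentration_ng_per_g = pmax(0, mu + e))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "config") <- config
  class(out) <- c("measurement_table", "data.frame")
  out
}
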