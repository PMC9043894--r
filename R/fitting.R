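#' Coefficient of determination
#'
#' `1 - SS_res / SS_tot` with the total sum of squares taken about the
#' observed mean (the conventional report of curve-fitting software).
#'
#' @param observed,predicted Numeric vectors of equal length >= 2.
#' @return R-squared, dimensionless.
#' @export
r_squared <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) < 2)
    stop("observed and predicted must have equal length >= 2",
         call. = FALSE)
  if (any(!is.finite(observed)) || any(!is.finite(predicted)))
    stop("non-finite values", call. = FALSE)
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0)
    stop("undefined statistic: observations have zero variance",
         call. = FALSE)
  1 - sum((observed - predicted)^2) / ss_tot
}

.fingerprint <- function(t, y) {
  ord <- order(t, y)
  paste(format(c(t[ord], y[ord]), digits = 15, trim = TRUE),
        collapse = ",")
}

.get_ty <- function(data) {
  tc <- if ("time_days" %in% names(data)) "time_days" else "t"
  yc <- if ("concentration_ng_per_g" %in% names(data))
    "concentration_ng_per_g" else "y"
  if (!tc %in% names(data) || !yc %in% names(data))
    stop("data must have columns time_days/concentration_ng_per_g (or t/y)",
         call. = FALSE)
  if ("condition_id" %in% names(data) &&
      length(unique(data$condition_id)) > 1)
    stop("data slice must contain a single condition", call. = FALSE)
  d <- data.frame(t = as.numeric(data[[tc]]), y = as.numeric(data[[yc]]))
  if (any(!is.finite(d$t)) || any(!is.finite(d$y)))
    stop("non-finite time or concentration", call. = FALSE)
  d[order(d$t, d$y), , drop = FALSE]
}

#' Starting values for the degradation model fits
#'
#' Plateau start: `Y0` from the mean of the last two scheduled time
#' points, `a` from the earliest-time mean minus that plateau, and `b`
#' from the slope of an OLS line of `log(Y - Y0 + eps)` against time over
#' the points above the plateau (fallback `ln 2 / (t_max / 10)`). The
#' first-order start is the same with `Y0` forced to 0. `eps = 1e-6`
#' concentration units.
#'
#' @param data One condition's measurements (columns `time_days`,
#'   `concentration_ng_per_g`, or `t`, `y`).
#' @param model_kind `"first_order"` or `"plateau"`.
#' @return A `first_order_params` or `plateau_params` start; degenerate
#'   (constant) data yield an `a` of `eps` with attribute
#'   `degenerate = TRUE`.
#' @export
initial_guess <- function(data, model_kind = c("plateau", "first_order")) {
  model_kind <- match.arg(model_kind)
  eps <- 1e-6
  d <- .get_ty(data)
  n_params <- if (model_kind == "plateau") 3L else 2L
  times <- sort(unique(d$t))
  if (length(times) < n_params + 1L)
    stop(sprintf("insufficient data: need >= %d distinct time points",
                 n_params + 1L), call. = FALSE)

  last2 <- times[length(times) - c(1, 0)]
  Y0_init <- if (model_kind == "plateau")
    max(0, mean(d$y[d$t %in% last2])) else 0
  a_init <- max(eps, mean(d$y[d$t == times[1]]) - Y0_init)

  above <- d$y > Y0_init
  b_init <- NA_real_
  if (sum(above) >= 2 && length(unique(d$t[above])) >= 2) {
    sl <- unname(stats::coef(stats::lm(log(y - Y0_init + eps) ~ t,
                                       data = d[above, ]))[2])
    if (is.finite(sl) && sl < 0) b_init <- abs(sl)
  }
  if (!is.finite(b_init) || b_init <= 0)
    b_init <- log(2) / (max(d$t) / 10)

  degenerate <- stats::var(d$y) == 0
  out <- if (model_kind == "plateau")
    plateau_params(Y0 = Y0_init, a = a_init, b = b_init)
  else first_order_params(a = a_init, b = b_init)
  attr(out, "degenerate") <- degenerate
  out
}

.fit_bounds <- function(model_kind, ymax) {
  if (model_kind == "plateau")
    list(lower = c(Y0 = 0, a = 1e-9, b = 1e-6),
         upper = c(Y0 = max(ymax, 1e-6), a = 2 * max(ymax, 1e-6), b = 20))
  else
    list(lower = c(a = 1e-9, b = 1e-6),
         upper = c(a = 2 * max(ymax, 1e-6), b = 20))
}

.try_nls <- function(d, model_kind, start, bounds) {
  form <- if (model_kind == "plateau")
    y ~ Y0 + a * exp(-b * t) else y ~ a * exp(-b * t)
  tryCatch({
    fit <- stats::nls(form, data = d, start = start,
                      algorithm = "port",
                      lower = bounds$lower, upper = bounds$upper,
                      control = stats::nls.control(maxiter = 500,
                                                   warnOnly = FALSE))
    list(coef = stats::coef(fit),
         ss_res = sum(stats::resid(fit)^2))
  }, error = function(e) NULL, warning = function(w) NULL)
}

.try_optim <- function(d, model_kind, start, bounds) {
  fn <- if (model_kind == "plateau")
    function(p) sum((d$y - (p[1] + p[2] * exp(-p[3] * d$t)))^2)
  else function(p) sum((d$y - (p[1] * exp(-p[2] * d$t)))^2)
  res <- tryCatch(
    stats::optim(unlist(start), fn, method = "L-BFGS-B",
                 lower = bounds$lower, upper = bounds$upper,
                 control = list(maxit = 2000, factr = 10)),
    error = function(e) NULL)
  if (is.null(res)) return(NULL)
  cf <- res$par
  names(cf) <- names(start)
  list(coef = cf, ss_res = res$value)
}

#' Fit a degradation model to one condition
#'
#' Bounded nonlinear least squares (port algorithm, with an L-BFGS-B
#' fallback) minimizing the residual sum of squares of the chosen model.
#' On non-convergence, up to `n_starts` restarts from deterministically
#' jittered starting values are attempted (jitter derived from `seed`).
#' Bounds keep parameters physical: `Y0` in `[0, max(Y)]`, `a` in
#' `(0, 2 max(Y)]`, `b` in `[1e-6, 20]` per day.
#'
#' @param data One condition's measurements.
#' @param model_kind `"first_order"` or `"plateau"`.
#' @param use_means Fit per-time-point means instead of all replicate
#'   observations (default `FALSE`: all observations).
#' @param seed Integer controlling the restart jitter only.
#' @param n_starts Number of jittered restarts on non-convergence.
#' @return A `fit_result` with the fitted parameters, `r_squared`,
#'   regression F-test `p_value`, `dt50_days` (for the plateau model this
#'   is the half-life of the degradable fraction), `n_obs`, `ss_res` and a
#'   `converged` flag. Fits with `Y0` below 1e-6 are reported with
#'   `Y0 = 0` and a note that the two models coincide.
#' @examples
#' sim <- simulate_dataset(simulation_config(
#'   truth = default_truth_set(sites = "Gongzhuling"), seed = 7))
#' one <- sim[sim$condition_id == "Gongzhuling_T35_W20", ]
#' fit_model(one, "plateau")
#' @export
fit_model <- function(data, model_kind = c("plateau", "first_order"),
                      use_means = FALSE, seed = 1L, n_starts = 5L) {
  model_kind <- match.arg(model_kind)
  d <- .get_ty(data)
  if (use_means) {
    agg <- stats::aggregate(y ~ t, data = d, FUN = mean)
    d <- agg[order(agg$t), c("t", "y")]
  }
  n_params <- if (model_kind == "plateau") 3L else 2L
  fp <- .fingerprint(d$t, d$y)
  cond <- if ("condition_id" %in% names(data))
    as.character(data$condition_id[1]) else NA_character_

  base <- structure(
    list(condition_id = cond, model_kind = model_kind, params = NULL,
         r_squared = NA_real_, p_value = NA_real_, dt50_days = NA_real_,
         n_obs = nrow(d), ss_res = NA_real_, ss_tot = NA_real_,
         converged = FALSE, n_params = n_params, fingerprint = fp,
         note = NULL),
    class = "fit_result")

  ss_tot <- sum((d$y - mean(d$y))^2)
  if (ss_tot == 0) {
    base$note <- "degenerate: zero variance across observations"
    return(base)
  }
  if (nrow(d) <= n_params) {
    base$note <- "insufficient observations"
    return(base)
  }

  start <- initial_guess(d, model_kind)
  bounds <- .fit_bounds(model_kind, max(d$y))
  start_vec <- unlist(unclass(start))

  starts <- list(as.list(start_vec))
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed) %% 2147483629)
  for (s in seq_len(n_starts)) {
    jit <- start_vec * exp(stats::runif(length(start_vec), -1, 1))
    jit <- pmin(pmax(jit, bounds$lower + 1e-12), bounds$upper)
    starts[[s + 1L]] <- as.list(jit)
  }
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())

  best <- NULL
  for (st in starts) {
    res <- .try_nls(d, model_kind, st, bounds)
    if (!is.null(res) && (is.null(best) || res$ss_res < best$ss_res))
      best <- res
    if (!is.null(best) && best$ss_res <= 1e-10 * ss_tot) break
  }
  if (is.null(best)) {
    for (st in starts) {
      res <- .try_optim(d, model_kind, st, bounds)
      if (!is.null(res) && (is.null(best) || res$ss_res < best$ss_res))
        best <- res
    }
  }
  if (is.null(best)) {
    base$note <- "optimizer failed to converge from all starts"
    return(base)
  }
  # polish: the port solver can stop a few parts in 1e4 short of the
  # minimum on near-perfect data; a tight bounded quasi-Newton pass from
  # its solution costs little and pins the optimum down
  pol <- .try_optim(d, model_kind, as.list(best$coef), bounds)
  if (!is.null(pol) && pol$ss_res < best$ss_res) best <- pol

  cf <- as.list(best$coef)
  if (model_kind == "plateau" && cf$Y0 < 1e-6) {
    cf$Y0 <- 0
    base$note <- "Y0 at zero boundary: plateau and first-order coincide"
  }
  params <- if (model_kind == "plateau")
    plateau_params(cf$Y0, cf$a, cf$b) else first_order_params(cf$a, cf$b)
  pred <- if (model_kind == "plateau")
    eval_plateau(params, d$t) else eval_first_order(params, d$t)
  ss_res <- sum((d$y - pred)^2)

  base$params <- params
  base$ss_res <- ss_res
  base$ss_tot <- ss_tot
  base$r_squared <- max(0, min(1, 1 - ss_res / ss_tot))
  base$dt50_days <- dt50_first_order(cf$b)
  base$converged <- TRUE
  base$p_value <- regression_p_value(base)
  base
}

#' Regression F-test p-value of a fit
#'
#' Upper-tail probability of
#' `F = (SS_reg / (p - 1)) / (SS_res / (n - p))` with
#' `SS_reg = SS_tot - SS_res`, the omnibus test that the fitted curve
#' explains more variance than the mean. Perfect fits underflow; the
#' p-value is floored at 1e-300.
#'
#' @param fit A converged `fit_result`.
#' @return The p-value in (0, 1].
#' @export
regression_p_value <- function(fit) {
  stopifnot(inherits(fit, "fit_result"))
  if (!fit$converged && is.na(fit$ss_res))
    stop("p-value requires a converged fit", call. = FALSE)
  n <- fit$n_obs; np <- fit$n_params
  if (n <= np) stop("n_obs must exceed n_params", call. = FALSE)
  if (!is.finite(fit$ss_tot) || fit$ss_tot <= 0)
    stop("undefined statistic: degenerate sums of squares", call. = FALSE)
  ss_reg <- max(0, fit$ss_tot - fit$ss_res)
  if (fit$ss_res <= 0) return(1e-300)
  f <- (ss_reg / (np - 1)) / (fit$ss_res / (n - np))
  max(1e-300, stats::pf(f, np - 1, n - np, lower.tail = FALSE))
}

#' Compare the nested degradation models on one condition
#'
#' The plateau model nests the first-order model (`Y0 = 0`), so its
#' converged residual sum of squares can never exceed the first-order
#' one. The preferred model is the plateau model only when its R-squared
#' advantage exceeds 1e-12; exact ties go to the simpler first-order
#' model (parsimony).
#'
#' @param fit_fo First-order `fit_result`.
#' @param fit_pl Plateau `fit_result`.
#' @return A `model_comparison` list: both R-squared values, their
#'   difference `delta_r2`, and `preferred`.
#' @export
compare_models <- function(fit_fo, fit_pl) {
  stopifnot(inherits(fit_fo, "fit_result"), inherits(fit_pl, "fit_result"))
  if (fit_fo$model_kind != "first_order" || fit_pl$model_kind != "plateau")
    stop("arguments must be a first-order and a plateau fit",
         call. = FALSE)
  if (!fit_fo$converged || !fit_pl$converged)
    stop("both fits must be converged", call. = FALSE)
  if (!identical(fit_fo$fingerprint, fit_pl$fingerprint))
    stop("fits were not produced from identical data", call. = FALSE)
  delta <- fit_pl$r_squared - fit_fo$r_squared
  structure(list(condition_id = fit_fo$condition_id,
                 r2_first_order = fit_fo$r_squared,
                 r2_plateau = fit_pl$r_squared,
                 delta_r2 = delta,
                 preferred = if (delta > 1e-12) "plateau" else
                   "first_order"),
            class = "model_comparison")
}

#' Fit both models to every condition of a measurement table
#'
#' @param table A `measurement_table` (or compatible long data frame).
#' @param use_means,seed Passed to [fit_model()].
#' @return A data frame with one row per condition and model:
#'   condition metadata, `model_kind`, `Y0`, `a`, `b`, `r_squared`,
#'   `p_value`, `dt50_days`, `n_obs`, `converged`.
#' @export
fit_all_conditions <- function(table, use_means = FALSE, seed = 1L) {
  stopifnot(is.data.frame(table), "condition_id" %in% names(table))
  meta_cols <- intersect(c("soil_site", "temperature_C",
                           "water_content_pct", "sterilized"),
                         names(table))
  conds <- unique(table$condition_id)
  rows <- lapply(conds, function(cid) {
    slice <- table[table$condition_id == cid, ]
    meta <- slice[1, meta_cols, drop = FALSE]
    do.call(rbind, lapply(c("first_order", "plateau"), function(mk) {
      f <- fit_model(slice, mk, use_means = use_means, seed = seed)
      cbind(data.frame(condition_id = cid), meta, data.frame(
        model_kind = mk,
        Y0 = if (mk == "plateau" && f$converged) f$params$Y0 else NA_real_,
        a = if (f$converged) f$params$a else NA_real_,
        b = if (f$converged) f$params$b else NA_real_,
        r_squared = f$r_squared, p_value = f$p_value,
        dt50_days = f$dt50_days, n_obs = f$n_obs,
        converged = f$converged))
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %s model%s\n", x$model_kind,
              if (is.na(x$condition_id)) "" else
                paste0(" for ", x$condition_id)))
  if (x$converged) {
    print(x$params)
    cat(sprintf("  R2 = %.4f, p = %.3g, DT50 = %.3f d, n = %d\n",
                x$r_squared, x$p_value, x$dt50_days, x$n_obs))
  } else {
    cat("  not converged:", x$note %||% "", "\n")
  }
  invisible(x)
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf(
    "<model_comparison>%s R2(first-order) = %.4f, R2(plateau) = %.4f,\n",
    if (is.na(x$condition_id)) "" else paste0(" ", x$condition_id, ":"),
    x$r2_first_order, x$r2_plateau))
  cat(sprintf("  delta R2 = %.4g -> preferred: %s\n", x$delta_r2,
              x$preferred))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
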