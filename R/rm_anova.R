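#' Assemble subject series from a measurement table
#'
#' A "subject" is one replicate of one condition: its measurements across
#' all scheduled times form one repeated-measures series. Series missing
#' any time level are excluded with a warning (listwise deletion; the
#' design is balanced by construction so this should be rare).
#'
#' @param table Long-format measurement data with `condition_id`,
#'   `replicate`, `time_days` and `concentration_ng_per_g` columns.
#' @return A list with the wide response matrix `Y` (subjects x time
#'   levels), the per-subject metadata data frame `meta`, and the sorted
#'   time levels `times`.
#' @keywords internal
as_subject_series <- function(table) {
  stopifnot(all(c("condition_id", "replicate", "time_days",
                  "concentration_ng_per_g") %in% names(table)))
  times <- sort(unique(table$time_days))
  k <- length(times)
  table$subject <- paste(table$condition_id, table$replicate, sep = "/")
  if (anyDuplicated(table[, c("subject", "time_days")]))
    stop("duplicate (condition, replicate, time) rows", call. = FALSE)
  subjects <- unique(table$subject)
  counts <- table(table$subject)
  complete <- names(counts)[counts == k]
  dropped <- setdiff(subjects, complete)
  if (length(dropped) > 0)
    warning(sprintf("excluding %d incomplete series (e.g. %s)",
                    length(dropped), dropped[1]), call. = FALSE)
  tab <- table[table$subject %in% complete, ]
  tab <- tab[order(tab$subject, tab$time_days), ]
  Y <- matrix(tab$concentration_ng_per_g, ncol = k, byrow = TRUE,
              dimnames = list(unique(tab$subject), format(times)))
  meta <- tab[tab$time_days == times[1],
              setdiff(names(tab), c("time_days",
                                    "concentration_ng_per_g"))]
  rownames(meta) <- meta$subject
  meta <- meta[rownames(Y), , drop = FALSE]
  list(Y = Y, meta = meta, times = times)
}

# Greenhouse-Geisser epsilon from the pooled within-cell covariance of
# the time-level responses: eps = tr(M)^2 / ((k-1) tr(M^2)) with
# M = C' S C for any orthonormal contrast basis C.
.gg_epsilon <- function(Y, cell) {
  k <- ncol(Y)
  cells <- split(seq_len(nrow(Y)), cell)
  df_tot <- 0
  S <- matrix(0, k, k)
  for (idx in cells) {
    if (length(idx) < 2) next
    d <- sweep(Y[idx, , drop = FALSE], 2, colMeans(Y[idx, , drop = FALSE]))
    S <- S + crossprod(d)
    df_tot <- df_tot + length(idx) - 1
  }
  if (df_tot < 1) return(NA_real_)
  S <- S / df_tot
  C <- stats::contr.poly(k)
  M <- t(C) %*% S %*% C
  tr <- sum(diag(M))
  if (!is.finite(tr) || tr <= .Machine$double.eps * k)
    return(NA_real_)
  eps <- tr^2 / ((k - 1) * sum(M^2))
  min(1, max(1 / (k - 1), eps))
}

.extract_stratum <- function(sm) {
  d <- as.data.frame(sm[[1]])
  names(d) <- c("df", "ss", "ms", "F", "p")[seq_len(ncol(d))]
  d$effect <- trimws(rownames(d))
  rownames(d) <- NULL
  d[, c("effect", "ss", "df", "ms", "F", "p")]
}

#' Split-plot repeated-measures ANOVA
#'
#' Univariate mixed-design ANOVA with one within-subject factor (time)
#' and any number of crossed between-subject factors. Between-subject
#' effects are tested against subject-within-cells error; time and
#' time-by-factor interactions against the subject-by-time residual.
#' Within-subject tests additionally carry the Greenhouse-Geisser
#' sphericity correction: degrees of freedom are multiplied by an
#' epsilon estimated from the pooled within-cell covariance matrix
#' (epsilon = 1 under compound symmetry; the corrected p-values guard
#' against the inflated type-I error of correlated repeated measures).
#'
#' @param table Long-format measurement data (see [as_subject_series()]).
#' @param between Character vector of between-subject factor column
#'   names, e.g. `c("soil_site", "water_content_pct", "temperature_C")`.
#' @param max_poly_order Maximum polynomial contrast order (default 3).
#' @param metric_time Use actual day values as polynomial contrast
#'   spacing instead of equally spaced level ranks (default `FALSE`,
#'   matching the common statistical-software default).
#' @return An `rm_anova` object: `$between` and `$within` ANOVA tables
#'   (within rows carry `gg_epsilon`, `df_gg` and `p_gg`), `$contrasts`
#'   (polynomial time contrasts), `$gg_epsilon`, and design metadata.
#' @examples
#' sim <- simulate_dataset(simulation_config(
#'   truth = default_truth_set(sites = c("Gongzhuling", "Jinan"),
#'                             include_sterilized = FALSE),
#'   seed = 3))
#' a <- rm_anova(sim, between = c("soil_site", "temperature_C"))
#' head(a$within)
#' @export
rm_anova <- function(table,
                     between = c("soil_site", "water_content_pct",
                                 "temperature_C"),
                     max_poly_order = 3L, metric_time = FALSE) {
  ser <- as_subject_series(table)
  Y <- ser$Y
  k <- ncol(Y)
  n <- nrow(Y)
  stopifnot(all(between %in% names(ser$meta)))

  meta <- ser$meta
  for (f in between) meta[[f]] <- factor(meta[[f]])
  cell <- if (length(between) > 0)
    interaction(meta[between], drop = FALSE) else factor(rep(1, n))
  if (any(table(droplevels(cell)) < 2))
    stop("need >= 2 subjects per between-subject cell", call. = FALSE)
  if (nlevels(cell) != nlevels(droplevels(cell)))
    stop("design error: empty between-subject cells", call. = FALSE)

  long <- data.frame(
    y = as.vector(t(Y)),
    subject = factor(rep(rownames(Y), each = k)),
    time = factor(rep(seq_len(k), times = n)))
  for (f in between) long[[f]] <- rep(meta[[f]], each = k)

  rhs <- if (length(between) > 0)
    sprintf("(%s) * time", paste(between, collapse = " * ")) else "time"
  form <- stats::as.formula(paste("y ~", rhs, "+ Error(subject)"))
  fit <- stats::aov(form, data = long)
  sm <- summary(fit)

  between_tab <- .extract_stratum(sm[["Error: subject"]])
  within_tab <- .extract_stratum(sm[["Error: Within"]])

  eps <- .gg_epsilon(Y, cell)
  err_row <- within_tab$effect == "Residuals"
  df_err <- within_tab$df[err_row]
  within_tab$gg_epsilon <- ifelse(err_row, NA_real_, eps)
  within_tab$df_gg <- within_tab$df * ifelse(is.na(eps), NA_real_, eps)
  within_tab$p_gg <- ifelse(
    err_row | is.na(eps) | !is.finite(within_tab$F), NA_real_,
    stats::pf(within_tab$F, within_tab$df * eps, df_err * eps,
              lower.tail = FALSE))

  contrasts <- .poly_contrasts(ser, between = between,
                               max_order = max_poly_order,
                               metric_time = metric_time)

  structure(list(between = between_tab, within = within_tab,
                 contrasts = contrasts, gg_epsilon = eps,
                 n_subjects = n, n_time_levels = k,
                 between_factors = between),
            class = "rm_anova")
}

#' Orthogonal polynomial contrasts of the time trend
#'
#' Projects each subject's series onto orthonormal polynomial contrast
#' vectors over the time levels and tests, per polynomial order, whether
#' the mean projection differs from zero (the decomposition of the
#' within-subject time effect into linear, quadratic, cubic ...
#' components). Each order uses its own subject-level error term with
#' `n_subjects - n_cells` degrees of freedom.
#'
#' @inheritParams rm_anova
#' @param max_order Highest polynomial order tested (default 3; must be
#'   below the number of time levels).
#' @return Data frame with one row per order: `order`, `label`, `ss`,
#'   `df`, `ss_error`, `df_error`, `F`, `p`.
#' @export
polynomial_time_contrasts <- function(table,
                                      between = c("soil_site",
                                                  "water_content_pct",
                                                  "temperature_C"),
                                      max_order = 3L,
                                      metric_time = FALSE) {
  .poly_contrasts(as_subject_series(table), between, max_order,
                  metric_time)
}

.poly_contrasts <- function(ser, between, max_order, metric_time) {
  Y <- ser$Y
  k <- ncol(Y)
  n <- nrow(Y)
  if (max_order >= k)
    stop("polynomial order must be below the number of time levels",
         call. = FALSE)
  meta <- ser$meta
  for (f in between) meta[[f]] <- factor(meta[[f]])
  cell <- if (length(between) > 0)
    interaction(meta[between], drop = TRUE) else factor(rep(1, n))
  g <- nlevels(cell)

  C <- if (metric_time)
    stats::contr.poly(k, scores = ser$times) else stats::contr.poly(k)
  labels <- c("linear", "quadratic", "cubic", "quartic", "quintic")
  rows <- lapply(seq_len(max_order), function(o) {
    z <- as.vector(Y %*% C[, o])
    ss <- n * mean(z)^2
    cm <- tapply(z, cell, mean)[cell]
    ss_err <- sum((z - cm)^2)
    df_err <- n - g
    f_stat <- if (ss_err > 0) (ss / 1) / (ss_err / df_err) else
      ifelse(ss > 0, Inf, NaN)
    data.frame(order = o,
               label = if (o <= length(labels)) labels[o] else
                 paste0("order", o),
               ss = ss, df = 1, ss_error = ss_err, df_error = df_err,
               F = f_stat,
               p = stats::pf(f_stat, 1, df_err, lower.tail = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf(
    "Repeated-measures ANOVA: %d subjects x %d time levels; GG epsilon = %s\n",
    x$n_subjects, x$n_time_levels,
    ifelse(is.na(x$gg_epsilon), "NA", sprintf("%.4f", x$gg_epsilon))))
  cat("\nBetween-subject effects:\n")
  print(format(x$between, digits = 4), row.names = FALSE)
  cat("\nWithin-subject effects (GG-corrected p in p_gg):\n")
  print(format(x$within, digits = 4), row.names = FALSE)
  cat("\nPolynomial time contrasts:\n")
  print(format(x$contrasts, digits = 4), row.names = FALSE)
  invisible(x)
}
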