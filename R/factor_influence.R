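# Map user-facing factor names to measurement-table columns.
.factor_columns <- c(temperature = "temperature_C",
                     water_content = "water_content_pct",
                     soil_type = "soil_site",
                     sterilization = "sterilized")

# The sterilization experiment is run separately on paired conditions;
# restrict to sterilized conditions plus their matched unsterilized
# counterparts (same site, temperature and water content).
.sterilization_subset <- function(fits) {
  st <- fits[fits$sterilized, , drop = FALSE]
  if (nrow(st) == 0)
    stop("no sterilized conditions present", call. = FALSE)
  key <- function(d) paste(d$soil_site, d$temperature_C,
                           d$water_content_pct)
  fits[fits$sterilized | key(fits) %in% key(st), , drop = FALSE]
}

#' Per-factor-level means of a degradation metric
#'
#' The early-stage metric is DT50 from the first-order fit; the
#' late-stage metric is the plateau Y0. Means are unweighted arithmetic
#' means over all conditions sharing a factor level. Sterilized
#' conditions are excluded when averaging the environmental factors (the
#' sterilization trial is a separate paired experiment); the
#' `sterilization` factor itself is evaluated only on the paired
#' sterilized/unsterilized conditions.
#'
#' @param fits Fit-results data frame from [fit_all_conditions()] (or a
#'   compatible table with condition metadata, `model_kind`, `dt50_days`,
#'   `Y0` and `converged` columns).
#' @param factor One of `"temperature"`, `"water_content"`,
#'   `"soil_type"`, `"sterilization"`.
#' @param metric `"dt50"` (days, early stage) or `"Y0"` (ng/g, late
#'   stage).
#' @return Named numeric vector of level means.
#' @examples
#' # printed per-site mean DT50 at 15 degC from three fitted conditions:
#' # mean(c(15.1, 10.5, 18.3)) = 14.63
#' @export
level_means <- function(fits, factor, metric = c("dt50", "Y0")) {
  metric <- match.arg(metric)
  factor <- match.arg(factor, names(.factor_columns))
  model_needed <- if (metric == "dt50") "first_order" else "plateau"
  value_col <- if (metric == "dt50") "dt50_days" else "Y0"

  d <- if (factor == "sterilization") .sterilization_subset(fits)
  else fits[!fits$sterilized, , drop = FALSE]
  d <- d[d$model_kind == model_needed, , drop = FALSE]
  if (nrow(d) == 0)
    stop(sprintf("no %s fits available for metric '%s'", model_needed,
                 metric), call. = FALSE)
  if (length(unique(d$model_kind)) > 1)
    stop("mixed model kinds for one metric", call. = FALSE)
  if (!all(d$converged))
    stop("all fits must be converged", call. = FALSE)

  col <- .factor_columns[[factor]]
  means <- tapply(d[[value_col]], d[[col]], mean)
  if (any(is.na(means)))
    stop("empty factor level encountered", call. = FALSE)
  counts <- table(d[[col]])
  if (length(unique(counts)) > 1)
    warning(sprintf("unequal condition counts across levels of '%s'",
                    factor), call. = FALSE)
  out <- as.numeric(means)
  names(out) <- names(means)
  out
}

#' Range of per-level means
#'
#' `max - min` of the level means: the influence of a factor on a
#' degradation metric, on the metric's own scale (days for DT50, ng/g
#' for Y0).
#'
#' @param level_means Named numeric vector from [level_means()];
#'   at least 2 levels.
#' @return The range (non-negative scalar).
#' @examples
#' influence_range(c(`15` = 17.3, `25` = 7.7, `35` = 4.3)) # 13.0
#' @export
influence_range <- function(level_means) {
  if (length(level_means) < 2)
    stop("need >= 2 levels", call. = FALSE)
  if (any(!is.finite(level_means)))
    stop("non-finite level means", call. = FALSE)
  max(level_means) - min(level_means)
}

#' Rank factors by influence range
#'
#' Sorts factors within each stage by descending range; ties are broken
#' alphabetically by factor name and flagged.
#'
#' @param influences Data frame with columns `factor`, `stage` and
#'   `range` (one row per factor per stage).
#' @return The same data frame sorted within stage, with `rank` and
#'   `tied` columns added.
#' @examples
#' rank_factors(data.frame(
#'   factor = c("temperature", "soil_type", "water_content",
#'              "sterilization"),
#'   stage = "early", range = c(13.0, 6.7, 5.0, 2.4)))
#' @export
rank_factors <- function(influences) {
  stopifnot(is.data.frame(influences),
            all(c("factor", "stage", "range") %in% names(influences)))
  out <- do.call(rbind, lapply(split(influences, influences$stage),
                               function(d) {
    ord <- order(-d$range, as.character(d$factor))
    d <- d[ord, , drop = FALSE]
    d$rank <- seq_len(nrow(d))
    d$tied <- duplicated(d$range) | duplicated(d$range, fromLast = TRUE)
    if (any(d$tied))
      message("tied influence ranges broken alphabetically in stage ",
              d$stage[1])
    d
  }))
  rownames(out) <- NULL
  out
}

#' Full factor-influence analysis
#'
#' Computes, for every factor, the per-level means of the early-stage
#' (DT50) and late-stage (Y0) metrics, their ranges, and the resulting
#' per-stage factor ranking.
#'
#' @inheritParams level_means
#' @param factors Factors to analyze (default: all four).
#' @return A `factor_influence` object: `$level_means` (nested list by
#'   stage and factor) and `$ranking` (data frame with `factor`, `stage`,
#'   `range`, `rank`, `tied`).
#' @export
factor_influence <- function(fits,
                             factors = names(.factor_columns)) {
  stages <- c(early = "dt50", late = "Y0")
  lm_list <- lapply(stages, function(metric) {
    out <- lapply(factors, function(f) level_means(fits, f, metric))
    names(out) <- factors
    out
  })
  ranges <- do.call(rbind, lapply(names(stages), function(stage) {
    data.frame(factor = factors, stage = stage,
               range = vapply(factors, function(f)
                 influence_range(lm_list[[stage]][[f]]), 0))
  }))
  structure(list(level_means = lm_list, ranking = rank_factors(ranges)),
            class = "factor_influence")
}

#' Format a ranking as an inequality chain
#'
#' @param ranking Ranking data frame from [rank_factors()].
#' @param stage Which stage to format.
#' @param unit Unit string appended to each range.
#' @return A single string, e.g.
#'   `"temperature > soil_type > water_content > sterilization
#'   (13.0d > 6.7d > 5.0d > 2.4d)"`.
#' @export
format_ranking <- function(ranking, stage, unit = "") {
  d <- ranking[ranking$stage == stage, , drop = FALSE]
  d <- d[order(d$rank), , drop = FALSE]
  sprintf("%s (%s)",
          paste(d$factor, collapse = " > "),
          paste(sprintf("%.1f%s", d$range, unit), collapse = " > "))
}

#' @export
print.factor_influence <- function(x, ...) {
  cat("Factor influence ranking:\n")
  cat("  early stage (DT50 range, d): ",
      format_ranking(x$ranking, "early", "d"), "\n", sep = "")
  cat("  late stage (Y0 range, ng/g): ",
      format_ranking(x$ranking, "late"), "\n", sep = "")
  invisible(x)
}
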