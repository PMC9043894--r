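#' Pipeline configuration
#'
#' @param input Path to a measurement CSV, or `NULL` to simulate.
#' @param sim A [simulation_config()] used when `input` is `NULL`.
#' @param use_means Fit per-time-point means instead of raw replicates.
#' @param between Between-subject factors for the main ANOVA.
#' @param max_poly_order Highest polynomial time contrast.
#' @param outdir Output directory (created if absent).
#' @param seed Seed forwarded to simulation and fit restarts.
#' @param plots Also write per-condition decay-curve plots (PDF).
#' @param verbosity 0 = silent, 1 = stage log lines.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input = NULL, sim = NULL, use_means = FALSE,
                            between = c("soil_site", "water_content_pct",
                                        "temperature_C"),
                            max_poly_order = 3L, outdir = "btdecay_out",
                            seed = 1L, plots = FALSE, verbosity = 1L) {
  if (is.null(input) && is.null(sim))
    sim <- simulation_config(seed = seed)
  if (!is.null(input) && !file.exists(input))
    stop("input file does not exist: ", input, call. = FALSE)
  structure(list(input = input, sim = sim, use_means = use_means,
                 between = between,
                 max_poly_order = as.integer(max_poly_order),
                 outdir = outdir, seed = as.integer(seed),
                 plots = isTRUE(plots), verbosity = verbosity),
            class = "pipeline_config")
}

.log_stage <- function(cfg, fmt, ...) {
  if (cfg$verbosity >= 1)
    message(sprintf("[btdecay %s] ", format(Sys.time(), "%H:%M:%S")),
            sprintf(fmt, ...))
}

#' Run the full degradation-analysis pipeline
#'
#' Reads (or simulates) a measurement table, runs the repeated-measures
#' ANOVA, fits both degradation models to every condition, compares
#' them, ranks the environmental factors, and writes all artifacts to
#' the output directory: `measurements.csv` (simulated runs only, with a
#' YAML sidecar), `fit_results.csv`, `model_comparison.csv`, `anova.csv`
#' (between, within and contrast sections), `ranking.csv` and
#' `report.md`. Every CSV carries the seed and configuration hash in a
#' comment header, so a run can be reproduced exactly.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory results
#'   (`measurements`, `fits`, `comparisons`, `anova`,
#'   `anova_sterilization`, `influence`, `n_nonconverged`, `files`).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  files <- character(0)

  tab <- if (is.null(config$input)) {
    .log_stage(config, "simulating dataset (seed %d)", config$sim$seed)
    sim <- simulate_dataset(config$sim)
    f <- file.path(config$outdir, "measurements.csv")
    write_measurements(sim, f)
    files <- c(files, f)
    sim
  } else {
    .log_stage(config, "reading measurements from %s", config$input)
    read_measurements(config$input)
  }
  .log_stage(config, "%d records, %d conditions", nrow(tab),
             length(unique(tab$condition_id)))

  # ANOVA: environmental factors on the unsterilized factorial; the
  # sterilization contrast separately on its paired conditions.
  env_tab <- tab[!tab$sterilized, ]
  between <- intersect(config$between, names(tab))
  between <- between[vapply(between, function(f)
    length(unique(env_tab[[f]])) > 1, TRUE)]
  an <- NULL
  if (length(between) > 0 && nrow(env_tab) > 0) {
    .log_stage(config, "repeated-measures ANOVA (between: %s)",
               paste(between, collapse = ", "))
    an <- rm_anova(env_tab, between = between,
                   max_poly_order = config$max_poly_order)
  }
  an_st <- NULL
  if (any(tab$sterilized)) {
    st_tab <- .sterilization_subset(tab)
    .log_stage(config, "repeated-measures ANOVA (sterilization pair)")
    an_st <- rm_anova(st_tab, between = "sterilized",
                      max_poly_order = config$max_poly_order)
  }
  if (!is.null(an) || !is.null(an_st)) {
    f <- file.path(config$outdir, "anova.csv")
    write_csv_with_header(.anova_to_csv(an, an_st), f, config$seed, hash)
    files <- c(files, f)
  }

  .log_stage(config, "fitting both models per condition")
  fits <- fit_all_conditions(tab, use_means = config$use_means,
                             seed = config$seed)
  n_nonconv <- sum(!fits$converged)
  if (n_nonconv > 0)
    warning(n_nonconv, " fits did not converge", call. = FALSE)
  f <- file.path(config$outdir, "fit_results.csv")
  write_csv_with_header(fits, f, config$seed, hash)
  files <- c(files, f)

  comparisons <- .compare_all(tab, fits, config)
  f <- file.path(config$outdir, "model_comparison.csv")
  write_csv_with_header(comparisons, f, config$seed, hash)
  files <- c(files, f)

  influence <- NULL
  if (all(fits$converged)) {
    .log_stage(config, "ranking factor influence")
    fi_factors <- names(.factor_columns)
    if (!any(fits$sterilized)) fi_factors <- setdiff(fi_factors,
                                                     "sterilization")
    fi_factors <- Filter(function(f)
      f == "sterilization" ||
        length(unique(fits[!fits$sterilized, .factor_columns[[f]]])) > 1,
      fi_factors)
    if (length(fi_factors) > 0) {
      influence <- factor_influence(fits, factors = fi_factors)
      f <- file.path(config$outdir, "ranking.csv")
      write_csv_with_header(influence$ranking, f, config$seed, hash)
      files <- c(files, f)
    }
  }

  f <- file.path(config$outdir, "report.md")
  writeLines(.render_report(fits, comparisons, an, an_st, influence,
                            config, hash), f)
  files <- c(files, f)

  if (config$plots) {
    f <- file.path(config$outdir, "curves.pdf")
    plot_condition_fits(tab, fits, file = f)
    files <- c(files, f)
  }
  .log_stage(config, "wrote %d files to %s", length(files),
             config$outdir)
  invisible(list(measurements = tab, fits = fits,
                 comparisons = comparisons, anova = an,
                 anova_sterilization = an_st, influence = influence,
                 n_nonconverged = n_nonconv, files = files))
}

.compare_all <- function(tab, fits, config) {
  conds <- unique(fits$condition_id)
  rows <- lapply(conds, function(cid) {
    slice <- tab[tab$condition_id == cid, ]
    fo <- fit_model(slice, "first_order", use_means = config$use_means,
                    seed = config$seed)
    pl <- fit_model(slice, "plateau", use_means = config$use_means,
                    seed = config$seed)
    if (!fo$converged || !pl$converged)
      return(data.frame(condition_id = cid, r2_first_order = NA,
                        r2_plateau = NA, delta_r2 = NA,
                        preferred = NA_character_))
    cm <- compare_models(fo, pl)
    data.frame(condition_id = cid, r2_first_order = cm$r2_first_order,
               r2_plateau = cm$r2_plateau, delta_r2 = cm$delta_r2,
               preferred = cm$preferred)
  })
  do.call(rbind, rows)
}

.anova_to_csv <- function(an, an_st) {
  one <- function(a, analysis) {
    if (is.null(a)) return(NULL)
    b <- a$between; b$section <- "between"
    w <- a$within; w$section <- "within"
    ct <- a$contrasts
    ct2 <- data.frame(effect = paste0("time:", ct$label), ss = ct$ss,
                      df = ct$df, ms = ct$ss / ct$df, F = ct$F, p = ct$p,
                      section = "contrast")
    cols <- c("section", "effect", "ss", "df", "ms", "F", "p",
              "gg_epsilon", "df_gg", "p_gg")
    fill <- function(d) {
      for (cc in setdiff(cols, names(d))) d[[cc]] <- NA
      d[, cols]
    }
    out <- rbind(fill(b), fill(w), fill(ct2))
    out$analysis <- analysis
    out[, c("analysis", cols)]
  }
  rbind(one(an, "environment"), one(an_st, "sterilization"))
}

.fmt_model <- function(fits, cid, kind) {
  r <- fits[fits$condition_id == cid & fits$model_kind == kind, ]
  if (nrow(r) != 1 || !r$converged) return("(not converged)")
  if (kind == "plateau")
    sprintf("Y = %.2f + %.2fe^(-%.4ft)", r$Y0, r$a, r$b)
  else sprintf("Y = %.2fe^(-%.4ft)", r$a, r$b)
}

.render_report <- function(fits, comparisons, an, an_st, influence,
                           config, hash) {
  lines <- c("# Degradation analysis report", "",
             sprintf("seed: %d; config hash: %s", config$seed, hash), "",
             "## Fitted degradation models", "",
             paste("| Condition | Model | R2 | p | DT50 (d) |"),
             "|---|---|---|---|---|")
  for (cid in unique(fits$condition_id)) {
    for (kind in c("first_order", "plateau")) {
      r <- fits[fits$condition_id == cid & fits$model_kind == kind, ]
      p_str <- if (!r$converged) "" else if (r$p_value < 1e-4)
        "<0.0001" else sprintf("%.4f", r$p_value)
      dt_str <- if (kind == "first_order" && r$converged)
        sprintf("%.3f", r$dt50_days) else ""
      lines <- c(lines, sprintf(
        "| %s | %s | %s | %s | %s |",
        if (kind == "first_order") cid else "",
        .fmt_model(fits, cid, kind),
        if (r$converged) sprintf("%.4f", r$r_squared) else "",
        p_str, dt_str))
    }
  }
  lines <- c(lines, "", "## Model comparison", "",
             sprintf("mean delta R2 (plateau - first-order): %.4f",
                     mean(comparisons$delta_r2, na.rm = TRUE)),
             sprintf("plateau preferred for %d of %d conditions",
                     sum(comparisons$preferred == "plateau",
                         na.rm = TRUE), nrow(comparisons)))
  if (!is.null(an)) {
    lines <- c(lines, "", "## Repeated-measures ANOVA (environment)", "",
               sprintf("GG epsilon = %.4f; within-subject effects:",
                       an$gg_epsilon))
    w <- an$within[an$within$effect != "Residuals", ]
    lines <- c(lines, sprintf("- %s: F = %.2f, GG-corrected p = %.3g",
                              w$effect, w$F, w$p_gg))
  }
  if (!is.null(an_st)) {
    w <- an_st$within[an_st$within$effect != "Residuals", ]
    b <- an_st$between[an_st$between$effect != "Residuals", ]
    lines <- c(lines, "", "## Repeated-measures ANOVA (sterilization)",
               "",
               sprintf("- between %s: F = %.2f, p = %.3g",
                       b$effect, b$F, b$p),
               sprintf("- %s: F = %.2f, GG-corrected p = %.3g",
                       w$effect, w$F, w$p_gg))
  }
  if (!is.null(influence)) {
    lines <- c(lines, "", "## Factor influence", "",
               paste0("early stage (DT50 range): ",
                      format_ranking(influence$ranking, "early", "d")),
               paste0("late stage (Y0 range): ",
                      format_ranking(influence$ranking, "late")))
  }
  lines
}

#' Plot per-condition decay curves with both fitted models
#'
#' @param table Measurement table.
#' @param fits Fit results from [fit_all_conditions()].
#' @param file PDF path; `NULL` plots to the active device.
#' @param conditions Conditions to plot (default all).
#' @export
plot_condition_fits <- function(table, fits, file = NULL,
                                conditions = unique(table$condition_id)) {
  if (!is.null(file)) {
    grDevices::pdf(file, width = 6, height = 4.5)
    on.exit(grDevices::dev.off())
  }
  for (cid in conditions) {
    d <- table[table$condition_id == cid, ]
    plot(d$time_days, d$concentration_ng_per_g, pch = 16,
         col = "grey40", xlab = "time (d)",
         ylab = "concentration (ng/g dry soil)", main = cid)
    tt <- seq(0, max(d$time_days), length.out = 300)
    fo <- fits[fits$condition_id == cid &
                 fits$model_kind == "first_order", ]
    pl <- fits[fits$condition_id == cid & fits$model_kind == "plateau", ]
    if (nrow(fo) == 1 && fo$converged)
      graphics::lines(tt, fo$a * exp(-fo$b * tt), col = "steelblue",
                      lwd = 2)
    if (nrow(pl) == 1 && pl$converged)
      graphics::lines(tt, pl$Y0 + pl$a * exp(-pl$b * tt),
                      col = "firebrick", lwd = 2, lty = 2)
    graphics::legend("topright", bty = "n", lwd = 2, lty = c(1, 2),
                     col = c("steelblue", "firebrick"),
                     legend = c("first-order", "plateau"))
  }
  invisible(NULL)
}
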