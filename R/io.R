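.measurement_header <- c("condition_id", "soil_site", "temperature_C",
                         "water_content_pct", "sterilized", "replicate",
                         "time_days", "concentration_ng_per_g")

#' Read a measurement table from CSV
#'
#' Expects the canonical long-format header
#' `condition_id,soil_site,temperature_C,water_content_pct,sterilized,replicate,time_days,concentration_ng_per_g`.
#' Lines starting with `#` (provenance headers written by the pipeline)
#' are skipped. Rows are validated — duplicate
#' (condition, replicate, time) keys and negative concentrations are
#' reported with their row numbers — and returned in stable
#' (condition, replicate, time) order.
#'
#' @param path CSV file path.
#' @return A `measurement_table` data frame.
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- utils::read.csv(path, comment.char = "#",
                       stringsAsFactors = FALSE)
  missing_cols <- setdiff(.measurement_header, names(d))
  if (length(missing_cols) > 0)
    stop("missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  d <- d[, .measurement_header]
  d$sterilized <- as.logical(d$sterilized)
  d$replicate <- as.integer(d$replicate)
  d$time_days <- as.numeric(d$time_days)
  d$concentration_ng_per_g <- as.numeric(d$concentration_ng_per_g)
  bad <- which(!is.finite(d$time_days) | d$time_days < 0)
  if (length(bad) > 0)
    stop("invalid time_days at row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  bad <- which(!is.finite(d$concentration_ng_per_g) |
                 d$concentration_ng_per_g < 0)
  if (length(bad) > 0)
    stop("negative or non-numeric concentration at row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  key <- paste(d$condition_id, d$replicate, d$time_days)
  dup <- which(duplicated(key))
  if (length(dup) > 0)
    stop("duplicate (condition, replicate, time) at row(s): ",
         paste(utils::head(dup, 5), collapse = ", "),
         " (key ", key[dup[1]], ")", call. = FALSE)
  d <- d[order(d$condition_id, d$replicate, d$time_days), ]
  rownames(d) <- NULL
  class(d) <- c("measurement_table", "data.frame")
  d
}

config_hash <- function(config) {
  cfg <- unclass(config)
  # volatile presentation fields must not change the scientific identity
  cfg <- cfg[setdiff(names(cfg), c("outdir", "verbosity", "plots"))]
  sprintf("%08x", .string_hash(paste(utils::capture.output(utils::str(
    cfg, digits.d = 15, vec.len = 1e6)), collapse = "\n")))
}

.provenance_header <- function(seed = NA, hash = NA) {
  c(sprintf("# generated by btdecay %s",
            as.character(utils::packageVersion("btdecay"))),
    sprintf("# seed: %s", seed), sprintf("# config_hash: %s", hash))
}

write_csv_with_header <- function(d, path, seed = NA, hash = NA) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(.provenance_header(seed, hash), con)
  utils::write.csv(format(d, digits = 17, trim = TRUE),
                   con, row.names = FALSE, quote = FALSE)
}

#' Write a measurement table to CSV
#'
#' Writes the canonical long format with a provenance comment header
#' (seed and configuration hash). When the table carries a simulation
#' config (attribute `"config"`), a YAML sidecar `<path>.yml` with the
#' full configuration is written alongside for exact reproduction. Times
#' are serialized with 15 significant digits so sub-day points round-trip
#' exactly.
#'
#' @param table A `measurement_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(table, path) {
  stopifnot(is.data.frame(table))
  cfg <- attr(table, "config")
  seed <- if (!is.null(cfg)) cfg$seed else NA
  hash <- if (!is.null(cfg)) config_hash(cfg) else NA
  write_csv_with_header(as.data.frame(table)[, .measurement_header],
                        path, seed, hash)
  if (!is.null(cfg)) {
    side <- list(truth = as.list(as.data.frame(cfg$truth)),
                 schedule = cfg$schedule,
                 replicates = cfg$replicates, noise_cv = cfg$noise_cv,
                 noise_floor_sd = cfg$noise_floor_sd, seed = cfg$seed,
                 config_hash = hash)
    yaml::write_yaml(side, paste0(path, ".yml"), precision = 15)
  }
  invisible(path)
}
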