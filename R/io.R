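# Tabular I/O for trial inputs and results. Everything is plain CSV with a
# header row, UTF-8, decimal point. Timestamps are ISO-8601, read as UTC.

#' Write a result table to CSV
#'
#' Writes any of the package's result data frames with a deterministic
#' column order (as stored) and a fixed numeric precision, so that a
#' re-read compares equal to the written object within that precision.
#'
#' @param results a data frame.
#' @param path output file path.
#' @param digits significant digits used to render floating-point columns.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, digits = 10) {
  if (!is.data.frame(results)) stop("'results' must be a data.frame")
  out <- as.data.frame(results)
  for (cl in names(out)) {
    if (is.numeric(out[[cl]]) && !is.integer(out[[cl]])) {
      out[[cl]] <- signif(out[[cl]], digits)
    }
    if (inherits(out[[cl]], "POSIXt")) {
      out[[cl]] <- format(out[[cl]], "%Y-%m-%dT%H:%M:%S", tz = "UTC")
    }
  }
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write results to '", path, "': ",
                        conditionMessage(ok))
  invisible(path)
}

.require_columns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(sprintf("%s: missing column(s) %s", what,
                 paste(sQuote(miss), collapse = ", ")))
  }
  invisible(df)
}

#' Read chamber gas-exchange records
#'
#' Expected columns: `sow_id`, `timestamp` (ISO-8601), `o2_conc`,
#' `co2_conc`, `ch4_conc` (volume-fraction differences between inlet and
#' exhaust air, O2 as depletion and CO2/CH4 as enrichment), `flow_l_min`,
#' and `state` (`"fed"` or `"fasted"`). Timestamps must be strictly
#' increasing within a sow.
#'
#' @param path CSV file path.
#' @return Data frame with `timestamp` parsed as POSIXct (UTC).
#' @export
read_gas_records <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .require_columns(df, c("sow_id", "timestamp", "o2_conc", "co2_conc",
                         "ch4_conc", "flow_l_min", "state"),
                   paste0("gas file '", path, "'"))
  ts <- as.POSIXct(df$timestamp, tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S"))
  if (anyNA(ts)) {
    stop(sprintf("gas file '%s': unparseable timestamp in row %d",
                 path, which(is.na(ts))[1]))
  }
  df$timestamp <- ts
  for (sid in unique(df$sow_id)) {
    t_s <- df$timestamp[df$sow_id == sid]
    if (is.unsorted(t_s, strictly = TRUE)) {
      stop(sprintf("gas file '%s': timestamps not strictly increasing for sow '%s'",
                   path, sid))
    }
  }
  bad <- with(df, o2_conc < 0 | o2_conc > 1 | co2_conc < 0 | co2_conc > 1 |
                ch4_conc < 0 | ch4_conc > 1)
  if (any(bad, na.rm = TRUE)) {
    stop(sprintf("gas file '%s': concentration outside [0, 1] in row %d",
                 path, which(bad)[1]))
  }
  df
}

#' Read total-collection records
#'
#' Expected columns: `sow_id`, `period`, `kind` (`"feces"` or `"urine"`),
#' `mass_kg_d`, `ge` (MJ/kg as-collected for feces; MJ/d for urine),
#' `n_g_d`, and `dm_pct` (feces only; may be `NA` for urine).
#'
#' @param path CSV file path.
#' @return Data frame of collection records.
#' @export
read_collection_records <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .require_columns(df, c("sow_id", "period", "kind", "ge", "n_g_d"),
                   paste0("collection file '", path, "'"))
  if (!all(df$kind %in% c("feces", "urine"))) {
    stop(sprintf("collection file '%s': kind must be 'feces' or 'urine'", path))
  }
  num <- intersect(c("mass_kg_d", "ge", "n_g_d", "dm_pct"), names(df))
  for (cl in num) {
    if (any(df[[cl]] < 0, na.rm = TRUE)) {
      stop(sprintf("collection file '%s': negative %s in row %d",
                   path, cl, which(df[[cl]] < 0)[1]))
    }
  }
  df
}

#' Read sow-period descriptors
#'
#' Expected columns: `sow_id`, `period`, `diet_id`, `bw_kg`,
#' `dm_intake_kg_d`, `feed_ge_mj_kg_dm`, plus the calorimetry schedule:
#' `fed_start` (date of the first fed calorimetry day), `n_fed_days`,
#' `fast_start` and `fast_end` (ISO-8601 timestamps of the fasting
#' window).
#'
#' @param path CSV file path.
#' @return Data frame with a derived `metabolic_bw` (`bw_kg^0.75`) column.
#' @export
read_sow_periods <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .require_columns(df, c("sow_id", "period", "diet_id", "bw_kg",
                         "dm_intake_kg_d", "feed_ge_mj_kg_dm"),
                   paste0("sow-period file '", path, "'"))
  if (any(df$bw_kg <= 0)) stop("sow-period file: bw_kg must be > 0")
  if (any(df$dm_intake_kg_d < 0)) stop("sow-period file: dm_intake_kg_d must be >= 0")
  df$metabolic_bw <- df$bw_kg^0.75
  for (cl in intersect(c("fast_start", "fast_end"), names(df))) {
    df[[cl]] <- as.POSIXct(df[[cl]], tz = "UTC",
                           tryFormats = c("%Y-%m-%dT%H:%M:%S",
                                          "%Y-%m-%d %H:%M:%S"))
  }
  df
}

#' Read diet formulations
#'
#' Long-format CSV with columns `diet_id`, `ingredient`, `inclusion_pct`
#' (as-fed). Checks that each diet's inclusions sum to 100 within 0.01.
#'
#' @param path CSV file path.
#' @return Data frame of formulation rows.
#' @export
read_diet_formulations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .require_columns(df, c("diet_id", "ingredient", "inclusion_pct"),
                   paste0("diet file '", path, "'"))
  tot <- tapply(df$inclusion_pct, df$diet_id, sum)
  off <- names(tot)[abs(tot - 100) > 0.01]
  if (length(off)) {
    warning("diet inclusions do not sum to 100: ",
            paste(sprintf("%s (%.2f)", off, tot[off]), collapse = ", "),
            call. = FALSE)
  }
  df
}
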