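# CSV interchange: disaggregated-estimate tables (one row per
# setting/year/dimension/subgroup), summary tables (one row per measure),
# and individual-level survey record tables. Comma-separated, UTF-8, "."
# decimal separator, empty cells for missing optional values.

# parse a character column to numeric with a diagnostic naming the row
parse_num <- function(x, column, optional = FALSE) {
  x <- trimws(x)
  blank <- is.na(x) | x == ""
  if (any(blank) && !optional) {
    stop("column '", column, "': missing value in data row(s) ",
         paste(which(blank), collapse = ", "))
  }
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!blank & is.na(out))
  if (length(bad))
    stop("column '", column, "': cannot parse value '", x[bad[1]],
         "' in data row ", bad[1])
  out
}

#' Read a disaggregated estimate table
#'
#' Reads a CSV with one row per setting/year/dimension/subgroup carrying a
#' prevalence estimate in percent and optional uncertainty columns.
#' Required columns: `setting`, `year`, `dimension`, `subgroup`,
#' `estimate`; optional: `se`, `ci_low`, `ci_high`, `n`, `pop_share`.
#' Rows whose `dimension` is not declared in `dimensions` are dropped with
#' a warning; unknown subgroup labels within a declared dimension are an
#' error, as are estimates outside \[0, 100\].
#'
#' @param path CSV file path.
#' @param dimensions A `dimension_spec` or list of them declaring the
#'   expected dimensions and subgroup labels.
#' @return A data frame sorted by setting, year, dimension (declaration
#'   order) and subgroup (spec order), with columns `setting`, `year`,
#'   `dimension`, `subgroup`, `estimate`, `se`, `ci_low`, `ci_high`, `n`,
#'   `pop_share` (missing optional values are `NA`).
#' @seealso [write_summary_table()], [ghana_mics_table1()]
#' @export
read_disaggregated_table <- function(path, dimensions) {
  dimensions <- as_dimension_list(dimensions)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, na.strings = NULL)
  req <- c("setting", "year", "dimension", "subgroup", "estimate")
  miss <- setdiff(req, names(raw))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  opt <- c("se", "ci_low", "ci_high", "n", "pop_share")
  for (cn in setdiff(opt, names(raw))) raw[[cn]] <- ""
  if (nrow(raw) == 0L) {
    out <- data.frame(setting = character(), year = integer(),
                      dimension = character(), subgroup = character(),
                      estimate = numeric(), se = numeric(),
                      ci_low = numeric(), ci_high = numeric(),
                      n = integer(), pop_share = numeric())
    return(out)
  }

  unknown <- !(raw$dimension %in% names(dimensions))
  if (any(unknown)) {
    warning("rejected ", sum(unknown), " row(s) with undeclared dimension(s): ",
            paste(unique(raw$dimension[unknown]), collapse = ", "))
    raw <- raw[!unknown, , drop = FALSE]
  }

  out <- data.frame(
    setting = raw$setting,
    year = as.integer(parse_num(raw$year, "year")),
    dimension = raw$dimension,
    subgroup = raw$subgroup,
    estimate = parse_num(raw$estimate, "estimate"),
    se = parse_num(raw$se, "se", optional = TRUE),
    ci_low = parse_num(raw$ci_low, "ci_low", optional = TRUE),
    ci_high = parse_num(raw$ci_high, "ci_high", optional = TRUE),
    n = as.integer(parse_num(raw$n, "n", optional = TRUE)),
    pop_share = parse_num(raw$pop_share, "pop_share", optional = TRUE)
  )

  bad <- which(out$estimate < 0 | out$estimate > 100)
  if (length(bad))
    stop("estimate outside [0, 100] in data row(s) ",
         paste(bad, collapse = ", "))

  # validate and order each setting/year/dimension block
  key <- interaction(out$setting, out$year, out$dimension, drop = TRUE)
  for (k in levels(key)) {
    blk <- out[key == k, , drop = FALSE]
    validate_estimates(blk, dimensions[[blk$dimension[1]]],
                       where = paste0("table block ", k))
  }
  dim_rank <- match(out$dimension, names(dimensions))
  sub_rank <- mapply(function(d, s) match(s, dimensions[[d]]$subgroups),
                     out$dimension, out$subgroup)
  out <- out[order(out$setting, out$year, dim_rank, sub_rank), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write an inequality summary table
#'
#' Serializes summary-measure results to CSV with columns `setting`,
#' `year`, `dimension`, `measure`, `estimate`, `ui_low`, `ui_high`,
#' `reference_subgroup`, `comparison_subgroup`. Values are written at full
#' precision so that a write/read round trip is lossless.
#'
#' @param results Data frame of summaries (e.g. from
#'   [health_inequality()] via `as.data.frame`), non-empty.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_summary_table <- function(results, path) {
  results <- as.data.frame(results)
  if (nrow(results) == 0L) stop("'results' must contain at least one row")
  cols <- c("setting", "year", "dimension", "measure", "estimate",
            "ui_low", "ui_high", "reference_subgroup", "comparison_subgroup")
  for (cn in setdiff(cols, names(results))) results[[cn]] <- NA
  ok <- tryCatch({
    utils::write.csv(results[, cols], path, row.names = FALSE, na = "")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write '", path, "': ", conditionMessage(ok))
  invisible(path)
}

#' Read an inequality summary table written by [write_summary_table()]
#'
#' @param path CSV file path.
#' @return Data frame with the summary-table columns.
#' @export
read_summary_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, na.strings = NULL)
  data.frame(
    setting = raw$setting,
    year = as.integer(parse_num(raw$year, "year", optional = TRUE)),
    dimension = raw$dimension,
    measure = raw$measure,
    estimate = parse_num(raw$estimate, "estimate"),
    ui_low = parse_num(raw$ui_low, "ui_low", optional = TRUE),
    ui_high = parse_num(raw$ui_high, "ui_high", optional = TRUE),
    reference_subgroup = raw$reference_subgroup,
    comparison_subgroup = raw$comparison_subgroup
  )
}

#' Read individual-level survey records
#'
#' Reads a CSV of respondent records for design-based estimation. Required
#' columns: `stratum`, `cluster`, `weight`, `outcome` (binary 0/1), plus
#' one column per declared dimension holding subgroup labels. Empty
#' stratifier cells are kept as `NA` (the record still contributes to the
#' overall average but is excluded from that dimension's disaggregation);
#' a message reports how many were flagged.
#'
#' @param path CSV file path.
#' @param dimensions A `dimension_spec` or list of them; each dimension
#'   name must match a column in the file.
#' @return Data frame with columns `stratum`, `cluster`, `weight`,
#'   `outcome` and one character column per dimension.
#' @export
read_survey_records <- function(path, dimensions) {
  dimensions <- as_dimension_list(dimensions)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, na.strings = NULL)
  req <- c("stratum", "cluster", "weight", "outcome")
  miss <- setdiff(c(req, names(dimensions)), names(raw))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  out <- data.frame(
    stratum = raw$stratum,
    cluster = raw$cluster,
    weight = parse_num(raw$weight, "weight"),
    outcome = parse_num(raw$outcome, "outcome")
  )
  if (any(out$weight <= 0))
    stop("column 'weight': non-positive weight in data row(s) ",
         paste(which(out$weight <= 0), collapse = ", "))
  if (!all(out$outcome %in% c(0, 1)))
    stop("column 'outcome': values outside {0, 1} in data row(s) ",
         paste(which(!(out$outcome %in% c(0, 1))), collapse = ", "))
  n_flagged <- 0L
  for (d in names(dimensions)) {
    v <- trimws(raw[[d]])
    v[v == ""] <- NA_character_
    n_flagged <- n_flagged + sum(is.na(v))
    known <- is.na(v) | v %in% dimensions[[d]]$subgroups
    if (!all(known))
      stop("column '", d, "': unknown subgroup label(s) ",
           paste(unique(v[!known]), collapse = ", "), " in data row(s) ",
           paste(which(!known), collapse = ", "))
    out[[d]] <- v
  }
  if (n_flagged > 0L)
    message(n_flagged, " missing stratifier value(s) flagged; records kept ",
            "for overall estimation")
  out
}

#' Write survey records to CSV
#'
#' Inverse of [read_survey_records()]; used by the simulator and the
#' command-line pipeline.
#'
#' @param records Data frame with `stratum`, `cluster`, `weight`,
#'   `outcome` and stratifier columns.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_survey_records <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}
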