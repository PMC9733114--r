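# Packaged fixtures transcribing the published Ghana MICS 2011/2017
# analysis of ITN use by pregnant women (disaggregated subgroup estimates,
# printed overall prevalences, and the printed inequality summary table),
# plus the reproduction pipeline that recomputes every summary measure
# from the subgroup estimates and compares against the printed values.

fixture_path <- function(name) {
  p <- system.file("extdata", name, package = "healthineq")
  if (p == "") stop("packaged fixture not found: ", name)
  p
}

#' Stratifier declarations for the packaged Ghana tables
#'
#' @return Named list of four [dimension_spec()]s matching the published
#'   table: `Economic status` (ordered wealth quintiles), `Education`
#'   (ordered), `Place of residence` (binary, Rural then Urban) and
#'   `Sub-national region` (non-ordered, Ghana's ten pre-2019 regions).
#' @export
ghana_dimensions <- function() {
  list(
    `Economic status` = dimension_spec("Economic status", "ordered",
      c("Quintile 1 (poorest)", "Quintile 2", "Quintile 3", "Quintile 4",
        "Quintile 5 (richest)")),
    Education = dimension_spec("Education", "ordered",
      c("No formal education", "Primary school",
        "Secondary/higher education")),
    `Place of residence` = dimension_spec("Place of residence", "binary",
      c("Rural", "Urban")),
    `Sub-national region` = dimension_spec("Sub-national region",
      "non_ordered",
      c("Ashanti", "Brong Ahafo", "Central", "Eastern", "Greater Accra",
        "Northern", "Upper East", "Upper West", "Volta", "Western"))
  )
}

#' Packaged disaggregated estimates (Ghana MICS 2011/2017, ITN use)
#'
#' Subgroup prevalence of pregnant women sleeping under an
#' insecticide-treated net, by wealth quintile, education, residence and
#' region, with 95% confidence bounds and unweighted counts, as published.
#'
#' @return Data frame in the [read_disaggregated_table()] layout.
#' @export
ghana_mics_table1 <- function() {
  read_disaggregated_table(fixture_path("ghana_mics_table1.csv"),
                           ghana_dimensions())
}

#' Published overall ITN-use prevalences (32.6% in 2011, 49.7% in 2017)
#'
#' These setting averages are survey outputs of the external microdata
#' and enter the complex measures (PAR, PAF) as fixture inputs.
#'
#' @return Data frame with columns `setting`, `year`, `estimate`.
#' @export
ghana_mics_overall <- function() {
  raw <- utils::read.csv(fixture_path("ghana_mics_overall.csv"),
                         colClasses = "character")
  data.frame(setting = raw$setting, year = as.integer(raw$year),
             estimate = as.numeric(raw$estimate))
}

#' Published inequality summary table (printed point estimates and UIs)
#'
#' @return Data frame with columns `setting`, `year`, `dimension`,
#'   `measure`, `estimate`, `ui_low`, `ui_high`, `note` (non-empty for
#'   cells with a known rounding-provenance discrepancy).
#' @export
ghana_mics_table2 <- function() {
  raw <- utils::read.csv(fixture_path("ghana_mics_table2.csv"),
                         colClasses = "character")
  data.frame(setting = raw$setting, year = as.integer(raw$year),
             dimension = raw$dimension, measure = raw$measure,
             estimate = as.numeric(raw$estimate),
             ui_low = as.numeric(raw$ui_low),
             ui_high = as.numeric(raw$ui_high),
             note = raw$note)
}

#' Back out a standard error from a logit confidence interval
#'
#' Published tables report asymmetric intervals consistent with a normal
#' interval on the logit scale; inverting that construction recovers an
#' approximate standard error for delta-method work downstream.
#'
#' @param estimate Prevalence in percent.
#' @param ci_low,ci_high Confidence bounds in percent.
#' @param level Coverage of the interval (default 0.95).
#' @return Standard error in percentage points (`NA` at boundary
#'   estimates).
#' @export
se_from_ci <- function(estimate, ci_low, ci_high, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- estimate / 100
  out <- ifelse(
    estimate <= 0 | estimate >= 100 | ci_low <= 0 | ci_high >= 100,
    NA_real_,
    (stats::qlogis(ci_high / 100) - stats::qlogis(ci_low / 100)) / (2 * z) *
      p * (1 - p) * 100
  )
  out
}

#' Recompute the published inequality table and compare cell by cell
#'
#' Runs the full measurement pipeline on the packaged subgroup estimates,
#' using the published overall prevalences as mu, and compares every
#' computed point estimate with the printed one after identical rounding
#' (one decimal, half away from zero). Cells with a known
#' rounding-provenance discrepancy carry an explanatory note from the
#' fixture; any other mismatch is annotated with the difference.
#'
#' @param ui_level UI coverage for the recomputed intervals.
#' @param table1,overall,printed The disaggregated estimates, overall
#'   prevalences and printed summary table; default to the packaged
#'   fixtures and exist mainly so sensitivity to a perturbed cell can be
#'   demonstrated.
#' @return An object of class `reproduction_report`: a data frame with
#'   columns `year`, `dimension`, `measure`, `computed`, `printed`,
#'   `match`, `note`, plus attributes `n_match` and `n_cells`.
#' @examples
#' rep <- reproduce_tables()
#' attr(rep, "n_match")
#' @export
reproduce_tables <- function(ui_level = 0.95, table1 = ghana_mics_table1(),
                             overall = ghana_mics_overall(),
                             printed = ghana_mics_table2()) {
  dims <- ghana_dimensions()
  t1 <- table1
  ov <- overall
  if (is.null(printed$note)) printed$note <- ""
  t1$se <- se_from_ci(t1$estimate, t1$ci_low, t1$ci_high)

  computed <- do.call(rbind, lapply(unique(printed$year), function(yr) {
    tab <- t1[t1$year == yr, , drop = FALSE]
    mu <- ov$estimate[ov$year == yr]
    fit <- health_inequality(tab, mu = setting_average(mu, 0), dims,
                             ui_level = ui_level)
    if (length(fit$failures))
      stop("reproduction failed for ", yr, ": ",
           paste(fit$failures, collapse = "; "))
    cbind(year = yr, fit$summaries)
  }))

  key <- function(d) paste(d$year, d$dimension, d$measure)
  m <- match(key(printed), key(computed))
  if (anyNA(m)) stop("computed table is missing printed cells")
  rep <- data.frame(
    year = printed$year,
    dimension = printed$dimension,
    measure = printed$measure,
    computed = computed$estimate[m],
    computed_ui_low = computed$ui_low[m],
    computed_ui_high = computed$ui_high[m],
    printed = printed$estimate,
    match = round_report(computed$estimate[m], 1) == printed$estimate,
    note = printed$note
  )
  need_note <- !rep$match & rep$note == ""
  rep$note[need_note] <- sprintf(
    "computed %s differs from printed %s",
    format(round_report(rep$computed[need_note], 1)),
    format(rep$printed[need_note]))
  structure(rep, class = c("reproduction_report", "data.frame"),
            n_match = sum(rep$match), n_cells = nrow(rep))
}

#' @export
print.reproduction_report <- function(x, ...) {
  cat(sprintf("Reproduction of the published inequality table: %d/%d point estimates match at 1-decimal rounding\n\n",
              attr(x, "n_match"), attr(x, "n_cells")))
  d <- as.data.frame(x)
  d$computed <- round_report(d$computed, 1)
  d$flag <- ifelse(d$match, "", "*")
  print(d[, c("year", "dimension", "measure", "computed", "printed", "flag")],
        row.names = FALSE)
  star <- d[!d$match, , drop = FALSE]
  if (nrow(star)) {
    cat("\nFlagged cells:\n")
    for (i in seq_len(nrow(star)))
      cat(sprintf("  * %s %s %s: %s\n", star$year[i], star$dimension[i],
                  star$measure[i], star$note[i]))
  }
  invisible(x)
}
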