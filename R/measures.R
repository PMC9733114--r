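# The four summary measures of health inequality used in WHO-style equity
# monitoring: Difference (D) and Ratio (R) are simple measures comparing
# two extreme subgroups; Population Attributable Risk (PAR) and Population
# Attributable Fraction (PAF) are complex measures comparing the reference
# (best-achievable) subgroup with the population average mu and therefore
# account for subgroup sizes through the weighting baked into mu.

#' Identify the extreme subgroups of a dimension
#'
#' For ordered and binary dimensions the extremes are fixed by the
#' declared subgroup order (the last label is the advantaged extreme),
#' regardless of the estimate values. For non-ordered dimensions the
#' extremes are data-driven: with a favourable indicator the advantaged
#' extreme is the best-performing (highest-estimate) subgroup and the
#' disadvantaged extreme the lowest; for an adverse indicator the roles
#' are mirrored. Ties are broken by label sort order with a warning.
#'
#' @param estimates Data frame of subgroup rows (columns `subgroup`,
#'   `estimate`, optionally `se`) for one dimension.
#' @param spec The [dimension_spec()].
#' @return List with elements `advantaged` and `disadvantaged`, each a
#'   one-row data frame.
#' @export
select_extremes <- function(estimates, spec) {
  miss <- setdiff(spec$subgroups, estimates$subgroup)
  if (length(miss))
    stop("dimension '", spec$name, "': missing declared subgroup(s): ",
         paste(miss, collapse = ", "))
  row_of <- function(g) estimates[match(g, estimates$subgroup), , drop = FALSE]
  if (spec$kind %in% c("ordered", "binary")) {
    adv <- row_of(spec$subgroups[length(spec$subgroups)])
    dis <- row_of(spec$subgroups[1L])
  } else {
    pick <- function(best) {
      e <- if (best) max(estimates$estimate) else min(estimates$estimate)
      hit <- estimates$subgroup[estimates$estimate == e]
      if (length(hit) > 1L) {
        hit <- sort(hit)
        warning("dimension '", spec$name, "': tie for the ",
                if (best) "highest" else "lowest",
                " estimate; picking '", hit[1L], "'")
      }
      row_of(hit[1L])
    }
    hi <- pick(TRUE)
    lo <- pick(FALSE)
    if (spec$favourable) { adv <- hi; dis <- lo } else { adv <- lo; dis <- hi }
  }
  list(advantaged = adv, disadvantaged = dis)
}

#' Uncertainty interval for a summary measure (delta method)
#'
#' Normal-theory intervals for the four measures: for D on the natural
#' scale with `se_D = sqrt(se1^2 + se2^2)`; for R on the log scale with
#' `se_logR = sqrt((se1/y1)^2 + (se2/y2)^2)`, back-transformed; for PAR
#' with `se_PAR = sqrt(se_ref^2 + se_mu^2)` (the covariance between the
#' reference subgroup and mu is ignored; the bootstrap route in
#' [health_inequality()] is the covariance-honest alternative); for PAF
#' the PAR interval scaled by `100/mu`.
#'
#' @param measure One of `"D"`, `"R"`, `"PAR"`, `"PAF"`.
#' @param estimates For D and R, `c(y1, y2)` (numerator/advantaged first);
#'   for PAR and PAF, the reference subgroup estimate `y_ref`.
#' @param ses Standard errors matching `estimates` (for PAR/PAF a single
#'   `se_ref`).
#' @param mu,se_mu Setting average and its standard error (PAR/PAF only).
#' @param centre Value the interval is centred on (defaults to the point
#'   estimate implied by the inputs; PAR passes its truncated estimate).
#' @param level Coverage in (0, 1).
#' @return `c(ui_low, ui_high)`.
#' @examples
#' measure_ui("D", c(10, 5), c(3, 4))  # half-width 1.96 * 5
#' @export
measure_ui <- function(measure = c("D", "R", "PAR", "PAF"),
                       estimates, ses, mu = NULL, se_mu = 0,
                       centre = NULL, level = 0.95) {
  measure <- match.arg(measure)
  if (anyNA(ses))
    stop("standard errors unavailable for the delta method; use the ",
         "bootstrap interval with record-level data instead")
  z <- stats::qnorm(1 - (1 - level) / 2)
  switch(measure,
    D = {
      est <- if (is.null(centre)) estimates[1] - estimates[2] else centre
      hw <- z * sqrt(ses[1]^2 + ses[2]^2)
      c(est - hw, est + hw)
    },
    R = {
      if (any(estimates <= 0)) stop("ratio interval needs positive estimates")
      r <- if (is.null(centre)) estimates[1] / estimates[2] else centre
      sl <- sqrt((ses[1] / estimates[1])^2 + (ses[2] / estimates[2])^2)
      c(r * exp(-z * sl), r * exp(z * sl))
    },
    PAR = {
      if (is.null(mu)) stop("PAR interval needs 'mu'")
      est <- if (is.null(centre)) estimates[1] - mu else centre
      hw <- z * sqrt(ses[1]^2 + se_mu^2)
      c(est - hw, est + hw)
    },
    PAF = {
      if (is.null(mu) || mu <= 0) stop("PAF interval needs 'mu' > 0")
      measure_ui("PAR", estimates, ses, mu = mu, se_mu = se_mu,
                 centre = centre, level = level) * 100 / mu
    }
  )
}

summary_row <- function(measure, estimate, ui, ref, cmp) {
  data.frame(measure = measure, estimate = estimate,
             ui_low = ui[1], ui_high = ui[2],
             reference_subgroup = ref, comparison_subgroup = cmp)
}

#' Difference (D): simple absolute inequality
#'
#' For ordered/binary dimensions `D = y_advantaged - y_disadvantaged`
#' (negative when the disadvantaged subgroup performs better, as for ITN
#' use); for non-ordered dimensions `D = y_max - y_min >= 0`.
#'
#' @inheritParams select_extremes
#' @param level UI coverage.
#' @return One-row data frame (`measure`, `estimate`, `ui_low`, `ui_high`,
#'   `reference_subgroup`, `comparison_subgroup`); percentage points.
#' @export
ineq_difference <- function(estimates, spec, level = 0.95) {
  ex <- select_extremes(estimates, spec)
  if (spec$kind == "non_ordered") {
    hi <- if (ex$advantaged$estimate >= ex$disadvantaged$estimate)
      ex$advantaged else ex$disadvantaged
    lo <- if (identical(hi, ex$advantaged)) ex$disadvantaged else ex$advantaged
    d <- hi$estimate - lo$estimate
    ui <- measure_ui("D", c(hi$estimate, lo$estimate),
                     c(se_of(hi), se_of(lo)), level = level)
    return(summary_row("D", d, ui, hi$subgroup, lo$subgroup))
  }
  d <- ex$advantaged$estimate - ex$disadvantaged$estimate
  ui <- measure_ui("D", c(ex$advantaged$estimate, ex$disadvantaged$estimate),
                   c(se_of(ex$advantaged), se_of(ex$disadvantaged)),
                   level = level)
  summary_row("D", d, ui, ex$advantaged$subgroup, ex$disadvantaged$subgroup)
}

#' Ratio (R): simple relative inequality
#'
#' For ordered/binary dimensions `R = y_advantaged / y_disadvantaged`;
#' for non-ordered dimensions `R = y_max / y_min >= 1`. The UI is a
#' normal interval on `log R`, back-transformed.
#'
#' @inheritParams ineq_difference
#' @return One-row summary data frame; dimensionless.
#' @export
ineq_ratio <- function(estimates, spec, level = 0.95) {
  ex <- select_extremes(estimates, spec)
  if (spec$kind == "non_ordered") {
    hi <- if (ex$advantaged$estimate >= ex$disadvantaged$estimate)
      ex$advantaged else ex$disadvantaged
    lo <- if (identical(hi, ex$advantaged)) ex$disadvantaged else ex$advantaged
    num <- hi; den <- lo
  } else {
    num <- ex$advantaged; den <- ex$disadvantaged
  }
  if (den$estimate == 0)
    stop("dimension '", spec$name, "': zero denominator, ratio undefined")
  r <- num$estimate / den$estimate
  ui <- measure_ui("R", c(num$estimate, den$estimate),
                   c(se_of(num), se_of(den)), level = level)
  summary_row("R", r, ui, num$subgroup, den$subgroup)
}

# se column may be absent or NA; delta formulas then error via measure_ui
se_of <- function(row) {
  if (!("se" %in% names(row))) return(NA_real_)
  row$se
}

#' Population Attributable Risk (PAR): complex absolute inequality
#'
#' `PAR = y_ref - mu`, the population-level gain achievable if every
#' subgroup attained the reference level. For ordered/binary dimensions
#' the reference is the most-advantaged subgroup; for non-ordered
#' dimensions with a favourable indicator it is the best-performing
#' (highest-estimate) subgroup, mirrored for adverse indicators. By
#' convention a PAR pointing the "wrong" way (reference below the average
#' for a favourable indicator) is truncated to zero — no inequality in
#' the attributable sense — while the UI stays centred on the reported
#' value with the untruncated standard error, matching published tables
#' that print PAR 0 with symmetric bounds.
#'
#' @inheritParams ineq_difference
#' @param mu A [setting_average()] (or single numeric, percent).
#' @param truncate Truncate the point estimate at zero (default `TRUE`).
#' @return One-row summary data frame; percentage points.
#' @export
ineq_par <- function(estimates, spec, mu, truncate = TRUE, level = 0.95) {
  if (missing(mu) || is.null(mu)) stop("PAR needs the setting average 'mu'")
  if (is.numeric(mu)) mu <- setting_average(mu)
  ex <- select_extremes(estimates, spec)
  ref <- ex$advantaged  # best-performing under the non_ordered rule above
  raw <- ref$estimate - mu$mu
  est <- raw
  if (truncate)
    est <- if (spec$favourable) max(0, raw) else min(0, raw)
  ui <- measure_ui("PAR", ref$estimate, se_of(ref), mu = mu$mu,
                   se_mu = mu$se_mu, centre = est, level = level)
  summary_row("PAR", est, ui, ref$subgroup, "(overall average)")
}

#' Population Attributable Fraction (PAF): complex relative inequality
#'
#' `PAF = 100 * PAR / mu`, PAR expressed as a percentage of the overall
#' average; applied to the point estimate and both UI bounds of the PAR
#' result, so the identity holds exactly pre-rounding. Zero PAF (like
#' zero PAR) means no inequality.
#'
#' @param par One-row PAR summary from [ineq_par()].
#' @param mu A [setting_average()] (or single numeric, percent), > 0.
#' @return One-row summary data frame; percent.
#' @export
ineq_paf <- function(par, mu) {
  if (is.numeric(mu)) mu <- setting_average(mu)
  if (mu$mu <= 0) stop("PAF undefined: mu must be positive")
  f <- 100 / mu$mu
  summary_row("PAF", par$estimate * f, c(par$ui_low, par$ui_high) * f,
              par$reference_subgroup, par$comparison_subgroup)
}

#' Compute all four inequality summary measures
#'
#' The main fitting function: given a disaggregated table of subgroup
#' estimates (or raw survey records) and the setting average, computes
#' D, R, PAR and PAF with uncertainty intervals for every declared
#' dimension. A failure in one dimension (e.g. a missing subgroup) is
#' recorded and does not abort the others.
#'
#' @param table Data frame of subgroup estimates with columns `dimension`,
#'   `subgroup`, `estimate` and (for delta intervals) `se`; ignored when
#'   `records` is supplied.
#' @param mu Setting average: a [setting_average()] or single numeric in
#'   percent (its se then defaults to 0, as when mu comes from a published
#'   table); computed from `records` when those are given.
#' @param dimensions A [dimension_spec()] or list of them.
#' @param records,design Optional individual-level records and
#'   [svy_design()]; when supplied, subgroup estimates and mu are computed
#'   by [weighted_prevalence()] / [overall_average()], and the bootstrap
#'   interval becomes available.
#' @param ui_method `"delta"` (closed-form, default) or `"bootstrap"`
#'   (percentile interval over cluster resamples; requires `records`).
#' @param reps Bootstrap replicates (default 1000).
#' @param seed Optional seed for the bootstrap.
#' @param ui_level UI coverage (default 0.95).
#' @param truncate_par Truncate PAR (and hence PAF) at zero.
#' @param report_decimals Decimals used by the print method.
#' @return An object of class `health_inequality` with components
#'   `summaries` (data frame: `dimension`, `measure`, `estimate`,
#'   `ui_low`, `ui_high`, `reference_subgroup`, `comparison_subgroup`),
#'   `failures` (named character vector of per-dimension errors), `mu`,
#'   `table`, `dimensions` and `call`. Methods: `print`, `summary`,
#'   `coef`, `confint`, `as.data.frame`.
#' @examples
#' spec <- dimension_spec("residence", "binary", c("Rural", "Urban"))
#' tab <- data.frame(dimension = "residence",
#'                   subgroup = c("Rural", "Urban"),
#'                   estimate = c(43.6, 18.8), se = c(2.6, 3.2))
#' fit <- health_inequality(tab, mu = 32.6, dimensions = spec)
#' coef(fit)
#' @export
health_inequality <- function(table = NULL, mu = NULL, dimensions,
                              records = NULL, design = svy_design(),
                              ui_method = c("delta", "bootstrap"),
                              reps = 1000, seed = NULL, ui_level = 0.95,
                              truncate_par = TRUE, report_decimals = 1) {
  ui_method <- match.arg(ui_method)
  dimensions <- as_dimension_list(dimensions)
  if (!is.null(records)) {
    table <- do.call(rbind, lapply(dimensions, function(d)
      weighted_prevalence(records, design, d, level = ui_level)))
    mu <- overall_average(records, design, level = ui_level)
  }
  if (is.null(table) || is.null(mu))
    stop("supply either 'table' and 'mu', or 'records'")
  if (is.numeric(mu)) mu <- setting_average(mu)
  # published tables often carry CIs but no SEs: invert the logit interval
  if (!("se" %in% names(table))) table$se <- NA_real_
  if (all(c("ci_low", "ci_high") %in% names(table))) {
    fill <- is.na(table$se) & !is.na(table$ci_low) & !is.na(table$ci_high)
    table$se[fill] <- se_from_ci(table$estimate[fill], table$ci_low[fill],
                                 table$ci_high[fill], level = ui_level)
  }
  if (ui_method == "bootstrap" && is.null(records))
    stop("bootstrap intervals require record-level data ('records')")

  boot <- NULL
  if (ui_method == "bootstrap")
    boot <- bootstrap_measures(records, design, dimensions, reps = reps,
                               seed = seed, level = ui_level,
                               truncate_par = truncate_par)

  out <- list()
  failures <- character()
  for (d in names(dimensions)) {
    spec <- dimensions[[d]]
    est <- table[table$dimension == d, , drop = FALSE]
    res <- tryCatch({
      rows <- rbind(
        ineq_difference(est, spec, level = ui_level),
        ineq_ratio(est, spec, level = ui_level),
        p <- ineq_par(est, spec, mu, truncate = truncate_par,
                      level = ui_level),
        ineq_paf(p, mu)
      )
      if (!is.null(boot)) {
        for (m in rows$measure) {
          b <- boot[[d]][[m]]
          if (!is.null(b)) {
            rows[rows$measure == m, c("ui_low", "ui_high")] <- as.list(b)
          }
        }
      }
      cbind(dimension = d, rows)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[d] <- conditionMessage(res)
    } else {
      out[[d]] <- res
    }
  }
  structure(
    list(summaries = if (length(out)) do.call(rbind, c(out, list(make.row.names = FALSE)))
         else NULL,
         failures = failures, mu = mu, table = table,
         dimensions = dimensions, ui_level = ui_level,
         ui_method = ui_method, report_decimals = report_decimals,
         call = match.call()),
    class = "health_inequality"
  )
}

# percentile cluster bootstrap: PSUs resampled with replacement within
# strata; every measure recomputed per resample (extremes re-selected for
# non-ordered dimensions), intervals from the raw/untruncated PAR scale
bootstrap_measures <- function(records, design, dimensions, reps = 1000,
                               seed = NULL, level = 0.95,
                               truncate_par = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  st <- as.character(records[[design$stratum]])
  cl <- as.character(records[[design$cluster]])
  w <- records[[design$weight]]
  y <- records[[design$outcome]]
  psu <- paste(st, cl, sep = "\r")
  psu_ids <- split(unique(psu), st[!duplicated(psu)])
  idx_of <- split(seq_along(psu), psu)

  point <- function(idx) {
    wi <- w[idx]; yi <- y[idx]
    mu_b <- 100 * sum(wi * yi) / sum(wi)
    sapply(dimensions, function(spec) {
      v <- records[[spec$name]][idx]
      ok <- !is.na(v)
      W <- rowsum(wi[ok], v[ok])[, 1]
      Y <- rowsum((wi * yi)[ok], v[ok])[, 1]
      p <- 100 * Y / W
      if (!all(spec$subgroups %in% names(p)))
        return(c(D = NA, R = NA, PAR = NA, PAF = NA))
      if (spec$kind %in% c("ordered", "binary")) {
        adv <- p[spec$subgroups[length(spec$subgroups)]]
        dis <- p[spec$subgroups[1L]]
        d <- adv - dis; r <- adv / dis
        ref <- if (spec$favourable) adv else dis
      } else {
        d <- max(p) - min(p); r <- max(p) / min(p)
        ref <- if (spec$favourable) max(p) else min(p)
      }
      par <- ref - mu_b
      c(D = unname(d), R = unname(r), PAR = unname(par),
        PAF = unname(100 * par / mu_b))
    }, simplify = FALSE)
  }

  draws <- vector("list", reps)
  for (b in seq_len(reps)) {
    take <- unlist(lapply(psu_ids, function(ids)
      sample(ids, length(ids), replace = TRUE)), use.names = FALSE)
    draws[[b]] <- point(unlist(idx_of[take], use.names = FALSE))
  }
  a <- (1 - level) / 2
  lapply(stats::setNames(names(dimensions), names(dimensions)), function(d) {
    m <- do.call(rbind, lapply(draws, `[[`, d))
    lapply(stats::setNames(colnames(m), colnames(m)), function(mm)
      unname(stats::quantile(m[, mm], c(a, 1 - a), na.rm = TRUE)))
  })
}

#' Do two uncertainty intervals overlap?
#'
#' Non-overlap of the UIs from two surveys is the conventional reading of
#' a statistically significant change in a summary measure.
#'
#' @param a,b Length-2 numeric vectors `c(low, high)`.
#' @return `TRUE` if the intervals overlap.
#' @export
ui_overlap <- function(a, b) a[1] <= b[2] && b[1] <= a[2]

#' @export
print.health_inequality <- function(x, ...) {
  cat(sprintf("Health inequality summary measures (mu = %s%%, %s%% UI, %s)\n\n",
              format(round_report(x$mu$mu, x$report_decimals)),
              format(100 * x$ui_level), x$ui_method))
  if (!is.null(x$summaries)) {
    s <- x$summaries
    s$estimate <- round_report(s$estimate, x$report_decimals)
    s$ui_low <- round_report(s$ui_low, x$report_decimals)
    s$ui_high <- round_report(s$ui_high, x$report_decimals)
    print(s[, c("dimension", "measure", "estimate", "ui_low", "ui_high")],
          row.names = FALSE)
  }
  if (length(x$failures)) {
    cat("\nFailed dimensions:\n")
    for (d in names(x$failures)) cat("  ", d, ": ", x$failures[d], "\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.health_inequality <- function(object, ...) {
  s <- object$summaries
  if (!is.null(s)) {
    s$class <- ifelse(s$measure %in% c("D", "R"), "simple", "complex")
    s$scale <- ifelse(s$measure %in% c("D", "PAR"), "absolute", "relative")
    s$no_inequality <- ifelse(s$measure == "R", 1, 0)
  }
  structure(list(summaries = s, failures = object$failures,
                 mu = object$mu, report_decimals = object$report_decimals),
            class = "summary.health_inequality")
}

#' @export
print.summary.health_inequality <- function(x, ...) {
  s <- x$summaries
  if (!is.null(s)) {
    s$estimate <- round_report(s$estimate, x$report_decimals)
    s$ui_low <- round_report(s$ui_low, x$report_decimals)
    s$ui_high <- round_report(s$ui_high, x$report_decimals)
    print(s[, c("dimension", "measure", "class", "scale", "estimate",
                "ui_low", "ui_high", "reference_subgroup")],
          row.names = FALSE)
  }
  if (length(x$failures)) {
    cat("\nFailed dimensions:\n")
    for (d in names(x$failures)) cat("  ", d, ": ", x$failures[d], "\n", sep = "")
  }
  invisible(x)
}

#' @export
coef.health_inequality <- function(object, ...) {
  s <- object$summaries
  if (is.null(s)) return(numeric())
  stats::setNames(s$estimate, paste(s$dimension, s$measure, sep = ":"))
}

#' @export
confint.health_inequality <- function(object, parm, level, ...) {
  s <- object$summaries
  if (is.null(s)) return(NULL)
  m <- cbind(s$ui_low, s$ui_high)
  rownames(m) <- paste(s$dimension, s$measure, sep = ":")
  a <- (1 - object$ui_level) / 2
  colnames(m) <- paste0(format(100 * c(a, 1 - a), trim = TRUE), " %")
  if (!missing(parm)) m <- m[parm, , drop = FALSE]
  m
}

#' @export
as.data.frame.health_inequality <- function(x, ...) x$summaries
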