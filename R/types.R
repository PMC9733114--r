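#' Declare an equity stratifier (inequality dimension)
#'
#' A dimension describes one way of partitioning the population when
#' disaggregating a health indicator: wealth quintile, education level,
#' place of residence, sub-national region, and so on.
#'
#' @param name Dimension name as it appears in data files.
#' @param kind `"ordered"` for dimensions with an inherent
#'   disadvantaged-to-advantaged ranking (wealth quintile, education),
#'   `"binary"` for two-level ordered dimensions (residence), or
#'   `"non_ordered"` for dimensions without a ranking (region), where the
#'   extreme subgroups are found from the data.
#' @param subgroups Character vector of subgroup labels. For
#'   `kind = "ordered"` or `"binary"` they must be listed from
#'   most-disadvantaged to most-advantaged; the last label is the
#'   advantaged extreme.
#' @param favourable `TRUE` when higher indicator values are desirable
#'   (e.g. sleeping under an insecticide-treated net), `FALSE` for adverse
#'   indicators (e.g. mortality).
#' @return An object of class `dimension_spec`.
#' @examples
#' dimension_spec("Economic status", "ordered",
#'   c("Quintile 1 (poorest)", "Quintile 2", "Quintile 3",
#'     "Quintile 4", "Quintile 5 (richest)"))
#' @export
dimension_spec <- function(name, kind = c("ordered", "binary", "non_ordered"),
                           subgroups, favourable = TRUE) {
  kind <- match.arg(kind)
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("'name' must be a single non-empty string")
  subgroups <- as.character(subgroups)
  if (length(subgroups) < 2L)
    stop("dimension '", name, "' needs at least 2 subgroups")
  if (anyDuplicated(subgroups))
    stop("dimension '", name, "' has duplicated subgroup labels")
  if (kind == "binary" && length(subgroups) != 2L)
    stop("binary dimension '", name, "' must have exactly 2 subgroups")
  structure(
    list(name = name, kind = kind, subgroups = subgroups,
         favourable = isTRUE(favourable)),
    class = "dimension_spec"
  )
}

#' @export
print.dimension_spec <- function(x, ...) {
  cat(sprintf("<dimension_spec> %s (%s, %s indicator)\n", x$name, x$kind,
              if (x$favourable) "favourable" else "adverse"))
  cat("  subgroups:", paste(x$subgroups, collapse = " < "), "\n")
  invisible(x)
}

# normalise a dimension_spec or list of them into a list named by dimension
as_dimension_list <- function(dimensions) {
  if (inherits(dimensions, "dimension_spec")) dimensions <- list(dimensions)
  if (!is.list(dimensions) ||
      !all(vapply(dimensions, inherits, logical(1), "dimension_spec")))
    stop("'dimensions' must be a dimension_spec or a list of them")
  stats::setNames(dimensions, vapply(dimensions, `[[`, character(1), "name"))
}

#' Overall (setting-level) average prevalence
#'
#' Container for the overall weighted prevalence mu used by the complex
#' measures PAR and PAF, on the 0-100 percent scale.
#'
#' @param mu Overall prevalence in percent.
#' @param se_mu Standard error in percentage points (0 when unknown, e.g.
#'   when mu is taken from a published table).
#' @param n Unweighted respondent count (optional).
#' @return An object of class `setting_average`.
#' @export
setting_average <- function(mu, se_mu = 0, n = NA_integer_) {
  if (!is.numeric(mu) || length(mu) != 1L || is.na(mu) || mu < 0 || mu > 100)
    stop("'mu' must be a single value in [0, 100]")
  if (!is.numeric(se_mu) || length(se_mu) != 1L || is.na(se_mu) || se_mu < 0)
    stop("'se_mu' must be a single non-negative value")
  structure(list(mu = mu, se_mu = se_mu, n = n), class = "setting_average")
}

#' @export
print.setting_average <- function(x, ...) {
  cat(sprintf("<setting_average> mu = %.2f%% (se = %.2f)\n", x$mu, x$se_mu))
  invisible(x)
}

#' Round for reporting (half away from zero)
#'
#' Published inequality tables round half away from zero at a fixed number
#' of decimals; base R's `round()` rounds half to even, so a dedicated rule
#' is needed to compare against printed values.
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 1, the usual reporting precision).
#' @return Rounded numeric vector.
#' @examples
#' round_report(c(91.15, -26.05))  # 91.2, -26.1
#' @export
round_report <- function(x, digits = 1) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

# validate a block of subgroup estimate rows against its dimension spec;
# `where` names the source for diagnostics
validate_estimates <- function(est, spec, where = "estimates") {
  bad <- which(!(est$subgroup %in% spec$subgroups))
  if (length(bad))
    stop(where, ": unknown subgroup label(s) for dimension '", spec$name,
         "': ", paste(unique(est$subgroup[bad]), collapse = ", "))
  out <- which(est$estimate < 0 | est$estimate > 100)
  if (length(out))
    stop(where, ": estimate outside [0, 100] in row(s) ",
         paste(out, collapse = ", "), " of dimension '", spec$name, "'")
  if (all(c("ci_low", "ci_high") %in% names(est))) {
    has <- !is.na(est$ci_low) & !is.na(est$ci_high)
    badci <- which(has & (est$ci_low > est$estimate | est$estimate > est$ci_high))
    if (length(badci))
      stop(where, ": confidence bounds do not bracket the estimate in row(s) ",
           paste(badci, collapse = ", "), " of dimension '", spec$name, "'")
  }
  if ("n" %in% names(est) && any(!is.na(est$n) & est$n < 0))
    stop(where, ": negative sample size in dimension '", spec$name, "'")
  if ("pop_share" %in% names(est) && all(!is.na(est$pop_share))) {
    s <- sum(est$pop_share)
    if (abs(s - 1) > 1e-9)
      stop(where, ": population shares for dimension '", spec$name,
           "' sum to ", format(s), ", not 1")
  }
  invisible(est)
}
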