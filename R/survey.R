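# Design-based estimation for a binary indicator under multistage
# stratified cluster sampling: weighted prevalence with Taylor-linearized
# standard errors (with-replacement, between-PSU within strata) and
# logit-transformed confidence intervals.

#' Declare the survey design columns
#'
#' Maps record columns to design roles and fixes the policy for strata
#' containing a single primary sampling unit (PSU), where the
#' between-PSU variance is undefined.
#'
#' @param stratum,cluster,weight,outcome Column names in the record data
#'   frame holding the stratum id, PSU id, positive sampling weight and
#'   binary outcome.
#' @param single_psu Policy for single-PSU strata: `"certainty"` (the
#'   stratum contributes zero variance, with a warning), `"collapse"`
#'   (all single-PSU strata are pooled into one pseudo-stratum) or
#'   `"error"`.
#' @return An object of class `svy_design_spec`.
#' @export
svy_design <- function(stratum = "stratum", cluster = "cluster",
                       weight = "weight", outcome = "outcome",
                       single_psu = c("certainty", "collapse", "error")) {
  single_psu <- match.arg(single_psu)
  structure(list(stratum = stratum, cluster = cluster, weight = weight,
                 outcome = outcome, single_psu = single_psu),
            class = "svy_design_spec")
}

# variance of a weighted total of linearized contributions u under the
# with-replacement approximation: sum_h n_h/(n_h-1) sum_c (z_hc - zbar_h)^2,
# where z_hc are PSU totals of u and n_h counts all PSUs in stratum h
taylor_var <- function(u, stratum, cluster, single_psu) {
  key <- paste(stratum, cluster, sep = "\r")
  z <- rowsum(u, key, reorder = FALSE)[, 1]
  zs <- stratum[!duplicated(key)]
  nh <- table(zs)
  singles <- names(nh)[nh == 1L]
  if (length(singles)) {
    if (single_psu == "error")
      stop("stratum(s) with a single PSU: ",
           paste(singles, collapse = ", "),
           "; variance undefined under policy 'error'")
    if (single_psu == "collapse" && length(singles) >= 2L) {
      zs[zs %in% singles] <- ".collapsed"
    } else {
      warning("single-PSU stratum(s) treated as certainty (zero variance): ",
              paste(singles, collapse = ", "))
      keep <- !(zs %in% singles)
      z <- z[keep]
      zs <- zs[keep]
    }
  }
  v <- 0
  for (h in unique(zs)) {
    zh <- z[zs == h]
    n <- length(zh)
    if (n >= 2L) v <- v + n / (n - 1) * sum((zh - mean(zh))^2)
  }
  v
}

# point estimate + linearized se for one domain (logical index), on the
# percent scale; records outside the domain contribute zero to the PSU
# totals but their PSUs still count
domain_prevalence <- function(y, w, stratum, cluster, domain, single_psu) {
  W <- sum(w[domain])
  p <- sum(w[domain] * y[domain]) / W
  u <- numeric(length(y))
  u[domain] <- w[domain] * (y[domain] - p) / W
  v <- taylor_var(u, stratum, cluster, single_psu)
  list(estimate = 100 * p, se = 100 * sqrt(max(v, 0)),
       n = sum(domain), W = W)
}

#' Design-based subgroup prevalence
#'
#' Computes, for each subgroup of a dimension, the weighted prevalence
#' `100 * sum(w*y)/sum(w)`, its Taylor-linearized standard error under the
#' stratified with-replacement cluster design, a logit-transformed
#' confidence interval, the unweighted count and the weighted population
#' share. Records with a missing value on the dimension are excluded from
#' the disaggregation (their PSUs still anchor the variance strata).
#'
#' @param records Data frame of respondent records (see
#'   [read_survey_records()]).
#' @param design A [svy_design()] specification.
#' @param dimension A [dimension_spec()]; its name must be a column of
#'   `records`. `NULL` computes the overall estimate as a single row.
#' @param level Confidence level (default 0.95).
#' @return Data frame with columns `dimension`, `subgroup`, `estimate`,
#'   `se`, `ci_low`, `ci_high`, `n`, `pop_share`. Declared subgroups with
#'   zero records are omitted with a warning.
#' @examples
#' rec <- data.frame(stratum = "s", cluster = rep(1:3, each = 2),
#'                   weight = c(1, 1, 2, 2, 3, 3),
#'                   outcome = c(1, 0, 1, 0, 1, 1),
#'                   grp = "all")
#' weighted_prevalence(rec, svy_design(),
#'                     dimension_spec("grp", "non_ordered", c("all", "none")))
#' @export
weighted_prevalence <- function(records, design = svy_design(),
                                dimension = NULL, level = 0.95) {
  y <- records[[design$outcome]]
  w <- records[[design$weight]]
  st <- as.character(records[[design$stratum]])
  cl <- as.character(records[[design$cluster]])
  if (any(w <= 0)) stop("weights must be positive")
  if (!all(y %in% c(0, 1))) stop("outcome must be binary 0/1")

  if (is.null(dimension)) {
    r <- domain_prevalence(y, w, st, cl, rep(TRUE, length(y)),
                           design$single_psu)
    ci <- logit_ci(r$estimate, r$se, level = level, n = r$n)
    return(data.frame(dimension = "(overall)", subgroup = "(all)",
                      estimate = r$estimate, se = r$se,
                      ci_low = ci[1], ci_high = ci[2],
                      n = r$n, pop_share = 1))
  }

  v <- records[[dimension$name]]
  if (is.null(v)) stop("records lack column '", dimension$name, "'")
  rows <- lapply(dimension$subgroups, function(g) {
    dom <- !is.na(v) & v == g
    if (!any(dom)) return(NULL)
    r <- domain_prevalence(y, w, st, cl, dom, design$single_psu)
    ci <- logit_ci(r$estimate, r$se, level = level, n = r$n)
    data.frame(dimension = dimension$name, subgroup = g,
               estimate = r$estimate, se = r$se,
               ci_low = ci[1], ci_high = ci[2], n = r$n,
               pop_share = r$W)
  })
  empty <- dimension$subgroups[vapply(rows, is.null, logical(1))]
  if (length(empty))
    warning("subgroup(s) with zero records omitted for dimension '",
            dimension$name, "': ", paste(empty, collapse = ", "))
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no records carry dimension '", dimension$name, "'")
  out$pop_share <- out$pop_share / sum(out$pop_share)
  rownames(out) <- NULL
  out
}

#' Overall weighted prevalence (the setting average mu)
#'
#' The overall average is a setting-level quantity: records with missing
#' stratifier values are included.
#'
#' @inheritParams weighted_prevalence
#' @return A [setting_average()] with `mu` (percent) and `se_mu`
#'   (percentage points).
#' @export
overall_average <- function(records, design = svy_design(), level = 0.95) {
  if (nrow(records) == 0L) stop("no records")
  r <- weighted_prevalence(records, design, dimension = NULL, level = level)
  setting_average(r$estimate, r$se, r$n)
}

#' Logit-transformed confidence interval for a prevalence
#'
#' Builds the normal interval on the logit scale with the delta-method
#' standard error and back-transforms, giving an interval contained in
#' (0, 100) and asymmetric about the estimate (longer toward 50%). At
#' boundary estimates (0 or 100) it falls back to the exact one-sided
#' Clopper-Pearson bound, which requires `n`.
#'
#' @param estimate Prevalence in percent.
#' @param se Standard error in percentage points.
#' @param level Confidence level in (0, 1).
#' @param n Unweighted count, used only for the boundary fallback.
#' @return Numeric vector `c(ci_low, ci_high)` in percent.
#' @examples
#' logit_ci(51.4, 3.6)   # asymmetric, inside (0, 100)
#' logit_ci(100, 0, n = 20)
#' @export
logit_ci <- function(estimate, se, level = 0.95, n = NULL) {
  if (level <= 0 || level >= 1) stop("'level' must be in (0, 1)")
  if (estimate < 0 || estimate > 100) stop("'estimate' must be in [0, 100]")
  a <- (1 - level) / 2
  if (estimate == 0 || estimate == 100) {
    if (is.null(n) || is.na(n) || n < 1)
      stop("boundary estimate: supply 'n' for the exact one-sided bound")
    if (estimate == 0) return(c(0, 100 * (1 - a^(1 / n))))
    return(c(100 * a^(1 / n), 100))
  }
  if (se == 0) return(c(estimate, estimate))
  p <- estimate / 100
  l <- stats::qlogis(p)
  sl <- (se / 100) / (p * (1 - p))
  z <- stats::qnorm(1 - a)
  100 * stats::plogis(c(l - z * sl, l + z * sl))
}
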