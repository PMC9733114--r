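# Simulator for MICS-like household surveys: regions split into urban and
# rural strata, census enumeration areas (EAs) as clusters, systematic
# PPS selection of EAs, equal-probability household sampling within EAs,
# inverse-probability weights, a binary outcome with an EA-level random
# intercept on the log-odds scale, and asset-based wealth quintiles from
# the first principal component of binary asset indicators.

#' Configure a synthetic survey population
#'
#' @param regions Data frame with one row per region: `label`,
#'   `urban_share` (proportion of the region's EAs in the urban stratum),
#'   `eas_per_stratum` (average EA count per stratum: the region holds
#'   `2 * eas_per_stratum` EAs, split between urban and rural by
#'   `urban_share`, at least one each), `hh_per_ea` (mean households per
#'   EA) and `baseline` (region prevalence anchor in percent, the
#'   log-odds intercept `qlogis(baseline/100)`).
#' @param beta_urban Additive log-odds effect of urban residence.
#' @param beta_wealth Length-5 log-odds effects for latent wealth quintiles
#'   1 (poorest) to 5 (richest).
#' @param beta_education Length-3 log-odds effects for education levels
#'   none / primary / secondary or higher.
#' @param icc Target intra-cluster correlation of the outcome on the
#'   latent logistic scale, in \[0, 1): the EA random-intercept variance is
#'   `icc * pi^2/3 / (1 - icc)`.
#' @param n_assets Number of binary household asset indicators.
#' @param asset_strength Log-odds loading of the latent wealth score on
#'   asset ownership.
#' @param eligibility Per-household probability of containing an eligible
#'   (pregnant) woman; only eligible women become analysis records.
#' @param hh_size_dispersion Log-normal sd of EA household counts around
#'   `hh_per_ea` (0 gives exact counts, and PPS reduces to equal
#'   probability selection).
#' @param seed Integer seed; all generator output is a pure function of
#'   (config, seed).
#' @return An object of class `population_config`.
#' @seealso [default_ghana_config()], [build_frame()], [draw_sample()]
#' @export
population_config <- function(regions,
                              beta_urban = 0,
                              beta_wealth = rep(0, 5),
                              beta_education = rep(0, 3),
                              icc = 0.05,
                              n_assets = 12,
                              asset_strength = 1.2,
                              eligibility = 0.5,
                              hh_size_dispersion = 0,
                              seed = 1L) {
  need <- c("label", "urban_share", "eas_per_stratum", "hh_per_ea", "baseline")
  if (!is.data.frame(regions) || !all(need %in% names(regions)))
    stop("'regions' must be a data frame with columns ",
         paste(need, collapse = ", "))
  if (any(regions$eas_per_stratum < 2) || any(regions$hh_per_ea <= 0))
    stop("each region needs at least 2 EAs per stratum and positive ",
         "household counts")
  if (any(regions$urban_share < 0 | regions$urban_share > 1))
    stop("urban_share must lie in [0, 1]")
  if (any(regions$baseline <= 0 | regions$baseline >= 100))
    stop("region baseline prevalences must lie in (0, 100)")
  if (icc < 0 || icc >= 1) stop("'icc' must lie in [0, 1)")
  if (length(beta_wealth) != 5L) stop("'beta_wealth' must have length 5")
  if (length(beta_education) != 3L) stop("'beta_education' must have length 3")
  if (eligibility <= 0 || eligibility > 1)
    stop("'eligibility' must lie in (0, 1]")
  if (n_assets < 2L) stop("need at least 2 asset indicators")
  structure(list(regions = regions, beta_urban = beta_urban,
                 beta_wealth = beta_wealth, beta_education = beta_education,
                 icc = icc, n_assets = n_assets,
                 asset_strength = asset_strength, eligibility = eligibility,
                 hh_size_dispersion = hh_size_dispersion,
                 seed = as.integer(seed)),
            class = "population_config")
}

# EA random-intercept sd from the target ICC (latent logistic threshold
# approximation: residual variance pi^2/3)
icc_to_sigma <- function(icc) sqrt(icc * (pi^2 / 3) / (1 - icc))

#' Stratifier declarations matching the synthetic generator
#'
#' @param config A [population_config()].
#' @return Named list of [dimension_spec()]s: `wealth` (ordered,
#'   quintile 1 poorest to quintile 5 richest), `education` (ordered),
#'   `residence` (binary, Rural then Urban) and — for configs with two or
#'   more regions — `region` (non-ordered, labels from the config).
#' @export
synthetic_dimensions <- function(config) {
  out <- list(
    wealth = dimension_spec("wealth", "ordered",
      c("Quintile 1 (poorest)", "Quintile 2", "Quintile 3", "Quintile 4",
        "Quintile 5 (richest)")),
    education = dimension_spec("education", "ordered",
      c("No education", "Primary", "Secondary or higher")),
    residence = dimension_spec("residence", "binary", c("Rural", "Urban"))
  )
  if (nrow(config$regions) >= 2L)
    out$region <- dimension_spec("region", "non_ordered",
                                 as.character(config$regions$label))
  out
}

#' Build the household sampling frame
#'
#' Generates the full synthetic population: strata (region x urban/rural),
#' EAs with household counts (the PPS size measure), and households
#' carrying residence, a latent wealth score (with a small EA-level
#' component, so assets cluster geographically), education, binary asset
#' indicators, an asset-index wealth quintile computed once census-style
#' from the whole frame, an eligible-woman flag and — for eligible women —
#' a realized binary outcome drawn from the log-odds model with the EA
#' random intercept. Deterministic given the config (which carries the
#' seed).
#'
#' @param config A [population_config()].
#' @return Data frame with one row per household, of class `synthetic_frame`
#'   (attributes: `config`, asset column names).
#' @export
build_frame <- function(config) {
  if (!inherits(config, "population_config")) stop("need a population_config")
  set.seed(config$seed)
  reg <- config$regions
  eas <- do.call(rbind, lapply(seq_len(nrow(reg)), function(i) {
    r <- reg[i, ]
    total_ea <- 2L * r$eas_per_stratum
    # both strata get at least 2 EAs so between-PSU variances exist
    n_urban <- min(total_ea - 2L, max(2L, round(total_ea * r$urban_share)))
    do.call(rbind, lapply(c("urban", "rural"), function(s) {
      n_ea <- if (s == "urban") n_urban else total_ea - n_urban
      sz <- if (config$hh_size_dispersion > 0)
        pmax(4L, as.integer(round(r$hh_per_ea *
          exp(stats::rnorm(n_ea, -config$hh_size_dispersion^2 / 2,
                           config$hh_size_dispersion)))))
      else rep(as.integer(round(r$hh_per_ea)), n_ea)
      data.frame(region = r$label,
                 stratum = paste(r$label, s, sep = "/"),
                 residence = if (s == "urban") "Urban" else "Rural",
                 size = sz)
    }))
  }))
  eas$ea <- sprintf("EA%04d", seq_len(nrow(eas)))
  n_ea <- nrow(eas)
  if (n_ea == 0L) stop("degenerate config: no enumeration areas")

  sigma_u <- icc_to_sigma(config$icc)
  u_ea <- stats::rnorm(n_ea, 0, sigma_u)
  wealth_ea <- stats::rnorm(n_ea)       # geographic clustering of assets
  urban_ea <- eas$residence == "Urban"

  idx <- rep(seq_len(n_ea), eas$size)
  n_hh <- length(idx)
  hh <- data.frame(
    region = eas$region[idx],
    stratum = eas$stratum[idx],
    ea = eas$ea[idx],
    ea_size = eas$size[idx],
    residence = eas$residence[idx]
  )
  hh$hh_id <- paste(hh$ea, stats::ave(idx, idx, FUN = seq_along), sep = "-")

  # latent wealth: household noise + EA component + urban premium
  hh$latent_wealth <- sqrt(0.75) * stats::rnorm(n_hh) +
    0.5 * wealth_ea[idx] + 0.8 * urban_ea[idx]
  lw_q <- cut(hh$latent_wealth,
              stats::quantile(hh$latent_wealth, seq(0, 1, 0.2)),
              include.lowest = TRUE, labels = FALSE)

  # education rises with wealth and urban residence
  edu_score <- 0.8 * scale(hh$latent_wealth)[, 1] +
    0.4 * urban_ea[idx] + stats::rnorm(n_hh)
  hh$education <- c("No education", "Primary", "Secondary or higher")[
    findInterval(edu_score, c(-0.3, 0.8)) + 1L]

  assets <- matrix(0L, n_hh, config$n_assets)
  a0 <- seq(-1, 1, length.out = config$n_assets)
  for (k in seq_len(config$n_assets))
    assets[, k] <- stats::rbinom(n_hh, 1,
      stats::plogis(a0[k] + config$asset_strength * hh$latent_wealth))
  colnames(assets) <- sprintf("asset%02d", seq_len(config$n_assets))

  # census asset index: PCA on the full frame, unweighted cutpoints
  hh$wealth <- assign_wealth_quintiles(assets)

  hh$eligible <- stats::rbinom(n_hh, 1, config$eligibility) == 1

  b0 <- stats::qlogis(reg$baseline[match(hh$region, reg$label)] / 100)
  wq_idx <- lw_q  # outcome model uses the latent quintile
  lp_fixed <- b0 +
    config$beta_urban * urban_ea[idx] +
    config$beta_wealth[wq_idx] +
    config$beta_education[match(hh$education,
      c("No education", "Primary", "Secondary or higher"))]
  hh$lp_fixed <- lp_fixed
  hh$p <- stats::plogis(lp_fixed + u_ea[idx])
  hh$outcome <- ifelse(hh$eligible, stats::rbinom(n_hh, 1, hh$p), NA_integer_)

  out <- cbind(hh, as.data.frame(assets))
  attr(out, "config") <- config
  attr(out, "asset_cols") <- colnames(assets)
  class(out) <- c("synthetic_frame", "data.frame")
  out
}

# systematic PPS: k picks on the cumulated-size scale with a random
# start; units whose size-based inclusion probability reaches 1 become
# certainty selections (standard large-unit handling)
systematic_pps <- function(size, k) {
  n <- length(size)
  if (k > n) stop("cannot select ", k, " EAs from ", n)
  if (k == n) return(list(pick = seq_len(n), pi = rep(1, n)))
  pi1 <- rep(NA_real_, n)
  cert <- logical(n)
  repeat {
    rest <- which(!cert)
    kr <- k - sum(cert)
    p <- kr * size[rest] / sum(size[rest])
    over <- rest[p >= 1]
    if (!length(over) || kr <= 0) { pi1[rest] <- p; break }
    cert[over] <- TRUE
  }
  pi1[cert] <- 1
  rest <- which(!cert)
  kr <- k - sum(cert)
  pick <- which(cert)
  if (kr > 0) {
    cum <- cumsum(size[rest])
    interval <- sum(size[rest]) / kr
    pts <- stats::runif(1, 0, interval) + (seq_len(kr) - 1) * interval
    pick <- c(pick, rest[findInterval(pts, c(0, cum),
                                      rightmost.closed = TRUE)])
  }
  list(pick = sort(pick), pi = pi1)
}

#' Draw a two-stage stratified cluster sample
#'
#' Stage 1 selects `ea_take` EAs per stratum systematically with
#' probability proportional to household count; stage 2 selects an
#' equal-probability sample of `hh_take` households within each sampled
#' EA (all of them when `hh_take` is `Inf` or exceeds the EA size).
#' Weights are inverse products of the stage inclusion probabilities, so
#' a census take (`ea_take` = all EAs, `hh_take = Inf`) yields weights of
#' exactly 1. Analysis records are the eligible women in sampled
#' households.
#'
#' @param frame A [build_frame()] result.
#' @param ea_take EAs to select per stratum.
#' @param hh_take Households to select per sampled EA.
#' @param seed Integer seed for the sampling stages.
#' @param wealth `"frame"` (default) keeps the census asset-index quintile
#'   carried by the frame; `"sample"` recomputes quintiles survey-style
#'   from the sampled respondents' assets with weighted cutpoints.
#' @return Data frame of respondent records with columns `stratum`,
#'   `cluster`, `weight`, `outcome`, `region`, `residence`, `education`,
#'   `wealth`.
#' @export
draw_sample <- function(frame, ea_take, hh_take = Inf, seed = 1L,
                        wealth = c("frame", "sample")) {
  wealth <- match.arg(wealth)
  set.seed(as.integer(seed))
  asset_cols <- attr(frame, "asset_cols")
  frame <- as.data.frame(frame)

  sampled <- list()
  for (h in unique(frame$stratum)) {
    fh <- frame[frame$stratum == h, , drop = FALSE]
    ea_tab <- fh[!duplicated(fh$ea), c("ea", "ea_size")]
    # randomized systematic PPS: shuffling the list order before the
    # systematic pass restores a rich sample support (field frames are
    # orders of magnitude larger than simulated ones)
    ea_tab <- ea_tab[sample.int(nrow(ea_tab)), , drop = FALSE]
    sel <- systematic_pps(ea_tab$ea_size, min(ea_take, nrow(ea_tab)))
    for (j in sel$pick) {
      block <- fh[fh$ea == ea_tab$ea[j], , drop = FALSE]
      m <- nrow(block)
      take <- min(hh_take, m)
      rows <- if (take == m) block else block[sample.int(m, take), , drop = FALSE]
      rows$weight <- 1 / (sel$pi[j] * (take / m))
      sampled[[length(sampled) + 1L]] <- rows
    }
  }
  s <- do.call(rbind, sampled)
  rec <- s[s$eligible, , drop = FALSE]
  if (nrow(rec) == 0L) stop("sample contains no eligible women")
  if (wealth == "sample")
    rec$wealth <- assign_wealth_quintiles(
      as.matrix(rec[, asset_cols, drop = FALSE]), weights = rec$weight)
  out <- data.frame(stratum = rec$stratum, cluster = rec$ea,
                    weight = rec$weight, outcome = rec$outcome,
                    region = rec$region, residence = rec$residence,
                    education = rec$education, wealth = rec$wealth)
  rownames(out) <- NULL
  out
}

#' Asset-index wealth quintiles by principal component analysis
#'
#' The wealth score is the first principal component of the standardized
#' asset matrix, sign-aligned so that a higher score means more assets;
#' quintiles are cut at the weighted 20/40/60/80th percentiles of the
#' score. Constant asset columns are dropped with a warning.
#'
#' @param assets Numeric matrix, one row per household, binary (or
#'   ordinal) asset indicators in columns.
#' @param weights Optional positive weights for the percentile cutpoints
#'   (the PCA itself is unweighted, as in the DHS/MICS wealth index).
#' @return Character vector of labels `"Quintile 1 (poorest)"` ...
#'   `"Quintile 5 (richest)"`.
#' @export
assign_wealth_quintiles <- function(assets, weights = NULL) {
  assets <- as.matrix(assets)
  if (nrow(assets) < 5L) stop("need at least 5 households")
  sds <- apply(assets, 2, stats::sd)
  if (all(sds == 0)) stop("all asset columns are constant")
  if (any(sds == 0)) {
    warning("dropping constant asset column(s): ",
            paste(colnames(assets)[sds == 0], collapse = ", "))
    assets <- assets[, sds > 0, drop = FALSE]
  }
  if (ncol(assets) < 2L) stop("need at least 2 non-constant asset columns")
  pc <- stats::prcomp(assets, center = TRUE, scale. = TRUE)
  score <- pc$x[, 1]
  if (stats::cor(score, rowMeans(assets)) < 0) score <- -score
  if (is.null(weights)) weights <- rep(1, length(score))
  cuts <- weighted_quantile(score, weights, c(0.2, 0.4, 0.6, 0.8))
  labs <- c("Quintile 1 (poorest)", "Quintile 2", "Quintile 3",
            "Quintile 4", "Quintile 5 (richest)")
  # left-open intervals: a household sitting on a cutpoint stays in the
  # lower quintile, so equal weights give (near-)equal quintile sizes
  labs[findInterval(score, cuts, left.open = TRUE) + 1L]
}

# weighted quantile of type "inverse of the left-continuous weighted ECDF"
weighted_quantile <- function(x, w, probs) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  vapply(probs, function(p) x[which(cw >= p)[1]], numeric(1))
}

#' Generator truth: subgroup prevalences and the four measures
#'
#' Computes the generator's true subgroup prevalences per dimension, the
#' true overall average mu, and the true D/R/PAR/PAF, using the same
#' formulas as the estimators.
#'
#' `type = "expected"` integrates the EA random intercept out of the
#' log-odds model and averages the resulting per-woman probabilities over
#' the frame composition (eligible women) — the model-level truth.
#' `type = "realized"` averages the frame's realized binary outcomes — the
#' finite-population (design-based) estimand, which a census run of the
#' estimation pipeline reproduces exactly.
#'
#' @param config A [population_config()], or a frame from [build_frame()].
#' @param type `"expected"` or `"realized"`.
#' @return An object of class `synthetic_truth`: list with `prevalences`
#'   (data frame `dimension`, `subgroup`, `estimate`), `mu`, and
#'   `measures` (data frame `dimension`, `measure`, `estimate`).
#' @export
true_summaries <- function(config, type = c("realized", "expected")) {
  type <- match.arg(type)
  frame <- if (inherits(config, "synthetic_frame")) config
           else build_frame(config)
  cfg <- attr(frame, "config")
  dims <- synthetic_dimensions(cfg)
  el <- frame[frame$eligible, , drop = FALSE]

  val <- if (type == "realized") el$outcome else {
    sigma <- icc_to_sigma(cfg$icc)
    if (sigma == 0) stats::plogis(el$lp_fixed)
    else {
      # integrate the EA intercept out, per unique linear predictor
      ulp <- unique(el$lp_fixed)
      pm <- vapply(ulp, function(l)
        stats::integrate(function(u)
          stats::plogis(l + u) * stats::dnorm(u, 0, sigma),
          -Inf, Inf)$value, numeric(1))
      pm[match(el$lp_fixed, ulp)]
    }
  }

  mu <- 100 * mean(val)
  prev <- do.call(rbind, lapply(dims, function(spec) {
    g <- el[[spec$name]]
    m <- tapply(val, g, mean) * 100
    data.frame(dimension = spec$name, subgroup = names(m),
               estimate = as.numeric(m), se = 0)
  }))
  rownames(prev) <- NULL

  fit <- health_inequality(prev, mu = setting_average(mu, 0), dims)
  if (length(fit$failures))
    stop("truth computation failed: ",
         paste(fit$failures, collapse = "; "))
  structure(list(prevalences = prev, mu = mu,
                 measures = fit$summaries[, c("dimension", "measure",
                                              "estimate")],
                 type = type),
            class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("<synthetic_truth> (%s) mu = %.2f%%\n", x$type, x$mu))
  m <- x$measures
  m$estimate <- round(m$estimate, 2)
  print(m, row.names = FALSE)
  invisible(x)
}

#' Default scenario: a Ghana-2017-like population
#'
#' Ten regions with urban/rural strata, region frame sizes proportional
#' to 2010 census population shares, and region anchors calibrated so the
#' marginal regional prevalences approximate the 2017 survey column of
#' the packaged Ghana table; residence, wealth and education log-odds
#' effects set from the printed 2017 gradients. Sampling 3 EAs per
#' stratum and 31 households per EA (eligibility 0.5) yields about 930
#' respondents — the published survey's pregnant-women sample size — with
#' small regions oversampled relative to population, as in MICS.
#'
#' @param seed Integer seed.
#' @return A [population_config()].
#' @export
default_ghana_config <- function(seed = 20170L) {
  regions <- data.frame(
    label = c("Ashanti", "Brong Ahafo", "Central", "Eastern",
              "Greater Accra", "Northern", "Upper East", "Upper West",
              "Volta", "Western"),
    urban_share = c(0.60, 0.45, 0.47, 0.43, 0.90, 0.30, 0.21, 0.16,
                    0.34, 0.42),
    eas_per_stratum = c(23L, 11L, 11L, 13L, 20L, 12L, 5L, 4L, 10L, 12L),
    hh_per_ea = 40,
    baseline = c(56.2, 67.3, 48.9, 59.6, 26.3, 51.5, 78.7, 62.9,
                 74.8, 57.9)
  )
  population_config(
    regions,
    beta_urban = -0.6,
    beta_wealth = c(0, -0.3, -0.6, -0.9, -1.2) + 0.6,
    beta_education = c(0, -0.15, -0.3) + 0.15,
    icc = 0.08,
    n_assets = 12,
    asset_strength = 1.2,
    eligibility = 0.5,
    hh_size_dispersion = 0.25,
    seed = seed
  )
}
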