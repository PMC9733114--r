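# Fixtures built in code: small generator configs and hand-written tables.

# n_regions small populations with explicit baselines (percent)
tiny_config <- function(baselines = c(40, 60), eas = 5L, hh = 20,
                        urban = 0.5, icc = 0.05, eligibility = 1,
                        dispersion = 0, seed = 1L, ...) {
  n <- length(baselines)
  regions <- data.frame(
    label = paste0("R", seq_len(n)),
    urban_share = rep(urban, length.out = n),
    eas_per_stratum = rep(as.integer(eas), length.out = n),
    hh_per_ea = rep(hh, length.out = n),
    baseline = baselines
  )
  population_config(regions, icc = icc, eligibility = eligibility,
                    hh_size_dispersion = dispersion, seed = seed, ...)
}

# the 2-stratum, 30-PSU single-region design used for variance checks
oracle_design_records <- function(seed_frame = 11L, seed_draw = 3L) {
  cfg <- tiny_config(baselines = 45, eas = 15L, hh = 30, icc = 0.10,
                     eligibility = 0.6, dispersion = 0.3,
                     seed = seed_frame)
  fr <- build_frame(cfg)
  list(config = cfg, frame = fr,
       records = draw_sample(fr, ea_take = 15, hh_take = 20,
                             seed = seed_draw))
}

# independent cluster-bootstrap standard error of the overall weighted
# prevalence: PSUs resampled with replacement within strata
bootstrap_se_oracle <- function(records, reps = 2000, seed = 1234) {
  set.seed(seed)
  psu <- paste(records$stratum, records$cluster, sep = "\r")
  stra <- records$stratum[!duplicated(psu)]
  ids <- split(unique(psu), stra)
  idx <- split(seq_len(nrow(records)), psu)
  est <- replicate(reps, {
    take <- unlist(lapply(ids, function(x) sample(x, length(x), TRUE)))
    i <- unlist(idx[take], use.names = FALSE)
    100 * sum(records$weight[i] * records$outcome[i]) / sum(records$weight[i])
  })
  stats::sd(est)
}

# a hand-written subgroup table for one binary dimension
toy_binary_table <- function(est = c(40, 20), se = c(2, 3)) {
  data.frame(dimension = "residence", subgroup = c("Rural", "Urban"),
             estimate = est, se = se)
}

toy_binary_spec <- function() dimension_spec("residence", "binary",
                                             c("Rural", "Urban"))
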