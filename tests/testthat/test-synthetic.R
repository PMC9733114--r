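test_that("frame construction counts, determinism and validation", {
  cfg <- tiny_config(baselines = c(40, 60), eas = 5L, hh = 20, seed = 9L)
  fr <- build_frame(cfg)
  expect_equal(nrow(fr), 2 * 2 * 5 * 20)  # regions x strata x EAs x households
  expect_setequal(unique(fr$stratum),
                  c("R1/urban", "R1/rural", "R2/urban", "R2/rural"))
  expect_true(all(c("latent_wealth", "education", "wealth", "eligible",
                    "outcome") %in% names(fr)))
  fr2 <- build_frame(cfg)
  expect_identical(fr, fr2)  # pure function of (config, seed)
  expect_error(tiny_config(eas = 1L), "at least 2 EAs")
  expect_error(tiny_config(baselines = c(0, 50)), "\\(0, 100\\)")
})

test_that("icc = 0 leaves only binomial variation between EAs", {
  # no covariate effects, eligibility 1: EA prevalences are iid binomial
  cfg <- tiny_config(baselines = 35, eas = 250L, hh = 20, icc = 0,
                     eligibility = 1, seed = 21L)
  fr <- build_frame(cfg)
  ea_p <- tapply(fr$outcome, fr$ea, mean)
  expect_gte(length(ea_p), 500)
  p <- mean(fr$outcome)
  v_obs <- var(ea_p)
  v_bin <- p * (1 - p) / 20
  # sampling error of a variance over 500 EAs is about 6%; allow 20%
  expect_lt(abs(v_obs - v_bin) / v_bin, 0.20)
})

test_that("positive icc inflates between-EA variance beyond binomial", {
  cfg <- tiny_config(baselines = 35, eas = 250L, hh = 20, icc = 0.15,
                     eligibility = 1, seed = 22L)
  fr <- build_frame(cfg)
  ea_p <- tapply(fr$outcome, fr$ea, mean)
  p <- mean(fr$outcome)
  expect_gt(var(ea_p), 1.5 * p * (1 - p) / 20)
})

test_that("PPS sampling: equal sizes give equal weights, census gives 1", {
  cfg <- tiny_config(baselines = c(40, 60), eas = 6L, hh = 20,
                     dispersion = 0, seed = 31L)
  fr <- build_frame(cfg)
  rec <- draw_sample(fr, ea_take = 3, hh_take = 10, seed = 1)
  w_by_stratum <- tapply(rec$weight, rec$stratum, function(w)
    length(unique(round(w, 10))))
  expect_true(all(w_by_stratum == 1))

  cen <- draw_sample(fr, ea_take = 6L, hh_take = Inf, seed = 1)
  expect_true(all(cen$weight == 1))
  expect_equal(as.vector(table(cen$region)[c("R1", "R2")]),
               as.vector(table(fr$region[fr$eligible])[c("R1", "R2")]))
  expect_equal(100 * weighted.mean(cen$outcome, cen$weight),
               100 * mean(fr$outcome[fr$eligible]))
})

test_that("same seed reproduces the sample; weights estimate frame sizes", {
  cfg <- tiny_config(baselines = c(40, 60), eas = 8L, hh = 25,
                     dispersion = 0.3, seed = 41L)
  fr <- build_frame(cfg)
  r1 <- draw_sample(fr, 4, 12, seed = 99)
  r2 <- draw_sample(fr, 4, 12, seed = 99)
  expect_identical(r1, r2)

  # Horvitz-Thompson: sum of record weights estimates the stratum count of
  # eligible women; check the Monte-Carlo mean over replicates
  truth <- table(fr$stratum[fr$eligible])
  reps <- 200
  est <- matrix(NA, reps, length(truth),
                dimnames = list(NULL, names(truth)))
  for (r in seq_len(reps)) {
    s <- draw_sample(fr, 4, 12, seed = 7000 + r)
    tot <- tapply(s$weight, s$stratum, sum)
    est[r, names(tot)] <- tot
  }
  for (h in names(truth)) {
    m <- mean(est[, h], na.rm = TRUE)
    mc_se <- sd(est[, h], na.rm = TRUE) / sqrt(sum(!is.na(est[, h])))
    expect_lt(abs(m - truth[[h]]), 3 * mc_se + 1e-9)
  }
})

test_that("PPS with unequal sizes is unbiased for the frame prevalence", {
  cfg <- tiny_config(baselines = c(35, 65), eas = 10L, hh = 25, icc = 0.1,
                     dispersion = 0.4, eligibility = 1, seed = 51L)
  fr <- build_frame(cfg)
  truth <- 100 * mean(fr$outcome[fr$eligible])
  reps <- 300
  est <- numeric(reps)
  for (r in seq_len(reps)) {
    s <- draw_sample(fr, 4, 12, seed = 9000 + r)
    est[r] <- 100 * weighted.mean(s$outcome, s$weight)
  }
  expect_lt(abs(mean(est) - truth), 3 * sd(est) / sqrt(reps))
})

test_that("wealth quintiles recover a monotone asset gradient", {
  set.seed(61)
  n <- 2000
  latent <- rnorm(n)
  # assets strongly monotone in latent wealth
  X <- sapply(seq(-1.5, 1.5, length.out = 10), function(a)
    rbinom(n, 1, plogis(a + 2.5 * latent)))
  q <- assign_wealth_quintiles(X)
  qi <- as.integer(factor(q, levels = c("Quintile 1 (poorest)", "Quintile 2",
                                        "Quintile 3", "Quintile 4",
                                        "Quintile 5 (richest)")))
  # discrete asset patterns tie at the cutpoints, so sizes are only
  # near-equal
  expect_true(all(abs(table(qi) - 400) <= 0.05 * 400))
  expect_gt(cor(qi, latent, method = "spearman"), 0.8)
  # sign alignment: richer quintiles own more assets
  expect_gt(mean(rowSums(X)[qi == 5]), mean(rowSums(X)[qi == 1]))

  # constant columns are dropped with a warning; all-constant errors
  Xc <- cbind(X, const = 1L)
  expect_warning(q2 <- assign_wealth_quintiles(Xc), "constant")
  expect_equal(q2, q)
  expect_error(assign_wealth_quintiles(matrix(1, 10, 3)), "constant")
  expect_error(assign_wealth_quintiles(X[1:3, ]), "at least 5")
})

test_that("generator truth satisfies the no-inequality and identity laws", {
  # single region, no effects: every measure at its null value
  cfg <- tiny_config(baselines = 40, eas = 4L, hh = 15, icc = 0.1,
                     seed = 71L)
  tr <- true_summaries(cfg, type = "expected")
  m <- tr$measures
  expect_equal(m$estimate[m$measure == "D"], rep(0, 3), tolerance = 1e-9)
  expect_equal(m$estimate[m$measure == "R"], rep(1, 3), tolerance = 1e-9)
  expect_equal(m$estimate[m$measure == "PAR"], rep(0, 3), tolerance = 1e-9)
  expect_equal(m$estimate[m$measure == "PAF"], rep(0, 3), tolerance = 1e-9)

  # two regions anchored at published extremes: true D is their gap
  cfg2 <- tiny_config(baselines = c(62.3, 11.8), eas = 4L, hh = 15,
                      icc = 0, seed = 72L)
  tr2 <- true_summaries(cfg2, type = "expected")
  m2 <- tr2$measures
  expect_equal(m2$estimate[m2$dimension == "region" & m2$measure == "D"],
               50.5)
  expect_equal(m2$estimate[m2$dimension == "region" & m2$measure == "R"],
               62.3 / 11.8)

  # PAF identity holds for arbitrary configs, both truth types
  cfg3 <- default_ghana_config(seed = 73L)
  for (ty in c("expected", "realized")) {
    tr3 <- true_summaries(cfg3, type = ty)
    m3 <- tr3$measures
    for (d in unique(m3$dimension)) {
      par <- m3$estimate[m3$dimension == d & m3$measure == "PAR"]
      paf <- m3$estimate[m3$dimension == d & m3$measure == "PAF"]
      expect_equal(paf, 100 * par / tr3$mu)
    }
  }
})

test_that("yaml config files round-trip through the reader and writer", {
  cfg <- default_ghana_config(seed = 81L)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_population_config(cfg, f)
  back <- read_population_config(f)
  expect_equal(back$regions$baseline, cfg$regions$baseline)
  expect_equal(back$beta_wealth, cfg$beta_wealth)
  expect_equal(back$seed, cfg$seed)
  expect_identical(class(back), "population_config")
  # same config, same frame (up to YAML's numeric serialization precision)
  expect_equal(build_frame(back), build_frame(cfg), tolerance = 1e-9)
})
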