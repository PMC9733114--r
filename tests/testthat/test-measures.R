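dims_gh <- ghana_dimensions()
t1 <- ghana_mics_table1()
t1$se <- se_from_ci(t1$estimate, t1$ci_low, t1$ci_high)
tab_of <- function(yr, dim) t1[t1$year == yr & t1$dimension == dim, ]

test_that("extreme subgroups follow the dimension kind", {
  # non-ordered: data-driven extremes
  ex <- select_extremes(tab_of(2017, "Sub-national region"),
                        dims_gh$`Sub-national region`)
  expect_equal(ex$advantaged$subgroup, "Upper East")
  expect_equal(ex$advantaged$estimate, 75.5)
  expect_equal(ex$disadvantaged$subgroup, "Greater Accra")
  expect_equal(ex$disadvantaged$estimate, 17.5)

  # ordered: declared extremes regardless of values (quintile 5 performs
  # worse than quintile 1 for ITN use, but stays the advantaged group)
  ex <- select_extremes(tab_of(2011, "Economic status"),
                        dims_gh$`Economic status`)
  expect_equal(ex$advantaged$subgroup, "Quintile 5 (richest)")
  expect_equal(ex$disadvantaged$subgroup, "Quintile 1 (poorest)")
  expect_lt(ex$advantaged$estimate, ex$disadvantaged$estimate)

  # ties in non-ordered dimensions: deterministic pick plus warning
  spec <- dimension_spec("reg", "non_ordered", c("B", "A", "C"))
  est <- data.frame(subgroup = c("B", "A", "C"), estimate = c(50, 50, 10))
  expect_warning(ex <- select_extremes(est, spec), "tie")
  expect_equal(ex$advantaged$subgroup, "A")

  expect_error(select_extremes(est[1:2, ], spec), "missing declared")
})

test_that("difference reproduces published values and conventions", {
  d <- ineq_difference(tab_of(2011, "Sub-national region"),
                       dims_gh$`Sub-national region`)
  expect_equal(d$estimate, 62.3 - 11.8)  # printed 50.5
  d <- ineq_difference(tab_of(2011, "Economic status"),
                       dims_gh$`Economic status`)
  expect_equal(d$estimate, 15.8 - 51.4)  # printed -35.6

  spec <- toy_binary_spec()
  eq <- data.frame(dimension = "residence", subgroup = c("Rural", "Urban"),
                   estimate = c(30, 30), se = c(0, 0))
  expect_equal(ineq_difference(eq, spec)$estimate, 0)
})

test_that("ratio reproduces published values and guards the denominator", {
  r <- ineq_ratio(tab_of(2011, "Sub-national region"),
                  dims_gh$`Sub-national region`)
  expect_equal(round_report(r$estimate), 5.3)
  r <- ineq_ratio(tab_of(2011, "Education"), dims_gh$Education)
  expect_equal(round_report(r$estimate), 0.6)

  spec <- toy_binary_spec()
  eq <- data.frame(subgroup = c("Rural", "Urban"), estimate = c(30, 30),
                   se = c(1, 1))
  expect_equal(ineq_ratio(eq, spec)$estimate, 1)
  zero <- data.frame(subgroup = c("Rural", "Urban"), estimate = c(0, 30),
                     se = c(0, 1))
  expect_error(ineq_ratio(zero, spec), "denominator")
})

test_that("PAR uses the reference subgroup and truncates at zero", {
  mu17 <- setting_average(49.7, 0)
  p <- ineq_par(tab_of(2017, "Sub-national region"),
                dims_gh$`Sub-national region`, mu17)
  expect_equal(p$estimate, 75.5 - 49.7)  # printed 25.8
  expect_equal(p$reference_subgroup, "Upper East")

  mu11 <- setting_average(32.6, 0)
  p <- ineq_par(tab_of(2011, "Economic status"), dims_gh$`Economic status`,
                mu11)
  expect_equal(p$estimate, 0)  # richest 15.8 < mu, truncated
  # UI symmetric about the reported (truncated) value, printed-table style
  expect_equal(p$ui_low, -p$ui_high)
  expect_lt(p$ui_low, 0)

  raw <- ineq_par(tab_of(2011, "Economic status"), dims_gh$`Economic status`,
                  mu11, truncate = FALSE)
  expect_equal(raw$estimate, 15.8 - 32.6)

  at_mu <- data.frame(subgroup = c("Rural", "Urban"),
                      estimate = c(20, 49.7), se = c(1, 1))
  expect_equal(ineq_par(at_mu, toy_binary_spec(), mu17)$estimate, 0)
  expect_error(ineq_par(at_mu, toy_binary_spec(), NULL), "mu")
})

test_that("PAF is PAR scaled by 100/mu, bounds included", {
  mu <- setting_average(49.7, 0)
  par <- ineq_par(tab_of(2017, "Sub-national region"),
                  dims_gh$`Sub-national region`, mu)
  paf <- ineq_paf(par, mu)
  expect_equal(paf$estimate, 100 * par$estimate / 49.7)
  expect_equal(round_report(paf$estimate), 51.9)
  expect_equal(paf$ui_low, 100 * par$ui_low / 49.7)

  zero <- par; zero$estimate <- 0; zero$ui_low <- -1; zero$ui_high <- 1
  expect_equal(ineq_paf(zero, mu)$estimate, 0)
  full <- par; full$estimate <- 49.7
  expect_equal(ineq_paf(full, mu)$estimate, 100)
  expect_error(ineq_paf(par, setting_average(0)), "positive")
})

test_that("delta-method uncertainty intervals have the stated closed forms", {
  # 3-4-5: se_D = 5, 95% half-width 9.8
  ui <- measure_ui("D", c(10, 5), c(3, 4))
  expect_equal(ui[2] - 5, qnorm(0.975) * 5)
  expect_equal(round_report(ui[2] - 5), 9.8)
  # zero ses collapse every interval
  expect_equal(measure_ui("D", c(10, 5), c(0, 0)), c(5, 5))
  expect_equal(measure_ui("R", c(10, 5), c(0, 0)), c(2, 2))
  expect_equal(measure_ui("PAR", 60, 0, mu = 50, se_mu = 0), c(10, 10))
  # log-scale ratio interval
  ui <- measure_ui("R", c(40, 20), c(2, 3))
  sl <- sqrt((2 / 40)^2 + (3 / 20)^2)
  expect_equal(ui, 2 * exp(c(-1, 1) * qnorm(0.975) * sl))
  # PAF is the PAR interval rescaled
  expect_equal(measure_ui("PAF", 60, 2, mu = 50, se_mu = 1),
               measure_ui("PAR", 60, 2, mu = 50, se_mu = 1) * 2)
  expect_error(measure_ui("D", c(10, 5), c(NA, 4)), "bootstrap")
})

test_that("health_inequality computes all measures and isolates failures", {
  fit <- health_inequality(t1[t1$year == 2017, ], mu = 49.7, dims_gh)
  expect_s3_class(fit, "health_inequality")
  expect_equal(nrow(fit$summaries), 16)
  co <- coef(fit)
  expect_equal(round_report(co[["Sub-national region:D"]]), 58.0)
  expect_equal(round_report(co[["Sub-national region:PAF"]]), 51.9)
  expect_equal(unname(confint(fit)["Sub-national region:D", 1]) <
                 co[["Sub-national region:D"]], TRUE)

  # one broken dimension leaves the other twelve rows intact
  broken <- t1[t1$year == 2017 & t1$subgroup != "Quintile 3", ]
  fit2 <- health_inequality(broken, mu = 49.7, dims_gh)
  expect_equal(nrow(fit2$summaries), 12)
  expect_named(fit2$failures, "Economic status")
  expect_match(fit2$failures, "Quintile 3")

  # perfect equality on a single binary dimension
  eq <- data.frame(dimension = "residence", subgroup = c("Rural", "Urban"),
                   estimate = c(49.7, 49.7), se = c(0, 0))
  fit3 <- health_inequality(eq, mu = 49.7, toy_binary_spec())
  expect_equal(unname(coef(fit3)), c(0, 1, 0, 0))
})

test_that("measure identities and invariances hold over random tables", {
  set.seed(2024)
  specs <- list(
    dimension_spec("ord", "ordered", paste0("g", 1:4)),
    dimension_spec("bin", "binary", c("lo", "hi")),
    dimension_spec("non", "non_ordered", paste0("r", 1:6))
  )
  for (rep in 1:25) {
    for (spec in specs) {
      k <- length(spec$subgroups)
      est <- data.frame(dimension = spec$name, subgroup = spec$subgroups,
                        estimate = runif(k, 5, 95), se = runif(k, 0.5, 4))
      mu <- setting_average(runif(1, 10, 90), runif(1, 0.5, 3))
      fit <- health_inequality(est, mu, spec)
      s <- fit$summaries
      getm <- function(m, col = "estimate") s[s$measure == m, col]

      # PAF = 100 * PAR / mu exactly, pre-rounding, bounds included
      expect_equal(getm("PAF"), 100 * getm("PAR") / mu$mu)
      expect_equal(getm("PAF", "ui_low"), 100 * getm("PAR", "ui_low") / mu$mu)

      # sign/ordering conventions
      if (spec$kind == "non_ordered") {
        expect_gte(getm("D"), 0)
        expect_gte(getm("R"), 1)
      } else {
        expect_equal(sign(getm("D")), sign(log(getm("R"))))
      }

      # truncation: PAR = 0 iff the reference does not beat the average
      y_ref <- est$estimate[est$subgroup ==
                              s$reference_subgroup[s$measure == "PAR"]]
      expect_gte(getm("PAR"), 0)
      expect_equal(getm("PAR") == 0, y_ref <= mu$mu)

      # scale equivariance: D and PAR scale with k, R and PAF do not
      kf <- runif(1, 0.3, 1.1)
      est2 <- transform(est, estimate = estimate * kf, se = se * kf)
      mu2 <- setting_average(mu$mu * kf, mu$se_mu * kf)
      s2 <- health_inequality(est2, mu2, spec)$summaries
      getm2 <- function(m) s2[s2$measure == m, "estimate"]
      expect_equal(getm2("D"), kf * getm("D"))
      expect_equal(getm2("PAR"), kf * getm("PAR"))
      expect_equal(getm2("R"), getm("R"))
      expect_equal(getm2("PAF"), getm("PAF"))
    }
  }
})

test_that("delta and bootstrap intervals agree on a clustered design", {
  od <- oracle_design_records()
  dims <- synthetic_dimensions(od$config)["residence"]
  fit_d <- health_inequality(records = od$records, dimensions = dims)
  fit_b <- health_inequality(records = od$records, dimensions = dims,
                             ui_method = "bootstrap", reps = 2000,
                             seed = 77)
  d_d <- fit_d$summaries[fit_d$summaries$measure == "D", ]
  d_b <- fit_b$summaries[fit_b$summaries$measure == "D", ]
  hw <- (d_d$ui_high - d_d$ui_low) / 2
  expect_lt(abs(d_d$ui_low - d_b$ui_low), 0.15 * hw)
  expect_lt(abs(d_d$ui_high - d_b$ui_high), 0.15 * hw)
})

test_that("uncertainty-interval overlap reads as in two-survey comparisons", {
  expect_true(ui_overlap(c(30.7, 70.4), c(42.2, 73.8)))
  expect_false(ui_overlap(c(0.2, 0.6), c(0.7, 0.9)))
})
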