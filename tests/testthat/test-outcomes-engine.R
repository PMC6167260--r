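nh_default <- natural_history(
  m_nocare_u5 = 0.8, m_care_u5 = 0.1, sb_frac = 0.05,
  shares_nocare = c(0.05, 0.35, 0.60), shares_care = c(0.30, 0.45, 0.25),
  death_age_bands = data.frame(age = c(0.04, 0.5), share = c(0.5, 0.5)))

test_that("birth outcomes split the affected prevalence exactly", {
  b <- birth_outcome_envelope(2.0, 0.24, nh_default)
  expect_equal(b$stillbirths, 0.088)
  expect_equal(b$livebirths, 1.672)
  expect_equal(b$terminations + b$stillbirths + b$livebirths, 2.0)
  expect_equal(birth_outcome_envelope(1.0, 1.0, nh_default)$livebirths, 0)
  nh0 <- natural_history(0.8, 0.1, 0, c(0.05, 0.35, 0.6),
                         c(0.3, 0.45, 0.25))
  expect_equal(birth_outcome_envelope(2.0, 0.24, nh0)$livebirths, 1.76)
  expect_error(birth_outcome_envelope(1.0, 1.2, nh_default), "exceed")
})

test_that("under-5 outcomes mix the binary access strata by survivor mass", {
  u <- under5_outcomes(1.672, 0.5, nh_default)
  expect_equal(u$u5_deaths, 1.672 * 0.45)
  expect_equal(u$u5_deaths + u$cured + u$mild_moderate + u$severe, 1.672)
  # full access: care parameters exactly
  u1 <- under5_outcomes(1, 1, nh_default)
  expect_equal(u1$u5_deaths, 0.1)
  expect_equal(c(u1$cured, u1$mild_moderate, u1$severe),
               0.9 * c(0.30, 0.45, 0.25))
  # equal mortalities: deaths independent of access
  nh_eq <- natural_history(0.3, 0.3, 0.05, c(0.05, 0.35, 0.6),
                           c(0.3, 0.45, 0.25))
  expect_equal(under5_outcomes(1, 0.2, nh_eq)$u5_deaths,
               under5_outcomes(1, 0.9, nh_eq)$u5_deaths)
  # worked stratum example: survivor-mass weights, not raw access
  acc <- 0.5; L <- 1
  surv_care <- acc * (1 - 0.1); surv_nocare <- (1 - acc) * (1 - 0.8)
  u2 <- under5_outcomes(L, acc, nh_default)
  expect_equal(u2$cured, surv_care * 0.30 + surv_nocare * 0.05)
})

test_that("deaths fall and cures rise with access", {
  accs <- seq(0, 1, 0.1)
  deaths <- vapply(accs, function(a)
    under5_outcomes(1, a, nh_default)$u5_deaths, numeric(1))
  cured <- vapply(accs, function(a)
    under5_outcomes(1, a, nh_default)$cured, numeric(1))
  expect_true(all(diff(deaths) < 0))
  expect_true(all(diff(cured) > 0))
})

test_that("mean age at death is the share-weighted band mean, NA for zero deaths", {
  expect_equal(mean_age_at_death(0.5, data.frame(age = 0.5, share = 1)),
               0.5)
  expect_equal(mean_age_at_death(
    0.5, data.frame(age = c(0.04, 0.5), share = c(0.5, 0.5))), 0.27)
  expect_true(is.na(mean_age_at_death(0, data.frame(age = 0.5, share = 1))))
  expect_error(mean_age_at_death(0.5, data.frame()), "required")
})

test_that("both conservation identities hold across 10,000 random parameter draws", {
  set.seed(2024)
  n <- 10000
  prev <- runif(n, 0, 10)
  tops <- runif(n) * prev
  acc <- runif(n)
  m_no <- runif(n)
  m_ca <- runif(n) * m_no
  sbf <- runif(n)
  sh <- matrix(rgamma(3 * n, 1), ncol = 3); sh <- sh / rowSums(sh)
  sh2 <- matrix(rgamma(3 * n, 1), ncol = 3); sh2 <- sh2 / rowSums(sh2)
  worst1 <- worst2 <- 0
  for (i in seq_len(n)) {
    nh <- natural_history(m_no[i], m_ca[i], sbf[i], sh[i, ], sh2[i, ])
    env <- outcome_envelope(prev[i], tops[i], acc[i], nh)
    worst1 <- max(worst1, abs(env$terminations + env$stillbirths +
                                env$livebirths - env$affected_post_prevention))
    worst2 <- max(worst2, abs(env$u5_deaths + env$cured +
                                env$mild_moderate + env$severe -
                                env$livebirths))
    if (i <= 50) {
      expect_true(all(unlist(env[1, 1:8]) >= -1e-12))
    }
  }
  expect_lt(worst1, 1e-9)
  expect_lt(worst2, 1e-9)
})

test_that("regional aggregation is a births-weighted mean, order-invariant and split-invariant", {
  df <- data.frame(region = c("X", "X"), livebirths = c(1000, 3000),
                   rate = c(2, 4), count = c(5, 7))
  agg <- aggregate_regions(df, rate_cols = "rate", count_cols = "count",
                           world_row = FALSE)
  expect_equal(agg$rate, 3.5)
  expect_equal(agg$count, 12)
  # single country: identity
  one <- aggregate_regions(df[1, ], rate_cols = "rate", world_row = FALSE)
  expect_equal(one$rate, 2)
  # constant rates aggregate to that rate
  cst <- data.frame(region = c("X", "Y", "Y"),
                    livebirths = c(10, 20, 5), rate = 1.3)
  expect_true(all(aggregate_regions(cst, "rate")$rate == 1.3))
  # order invariance
  shuf <- df[2:1, ]
  expect_equal(aggregate_regions(shuf, "rate", world_row = FALSE)$rate, 3.5)
  # splitting a country in two equal-rate halves changes nothing
  split2 <- data.frame(region = "X", livebirths = c(1000, 1500, 1500),
                       rate = c(2, 4, 4))
  expect_equal(aggregate_regions(split2, "rate", world_row = FALSE)$rate,
               3.5)
  # world row equals the weighted mean of regional rows
  multi <- data.frame(region = c("X", "Y"), livebirths = c(100, 300),
                      rate = c(1, 5))
  out <- aggregate_regions(multi, "rate")
  wrow <- out[out$region == "World", ]
  expect_equal(wrow$rate, 4)
  expect_error(aggregate_regions(
    data.frame(region = "X", livebirths = 0, rate = 1), "rate"), "weight")
})

test_that("the pipeline is linear in the baseline prevalences", {
  # homogeneity holds for condition classes whose prevention operators are
  # proportional (anti-D, counselling, TOP); the fortification floor is an
  # absolute rate, so NTDs are exempt, and recessive baselines derive from
  # the allele frequency rather than a scalable input
  fx <- generate_fixtures(6, seed = 3)
  res1 <- suppressWarnings(run_pipeline(fx$countries, fx$conditions))
  cond2 <- fx$conditions
  cond2$baseline_prevalence_per_1000 <- 3 * cond2$baseline_prevalence_per_1000
  keep <- !cond2$condition_class %in% c("single_gene_recessive", "ntd")
  res3 <- suppressWarnings(
    run_pipeline(fx$countries, cond2[keep, ]))
  e1 <- res1$estimates[!res1$estimates$condition_class %in%
                         c("single_gene_recessive", "ntd"), ]
  fields <- c("affected_post_prevention", "terminations", "stillbirths",
              "livebirths_rate", "u5_deaths", "cured", "mild_moderate",
              "severe")
  for (f in fields)
    expect_equal(res3$estimates[[f]], 3 * e1[[f]], tolerance = 1e-9)
})
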