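test_that("Hardy-Weinberg prevalence with consanguinity augmentation", {
  expect_equal(hardy_weinberg_prevalence(0.05), 0.0025)
  expect_equal(hardy_weinberg_prevalence(0, 0.04), 0)
  expect_equal(hardy_weinberg_prevalence(0.05, 0.0625), 0.00546875)
  expect_error(hardy_weinberg_prevalence(0.6), "0.5")
})

test_that("retrospective fall matches the stop-at-first-affected closed form", {
  expect_equal(retrospective_fall(counselling_context(1)), 0)
  expect_equal(retrospective_fall(counselling_context(6)),
               1 - (1 - 0.75^6) / 1.5)
  expect_equal(round(retrospective_fall(counselling_context(6)), 3), 0.452)
  expect_equal(round(retrospective_fall(counselling_context(2.5)), 4),
               0.1794, tolerance = 1e-3)
  # with prenatal diagnosis the avoidable excess is removed with prob u
  ctx <- counselling_context(6, pnd_available = TRUE, pnd_uptake = 0.5)
  expect_equal(retrospective_fall(ctx),
               0.5 * retrospective_fall(counselling_context(6)))
})

test_that("retrospective fall is near 50% at family size six and 15% at the global norm", {
  expect_lte(abs(retrospective_fall(counselling_context(6)) - 0.50), 0.10)
  expect_lte(abs(retrospective_fall(counselling_context(2.5)) - 0.15), 0.05)
})

test_that("prospective fall is zero for small families, ~50% at six, and equals uptake with PND", {
  expect_equal(prospective_fall(counselling_context(2)), 0)
  expect_equal(prospective_fall(counselling_context(2.5)), 0)
  expect_equal(prospective_fall(counselling_context(6)), 1 - (2 / 3) / 1.5)
  expect_lte(abs(prospective_fall(counselling_context(6)) - 0.50), 0.10)
  expect_equal(prospective_fall(
    counselling_context(4, pnd_available = TRUE, pnd_uptake = 0.97)), 0.97)
  expect_equal(prospective_fall(
    counselling_context(4, pnd_available = TRUE, pnd_uptake = 0.15)), 0.15)
})

test_that("both falls are non-decreasing in family size and bounded in [0, 1)", {
  Ns <- seq(1, 10, by = 0.5)
  retro <- vapply(Ns, function(n)
    retrospective_fall(counselling_context(n)), numeric(1))
  pro <- vapply(Ns, function(n)
    prospective_fall(counselling_context(n)), numeric(1))
  expect_true(all(diff(retro) >= 0))
  expect_true(all(diff(pro) >= 0))
  expect_true(all(retro >= 0 & retro < 1))
  expect_true(all(pro >= 0 & pro < 1))
  # earlier detection does at least as well once families are large enough
  # for the two-healthy-children limit to bind (N >= 4)
  large <- Ns >= 4
  expect_true(all(pro[large] >= retro[large]))
  # and always with prenatal diagnosis
  for (u in c(0.15, 0.5, 0.97))
    for (n in Ns) {
      ctx <- counselling_context(n, pnd_available = TRUE, pnd_uptake = u)
      expect_gte(prospective_fall(ctx), retrospective_fall(ctx))
    }
})

test_that("counselling-adjusted prevalence composes the coverages", {
  ctx0 <- counselling_context(6)
  expect_equal(counselling_adjusted_prevalence(2.0, ctx0), 2.0)
  ctx_r <- counselling_context(6, retro_coverage = 0.5)
  expect_equal(counselling_adjusted_prevalence(2.0, ctx_r),
               2.0 * (1 - 0.5 * retrospective_fall(counselling_context(6))))
  expect_equal(round(counselling_adjusted_prevalence(2.0, ctx_r), 3), 1.548)
  ctx_p <- counselling_context(4, pnd_available = TRUE, pnd_uptake = 0.97,
                               pro_coverage = 1)
  expect_equal(counselling_adjusted_prevalence(2.0, ctx_p), 2.0 * 0.03)
})

test_that("counselling-adjusted prevalence is monotone non-increasing in every lever", {
  base <- 2.0
  grid <- seq(0, 1, 0.25)
  for (lever in c("pro", "retro", "uptake", "N")) {
    vals <- vapply(grid, function(g) {
      ctx <- switch(lever,
        pro = counselling_context(6, pnd_available = TRUE, pnd_uptake = 0.5,
                                  retro_coverage = 0.5, pro_coverage = g),
        retro = counselling_context(6, retro_coverage = g),
        uptake = counselling_context(6, pnd_available = TRUE,
                                     pnd_uptake = g, retro_coverage = 0.5,
                                     pro_coverage = 0.5),
        N = counselling_context(1 + 7 * g, retro_coverage = 0.5,
                                pro_coverage = 0.3))
      counselling_adjusted_prevalence(base, ctx)
    }, numeric(1))
    expect_true(all(diff(vals) <= 1e-12), label = paste("monotone in", lever))
    expect_true(all(vals >= 0 & vals <= base))
  }
})

test_that("Monte-Carlo stopping-rule simulation agrees with the closed forms", {
  n_mc <- 20000   # quick per-module check; the full-size sweep runs in the
                  # acceptance suite
  for (N in c(2, 4, 6)) {
    sim <- simulate_reproductive_outcomes("retrospective", N,
                                          n_couples = n_mc, seed = 11)
    expect_lte(abs(sim$fall - retrospective_fall(counselling_context(N))),
               3 * sim$se)
    sim_u <- simulate_reproductive_outcomes("retrospective", N,
                                            pnd_uptake = 0.5,
                                            n_couples = n_mc, seed = 12)
    ctx <- counselling_context(N, pnd_available = TRUE, pnd_uptake = 0.5)
    expect_lte(abs(sim_u$fall - retrospective_fall(ctx)), 3 * sim_u$se)
  }
  # prospective: interior family sizes (the floor region is a behavioural
  # assumption, not a stopping-rule outcome)
  for (N in c(3, 6, 8)) {
    sim <- simulate_reproductive_outcomes("prospective", N,
                                          n_couples = n_mc, seed = 13)
    expect_lte(abs(sim$fall - (1 - (2 / 3) / (N / 4))), 3 * sim$se)
  }
  sim97 <- simulate_reproductive_outcomes("prospective", 4,
                                          pnd_uptake = 0.97,
                                          n_couples = n_mc, seed = 14)
  expect_lte(abs(sim97$fall - 0.97), 3 * sim97$se)
})

test_that("the simulator is seed-deterministic and leaves the RNG state alone", {
  a <- simulate_reproductive_outcomes("retrospective", 4, seed = 99,
                                      n_couples = 5000)
  b <- simulate_reproductive_outcomes("retrospective", 4, seed = 99,
                                      n_couples = 5000)
  expect_identical(a, b)
  # caller's RNG stream is unaffected by the simulation in between
  set.seed(123); x1 <- runif(1)
  simulate_reproductive_outcomes("prospective", 4, seed = 99,
                                 n_couples = 1000)
  x2 <- runif(1)
  set.seed(123)
  expect_identical(runif(2), c(x1, x2))
})
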