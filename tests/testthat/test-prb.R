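test_that("poverty cases averted follow the elasticity arithmetic", {
  # beta = -0.5, p = 0.2, N = 1e6, 1% increase -> 1,000 cases averted
  expect_equal(poverty_cases_averted(-0.5, 0.2, 1e6), 1000)
  expect_equal(poverty_cases_averted(0, 0.37, 5e6), 0)
  expect_equal(poverty_cases_averted(-0.5, 0.2, 2e6),
               2 * poverty_cases_averted(-0.5, 0.2, 1e6))
  expect_lt(poverty_cases_averted(0.3, 0.2, 1e6), 0) # harmful sign passes through
})

test_that("budget increments scale and add up", {
  expect_equal(budget_increment(100, 1e6), 1e6)
  expect_equal(budget_increment(100, 1e6, pct = 0), 0)
  expect_equal(budget_increment(80, 3e6 + 4e6),
               budget_increment(80, 3e6) + budget_increment(80, 4e6))
})

test_that("the country benchmark equals the two-step increment/cases oracle", {
  snap <- tibble::tibble(country_id = "X", income_group = "low",
                         p = 0.5, phe_pc = 100, N = 7.3e6)
  # oracle: compute the spending increment and the cases averted separately
  oracle <- budget_increment(100, 7.3e6, 1) /
    poverty_cases_averted(-1, 0.5, 7.3e6, 1)
  prb <- country_prb(-1, snap)
  expect_equal(as.numeric(prb), oracle)
  expect_equal(as.numeric(prb), 200) # closed form phe / (-beta * p)
})

test_that("plausible pooled-coefficient magnitudes give a benchmark near $1,045", {
  snap <- tibble::tibble(p = 0.28, phe_pc = 134, N = 1e6)
  two_step <- budget_increment(134, 1e6) /
    poverty_cases_averted(-0.458, 0.28, 1e6)
  expect_equal(as.numeric(country_prb(-0.458, snap)), two_step)
  expect_equal(as.numeric(country_prb(-0.458, snap)), 134 / (0.458 * 0.28),
               tolerance = 1e-12)
  expect_equal(as.numeric(country_prb(-0.458, snap)), 1044.9,
               tolerance = 1e-4)
})

test_that("the benchmark is exactly independent of population and percent size", {
  base <- tibble::tibble(p = 0.31, phe_pc = 57, N = 1e6)
  big <- base; big$N <- 9.9e8
  expect_equal(as.numeric(country_prb(-0.44, base)),
               as.numeric(country_prb(-0.44, big)), tolerance = 1e-12)
  expect_equal(as.numeric(country_prb(-0.44, base, pct = 1)),
               as.numeric(country_prb(-0.44, base, pct = 0.5)),
               tolerance = 1e-12)
})

test_that("benchmark monotonicity: decreasing in |beta| and p, increasing in spending", {
  snap <- function(p, phe) tibble::tibble(p = p, phe_pc = phe, N = 1e6)
  expect_lt(as.numeric(country_prb(-0.8, snap(0.3, 100))),
            as.numeric(country_prb(-0.4, snap(0.3, 100))))
  expect_lt(as.numeric(country_prb(-0.4, snap(0.5, 100))),
            as.numeric(country_prb(-0.4, snap(0.3, 100))))
  expect_gt(as.numeric(country_prb(-0.4, snap(0.3, 200))),
            as.numeric(country_prb(-0.4, snap(0.3, 100))))
})

test_that("a non-negative elasticity yields a flagged undefined price, never negative", {
  snap <- tibble::tibble(p = 0.3, phe_pc = 50, N = 1e6)
  out <- country_prb(0.2, snap)
  expect_true(is.na(out))
  expect_equal(attr(out, "undefined"), 1L)
})

test_that("a single draw at the point estimate collapses the summary", {
  snaps <- tibble::tibble(country_id = c("A", "B"),
                          income_group = c("low", "low"),
                          p = c(0.4, 0.2), phe_pc = c(30, 90), N = c(1e6, 2e6))
  s <- aggregate_prb(-0.5, snaps, group = "all", beta_point = -0.5)
  point <- mean(c(30 / (0.5 * 0.4), 90 / (0.5 * 0.2)))
  expect_equal(s$median, point)
  expect_equal(s$mean, point)
  expect_equal(s$lower_ur, point)
  expect_equal(s$upper_ur, point)
  expect_equal(s$mean_at_point, point)
  # two identical countries reduce to the single-country benchmark
  twin <- tibble::tibble(country_id = c("A", "A2"), income_group = "low",
                         p = 0.4, phe_pc = 30, N = 1e6)
  expect_equal(aggregate_prb(-0.5, twin)$median, 30 / (0.5 * 0.4))
})

test_that("uncertainty bounds equal the monotone map at matching beta quantiles", {
  set.seed(99)
  snaps <- tibble::tibble(country_id = sprintf("C%02d", 1:12),
                          income_group = "low",
                          p = runif(12, 0.1, 0.6),
                          phe_pc = runif(12, 10, 200),
                          N = runif(12, 1e6, 1e8))
  betas <- -exp(rnorm(1000, log(0.5), 0.25)) # all negative
  s <- aggregate_prb(betas, snaps, group = "all")
  # brute-force oracle: per-iteration country means, sorted percentiles
  iter_means <- vapply(betas, function(b)
    mean(as.numeric(country_prb(b, snaps))), 0)
  expect_equal(s$median, percentile_oracle(iter_means, 0.5), tolerance = 1e-10)
  expect_equal(s$lower_ur, percentile_oracle(iter_means, 0.025),
               tolerance = 1e-10)
  expect_equal(s$upper_ur, percentile_oracle(iter_means, 0.975),
               tolerance = 1e-10)
  expect_equal(s$mean, mean(iter_means), tolerance = 1e-10)
  expect_true(s$lower_ur <= s$median && s$median <= s$upper_ur)
  # quantiles commute with the increasing map beta -> K/(-beta): at draw
  # counts where the 2.5/50/97.5 percentiles fall exactly on order
  # statistics (no interpolation), the bounds equal the map evaluated at
  # the matching beta quantiles
  betas1 <- -exp(rnorm(1001, log(0.5), 0.25))
  s1 <- aggregate_prb(betas1, snaps, group = "all")
  K <- mean(snaps$phe_pc / snaps$p)
  expect_equal(s1$median, K / (-percentile_oracle(betas1, 0.5)),
               tolerance = 1e-10)
  expect_equal(s1$lower_ur, K / (-percentile_oracle(betas1, 0.025)),
               tolerance = 1e-10)
  expect_equal(s1$upper_ur, K / (-percentile_oracle(betas1, 0.975)),
               tolerance = 1e-10)
})

test_that("non-negative draws are dropped with a reported count", {
  snaps <- tibble::tibble(country_id = "A", income_group = "low",
                          p = 0.3, phe_pc = 60, N = 1e6)
  betas <- c(-0.5, -0.4, 0.1, 0, -0.6)
  s <- aggregate_prb(betas, snaps)
  expect_equal(s$n_dropped, 2L)
  expect_equal(s$n_iterations, 5L)
  expect_error(aggregate_prb(c(0.1, 0.2), snaps), "non-negative")
})

test_that("currency rescaling scales every benchmark by the same factor", {
  snaps <- tibble::tibble(country_id = c("A", "B"), income_group = "low",
                          p = c(0.4, 0.2), phe_pc = c(30, 90), N = 1e6)
  betas <- c(-0.6, -0.5, -0.4)
  s1 <- aggregate_prb(betas, snaps)
  scaled <- snaps; scaled$phe_pc <- scaled$phe_pc * 2.5
  s2 <- aggregate_prb(betas, scaled)
  expect_equal(s2$median, 2.5 * s1$median, tolerance = 1e-12)
  expect_equal(s2$per_country_point, 2.5 * s1$per_country_point,
               tolerance = 1e-12)
})

test_that("the grouped benchmark table uses group-specific or pooled fits", {
  rows <- random_rows(8, 5, seed = 17)
  rows$income_group <- rep(c("low", "lower_middle"), each = 20)
  rows$log_pov <- rows$log_pov - 0.6 * rows$log_phe_lag
  fit_all <- fit_fixed_effects(rows, regression_spec(TRUE, character()))
  fit_low <- fit_fixed_effects(rows, regression_spec(TRUE, character(),
                                                     income_groups = "low"))
  snaps <- country_snapshots(rows)
  tab <- prb_table(list(all = fit_all, low = fit_low), snaps,
                   n = 400, seed = 4)
  expect_setequal(tab$group, c("all", "low", "lower_middle"))
  expect_true(all(tab$lower_ur <= tab$median & tab$median <= tab$upper_ur))
  # pooled sourcing reproduces the all-column beta for every group
  tab_p <- prb_table(list(all = fit_all, low = fit_low), snaps,
                     n = 400, seed = 4, beta_source = "pooled")
  expect_equal(tab_p$median[tab_p$group == "all"],
               tab$median[tab$group == "all"])
})
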