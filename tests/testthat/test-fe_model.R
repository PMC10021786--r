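test_that("within estimator reproduces the hand-computed two-country slope", {
  # demeaned within-country data: A x = (-0.5, 0.5), y = (-0.25, 0.25);
  # B x = (-1, 1), y = (0.5, -0.5)  =>  beta = (0.25 - 1.0) / 2.5 = -0.30
  rows <- make_rows(
    country = c("A", "A", "B", "B"), year = c(2001L, 2002L, 2001L, 2002L),
    log_pov = c(-1 - 0.25, -1 + 0.25, -2 + 0.5, -2 - 0.5),
    log_phe_lag = c(3 - 0.5, 3 + 0.5, 4 - 1, 4 + 1))
  fit <- fit_fixed_effects(rows, regression_spec(TRUE, character()))
  expect_equal(fit$beta, -0.30, tolerance = 1e-12)
  expect_equal(fit$n_obs, 4L)
  expect_equal(fit$n_countries, 2L)
})

test_that("a noiseless fixed-effects panel is recovered exactly", {
  set.seed(21)
  nc <- 8; nt <- 6
  alpha <- rnorm(nc, -1, 0.3)
  rows <- make_rows(
    country = rep(sprintf("C%02d", 1:nc), each = nt),
    year = rep(2000L + 1:nt, nc),
    log_pov = 0, log_phe_lag = rnorm(nc * nt, 4, 0.5))
  rows$log_pov <- alpha[rep(1:nc, each = nt)] - 0.7 * rows$log_phe_lag
  fit <- fit_fixed_effects(rows, regression_spec(TRUE, character()))
  expect_equal(fit$beta, -0.7, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(unname(fit$fixed_effects), alpha, tolerance = 1e-10)
})

test_that("within estimator matches the LSDV oracle on random panels", {
  for (seed in 1:12) {
    nc <- sample(3:10, 1); nt <- sample(3:5, 1)
    rows <- random_rows(nc, nt, seed = 100 + seed)
    for (controls in list(character(), c("log_gdp", "gini"))) {
      fit <- fit_fixed_effects(rows, regression_spec(TRUE, controls))
      oracle <- lsdv_oracle(rows, controls)
      expect_equal(unname(fit$coefficients), unname(oracle$coef),
                   tolerance = 1e-8)
      expect_equal(unname(fit$se), unname(oracle$se), tolerance = 1e-8)
      expect_equal(fit$r_squared, oracle$r2, tolerance = 1e-8)
    }
  }
})

test_that("pooled OLS (no fixed effects) matches lm with intercept", {
  rows <- random_rows(6, 4, seed = 77)
  fit <- fit_fixed_effects(rows, regression_spec(FALSE, c("log_gdp", "gini")))
  oracle <- lsdv_oracle(rows, c("log_gdp", "gini"), fixed_effects = FALSE)
  expect_equal(unname(fit$coefficients), unname(oracle$coef),
               tolerance = 1e-8)
  expect_equal(unname(fit$se), unname(oracle$se), tolerance = 1e-8)
  expect_false(is.na(fit$intercept))
})

test_that("the elasticity is invariant to currency rescaling and outcome shifts", {
  rows <- random_rows(7, 4, seed = 5)
  base <- fit_fixed_effects(rows, regression_spec(TRUE, c("log_gdp", "gini")))
  scaled <- rows
  scaled$log_phe_lag <- scaled$log_phe_lag + log(3.7) # phe_pc * 3.7
  fit_s <- fit_fixed_effects(scaled, regression_spec(TRUE, c("log_gdp", "gini")))
  expect_equal(fit_s$beta, base$beta, tolerance = 1e-10)
  expect_equal(fit_s$se, base$se, tolerance = 1e-10)
  shifted <- rows
  shifted$log_pov <- shifted$log_pov + 0.9
  fit_y <- fit_fixed_effects(shifted, regression_spec(TRUE, c("log_gdp", "gini")))
  expect_equal(fit_y$beta, base$beta, tolerance = 1e-10)
  expect_equal(fit_y$fixed_effects, base$fixed_effects + 0.9,
               tolerance = 1e-10)
})

test_that("a control constant within every country triggers a named rank error", {
  rows <- random_rows(5, 4, seed = 9)
  rows$gini <- rep(c(30, 35, 40, 45, 50), each = 4) # time-invariant
  expect_error(fit_fixed_effects(rows, regression_spec(TRUE, c("log_gdp", "gini"))),
               "rank deficient.*gini")
})

test_that("singleton countries are dropped with a warning under fixed effects", {
  rows <- rbind(random_rows(4, 3, seed = 3),
                make_rows("LONE", 2005L, -1, 4))
  expect_warning(fit <- fit_fixed_effects(rows, regression_spec(TRUE, character())),
                 "singleton")
  expect_equal(fit$n_countries, 4L)
  expect_equal(fit$n_obs, 12L)
})

test_that("cluster-robust vcov is symmetric PSD and changes only the SEs", {
  rows <- random_rows(8, 5, seed = 31)
  cl <- fit_fixed_effects(rows, regression_spec(TRUE, c("log_gdp", "gini"),
                                                vcov_kind = "cluster_by_country"))
  classical <- fit_fixed_effects(rows, regression_spec(TRUE, c("log_gdp", "gini")))
  expect_equal(cl$coefficients, classical$coefficients, tolerance = 1e-12)
  expect_equal(cl$vcov, t(cl$vcov), tolerance = 1e-12)
  expect_true(all(eigen(cl$vcov, symmetric = TRUE,
                        only.values = TRUE)$values > -1e-12))
  expect_equal(cl$se, sqrt(diag(cl$vcov)), tolerance = 1e-12)
})

test_that("coefficient draws honor the degenerate, deterministic, and CLT contracts", {
  rows <- random_rows(6, 5, seed = 13)
  fit <- fit_fixed_effects(rows, regression_spec(TRUE, c("log_gdp", "gini")))
  # zero vcov -> every draw equals the point estimate
  degen <- fit
  degen$vcov <- matrix(0, 3, 3, dimnames = dimnames(fit$vcov))
  d0 <- sample_coefficients(degen, n = 25, seed = 1)
  expect_true(all(abs(sweep(d0, 2, fit$coefficients)) < 1e-12))
  # fixed seed -> identical sequences
  expect_identical(sample_coefficients(fit, 200, seed = 42),
                   sample_coefficients(fit, 200, seed = 42))
  # CLT bound on the sample mean of the elasticity draws, n = 100,000
  n <- 1e5
  draws <- sample_coefficients(fit, n, seed = 7)[, "log_phe_lag"]
  sigma <- sqrt(fit$vcov["log_phe_lag", "log_phe_lag"])
  expect_lt(abs(mean(draws) - fit$beta), 4 * sigma / sqrt(n))
  expect_equal(stats::sd(draws), sigma, tolerance = 0.02)
})

test_that("non-PSD vcov is rejected by the sampler", {
  rows <- random_rows(5, 4, seed = 2)
  fit <- fit_fixed_effects(rows, regression_spec(TRUE, character()))
  fit$vcov <- matrix(-1, 1, 1, dimnames = dimnames(fit$vcov))
  expect_error(sample_coefficients(fit, 10, seed = 1), "positive semi-definite")
})

test_that("the regression table renders significance markers and diagnostics", {
  rows <- random_rows(10, 5, seed = 55)
  rows$log_pov <- rows$log_pov - 2 * rows$log_phe_lag # force significance
  fit <- fit_fixed_effects(rows, regression_spec(TRUE, c("log_gdp", "gini")))
  lines <- regression_table(list(`(1)` = fit))
  txt <- paste(lines, collapse = "\n")
  expect_match(txt, "\\*\\*\\*")
  expect_match(txt, "Observations")
  expect_match(txt, "# countries")
  expect_match(txt, "p<0.01")
})
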