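# Shared fixtures and independent oracles, all built in code.

# A small valid panel data frame in logical-column form.
toy_panel_df <- function() {
  tibble::tibble(
    country_id = c("AAA", "AAA", "BBB", "BBB"),
    year = c(2005L, 2006L, 2005L, 2006L),
    income_group = c("low", "low", "lower_middle", "lower_middle"),
    pov = c(0.50, 0.45, 0.20, 0.18),
    phe_pc = c(20, 22, 130, 140),
    gdp_pc = c(1500, 1550, 5000, 5200),
    gini = c(40, 41, 38, 38),
    population = c(2e7, 2e7, 5e7, 5e7),
    ext_pc = c(5, 6, 2, 2)
  )
}

# Write a data frame as a WDI-style CSV with default file headers.
write_toy_panel <- function(df = toy_panel_df(), path = tempfile(fileext = ".csv")) {
  sch <- povbench::wdi_schema()
  cols <- c("country_id", "year", "income_group", "pov", "phe_pc",
            "gdp_pc", "gini", "population",
            if ("ext_pc" %in% names(df)) "ext_pc")
  logical_names <- c("country", "year", "income_group", "pov", "phe_pc",
                     "gdp_pc", "gini", "population",
                     if ("ext_pc" %in% names(df)) "ext_pc")
  out <- df[, cols]
  names(out) <- unname(sch[logical_names])
  utils::write.csv(out, path, row.names = FALSE)
  path
}

# Estimation rows from raw (already-logged) values, bypassing file I/O.
make_rows <- function(country, year, log_pov, log_phe_lag,
                      log_gdp = 0, gini = 0, population = 1e6,
                      income_group = "low") {
  tibble::tibble(
    country_id = country, year = year, income_group = income_group,
    log_pov = log_pov, log_phe_lag = log_phe_lag,
    log_gdp = log_gdp, gini = gini, population = population,
    pov = exp(log_pov), phe_pc = exp(log_phe_lag)
  )
}

# Random estimation rows: nc countries x nt years, Gaussian data.
random_rows <- function(nc, nt, seed) {
  set.seed(seed)
  n <- nc * nt
  make_rows(
    country = rep(sprintf("C%02d", seq_len(nc)), each = nt),
    year = rep(2000L + seq_len(nt), nc),
    log_pov = rnorm(n, -1.5, 0.5),
    log_phe_lag = rnorm(n, 4, 0.6),
    log_gdp = rnorm(n, 8, 0.4),
    gini = runif(n, 30, 55)
  )
}

# Brute-force dummy-variable (LSDV) OLS oracle via lm(): slope coefficients,
# classical SEs, and R-squared. Independent of the within-transformation
# implementation under test.
lsdv_oracle <- function(rows, controls = character(), fixed_effects = TRUE) {
  d <- as.data.frame(rows)
  terms <- c("log_phe_lag", controls,
             if (fixed_effects) "factor(country_id)")
  fit <- stats::lm(stats::reformulate(terms, "log_pov"), data = d)
  sm <- summary(fit)
  keep <- c("log_phe_lag", controls)
  list(coef = stats::coef(fit)[keep],
       se = sm$coefficients[keep, "Std. Error"],
       r2 = sm$r.squared)
}

# Sort-based percentile oracle: type-7 interpolation done by hand.
percentile_oracle <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}
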