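# Synthetic country-year panels drawn from the log-log fixed-effects
# data-generating process with known parameters, plus synthetic SPL
# indicator tables, so every pipeline stage is testable end to end without
# any external data download.

#' Configuration of the synthetic panel generator
#'
#' The generative model is the estimation model run forwards:
#' `ln pov_{c,t} = alpha_c + beta_true * ln phe_{c,t-1} +
#' gamma_gdp * ln gdp_{c,t} + gamma_gini * gini_{c,t} + eps_{c,t}`,
#' with i.i.d. Gaussian noise. Spending and GDP follow geometric paths with
#' drift (so logs are always defined) and mildly autocorrelated
#' innovations; the Gini follows a slow random walk around its group mean.
#'
#' Country fixed effects are centred so that each group's mean poverty
#' level sits at `target_pov`, given the group's mid-sample spending and
#' GDP levels. Because the model is linear in `ln pov`, unbounded Gaussian
#' noise can push draws above a headcount ratio of 1; the generator refuses
#' to clamp and instead hard-errors, so `target_pov` defaults leave several
#' noise standard deviations of headroom below 1. Spending, GDP, and Gini
#' magnitudes mirror a low/lower-middle-income country frame (mean spending
#' around $26 vs $134 per capita).
#'
#' @param n_countries_by_group Named integer vector, countries per income
#'   group (default 20 low + 43 lower-middle).
#' @param years Inclusive years with poverty outcomes. A lag-source record
#'   (spending and covariates only) is also emitted one year before the
#'   first outcome year, so with a 1-year lag every outcome year yields an
#'   estimation row.
#' @param beta_true True spending elasticity (< 0 typical).
#' @param gamma_gdp,gamma_gini True control coefficients.
#' @param alpha_sd Between-country sd of the fixed effects.
#' @param target_pov Named vector: group-level mean poverty headcount ratio
#'   the fixed effects are centred on.
#' @param phe_log_mean,phe_log_sd,phe_drift,phe_innovation_sd Spending
#'   process: per-group initial log-level mean/sd, annual log drift, and
#'   innovation sd.
#' @param gdp_log_mean,gdp_log_sd,gdp_drift,gdp_innovation_sd GDP process,
#'   analogous.
#' @param gini_mean,gini_sd,gini_innovation_sd Gini process (0-100 scale).
#' @param noise_sd Sd of the i.i.d. error on `ln pov`.
#' @param population_log_mean,population_log_sd Per-group log-normal
#'   population parameters.
#' @param missing_rate Probability each country-year record is dropped
#'   (emulating incomplete reporting).
#' @param seed Master seed; per-stream substreams are derived from it so
#'   adding a stream never perturbs the others.
#' @return A `synthetic_panel_config` list.
#' @export
synthetic_panel_config <- function(
    n_countries_by_group = c(low = 20, lower_middle = 43),
    years = 2002:2019,
    beta_true = -0.5,
    gamma_gdp = -0.3,
    gamma_gini = 0.01,
    alpha_sd = 0.15,
    target_pov = c(low = 0.13, lower_middle = 0.06),
    phe_log_mean = c(low = log(26), lower_middle = log(134)),
    phe_log_sd = 0.25, phe_drift = 0.04, phe_innovation_sd = 0.08,
    gdp_log_mean = c(low = log(1775), lower_middle = log(5910)),
    gdp_log_sd = 0.30, gdp_drift = 0.02, gdp_innovation_sd = 0.04,
    gini_mean = 40, gini_sd = 5, gini_innovation_sd = 0.5,
    noise_sd = 0.3,
    population_log_mean = c(low = log(2e7), lower_middle = log(5e7)),
    population_log_sd = 1.0,
    missing_rate = 0.25,
    seed = 1L) {
  groups <- names(n_countries_by_group)
  stopifnot(length(groups) > 0, all(groups %in% INCOME_GROUPS),
            all(n_countries_by_group >= 1), length(years) >= 2,
            noise_sd >= 0, missing_rate >= 0, missing_rate < 1,
            all(groups %in% names(target_pov)),
            all(groups %in% names(phe_log_mean)),
            all(groups %in% names(gdp_log_mean)),
            all(groups %in% names(population_log_mean)))
  structure(as.list(environment()), class = "synthetic_panel_config")
}

#' Generate a synthetic country-year panel from known parameters
#'
#' Simulates the full data-generating process of the elasticity model and
#' returns a validated `pov_panel` (it round-trips through the same
#' validation as file input, with zero rejections when `missing_rate = 0`).
#' The `truth` attribute records every generative parameter, the per-country
#' fixed effects, and the realized last-year snapshots, enabling exact
#' parameter-recovery experiments.
#'
#' Any draw implying a poverty headcount ratio above 1 is a hard error
#' naming the offending country-year: the generator never truncates, which
#' forces configurations to keep the log-poverty distribution inside its
#' domain.
#'
#' @param config A [synthetic_panel_config()].
#' @return A `pov_panel` with attribute `truth`.
#' @export
generate_panel <- function(config) {
  stopifnot(inherits(config, "synthetic_panel_config"))
  cf <- config
  groups <- names(cf$n_countries_by_group)
  country_group <- rep(groups, cf$n_countries_by_group)
  n_c <- length(country_group)
  ids <- sprintf("SYN%03d", seq_len(n_c))
  yrs <- c(min(cf$years) - 1L, as.integer(cf$years)) # lead year for the lag
  n_t <- length(yrs)
  mid_shift <- cf$phe_drift * (n_t - 1) / 2
  gdp_mid_shift <- cf$gdp_drift * (n_t - 1) / 2

  sim <- with_seed(substream_seed(cf$seed, "panel"), {
    alpha <- numeric(n_c)
    log_phe <- log_gdp <- gini <- matrix(NA_real_, n_c, n_t)
    for (i in seq_len(n_c)) {
      grp <- country_group[i]
      # center the fixed effect so group mean ln(pov) sits at the target
      mu_alpha <- log(cf$target_pov[[grp]]) -
        cf$beta_true * (cf$phe_log_mean[[grp]] + mid_shift) -
        cf$gamma_gdp * (cf$gdp_log_mean[[grp]] + gdp_mid_shift) -
        cf$gamma_gini * cf$gini_mean
      alpha[i] <- stats::rnorm(1, mu_alpha, cf$alpha_sd)
      log_phe[i, ] <- cumsum(c(
        stats::rnorm(1, cf$phe_log_mean[[grp]], cf$phe_log_sd),
        stats::rnorm(n_t - 1, cf$phe_drift, cf$phe_innovation_sd)))
      log_gdp[i, ] <- cumsum(c(
        stats::rnorm(1, cf$gdp_log_mean[[grp]], cf$gdp_log_sd),
        stats::rnorm(n_t - 1, cf$gdp_drift, cf$gdp_innovation_sd)))
      gini[i, ] <- cumsum(c(stats::rnorm(1, cf$gini_mean, cf$gini_sd),
                            stats::rnorm(n_t - 1, 0, cf$gini_innovation_sd)))
    }
    gini <- pmin(pmax(gini, 0), 100)
    pop <- exp(stats::rnorm(n_c, cf$population_log_mean[country_group],
                            cf$population_log_sd))
    list(alpha = alpha, log_phe = log_phe, log_gdp = log_gdp, gini = gini,
         pop = pop)
  })

  eps <- with_seed(substream_seed(cf$seed, "noise"),
                   matrix(stats::rnorm(n_c * (n_t - 1), 0, cf$noise_sd),
                          n_c, n_t - 1))

  # ln pov_{c,t} = alpha_c + beta ln phe_{c,t-1} + gamma X_{c,t} + eps
  recs <- vector("list", n_c)
  for (i in seq_len(n_c)) {
    t_idx <- 2:n_t
    log_pov <- sim$alpha[i] + cf$beta_true * sim$log_phe[i, t_idx - 1] +
      cf$gamma_gdp * sim$log_gdp[i, t_idx] +
      cf$gamma_gini * sim$gini[i, t_idx] + eps[i, ]
    if (any(log_pov > 0)) {
      bad <- t_idx[which.max(log_pov)]
      stop("generated poverty headcount above 1 for (", ids[i], ", ",
           yrs[bad], "): pov = ", format(exp(max(log_pov))),
           "; lower target_pov or the dispersion parameters")
    }
    recs[[i]] <- tibble::tibble(
      country_id = ids[i], year = yrs[t_idx],
      income_group = country_group[i],
      pov = exp(log_pov), phe_pc = exp(sim$log_phe[i, t_idx]),
      gdp_pc = exp(sim$log_gdp[i, t_idx]), gini = sim$gini[i, t_idx],
      population = sim$pop[i], ext_pc = NA_real_)
  }
  df <- dplyr::bind_rows(recs)
  # lag-source records (first simulated year) for each country
  lead <- tibble::tibble(
    country_id = ids, year = yrs[1], income_group = country_group,
    pov = NA_real_, phe_pc = exp(sim$log_phe[, 1]),
    gdp_pc = exp(sim$log_gdp[, 1]), gini = sim$gini[, 1],
    population = sim$pop, ext_pc = NA_real_)

  if (cf$missing_rate > 0) {
    keep <- with_seed(substream_seed(cf$seed, "missing"),
                      stats::runif(nrow(df)) >= cf$missing_rate)
    df <- df[keep, , drop = FALSE]
  }
  df <- dplyr::bind_rows(df, lead) |>
    dplyr::arrange(.data$country_id, .data$year)

  panel <- as_pov_panel(df, year_min = min(yrs),
                        source = "synthetic generator")
  snapshots <- tibble::as_tibble(panel) |>
    dplyr::filter(!is.na(.data$pov)) |>
    dplyr::group_by(.data$country_id) |>
    dplyr::slice(which.max(.data$year)) |>
    dplyr::ungroup()
  truth <- list(config = unclass_config(cf),
                alpha = stats::setNames(sim$alpha, ids),
                snapshots = snapshots)
  structure(panel, truth = truth)
}

unclass_config <- function(cf) {
  out <- unclass(cf)
  out[vapply(out, is.function, TRUE)] <- NULL
  out
}

#' Generate a synthetic SPL indicator table with known true costs
#'
#' Draws per-country coverage, yearly per-beneficiary transfer amounts,
#' relative poverty reduction, pre-transfer poverty, and population from
#' uniform (log-uniform for population) ranges, and precomputes the true
#' cost per poverty case averted from the declared formula so distribution
#' summaries can be checked exactly.
#'
#' @param n_countries_by_group Named integer vector of countries per income
#'   group (default 11 low + 22 lower-middle).
#' @param ranges List of `c(min, max)` ranges: `coverage`, `transfer_pc`
#'   (yearly $ per beneficiary), `pov_reduction` (relative fraction),
#'   `pre_transfer_pov`, `log_population`.
#' @param seed Integer seed.
#' @return An `spl_table` (yearly transfers, relative-percent reduction)
#'   with attribute `truth_costs`: named vector of true per-country costs.
#' @export
generate_spl_table <- function(
    n_countries_by_group = c(low = 11, lower_middle = 22),
    ranges = list(coverage = c(0.10, 0.80),
                  transfer_pc = c(20, 400),
                  pov_reduction = c(0.02, 0.50),
                  pre_transfer_pov = c(0.05, 0.60),
                  log_population = log(c(2e6, 2e8))),
    seed = 1L) {
  groups <- names(n_countries_by_group)
  stopifnot(all(groups %in% INCOME_GROUPS),
            all(vapply(ranges, length, 0L) == 2),
            all(vapply(ranges, function(r) r[2] >= r[1], TRUE)))
  grp <- rep(groups, n_countries_by_group)
  n <- length(grp)
  df <- with_seed(substream_seed(seed, "spl"), {
    ru <- function(r) stats::runif(n, r[1], r[2])
    tibble::tibble(
      country_id = sprintf("SPL%03d", seq_len(n)),
      income_group = grp,
      coverage = ru(ranges$coverage),
      transfer_pc = ru(ranges$transfer_pc),
      pov_reduction = ru(ranges$pov_reduction),
      pre_transfer_pov = ru(ranges$pre_transfer_pov),
      population = exp(ru(ranges$log_population)),
      year = 2019L)
  })
  out <- as_spl_table(df, transfer_period = "yearly",
                      reduction_kind = "relative_percent")
  truth <- df$coverage * df$transfer_pc /
    (df$pov_reduction * df$pre_transfer_pov)
  structure(out, truth_costs = stats::setNames(truth, df$country_id))
}
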