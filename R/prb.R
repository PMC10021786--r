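# Poverty reduction benchmarks: convert the fitted spending elasticity into
# a per-country dollar cost of averting one poverty case, and propagate
# estimation uncertainty through Monte-Carlo coefficient draws.

#' Poverty cases averted by a percent increase in health spending
#'
#' With elasticity `beta`, a `pct`-percent increase in per-capita government
#' health spending changes the number of people in poverty by
#' `beta * (pct/100) * p * N`. The value returned is the number of cases
#' *averted*, i.e. positive when `beta < 0`.
#'
#' @param beta Elasticity of the poverty headcount ratio with respect to
#'   lagged spending (dimensionless; negative means spending reduces
#'   poverty).
#' @param p Poverty headcount ratio, in (0, 1].
#' @param N Population (persons, > 0).
#' @param pct Percent increase in spending (default 1).
#' @return Persons lifted out of poverty (negative if `beta > 0`).
#' @export
poverty_cases_averted <- function(beta, p, N, pct = 1) {
  stopifnot(all(p > 0), all(p <= 1), all(N > 0))
  -(beta * pct / 100) * p * N
}

#' Budget increment for a percent increase in health spending
#'
#' @param phe_pc Per-capita government health expenditure ($, > 0).
#' @inheritParams poverty_cases_averted
#' @return Dollars: `(pct/100) * phe_pc * N`.
#' @export
budget_increment <- function(phe_pc, N, pct = 1) {
  stopifnot(all(phe_pc > 0), all(N > 0))
  (pct / 100) * phe_pc * N
}

#' Last-year country snapshots for benchmark computation
#'
#' Takes, for each country, the last year with complete data on poverty and
#' spending — the basis on which per-country benchmarks are computed.
#' Population is required at this stage (it is optional for estimation);
#' countries without it are dropped with a warning.
#'
#' @param rows `estimation_rows`.
#' @return Tibble: `country_id`, `income_group`, `year`, `p` (poverty
#'   headcount ratio), `phe_pc` (current-year spending), `N` (population).
#' @export
country_snapshots <- function(rows) {
  df <- tibble::as_tibble(rows)
  snap <- df |>
    dplyr::group_by(.data$country_id) |>
    dplyr::slice(which.max(.data$year)) |>
    dplyr::ungroup() |>
    dplyr::transmute(.data$country_id, .data$income_group, .data$year,
                     p = .data$pov, .data$phe_pc, N = .data$population)
  no_pop <- is.na(snap$N)
  if (any(no_pop)) {
    warning("dropping ", sum(no_pop),
            " countr", if (sum(no_pop) == 1) "y" else "ies",
            " without population data: ",
            paste(utils::head(snap$country_id[no_pop], 5), collapse = ", "))
    snap <- snap[!no_pop, , drop = FALSE]
  }
  snap
}

#' Per-country poverty reduction benchmark at a given elasticity
#'
#' The benchmark is the budget increment of a marginal spending increase
#' divided by the poverty cases it averts. Population and the size of the
#' percent increase cancel algebraically, leaving `phe_pc / (-beta * p)`
#' dollars per poverty case averted. A non-negative elasticity implies no
#' cases averted, so the benchmark is undefined (`NA`, flagged), never a
#' negative price.
#'
#' @param beta Elasticity (scalar).
#' @param snapshot One-row data frame (or list) with `p`, `phe_pc`, and
#'   optionally `N`; see [country_snapshots()]. May have several rows, in
#'   which case a vector is returned.
#' @param pct Percent spending increase; cancels exactly (kept for the
#'   two-step construction).
#' @return Dollars per poverty case averted (vector over snapshot rows),
#'   `NA` where undefined; attribute `undefined` counts flagged entries.
#' @export
country_prb <- function(beta, snapshot, pct = 1) {
  stopifnot(length(beta) == 1)
  p <- snapshot$p
  phe <- snapshot$phe_pc
  N <- snapshot$N %||% rep(1e6, length(p))
  N[is.na(N)] <- 1e6 # cancels; placeholder keeps the two-step form valid
  if (beta >= 0) {
    out <- rep(NA_real_, length(p))
    attr(out, "undefined") <- length(p)
    return(out)
  }
  out <- budget_increment(phe, N, pct) / poverty_cases_averted(beta, p, N, pct)
  attr(out, "undefined") <- 0L
  out
}

#' Aggregate Monte-Carlo benchmark draws into a group summary
#'
#' For each coefficient draw, computes the unweighted mean benchmark across
#' the group's countries; the median, mean, and 2.5/97.5 percentiles of
#' these iteration-means form the reported estimate and its 95% uncertainty
#' range. Draws with a non-negative elasticity yield an undefined price and
#' are dropped from the summary with a reported count.
#'
#' @param draws Matrix from [sample_coefficients()] (the `log_phe_lag`
#'   column is used) or a numeric vector of elasticity draws.
#' @param snapshots Tibble from [country_snapshots()].
#' @param group `"all"` or an income-group label; rows of `snapshots` are
#'   filtered accordingly.
#' @param beta_point Elasticity point estimate for the per-country point
#'   benchmarks (defaults to the mean of the draws).
#' @param weights `"none"` (unweighted country mean, the default) or
#'   `"population"`.
#' @return A `prb_summary`: list with `group`, `median`, `mean`, `lower_ur`,
#'   `upper_ur` (2.5/97.5 percentiles), `mean_at_point` (benchmark mean at
#'   `beta_point`), `n_iterations`, `n_dropped`, `n_countries`, and
#'   `per_country_point`.
#' @export
aggregate_prb <- function(draws, snapshots, group = "all", beta_point = NULL,
                          weights = c("none", "population")) {
  weights <- match.arg(weights)
  betas <- if (is.matrix(draws)) draws[, "log_phe_lag"] else as.numeric(draws)
  stopifnot(length(betas) >= 1)
  snap <- if (identical(group, "all")) snapshots else
    snapshots[snapshots$income_group == group, , drop = FALSE]
  if (nrow(snap) == 0) stop("no countries in group '", group, "'")
  beta_point <- beta_point %||% mean(betas)

  w <- if (weights == "population") snap$N / sum(snap$N) else
    rep(1 / nrow(snap), nrow(snap))
  ok <- betas < 0
  n_dropped <- sum(!ok)
  if (!any(ok)) stop("all ", length(betas),
                     " coefficient draws are non-negative; ",
                     "benchmark undefined for every iteration")
  # mean_c w_c * phe_c / (-beta p_c) = K / (-beta), computed per iteration
  K <- sum(w * snap$phe_pc / snap$p)
  iter_means <- K / (-betas[ok])

  per_country <- country_prb(beta_point, snap)
  structure(list(
    group = group,
    median = pb_percentile(iter_means, 0.5),
    mean = mean(iter_means),
    lower_ur = pb_percentile(iter_means, 0.025),
    upper_ur = pb_percentile(iter_means, 0.975),
    mean_at_point = if (beta_point < 0) K / (-beta_point) else NA_real_,
    n_iterations = length(betas),
    n_dropped = n_dropped,
    n_countries = nrow(snap),
    weights = weights,
    per_country_point = stats::setNames(as.numeric(per_country),
                                        snap$country_id)
  ), class = "prb_summary")
}

#' @export
print.prb_summary <- function(x, ...) {
  cat(sprintf(
    "PRB [%s]: median $%s (95%% UR $%s-$%s), mean $%s | %d countries, %d draws (%d dropped)\n",
    x$group, format(round(x$median), big.mark = ","),
    format(round(x$lower_ur), big.mark = ","),
    format(round(x$upper_ur), big.mark = ","),
    format(round(x$mean), big.mark = ","),
    x$n_countries, x$n_iterations, x$n_dropped))
  invisible(x)
}

#' Benchmark table across country groupings
#'
#' Builds the grouped benchmark table: one column per country category, with
#' the lower uncertainty bound, median, mean, and upper uncertainty bound of
#' the cost per poverty case averted. By default each group column uses its
#' own group-specific fit and the "all" column the pooled fit
#' (`beta_source = "group_specific"`); `beta_source = "pooled"` applies the
#' pooled fit's draws to every column.
#'
#' @param fits Named list of `fit_result`s: must contain `all` and, for
#'   group-specific sourcing, one entry per income group present.
#' @param snapshots Tibble from [country_snapshots()].
#' @param n Number of Monte-Carlo draws per column (default 1000).
#' @param seed Integer seed (substreamed per group).
#' @param beta_source `"group_specific"` or `"pooled"`.
#' @return Tibble: `group`, `lower_ur`, `median`, `mean`, `upper_ur`,
#'   `n_countries`, `n_dropped`; summaries list in attribute `summaries`.
#' @export
prb_table <- function(fits, snapshots, n = 1000, seed = 1L,
                      beta_source = c("group_specific", "pooled")) {
  beta_source <- match.arg(beta_source)
  if (inherits(fits, "fit_result")) fits <- list(all = fits)
  if (!"all" %in% names(fits)) stop("fits must contain an 'all' entry")
  groups <- c("all", intersect(INCOME_GROUPS,
                               unique(snapshots$income_group)))
  summaries <- lapply(groups, function(g) {
    fit <- if (beta_source == "pooled" || g == "all" || is.null(fits[[g]]))
      fits[["all"]] else fits[[g]]
    draws <- sample_coefficients(fit, n = n,
                                 seed = substream_seed(seed, paste0("prb:", g)))
    aggregate_prb(draws, snapshots, group = g, beta_point = fit$beta)
  })
  names(summaries) <- groups
  out <- dplyr::bind_rows(lapply(summaries, function(s)
    tibble::tibble(group = s$group, lower_ur = s$lower_ur, median = s$median,
                   mean = s$mean, upper_ur = s$upper_ur,
                   n_countries = s$n_countries, n_dropped = s$n_dropped)))
  attr(out, "summaries") <- summaries
  out
}
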