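# Social-protection-and-labor (SPL) program costs per poverty case averted,
# computed from ASPIRE-style country indicators: system coverage, average
# transfer amounts, and the poverty-headcount reduction achieved by SPL
# programs, each at the last year available per country.

#' Default column mapping for an ASPIRE-style CSV extract
#'
#' @param country,income_group,coverage,transfer_pc,pov_reduction,pre_transfer_pov,population,year
#'   File column names for the SPL indicator fields.
#' @return Named character vector mapping logical names to file columns.
#' @export
aspire_schema <- function(country = "country", income_group = "income_group",
                          coverage = "spl_coverage",
                          transfer_pc = "spl_transfer_pc",
                          pov_reduction = "spl_pov_reduction",
                          pre_transfer_pov = "pre_transfer_pov",
                          population = "population", year = "year") {
  c(country = country, income_group = income_group, coverage = coverage,
    transfer_pc = transfer_pc, pov_reduction = pov_reduction,
    pre_transfer_pov = pre_transfer_pov, population = population, year = year)
}

#' Load a per-country SPL indicator table from CSV
#'
#' The transfer-period and reduction-kind declarations are deliberately
#' explicit arguments rather than guesses: indicator extracts vary in
#' whether transfers are daily, monthly, or yearly amounts, and in whether
#' the poverty impact is a relative percent reduction or percentage points.
#'
#' @param path CSV file.
#' @param schema Column mapping from [aspire_schema()].
#' @param transfer_period `"daily"`, `"monthly"`, or `"yearly"` — the period
#'   the per-beneficiary transfer amount refers to.
#' @param reduction_kind `"relative_percent"` (fractional reduction relative
#'   to pre-transfer poverty; requires `pre_transfer_pov`) or
#'   `"percentage_points"` (absolute headcount-ratio change, as a fraction).
#' @return Tibble of class `spl_table` with the logical columns plus the two
#'   declarations as attributes.
#' @export
load_spl <- function(path, schema = aspire_schema(),
                     transfer_period = c("yearly", "monthly", "daily"),
                     reduction_kind = c("relative_percent",
                                        "percentage_points")) {
  transfer_period <- match.arg(transfer_period)
  reduction_kind <- match.arg(reduction_kind)
  if (!file.exists(path)) stop("cannot read SPL file: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8", check.names = FALSE)
  need <- setdiff(names(aspire_schema()), "pre_transfer_pov")
  missing_cols <- need[!schema[need] %in% names(raw)]
  if (length(missing_cols) > 0) {
    stop("mapped column(s) not found in ", path, ": ",
         paste(schema[missing_cols], collapse = ", "))
  }
  df <- tibble::tibble(
    country_id = as.character(raw[[schema[["country"]]]]),
    income_group = normalize_income_group(raw[[schema[["income_group"]]]]),
    coverage = as.numeric(raw[[schema[["coverage"]]]]),
    transfer_pc = as.numeric(raw[[schema[["transfer_pc"]]]]),
    pov_reduction = as.numeric(raw[[schema[["pov_reduction"]]]]),
    pre_transfer_pov = if (schema[["pre_transfer_pov"]] %in% names(raw))
      as.numeric(raw[[schema[["pre_transfer_pov"]]]]) else NA_real_,
    population = as.numeric(raw[[schema[["population"]]]]),
    year = as.integer(raw[[schema[["year"]]]])
  )
  as_spl_table(df, transfer_period = transfer_period,
               reduction_kind = reduction_kind)
}

#' Validate an in-memory SPL indicator table
#'
#' @param df Data frame with the logical SPL columns (see [load_spl()]).
#' @inheritParams load_spl
#' @return Tibble of class `spl_table`.
#' @export
as_spl_table <- function(df, transfer_period = c("yearly", "monthly", "daily"),
                         reduction_kind = c("relative_percent",
                                            "percentage_points")) {
  transfer_period <- match.arg(transfer_period)
  reduction_kind <- match.arg(reduction_kind)
  df <- tibble::as_tibble(df)
  if (!"pre_transfer_pov" %in% names(df)) df$pre_transfer_pov <- NA_real_
  if (any(df$coverage < 0 | df$coverage > 1, na.rm = TRUE)) {
    stop("coverage must lie in [0, 1]")
  }
  if (any(df$transfer_pc < 0, na.rm = TRUE)) stop("negative transfer amount")
  if (any(df$pov_reduction < 0, na.rm = TRUE)) {
    stop("negative poverty reduction")
  }
  if (reduction_kind == "relative_percent" &&
      any(is.na(df$pre_transfer_pov) | df$pre_transfer_pov <= 0 |
          df$pre_transfer_pov > 1)) {
    stop("reduction_kind 'relative_percent' requires pre_transfer_pov in ",
         "(0, 1] for every country")
  }
  structure(df, class = c("spl_table", class(df)),
            transfer_period = transfer_period,
            reduction_kind = reduction_kind)
}

annualization_factor <- function(period) {
  switch(period, daily = 365, monthly = 12, yearly = 1,
         stop("unknown transfer period: ", period))
}

#' Cost per poverty case averted of a country's SPL programs
#'
#' Annual program cost is `coverage * population * annualized transfer per
#' beneficiary`; poverty cases averted are `pov_reduction *
#' pre_transfer_pov * population` (relative reduction, as a fraction) or
#' `pov_reduction * population` (percentage points, as a fraction). The
#' ratio is independent of population. Countries with zero cases averted
#' are flagged undefined (`NA`), never an infinite price.
#'
#' @param spl An `spl_table` (all rows are computed) — see [as_spl_table()].
#' @return Numeric vector of dollars per poverty case averted, named by
#'   country; attribute `undefined` counts flagged entries.
#' @export
spl_cost_per_case <- function(spl) {
  stopifnot(inherits(spl, "spl_table"))
  fac <- annualization_factor(attr(spl, "transfer_period"))
  annual_cost <- spl$coverage * spl$population * spl$transfer_pc * fac
  averted <- if (attr(spl, "reduction_kind") == "relative_percent") {
    spl$pov_reduction * spl$pre_transfer_pov * spl$population
  } else {
    spl$pov_reduction * spl$population
  }
  out <- ifelse(averted > 0, annual_cost / averted, NA_real_)
  names(out) <- spl$country_id
  attr(out, "undefined") <- sum(averted <= 0)
  out
}

#' Cross-country distribution of SPL costs per poverty case averted
#'
#' Per income group and overall: 10th percentile, median, mean, and 90th
#' percentile of the per-country costs (same percentile convention as the
#' benchmark module, [pb_percentile()]). Countries with undefined costs are
#' excluded with a reported count; empty groups are omitted with a warning.
#'
#' @param costs Named cost vector from [spl_cost_per_case()].
#' @param income_groups Character vector aligned with `costs` giving each
#'   country's income group (taken from the `spl_table` it came from).
#' @return Tibble of class `spl_cost_summary`: `group`, `p10`, `median`,
#'   `mean`, `p90`, `n_countries`, `n_undefined`.
#' @export
summarize_spl <- function(costs, income_groups) {
  stopifnot(length(costs) == length(income_groups))
  one <- function(x, label) {
    n_undef <- sum(is.na(x))
    x <- x[!is.na(x)]
    if (length(x) == 0) {
      warning("no defined SPL costs in group '", label, "'; omitted")
      return(NULL)
    }
    tibble::tibble(group = label, p10 = pb_percentile(x, 0.10),
                   median = pb_percentile(x, 0.50), mean = mean(x),
                   p90 = pb_percentile(x, 0.90),
                   n_countries = length(x), n_undefined = n_undef)
  }
  groups <- intersect(INCOME_GROUPS, unique(income_groups))
  out <- dplyr::bind_rows(c(
    list(one(as.numeric(costs), "all")),
    lapply(groups, function(g)
      one(as.numeric(costs)[income_groups == g], g))
  ))
  structure(out, class = c("spl_cost_summary", class(out)))
}
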