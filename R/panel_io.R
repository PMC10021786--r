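# Panel ingestion: read, validate, lag, and filter the country-year panel
# into the estimation-ready rows the log-log fixed-effects model consumes.

#' Default column mapping for a WDI-style CSV extract
#'
#' Maps the package's logical column names to the header names of the input
#' file. Override any entry to load extracts with different headers without
#' code changes, e.g. `wdi_schema(pov = "SI.POV.DDAY")`.
#'
#' @param country,year,income_group,pov,phe_pc,gdp_pc,gini,population,ext_pc
#'   File column names for, respectively: country identifier, calendar year,
#'   income-group label, poverty headcount ratio (proportion, $1.90/day 2011
#'   PPP), per-capita domestic general government health expenditure (constant
#'   2017 international $), per-capita GDP (same units), Gini index (0-100),
#'   population, and (optional) per-capita external health expenditure.
#' @return Named character vector mapping logical names to file columns.
#' @export
wdi_schema <- function(country = "country", year = "year",
                       income_group = "income_group",
                       pov = "pov_headcount_190",
                       phe_pc = "gov_health_exp_pc_ppp2017",
                       gdp_pc = "gdp_pc_ppp2017",
                       gini = "gini", population = "population",
                       ext_pc = "ext_health_exp_pc_ppp2017") {
  c(country = country, year = year, income_group = income_group, pov = pov,
    phe_pc = phe_pc, gdp_pc = gdp_pc, gini = gini, population = population,
    ext_pc = ext_pc)
}

INCOME_GROUPS <- c("low", "lower_middle", "upper_middle")

# drop panel/estimation-row bookkeeping attributes before re-deriving them
strip_row_attrs <- function(df) {
  for (a in c("lag", "spending", "country_years", "metadata", "rejections",
              "year_min", "truth")) {
    attr(df, a) <- NULL
  }
  class(df) <- setdiff(class(df), c("estimation_rows", "pov_panel"))
  df
}

normalize_income_group <- function(x) {
  y <- gsub("[ -]+", "_", tolower(trimws(as.character(x))))
  y[y %in% c("low_income", "li")] <- "low"
  y[y %in% c("lower_middle_income", "lmi", "lowermiddle")] <- "lower_middle"
  y[y %in% c("upper_middle_income", "umi", "uppermiddle")] <- "upper_middle"
  y
}

#' Load and validate a country-year panel from CSV
#'
#' Reads a long-format WDI-style extract (one row per country-year), maps
#' columns through `schema`, validates every record against the model's
#' domain constraints, and returns the retained records as a `pov_panel`.
#' Rejected rows are kept (with machine-readable reason codes) in the
#' `rejections` attribute; duplicate (country, year) keys among otherwise
#' valid rows are a hard error, never silently resolved.
#'
#' Validation rules: spending per capita must be present and positive on
#' every record (a record is either a regressor row or a lag source);
#' poverty, when present, must lie in (0, 1] (logs are taken downstream),
#' GDP per capita positive, Gini in \[0, 100\], population positive, and
#' external spending non-negative. Records with *missing* poverty, GDP,
#' Gini, or population are retained as incomplete — they can still provide
#' lagged spending — and are excluded from estimation rows rather than
#' imputed. The year must be `>= year_min` (default 2000).
#'
#' @param path CSV file (UTF-8, header row).
#' @param schema Column mapping from [wdi_schema()].
#' @param year_min,year_max Inclusive year window; records outside are
#'   rejected with a reason code. `year_max = NULL` leaves the upper bound
#'   open.
#' @return A `pov_panel`: a tibble of validated records with attributes
#'   `rejections` (tibble: row, country, year, reason), `year_min`, and
#'   `metadata`.
#' @seealso [build_estimation_rows()], [panel_rejections()]
#' @export
load_panel <- function(path, schema = wdi_schema(), year_min = 2000,
                       year_max = NULL) {
  if (!file.exists(path)) stop("cannot read panel file: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8", check.names = FALSE)
  required <- setdiff(names(wdi_schema()), "ext_pc")
  missing_cols <- required[!schema[required] %in% names(raw)]
  if (length(missing_cols) > 0) {
    stop("mapped column(s) not found in ", path, ": ",
         paste0(schema[missing_cols], " (", missing_cols, ")", collapse = ", "))
  }
  df <- tibble::tibble(
    country_id = as.character(raw[[schema[["country"]]]]),
    year = suppressWarnings(as.integer(raw[[schema[["year"]]]])),
    income_group = normalize_income_group(raw[[schema[["income_group"]]]]),
    pov = suppressWarnings(as.numeric(raw[[schema[["pov"]]]])),
    phe_pc = suppressWarnings(as.numeric(raw[[schema[["phe_pc"]]]])),
    gdp_pc = suppressWarnings(as.numeric(raw[[schema[["gdp_pc"]]]])),
    gini = suppressWarnings(as.numeric(raw[[schema[["gini"]]]])),
    population = suppressWarnings(as.numeric(raw[[schema[["population"]]]])),
    ext_pc = if (schema[["ext_pc"]] %in% names(raw)) {
      suppressWarnings(as.numeric(raw[[schema[["ext_pc"]]]]))
    } else NA_real_
  )
  as_pov_panel(df, year_min = year_min, year_max = year_max,
               source = path)
}

#' Validate an in-memory data frame as a country-year panel
#'
#' Applies the same record-level validation as [load_panel()] to a data frame
#' already using the package's logical column names (`country_id`, `year`,
#' `income_group`, `pov`, `phe_pc`, `gdp_pc`, `gini`, `population`, and
#' optionally `ext_pc`). Income-group labels are frozen per country at the
#' country's most recent retained year.
#'
#' @param df Data frame of country-year records.
#' @inheritParams load_panel
#' @param source Provenance note stored in the panel metadata.
#' @return A `pov_panel` (see [load_panel()]).
#' @export
as_pov_panel <- function(df, year_min = 2000, year_max = NULL,
                         source = "<in-memory>") {
  df <- tibble::as_tibble(df)
  if (!"ext_pc" %in% names(df)) df$ext_pc <- NA_real_
  needed <- c("country_id", "year", "income_group", "pov", "phe_pc",
              "gdp_pc", "gini", "population")
  miss <- setdiff(needed, names(df))
  if (length(miss) > 0) stop("panel is missing column(s): ",
                             paste(miss, collapse = ", "))
  df$income_group <- normalize_income_group(df$income_group)

  reason <- rep(NA_character_, nrow(df))
  flag <- function(cond, msg) {
    hit <- is.na(reason) & cond
    reason[hit] <<- msg
  }
  flag(is.na(df$country_id) | df$country_id == "", "missing country id")
  flag(is.na(df$year), "missing or unparseable year")
  flag(!is.na(df$year) & df$year < year_min, "year before window start")
  if (!is.null(year_max)) {
    flag(!is.na(df$year) & df$year > year_max, "year after window end")
  }
  flag(!df$income_group %in% INCOME_GROUPS, "unrecognized income group")
  # spending is required on every record (it is either a regressor or a lag
  # source); poverty/GDP/Gini may be missing — such records are retained as
  # incomplete and excluded from estimation rows, never imputed
  flag(is.na(df$phe_pc), "missing government health spending")
  flag(!is.na(df$phe_pc) & df$phe_pc <= 0,
       "nonpositive spending (log undefined)")
  flag(!is.na(df$pov) & df$pov <= 0, "nonpositive poverty (log undefined)")
  flag(!is.na(df$pov) & df$pov > 1, "poverty ratio above 1")
  flag(!is.na(df$gdp_pc) & df$gdp_pc <= 0, "nonpositive GDP (log undefined)")
  flag(!is.na(df$gini) & (df$gini < 0 | df$gini > 100),
       "Gini outside [0, 100]")
  flag(!is.na(df$population) & df$population <= 0, "nonpositive population")
  flag(!is.na(df$ext_pc) & df$ext_pc < 0, "negative external spending")

  rejections <- tibble::tibble(
    row = which(!is.na(reason)),
    country = df$country_id[!is.na(reason)],
    year = df$year[!is.na(reason)],
    reason = reason[!is.na(reason)]
  )
  keep <- df[is.na(reason), , drop = FALSE]

  dup <- duplicated(keep[, c("country_id", "year")])
  if (any(dup)) {
    k <- keep[dup, ][1, ]
    stop("duplicate (country, year) key in panel: (",
         k$country_id, ", ", k$year, ")")
  }

  # freeze income group per country at the most recent retained year
  if (nrow(keep) > 0) {
    keep <- keep |>
      dplyr::group_by(.data$country_id) |>
      dplyr::mutate(
        income_group = .data$income_group[which.max(.data$year)]
      ) |>
      dplyr::ungroup() |>
      dplyr::arrange(.data$country_id, .data$year)
  }

  structure(keep,
            class = c("pov_panel", class(keep)),
            rejections = rejections,
            year_min = year_min,
            metadata = list(source = source, year_min = year_min,
                            year_max = year_max,
                            n_input = nrow(df), n_retained = nrow(keep),
                            n_rejected = nrow(rejections)))
}

#' Rejection log of a validated panel
#'
#' @param panel A `pov_panel`.
#' @return Tibble with columns `row`, `country`, `year`, `reason`.
#' @export
panel_rejections <- function(panel) {
  attr(panel, "rejections") %||%
    tibble::tibble(row = integer(), country = character(),
                   year = integer(), reason = character())
}

#' Build estimation rows with lagged spending
#'
#' Aligns each country-year record with the same country's spending record
#' exactly `lag` years earlier and emits one estimation row per (country,
#' year) whose lag source exists in the validated panel. All transforms are
#' natural logs. Under the `government_plus_external` spending variant the
#' lagged regressor is `ln(phe_pc + ext_pc)` at `t - lag`; lag-source records
#' without external-spending data are then excluded (complete cases).
#'
#' @param panel A `pov_panel`.
#' @param lag Positive integer lag in years (1 by default; 5 is the
#'   long-lag sensitivity). The source must exist at exactly `t - lag`.
#' @param spending `"government"` or `"government_plus_external"`.
#' @return Tibble of class `estimation_rows`: `country_id`, `year`,
#'   `income_group`, `log_pov`, `log_phe_lag`, `log_gdp`, `gini`,
#'   `population`, plus untransformed `pov` and `phe_pc` (current-year
#'   spending, retained for benchmark computation).
#' @export
build_estimation_rows <- function(panel, lag = 1,
                                  spending = c("government",
                                               "government_plus_external")) {
  spending <- match.arg(spending)
  if (!is.numeric(lag) || length(lag) != 1 || lag != round(lag) || lag <= 0) {
    stop("lag must be a positive integer number of years")
  }
  lag <- as.integer(lag)
  df <- strip_row_attrs(tibble::as_tibble(panel))
  if (spending == "government_plus_external" && all(is.na(df$ext_pc))) {
    stop("spending variant 'government_plus_external' requested but the ",
         "panel has no external health expenditure data")
  }
  src <- df |>
    dplyr::transmute(.data$country_id, year = .data$year + lag,
                     phe_src = .data$phe_pc, ext_src = .data$ext_pc)
  rows <- df |>
    dplyr::inner_join(src, by = c("country_id", "year"))
  if (spending == "government_plus_external") {
    rows <- rows |> dplyr::filter(!is.na(.data$ext_src))
    rows$spend_lag <- rows$phe_src + rows$ext_src
  } else {
    rows$spend_lag <- rows$phe_src
  }
  out <- rows |>
    dplyr::filter(!is.na(.data$pov), !is.na(.data$gdp_pc),
                  !is.na(.data$gini)) |>
    dplyr::transmute(
      .data$country_id, .data$year, .data$income_group,
      log_pov = log(.data$pov),
      log_phe_lag = log(.data$spend_lag),
      log_gdp = log(.data$gdp_pc),
      .data$gini, .data$population, .data$pov, .data$phe_pc
    ) |>
    dplyr::arrange(.data$country_id, .data$year)
  structure(out, class = unique(c("estimation_rows", class(out))),
            lag = lag, spending = spending)
}

#' Restrict to countries with enough complete years
#'
#' Keeps countries (optionally within selected income groups) that have at
#' least `min_years` complete estimation rows — the sample-construction rule
#' "at least two complete years since 2000". Idempotent.
#'
#' @param rows `estimation_rows` from [build_estimation_rows()].
#' @param min_years Minimum complete rows per retained country (default 2).
#' @param income_groups Character subset of
#'   `c("low", "lower_middle", "upper_middle")`, or `NULL` for all.
#' @return Filtered `estimation_rows`; per-country year counts in the
#'   `country_years` attribute.
#' @export
filter_complete <- function(rows, min_years = 2, income_groups = NULL) {
  stopifnot(min_years >= 1)
  df <- strip_row_attrs(tibble::as_tibble(rows))
  if (!is.null(income_groups)) {
    bad <- setdiff(income_groups, INCOME_GROUPS)
    if (length(bad) > 0) stop("unknown income group(s): ",
                              paste(bad, collapse = ", "))
    df <- df |> dplyr::filter(.data$income_group %in% income_groups)
  }
  counts <- df |> dplyr::count(.data$country_id, name = "n_years")
  keep_ids <- counts$country_id[counts$n_years >= min_years]
  out <- df |> dplyr::filter(.data$country_id %in% keep_ids)
  if (nrow(out) == 0) {
    stop("no countries satisfy the completeness filter (min_years = ",
         min_years, "); candidate countries: ", nrow(counts),
         ", max complete years: ",
         if (nrow(counts)) max(counts$n_years) else 0)
  }
  structure(out, class = unique(c("estimation_rows", class(out))),
            lag = attr(rows, "lag"), spending = attr(rows, "spending"),
            country_years = counts[counts$n_years >= min_years, ])
}

#' Summary statistics at each country's first or last available year
#'
#' Reproduces the layout of a first-year/last-year summary table: for each
#' income group and overall, the mean poverty headcount, mean lagged
#' spending, mean GDP per capita, and mean Gini, computed on each country's
#' first (or last) available estimation row.
#'
#' @param rows `estimation_rows`.
#' @param at `"first_year"` or `"last_year"`.
#' @return Tibble: `group`, `n_countries`, `mean_pov`, `mean_phe_lag`,
#'   `mean_gdp_pc`, `mean_gini`.
#' @export
summarize_panel <- function(rows, at = c("first_year", "last_year")) {
  at <- match.arg(at)
  df <- tibble::as_tibble(rows)
  if (nrow(df) == 0) stop("no estimation rows to summarize")
  pick <- df |>
    dplyr::group_by(.data$country_id) |>
    dplyr::slice(if (at == "first_year") which.min(.data$year)
                 else which.max(.data$year)) |>
    dplyr::ungroup()
  one <- function(d, label) {
    tibble::tibble(
      group = label,
      n_countries = dplyr::n_distinct(d$country_id),
      mean_pov = mean(d$pov),
      mean_phe_lag = mean(exp(d$log_phe_lag)),
      mean_gdp_pc = mean(exp(d$log_gdp)),
      mean_gini = mean(d$gini)
    )
  }
  groups <- sort(unique(pick$income_group))
  dplyr::bind_rows(
    one(pick, "all"),
    lapply(groups, function(g) one(pick[pick$income_group == g, ], g))
  )
}
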