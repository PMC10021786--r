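# Pipeline orchestration: staged runs (simulate -> fit -> prb -> spl ->
# report) with every artifact stamped by a config hash and seed, so a rerun
# with the same config and inputs reproduces all numeric outputs
# byte-for-byte.

STAGES <- c("simulate", "fit", "prb", "spl", "report")

#' Pipeline run configuration
#'
#' A single structured object controlling all stages; it is serialized in
#' full into the run manifest, so every number in every output table is
#' recomputable from the manifest plus the inputs alone.
#'
#' @param panel_path Panel CSV, or `NULL` to use the synthetic panel written
#'   by the `simulate` stage.
#' @param spl_path SPL indicator CSV, or `NULL` for the synthetic table.
#' @param panel_schema,spl_schema Named lists overriding entries of
#'   [wdi_schema()] / [aspire_schema()].
#' @param year_min,year_max Panel year window.
#' @param lag Spending lag in years.
#' @param spending `"government"` or `"government_plus_external"`.
#' @param min_years Completeness threshold per country.
#' @param income_groups Income groups retained for estimation.
#' @param vcov_kind `"classical"` or `"cluster_by_country"`.
#' @param n_draws Monte-Carlo draws for uncertainty ranges.
#' @param seed Master seed for all stochastic stages.
#' @param beta_source `"group_specific"` or `"pooled"` benchmark sourcing.
#' @param weights `"none"` or `"population"` cross-country aggregation.
#' @param transfer_period,reduction_kind SPL unit declarations (see
#'   [load_spl()]).
#' @param out_dir Output directory for all artifacts.
#' @param synthetic Named list of overrides for [synthetic_panel_config()].
#' @param spl_synthetic Named list of overrides for [generate_spl_table()].
#' @return A `run_config` list.
#' @export
run_config <- function(panel_path = NULL, spl_path = NULL,
                       panel_schema = list(), spl_schema = list(),
                       year_min = 2000, year_max = NULL,
                       lag = 1, spending = "government",
                       min_years = 2,
                       income_groups = c("low", "lower_middle"),
                       vcov_kind = "classical",
                       n_draws = 1000, seed = 1L,
                       beta_source = "group_specific",
                       weights = "none",
                       transfer_period = "yearly",
                       reduction_kind = "relative_percent",
                       out_dir = "povbench_out",
                       synthetic = list(), spl_synthetic = list()) {
  structure(as.list(environment()), class = "run_config")
}

artifact <- function(config, ...) file.path(config$out_dir, ...)

require_artifact <- function(config, file, stage_needed) {
  path <- artifact(config, file)
  if (!file.exists(path)) {
    stop("missing upstream artifact '", file, "': run the '", stage_needed,
         "' stage first (or point the config at an input file)")
  }
  path
}

write_csv_plain <- function(df, path) {
  utils::write.csv(as.data.frame(df), path, row.names = FALSE)
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order:
#' \describe{
#'   \item{simulate}{generate a synthetic panel + SPL table (+ truth JSON).}
#'   \item{fit}{load/validate the panel, build lagged estimation rows,
#'     apply the completeness filter, and fit the specification ladder
#'     (bivariate, fixed effects, fixed effects + controls) plus per-group
#'     fits.}
#'   \item{prb}{Monte-Carlo poverty-reduction benchmarks per group.}
#'   \item{spl}{SPL costs per poverty case averted and their distribution.}
#'   \item{report}{publication-style text tables and figures.}
#' }
#' A stage whose upstream artifact is missing fails with an error naming
#' the stage to run first.
#'
#' @param config A [run_config()].
#' @param stages Subset of `c("simulate", "fit", "prb", "spl", "report")`.
#' @return Invisibly, the run manifest (also written to `manifest.json`).
#' @export
run_pipeline <- function(config = run_config(), stages = STAGES) {
  stopifnot(inherits(config, "run_config"))
  bad <- setdiff(stages, STAGES)
  if (length(bad) > 0) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  stages <- STAGES[STAGES %in% stages]
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_msg <- function(...) message("[povbench] ", ...)

  if ("simulate" %in% stages) {
    syn <- do.call(synthetic_panel_config,
                   utils::modifyList(list(seed = config$seed),
                                     config$synthetic))
    panel <- generate_panel(syn)
    write_csv_plain(panel_as_csv(panel), artifact(config, "panel.csv"))
    spl <- do.call(generate_spl_table,
                   utils::modifyList(list(seed = config$seed),
                                     config$spl_synthetic))
    write_csv_plain(spl_as_csv(spl), artifact(config, "spl.csv"))
    truth <- attr(panel, "truth")
    truth$spl_truth_costs <- as.list(attr(spl, "truth_costs"))
    jsonlite::write_json(truth, artifact(config, "truth.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         force = TRUE)
    log_msg("simulate: ", nrow(panel), " panel records, ", nrow(spl),
            " SPL countries")
  }

  if ("fit" %in% stages) {
    panel_path <- config$panel_path %||%
      require_artifact(config, "panel.csv", "simulate")
    schema <- do.call(wdi_schema, config$panel_schema)
    panel <- load_panel(panel_path, schema = schema,
                        year_min = config$year_min,
                        year_max = config$year_max)
    write_csv_plain(panel_rejections(panel),
                    artifact(config, "rejections.csv"))
    rows <- build_estimation_rows(panel, lag = config$lag,
                                  spending = config$spending)
    rows <- filter_complete(rows, min_years = config$min_years,
                            income_groups = config$income_groups)
    log_msg("fit: ", nrow(rows), " estimation rows, ",
            dplyr::n_distinct(rows$country_id), " countries (",
            nrow(panel_rejections(panel)), " records rejected)")

    ladder <- list(
      bivariate = regression_spec(FALSE, character(), lag = config$lag,
                                  spending = config$spending,
                                  vcov_kind = config$vcov_kind),
      fixed_effects = regression_spec(TRUE, character(), lag = config$lag,
                                      spending = config$spending,
                                      vcov_kind = config$vcov_kind),
      preferred = regression_spec(TRUE, c("log_gdp", "gini"),
                                  lag = config$lag,
                                  spending = config$spending,
                                  vcov_kind = config$vcov_kind)
    )
    fits <- lapply(ladder, function(sp) fit_fixed_effects(rows, sp))
    group_fits <- list(all = fits$preferred)
    for (g in intersect(config$income_groups, unique(rows$income_group))) {
      sp <- regression_spec(TRUE, c("log_gdp", "gini"), lag = config$lag,
                            spending = config$spending, income_groups = g,
                            vcov_kind = config$vcov_kind)
      group_fits[[g]] <- tryCatch(fit_fixed_effects(rows, sp),
                                  error = function(e) {
                                    log_msg("fit: skipping group '", g,
                                            "': ", conditionMessage(e))
                                    NULL
                                  })
    }
    group_fits <- Filter(Negate(is.null), group_fits)
    jsonlite::write_json(
      list(ladder = lapply(fits, fit_to_list),
           groups = lapply(group_fits, fit_to_list)),
      artifact(config, "fits.json"),
      auto_unbox = TRUE, digits = NA, null = "null", force = TRUE)
    write_csv_plain(country_snapshots(rows),
                    artifact(config, "snapshots.csv"))
    write_csv_plain(summarize_panel(rows, "first_year"),
                    artifact(config, "summary_first_year.csv"))
    write_csv_plain(summarize_panel(rows, "last_year"),
                    artifact(config, "summary_last_year.csv"))
  }

  if ("prb" %in% stages) {
    fits_path <- require_artifact(config, "fits.json", "fit")
    snap_path <- require_artifact(config, "snapshots.csv", "fit")
    stored <- jsonlite::read_json(fits_path, simplifyVector = TRUE)
    group_fits <- lapply(stored$groups, fit_from_list)
    snapshots <- tibble::as_tibble(
      utils::read.csv(snap_path, stringsAsFactors = FALSE))
    tab <- prb_table(group_fits, snapshots, n = config$n_draws,
                     seed = config$seed, beta_source = config$beta_source)
    write_csv_plain(tab, artifact(config, "prb_table.csv"))
    summaries <- attr(tab, "summaries")
    per_country <- tibble::tibble(
      country_id = names(summaries$all$per_country_point),
      prb = as.numeric(summaries$all$per_country_point)) |>
      dplyr::left_join(snapshots[, c("country_id", "income_group")],
                       by = "country_id")
    write_csv_plain(per_country, artifact(config, "prb_per_country.csv"))
    log_msg("prb: median all-countries benchmark $",
            format(round(tab$median[tab$group == "all"]), big.mark = ","))
  }

  if ("spl" %in% stages) {
    spl_path <- config$spl_path %||%
      require_artifact(config, "spl.csv", "simulate")
    schema <- do.call(aspire_schema, config$spl_schema)
    spl <- load_spl(spl_path, schema = schema,
                    transfer_period = config$transfer_period,
                    reduction_kind = config$reduction_kind)
    costs <- spl_cost_per_case(spl)
    per_country <- tibble::tibble(country_id = names(costs),
                                  income_group = spl$income_group,
                                  cost_per_case = as.numeric(costs)) |>
      dplyr::arrange(dplyr::desc(.data$cost_per_case))
    write_csv_plain(per_country, artifact(config, "spl_costs.csv"))
    write_csv_plain(summarize_spl(costs, spl$income_group),
                    artifact(config, "spl_summary.csv"))
    log_msg("spl: ", sum(!is.na(costs)), " countries with defined costs (",
            attr(costs, "undefined"), " undefined)")
  }

  if ("report" %in% stages) {
    render_tables_and_figures(config$out_dir)
    log_msg("report: tables and figures written to ", config$out_dir)
  }

  manifest <- list(
    package = "povbench",
    version = as.character(utils::packageVersion("povbench")),
    config = unclass_config(config),
    config_hash = config_hash(unclass_config(config)),
    seed = config$seed,
    stages = stages,
    annualization = list(daily = 365, monthly = 12, yearly = 1),
    percentile_definition = "inclusive linear interpolation (type 7)",
    artifacts = sort(setdiff(list.files(config$out_dir), "manifest.json"))
  )
  jsonlite::write_json(manifest, artifact(config, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(manifest)
}

# panel/spl tibbles -> CSV columns using the default file schemas, so the
# written files round-trip through load_panel()/load_spl()
panel_as_csv <- function(panel) {
  df <- tibble::as_tibble(panel)
  stats::setNames(
    df[, c("country_id", "year", "income_group", "pov", "phe_pc", "gdp_pc",
           "gini", "population", "ext_pc")],
    unname(wdi_schema()[c("country", "year", "income_group", "pov", "phe_pc",
                          "gdp_pc", "gini", "population", "ext_pc")]))
}

spl_as_csv <- function(spl) {
  df <- tibble::as_tibble(spl)
  stats::setNames(
    df[, c("country_id", "income_group", "coverage", "transfer_pc",
           "pov_reduction", "pre_transfer_pov", "population", "year")],
    unname(aspire_schema()[c("country", "income_group", "coverage",
                             "transfer_pc", "pov_reduction",
                             "pre_transfer_pov", "population", "year")]))
}

# rebuild a minimal fit_result from its JSON serialization
fit_from_list <- function(x) {
  coefs <- unlist(x$coefficients)
  V <- as.matrix(x$vcov)
  dimnames(V) <- list(names(coefs), names(coefs))
  spec <- x$spec
  structure(list(coefficients = coefs, beta = unname(coefs["log_phe_lag"]),
                 se = unlist(x$se), vcov = V, r_squared = x$r_squared,
                 df_residual = x$df_residual, n_obs = x$n_obs,
                 n_countries = x$n_countries,
                 spec = structure(spec, class = "regression_spec")),
            class = "fit_result")
}

#' Render publication-style tables and figures from run artifacts
#'
#' Writes, from the artifacts already present in `out_dir`: the first/last
#' year summary table, the regression table (specification ladder and group
#' columns, with significance markers), the benchmark table, and — from the
#' SPL artifacts — a cost-distribution histogram and a sorted per-country
#' bar chart, each as SVG and PNG.
#'
#' @param out_dir Directory holding pipeline artifacts.
#' @param formats Figure formats, subset of `c("svg", "png")`.
#' @return Invisibly, the files written.
#' @export
render_tables_and_figures <- function(out_dir, formats = c("svg", "png")) {
  cfg <- list(out_dir = out_dir)
  class(cfg) <- "run_config"
  written <- character()

  fits_path <- file.path(out_dir, "fits.json")
  if (!file.exists(fits_path)) {
    stop("missing upstream artifact 'fits.json': run the 'fit' stage first")
  }
  stored <- jsonlite::read_json(fits_path, simplifyVector = TRUE)
  ladder <- lapply(stored$ladder, fit_from_list)
  groups <- lapply(stored$groups, fit_from_list)
  tab_lines <- c("Specification ladder", "",
                 regression_table(stats::setNames(ladder,
                                                  c("(1)", "(2)", "(3)"))),
                 "", "Income-group fits (preferred specification)", "",
                 regression_table(groups))
  writeLines(tab_lines, file.path(out_dir, "regression_table.txt"))
  written <- c(written, "regression_table.txt")

  spl_path <- file.path(out_dir, "spl_costs.csv")
  if (file.exists(spl_path)) {
    costs <- utils::read.csv(spl_path, stringsAsFactors = FALSE)
    costs <- costs[!is.na(costs$cost_per_case), , drop = FALSE]
    fig1 <- ggplot2::ggplot(costs, ggplot2::aes(x = .data$cost_per_case)) +
      ggplot2::geom_histogram(bins = 20, fill = "grey35", colour = "white") +
      ggplot2::scale_x_log10(labels = function(x)
        format(x, big.mark = ",", scientific = FALSE)) +
      ggplot2::labs(x = "Cost ($) per poverty case averted (log scale)",
                    y = "Number of countries",
                    title = "Distribution of SPL costs per poverty case averted") +
      ggplot2::theme_minimal()
    costs$country_id <- stats::reorder(costs$country_id,
                                       -costs$cost_per_case)
    fig2 <- ggplot2::ggplot(costs,
                            ggplot2::aes(x = .data$country_id,
                                         y = .data$cost_per_case / 1000)) +
      ggplot2::geom_col(fill = "grey35") +
      ggplot2::labs(x = NULL, y = "Cost per poverty case averted (1,000 $)",
                    title = "Country-specific SPL costs per poverty case averted") +
      ggplot2::theme_minimal() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                         vjust = 0.5,
                                                         size = 6))
    for (fmt in formats) {
      for (nm in c("fig1_cost_distribution", "fig2_cost_by_country")) {
        f <- file.path(out_dir, paste0(nm, ".", fmt))
        if (fmt == "svg") grDevices::svg(f, width = 7, height = 5)
        else grDevices::png(f, width = 7, height = 5, units = "in",
                            res = 150)
        print(if (nm == "fig1_cost_distribution") fig1 else fig2)
        grDevices::dev.off()
        written <- c(written, basename(f))
      }
    }
  }

  prb_path <- file.path(out_dir, "prb_table.csv")
  if (file.exists(prb_path)) {
    prb <- utils::read.csv(prb_path, stringsAsFactors = FALSE)
    fmt_d <- function(x) ifelse(is.na(x), "-",
                                paste0("$", format(round(x), big.mark = ",",
                                                   trim = TRUE)))
    lines <- c("Poverty reduction benchmarks (cost per poverty case averted)",
               "",
               sprintf("%-24s %14s %14s %14s %14s %6s", "Country category",
                       "Lower UR", "Median", "Mean", "Upper UR", "N"),
               vapply(seq_len(nrow(prb)), function(i)
                 sprintf("%-24s %14s %14s %14s %14s %6d", prb$group[i],
                         fmt_d(prb$lower_ur[i]), fmt_d(prb$median[i]),
                         fmt_d(prb$mean[i]), fmt_d(prb$upper_ur[i]),
                         prb$n_countries[i]), ""),
               "", "UR = 2.5-97.5 percentile uncertainty range over draws.")
    writeLines(lines, file.path(out_dir, "prb_table.txt"))
    written <- c(written, "prb_table.txt")
  }
  invisible(written)
}
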