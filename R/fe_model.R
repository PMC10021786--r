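# Log-log country-fixed-effects regression of poverty on lagged health
# spending. The within (demeaning) transformation is implemented directly so
# that classical standard errors carry the fixed-effect degrees-of-freedom
# correction and match the explicit-dummy (LSDV) formulation exactly.

#' Regression specification for the elasticity model
#'
#' The three canonical specifications form a ladder: bivariate pooled OLS
#' (`include_fixed_effects = FALSE, controls = character()`), country fixed
#' effects without controls, and the preferred specification with fixed
#' effects plus log GDP per capita and the Gini index.
#'
#' @param include_fixed_effects Absorb a time-invariant country intercept?
#' @param controls Ordered subset of `c("log_gdp", "gini")`.
#' @param lag Spending lag in years (echoed into results; the lag itself is
#'   applied by [build_estimation_rows()]).
#' @param spending `"government"` or `"government_plus_external"` (echo).
#' @param income_groups Income groups the fit is restricted to, or `NULL`.
#' @param vcov_kind `"classical"` (homoskedastic OLS with fixed-effect
#'   degrees of freedom) or `"cluster_by_country"` (CR1 cluster-robust).
#' @return A `regression_spec` list.
#' @export
regression_spec <- function(include_fixed_effects = TRUE,
                            controls = c("log_gdp", "gini"),
                            lag = 1,
                            spending = "government",
                            income_groups = NULL,
                            vcov_kind = c("classical", "cluster_by_country")) {
  vcov_kind <- match.arg(vcov_kind)
  bad <- setdiff(controls, c("log_gdp", "gini"))
  if (length(bad) > 0) stop("unknown control(s): ", paste(bad, collapse = ", "))
  structure(list(include_fixed_effects = isTRUE(include_fixed_effects),
                 controls = as.character(controls), lag = lag,
                 spending = spending, income_groups = income_groups,
                 vcov_kind = vcov_kind),
            class = "regression_spec")
}

#' Fit the poverty-spending elasticity model
#'
#' Estimates `ln(pov) ~ ln(phe, lagged) + controls` with (optionally) a
#' country fixed effect. Under fixed effects the slopes are obtained by OLS
#' on country-demeaned variables; the residual degrees of freedom subtract
#' one per country, so classical standard errors equal those of the
#' equivalent dummy-variable regression. R-squared is reported for the full
#' model including the country effects (LSDV R-squared). Countries reduced
#' to a single row (which carry no within-country information) are dropped
#' with a warning.
#'
#' @param rows `estimation_rows` from [build_estimation_rows()] /
#'   [filter_complete()].
#' @param spec A [regression_spec()].
#' @return A `fit_result`: list with `coefficients` (named slope vector,
#'   `log_phe_lag` first), `beta` (the elasticity), `se`, `vcov`,
#'   `r_squared`, `sigma2`, `df_residual`, `n_obs`, `n_countries`,
#'   `fixed_effects` (named country intercepts when estimated), `intercept`
#'   (pooled case), and the echoed `spec`.
#' @export
fit_fixed_effects <- function(rows, spec = regression_spec()) {
  stopifnot(inherits(spec, "regression_spec"))
  df <- tibble::as_tibble(rows)
  if (!is.null(spec$income_groups)) {
    df <- df[df$income_group %in% spec$income_groups, , drop = FALSE]
  }
  vars <- c("log_phe_lag", spec$controls)
  df <- df[stats::complete.cases(df[, c("log_pov", vars)]), , drop = FALSE]
  if (nrow(df) == 0) stop("no usable rows for the requested specification")

  if (spec$include_fixed_effects) {
    n_per <- table(df$country_id)
    singletons <- names(n_per)[n_per < 2]
    if (length(singletons) > 0) {
      warning("dropping ", length(singletons),
              " singleton countr", if (length(singletons) == 1) "y" else "ies",
              " under fixed effects: ",
              paste(utils::head(singletons, 5), collapse = ", "),
              if (length(singletons) > 5) ", ..." else "")
      df <- df[!df$country_id %in% singletons, , drop = FALSE]
    }
    if (nrow(df) == 0) stop("no countries with >= 2 rows for fixed effects")
  }

  y <- df$log_pov
  X <- as.matrix(df[, vars, drop = FALSE])
  g <- factor(df$country_id)
  n <- nrow(X)
  G <- nlevels(g)

  if (spec$include_fixed_effects) {
    demean <- function(m) m - rowsum(m, g)[g, , drop = FALSE] /
      as.vector(table(g))[g]
    Xd <- demean(X)
    yd <- demean(cbind(y))[, 1]
    k_fe <- G
  } else {
    Xd <- cbind(`(Intercept)` = 1, X)
    yd <- y
    k_fe <- 0L
  }

  qrX <- qr(Xd)
  if (qrX$rank < ncol(Xd)) {
    est <- qr.coef(qrX, yd)
    offending <- names(est)[is.na(est)] %||% colnames(Xd)[is.na(est)]
    stop("design matrix is rank deficient",
         if (spec$include_fixed_effects) " after the within transformation",
         "; offending column(s): ", paste(offending, collapse = ", "))
  }
  coefs_all <- qr.coef(qrX, yd)
  resid <- yd - as.vector(Xd %*% coefs_all)
  # FE consumes one degree of freedom per country (within-estimator correction)
  df_resid <- n - ncol(Xd) - k_fe
  if (df_resid <= 0) stop("not enough observations for the specification")
  sigma2 <- sum(resid^2) / df_resid
  XtX_inv <- solve(crossprod(Xd))
  dimnames(XtX_inv) <- list(colnames(Xd), colnames(Xd))

  if (spec$vcov_kind == "classical") {
    vcov_all <- sigma2 * XtX_inv
  } else {
    # CR1 cluster-robust by country on the (demeaned) regressors
    meat <- matrix(0, ncol(Xd), ncol(Xd))
    for (lev in levels(g)) {
      idx <- which(g == lev)
      s <- crossprod(Xd[idx, , drop = FALSE], resid[idx])
      meat <- meat + tcrossprod(s)
    }
    adj <- (G / (G - 1)) * ((n - 1) / df_resid)
    vcov_all <- adj * XtX_inv %*% meat %*% XtX_inv
    dimnames(vcov_all) <- list(colnames(Xd), colnames(Xd))
  }

  slope_names <- vars
  coefs <- coefs_all[slope_names]
  vcov_sl <- vcov_all[slope_names, slope_names, drop = FALSE]
  se <- sqrt(diag(vcov_sl))

  if (spec$include_fixed_effects) {
    # country intercepts recovered from group means; LSDV R^2 on raw y
    fe <- as.vector(rowsum(cbind(y - X %*% coefs), g) / as.vector(table(g)))
    names(fe) <- levels(g)
    fitted <- as.vector(X %*% coefs) + fe[as.character(g)]
    intercept <- NA_real_
  } else {
    fe <- NULL
    intercept <- coefs_all[["(Intercept)"]]
    fitted <- as.vector(Xd %*% coefs_all)
  }
  r2 <- 1 - sum((y - fitted)^2) / sum((y - mean(y))^2)

  structure(list(coefficients = coefs, beta = unname(coefs["log_phe_lag"]),
                 se = se, vcov = vcov_sl, r_squared = r2, sigma2 = sigma2,
                 df_residual = df_resid, n_obs = n, n_countries = G,
                 fixed_effects = fe, intercept = intercept, spec = spec),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Log-log poverty elasticity fit",
      if (x$spec$include_fixed_effects) "(country fixed effects)" else
        "(pooled OLS)", "\n")
  tt <- data.frame(estimate = x$coefficients, se = x$se,
                   t = x$coefficients / x$se)
  tt$p <- 2 * stats::pt(-abs(tt$t), df = x$df_residual)
  print(round(tt, 4))
  cat(sprintf("R-squared %.3f | %d obs | %d countries | vcov: %s\n",
              x$r_squared, x$n_obs, x$n_countries, x$spec$vcov_kind))
  invisible(x)
}

#' Serialize a fit to a JSON-ready list
#'
#' @param fit A `fit_result`.
#' @return List of coefficients, standard errors, vcov, diagnostics, and the
#'   echoed specification (suitable for `jsonlite::write_json`).
#' @export
fit_to_list <- function(fit) {
  list(coefficients = as.list(fit$coefficients),
       se = as.list(stats::setNames(fit$se, names(fit$coefficients))),
       vcov = unclass(fit$vcov),
       r_squared = fit$r_squared,
       df_residual = fit$df_residual,
       n_obs = fit$n_obs, n_countries = fit$n_countries,
       spec = unclass(fit$spec))
}

significance_stars <- function(p) {
  ifelse(p < 0.01, "***", ifelse(p < 0.05, "**", ifelse(p < 0.10, "*", "")))
}

#' Render one or more fits as a text regression table
#'
#' Side-by-side specification columns in the conventional journal layout:
#' coefficient with significance markers (`***` p<0.01, `**` p<0.05, `*`
#' p<0.10), standard error in parentheses beneath, then fit statistics.
#'
#' @param fits Named list of `fit_result` objects (names become column
#'   headers).
#' @return Character vector of table lines (print with `cat(..., sep =
#'   "\n")`).
#' @export
regression_table <- function(fits) {
  if (inherits(fits, "fit_result")) fits <- list(fit = fits)
  labels <- c(log_phe_lag = "Log gov. health spending (lagged)",
              log_gdp = "Log GDP per capita", gini = "Gini index")
  all_terms <- unique(unlist(lapply(fits, function(f) names(f$coefficients))))
  header <- c("", names(fits))
  rows <- list(header)
  for (term in all_terms) {
    est_line <- c(labels[[term]] %||% term)
    se_line <- c("")
    for (f in fits) {
      if (term %in% names(f$coefficients)) {
        b <- f$coefficients[[term]]
        s <- f$se[[which(names(f$coefficients) == term)]]
        p <- 2 * stats::pt(-abs(b / s), df = f$df_residual)
        est_line <- c(est_line, sprintf("%.3f%s", b, significance_stars(p)))
        se_line <- c(se_line, sprintf("(%.3f)", s))
      } else {
        est_line <- c(est_line, "")
        se_line <- c(se_line, "")
      }
    }
    rows <- c(rows, list(est_line, se_line))
  }
  rows <- c(rows, list(
    c("Country fixed effects",
      vapply(fits, function(f)
        if (f$spec$include_fixed_effects) "X" else "", "")),
    c("Observations", vapply(fits, function(f) as.character(f$n_obs), "")),
    c("R-squared", vapply(fits, function(f) sprintf("%.2f", f$r_squared), "")),
    c("# countries", vapply(fits, function(f)
      as.character(f$n_countries), ""))
  ))
  widths <- apply(do.call(rbind, rows), 2, function(col) max(nchar(col)))
  lines <- vapply(rows, function(r)
    paste(mapply(formatC, r, width = widths,
                 flag = c("-", rep("", length(r) - 1))), collapse = "  "), "")
  c(lines[1], strrep("-", nchar(lines[1])), lines[-1],
    "Standard errors in parentheses. ***p<0.01 **p<0.05 *p<0.10.")
}

#' Draw slope-coefficient vectors from the fitted sampling distribution
#'
#' Draws i.i.d. multivariate-normal coefficient vectors with mean equal to
#' the fitted slopes and covariance equal to the fit's variance-covariance
#' matrix — the parametric propagation of estimation uncertainty into
#' downstream benchmarks. The full slope vector is sampled and consumers
#' extract the `log_phe_lag` component (marginally identical to sampling the
#' elasticity alone).
#'
#' @param fit A `fit_result`.
#' @param n Number of draws (>= 1).
#' @param seed Integer seed; the caller's RNG state is untouched.
#' @return `n` x `k` matrix of draws, columns named as the coefficients.
#' @export
sample_coefficients <- function(fit, n = 1000, seed = 1L) {
  stopifnot(inherits(fit, "fit_result"), n >= 1)
  V <- (fit$vcov + t(fit$vcov)) / 2
  ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1)) {
    stop("vcov is not positive semi-definite (min eigenvalue ",
         format(min(ev)), ")")
  }
  draws <- with_seed(seed, MASS::mvrnorm(n, mu = fit$coefficients,
                                         Sigma = V, tol = 1e-6))
  if (n == 1) draws <- matrix(draws, nrow = 1,
                              dimnames = list(NULL, names(fit$coefficients)))
  colnames(draws) <- names(fit$coefficients)
  draws
}
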