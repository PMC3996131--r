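# Statistical procedures: the metric-by-radius correlation screen with
# Bonferroni correction, standardized-coefficient OLS, deprivation-tertile
# stratification, and the network-radius sweep.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

cor_cell <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  n <- sum(ok)
  if (n < 3 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
    return(list(n = n, r = NA_real_, p = NA_real_))
  }
  ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
  list(n = n, r = unname(ct$estimate), p = ct$p.value)
}

#' Correlation screen over the metric-by-radius grid
#'
#' Tests every metric at every radius for Pearson correlation with the
#' outcome, over areal units, with pairwise-complete deletion. P-values are
#' Bonferroni-corrected by the number of cells actually tested (80 for the
#' default 16 metrics x 5 radii grid, capped at 1); because testing over
#' multiple scales can also be viewed as a per-metric calibration exercise,
#' the relaxed alternative factor (the number of metrics) is carried in the
#' result as metadata.
#'
#' @param table unit-level table from [aggregate_metrics()]
#' @param metrics metric names (default all 16, [METRIC_NAMES])
#' @param radii radii whose columns to test (default 300-1500 by 300)
#' @param outcome outcome column (default `"cohesion"`)
#' @param continuous logical, used to resolve column names
#' @param bonferroni_factor override the correction factor (default: cells
#'   actually tested)
#' @return object of class `severance_screen`; see [tidy.severance_screen()]
#' @export
pearson_screen <- function(table, metrics = METRIC_NAMES,
                           radii = c(300, 600, 900, 1200, 1500),
                           outcome = "cohesion", continuous = TRUE,
                           bonferroni_factor = NULL) {
  stopifnot(outcome %in% names(table))
  grid <- tidyr::expand_grid(metric = metrics, radius_m = radii)
  grid$column <- metric_column(grid$metric, grid$radius_m, continuous)
  missing_cols <- setdiff(grid$column, names(table))
  if (length(missing_cols)) {
    stop("table lacks metric column(s): ", paste(utils::head(missing_cols, 5),
                                                 collapse = ", "))
  }
  cells <- purrr::map(grid$column, function(cl) cor_cell(table[[cl]], table[[outcome]]))
  grid$n <- vapply(cells, `[[`, numeric(1), "n")
  grid$r <- vapply(cells, `[[`, numeric(1), "r")
  grid$p <- vapply(cells, `[[`, numeric(1), "p")
  n_tested <- sum(!is.na(grid$r))
  factor <- if (is.null(bonferroni_factor)) n_tested else bonferroni_factor
  grid$p_bonferroni <- pmin(1, grid$p * factor)
  best <- grid[!is.na(grid$r), ]
  best <- best[order(-abs(best$r)), ][1, ]
  structure(list(grid = grid, best = best, factor = factor,
                 alt_factor = length(unique(metrics)), outcome = outcome),
            class = "severance_screen")
}

#' @export
print.severance_screen <- function(x, ...) {
  cat("<severance_screen> ", nrow(x$grid), " cells vs '", x$outcome,
      "' (Bonferroni factor ", x$factor, "; relaxed per-metric alternative ",
      x$alt_factor, ")\n", sep = "")
  cat("  best cell: ", x$best$column, "  r = ", round(x$best$r, 3),
      "  p = ", format(x$best$p, digits = 3),
      "  adjusted p = ", format(x$best$p_bonferroni, digits = 3),
      "  (n = ", x$best$n, ")\n", sep = "")
  invisible(x)
}

#' @rdname pearson_screen
#' @param x a `severance_screen`
#' @param ... unused
#' @export
tidy.severance_screen <- function(x, ...) x$grid

#' Standardized-coefficient OLS regression
#'
#' The outcome and all predictors are z-scored by their sample mean and
#' standard deviation (denominator n - 1), so the coefficients are
#' standardized; with a single predictor the coefficient equals the Pearson
#' correlation. By default the 0/1 urban flag is z-scored like any other
#' predictor, so "standardized coefficient" has a single definition across
#' the coefficient table; set `scale_binary = FALSE` to leave binary
#' predictors on their raw 0/1 scale. Listwise deletion; two-sided t tests
#' on n - p - 1 degrees of freedom.
#'
#' @param data data frame of units
#' @param outcome outcome column name
#' @param predictors character vector of predictor column names
#' @param scale_binary z-score binary (two-valued 0/1) predictors too
#'   (default TRUE)
#' @return object of class `severance_ols` with [tidy()] and [glance()]
#'   methods
#' @export
ols_standardized <- function(data, outcome, predictors,
                             scale_binary = TRUE) {
  stopifnot(all(c(outcome, predictors) %in% names(data)))
  df <- data[stats::complete.cases(data[, c(outcome, predictors)]),
             c(outcome, predictors)]
  n <- nrow(df)
  if (n <= length(predictors) + 1) {
    stop("not enough complete observations (n = ", n, ") for ",
         length(predictors), " predictor(s)")
  }
  zscore <- function(v) (v - mean(v)) / stats::sd(v)
  X <- matrix(NA_real_, n, length(predictors),
              dimnames = list(NULL, predictors))
  for (p in predictors) {
    v <- df[[p]]
    if (stats::sd(v) == 0) stop("predictor has zero variance: ", p)
    is_binary <- all(v %in% c(0, 1))
    X[, p] <- if (is_binary && !scale_binary) v else zscore(v)
  }
  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1) {
    dep <- predictors[qrX$pivot[seq_len(ncol(X) + 1) > qrX$rank] - 1]
    stop("exactly collinear predictor(s): ", paste(dep, collapse = ", "))
  }
  y <- zscore(df[[outcome]])
  fit <- stats::lm(y ~ X)
  sm <- summary(fit)
  co <- sm$coefficients[-1, , drop = FALSE]
  coefs <- tibble::tibble(
    term = predictors,
    estimate = unname(co[, 1]),
    std_error = unname(co[, 2]),
    statistic = unname(co[, 3]),
    p_value = unname(co[, 4])
  )
  structure(list(
    coefficients = coefs,
    r_squared = sm$r.squared,
    adj_r_squared = sm$adj.r.squared,
    n = n,
    df_residual = fit$df.residual,
    outcome = outcome,
    predictors = predictors,
    scale_binary = scale_binary
  ), class = "severance_ols")
}

#' @export
print.severance_ols <- function(x, ...) {
  cat("<severance_ols> ", x$outcome, " ~ ", paste(x$predictors, collapse = " + "),
      "   (n = ", x$n, ")\n", sep = "")
  cat("  r2 = ", round(x$r_squared, 3), ", adjusted r2 = ",
      round(x$adj_r_squared, 3), "\n", sep = "")
  print(as.data.frame(x$coefficients), digits = 3)
  invisible(x)
}

#' @rdname ols_standardized
#' @param x a `severance_ols`
#' @param ... unused
#' @export
tidy.severance_ols <- function(x, ...) x$coefficients

#' @rdname ols_standardized
#' @export
glance.severance_ols <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, adj_r_squared = x$adj_r_squared,
                 n = x$n, df_residual = x$df_residual)
}

#' Multivariate model within each tertile of deprivation
#'
#' Units are ranked by deprivation (ties broken by unit id for
#' reproducibility) and split into three equal-size groups; within each
#' tertile the standardized multivariate model
#' `outcome ~ hull + deprivation + urban` is re-fit, with standardization
#' computed within-tertile. Predictors with zero within-tertile variance are
#' dropped and flagged.
#'
#' @param table unit-level table with `unit_id`, `deprivation` and the model
#'   columns
#' @param outcome outcome column (default `"cohesion"`)
#' @param hull_col hull metric column (default `"HullR600c"`)
#' @param predictors full predictor set (default hull, deprivation, urban)
#' @param scale_binary see [ols_standardized()]
#' @return object of class `severance_tertiles`: per-tertile models (tertile
#'   0 = least deprived, 2 = most deprived), boundaries, and a summary table
#' @export
tertile_models <- function(table, outcome = "cohesion", hull_col = "HullR600c",
                           predictors = c(hull_col, "deprivation", "urban"),
                           scale_binary = TRUE) {
  stopifnot(all(c("unit_id", "deprivation") %in% names(table)))
  ord <- order(table$deprivation, table$unit_id)
  n <- nrow(table)
  tertile <- integer(n)
  tertile[ord] <- ceiling(3 * seq_len(n) / n) - 1L  # 0 least .. 2 most deprived
  models <- vector("list", 3)
  dropped <- vector("list", 3)
  bounds <- tibble::tibble(tertile = 0:2, n = NA_integer_,
                           deprivation_min = NA_real_, deprivation_max = NA_real_)
  for (t in 0:2) {
    sub <- table[tertile == t, ]
    bounds$n[t + 1] <- nrow(sub)
    bounds$deprivation_min[t + 1] <- min(sub$deprivation)
    bounds$deprivation_max[t + 1] <- max(sub$deprivation)
    keep <- predictors[vapply(predictors, function(p) {
      v <- sub[[p]][stats::complete.cases(sub[, c(outcome, predictors)])]
      length(v) > 0 && stats::sd(v) > 0
    }, logical(1))]
    dropped[[t + 1]] <- setdiff(predictors, keep)
    models[[t + 1]] <- if (length(keep) &&
                           nrow(sub) > length(keep) + 1) {
      ols_standardized(sub, outcome, keep, scale_binary = scale_binary)
    } else NULL
    if (length(dropped[[t + 1]])) {
      warning("tertile ", t, ": dropped zero-variance predictor(s): ",
              paste(dropped[[t + 1]], collapse = ", "), call. = FALSE)
    }
  }
  structure(list(models = models, tertile = tertile, boundaries = bounds,
                 dropped = dropped, outcome = outcome, predictors = predictors),
            class = "severance_tertiles")
}

#' @rdname tertile_models
#' @param x a `severance_tertiles`
#' @param ... unused
#' @return `tidy()`: one row per tertile x term with estimates and p values,
#'   plus per-tertile `r_squared` and multiple correlation `r`
#' @export
tidy.severance_tertiles <- function(x, ...) {
  purrr::map_dfr(0:2, function(t) {
    m <- x$models[[t + 1]]
    if (is.null(m)) {
      return(tibble::tibble(tertile = t, r_squared = NA_real_, r = NA_real_,
                            term = NA_character_, estimate = NA_real_,
                            p_value = NA_real_))
    }
    dplyr::bind_cols(
      tibble::tibble(tertile = t, r_squared = m$r_squared,
                     r = sqrt(m$r_squared)),
      m$coefficients[, c("term", "estimate", "p_value")]
    )
  })
}

#' @export
print.severance_tertiles <- function(x, ...) {
  cat("<severance_tertiles> ", x$outcome, " ~ ",
      paste(x$predictors, collapse = " + "), ", by deprivation tertile\n", sep = "")
  print(as.data.frame(tidy(x)), digits = 3)
  invisible(x)
}

#' Bivariate correlation of a reach metric across network radii
#'
#' Recomputes the metric at each radius, re-aggregates to units (aggregation
#' and buffer held fixed across radii), and correlates with the outcome,
#' tracing how the association varies with the spatial scale of analysis.
#' `HullR` uses a fast dedicated path; other metrics run the full engine.
#'
#' @param net a `spatial_network`
#' @param units units tibble with `unit_id`, `polygon`
#' @param outcomes tibble keyed by `unit_id` containing the outcome column
#' @param radii positive ascending radii in meters (default 100-1500 by 100)
#' @param metric metric to sweep (default `"HullR"`)
#' @param outcome outcome column (default `"cohesion"`)
#' @param buffer_m aggregation buffer (default 30)
#' @param continuous continuous-space analysis (default TRUE)
#' @param assignment optional precomputed [assign_links()] result
#' @return object of class `severance_sweep`: tibble `radius_m`, `n`, `r`,
#'   `p` plus the peak radius (largest absolute correlation)
#' @export
radius_sweep <- function(net, units, outcomes, radii = seq(100, 1500, by = 100),
                         metric = "HullR", outcome = "cohesion", buffer_m = 30,
                         continuous = TRUE, assignment = NULL) {
  stopifnot(all(radii > 0), !is.unsorted(radii))
  if (is.null(assignment)) assignment <- assign_links(units, net, buffer_m)
  rows <- if (identical(metric, "HullR")) {
    hullr_profile(net, radii, continuous = continuous)
  } else {
    network_metrics(net, radii = radii, continuous = continuous,
                    betweenness = metric %in% c("BtA", "TPBtA", "TPDA"))
  }
  agg <- aggregate_metrics(assignment, rows, outcomes = outcomes,
                           continuous = continuous, units = units)
  curve <- purrr::map_dfr(radii, function(r) {
    cl <- metric_column(metric, r, continuous)
    cc <- cor_cell(agg[[cl]], agg[[outcome]])
    tibble::tibble(radius_m = r, n = cc$n, r = cc$r, p = cc$p)
  })
  peak <- curve$radius_m[which.max(abs(curve$r))]
  structure(list(curve = curve, peak_radius_m = peak, metric = metric,
                 outcome = outcome), class = "severance_sweep")
}

#' @rdname radius_sweep
#' @param x a `severance_sweep`
#' @param ... unused
#' @export
tidy.severance_sweep <- function(x, ...) x$curve

#' @export
print.severance_sweep <- function(x, ...) {
  cat("<severance_sweep> ", x$metric, " vs ", x$outcome, " over ",
      nrow(x$curve), " radii; peak |r| at ", x$peak_radius_m, " m (r = ",
      round(x$curve$r[x$curve$radius_m == x$peak_radius_m], 3), ")\n", sep = "")
  invisible(x)
}
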