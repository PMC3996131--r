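fake_table <- function(n = 60, seed = 5) {
  withr::with_seed(seed, {
    tibble::tibble(
      unit_id = sprintf("u%03d", seq_len(n)),
      HullR600c = stats::rnorm(n, 400, 60),
      deprivation = stats::rnorm(n),
      urban = stats::rbinom(n, 1, 0.5),
      cohesion = stats::rnorm(n)
    )
  })
}

test_that("screen finds an exact linear relationship with r = 1", {
  tb <- fake_table()
  tb$cohesion <- 2 * tb$HullR600c - 3
  sc <- pearson_screen(tb, metrics = "HullR", radii = 600)
  expect_equal(sc$grid$r, 1, tolerance = 1e-12)
  expect_lt(sc$grid$p, 1e-30)
  expect_equal(sc$best$column, "HullR600c")
})

test_that("constant metric columns yield missing r without crashing", {
  tb <- fake_table()
  tb$HullR300c <- 5
  sc <- pearson_screen(tb, metrics = "HullR", radii = c(300, 600))
  expect_true(is.na(sc$grid$r[sc$grid$radius_m == 300]))
  expect_equal(sc$best$radius_m, 600)
  # the constant cell is excluded from the count of tests actually run
  expect_equal(sc$factor, 1)
})

test_that("Bonferroni adjustment is capped at 1 and monotone in raw p", {
  tb <- fake_table(n = 120)
  sc <- pearson_screen(tb, metrics = c("HullR"), radii = 600,
                       bonferroni_factor = 80)
  expect_true(all(sc$grid$p_bonferroni <= 1))
  expect_equal(sc$grid$p_bonferroni, pmin(1, sc$grid$p * 80))
  expect_equal(sc$alt_factor, 1)
})

test_that("single-predictor standardized coefficient equals Pearson r", {
  tb <- fake_table(n = 80, seed = 9)
  fit <- ols_standardized(tb, "cohesion", "HullR600c")
  r <- stats::cor(tb$cohesion, tb$HullR600c)
  expect_equal(fit$coefficients$estimate, r, tolerance = 1e-12)
  expect_equal(fit$r_squared, r^2, tolerance = 1e-12)
  # y = z(x) exactly
  tb$cohesion <- (tb$HullR600c - mean(tb$HullR600c)) / stats::sd(tb$HullR600c)
  fit1 <- suppressWarnings(ols_standardized(tb, "cohesion", "HullR600c"))
  expect_equal(fit1$coefficients$estimate, 1, tolerance = 1e-12)
  expect_equal(fit1$r_squared, 1, tolerance = 1e-12)
})

test_that("regression output is invariant to affine rescaling of inputs", {
  tb <- fake_table(n = 90, seed = 12)
  tb$cohesion <- -0.4 * scale(tb$deprivation)[, 1] +
    0.3 * scale(tb$HullR600c)[, 1] + stats::rnorm(90, 0, 0.8)
  f1 <- ols_standardized(tb, "cohesion", c("deprivation", "HullR600c", "urban"))
  tb2 <- tb
  tb2$HullR600c <- tb2$HullR600c * 3.7 - 1000
  tb2$cohesion <- tb2$cohesion / 5 + 2
  f2 <- ols_standardized(tb2, "cohesion", c("deprivation", "HullR600c", "urban"))
  expect_equal(f2$coefficients$estimate, f1$coefficients$estimate,
               tolerance = 1e-9)
  expect_equal(f2$coefficients$p_value, f1$coefficients$p_value,
               tolerance = 1e-9)
  expect_equal(f2$r_squared, f1$r_squared, tolerance = 1e-9)
})

test_that("t tests use n - p - 1 degrees of freedom and match cor.test", {
  tb <- fake_table(n = 40, seed = 3)
  fit <- ols_standardized(tb, "cohesion", "HullR600c")
  expect_equal(fit$df_residual, 40 - 1 - 1)
  ct <- stats::cor.test(tb$cohesion, tb$HullR600c)
  expect_equal(fit$coefficients$p_value, ct$p.value, tolerance = 1e-12)
})

test_that("exact collinearity raises a named error", {
  tb <- fake_table(n = 50)
  tb$HullR2 <- 2 * tb$HullR600c
  expect_error(ols_standardized(tb, "cohesion",
                                c("HullR600c", "HullR2", "urban")),
               "collinear")
})

test_that("tidy and glance return the coefficient table and fit summary", {
  tb <- fake_table(n = 70, seed = 21)
  fit <- ols_standardized(tb, "cohesion", c("deprivation", "urban"))
  td <- tidy(fit)
  expect_equal(td$term, c("deprivation", "urban"))
  expect_true(all(c("estimate", "std_error", "statistic", "p_value") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$n, 70)
  expect_lte(gl$adj_r_squared, gl$r_squared)
})

test_that("tertile split partitions the units into three equal groups", {
  tb <- fake_table(n = 9, seed = 8)
  tb$deprivation <- c(5, 1, 3, 8, 2, 9, 4, 7, 6)
  tm <- suppressWarnings(tertile_models(tb))
  expect_equal(as.integer(table(tm$tertile)), c(3L, 3L, 3L))
  expect_equal(sort(unique(tm$tertile)), 0:2)
  # the partition respects the deprivation ordering
  expect_lte(tm$boundaries$deprivation_max[1], tm$boundaries$deprivation_min[2])
  expect_lte(tm$boundaries$deprivation_max[2], tm$boundaries$deprivation_min[3])
})

test_that("ties in deprivation are broken by unit id, independent of row order", {
  tb <- fake_table(n = 12, seed = 2)
  tb$deprivation <- rep(1, 12)
  tm1 <- suppressWarnings(tertile_models(tb))
  perm <- withr::with_seed(99, sample(12))
  tm2 <- suppressWarnings(tertile_models(tb[perm, ]))
  expect_equal(as.integer(table(tm1$tertile)), c(4L, 4L, 4L))
  by_unit1 <- tm1$tertile[match(tb$unit_id, tb$unit_id)]
  by_unit2 <- tm2$tertile[match(tb$unit_id, tb$unit_id[perm])]
  expect_equal(by_unit2, by_unit1)
})

test_that("zero-variance predictors are dropped within a tertile with a flag", {
  tb <- fake_table(n = 30, seed = 4)
  tb$urban <- c(rep(0, 10), rep(1, 20))
  tb$deprivation <- sort(tb$deprivation)  # tertile 0 gets urban all 0
  w <- testthat::capture_warnings(tm <- tertile_models(tb))
  expect_true(any(grepl("zero-variance", w)))
  expect_true("urban" %in% tm$dropped[[1]])
  expect_false("urban" %in% tm$models[[1]]$predictors)
})

test_that("a single-radius sweep equals the screen's cell", {
  net <- chain_net(12)
  units <- tibble::tibble(
    unit_id = c("a", "b"),
    polygon = list(list(rect_ring(900, 900, 1600, 1100)),
                   list(rect_ring(1600, 900, 2300, 1100))))
  withr::with_seed(31, {
    outc <- tibble::tibble(unit_id = c("a", "b"),
                           cohesion = stats::rnorm(2))
  })
  # need >= 3 pairs for a p value: use 4 units
  units <- tibble::tibble(
    unit_id = c("a", "b", "c", "d"),
    polygon = list(list(rect_ring(900, 900, 1250, 1100)),
                   list(rect_ring(1250, 900, 1600, 1100)),
                   list(rect_ring(1600, 900, 1950, 1100)),
                   list(rect_ring(1950, 900, 2300, 1100))))
  withr::with_seed(31, {
    outc <- tibble::tibble(unit_id = units$unit_id, cohesion = stats::rnorm(4))
  })
  sw <- radius_sweep(net, units, outc, radii = 600)
  a <- assign_links(units, net, 30)
  rows <- hullr_profile(net, 600)
  agg <- aggregate_metrics(a, rows, outcomes = outc, units = units)
  sc <- pearson_screen(agg, metrics = "HullR", radii = 600)
  expect_equal(sw$curve$r, sc$grid$r, tolerance = 1e-12)
  expect_equal(sw$curve$n, sc$grid$n)
})

test_that("sweep and screen plots build without error", {
  tb <- fake_table(n = 50, seed = 6)
  for (m in METRIC_NAMES) {
    for (r in c(300, 600)) tb[[metric_column(m, r)]] <- stats::rnorm(50)
  }
  sc <- pearson_screen(tb, radii = c(300, 600))
  expect_s3_class(autoplot(sc), "ggplot")
  sw <- structure(list(curve = tibble::tibble(radius_m = c(300, 600),
                                              n = 50, r = c(0.1, 0.3),
                                              p = c(0.5, 0.01)),
                       peak_radius_m = 600, metric = "HullR",
                       outcome = "cohesion"), class = "severance_sweep")
  expect_s3_class(autoplot(sw), "ggplot")
})
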