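# Pipeline orchestration: metrics -> aggregate -> mine -> regress ->
# tertiles -> sweep, with a machine-readable report and a run log.

#' Build a run configuration
#'
#' @param network_path GeoJSON network (ignored when `simulate = TRUE`)
#' @param units_path GeoJSON district polygons
#' @param outcomes_path CSV of unit outcomes
#' @param out_dir output directory (created if needed)
#' @param radii metric radii (m)
#' @param sweep_radii radii for the radius sweep (m)
#' @param continuous continuous-space analysis
#' @param buffer_m aggregation buffer (m)
#' @param bonferroni_factor screen correction factor (NULL: cells tested)
#' @param seed integer seed for all randomness
#' @param simulate generate synthetic inputs instead of reading files
#' @param n_units districts when simulating
#' @param tiles_x,tiles_y borough size (600 m tiles) when simulating
#' @param stages character vector of stages to run, a subset of
#'   `c("metrics", "aggregate", "mine", "regress", "tertiles", "sweep")`
#' @param hull_col hull column for regressions and tertiles
#' @param scale_binary z-score the binary urban flag (see [ols_standardized()])
#' @return a `run_config` list
#' @export
run_config <- function(network_path = NULL, units_path = NULL,
                       outcomes_path = NULL, out_dir = tempfile("severance_run_"),
                       radii = c(300, 600, 900, 1200, 1500),
                       sweep_radii = seq(100, 1500, by = 100),
                       continuous = TRUE, buffer_m = 30,
                       bonferroni_factor = NULL, seed = 1,
                       simulate = is.null(network_path), n_units = 325,
                       tiles_x = 8, tiles_y = 8,
                       stages = c("metrics", "aggregate", "mine", "regress",
                                  "tertiles", "sweep"),
                       hull_col = NULL, scale_binary = TRUE) {
  cfg <- list(network_path = network_path, units_path = units_path,
              outcomes_path = outcomes_path, out_dir = out_dir, radii = radii,
              sweep_radii = sweep_radii, continuous = continuous,
              buffer_m = buffer_m, bonferroni_factor = bonferroni_factor,
              seed = seed, simulate = simulate, n_units = n_units,
              tiles_x = tiles_x, tiles_y = tiles_y,
              stages = stages,
              hull_col = if (is.null(hull_col)) metric_column("HullR", 600, continuous) else hull_col,
              scale_binary = scale_binary)
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from a YAML file
#' @param path YAML file with fields of [run_config()]
#' @return a `run_config`
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

write_run_config <- function(cfg, path) {
  vals <- unclass(cfg)
  vals <- vals[!vapply(vals, is.null, logical(1))]
  yaml::write_yaml(vals, path)
  invisible(path)
}

#' Run the severance analysis pipeline
#'
#' Executes the toggled stages in order; every output is a pure function of
#' the inputs and the seed, so re-running with the same configuration is
#' bit-identical. A stage failure halts the run with the failing stage named;
#' outputs of completed stages are retained in `out_dir`.
#'
#' @param config a [run_config()] (or a path to a YAML config)
#' @return the run report (list of stage results), invisibly; files are
#'   written under `config$out_dir`
#' @export
run_pipeline <- function(config = run_config()) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  logfile <- file.path(config$out_dir, "run.log")
  logmsg <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S "), paste0(...))
    message(line)
    cat(line, "\n", file = logfile, append = TRUE)
  }
  write_run_config(config, file.path(config$out_dir, "run_config.yaml"))
  report <- list(config = config)
  stage <- function(name, expr) {
    if (!(name %in% config$stages || name %in% c("inputs"))) return(NULL)
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # inputs
  if (config$simulate) {
    logmsg("simulating synthetic borough (seed ", config$seed, ", ",
           config$n_units, " districts)")
    net <- gen_network("composite", seed = config$seed,
                       tiles_x = config$tiles_x, tiles_y = config$tiles_y)
    units <- gen_districts(net, config$n_units, seed = config$seed)
    outcomes <- NULL # generated after aggregation (needs HullR)
  } else {
    logmsg("reading network from ", config$network_path)
    net <- read_network_geojson(config$network_path)
    units <- read_units_geojson(config$units_path)
    outcomes <- read_outcomes_csv(config$outcomes_path)
  }
  logmsg("network: ", nrow(net$links), " links, ", nrow(net$nodes), " nodes; ",
         nrow(units), " units")

  metric_rows <- stage("metrics", {
    m <- network_metrics(net, radii = config$radii,
                         continuous = config$continuous)
    logmsg("metrics: ", nrow(m), " link x radius rows; dropped destinations ",
           sum(m$dropped_destinations))
    write_metrics_csv(m, file.path(config$out_dir, "link_metrics.csv"))
    m
  })

  table <- stage("aggregate", {
    assignment <- assign_links(units, net, buffer_m = config$buffer_m)
    agg <- aggregate_metrics(assignment, metric_rows,
                             continuous = config$continuous, units = units)
    if (config$simulate) {
      outcomes <- gen_outcomes(agg, units, seed = config$seed)
      write_units_csv(outcomes, file.path(config$out_dir, "outcomes.csv"))
    }
    tab <- dplyr::left_join(agg, outcomes, by = "unit_id")
    empty <- sum(tab$n_links == 0)
    logmsg("aggregate: ", nrow(tab), " units (", empty, " captured no links)")
    write_units_csv(tab, file.path(config$out_dir, "unit_table.csv"))
    report$assignment <- assignment
    tab
  })
  report$table <- table

  report$screen <- stage("mine", {
    sc <- pearson_screen(table, radii = config$radii,
                         continuous = config$continuous,
                         bonferroni_factor = config$bonferroni_factor)
    logmsg("mine: best cell ", sc$best$column, " r = ", round(sc$best$r, 3),
           " adjusted p = ", format(sc$best$p_bonferroni, digits = 3))
    utils::write.csv(tidy(sc), file.path(config$out_dir, "screen.csv"),
                     row.names = FALSE)
    sc
  })

  report$models <- stage("regress", {
    hull <- config$hull_col
    specs <- list(
      multiple = c("deprivation", hull, "urban"),
      deprivation = "deprivation", hull = hull, urban = "urban"
    )
    names(specs)[3] <- hull
    models <- purrr::map(specs, function(p) {
      ols_standardized(table, "cohesion", p, scale_binary = config$scale_binary)
    })
    summary_tbl <- purrr::map_dfr(names(models), function(nm) {
      dplyr::bind_cols(tibble::tibble(model = nm), glance(models[[nm]]))
    })
    coef_tbl <- tidy(models$multiple)
    logmsg("regress: multiple model r2 = ", round(models$multiple$r_squared, 3))
    utils::write.csv(summary_tbl, file.path(config$out_dir, "model_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(coef_tbl, file.path(config$out_dir, "model_coefficients.csv"),
                     row.names = FALSE)
    models
  })

  report$tertiles <- stage("tertiles", {
    tm <- tertile_models(table, hull_col = config$hull_col,
                         scale_binary = config$scale_binary)
    logmsg("tertiles: HullR coefficient by tertile ",
           paste(round(tidy(tm)$estimate[tidy(tm)$term == config$hull_col], 2),
                 collapse = " / "))
    utils::write.csv(tidy(tm), file.path(config$out_dir, "tertiles.csv"),
                     row.names = FALSE)
    tm
  })

  report$sweep <- stage("sweep", {
    sw <- radius_sweep(net, units, table[, c("unit_id", "cohesion")],
                       radii = config$sweep_radii, buffer_m = config$buffer_m,
                       continuous = config$continuous,
                       assignment = report$assignment)
    logmsg("sweep: peak |r| at ", sw$peak_radius_m, " m")
    utils::write.csv(tidy(sw), file.path(config$out_dir, "sweep.csv"),
                     row.names = FALSE)
    sw
  })

  report$net <- net
  report$units <- units
  logmsg("done; outputs in ", config$out_dir)
  invisible(report)
}
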