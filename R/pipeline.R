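#' Analyse a plate-record table condition by condition
#'
#' Runs the estimation stage over every amino-acid condition of a plate:
#' equilibrium detection on the monoculture and co-culture tracks, the
#' bootstrap equilibrium-fraction estimate where fitness records allow it,
#' and the experimental regime call.
#'
#' @param plate Plate records (see [read_plate()]).
#' @param rel_tol Neutrality band for the regime call.
#' @param od_per_density OD units per unit density.
#' @param n_boot Bootstrap resamples for the equilibrium fraction.
#' @param seed Optional seed for the bootstrap.
#' @return Data frame, one row per condition: `trp_uM`, `label`,
#'   `effect_x`, `effect_y`, estimated densities, the equilibrium-fraction
#'   estimate and its CI (NA where not estimable).
#' @export
analyze_plate <- function(plate, rel_tol = 0.05, od_per_density = 1,
                          n_boot = 500, seed = NULL) {
  conds <- sort(unique(plate$trp_uM))
  rows <- lapply(conds, function(trp) {
    at <- plate[plate$trp_uM == trp, , drop = FALSE]
    mono_x <- at[at$culture_type == "mono_x", , drop = FALSE]
    mono_y <- at[at$culture_type == "mono_y", , drop = FALSE]
    co <- at[at$culture_type == "co", , drop = FALSE]
    reg <- tryCatch(
      classify_experimental_regime(mono_x, mono_y, co, rel_tol = rel_tol,
                                   od_per_density = od_per_density),
      error = function(e) NULL)
    eqf <- tryCatch({
      rec <- day_fitness_records(co)
      b <- equilibrium_fraction_bootstrap(rec, n_boot = n_boot, seed = seed)
      c(b$estimate, b$ci)
    }, error = function(e) c(NA_real_, NA_real_, NA_real_))
    data.frame(
      trp_uM = trp,
      label = if (is.null(reg)) NA_character_ else reg$name,
      effect_x = if (is.null(reg)) NA_character_ else reg$effect_x,
      effect_y = if (is.null(reg)) NA_character_ else reg$effect_y,
      x_co = if (is.null(reg)) NA_real_ else reg$details$x_co,
      y_co = if (is.null(reg)) NA_real_ else reg$details$y_co,
      x_mono = if (is.null(reg)) NA_real_ else reg$details$x_mono,
      y_mono = if (is.null(reg)) NA_real_ else reg$details$y_mono,
      eq_fraction = eqf[1], eq_fraction_lo = eqf[2], eq_fraction_hi = eqf[3])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# stable small hash of a stage name, used to derive per-stage seeds
.stage_seed <- function(base_seed, stage) {
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 1000003
  (as.integer(base_seed) + h) %% 2147483647L
}

.scenarios <- c("bifurcation_scan", "regime_map", "fate_grid",
                "gillespie_ensemble", "invasion_scan", "synthetic_plate",
                "analyze_plate", "end_to_end")

#' Run a named analysis scenario from a config
#'
#' Config-driven entry point tying the stages together. The config (a list,
#' or a path to a YAML/JSON file) names a `scenario`, an optional `out_dir`
#' (default: a timestamped directory under the working directory), a `seed`
#' (fanned out per stage through a stable hash of the stage name, so every
#' stage is independently reproducible), a `params` block passed to
#' [cf_params()], and scenario-specific fields. All outputs are CSV/JSON;
#' a `manifest.json` records the config echo, seed, package version and
#' wall time. On error, partial outputs are removed.
#'
#' Scenarios: `bifurcation_scan` (fields a_min/a_max/a_step),
#' `regime_map` (a grid plus optional `second_param` = "c"/"delta" and
#' `second_values`), `fate_grid` (n_values/f_values/t_end),
#' `gillespie_ensemble` (omega/t_max/n_replicates/initial_counts),
#' `invasion_scan` (a grid), `synthetic_plate` (an [experiment_config()]
#' block under `experiment`), `analyze_plate` (`plate_path`), and
#' `end_to_end` (synthetic plate -> analysis -> comparison with the
#' batch-protocol model prediction; the manifest records the agreement
#' count).
#'
#' @param config A list or a YAML/JSON file path.
#' @return The output directory path, invisibly; scenario outputs and
#'   `manifest.json` inside it.
#' @export
run_scenario <- function(config) {
  t0 <- Sys.time()
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("no such config file: ", config)
    config <- if (grepl("\\.json$", config, ignore.case = TRUE))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  if (is.null(config$scenario) || !config$scenario %in% .scenarios)
    stop("unknown scenario '", config$scenario %||% "<missing>",
         "'; must be one of: ", paste(.scenarios, collapse = ", "))
  out_dir <- config$out_dir %||%
    file.path("runs", paste0(config$scenario, "_",
                             format(t0, "%Y%m%d_%H%M%S")))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed %||% 1L)
  params <- do.call(cf_params, as.list(config$params %||% list()))
  made <- character(0)
  emit <- function(name) { made <<- c(made, file.path(out_dir, name));
                           file.path(out_dir, name) }
  extras <- list()

  ok <- FALSE
  on.exit(if (!ok) unlink(made), add = TRUE)

  grid_of <- function(cfg, lo = 0.01, hi = 1, step = 0.01)
    seq(cfg$a_min %||% lo, cfg$a_max %||% hi, by = cfg$a_step %||% step)

  switch(config$scenario,
    bifurcation_scan = {
      bs <- bifurcation_scan(params, grid_of(config))
      write_bifurcation(bs, emit("bifurcation.csv"), emit("boundaries.json"))
    },
    regime_map = {
      if (is.null(config$second_values)) {
        sc <- regime_scan(params, grid_of(config),
                          rel_tol = config$rel_tol %||% 0.01)
        write_regime_map(attr(sc, "per_a"), emit("regimes.csv"),
                         emit("legend.json"))
      } else {
        m <- regime_map_2d(params, grid_of(config), config$second_values,
                           second_param = config$second_param %||% "c",
                           rel_tol = config$rel_tol %||% 0.01)
        write_regime_map(m, emit("regimes.csv"), emit("legend.json"))
      }
    },
    fate_grid = {
      fg <- fate_grid(params,
                      config$n_values %||% 10^seq(-4, -0.5, length.out = 8),
                      config$f_values %||% 10^seq(-2, 2, length.out = 6),
                      t_end = config$t_end %||% 500)
      utils::write.csv(fg, emit("fate_grid.csv"), row.names = FALSE)
    },
    gillespie_ensemble = {
      es <- gillespie_ensemble(
        params,
        initial_counts = unlist(config$initial_counts %||% c(1000, 1000)),
        omega = config$omega %||% 10000,
        t_max = config$t_max %||% 50,
        n_replicates = config$n_replicates %||% 10,
        seeds = .stage_seed(seed, "gillespie"))
      utils::write.csv(
        data.frame(time = es$time, mean_X = es$mean_X, mean_Y = es$mean_Y,
                   mean_n = es$mean_n, var_n = es$var_n, var_f = es$var_f),
        emit("ensemble_trajectory.csv"), row.names = FALSE)
      jsonlite::write_json(
        list(extinction_fraction = es$extinction_fraction,
             n_replicates = es$n_replicates),
        emit("ensemble_summary.json"), auto_unbox = TRUE, digits = NA)
    },
    invasion_scan = {
      fp <- four_strain_params(params)
      sc <- invasion_scan(fp, grid_of(config, 0.02, 1, 0.07))
      utils::write.csv(sc, emit("invasion.csv"), row.names = FALSE)
    },
    synthetic_plate = {
      cfg <- do.call(experiment_config,
                     c(as.list(config$experiment %||% list()),
                       if (is.null(config$experiment$seed))
                         list(seed = .stage_seed(seed, "plate"))))
      plate <- simulate_plate(cfg, params)
      write_plate(plate, emit("plate.csv"))
    },
    analyze_plate = {
      if (is.null(config$plate_path)) stop("analyze_plate needs plate_path")
      plate <- read_plate(config$plate_path)
      res <- analyze_plate(plate, seed = .stage_seed(seed, "analyze"))
      utils::write.csv(res, emit("analysis.csv"), row.names = FALSE)
      jsonlite::write_json(res, emit("analysis.json"), digits = NA,
                           dataframe = "rows", na = "null")
    },
    end_to_end = {
      cfg <- do.call(experiment_config,
                     c(as.list(config$experiment %||% list()),
                       if (is.null(config$experiment$seed))
                         list(seed = .stage_seed(seed, "plate"))))
      plate <- simulate_plate(cfg, params)
      write_plate(plate, emit("plate.csv"))
      res <- analyze_plate(plate, seed = .stage_seed(seed, "analyze"))
      pred <- vapply(res$trp_uM, function(trp) {
        p <- params; p$a <- conc_to_a(trp, cfg$conc_scale)
        classify_regime_batch(p, cfg$dilution_factor, cfg$t_day,
                              n0 = cfg$n0)$name
      }, "")
      res$predicted <- pred
      res$agree <- !is.na(res$label) & res$label == res$predicted
      utils::write.csv(res, emit("end_to_end.csv"), row.names = FALSE)
      extras$agreement <- list(agree = sum(res$agree),
                               total = nrow(res))
    })

  manifest <- c(list(scenario = config$scenario, seed = seed,
                     config = config,
                     package_version = as.character(
                       utils::packageVersion("crossfeedr")),
                     r_version = R.version.string,
                     wall_time_s = as.numeric(difftime(Sys.time(), t0,
                                                       units = "secs")),
                     outputs = basename(made)),
                extras)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       na = "null")
  ok <- TRUE
  invisible(out_dir)
}
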