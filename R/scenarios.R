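#' The mitigation-scenario matrix
#'
#' Sixteen scenarios: for each environmental half-life class (DT50 = 25
#' days, block A; 1.3 days, block B) the eight combinations of toxicity
#' LR90/LR50/LR25, spray-drift reduction 50 % (90 % only for LR90) and
#' grassy field margins off/on. The baseline ("worst-case") per block is
#' LR90 + 50 % drift reduction + no margins.
#'
#' @return data.frame with columns id, dt50_class, lr_class,
#'   drift_reduction, margins_on, is_baseline
#' @export
build_matrix <- function() {
  rows <- list()
  for (dt in c(25, 1.3)) {
    blk <- if (dt == 25) "A" else "B"
    combos <- rbind(
      expand.grid(lr = "LR90", dr = c(0.5, 0.9), fm = c(FALSE, TRUE),
                  stringsAsFactors = FALSE),
      expand.grid(lr = c("LR50", "LR25"), dr = 0.5, fm = c(FALSE, TRUE),
                  stringsAsFactors = FALSE)
    )
    combos$dt <- dt; combos$blk <- blk
    rows[[blk]] <- combos
  }
  m <- do.call(rbind, rows)
  stopifnot(all(m$dr[m$lr != "LR90"] == 0.5))
  out <- data.frame(
    id = sprintf("%s_%s_DR%d_FM%s", m$blk, m$lr, m$dr * 100,
                 ifelse(m$fm, "ON", "OFF")),
    dt50_class = m$dt,
    lr_class = m$lr,
    drift_reduction = m$dr,
    margins_on = m$fm,
    stringsAsFactors = FALSE
  )
  out$is_baseline <- out$lr_class == "LR90" & out$drift_reduction == 0.5 &
    !out$margins_on
  stopifnot(nrow(out) == 16L, sum(out$is_baseline) == 2L)
  rownames(out) <- NULL
  out
}

#' Experiment configuration
#'
#' The desk-scale default runs a 1 km2 landscape at 2-m cells for 5 years
#' with 3 replicates; the full-scale profile of the original study
#' (10 km x 10 km at 1-m cells, 30 years, 10 replicates) is reachable by
#' overriding `landscape`, `n_years` and `n_replicates` but is
#' long-running. Initial density follows 200 000 super-individuals per
#' 100 km2 (2000 per km2), area-scaled. Replicates share the landscape
#' geometry but redraw beetle placement and rotation starting points.
#'
#' @param landscape a [landscape_config()]
#' @param n_replicates replicate runs per scenario
#' @param n_years simulated years (no burn-in)
#' @param master_seed master seed; per-(scenario, replicate) streams are
#'   derived from it
#' @param endpoint_day day-of-year of the annual census (59 = March 1)
#' @param density_per_km2 initial super-individuals per km2
#' @param margin_fraction,margin_width_m field-margin measure (FM_ON)
#' @param params a [beetle_params()]
#' @param ... overrides stored as-is
#' @return config list, class `experiment_config`
#' @export
experiment_config <- function(landscape = landscape_config(),
                              n_replicates = 3, n_years = 5,
                              master_seed = 1L, endpoint_day = 59,
                              density_per_km2 = 2000,
                              margin_fraction = 0.5, margin_width_m = 4,
                              params = beetle_params(), ...) {
  stopifnot(n_replicates >= 1, n_years >= 1)
  cfg <- list(landscape = landscape, n_replicates = n_replicates,
              n_years = n_years, master_seed = as.integer(master_seed),
              endpoint_day = endpoint_day,
              density_per_km2 = density_per_km2,
              margin_fraction = margin_fraction,
              margin_width_m = margin_width_m,
              params = params, ...)
  class(cfg) <- "experiment_config"
  cfg
}

#' Derive an independent RNG seed for one (scenario, replicate) stream
#'
#' Deterministic mixing of master seed, scenario index and replicate,
#' kept below 2^31 so it is a valid R integer seed. All stochastic
#' operations of a replicate draw from its stream in a fixed order, so
#' runs are bit-reproducible and independent of scenario execution order.
#'
#' @param master master seed
#' @param scenario_idx scenario row number
#' @param replicate replicate number
#' @return integer seed
#' @export
rng_stream_seed <- function(master, scenario_idx, replicate) {
  as.integer((abs(as.numeric(master)) * 7919 + scenario_idx * 104729 +
                replicate * 7) %% 2147483647)
}

#' Simulate one replicate of one scenario
#'
#' Runs the daily agent model over `n_years` on the given (already
#' margin/buffer-prepared) landscape and returns the annual endpoint
#' records plus a daily population log.
#'
#' @param grid prepared `landscape_grid` (buffers and, for FM_ON
#'   scenarios, margins applied)
#' @param scenario one row of [build_matrix()]
#' @param config an [experiment_config()]
#' @param weather weather table covering `n_years`
#' @param replicate replicate number (drives the RNG stream)
#' @param scenario_idx scenario row number (drives the RNG stream)
#' @param rotations,plans,mort_table farming configuration
#' @param keep_daily_log keep the day-by-day population log
#' @return list(endpoints, daily_log)
#' @export
simulate_replicate <- function(grid, scenario, config, weather,
                               replicate = 1L, scenario_idx = 1L,
                               rotations = default_rotations(),
                               plans = default_plans(),
                               mort_table = default_mortality_table(),
                               keep_daily_log = FALSE) {
  set.seed(rng_stream_seed(config$master_seed, scenario_idx, replicate))
  params <- config$params
  product <- pesticide_product(scenario$lr_class, dt50_20 = scenario$dt50_class)
  curve <- drift_curve(reduction = scenario$drift_reduction)

  parcels <- init_rotation_start(grid$parcels)
  pop <- init_population(grid, density_per_km2 = config$density_per_km2,
                         params = params)
  expo <- new_exposure_grid(grid)

  # 5-day running mean temperature for the spring trigger
  tm5 <- stats::filter(weather$temp, rep(1 / 5, 5), sides = 1)
  tm5[is.na(tm5)] <- weather$temp[is.na(tm5)]

  records <- vector("list", config$n_years)
  logs <- if (keep_daily_log) vector("list", config$n_years * 365L) else NULL
  li <- 0L
  for (year in seq_len(config$n_years)) {
    events <- schedule_landscape_year(parcels, grid$farms, year, weather,
                                      rotations, plans)
    events_by_day <- split(events, events$day)
    for (doy in 1:365) {
      d <- (year - 1L) * 365L + doy
      wrow <- weather[d, ]
      if (doy == params$overwinter_doy) {
        pop <- overwinter_mortality(pop, grid, params)$pop
      }
      st <- step_day(pop, grid, expo, events_by_day[[as.character(doy)]],
                     wrow, tm5[d], product, curve, params, mort_table)
      pop <- st$pop; expo <- st$expo
      if (keep_daily_log) {
        li <- li + 1L
        logs[[li]] <- cbind(year = year, st$log)
      }
      if (doy == config$endpoint_day) {
        ep <- measure_endpoints(pop, grid)
        records[[year]] <- cbind(scenario_id = scenario$id,
                                 replicate = replicate, year = year, ep)
      }
    }
    parcels <- advance_rotation(parcels)
  }
  list(endpoints = do.call(rbind, records),
       daily_log = if (keep_daily_log) do.call(rbind, logs[seq_len(li)]) else NULL)
}

#' Run a replicated multi-scenario experiment
#'
#' Builds the landscape once (buffers applied; a second variant with
#' grassy margins for FM_ON scenarios — the two differ only in the margin
#' layer), generates weather, then runs every scenario x replicate with an
#' independent derived RNG stream. Endpoints are summarized per scenario
#' and AOR relative changes are computed against the matching per-DT50
#' baseline. Output tables are written as CSV when `outdir` is given; on a
#' mid-run failure the completed rows are flushed with a failure marker
#' file.
#'
#' @param config an [experiment_config()]
#' @param scenarios rows of [build_matrix()] to run (default: all 16)
#' @param outdir optional output directory for CSV tables
#' @param quiet suppress progress messages
#' @return list(endpoints, summary, aor, scenarios, metrics)
#' @export
run_experiment <- function(config = experiment_config(),
                           scenarios = build_matrix(), outdir = NULL,
                           quiet = FALSE) {
  base <- generate_landscape(config$landscape, seed = config$master_seed)
  grid_off <- add_water_buffers(base)
  grid_on <- add_field_margins(grid_off, config$margin_fraction,
                               config$margin_width_m,
                               seed = config$master_seed + 1L)
  weather <- generate_weather(config$n_years, seed = config$master_seed + 7L)
  metrics <- compute_metrics(grid_off)

  all_eps <- list()
  flush <- function(marker = NULL) {
    if (is.null(outdir)) return(invisible())
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    if (length(all_eps)) {
      utils::write.csv(do.call(rbind, all_eps),
                       file.path(outdir, "endpoints.csv"), row.names = FALSE)
    }
    if (!is.null(marker)) {
      writeLines(marker, file.path(outdir, "FAILED"))
    }
  }
  for (si in seq_len(nrow(scenarios))) {
    sc <- scenarios[si, ]
    grid <- if (sc$margins_on) grid_on else grid_off
    for (rep in seq_len(config$n_replicates)) {
      if (!quiet) {
        message(sprintf("scenario %s replicate %d/%d", sc$id, rep,
                        config$n_replicates))
      }
      res <- tryCatch(
        simulate_replicate(grid, sc, config, weather, replicate = rep,
                           scenario_idx = match(sc$id, build_matrix()$id,
                                                nomatch = si)),
        error = function(e) e)
      if (inherits(res, "error")) {
        flush(marker = sprintf("failed at %s rep %d: %s", sc$id, rep,
                               conditionMessage(res)))
        stop(res)
      }
      all_eps[[length(all_eps) + 1L]] <- res$endpoints
    }
  }
  endpoints <- do.call(rbind, all_eps)
  summary <- summarize_endpoints(endpoints)

  aor <- list()
  for (blk in unique(scenarios$dt50_class)) {
    sub <- scenarios[scenarios$dt50_class == blk, ]
    base_id <- sub$id[sub$is_baseline]
    if (length(base_id) == 1 && base_id %in% summary$scenario_id) {
      s <- summary[summary$scenario_id %in% sub$id, ]
      aor[[as.character(blk)]] <- cbind(dt50_class = blk,
                                        relative_change(s, base_id))
    }
  }
  aor <- if (length(aor)) do.call(rbind, aor) else NULL

  if (!is.null(outdir)) {
    flush()
    utils::write.csv(summary, file.path(outdir, "summary.csv"),
                     row.names = FALSE)
    if (!is.null(aor)) {
      utils::write.csv(aor, file.path(outdir, "aor.csv"), row.names = FALSE)
    }
    utils::write.csv(scenarios, file.path(outdir, "scenarios.csv"),
                     row.names = FALSE)
  }
  list(endpoints = endpoints, summary = summary, aor = aor,
       scenarios = scenarios, metrics = metrics)
}
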