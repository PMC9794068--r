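#' Population endpoints on the annual sampling day
#'
#' Partitions the landscape into square aggregation cells (default
#' 50 m x 50 m; partial cells at the boundary are dropped when the extent
#' is not a multiple) and computes the three endpoints: overall density
#' (adult females per m2 over the whole landscape), Occupancy (proportion
#' of aggregation cells holding at least `threshold` adult females, i.e.
#' at least one super-individual at the default factor 100) and Abundance
#' (mean adult-female density over occupied cells, females per m2).
#' Hibernating adults count: on the March 1 sampling day most of the
#' population sits in its winter quarters.
#'
#' An exact partition identity is asserted on every call: total females in
#' the aggregated region = mass in occupied cells + sub-threshold mass.
#'
#' @param pop a `beetle_pop`
#' @param grid the `landscape_grid`
#' @param agg_size_m aggregation cell side in metres (default 50)
#' @param threshold adult females required for a cell to count as occupied
#' @return one-row data.frame (overall_density, occupancy, abundance,
#'   n_adults)
#' @export
measure_endpoints <- function(pop, grid, agg_size_m = 50, threshold = 100) {
  cells_per_agg <- max(1L, as.integer(round(agg_size_m / grid$cell_size)))
  nax <- grid$nx %/% cells_per_agg
  nay <- grid$ny %/% cells_per_agg
  if (nax < 1L || nay < 1L) stop("measure_endpoints: aggregation cell larger than landscape")

  adults <- pop$stage == STAGE_ADULT
  n_adults <- sum(adults)
  area_m2 <- grid$width_m * grid$height_m
  overall_density <- n_adults * pop$super_factor / area_m2

  if (n_adults == 0L) {
    return(data.frame(overall_density = 0, occupancy = 0, abundance = 0,
                      n_adults = 0L))
  }
  ar <- (pop$row[adults] - 1L) %/% cells_per_agg
  ac <- (pop$col[adults] - 1L) %/% cells_per_agg
  keep <- ar < nay & ac < nax
  counts <- numeric(nax * nay)
  if (any(keep)) {
    bin <- ac[keep] * nay + ar[keep] + 1L
    tab <- tabulate(bin, nbins = nax * nay)
    counts <- tab * pop$super_factor
  }
  occupied <- counts >= threshold
  occupancy <- mean(occupied)
  agg_area_m2 <- (cells_per_agg * grid$cell_size)^2
  abundance <- if (any(occupied)) mean(counts[occupied]) / agg_area_m2 else 0

  # partition identity over the aggregated region
  stopifnot(isTRUE(all.equal(sum(counts),
                             sum(counts[occupied]) + sum(counts[!occupied]))))
  data.frame(overall_density = overall_density, occupancy = occupancy,
             abundance = abundance, n_adults = n_adults)
}

#' Summarize endpoint records over years and replicates
#'
#' Per replicate, endpoints are averaged over years; per scenario, the
#' replicate means are averaged and their coefficient of variation
#' (sample-sd convention, sd/mean) is reported.
#'
#' @param records data.frame with columns scenario_id, replicate, year,
#'   overall_density, occupancy, abundance
#' @return data.frame, one row per scenario x endpoint: mean, cv,
#'   n_replicates
#' @export
summarize_endpoints <- function(records) {
  stopifnot(nrow(records) >= 1)
  dt <- data.table::as.data.table(records)
  long <- data.table::melt(dt,
    id.vars = c("scenario_id", "replicate", "year"),
    measure.vars = c("overall_density", "occupancy", "abundance"),
    variable.name = "endpoint", value.name = "value")
  rep_means <- long[, list(rep_mean = mean(value)),
                    by = c("scenario_id", "endpoint", "replicate")]
  out <- rep_means[, list(
    mean = mean(rep_mean),
    cv = if (.N > 1 && mean(rep_mean) > 0) stats::sd(rep_mean) / mean(rep_mean) else 0,
    sd = if (.N > 1) stats::sd(rep_mean) else 0,
    n_replicates = .N), by = c("scenario_id", "endpoint")]
  as.data.frame(out)
}

#' Relative change of scenario endpoints against a baseline (AOR deltas)
#'
#' For each non-baseline scenario, the percentage change of each endpoint
#' mean relative to the matching baseline:
#' `100 * (x - x_base) / x_base`. Baselines map to zero; a zero baseline
#' value yields `NA`.
#'
#' @param summary output of [summarize_endpoints()]
#' @param baseline_id scenario_id of the baseline ("worst-case") scenario
#' @return data.frame (scenario_id, d_density, d_occupancy, d_abundance),
#'   ready for AOR plotting (x = d_occupancy, y = d_abundance)
#' @export
relative_change <- function(summary, baseline_id) {
  base <- summary[summary$scenario_id == baseline_id, ]
  if (nrow(base) == 0) stop("relative_change: baseline scenario not in summary")
  bval <- stats::setNames(base$mean, as.character(base$endpoint))
  pick <- function(sc, ep) {
    x <- summary$mean[summary$scenario_id == sc & summary$endpoint == ep]
    b <- bval[[ep]]
    if (length(x) == 0 || is.na(b) || b == 0) return(NA_real_)
    100 * (x - b) / b
  }
  ids <- unique(summary$scenario_id)
  data.frame(
    scenario_id = ids,
    d_density = vapply(ids, pick, numeric(1), ep = "overall_density"),
    d_occupancy = vapply(ids, pick, numeric(1), ep = "occupancy"),
    d_abundance = vapply(ids, pick, numeric(1), ep = "abundance"),
    row.names = NULL
  )
}
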