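#' Default configuration for the synthetic landscape generator
#'
#' Desk-scale defaults: a 1 km x 1 km landscape at 2-m cells with about 40
#' fields (mean field size ~2 ha), a farm-type mix dominated by arable and
#' vegetable farming (the systems with insecticide-treated crops), and a
#' modest semi-natural fraction. The full-scale profile used by the original
#' study (10 km x 10 km at 1-m cells, 1200-3700 fields) is reachable by
#' overriding `extent_m`, `cell_size_m` and `n_fields`.
#'
#' @param extent_m landscape extent in metres, length-2 (width, height)
#' @param cell_size_m raster cell size in metres
#' @param n_fields target number of field parcels (realized within +/- 20 %)
#' @param mean_field_size_ha optional consistency target; if given,
#'   `n_fields * mean_field_size_ha` must fit into the cultivated share
#' @param farm_type_mix named probability vector over farm types
#' @param seminatural_fraction,woodland_fraction,builtup_fraction area
#'   fractions assigned to non-field patches (boundary strips between
#'   fields count towards the herbaceous semi-natural allotment and are
#'   omitted when `seminatural_fraction` is 0)
#' @param n_ditches number of water ditches placed along field boundaries
#' @param fields_per_farm mean number of fields per farm unit
#' @return config list, class `landscape_config`
#' @export
landscape_config <- function(extent_m = c(1000, 1000), cell_size_m = 2,
                             n_fields = 40, mean_field_size_ha = NULL,
                             farm_type_mix = c(animal_grazing = 0.20,
                                               arable = 0.30,
                                               arable_vegetable = 0.30,
                                               starch_potato = 0.10,
                                               flower = 0.05,
                                               other = 0.05),
                             seminatural_fraction = 0.07,
                             woodland_fraction = 0.03,
                             builtup_fraction = 0.02,
                             n_ditches = 6,
                             fields_per_farm = 4) {
  if (length(extent_m) == 1L) extent_m <- rep(extent_m, 2L)
  cfg <- list(extent_m = extent_m, cell_size_m = cell_size_m,
              n_fields = n_fields, mean_field_size_ha = mean_field_size_ha,
              farm_type_mix = farm_type_mix,
              seminatural_fraction = seminatural_fraction,
              woodland_fraction = woodland_fraction,
              builtup_fraction = builtup_fraction,
              n_ditches = n_ditches, fields_per_farm = fields_per_farm)
  class(cfg) <- "landscape_config"
  validate_landscape_config(cfg)
  cfg
}

validate_landscape_config <- function(cfg) {
  if (any(cfg$extent_m < 100)) {
    stop("landscape_config: extent must be at least 100 m x 100 m")
  }
  if (cfg$cell_size_m <= 0) stop("landscape_config: cell size must be positive")
  fracs <- cfg$seminatural_fraction + cfg$woodland_fraction + cfg$builtup_fraction
  if (fracs >= 0.9) stop("landscape_config: non-field fractions leave too little farmland")
  if (abs(sum(cfg$farm_type_mix) - 1) > 1e-6) {
    stop("landscape_config: farm_type_mix must sum to 1")
  }
  field_area_ha <- prod(cfg$extent_m) * (1 - fracs) / 1e4
  if (!is.null(cfg$mean_field_size_ha)) {
    if (cfg$n_fields * cfg$mean_field_size_ha > field_area_ha * 1.05) {
      stop("landscape_config: field area demand (n_fields x mean size) exceeds extent")
    }
  }
  if (field_area_ha / cfg$n_fields < 0.02) {
    stop("landscape_config: too many fields for the extent (mean size < 0.02 ha)")
  }
  invisible(cfg)
}

# recursive binary splitting of the landscape rectangle into leaves of
# roughly equal area; rects are (c0, c1, r0, r1) in cell indices
split_rects <- function(nx, ny, n_leaves, min_side = 4L) {
  rects <- list(c(1L, nx, 1L, ny))
  while (length(rects) < n_leaves) {
    areas <- vapply(rects, function(r) (r[2] - r[1] + 1) * (r[4] - r[3] + 1), numeric(1))
    i <- which.max(areas)
    r <- rects[[i]]
    w <- r[2] - r[1] + 1L; h <- r[4] - r[3] + 1L
    if (max(w, h) < 2L * min_side) break   # nothing splittable left
    at <- function(len) {
      lo <- max(min_side, floor(len * 0.35))
      hi <- min(len - min_side, ceiling(len * 0.65))
      if (lo > hi) return(NA_integer_)
      if (lo == hi) lo else sample(lo:hi, 1L)
    }
    if (w >= h) {
      cut <- at(w)
      if (is.na(cut)) break
      a <- c(r[1], r[1] + cut - 1L, r[3], r[4])
      b <- c(r[1] + cut, r[2], r[3], r[4])
    } else {
      cut <- at(h)
      if (is.na(cut)) break
      a <- c(r[1], r[2], r[3], r[3] + cut - 1L)
      b <- c(r[1], r[2], r[3] + cut, r[4])
    }
    rects[[i]] <- a
    rects[[length(rects) + 1L]] <- b
  }
  rects
}

#' Generate a synthetic agricultural landscape
#'
#' Builds a categorical raster landscape of axis-aligned rectangular field
#' parcels (produced by seeded recursive splits), grouped into farm units of
#' distinct types, interspersed with herbaceous and woodland patches,
#' built-up blocks and water ditches running along field boundaries. Fields
#' of animal-grazing farms become managed grassland; all other fields are
#' arable. One-cell grassy boundary strips separate adjacent parcels and
#' provide overwintering habitat.
#'
#' @param config a [landscape_config()] list
#' @param seed integer seed; the build is deterministic for a fixed seed
#' @return a `landscape_grid`: list with `element` and `field_id` raster
#'   matrices (row 1 = southern edge), `parcels` and `farms` tables,
#'   `cell_size`, `nx`, `ny`, `width_m`, `height_m`.
#' @export
generate_landscape <- function(config = landscape_config(), seed = 1L) {
  validate_landscape_config(config)
  set.seed(as.integer(seed))
  cs <- config$cell_size_m
  nx <- as.integer(round(config$extent_m[1] / cs))
  ny <- as.integer(round(config$extent_m[2] / cs))

  fracs <- config$seminatural_fraction + config$woodland_fraction +
    config$builtup_fraction
  n_leaves <- ceiling(config$n_fields / (1 - fracs))
  rects <- split_rects(nx, ny, n_leaves)
  areas <- vapply(rects, function(r) (r[2] - r[1] + 1) * (r[4] - r[3] + 1), numeric(1))
  total <- sum(areas)

  # assign shuffled leaves to non-field classes until their area targets fill
  ord <- sample(length(rects))
  assign_class <- rep("field", length(rects))
  take <- function(avail, frac) {
    got <- 0; taken <- integer(0)
    for (i in avail) {
      if (got >= frac * total) break
      taken <- c(taken, i); got <- got + areas[i]
    }
    taken
  }
  avail <- ord
  bu <- take(avail, config$builtup_fraction)
  avail <- setdiff(avail, bu)
  wl <- take(avail, config$woodland_fraction)
  avail <- setdiff(avail, wl)
  hb <- take(avail, config$seminatural_fraction)
  assign_class[bu] <- "built_up"
  assign_class[wl] <- "woodland"
  assign_class[hb] <- "herbaceous_seminatural"

  field_idx <- which(assign_class == "field")
  n_fields <- length(field_idx)
  if (n_fields == 0L) stop("generate_landscape: configuration produced no fields")

  element <- matrix(element_code("other"), nrow = ny, ncol = nx)
  field_id <- matrix(0L, nrow = ny, ncol = nx)

  for (i in seq_along(rects)) {
    if (assign_class[i] == "field") next
    r <- rects[[i]]
    element[r[3]:r[4], r[1]:r[2]] <- element_code(assign_class[i])
  }

  # farms: chunk parcels in spatial order, draw a type per farm
  frects <- rects[field_idx]
  sp_ord <- order(vapply(frects, `[`, numeric(1), 1),
                  vapply(frects, `[`, numeric(1), 3))
  frects <- frects[sp_ord]
  n_farms <- max(1L, round(n_fields / config$fields_per_farm))
  farm_of <- sort(rep_len(seq_len(n_farms), n_fields))
  farm_types <- sample(names(config$farm_type_mix), n_farms, replace = TRUE,
                       prob = config$farm_type_mix)
  farms <- data.frame(id = seq_len(n_farms), farm_type = farm_types,
                      stringsAsFactors = FALSE)

  strips <- list()   # carved boundary strips, candidates for ditches
  use_strips <- config$seminatural_fraction > 0
  parcels <- vector("list", n_fields)
  for (k in seq_len(n_fields)) {
    r <- frects[[k]]
    c0 <- r[1]; c1 <- r[2]; r0 <- r[3]; r1 <- r[4]
    # carve a 1-cell grassy strip on the low-x / low-y internal edges
    if (use_strips && c0 > 1L) {
      element[r0:r1, c0] <- element_code("herbaceous_seminatural")
      strips[[length(strips) + 1L]] <- cbind(row = r0:r1, col = c0)
      c0 <- c0 + 1L
    }
    if (use_strips && r0 > 1L) {
      element[r0, c0:c1] <- element_code("herbaceous_seminatural")
      strips[[length(strips) + 1L]] <- cbind(row = r0, col = c0:c1)
      r0 <- r0 + 1L
    }
    ftype <- farm_types[farm_of[k]]
    el <- if (ftype == "animal_grazing") "managed_grassland" else "arable_field"
    element[r0:r1, c0:c1] <- element_code(el)
    field_id[r0:r1, c0:c1] <- k
    w_m <- (c1 - c0 + 1L) * cs; h_m <- (r1 - r0 + 1L) * cs
    parcels[[k]] <- data.frame(
      id = k, farm_id = farm_of[k],
      area_ha = w_m * h_m / 1e4,
      perimeter_m = 2 * (w_m + h_m),
      soil_type = NA_character_,
      rotation_index = NA_integer_,
      has_margin = FALSE,
      col0 = c0, col1 = c1, row0 = r0, row1 = r1,
      stringsAsFactors = FALSE)
  }
  parcels <- do.call(rbind, parcels)
  parcels$soil_type <- sample(c("sand", "clay", "peat"), n_fields,
                              replace = TRUE, prob = c(0.5, 0.4, 0.1))

  # ditches: convert a sample of boundary strips to water
  if (config$n_ditches > 0 && length(strips) > 0) {
    pick <- sample(length(strips), min(config$n_ditches, length(strips)))
    for (i in pick) {
      s <- strips[[i]]
      element[s] <- element_code("water")
    }
  }

  grid <- list(element = element, field_id = field_id,
               parcels = parcels, farms = farms,
               cell_size = cs, nx = nx, ny = ny,
               width_m = nx * cs, height_m = ny * cs,
               version = 1L, cache = new.env(parent = emptyenv()))
  class(grid) <- "landscape_grid"
  grid
}

#' @export
print.landscape_grid <- function(x, ...) {
  cat(sprintf("landscape_grid: %.0f m x %.0f m at %g-m cells (%d x %d)\n",
              x$width_m, x$height_m, x$cell_size, x$nx, x$ny))
  cat(sprintf("  %d field parcels on %d farms; mean field size %.2f ha\n",
              nrow(x$parcels), nrow(x$farms), mean(x$parcels$area_ha)))
  tab <- table(element_name(x$element))
  cat("  cover:", paste(sprintf("%s %.1f%%", names(tab),
                                100 * tab / length(x$element)), collapse = ", "),
      "\n")
  invisible(x)
}

# cells of a parcel currently under crop (excludes margins and buffers)
cropped_cells <- function(grid, id) {
  which(grid$field_id == id &
          (grid$element == ELEMENT_TYPES[["arable_field"]] |
             grid$element == ELEMENT_TYPES[["managed_grassland"]]))
}

#' Add grassy field margins to a fraction of parcels
#'
#' Carves an inner ring of `width_m` grassy margin from the cropped area of
#' a seeded random subset of parcels. Margin cells keep the parcel's
#' `field_id` but are excluded from cultivation and spraying, and act as
#' overwintering habitat. Parcels too small to hold the ring are skipped
#' (recorded in the `skipped` attribute). Re-applying with the same
#' fraction is a no-op: only the shortfall to `round(fraction * n_fields)`
#' margined parcels is added.
#'
#' @param grid a `landscape_grid`
#' @param fraction proportion of all parcels that should carry a margin
#' @param width_m margin width in metres (>= one cell)
#' @param seed optional integer seed for the parcel draw
#' @return modified `landscape_grid`
#' @export
add_field_margins <- function(grid, fraction, width_m = 4, seed = NULL) {
  stopifnot(fraction >= 0, fraction <= 1, width_m >= grid$cell_size)
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (fraction == 0) return(grid)
  mw <- max(1L, as.integer(round(width_m / grid$cell_size)))
  p <- grid$parcels
  n_target <- round(fraction * nrow(p))
  n_have <- sum(p$has_margin)
  n_add <- n_target - n_have
  if (n_add <= 0) return(grid)
  fits <- !p$has_margin &
    (p$col1 - p$col0 + 1L) > 2L * mw & (p$row1 - p$row0 + 1L) > 2L * mw
  cand <- which(fits)
  skipped <- integer(0)
  if (length(cand) < n_add) {
    skipped <- which(!p$has_margin & !fits)
    message(sprintf("add_field_margins: %d parcels too small for a %g-m margin, skipped",
                    length(skipped), width_m))
  }
  chosen <- if (length(cand) <= n_add) cand else sort(sample(cand, n_add))
  for (id in chosen) {
    c0 <- p$col0[id]; c1 <- p$col1[id]; r0 <- p$row0[id]; r1 <- p$row1[id]
    ring_rows <- c(r0:(r0 + mw - 1L), (r1 - mw + 1L):r1)
    sub <- grid$element[r0:r1, c0:c1]
    ring <- matrix(FALSE, nrow(sub), ncol(sub))
    ring[seq_len(mw), ] <- TRUE; ring[nrow(ring) - seq_len(mw) + 1L, ] <- TRUE
    ring[, seq_len(mw)] <- TRUE; ring[, ncol(ring) - seq_len(mw) + 1L] <- TRUE
    cropped <- sub == ELEMENT_TYPES[["arable_field"]] |
      sub == ELEMENT_TYPES[["managed_grassland"]]
    sub[ring & cropped] <- ELEMENT_TYPES[["field_margin"]]
    grid$element[r0:r1, c0:c1] <- sub
    grid$parcels$has_margin[id] <- TRUE
  }
  attr(grid, "skipped_margins") <- skipped
  grid$version <- grid$version + 1L
  grid
}

#' Add crop-free buffer strips along water
#'
#' Every cropped field cell 4-adjacent to a water cell becomes a crop-free
#' buffer (one cell wide, i.e. at least the legally required 1 m). Buffer
#' cells keep their `field_id` but are never cultivated or sprayed; their
#' vegetation is reset to fallow at the start of each simulation year.
#' Idempotent: a second application changes nothing.
#'
#' @param grid a `landscape_grid`
#' @return modified `landscape_grid`
#' @export
add_water_buffers <- function(grid) {
  el <- grid$element
  water <- el == ELEMENT_TYPES[["water"]]
  if (!any(water)) return(grid)
  ny <- nrow(el); nx <- ncol(el)
  near_water <- matrix(FALSE, ny, nx)
  near_water[-ny, ] <- near_water[-ny, ] | water[-1, ]
  near_water[-1, ]  <- near_water[-1, ]  | water[-ny, ]
  near_water[, -nx] <- near_water[, -nx] | water[, -1]
  near_water[, -1]  <- near_water[, -1]  | water[, -nx]
  cropped <- el == ELEMENT_TYPES[["arable_field"]] |
    el == ELEMENT_TYPES[["managed_grassland"]]
  conv <- near_water & cropped
  if (any(conv)) {
    grid$element[conv] <- ELEMENT_TYPES[["crop_free_buffer"]]
    grid$version <- grid$version + 1L
  }
  grid
}

#' Landscape and farmland heterogeneity metrics
#'
#' Computes the metric set used to characterize structural and farmland
#' heterogeneity: percentage cover of herbaceous and woodland habitats,
#' Shannon diversity of the six landscape categories (arable land,
#' herbaceous semi-natural, woodland, built-up, water, other), the
#' landscape shape index `0.25 * E / sqrt(A)` (raster edge counting,
#' landscape boundary included), Shannon diversity of farm types weighted
#' by field area, the share of animal farms, field count, mean field size
#' and field-boundary density (sum of parcel perimeters over cultivated
#' area).
#'
#' @param grid a `landscape_grid`
#' @param farms optional farm table (defaults to `grid$farms`)
#' @return named list of metrics, class `heterogeneity_metrics`
#' @export
compute_metrics <- function(grid, farms = grid$farms) {
  el <- grid$element
  cs <- grid$cell_size
  n_cells <- length(el)
  cat <- category_matrix(el)

  share <- table(cat) / n_cells
  shannon <- function(p) {
    p <- p[p > 0]
    -sum(p * log(p))
  }
  landscape_shannon <- shannon(as.numeric(share))

  ny <- nrow(el); nx <- ncol(el)
  horiz <- sum(cat[, -1, drop = FALSE] != cat[, -nx, drop = FALSE])
  vert <- sum(cat[-1, , drop = FALSE] != cat[-ny, , drop = FALSE])
  boundary_edges <- 2L * (nx + ny)
  E_m <- (horiz + vert + boundary_edges) * cs
  A_m2 <- n_cells * cs^2
  lsi <- 0.25 * E_m / sqrt(A_m2)

  p <- grid$parcels
  farm_type_of <- farms$farm_type[match(p$farm_id, farms$id)]
  area_by_type <- tapply(p$area_ha, farm_type_of, sum)
  farming_shannon <- shannon(as.numeric(area_by_type / sum(p$area_ha)))
  share_animal <- 100 * mean(farms$farm_type == "animal_grazing")

  cultivated_m2 <- sum(p$area_ha) * 1e4
  out <- list(
    coverage_herbaceous = 100 * sum(cat == "herbaceous") / n_cells,
    coverage_woodland = 100 * sum(cat == "woodland") / n_cells,
    landscape_shannon = landscape_shannon,
    landscape_shape_index = lsi,
    farming_shannon = farming_shannon,
    share_animal_farms = share_animal,
    n_fields = nrow(p),
    mean_field_size = mean(p$area_ha),
    field_boundary_density = sum(p$perimeter_m) / cultivated_m2
  )
  class(out) <- "heterogeneity_metrics"
  out
}

#' @export
print.heterogeneity_metrics <- function(x, ...) {
  for (nm in names(unclass(x))) cat(sprintf("%-24s %.4g\n", nm, x[[nm]]))
  invisible(x)
}

#' Export landscape rasters and tables
#'
#' Writes the element-type and field-id bands as ESRI ASCII grids and the
#' parcel and farm tables as CSV.
#'
#' @param grid a `landscape_grid`
#' @param dir output directory (created if missing)
#' @export
export_landscape <- function(grid, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_ascii_grid(grid$element, file.path(dir, "element_type.asc"), grid$cell_size)
  write_ascii_grid(grid$field_id, file.path(dir, "field_id.asc"), grid$cell_size)
  utils::write.csv(grid$parcels, file.path(dir, "parcels.csv"), row.names = FALSE)
  utils::write.csv(grid$farms, file.path(dir, "farms.csv"), row.names = FALSE)
  invisible(dir)
}
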