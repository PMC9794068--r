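## Super-individual agent model of Bembidion lampros.
##
## Agents are held as parallel vectors in a plain list (class "beetle_pop"):
## stage (1 egg, 2 larva, 3 pupa, 4 adult female), cell row/col, accumulated
## degree-days, hibernation flag and movement mode. Each agent represents
## `super_factor` real beetles (default 100) and lives or dies as a unit.

STAGE_EGG <- 1L; STAGE_LARVA <- 2L; STAGE_PUPA <- 3L; STAGE_ADULT <- 4L
MODE_FORAGE <- 0L; MODE_AUTUMN <- 1L; MODE_SPRING <- 2L

# habitat classes by element code
HAB_FORBIDDEN <- c("water", "built_up")
HAB_OVERWINTER <- c("herbaceous_seminatural", "field_margin", "woodland")
HAB_BREEDING <- c("arable_field", "managed_grassland", "field_margin",
                  "crop_free_buffer")
HAB_FORAGE <- c("arable_field", "managed_grassland", "herbaceous_seminatural",
                "field_margin", "crop_free_buffer")
HAB_SUITABLE <- c(HAB_FORAGE, "woodland")

#' Default life-history and behaviour parameters
#'
#' Literature-magnitude defaults for a small univoltine spring-breeding
#' carabid; none of these values are printed in the study this package
#' models, so all are configurable and excluded from acceptance anchors.
#' Degree-day requirements (base 5 deg C) give an egg-to-adult time of
#' roughly six weeks in a warm summer; juvenile daily background mortality
#' is high, as is typical for the group. Movement uses a maximum dispersal
#' rate of 14 m per day.
#'
#' @param ... named overrides of any default
#' @return parameter list, class `beetle_params`
#' @export
beetle_params <- function(...) {
  p <- list(
    super_factor = 100L,
    base_temp = 5,                         # deg C, development threshold
    dd_req = c(egg = 90, larva = 250, pupa = 130),   # deg C days per stage
    juv_mort = c(egg = 0.03, larva = 0.06, pupa = 0.03),  # daily background
    fecundity_mean = 0.65,                 # super-eggs per female-agent day
    breeding_window = c(135, 196),         # late spring .. mid summer
    max_step = 14,                         # m/day maximum displacement
    bias_weight = 0.9,                     # strength of directed movement
    p_accept_suboptimal = 0.2,
    move_retries = 4L,
    autumn_start_doy = 274,                # Oct 1
    autumn_daily_p = 0.15,                 # daily chance to start migration
    hibernation_doy = 320,                 # latest onset, hibernate in place
    spring_temp_threshold = 7,             # 5-day running mean, deg C
    spring_doy_window = c(32, 150),
    overwinter_doy = 45,                   # day the winter toll is taken
    overwinter_mort = c(habitat = 0.30, exposed = 0.95),
    density_cap = c(adult = 2L, larva = 2L),  # per 3 m x 3 m window
    expose_hibernating = FALSE
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (!nm %in% names(p)) stop("beetle_params: unknown parameter ", nm)
    p[[nm]] <- dots[[nm]]
  }
  class(p) <- "beetle_params"
  p
}

#' Default farm-operation mortality table
#'
#' Per event type, death probabilities for juveniles (below the soil
#' surface, hit by soil cultivation) and adults (surface-active, hit by
#' mechanical operations). Spray events kill through the exposure pathway,
#' not through this table. Configurable defaults in the magnitude range of
#' published cultivation-mortality estimates.
#'
#' @return named list: per event type `c(juvenile =, adult =)`
#' @export
default_mortality_table <- function() {
  list(
    plough            = c(juvenile = 0.50, adult = 0.30),
    harrow            = c(juvenile = 0.40, adult = 0.25),
    sow               = c(juvenile = 0.20, adult = 0.10),
    fertilize         = c(juvenile = 0.00, adult = 0.00),
    insecticide_spray = c(juvenile = 0.00, adult = 0.00),
    fungicide_spray   = c(juvenile = 0.00, adult = 0.00),
    herbicide_spray   = c(juvenile = 0.00, adult = 0.00),
    harvest           = c(juvenile = 0.05, adult = 0.15),
    grass_cut         = c(juvenile = 0.05, adult = 0.20)
  )
}

# habitat masks are pure functions of the element raster; cached per
# landscape layout version since they are hit several times per day
hab_mask <- function(grid, classes) {
  key <- sprintf("mask_%s_v%d", paste(substr(sort(classes), 1, 2), collapse = ""),
                 grid$version)
  m <- get0(key, envir = grid$cache, inherits = FALSE)
  if (is.null(m)) {
    codes <- element_code(classes)
    m <- matrix(grid$element %in% codes, nrow = grid$ny)
    assign(key, m, envir = grid$cache)
  }
  m
}

cell_index <- function(pop, grid) (pop$col - 1L) * grid$ny + pop$row

# nearest-habitat maps, cached per landscape layout version
nearest_map_cached <- function(grid, what = c("overwinter", "field")) {
  what <- match.arg(what)
  key <- sprintf("near_%s_v%d", what, grid$version)
  m <- get0(key, envir = grid$cache, inherits = FALSE)
  if (is.null(m)) {
    classes <- if (what == "overwinter") HAB_OVERWINTER
               else c("arable_field", "managed_grassland")
    m <- nearest_source_map(hab_mask(grid, classes))$source
    assign(key, m, envir = grid$cache)
  }
  m
}

#' Initialize the beetle population
#'
#' Places adult (female) super-individuals uniformly at random over
#' suitable habitat: fields, field margins, boundary strips and other
#' semi-natural cells. The default density matches 200 000
#' super-individuals per 100 km2, scaled to the landscape area. The run
#' starts in winter, so all adults begin hibernating in place.
#'
#' @param grid a `landscape_grid`
#' @param n_super number of super-individuals; default scales
#'   `density_per_km2` by landscape area
#' @param density_per_km2 super-individuals per km2 (default 2000)
#' @param params a [beetle_params()] list
#' @return population state, class `beetle_pop`
#' @export
init_population <- function(grid, n_super = NULL, density_per_km2 = 2000,
                            params = beetle_params()) {
  if (is.null(n_super)) {
    n_super <- round(density_per_km2 * grid$width_m * grid$height_m / 1e6)
  }
  suitable <- which(hab_mask(grid, HAB_SUITABLE))
  if (length(suitable) == 0L) {
    stop("init_population: landscape has no suitable habitat")
  }
  cells <- suitable[sample.int(length(suitable), n_super, replace = TRUE)]
  pop <- list(
    stage = rep(STAGE_ADULT, n_super),
    row = ((cells - 1L) %% grid$ny) + 1L,
    col = ((cells - 1L) %/% grid$ny) + 1L,
    dd = numeric(n_super),
    hib = rep(TRUE, n_super),
    mode = rep(MODE_FORAGE, n_super),
    super_factor = params$super_factor
  )
  class(pop) <- "beetle_pop"
  pop
}

#' @export
print.beetle_pop <- function(x, ...) {
  tab <- table(factor(x$stage, levels = 1:4,
                      labels = c("egg", "larva", "pupa", "adult")))
  cat(sprintf("beetle_pop: %d super-individuals (x%d beetles); %d hibernating\n",
              length(x$stage), x$super_factor, sum(x$hib)))
  print(tab)
  invisible(x)
}

pop_subset <- function(pop, keep) {
  pop$stage <- pop$stage[keep]; pop$row <- pop$row[keep]
  pop$col <- pop$col[keep]; pop$dd <- pop$dd[keep]
  pop$hib <- pop$hib[keep]; pop$mode <- pop$mode[keep]
  pop
}

pop_append <- function(pop, stage, row, col) {
  n <- length(row)
  if (n == 0L) return(pop)
  pop$stage <- c(pop$stage, rep(stage, n))
  pop$row <- c(pop$row, row); pop$col <- c(pop$col, col)
  pop$dd <- c(pop$dd, numeric(n))
  pop$hib <- c(pop$hib, rep(FALSE, n))
  pop$mode <- c(pop$mode, rep(MODE_FORAGE, n))
  pop
}

#' Daily development of juvenile stages
#'
#' Juveniles accumulate degree-days above the base temperature and
#' transition when their stage requirement is met (counter resets per
#' stage); they also face daily background mortality. Emerging adults
#' start foraging.
#'
#' @param pop a `beetle_pop`
#' @param temp_c today's mean temperature
#' @param params a [beetle_params()]
#' @return list(pop, deaths = number of juveniles lost)
#' @export
develop <- function(pop, temp_c, params = beetle_params()) {
  juv <- pop$stage < STAGE_ADULT
  if (!any(juv)) return(list(pop = pop, deaths = 0L))
  mort_by_stage <- c(params$juv_mort[["egg"]], params$juv_mort[["larva"]],
                     params$juv_mort[["pupa"]], 0)
  dies <- juv & (stats::runif(length(pop$stage)) < mort_by_stage[pop$stage])
  deaths <- sum(dies)
  pop <- pop_subset(pop, !dies)
  juv <- pop$stage < STAGE_ADULT
  inc <- max(0, temp_c - params$base_temp)
  if (inc > 0 && any(juv)) {
    pop$dd[juv] <- pop$dd[juv] + inc
    req <- c(params$dd_req[["egg"]], params$dd_req[["larva"]],
             params$dd_req[["pupa"]], Inf)
    ready <- juv & pop$dd >= req[pop$stage]
    if (any(ready)) {
      pop$stage[ready] <- pop$stage[ready] + 1L
      pop$dd[ready] <- 0
    }
  }
  list(pop = pop, deaths = deaths)
}

#' Daily egg production
#'
#' Non-hibernating adult females inside the breeding window and on
#' breeding habitat (fields and their edges) lay a Poisson-distributed
#' number of eggs into their own cell.
#'
#' @param pop a `beetle_pop`
#' @param grid the `landscape_grid`
#' @param doy day of year
#' @param params a [beetle_params()]
#' @return list(pop, births)
#' @export
reproduce <- function(pop, grid, doy, params = beetle_params()) {
  if (doy < params$breeding_window[1] || doy > params$breeding_window[2] ||
      params$fecundity_mean <= 0) {
    return(list(pop = pop, births = 0L))
  }
  breed_mask <- hab_mask(grid, HAB_BREEDING)
  idx <- cell_index(pop, grid)
  mums <- which(pop$stage == STAGE_ADULT & !pop$hib & breed_mask[idx])
  if (length(mums) == 0L) return(list(pop = pop, births = 0L))
  n_eggs <- stats::rpois(length(mums), params$fecundity_mean)
  tot <- sum(n_eggs)
  if (tot == 0L) return(list(pop = pop, births = 0L))
  rows <- rep.int(pop$row[mums], n_eggs)
  cols <- rep.int(pop$col[mums], n_eggs)
  pop <- pop_append(pop, STAGE_EGG, rows, cols)
  list(pop = pop, births = tot)
}

# truncated cell offsets guarantee displacement <= the drawn distance
offset_cells <- function(dist_m, angle, cs) {
  list(dr = trunc(dist_m * sin(angle) / cs),
       dc = trunc(dist_m * cos(angle) / cs))
}

# directed step of at most max_step metres towards target cells
directed_step <- function(row, col, trow, tcol, max_step, cs) {
  dr <- trow - row; dc <- tcol - col
  dist_m <- sqrt(dr^2 + dc^2) * cs
  reach <- dist_m <= max_step
  s <- ifelse(dist_m > 0, pmin(1, max_step / dist_m), 0)
  list(row = ifelse(reach, trow, row + trunc(dr * s)),
       col = ifelse(reach, tcol, col + trunc(dc * s)))
}

#' Daily movement of adult beetles
#'
#' Non-hibernating adults move up to `max_step` metres per day. Foraging
#' movement is a uniformly random direction and distance, redrawn a few
#' times if the destination is unsuitable; sub-optimal (non-forbidden)
#' habitat is accepted with `p_accept_suboptimal`, water and built-up
#' never. From October 1 an adult starts autumn migration with a daily
#' probability and then heads (with probability `bias_weight` per day,
#' otherwise a random step) towards the nearest overwintering cell, where
#' it hibernates; any still-moving migrant hibernates in place at
#' `hibernation_doy`. Hibernating adults wake when the 5-day running mean
#' temperature passes the spring threshold inside the spring window and
#' head back towards the nearest field.
#'
#' @param pop a `beetle_pop`
#' @param grid the `landscape_grid`
#' @param doy day of year
#' @param temp_mean5 5-day running mean temperature
#' @param params a [beetle_params()]
#' @return updated `beetle_pop`
#' @export
move_beetles <- function(pop, grid, doy, temp_mean5,
                         params = beetle_params()) {
  n <- length(pop$stage)
  if (n == 0L) return(pop)
  cs <- grid$cell_size
  adult <- pop$stage == STAGE_ADULT

  # spring wake-up
  if (doy >= params$spring_doy_window[1] && doy <= params$spring_doy_window[2] &&
      temp_mean5 >= params$spring_temp_threshold) {
    wake <- adult & pop$hib
    if (any(wake)) {
      pop$hib[wake] <- FALSE
      pop$mode[wake] <- MODE_SPRING
    }
  }

  # autumn migration onset
  if (doy >= params$autumn_start_doy) {
    cand <- adult & !pop$hib & pop$mode == MODE_FORAGE
    start <- cand & (stats::runif(n) < params$autumn_daily_p)
    pop$mode[start] <- MODE_AUTUMN
  }

  movers <- which(adult & !pop$hib)
  if (length(movers) == 0L) return(pop)
  if (params$max_step <= 0) return(pop)

  forbid_mask <- hab_mask(grid, HAB_FORBIDDEN)
  forage_mask <- hab_mask(grid, HAB_FORAGE)
  ow_mask <- hab_mask(grid, HAB_OVERWINTER)
  ny <- grid$ny; nx <- grid$nx

  mode <- pop$mode[movers]
  row <- pop$row[movers]; col <- pop$col[movers]
  new_row <- row; new_col <- col

  ## directed movers (autumn towards overwintering habitat, spring towards
  ## fields); with prob (1 - bias_weight) they take a random step instead
  dir_ix <- which(mode != MODE_FORAGE)
  if (length(dir_ix)) {
    biased <- stats::runif(length(dir_ix)) < params$bias_weight
    for (m in c(MODE_AUTUMN, MODE_SPRING)) {
      sel <- dir_ix[biased & mode[dir_ix] == m]
      if (!length(sel)) next
      near <- nearest_map_cached(grid,
                                 if (m == MODE_AUTUMN) "overwinter" else "field")
      tgt <- near[(col[sel] - 1L) * ny + row[sel]]
      trow <- ((tgt - 1L) %% ny) + 1L
      tcol <- ((tgt - 1L) %/% ny) + 1L
      st <- directed_step(row[sel], col[sel], trow, tcol, params$max_step, cs)
      dest <- (pmin(nx, pmax(1L, st$col)) - 1L) * ny + pmin(ny, pmax(1L, st$row))
      ok <- !forbid_mask[dest]
      new_row[sel[ok]] <- pmin(ny, pmax(1L, st$row))[ok]
      new_col[sel[ok]] <- pmin(nx, pmax(1L, st$col))[ok]
    }
    # unbiased directed movers take a plain random step this day
    rand_ix <- dir_ix[!biased]
  } else {
    rand_ix <- integer(0)
  }

  ## random (foraging) steps, with redraws for unsuitable destinations
  rnd <- c(which(mode == MODE_FORAGE), rand_ix)
  if (length(rnd)) {
    unresolved <- rnd
    for (try in seq_len(params$move_retries)) {
      k <- length(unresolved)
      if (k == 0L) break
      ang <- stats::runif(k) * 2 * pi
      dst <- stats::runif(k) * params$max_step
      off <- offset_cells(dst, ang, cs)
      r2 <- pmin(ny, pmax(1L, row[unresolved] + off$dr))
      c2 <- pmin(nx, pmax(1L, col[unresolved] + off$dc))
      dest <- (c2 - 1L) * ny + r2
      # seeking hibernation habitat counts as optimal in autumn mode
      optimal <- ifelse(mode[unresolved] == MODE_AUTUMN,
                        ow_mask[dest] | forage_mask[dest], forage_mask[dest])
      accept <- optimal
      if (try == params$move_retries) {
        sub_ok <- !forbid_mask[dest] & !optimal &
          (stats::runif(k) < params$p_accept_suboptimal)
        accept <- accept | sub_ok
      }
      new_row[unresolved[accept]] <- r2[accept]
      new_col[unresolved[accept]] <- c2[accept]
      unresolved <- unresolved[!accept]
    }
  }

  pop$row[movers] <- new_row
  pop$col[movers] <- new_col

  ## arrivals
  idx <- (new_col - 1L) * ny + new_row
  arr_auto <- mode == MODE_AUTUMN & ow_mask[idx]
  if (any(arr_auto)) {
    sel <- movers[arr_auto]
    pop$hib[sel] <- TRUE
    pop$mode[sel] <- MODE_FORAGE
  }
  field_mask <- hab_mask(grid, c("arable_field", "managed_grassland"))
  arr_spr <- mode == MODE_SPRING & field_mask[idx]
  pop$mode[movers[arr_spr]] <- MODE_FORAGE

  # forced hibernation late in the year, wherever the beetle sits
  if (doy >= params$hibernation_doy) {
    late <- pop$stage == STAGE_ADULT & !pop$hib & pop$mode == MODE_AUTUMN
    pop$hib[late] <- TRUE
    pop$mode[late] <- MODE_FORAGE
  }
  pop
}

# odd window width in cells covering the 3 m x 3 m density square
density_window_halfwidth <- function(cell_size) {
  w <- round(3 / cell_size)
  if (w %% 2L == 0L) w <- w - 1L
  max(0L, (w - 1L) %/% 2L)
}

#' Density-dependent removal (intraspecific predation)
#'
#' Enforces the cap of at most 2 adults and 2 larvae within the 3 m x 3 m
#' window centred on any remaining agent. At 1-m cells the window is the
#' exact 3 x 3 cell square; at coarser desk-scale cells the physical
#' window rounds to a single cell and the cap is enforced per cell.
#' Excess agents are removed uniformly at random (processing order is
#' randomized). Hibernating adults aggregate naturally and are exempt.
#'
#' @param pop a `beetle_pop`
#' @param grid the `landscape_grid`
#' @param params a [beetle_params()]
#' @return list(pop, removals)
#' @export
density_dependence <- function(pop, grid, params = beetle_params()) {
  h <- density_window_halfwidth(grid$cell_size)
  caps <- params$density_cap
  removals <- 0L
  drop <- logical(length(pop$stage))
  for (cls in c("adult", "larva")) {
    stage <- if (cls == "adult") STAGE_ADULT else STAGE_LARVA
    sel <- which(pop$stage == stage & !(pop$hib & stage == STAGE_ADULT))
    if (length(sel) <= caps[[cls]]) next
    ord <- sel[sample.int(length(sel))]
    if (h == 0L) {
      cells <- (pop$col[ord] - 1L) * grid$ny + pop$row[ord]
      nth <- data.table::rowid(cells)
      kick <- ord[nth > caps[[cls]]]
    } else {
      kick <- dd_window_enforce(pop$row[ord], pop$col[ord], ord,
                                grid$ny, grid$nx, h, caps[[cls]])
    }
    drop[kick] <- TRUE
    removals <- removals + length(kick)
  }
  if (removals > 0L) pop <- pop_subset(pop, !drop)
  list(pop = pop, removals = removals)
}

# sequential greedy acceptance guaranteeing that every window centred on a
# retained agent's cell holds <= cap agents of the class
dd_window_enforce <- function(row, col, ids, ny, nx, h, cap) {
  counts <- matrix(0L, ny, nx)
  kick <- integer(0)
  for (i in seq_along(ids)) {
    r <- row[i]; c <- col[i]
    r0 <- max(1L, r - h); r1 <- min(ny, r + h)
    c0 <- max(1L, c - h); c1 <- min(nx, c + h)
    win <- counts[r0:r1, c0:c1, drop = FALSE]
    ok <- TRUE
    # own window after insertion
    if (sum(win) + 1L > cap) {
      ok <- FALSE
    } else if (any(win > 0L)) {
      # windows centred on already-accepted occupied cells near the candidate
      occ <- which(win > 0L, arr.ind = TRUE)
      for (j in seq_len(nrow(occ))) {
        zr <- r0 + occ[j, 1] - 1L; zc <- c0 + occ[j, 2] - 1L
        zr0 <- max(1L, zr - h); zr1 <- min(ny, zr + h)
        zc0 <- max(1L, zc - h); zc1 <- min(nx, zc + h)
        if (sum(counts[zr0:zr1, zc0:zc1]) + 1L > cap) { ok <- FALSE; break }
      }
    }
    if (ok) counts[r, c] <- counts[r, c] + 1L else kick <- c(kick, ids[i])
  }
  kick
}

#' Mortality from one farm operation
#'
#' Agents in the cropped cells of the event's field die with the
#' table probability for their stage class (juveniles below the soil
#' surface are hit by soil cultivation, adults by surface operations).
#' Margin and buffer cells are not cultivated and are spared.
#'
#' @param pop a `beetle_pop`
#' @param grid the `landscape_grid`
#' @param field_id the treated parcel
#' @param event_type management event type
#' @param table a [default_mortality_table()]
#' @return list(pop, deaths)
#' @export
farm_operation_mortality <- function(pop, grid, field_id, event_type,
                                     table = default_mortality_table()) {
  probs <- table[[event_type]]
  if (is.null(probs)) {
    stop("farm_operation_mortality: no mortality entry for event type ",
         event_type)
  }
  if (all(probs == 0)) return(list(pop = pop, deaths = 0L))
  crop <- cropped_cells(grid, field_id)
  idx <- cell_index(pop, grid)
  inside <- idx %in% crop
  if (!any(inside)) return(list(pop = pop, deaths = 0L))
  p <- ifelse(pop$stage == STAGE_ADULT, probs[["adult"]], probs[["juvenile"]])
  dies <- inside & (stats::runif(length(idx)) < p)
  deaths <- sum(dies)
  if (deaths > 0L) pop <- pop_subset(pop, !dies)
  list(pop = pop, deaths = deaths)
}

#' Winter mortality toll
#'
#' Applied once per winter: hibernating adults on overwintering habitat
#' (margins, boundary strips, woodland) die with the habitat probability;
#' adults caught anywhere else use the higher exposed probability.
#' Juveniles (none normally present in winter) are untouched.
#'
#' @param pop a `beetle_pop`
#' @param grid the `landscape_grid`
#' @param params a [beetle_params()]
#' @return list(pop, deaths)
#' @export
overwinter_mortality <- function(pop, grid, params = beetle_params()) {
  adult <- pop$stage == STAGE_ADULT
  if (!any(adult)) return(list(pop = pop, deaths = 0L))
  ow_mask <- hab_mask(grid, HAB_OVERWINTER)
  idx <- cell_index(pop, grid)
  sheltered <- pop$hib & ow_mask[idx]
  p <- ifelse(sheltered, params$overwinter_mort[["habitat"]],
              params$overwinter_mort[["exposed"]])
  dies <- adult & (stats::runif(length(idx)) < p)
  deaths <- sum(dies)
  if (deaths > 0L) pop <- pop_subset(pop, !dies)
  list(pop = pop, deaths = deaths)
}

#' One simulated day
#'
#' Fixed sub-step order: (1) farm events of the day (operation mortality,
#' then insecticide applications to the exposure grid), (2) exposure decay
#' followed by trigger mortality of surface-active adults, (3) juvenile
#' development and background mortality, (4) reproduction, (5) movement,
#' (6) density dependence. Sprays hit beetles before they can move off the
#' field, matching the observation that the population is largely in-field
#' at spraying time. Agent bookkeeping is asserted every day:
#' end = start + births - deaths - removals.
#'
#' @param pop a `beetle_pop`
#' @param grid the `landscape_grid`
#' @param expo an `exposure_grid`
#' @param events_today data.frame of today's events (field_id, type, ...)
#' @param weather_today one row of the weather table
#' @param temp_mean5 5-day running mean temperature (for the spring trigger)
#' @param product the scenario's [pesticide_product()]
#' @param curve the scenario's [drift_curve()]
#' @param params a [beetle_params()]
#' @param mort_table a [default_mortality_table()]
#' @return list(pop, expo, log = one-row data.frame of daily counts)
#' @export
step_day <- function(pop, grid, expo, events_today, weather_today,
                     temp_mean5, product, curve,
                     params = beetle_params(),
                     mort_table = default_mortality_table()) {
  n_start <- length(pop$stage)
  births <- 0L; deaths <- 0L; removals <- 0L
  doy <- weather_today$doy
  temp <- weather_today$temp

  # (1) farm events
  if (!is.null(events_today) && nrow(events_today) > 0) {
    for (i in seq_len(nrow(events_today))) {
      ev <- events_today[i, ]
      om <- farm_operation_mortality(pop, grid, ev$field_id, ev$type, mort_table)
      pop <- om$pop; deaths <- deaths + om$deaths
      if (ev$type == "insecticide_spray") {
        expo <- apply_application(expo, grid, ev$field_id, product, curve)
      }
    }
  }

  # (2) exposure decay, then trigger mortality
  expo <- daily_decay(expo, temp, product)
  if (max(expo$conc) >= 1.0 && length(pop$stage) > 0) {
    exposed <- pop$stage == STAGE_ADULT &
      (params$expose_hibernating | !pop$hib)
    if (any(exposed)) {
      conc <- expo$conc[cell_index(pop, grid)]
      dies <- exposed & exposure_mortality(conc, product)
      deaths <- deaths + sum(dies)
      if (any(dies)) pop <- pop_subset(pop, !dies)
    }
  }

  # (3) development + juvenile background mortality
  dv <- develop(pop, temp, params)
  pop <- dv$pop; deaths <- deaths + dv$deaths

  # (4) reproduction
  rp <- reproduce(pop, grid, doy, params)
  pop <- rp$pop; births <- births + rp$births

  # (5) movement
  pop <- move_beetles(pop, grid, doy, temp_mean5, params)

  # (6) density dependence
  dd <- density_dependence(pop, grid, params)
  pop <- dd$pop; removals <- removals + dd$removals

  stopifnot(length(pop$stage) == n_start + births - deaths - removals)
  log <- data.frame(doy = doy, n_agents = length(pop$stage),
                    n_adults = sum(pop$stage == STAGE_ADULT),
                    n_hibernating = sum(pop$hib),
                    births = births, deaths = deaths, removals = removals)
  list(pop = pop, expo = expo, log = log)
}
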