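#' Default crop rotations per farm type
#'
#' Each rotation is an ordered list of exactly 100 crop entries; the
#' multiplicity of a crop equals the intended percentage of the farm's
#' area under that crop at any time. A field starts at a random position in
#' its farm's rotation and advances one entry per year, so after 100 years
#' every entry has been grown once. These rotations are plausible Dutch
#' compositions by farm type (vegetable/potato/flower farms carry the
#' insecticide-treated crops); they are configurable defaults, not values
#' from any survey.
#'
#' @return named list of character vectors, each of length 100
#' @export
default_rotations <- function() {
  mk <- function(...) {
    x <- c(...)
    stopifnot(sum(x) == 100)
    rep(names(x), times = x)
  }
  list(
    animal_grazing   = mk(grass = 100),
    arable           = mk(winter_wheat = 30, spring_barley = 20, beet = 15,
                          potato = 25, maize = 10),
    arable_vegetable = mk(potato = 25, carrot = 20, cabbage = 20,
                          winter_wheat = 20, spring_barley = 15),
    starch_potato    = mk(potato = 50, winter_wheat = 25, spring_barley = 25),
    flower           = mk(tulip = 40, winter_wheat = 30, spring_barley = 30),
    other            = mk(winter_wheat = 40, maize = 30, spring_barley = 30)
  )
}

#' Construct a management event
#'
#' @param type event type (plough, harrow, sow, fertilize, sprays,
#'   harvest, grass_cut)
#' @param start,end day-of-year window bounds
#' @param probability chance the event is carried out in a given year
#' @param product product reference for spray events
#' @return management event list
#' @export
mgmt_event <- function(type, start, end, probability = 1, product = NA_character_) {
  stopifnot(start <= end, probability >= 0, probability <= 1)
  list(type = type, window_start_day = start, window_end_day = end,
       probability = probability, product = product)
}

#' Default per-crop management plans
#'
#' Ordered farm activities with day-of-year windows and execution
#' probabilities. Insecticide sprays occur only on the intensively treated
#' crops (potato, carrot, cabbage, tulip). Windows and probabilities are
#' labelled defaults chosen for agronomic plausibility; none are printed in
#' the source literature.
#'
#' @return named list: per crop an ordered list of management events
#' @export
default_plans <- function() {
  list(
    winter_wheat = list(
      mgmt_event("fertilize", 75, 95, 0.9),
      mgmt_event("fungicide_spray", 130, 160, 0.6, "fung_std"),
      mgmt_event("harvest", 210, 235, 1),
      mgmt_event("plough", 240, 280, 0.8),
      mgmt_event("sow", 285, 310, 1)
    ),
    spring_barley = list(
      mgmt_event("plough", 60, 85, 0.9),
      mgmt_event("sow", 85, 110, 1),
      mgmt_event("fungicide_spray", 150, 175, 0.5, "fung_std"),
      mgmt_event("harvest", 215, 240, 1)
    ),
    maize = list(
      mgmt_event("plough", 95, 115, 0.9),
      mgmt_event("sow", 115, 135, 1),
      mgmt_event("herbicide_spray", 140, 160, 0.7, "herb_std"),
      mgmt_event("harvest", 270, 295, 1)
    ),
    beet = list(
      mgmt_event("plough", 70, 95, 0.9),
      mgmt_event("sow", 95, 120, 1),
      mgmt_event("herbicide_spray", 130, 150, 0.8, "herb_std"),
      mgmt_event("harvest", 270, 300, 1)
    ),
    potato = list(
      mgmt_event("plough", 80, 100, 1),
      mgmt_event("sow", 100, 120, 1),
      mgmt_event("insecticide_spray", 160, 190, 0.8, "ins_std"),
      mgmt_event("fungicide_spray", 175, 205, 0.9, "fung_std"),
      mgmt_event("harvest", 250, 280, 1)
    ),
    carrot = list(
      mgmt_event("plough", 85, 105, 1),
      mgmt_event("sow", 105, 130, 1),
      mgmt_event("insecticide_spray", 150, 180, 0.8, "ins_std"),
      mgmt_event("harvest", 255, 285, 1)
    ),
    cabbage = list(
      mgmt_event("plough", 85, 105, 1),
      mgmt_event("sow", 110, 135, 1),
      mgmt_event("insecticide_spray", 155, 185, 0.8, "ins_std"),
      mgmt_event("harvest", 245, 275, 1)
    ),
    tulip = list(   # autumn-planted bulbs: calendar order within the year
      mgmt_event("insecticide_spray", 120, 150, 0.8, "ins_std"),
      mgmt_event("harvest", 170, 195, 1),
      mgmt_event("plough", 280, 300, 1),
      mgmt_event("sow", 300, 320, 1)
    ),
    grass = list(
      mgmt_event("fertilize", 70, 95, 0.9),
      mgmt_event("grass_cut", 145, 165, 1),
      mgmt_event("grass_cut", 195, 215, 0.8),
      mgmt_event("grass_cut", 245, 265, 0.5)
    )
  )
}

#' Draw random rotation starting points for all parcels
#'
#' Each arable field starts at a uniformly drawn position in its farm's
#' 100-entry rotation, so a crop with k entries initially occupies about
#' k % of fields.
#'
#' @param parcels parcel table (from a `landscape_grid`)
#' @return parcel table with `rotation_index` in 0..99
#' @export
init_rotation_start <- function(parcels) {
  parcels$rotation_index <- sample(0:99, nrow(parcels), replace = TRUE)
  parcels
}

#' Advance every parcel one rotation entry (end of year)
#'
#' @param parcels parcel table with `rotation_index` set
#' @return parcel table, index advanced modulo 100
#' @export
advance_rotation <- function(parcels) {
  parcels$rotation_index <- (parcels$rotation_index + 1L) %% 100L
  parcels
}

#' Current crop of each parcel
#'
#' @param parcels parcel table with rotation indices
#' @param farms farm table
#' @param rotations rotation list, see [default_rotations()]
#' @return character vector of crop names, one per parcel
#' @export
current_crop <- function(parcels, farms, rotations = default_rotations()) {
  ftype <- farms$farm_type[match(parcels$farm_id, farms$id)]
  vapply(seq_len(nrow(parcels)), function(i) {
    rot <- rotations[[ftype[i]]]
    if (is.null(rot)) rot <- rotations[["other"]]
    rot[parcels$rotation_index[i] + 1L]
  }, character(1))
}

#' Schedule one year of management events for one field
#'
#' Each event of the crop's plan fires with its probability on a uniformly
#' drawn day inside its window. Spray events are shifted forward past days
#' with precipitation above `spray_precip_threshold` (up to `shift_cap`
#' days). Ordering is enforced: an event scheduled before its predecessor
#' is pushed after it; events that cannot be placed inside
#' `[window_start, window_end + shift_cap]` are dropped and recorded in the
#' `dropped` attribute.
#'
#' @param plan ordered list of management events for the crop
#' @param year simulation year (1-based)
#' @param weather weather table from [generate_weather()]
#' @param spray_precip_threshold mm of daily rain that postpones a spray
#' @param shift_cap maximum forward shift in days
#' @return data.frame (type, day, product); attribute `dropped` counts
#'   events lost to impossible ordering
#' @export
schedule_year <- function(plan, year, weather,
                          spray_precip_threshold = 2, shift_cap = 5) {
  wy <- weather[weather$year == year, ]
  rows <- list(); dropped <- 0L
  prev_day <- 0L
  spray_types <- c("insecticide_spray", "fungicide_spray", "herbicide_spray")
  for (ev in plan) {
    if (stats::runif(1) > ev$probability) next
    day <- if (ev$window_start_day == ev$window_end_day) ev$window_start_day
           else sample(ev$window_start_day:ev$window_end_day, 1L)
    is_cyclic <- ev$window_start_day < prev_day - 180L  # plan wraps the year (autumn->spring crops)
    if (!is_cyclic && day <= prev_day) day <- prev_day + 1L
    limit <- ev$window_end_day + shift_cap
    if (ev$type %in% spray_types) {
      while (day <= limit && day <= 365L && wy$precip[day] > spray_precip_threshold) {
        day <- day + 1L
      }
    }
    if (day > limit || day > 365L) { dropped <- dropped + 1L; next }
    if (!is_cyclic) prev_day <- day
    rows[[length(rows) + 1L]] <- data.frame(
      type = ev$type, day = day, product = ev$product, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(type = character(0), day = integer(0), product = character(0))
  attr(out, "dropped") <- dropped
  out
}

#' Schedule a whole landscape year
#'
#' Applies [schedule_year()] to every parcel's current crop.
#'
#' @inheritParams current_crop
#' @inheritParams schedule_year
#' @param plans management plan list, see [default_plans()]
#' @return data.frame (field_id, crop, type, day, product), sorted by day
#' @export
schedule_landscape_year <- function(parcels, farms, year, weather,
                                    rotations = default_rotations(),
                                    plans = default_plans(), ...) {
  crops <- current_crop(parcels, farms, rotations)
  out <- lapply(seq_len(nrow(parcels)), function(i) {
    plan <- plans[[crops[i]]]
    if (is.null(plan)) return(NULL)
    ev <- schedule_year(plan, year, weather, ...)
    if (nrow(ev) == 0) return(NULL)
    cbind(field_id = parcels$id[i], crop = crops[i], ev)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(field_id = integer(0), crop = character(0),
                      type = character(0), day = integer(0),
                      product = character(0))
  }
  out[order(out$day), , drop = FALSE]
}

#' Generate a synthetic multi-year daily weather series
#'
#' Temperate-maritime preset: a sinusoidal annual temperature cycle
#' (coldest mid-January) with AR(1) daily noise, precipitation from a
#' two-state wet/dry Markov chain with gamma-distributed wet-day amounts,
#' and lognormal daily mean wind speed. Years have 365 days, no leap days.
#'
#' @param n_years number of years (>= 1)
#' @param seed integer seed
#' @param preset list of climate parameters: `mean_temp` (deg C),
#'   `amplitude` (deg C), `ar1`, `noise_sd`, `p_wet_given_dry`,
#'   `p_wet_given_wet`, `rain_shape`, `rain_scale` (mm), `wind_meanlog`,
#'   `wind_sdlog`
#' @return data.frame (year, doy, day, temp, wind, precip)
#' @export
generate_weather <- function(n_years, seed = 1L,
                             preset = list(mean_temp = 10, amplitude = 7,
                                           ar1 = 0.7, noise_sd = 1.6,
                                           p_wet_given_dry = 0.3,
                                           p_wet_given_wet = 0.6,
                                           rain_shape = 0.8, rain_scale = 6,
                                           wind_meanlog = 1.25,
                                           wind_sdlog = 0.45)) {
  stopifnot(n_years >= 1)
  set.seed(as.integer(seed))
  n <- n_years * 365L
  doy <- rep(1:365, n_years)
  year <- rep(seq_len(n_years), each = 365L)
  seasonal <- preset$mean_temp - preset$amplitude * cos(2 * pi * (doy - 15) / 365)
  noise <- numeric(n)
  innov_sd <- preset$noise_sd * sqrt(1 - preset$ar1^2)
  eps <- stats::rnorm(n, 0, innov_sd)
  noise[1] <- stats::rnorm(1, 0, preset$noise_sd)
  for (i in 2:n) noise[i] <- preset$ar1 * noise[i - 1] + eps[i]
  temp <- seasonal + noise

  wet <- logical(n)
  u <- stats::runif(n)
  wet[1] <- u[1] < preset$p_wet_given_dry
  for (i in 2:n) {
    p <- if (wet[i - 1]) preset$p_wet_given_wet else preset$p_wet_given_dry
    wet[i] <- u[i] < p
  }
  precip <- numeric(n)
  precip[wet] <- stats::rgamma(sum(wet), shape = preset$rain_shape,
                               scale = preset$rain_scale)
  wind <- stats::rlnorm(n, preset$wind_meanlog, preset$wind_sdlog)
  data.frame(year = year, doy = doy, day = seq_len(n),
             temp = temp, wind = wind, precip = precip)
}

#' Simplified daily vegetation state for a crop
#'
#' Vegetation height follows a saturating degree-day curve (base 5 deg C)
#' reset at sowing and at harvest/cut; this stands in for a full biomass
#' model and only needs to deliver plausible height/cover dynamics.
#'
#' @param crop crop name (determines maximum height)
#' @param doy day of year at which to evaluate
#' @param weather_year weather rows of one year (365 rows)
#' @param events scheduled events of the field this year (for sowing and
#'   harvest/cut dates); without a sowing event growth starts at day 60
#' @param base_temp developmental base temperature (deg C)
#' @return list(height_cm, cover_class in {bare, low, medium, high})
#' @export
vegetation_state <- function(crop, doy, weather_year, events = NULL,
                             base_temp = 5) {
  hmax <- switch(crop,
                 winter_wheat = 90, spring_barley = 80, maize = 220,
                 beet = 50, potato = 60, carrot = 40, cabbage = 50,
                 tulip = 45, grass = 35, 50)
  sow_day <- 60L
  stop_days <- integer(0)
  if (!is.null(events) && nrow(events) > 0) {
    s <- events$day[events$type == "sow"]
    if (length(s)) sow_day <- min(s)
    stop_days <- events$day[events$type %in% c("harvest", "grass_cut", "plough")]
  }
  stop_days <- sort(stop_days[stop_days <= doy])
  start <- if (length(stop_days)) max(sow_day, max(stop_days)) else sow_day
  if (doy < start) return(list(height_cm = 0, cover_class = "bare"))
  days <- start:doy
  dd <- sum(pmax(0, weather_year$temp[days] - base_temp))
  height <- hmax * (1 - exp(-dd / 350))
  cover <- if (height < 5) "bare" else if (height < 20) "low"
           else if (height < 60) "medium" else "high"
  list(height_cm = height, cover_class = cover)
}
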