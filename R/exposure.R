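#' Daily mortality probability from an overall field lethality rate
#'
#' Converts an overall mortality proportion `m` measured over a `d`-day
#' field test into the daily mortality probability `p` applied while a
#' beetle sits above the trigger concentration, by solving
#' `(1 - m) = (1 - p)^d`. For the standard 7-day test this gives
#' p = 0.28 for LR90, 0.09 for LR50 and 0.04 for LR25 (2 d.p.).
#'
#' @param m overall mortality proportion over the test period, in [0, 1]
#' @param d test duration in days (>= 1)
#' @return daily probability of mortality
#' @export
daily_mortality_prob <- function(m, d) {
  if (any(m < 0) || any(m > 1)) stop("daily_mortality_prob: m must be in [0, 1]")
  if (any(d < 1)) stop("daily_mortality_prob: d must be >= 1")
  if (any(m == 1)) {
    warning("daily_mortality_prob: m = 1 is degenerate; returning p = 1")
  }
  1 - (1 - m)^(1 / d)
}

#' Temperature-adjusted environmental half-life
#'
#' Scales a pesticide's half-life measured at the 20 deg C reference
#' temperature to the temperature of interest with a Q10 rule:
#' `DT50(T) = DT50(20) * exp(ln(Q10) * (20 - T) / 10)`. Degradation slows
#' in the cold (longer half-life) and accelerates in warmth.
#'
#' @param dt50_20 half-life at 20 deg C, days (> 0)
#' @param temp_c temperature of interest, deg C
#' @param q10 ratio of degradation rate coefficients per 10 deg C
#'   (default 2.58)
#' @return half-life in days at `temp_c`
#' @export
temperature_adjusted_dt50 <- function(dt50_20, temp_c, q10 = 2.58) {
  if (any(dt50_20 <= 0)) stop("temperature_adjusted_dt50: dt50_20 must be > 0")
  dt50_20 * exp(log(q10) * (20 - temp_c) / 10)
}

#' Toxic-unit treatment rate
#'
#' Application rate, in multiples of the trigger concentration, calibrated
#' so that a deposit decaying first-order at 20 deg C stays at or above the
#' trigger threshold for the whole effect period:
#' `rate = 1 / 0.5^(duration / DT50) = 2^(duration / DT50)`.
#' For the 7-day effect period this gives 41.78 at DT50 = 1.3 days and
#' 1.21 at DT50 = 25 days.
#'
#' @param dt50 half-life at 20 deg C, days (> 0)
#' @param duration effect period in days (> 0)
#' @return treatment rate in trigger-concentration multiples (>= 1)
#' @export
treatment_rate <- function(dt50, duration) {
  if (any(dt50 <= 0)) stop("treatment_rate: dt50 must be > 0")
  if (any(duration <= 0)) stop("treatment_rate: duration must be > 0")
  2^(duration / dt50)
}

#' Insecticide product definition
#'
#' Bundles a lethality-rate class (overall mortality over the effect
#' period), an environmental half-life class and the derived daily
#' mortality probability and toxic-unit treatment rate.
#'
#' @param lr_class one of "LR90", "LR50", "LR25"
#' @param dt50_20 half-life at 20 deg C in days (1.3 or 25 in the scenario
#'   matrix; any positive value accepted)
#' @param duration effect period in days (default 7, the field-test length)
#' @param name product label
#' @return list of class `pesticide_product`
#' @export
pesticide_product <- function(lr_class = c("LR90", "LR50", "LR25"),
                              dt50_20 = 1.3, duration = 7,
                              name = NULL) {
  lr_class <- match.arg(lr_class)
  m <- c(LR90 = 0.90, LR50 = 0.50, LR25 = 0.25)[[lr_class]]
  out <- list(
    name = if (is.null(name)) sprintf("%s_dt%g", lr_class, dt50_20) else name,
    lr_class = lr_class,
    overall_mortality = m,
    effect_duration = duration,
    dt50_20 = dt50_20,
    daily_p = daily_mortality_prob(m, duration),
    treatment_rate = treatment_rate(dt50_20, duration)
  )
  class(out) <- "pesticide_product"
  out
}

#' Spray-drift deposition curve
#'
#' Power-law ground deposition with distance downwind of a sprayed field
#' edge, `%drift = A * dist^B`, truncated at `max_dist`. Drift-reducing
#' technology is modelled as a multiplicative scaling of the coefficient A
#' by `(1 - reduction)`, preserving the exponent.
#'
#' @param A coefficient (% at 1 m); default 2.7705 (field crops, downward
#'   spraying, no drift reduction)
#' @param B exponent (< 0); default -0.9787
#' @param max_dist maximum drift distance in metres (default 12)
#' @param reduction drift reduction fraction (0, 0.5 or 0.9 in the
#'   scenario matrix)
#' @return list of class `drift_curve`
#' @export
drift_curve <- function(A = 2.7705, B = -0.9787, max_dist = 12,
                        reduction = 0) {
  stopifnot(A > 0, B < 0, max_dist > 0, reduction >= 0, reduction <= 1)
  structure(list(A = A, B = B, max_dist = max_dist, reduction = reduction),
            class = "drift_curve")
}

#' Drift deposition fraction at a distance
#'
#' @param dist distance from the sprayed field edge in metres (> 0)
#' @param curve a [drift_curve()]
#' @return percentage of the in-field application rate deposited; 0 beyond
#'   `max_dist`
#' @export
drift_fraction <- function(dist, curve = drift_curve()) {
  if (any(dist <= 0)) stop("drift_fraction: dist must be > 0 (in-field cells are handled by apply_application)")
  out <- (1 - curve$reduction) * curve$A * dist^curve$B
  out[dist > curve$max_dist] <- 0
  out
}

#' Create an empty exposure grid aligned to a landscape
#'
#' Concentrations are held in trigger-threshold units: the mortality
#' trigger is at 1.0.
#'
#' @param grid a `landscape_grid`
#' @return list of class `exposure_grid` with a `conc` matrix
#' @export
new_exposure_grid <- function(grid) {
  structure(list(conc = matrix(0, nrow = grid$ny, ncol = grid$nx),
                 cell_size = grid$cell_size),
            class = "exposure_grid")
}

# Drift footprint of one parcel: cropped cells plus off-crop cells within
# max_dist of the sprayed area, with centre-to-nearest-sprayed-cell-edge
# Euclidean distances. Geometry is static between layout changes, so the
# footprint is cached on the landscape keyed by (field_id, layout version).
field_footprint <- function(grid, id, max_dist = 12) {
  key <- sprintf("f%d_v%d", id, grid$version)
  cached <- get0(key, envir = grid$cache, inherits = FALSE)
  if (!is.null(cached)) return(cached)

  crop <- cropped_cells(grid, id)
  if (length(crop) == 0L) {
    out <- list(crop = integer(0), ring = integer(0), dist = numeric(0))
    assign(key, out, envir = grid$cache)
    return(out)
  }
  ny <- grid$ny; nx <- grid$nx; cs <- grid$cell_size
  crow <- ((crop - 1L) %% ny) + 1L
  ccol <- ((crop - 1L) %/% ny) + 1L
  pad <- ceiling(max_dist / cs)
  r0 <- max(1L, min(crow) - pad); r1 <- min(ny, max(crow) + pad)
  c0 <- max(1L, min(ccol) - pad); c1 <- min(nx, max(ccol) + pad)
  cand <- as.matrix(expand.grid(row = r0:r1, col = c0:c1))
  cand_idx <- (cand[, "col"] - 1L) * ny + cand[, "row"]
  in_crop <- cand_idx %in% crop
  cand <- cand[!in_crop, , drop = FALSE]
  cand_idx <- cand_idx[!in_crop]
  if (nrow(cand) == 0L) {
    out <- list(crop = crop, ring = integer(0), dist = numeric(0))
    assign(key, out, envir = grid$cache)
    return(out)
  }

  # distance from candidate cell centre to the nearest edge of any sprayed
  # cell; only boundary cells of the sprayed set matter
  crop_set <- logical(ny * nx); crop_set[crop] <- TRUE
  interior <- (crow > 1L) & (crow < ny) & (ccol > 1L) & (ccol < nx)
  ii <- which(interior)
  if (length(ii)) {
    r <- crow[ii]; c <- ccol[ii]
    interior[ii] <- crop_set[(c - 1L) * ny + r - 1L] &
      crop_set[(c - 1L) * ny + r + 1L] &
      crop_set[(c - 2L) * ny + r] & crop_set[c * ny + r]
  }
  brow <- crow[!interior]; bcol <- ccol[!interior]

  px <- (cand[, "col"] - 0.5) * cs
  py <- (cand[, "row"] - 0.5) * cs
  bx0 <- (bcol - 1) * cs; bx1 <- bcol * cs
  by0 <- (brow - 1) * cs; by1 <- brow * cs
  dmin <- rep(Inf, length(px))
  for (j in seq_along(bx0)) {
    dx <- pmax(0, pmax(bx0[j] - px, px - bx1[j]))
    dy <- pmax(0, pmax(by0[j] - py, py - by1[j]))
    dmin <- pmin(dmin, sqrt(dx * dx + dy * dy))
  }
  keep <- dmin > 0 & dmin <= max_dist
  out <- list(crop = crop, ring = cand_idx[keep], dist = dmin[keep])
  assign(key, out, envir = grid$cache)
  out
}

#' Apply one insecticide application to the exposure grid
#'
#' Cropped cells of the field receive the product's toxic-unit treatment
#' rate; off-crop cells within the drift range receive
#' `rate * drift_fraction(dist) / 100`, with `dist` the Euclidean distance
#' from the cell centre to the nearest sprayed cell edge. Margin and
#' buffer cells of the field are not sprayed (they are off-crop) but do
#' receive drift.
#'
#' @param expo an `exposure_grid`
#' @param grid the `landscape_grid`
#' @param field_id parcel id being sprayed
#' @param product a [pesticide_product()]
#' @param curve a [drift_curve()]
#' @return updated `exposure_grid`
#' @export
apply_application <- function(expo, grid, field_id, product,
                              curve = drift_curve()) {
  if (!field_id %in% grid$parcels$id) {
    stop("apply_application: unknown field_id ", field_id)
  }
  fp <- field_footprint(grid, field_id, curve$max_dist)
  rate <- product$treatment_rate
  expo$conc[fp$crop] <- expo$conc[fp$crop] + rate
  if (length(fp$ring)) {
    expo$conc[fp$ring] <- expo$conc[fp$ring] +
      rate * drift_fraction(fp$dist, curve) / 100
  }
  expo
}

#' One day of first-order decay of the exposure grid
#'
#' Every cell is multiplied by `0.5^(1 / DT50(T))`, with the half-life
#' adjusted to today's temperature by the Q10 rule. At a constant
#' 20 deg C a treatment-rate deposit crosses the trigger after exactly the
#' effect duration.
#'
#' @param expo an `exposure_grid`
#' @param temp_c today's mean temperature, deg C
#' @param product the [pesticide_product()] whose half-life governs decay
#' @return updated `exposure_grid`
#' @export
daily_decay <- function(expo, temp_c, product) {
  if (max(expo$conc) <= 0) return(expo)
  f <- 0.5^(1 / temperature_adjusted_dt50(product$dt50_20, temp_c))
  expo$conc <- expo$conc * f
  expo
}

#' Threshold-trigger exposure mortality
#'
#' A beetle in a cell at or above the trigger concentration (1.0 toxic
#' units) dies with the product's daily probability; below the trigger it
#' always survives. There is no dose-response above the trigger.
#'
#' @param conc concentration(s) at the agents' cells, toxic units
#' @param product a [pesticide_product()]
#' @return logical vector, `TRUE` = dies today
#' @export
exposure_mortality <- function(conc, product) {
  (conc >= 1.0) & (stats::runif(length(conc)) < product$daily_p)
}
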