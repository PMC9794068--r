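test_that("generator is deterministic and hits its field-count target", {
  cfg <- landscape_config(extent_m = c(1000, 1000), cell_size_m = 2,
                          n_fields = 100)
  g1 <- generate_landscape(cfg, seed = 7)
  g2 <- generate_landscape(cfg, seed = 7)
  expect_identical(g1$element, g2$element)
  expect_identical(g1$field_id, g2$field_id)
  expect_identical(g1$parcels, g2$parcels)

  # realized field count within +/- 20 % of the 100-field target
  expect_gte(nrow(g1$parcels), 80)
  expect_lte(nrow(g1$parcels), 120)
  expect_setequal(unique(g1$field_id[g1$field_id > 0]), g1$parcels$id)

  g3 <- generate_landscape(cfg, seed = 8)
  expect_false(identical(g1$element, g3$element))
})

test_that("landscape invariants hold on generated grids", {
  g <- generate_landscape(landscape_config(), seed = 3)
  expect_true(all(g$element %in% ELEMENT_TYPES))
  # field ids sit exactly on cultivated or margin/buffer cells of parcels
  fieldish <- element_code(c("arable_field", "managed_grassland",
                             "field_margin", "crop_free_buffer"))
  expect_true(all((g$field_id > 0) == (g$element %in% fieldish)))
  expect_true(all(g$parcels$area_ha > 0))
  expect_true(all(g$parcels$farm_id %in% g$farms$id))
  # every parcel's rect matches its area bookkeeping
  with(g$parcels, expect_equal(area_ha,
    (col1 - col0 + 1) * (row1 - row0 + 1) * g$cell_size^2 / 1e4))
})

test_that("degenerate semi-natural fraction 0 gives a clean arable landscape", {
  cfg <- landscape_config(seminatural_fraction = 0, woodland_fraction = 0,
                          n_ditches = 0)
  g <- generate_landscape(cfg, seed = 1)
  expect_equal(sum(g$element == element_code("herbaceous_seminatural")), 0)
  expect_equal(sum(g$element == element_code("woodland")), 0)
  m <- compute_metrics(g)
  expect_equal(m$coverage_herbaceous, 0)
  expect_equal(m$coverage_woodland, 0)
})

test_that("infeasible configurations raise configuration errors", {
  expect_error(landscape_config(extent_m = c(50, 50)), "100 m")
  expect_error(landscape_config(n_fields = 500, mean_field_size_ha = 5),
               "exceeds extent")
  expect_error(landscape_config(n_fields = 1e6), "too many fields")
})

test_that("field margins carve the stated geometry and are idempotent", {
  g <- uniform_field_grid(100, cell_size = 1)
  g0 <- add_field_margins(g, fraction = 0, width_m = 4)
  expect_identical(g0$element, g$element)

  g1 <- add_field_margins(g, fraction = 1, width_m = 4, seed = 1)
  # 100 m x 100 m field with a 4-m ring leaves a 92 m x 92 m cropped interior
  cropped <- sum(g1$element == element_code("arable_field"))
  expect_equal(cropped, 92 * 92)
  expect_equal(sum(g1$element == element_code("field_margin")),
               100 * 100 - 92 * 92)
  # margin cells keep the parcel id
  expect_true(all(g1$field_id[g1$element == element_code("field_margin")] == 1L))

  g2 <- add_field_margins(g1, fraction = 1, width_m = 4, seed = 2)
  expect_identical(g2$element, g1$element)
})

test_that("margin fraction selects the exact number of parcels", {
  g <- generate_landscape(landscape_config(n_fields = 100), seed = 5)
  gm <- add_field_margins(g, fraction = 0.5, width_m = 4, seed = 9)
  expect_equal(sum(gm$parcels$has_margin), round(0.5 * nrow(gm$parcels)))
})

test_that("margins are skipped, with a message, on fields too small to hold them", {
  g <- uniform_field_grid(6, cell_size = 1)  # 6 m field cannot hold 2 x 4 m rings
  expect_message(gm <- add_field_margins(g, fraction = 1, width_m = 4),
                 "too small")
  expect_identical(gm$element, g$element)
})

test_that("water buffers convert exactly the adjacent field cells", {
  # no water: unchanged
  g <- uniform_field_grid(10)
  expect_identical(add_water_buffers(g)$element, g$element)

  # straight ditch along the western field edge -> one 1-cell buffer line
  el <- matrix("arable_field", 10, 10); el[, 1] <- "water"
  fid <- matrix(1L, 10, 10); fid[, 1] <- 0L
  g <- make_test_grid(el, fid)
  gb <- add_water_buffers(g)
  buf <- which(gb$element == element_code("crop_free_buffer"), arr.ind = TRUE)
  expect_equal(nrow(buf), 10)
  expect_true(all(buf[, 2] == 2))

  # L-shaped ditch: buffer count equals the hand-enumerated adjacency
  el <- matrix("arable_field", 10, 10)
  fid <- matrix(1L, 10, 10)
  el[1, 1:5] <- "water"; el[1:5, 1] <- "water"
  fid[1, 1:5] <- 0L; fid[1:5, 1] <- 0L
  g <- make_test_grid(el, fid)
  gb <- add_water_buffers(g)
  # by hand: row 2 cols 2..5 (above the horizontal arm), col 2 rows 3..5
  # (right of the vertical arm, (2,2) already counted), plus (1,6) and
  # (6,1) at the arm tips = 9
  expect_equal(sum(gb$element == element_code("crop_free_buffer")), 9)
  expect_true(gb$element[1, 6] == element_code("crop_free_buffer"))
  expect_true(gb$element[6, 1] == element_code("crop_free_buffer"))

  # idempotent
  expect_identical(add_water_buffers(gb)$element, gb$element)
})

test_that("closed-form metric examples come out exactly", {
  # single-category square landscape: no diversity, minimal shape index
  g <- uniform_field_grid(40)
  m <- compute_metrics(g)
  expect_equal(m$landscape_shannon, 0)
  expect_equal(m$landscape_shape_index, 1)

  # two categories at 50/50 -> Shannon = ln 2
  el <- matrix("arable_field", 40, 40); el[, 21:40] <- "woodland"
  fid <- matrix(0L, 40, 40); fid[, 1:20] <- 1L
  m2 <- compute_metrics(make_test_grid(el, fid))
  expect_equal(m2$landscape_shannon, log(2), tolerance = 1e-12)
})

test_that("metrics agree with a brute-force per-cell tally", {
  set.seed(42)
  for (rep in 1:3) {
    nn <- sample(20:50, 1)
    el <- matrix(sample(c("arable_field", "herbaceous_seminatural", "woodland",
                          "water", "built_up", "other"), nn * nn, TRUE), nn, nn)
    fid <- matrix(0L, nn, nn)
    fid[el == "arable_field"] <- 1L
    g <- make_test_grid(el, fid)
    m <- compute_metrics(g)

    # independent tally: category shares and edge walk
    cats <- c(arable_field = "arable", herbaceous_seminatural = "herbaceous",
              woodland = "woodland", water = "water", built_up = "built_up",
              other = "other")
    cm <- matrix(cats[el], nn, nn)
    p <- as.numeric(table(cm)) / (nn * nn)
    sh <- -sum(p * log(p))
    edges <- 2 * (nn + nn)                       # landscape boundary
    for (r in 1:nn) for (c in 1:nn) {
      if (c < nn && cm[r, c] != cm[r, c + 1]) edges <- edges + 1
      if (r < nn && cm[r, c] != cm[r + 1, c]) edges <- edges + 1
    }
    lsi <- 0.25 * edges / sqrt(nn * nn)
    expect_equal(m$landscape_shannon, sh, tolerance = 1e-12)
    expect_equal(m$landscape_shape_index, lsi, tolerance = 1e-12)
    expect_equal(m$coverage_herbaceous,
                 100 * mean(el == "herbaceous_seminatural"))
    expect_equal(m$coverage_woodland, 100 * mean(el == "woodland"))
  }
})

test_that("generator presets land in plausible heterogeneity ranges (soft check)", {
  g <- generate_landscape(landscape_config(), seed = 2)
  m <- compute_metrics(g)
  # logged, not asserted against the study's printed ranges: a 1-km2 desk
  # landscape is structurally coarser than a 10 x 10 km study area
  expect_gte(m$landscape_shannon, 0)
  expect_gte(m$landscape_shape_index, 1)
  expect_gte(m$farming_shannon, 0)
  expect_true(m$share_animal_farms >= 0 && m$share_animal_farms <= 100)
  cat(sprintf("\n[metrics] diversity %.2f LSI %.1f farming %.2f animal %.0f%%\n",
              m$landscape_shannon, m$landscape_shape_index,
              m$farming_shannon, m$share_animal_farms))
})

test_that("generator configs round-trip through their text schema", {
  cfg <- landscape_config(n_fields = 25, seminatural_fraction = 0.1)
  f <- withr::local_tempfile(fileext = ".json")
  write_landscape_config(cfg, f)
  back <- read_landscape_config(f)
  expect_equal(unclass(back), unclass(cfg))
  # unknown keys are rejected
  writeLines('{"n_fields": 10, "bogus_knob": 3}', f)
  expect_error(read_landscape_config(f), "unknown keys")
})

test_that("population snapshots export as tables and rasters", {
  g <- uniform_field_grid(10, cell_size = 2)
  pop <- place_adults(g, c(3, 3, 7), c(4, 4, 8))
  df <- as.data.frame(pop, grid = g)
  expect_equal(nrow(df), 3)
  expect_true(all(df$stage == "adult_female"))
  expect_equal(df$x_m, (df$col - 0.5) * 2)
  r <- population_raster(pop, g)
  expect_equal(r[3, 4], 2L)
  expect_equal(sum(r), 3L)
})

test_that("ascii grid round-trips", {
  m <- matrix(runif(12), 3, 4)
  f <- withr::local_tempfile(fileext = ".asc")
  write_ascii_grid(round(m, 6), f, cell_size = 2)
  r <- read_ascii_grid(f)
  expect_equal(r$mat, round(m, 6))
  expect_equal(r$cell_size, 2)
})
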