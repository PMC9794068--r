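# Build a landscape_grid by hand from a matrix of element-type names
# (row 1 = southern edge). Parcels are derived from the bounding boxes of
# positive field ids; all fields belong to one farm unless farm_types given.
make_test_grid <- function(el_names, field_id = NULL, cell_size = 1,
                           farm_types = "arable") {
  el <- matrix(carabidscape::element_code(el_names), nrow = nrow(el_names))
  ny <- nrow(el); nx <- ncol(el)
  if (is.null(field_id)) field_id <- matrix(0L, ny, nx)
  ids <- sort(unique(field_id[field_id > 0]))
  parcels <- do.call(rbind, lapply(ids, function(id) {
    w <- which(field_id == id, arr.ind = TRUE)
    r0 <- min(w[, 1]); r1 <- max(w[, 1]); c0 <- min(w[, 2]); c1 <- max(w[, 2])
    wm <- (c1 - c0 + 1) * cell_size; hm <- (r1 - r0 + 1) * cell_size
    data.frame(id = id, farm_id = ((id - 1) %% length(farm_types)) + 1L,
               area_ha = wm * hm / 1e4, perimeter_m = 2 * (wm + hm),
               soil_type = "sand", rotation_index = NA_integer_,
               has_margin = FALSE, col0 = c0, col1 = c1, row0 = r0, row1 = r1)
  }))
  if (is.null(parcels)) {
    parcels <- data.frame(id = integer(0), farm_id = integer(0),
                          area_ha = numeric(0), perimeter_m = numeric(0),
                          soil_type = character(0),
                          rotation_index = integer(0), has_margin = logical(0),
                          col0 = integer(0), col1 = integer(0),
                          row0 = integer(0), row1 = integer(0))
  }
  farms <- data.frame(id = seq_along(farm_types), farm_type = farm_types,
                      stringsAsFactors = FALSE)
  g <- list(element = el, field_id = field_id, parcels = parcels,
            farms = farms, cell_size = cell_size, nx = nx, ny = ny,
            width_m = nx * cell_size, height_m = ny * cell_size,
            version = 1L, cache = new.env(parent = emptyenv()))
  class(g) <- "landscape_grid"
  g
}

# uniform single-field landscape: nx x ny cells of arable field id 1,
# with an optional ring of boundary habitat around it
uniform_field_grid <- function(n = 20, cell_size = 1, ring = FALSE) {
  el <- matrix("arable_field", n, n)
  fid <- matrix(1L, n, n)
  if (ring) {
    el[1, ] <- el[n, ] <- "herbaceous_seminatural"
    el[, 1] <- el[, n] <- "herbaceous_seminatural"
    fid[1, ] <- fid[n, ] <- 0L
    fid[, 1] <- fid[, n] <- 0L
  }
  make_test_grid(el, fid, cell_size = cell_size)
}

# place adults at explicit (row, col) positions on a grid
place_adults <- function(grid, rows, cols, hib = FALSE,
                         params = carabidscape::beetle_params()) {
  n <- length(rows)
  pop <- list(stage = rep(4L, n), row = as.integer(rows),
              col = as.integer(cols), dd = numeric(n),
              hib = rep(hib, length.out = n), mode = rep(0L, n),
              super_factor = params$super_factor)
  class(pop) <- "beetle_pop"
  pop
}

# small fast landscape for simulation tests
small_sim_config <- function(n_years = 1, n_replicates = 1, seed = 11) {
  carabidscape::experiment_config(
    landscape = carabidscape::landscape_config(extent_m = c(400, 400),
                                               n_fields = 8, n_ditches = 2),
    n_years = n_years, n_replicates = n_replicates, master_seed = seed)
}

# independent brute-force check of the density-dependence predicate:
# every (2h+1)-cell square window centred on an occupied cell holds at
# most `cap` agents of the class
dd_predicate_holds <- function(rows, cols, ny, nx, h, cap) {
  if (length(rows) == 0) return(TRUE)
  counts <- matrix(0L, ny, nx)
  for (i in seq_along(rows)) counts[rows[i], cols[i]] <- counts[rows[i], cols[i]] + 1L
  for (i in seq_along(rows)) {
    r <- rows[i]; c <- cols[i]
    r0 <- max(1, r - h); r1 <- min(ny, r + h)
    c0 <- max(1, c - h); c1 <- min(nx, c + h)
    if (sum(counts[r0:r1, c0:c1]) > cap) return(FALSE)
  }
  TRUE
}
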