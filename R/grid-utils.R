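.datatable.aware <- TRUE

#' Element type codes used in the landscape raster
#'
#' Integer codes for the categorical element-type layer. The beetle model,
#' the exposure model and the heterogeneity metrics all index element types
#' through these codes.
#'
#' @format Named integer vector.
#' @export
ELEMENT_TYPES <- c(
  arable_field          = 1L,
  managed_grassland     = 2L,
  herbaceous_seminatural = 3L,
  woodland              = 4L,
  water                 = 5L,
  built_up              = 6L,
  field_margin          = 7L,
  crop_free_buffer      = 8L,
  other                 = 9L
)

#' @rdname ELEMENT_TYPES
#' @param name character element-type name(s)
#' @export
element_code <- function(name) {
  code <- ELEMENT_TYPES[name]
  if (anyNA(code)) stop("unknown element type: ", paste(name[is.na(code)], collapse = ", "))
  unname(code)
}

#' @rdname ELEMENT_TYPES
#' @param code integer code(s)
#' @export
element_name <- function(code) {
  names(ELEMENT_TYPES)[match(code, ELEMENT_TYPES)]
}

# Mapping of element types onto the six landscape-diversity categories
# (arable land, herbaceous semi-natural, woodland, built-up, water, other).
# Managed grassland and crop-free buffers count as arable land; grassy
# margins count as herbaceous semi-natural.
LANDSCAPE_CATEGORIES <- c(
  arable_field = "arable", managed_grassland = "arable",
  crop_free_buffer = "arable",
  herbaceous_seminatural = "herbaceous", field_margin = "herbaceous",
  woodland = "woodland", water = "water", built_up = "built_up",
  other = "other"
)

category_matrix <- function(element) {
  cat_by_code <- LANDSCAPE_CATEGORIES[element_name(seq_along(ELEMENT_TYPES))]
  m <- matrix(cat_by_code[element], nrow = nrow(element))
  m
}

#' Multi-source nearest-cell map on a raster
#'
#' Breadth-first (4-neighbourhood) propagation from all `TRUE` cells of
#' `mask`; for every cell returns the linear index of the nearest source
#' cell and the hop distance in cells. Used to give migrating beetles a
#' heading towards the nearest overwintering or foraging habitat. The
#' 4-neighbour metric is an approximation of Euclidean distance; headings
#' derived from it are adequate for movement bias.
#'
#' @param mask logical matrix (sources are `TRUE`)
#' @return list with integer matrices `source` (linear index of nearest
#'   source, `NA` where unreachable is impossible since grid is connected)
#'   and `dist` (cell hops).
#' @export
nearest_source_map <- function(mask) {
  ny <- nrow(mask); nx <- ncol(mask)
  n <- ny * nx
  src <- integer(n); src[] <- NA_integer_
  dist <- integer(n); dist[] <- NA_integer_
  frontier <- which(mask)
  if (length(frontier) == 0L) stop("nearest_source_map: mask has no TRUE cells")
  src[frontier] <- frontier
  dist[frontier] <- 0L
  d <- 0L
  while (length(frontier) > 0L) {
    d <- d + 1L
    row <- ((frontier - 1L) %% ny) + 1L
    up    <- frontier + 1L; up[row == ny] <- NA_integer_
    down  <- frontier - 1L; down[row == 1L] <- NA_integer_
    left  <- frontier - ny; left[left < 1L] <- NA_integer_
    right <- frontier + ny; right[right > n] <- NA_integer_
    nb <- c(up, down, left, right)
    parent <- rep.int(src[frontier], 4L)
    ok <- !is.na(nb)
    nb <- nb[ok]; parent <- parent[ok]
    new <- is.na(src[nb])
    nb <- nb[new]; parent <- parent[new]
    if (length(nb) > 0L) {
      # first writer wins on duplicates within a wave (same distance)
      first <- !duplicated(nb)
      nb <- nb[first]; parent <- parent[first]
      src[nb] <- parent
      dist[nb] <- d
    }
    frontier <- nb
  }
  list(source = matrix(src, nrow = ny), dist = matrix(dist, nrow = ny))
}

#' Write / read a single-band raster as ESRI ASCII grid
#'
#' Plain-text raster exchange format. Rows are written north-to-south;
#' internally row 1 is the southern (lower-left) edge, so the matrix is
#' flipped on write and read.
#'
#' @param mat numeric or integer matrix (row 1 = south)
#' @param path file path
#' @param cell_size cell size in metres
#' @param xll,yll lower-left corner coordinates (metres)
#' @export
write_ascii_grid <- function(mat, path, cell_size = 1, xll = 0, yll = 0) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(mat)),
    paste("nrows", nrow(mat)),
    paste("xllcorner", xll),
    paste("yllcorner", yll),
    paste("cellsize", cell_size),
    "NODATA_value -9999"
  ), con)
  for (r in rev(seq_len(nrow(mat)))) {
    writeLines(paste(mat[r, ], collapse = " "), con)
  }
  invisible(path)
}

#' @rdname write_ascii_grid
#' @return `read_ascii_grid` returns a list with `mat`, `cell_size`, `xll`, `yll`.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1:6]
  val <- function(key) {
    ln <- hdr[grepl(paste0("^", key), hdr, ignore.case = TRUE)]
    as.numeric(strsplit(trimws(ln), "\\s+")[[1]][2])
  }
  ncols <- as.integer(val("ncols")); nrows <- as.integer(val("nrows"))
  body <- lines[-(1:6)]
  vals <- as.numeric(unlist(strsplit(trimws(body), "\\s+")))
  stopifnot(length(vals) == ncols * nrows)
  mat <- matrix(vals, nrow = nrows, ncol = ncols, byrow = TRUE)
  mat <- mat[rev(seq_len(nrows)), , drop = FALSE]
  list(mat = mat, cell_size = val("cellsize"), xll = val("xllcorner"),
       yll = val("yllcorner"))
}
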