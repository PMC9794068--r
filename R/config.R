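#' Read and write generator configuration as structured text (JSON)
#'
#' The schema mirrors the arguments of [landscape_config()]; unknown keys
#' are rejected. JSON keeps the configs human-editable and diffable.
#'
#' @param config a `landscape_config`
#' @param path file path
#' @export
write_landscape_config <- function(config, path) {
  x <- unclass(config)
  x <- x[!vapply(x, is.null, logical(1))]   # NULLs have no JSON encoding
  x$farm_type_mix <- as.list(x$farm_type_mix)  # keep names: object, not array
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_landscape_config
#' @return `read_landscape_config` returns a validated [landscape_config()]
#' @export
read_landscape_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(landscape_config))
  known <- setdiff(known, "...")
  bad <- setdiff(names(raw), known)
  if (length(bad)) {
    stop("read_landscape_config: unknown keys: ", paste(bad, collapse = ", "))
  }
  raw <- raw[!vapply(raw, function(v) is.list(v) && length(v) == 0, logical(1))]
  if (!is.null(raw$farm_type_mix)) raw$farm_type_mix <- unlist(raw$farm_type_mix)
  do.call(landscape_config, raw)
}

#' Population snapshot as a data frame
#'
#' One row per super-individual: stage name, cell position and position in
#' metres (cell centres), development degree-days, hibernation flag.
#' Suitable for CSV export alongside per-cell count rasters.
#'
#' @param x a `beetle_pop`
#' @param grid the `landscape_grid` the population lives on (for metric
#'   coordinates); optional
#' @param ... unused
#' @return data.frame
#' @export
as.data.frame.beetle_pop <- function(x, grid = NULL, ...) {
  out <- data.frame(
    stage = c("egg", "larva", "pupa", "adult_female")[x$stage],
    row = x$row, col = x$col,
    dev_degree_days = x$dd,
    hibernating = x$hib
  )
  if (!is.null(grid)) {
    out$x_m <- (x$col - 0.5) * grid$cell_size
    out$y_m <- (x$row - 0.5) * grid$cell_size
  }
  out
}

#' Per-cell adult count raster of a population
#'
#' @param pop a `beetle_pop`
#' @param grid the `landscape_grid`
#' @param stage stage name to count (default adult_female)
#' @return integer matrix aligned with the landscape raster
#' @export
population_raster <- function(pop, grid, stage = "adult_female") {
  code <- match(stage, c("egg", "larva", "pupa", "adult_female"))
  sel <- pop$stage == code
  m <- matrix(0L, grid$ny, grid$nx)
  if (any(sel)) {
    idx <- (pop$col[sel] - 1L) * grid$ny + pop$row[sel]
    tab <- table(idx)
    m[as.integer(names(tab))] <- as.integer(tab)
  }
  m
}
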