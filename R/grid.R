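#' Generate a regular lat/lon ocean grid
#'
#' Builds an `n_lat` by `n_lon` grid of equal-angle cells covering the globe
#' (default resolution in the full pipeline is 30 arc-minutes, i.e. 360 x 720,
#' but any resolution works so tests can run on tiny grids). Cell areas use
#' the exact spherical band formula `R^2 * dlon * (sin(lat2) - sin(lat1))`
#' with R = 6,371 km, so the whole grid sums to `4 * pi * R^2`.
#'
#' A fraction of cells is flagged as land; land cells carry `NA` depth and
#' never receive productivity or catch. Sea-cell depths are drawn uniformly
#' from `depth_params$min` to `depth_params$max` metres (positive down).
#'
#' @param n_lat,n_lon Number of latitude / longitude bands (>= 1).
#' @param land_fraction Proportion of cells flagged as land, in `[0, 1)`.
#' @param depth_params List with `min` and `max` depth in metres; equal
#'   values give a constant-depth ocean.
#' @param seed Integer seed; the grid is a pure function of its arguments.
#' @return An object of class `of_grid`: a list with `cells` (tibble with
#'   `cell_id`, `row`, `col`, `lat`, `lon`, `area_km2`, `depth_m`, `sea`),
#'   `n_lat`, `n_lon` and `radius_km`. `cell_id` is 0-based row-major.
#' @export
#' @examples
#' g <- generate_grid(4, 8, land_fraction = 0.25, seed = 1)
#' sum(g$cells$area_km2) / (4 * pi * 6371^2)  # == 1
generate_grid <- function(n_lat, n_lon, land_fraction = 0.3,
                          depth_params = list(min = 10, max = 5000),
                          seed = 1L) {
  assert_scalar_number(n_lat, "n_lat", lower = 1)
  assert_scalar_number(n_lon, "n_lon", lower = 1)
  assert_scalar_number(land_fraction, "land_fraction", lower = 0, upper = 1)
  if (land_fraction >= 1) stop("`land_fraction` must be < 1", call. = FALSE)
  stopifnot(is.list(depth_params), depth_params$min > 0,
            depth_params$max >= depth_params$min)
  n_lat <- as.integer(n_lat); n_lon <- as.integer(n_lon)

  lat_edges <- seq(-90, 90, length.out = n_lat + 1)
  lon_edges <- seq(-180, 180, length.out = n_lon + 1)
  lat_mid <- (lat_edges[-1] + lat_edges[-(n_lat + 1)]) / 2
  lon_mid <- (lon_edges[-1] + lon_edges[-(n_lon + 1)]) / 2
  dlon_rad <- diff(lon_edges[1:2]) * pi / 180
  band_area <- EARTH_RADIUS_KM^2 * dlon_rad *
    (sin(lat_edges[-1] * pi / 180) - sin(lat_edges[-(n_lat + 1)] * pi / 180))

  n_cells <- n_lat * n_lon
  cells <- tibble(
    cell_id = seq_len(n_cells) - 1L,
    row = rep(seq_len(n_lat) - 1L, each = n_lon),
    col = rep(seq_len(n_lon) - 1L, times = n_lat),
    lat = rep(lat_mid, each = n_lon),
    lon = rep(lon_mid, times = n_lat),
    area_km2 = rep(band_area, each = n_lon)
  )

  with_seed(seed, {
    sea <- stats::runif(n_cells) >= land_fraction
    if (!any(sea)) sea[sample.int(n_cells, 1)] <- TRUE
    depth <- stats::runif(n_cells, depth_params$min, depth_params$max)
  })
  cells$sea <- sea
  cells$depth_m <- ifelse(sea, depth, NA_real_)

  structure(
    list(cells = cells, n_lat = n_lat, n_lon = n_lon,
         radius_km = EARTH_RADIUS_KM),
    class = "of_grid"
  )
}

#' @export
print.of_grid <- function(x, ...) {
  cat(sprintf("<of_grid> %d x %d cells (%d sea, %d land), R = %g km\n",
              x$n_lat, x$n_lon, sum(x$cells$sea), sum(!x$cells$sea),
              x$radius_km))
  invisible(x)
}

sea_cells <- function(grid) grid$cells[grid$cells$sea, , drop = FALSE]
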