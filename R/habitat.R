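#' Construct a habitat grid of reef pixels grouped into islands
#'
#' A habitat grid is the set of reef pixel centers particles are released
#' from and may settle onto. Pixels carry a contiguous 0-based `pixel_id`
#' and belong to exactly one island; island order is fixed by first
#' appearance in the table (a stable, documented order used for all
#' island-resolution matrices).
#'
#' @param lon,lat Pixel center coordinates in degrees (lon any convention,
#'   stored [0, 360)).
#' @param island_id Integer island label per pixel.
#' @param island_name Optional character island label per pixel (defaults to
#'   `"island_<id>"`).
#' @param pixel_id Optional 0-based contiguous ids (default `0:(n-1)`).
#' @return A `data.frame` of class `"habitat_grid"` with columns
#'   `pixel_id, lon, lat, island_id, island_name` and an `islands` attribute
#'   (unique island names in first-appearance order).
#' @export
habitat_grid <- function(lon, lat, island_id,
                         island_name = NULL, pixel_id = NULL) {
  n <- length(lon)
  if (length(lat) != n || length(island_id) != n)
    stopf("lon, lat, island_id must have equal length")
  if (is.null(pixel_id)) pixel_id <- seq_len(n) - 1L
  pixel_id <- as.integer(pixel_id)
  if (anyDuplicated(pixel_id)) stopf("duplicate pixel_id values")
  if (!identical(sort(pixel_id), seq_len(n) - 1L))
    stopf("pixel_id must be contiguous 0..%d", n - 1L)
  if (anyNA(island_id)) stopf("every pixel needs an island_id")
  if (any(abs(lat) > 90)) stopf("latitudes must lie in [-90, 90]")
  if (is.null(island_name)) island_name <- paste0("island_", island_id)
  g <- data.frame(pixel_id = pixel_id, lon = lon360(lon), lat = lat,
                  island_id = as.integer(island_id),
                  island_name = as.character(island_name),
                  stringsAsFactors = FALSE)
  g <- g[order(g$pixel_id), , drop = FALSE]
  rownames(g) <- NULL
  # one name per island id, and vice versa
  map <- unique(g[, c("island_id", "island_name")])
  if (anyDuplicated(map$island_id) || anyDuplicated(map$island_name))
    stopf("island_id and island_name must map one-to-one")
  attr(g, "islands") <- map$island_name
  attr(g, "island_ids") <- map$island_id
  class(g) <- c("habitat_grid", "data.frame")
  g
}

#' Number of islands in a habitat grid
#' @param grid A [habitat_grid()].
#' @return Integer count of distinct islands.
#' @export
n_islands <- function(grid) length(attr(grid, "islands"))

#' Read a habitat table from CSV
#'
#' Expects header `pixel_id,lon_deg,lat_deg,island_id,island_name`.
#' Longitudes in either [-180, 180) or [0, 360) are accepted and stored as
#' [0, 360).
#'
#' @param path CSV file path.
#' @return A [habitat_grid()].
#' @export
load_habitat_table <- function(path) {
  if (!file.exists(path)) stopf("habitat table not found: %s", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("pixel_id", "lon_deg", "lat_deg", "island_id", "island_name")
  if (!all(need %in% names(d)))
    stopf("habitat table must have columns: %s", paste(need, collapse = ","))
  habitat_grid(d$lon_deg, d$lat_deg, d$island_id, d$island_name, d$pixel_id)
}

#' Write a habitat table to CSV
#' @param grid A [habitat_grid()].
#' @param path Output CSV path (longitudes written on [0, 360)).
#' @return `path`, invisibly.
#' @export
write_habitat_table <- function(grid, path) {
  out <- data.frame(pixel_id = grid$pixel_id, lon_deg = grid$lon,
                    lat_deg = grid$lat, island_id = grid$island_id,
                    island_name = grid$island_name)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Great-circle distance via the haversine formula
#'
#' Distance on a sphere of radius [earth_radius_km()] between points given
#' in degrees. Vectorized over both endpoints (recycled).
#'
#' @param lon1,lat1,lon2,lat2 Coordinates in degrees.
#' @return Distance(s) in km.
#' @export
haversine_km <- function(lon1, lat1, lon2, lat2) {
  if (any(abs(c(lat1, lat2)) > 90)) stopf("latitudes must lie in [-90, 90]")
  rad <- pi / 180
  dlat <- (lat2 - lat1) * rad
  dlon <- (lon2 - lon1) * rad
  a <- sin(dlat / 2)^2 + cos(lat1 * rad) * cos(lat2 * rad) * sin(dlon / 2)^2
  2 * earth_radius_km() * asin(pmin(1, sqrt(a)))
}

#' Pairwise great-circle distance matrix between habitat pixels
#'
#' @param grid A [habitat_grid()].
#' @return An `n x n` symmetric matrix of km distances, rows/columns in
#'   `pixel_id` order, dimnames set to pixel ids.
#' @export
pixel_distance_matrix <- function(grid) {
  if (nrow(grid) == 0) stopf("empty habitat grid")
  n <- nrow(grid)
  D <- matrix(0, n, n, dimnames = list(grid$pixel_id, grid$pixel_id))
  for (i in seq_len(n)) {
    D[i, ] <- haversine_km(grid$lon[i], grid$lat[i], grid$lon, grid$lat)
  }
  # enforce exact symmetry against floating-point asymmetry
  (D + t(D)) / 2
}

#' Nearest habitat pixel within a settlement radius
#'
#' Finds, for each query position, the habitat pixel whose center is
#' nearest, provided that distance does not exceed `max_radius_km`;
#' otherwise `NA`. Ties (within 1e-9 km) resolve to the lowest `pixel_id`.
#' Vectorized over query positions.
#'
#' @param grid A [habitat_grid()].
#' @param lon,lat Query coordinates in degrees.
#' @param max_radius_km Positive settlement radius in km.
#' @return Integer vector of `pixel_id` values (`NA` where no pixel
#'   qualifies).
#' @export
nearest_pixel <- function(grid, lon, lat, max_radius_km) {
  if (max_radius_km <= 0) stopf("max_radius_km must be positive")
  nq <- length(lon)
  out <- rep(NA_integer_, nq)
  live <- !is.na(lon) & !is.na(lat)
  if (!any(live)) return(out)
  # distances query x pixel; grids are small enough for the dense matrix
  D <- outer(seq_len(sum(live)), seq_len(nrow(grid)),
             function(i, j) haversine_km(lon[live][i], lat[live][i],
                                         grid$lon[j], grid$lat[j]))
  dmin <- apply(D, 1L, min)
  # lowest pixel_id among pixels within tolerance of the minimum
  pick <- apply(D <= dmin + 1e-9, 1L, which.max)  # first TRUE = lowest id
  hit <- dmin <= max_radius_km
  res <- rep(NA_integer_, sum(live))
  res[hit] <- grid$pixel_id[pick[hit]]
  out[live] <- res
  out
}
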