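#' Spatial/temporal domain of a flow field
#'
#' @param lon_min,lon_max Longitude bounds in degrees (any convention; stored
#'   on [0, 360)). After mapping, `lon_min < lon_max` must hold, so a domain
#'   crossing the antimeridian is expressed as e.g. 175 to 210.
#' @param lat_min,lat_max Latitude bounds in degrees North, within [-90, 90].
#' @param time_min,time_max Optional time span (`POSIXct` or numeric seconds);
#'   `NULL` for steady fields.
#' @return An object of class `"flow_domain"`.
#' @export
flow_domain <- function(lon_min, lon_max, lat_min, lat_max,
                        time_min = NULL, time_max = NULL) {
  lon_min <- lon360(lon_min); lon_max <- lon360(lon_max)
  if (lon_max == 0) lon_max <- 360
  if (lon_min >= lon_max)
    stopf("domain longitudes must satisfy lon_min < lon_max after mapping to [0,360): got [%g, %g]",
          lon_min, lon_max)
  if (lat_min >= lat_max || abs(lat_min) > 90 || abs(lat_max) > 90)
    stopf("domain latitudes must be ordered and within [-90, 90]")
  structure(list(lon_min = lon_min, lon_max = lon_max,
                 lat_min = lat_min, lat_max = lat_max,
                 time_min = time_min, time_max = time_max),
            class = "flow_domain")
}

in_domain <- function(domain, lon, lat) {
  lon <- lon360(lon)
  ok <- lon >= domain$lon_min & lon <= domain$lon_max &
    lat >= domain$lat_min & lat <= domain$lat_max
  ok & !is.na(ok)   # NA coordinates (already-lost particles) are off-grid
}

#' Construct an analytic horizontal velocity field
#'
#' Analytic fields stand in for ocean-model currents: they are exact,
#' steady functions of position, defined everywhere inside their domain.
#' Available kinds:
#' \describe{
#'   \item{uniform}{constant `(u0, v0)` m/s everywhere.}
#'   \item{solid_body_eddy}{solid-body rotation about `(center_lon,
#'     center_lat)`: tangential speed grows linearly from 0 at the center to
#'     `peak_ms` at `radius_km`, then decays as `radius_km/r` outside
#'     (a Rankine vortex). `cyclonic = TRUE` (default) turns
#'     counter-clockwise.}
#'   \item{zonal_jet}{eastward jet centred on latitude `lat0` with Gaussian
#'     cross-jet profile of e-folding half-width `width_km` and core speed
#'     `speed_ms` (negative for a westward jet).}
#'   \item{double_gyre}{the classical two-cell recirculation on the domain
#'     rectangle, streamfunction `A sin(2 pi x) sin(pi y)` in normalized
#'     domain coordinates, peak speed scaled to `amplitude_ms`.}
#' }
#'
#' @param kind One of `"uniform"`, `"solid_body_eddy"`, `"zonal_jet"`,
#'   `"double_gyre"`.
#' @param params Named list of kind-specific parameters (see Details).
#' @param domain A [flow_domain()].
#' @return A `"flow_field"` object of kind `"analytic"`.
#' @export
make_analytic_flow <- function(kind, params, domain) {
  kinds <- c("uniform", "solid_body_eddy", "zonal_jet", "double_gyre")
  if (!kind %in% kinds)
    stopf("unknown analytic flow kind '%s' (expected one of: %s)",
          kind, paste(kinds, collapse = ", "))
  need <- switch(kind,
    uniform        = c("u0", "v0"),
    solid_body_eddy = c("center_lon", "center_lat", "radius_km", "peak_ms"),
    zonal_jet      = c("lat0", "width_km", "speed_ms"),
    double_gyre    = "amplitude_ms")
  missing <- setdiff(need, names(params))
  if (length(missing))
    stopf("analytic flow '%s' missing params: %s", kind,
          paste(missing, collapse = ", "))
  speeds <- unlist(params[intersect(names(params),
                                    c("u0", "v0", "peak_ms", "speed_ms", "amplitude_ms"))])
  if (any(abs(speeds) > 5))
    stopf("speed parameter |%g| m/s exceeds 5 m/s; rejected as misconfiguration",
          speeds[which.max(abs(speeds))])
  if (kind == "solid_body_eddy") {
    params$center_lon <- lon360(params$center_lon)
    if (params$radius_km <= 0) stopf("eddy radius_km must be positive")
  }
  structure(list(kind = "analytic", form = kind, params = params,
                 domain = domain, steady = TRUE),
            class = c("analytic_flow", "flow_field"))
}

#' Construct a gridded velocity field from in-memory arrays
#'
#' @param lon,lat Strictly increasing coordinate vectors in degrees.
#'   Longitudes are normalized to [0, 360) (the grid is re-sorted if the
#'   normalization reorders it).
#' @param u,v Velocity arrays in m/s. Either matrices `[lat, lon]` (steady)
#'   or 3-d arrays `[time, lat, lon]`. `NA` marks masked (land) cells;
#'   non-finite values other than `NA` are rejected.
#' @param time Numeric or `POSIXct` vector of snapshot times (strictly
#'   increasing), or `NULL` for a steady field.
#' @return A `"flow_field"` object of kind `"gridded"`.
#' @export
gridded_flow <- function(lon, lat, u, v, time = NULL) {
  if (length(dim(u)) == 2) { u <- array(u, c(1, dim(u))); v <- array(v, c(1, dim(v))) }
  if (!identical(dim(u), dim(v))) stopf("u and v arrays must have identical shape")
  nt <- dim(u)[1]
  if (is.null(time)) {
    if (nt != 1) stopf("time axis required for %d snapshots", nt)
    time_num <- NULL
  } else {
    time_num <- as.numeric(time)
    if (length(time_num) != nt) stopf("time axis length %d != snapshot count %d",
                                      length(time_num), nt)
    if (nt > 1 && any(diff(time_num) <= 0)) stopf("time axis must be strictly increasing")
  }
  if (dim(u)[2] != length(lat) || dim(u)[3] != length(lon))
    stopf("velocity arrays must be [time, lat, lon] = [*, %d, %d]", length(lat), length(lon))
  lon <- lon360(lon)
  ord <- order(lon)
  if (any(diff(ord) != 1)) {      # normalization reordered the axis
    lon <- lon[ord]
    u <- u[, , ord, drop = FALSE]; v <- v[, , ord, drop = FALSE]
  }
  if (any(diff(lon) <= 0)) stopf("longitude axis must be strictly monotonic after [0,360) mapping")
  if (any(diff(lat) <= 0)) stopf("latitude axis must be strictly increasing")
  bad <- (!is.finite(u) & !is.na(u)) | (!is.finite(v) & !is.na(v))
  if (any(bad)) stopf("non-finite velocity values present (use NA for land mask)")
  domain <- flow_domain(lon[1], lon[length(lon)], lat[1], lat[length(lat)],
                        if (!is.null(time_num)) min(time_num),
                        if (!is.null(time_num)) max(time_num))
  structure(list(kind = "gridded", lon = lon, lat = lat, time = time_num,
                 u = u, v = v, domain = domain, steady = is.null(time_num)),
            class = c("gridded_flow", "flow_field"))
}

#' Read a gridded velocity field from plain-text snapshot files
#'
#' Reads the package's plain-text gridded-velocity dialect: one CSV per time
#' snapshot with columns `lon,lat,u,v` covering a full regular lon/lat grid,
#' velocities in m/s, empty cells or `NA` marking land. Lines starting with
#' `#` are metadata; a `# units: <unit>` line, if present, must declare
#' `m s-1` (or `m/s`) — any other unit is a hard error, never silently
#' converted. Longitudes in either [-180, 180) or [0, 360) are accepted and
#' stored as [0, 360).
#'
#' @param paths Character vector of snapshot CSV paths (one per time step).
#' @param times Snapshot times (numeric seconds or `POSIXct`), required when
#'   `length(paths) > 1`; a single path with `times = NULL` yields a steady
#'   field.
#' @return A `"flow_field"` object of kind `"gridded"`.
#' @export
read_gridded_flow <- function(paths, times = NULL) {
  if (length(paths) > 1 && is.null(times))
    stopf("times required for multi-snapshot fields")
  snaps <- lapply(paths, read_flow_snapshot)
  lon <- snaps[[1]]$lon; lat <- snaps[[1]]$lat
  for (s in snaps[-1])
    if (!isTRUE(all.equal(s$lon, lon)) || !isTRUE(all.equal(s$lat, lat)))
      stopf("snapshot grids differ across files")
  nt <- length(snaps)
  u <- array(NA_real_, c(nt, length(lat), length(lon)))
  v <- u
  for (k in seq_len(nt)) { u[k, , ] <- snaps[[k]]$u; v[k, , ] <- snaps[[k]]$v }
  gridded_flow(lon, lat, u, v, time = times)
}

read_flow_snapshot <- function(path) {
  if (!file.exists(path)) stopf("flow snapshot not found: %s", path)
  header <- readLines(path, n = 20L)
  meta <- grep("^#", header, value = TRUE)
  units <- sub("^#\\s*units:\\s*", "", grep("^#\\s*units:", meta, value = TRUE))
  if (length(units) && !tolower(trimws(units[1])) %in% c("m s-1", "m/s", "m s^-1"))
    stopf("velocity units '%s' are not m/s; refusing to convert silently", units[1])
  d <- utils::read.csv(path, comment.char = "#")
  need <- c("lon", "lat", "u", "v")
  if (!all(need %in% names(d)))
    stopf("flow snapshot %s must have columns lon,lat,u,v", path)
  d$lon <- lon360(d$lon)
  lon <- sort(unique(d$lon)); lat <- sort(unique(d$lat))
  if (nrow(d) != length(lon) * length(lat))
    stopf("flow snapshot %s is not a complete regular grid", path)
  iy <- match(d$lat, lat); ix <- match(d$lon, lon)
  u <- matrix(NA_real_, length(lat), length(lon)); v <- u
  u[cbind(iy, ix)] <- d$u; v[cbind(iy, ix)] <- d$v
  list(lon = lon, lat = lat, u = u, v = v)
}

#' Sample horizontal velocity at arbitrary points
#'
#' Gridded fields are interpolated bilinearly in lon/lat and linearly in
#' time; analytic fields are evaluated exactly. Queries outside the spatial
#' domain (or outside the time span of an unsteady field) return the
#' `"offgrid"` status rather than extrapolating; queries whose bilinear
#' stencil touches a masked (land) cell return `"masked"`. Velocities are
#' `NA` wherever the status is not `"ok"` — the caller decides the particle's
#' fate.
#'
#' @param flow A `"flow_field"`.
#' @param lon,lat Query coordinates (degrees), vectorized.
#' @param t Query time (numeric seconds or `POSIXct`); ignored by steady
#'   fields.
#' @return A list with numeric vectors `u`, `v` (m/s) and character vector
#'   `status` (`"ok"`, `"offgrid"`, `"masked"`).
#' @export
sample_velocity <- function(flow, lon, lat, t = NULL) UseMethod("sample_velocity")

#' @export
sample_velocity.analytic_flow <- function(flow, lon, lat, t = NULL) {
  lon <- lon360(lon)
  n <- length(lon)
  ok <- in_domain(flow$domain, lon, lat)
  u <- rep(NA_real_, n); v <- rep(NA_real_, n)
  if (any(ok)) {
    p <- flow$params
    val <- switch(flow$form,
      uniform = list(u = rep(p$u0, sum(ok)), v = rep(p$v0, sum(ok))),
      solid_body_eddy = {
        mpd <- metres_per_degree() / 1000   # km per degree
        dx <- (lon[ok] - p$center_lon) * mpd * cos(p$center_lat * pi / 180)
        dy <- (lat[ok] - p$center_lat) * mpd
        r <- sqrt(dx^2 + dy^2)
        spd <- ifelse(r <= p$radius_km, p$peak_ms * r / p$radius_km,
                      p$peak_ms * p$radius_km / pmax(r, 1e-12))
        sgn <- if (isTRUE(p$cyclonic %||% TRUE)) 1 else -1
        theta <- atan2(dy, dx)
        list(u = -sgn * spd * sin(theta), v = sgn * spd * cos(theta))
      },
      zonal_jet = {
        mpd <- metres_per_degree() / 1000
        dy <- (lat[ok] - p$lat0) * mpd
        list(u = p$speed_ms * exp(-(dy / p$width_km)^2), v = rep(0, sum(ok)))
      },
      double_gyre = {
        dm <- flow$domain
        x <- (lon[ok] - dm$lon_min) / (dm$lon_max - dm$lon_min)
        y <- (lat[ok] - dm$lat_min) / (dm$lat_max - dm$lat_min)
        list(u = -p$amplitude_ms * sin(2 * pi * x) * cos(pi * y),
             v =  p$amplitude_ms * 2 * cos(2 * pi * x) * sin(pi * y) / 2)
      })
    u[ok] <- val$u; v[ok] <- val$v
  }
  list(u = u, v = v, status = ifelse(ok, "ok", "offgrid"))
}

#' @export
sample_velocity.gridded_flow <- function(flow, lon, lat, t = NULL) {
  lon <- lon360(lon)
  n <- length(lon)
  u <- rep(NA_real_, n); v <- rep(NA_real_, n)
  status <- rep("offgrid", n)
  ok <- in_domain(flow$domain, lon, lat)
  tnum <- if (is.null(t)) NULL else as.numeric(t)
  if (!flow$steady) {
    if (is.null(tnum)) stopf("query time required for unsteady fields")
    tok <- tnum >= flow$domain$time_min & tnum <= flow$domain$time_max
    ok <- ok & if (length(tok) == 1) rep(tok, n) else tok
  }
  if (!any(ok)) return(list(u = u, v = v, status = status))

  # bracketing indices along each axis; clamp so grid-edge points use the
  # last interior cell with weight 0/1 (sampling at a node is exact)
  ix <- findInterval(lon[ok], flow$lon, rightmost.closed = TRUE)
  iy <- findInterval(lat[ok], flow$lat, rightmost.closed = TRUE)
  ix <- pmin(pmax(ix, 1L), length(flow$lon) - 1L)
  iy <- pmin(pmax(iy, 1L), length(flow$lat) - 1L)
  if (length(flow$lon) == 1L) ix <- rep(1L, sum(ok))
  if (length(flow$lat) == 1L) iy <- rep(1L, sum(ok))
  wx <- if (length(flow$lon) > 1)
    (lon[ok] - flow$lon[ix]) / (flow$lon[ix + 1L] - flow$lon[ix]) else rep(0, sum(ok))
  wy <- if (length(flow$lat) > 1)
    (lat[ok] - flow$lat[iy]) / (flow$lat[iy + 1L] - flow$lat[iy]) else rep(0, sum(ok))

  interp_snapshot <- function(arr2, ix, iy, wx, wy) {
    nx1 <- length(flow$lon) > 1; ny1 <- length(flow$lat) > 1
    g <- function(dy, dx) arr2[cbind(iy + (if (ny1) dy else 0L),
                                     ix + (if (nx1) dx else 0L))]
    # a masked corner only masks the query if its bilinear weight is
    # nonzero, so node queries return the stored node value exactly
    term <- function(val, w) ifelse(w == 0, 0, val * w)
    term(g(0L, 0L), (1 - wx) * (1 - wy)) + term(g(0L, 1L), wx * (1 - wy)) +
      term(g(1L, 0L), (1 - wx) * wy) + term(g(1L, 1L), wx * wy)
  }
  sample_at <- function(k) {
    list(u = interp_snapshot(flow$u[k, , ], ix, iy, wx, wy),
         v = interp_snapshot(flow$v[k, , ], ix, iy, wx, wy))
  }
  if (flow$steady || length(flow$time) == 1L) {
    val <- sample_at(1L)
  } else {
    it <- findInterval(tnum, flow$time, rightmost.closed = TRUE)
    it <- pmin(pmax(it, 1L), length(flow$time) - 1L)
    if (length(unique(it)) == 1L) {
      k <- it[1]
      wt <- (tnum - flow$time[k]) / (flow$time[k + 1L] - flow$time[k])
      a <- sample_at(k); b <- sample_at(k + 1L)
      val <- list(u = a$u * (1 - wt) + b$u * wt, v = a$v * (1 - wt) + b$v * wt)
    } else {
      stopf("vectorized queries must share a single time value")
    }
  }
  masked <- is.na(val$u) | is.na(val$v)
  uu <- val$u; vv <- val$v
  uu[masked] <- NA_real_; vv[masked] <- NA_real_
  u[ok] <- uu; v[ok] <- vv
  status[ok] <- ifelse(masked, "masked", "ok")
  list(u = u, v = v, status = status)
}

#' @export
print.flow_field <- function(x, ...) {
  if (x$kind == "analytic") {
    cat(sprintf("<analytic flow field: %s>\n", x$form))
    cat("  params:", paste(names(x$params), unlist(x$params), sep = "=",
                           collapse = ", "), "\n")
  } else {
    cat(sprintf("<gridded flow field: %d x %d nodes, %s>\n",
                length(x$lat), length(x$lon),
                if (x$steady) "steady" else sprintf("%d snapshots", length(x$time))))
  }
  d <- x$domain
  cat(sprintf("  domain: lon [%g, %g], lat [%g, %g]\n",
              d$lon_min, d$lon_max, d$lat_min, d$lat_max))
  invisible(x)
}
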