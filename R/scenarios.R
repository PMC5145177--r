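#' Build a linear archipelago habitat grid
#'
#' Places island centers along a great-circle bearing from an origin at a
#' fixed spacing, then lays each island's pixels on a compact ~2-km square
#' grid around its center — an idealized linear island chain of the kind
#' the tracker's connectivity statistics are designed for.
#'
#' @param n_islands Number of islands (>= 1).
#' @param pixels_per_island Pixels per island (>= 1); laid out on the
#'   smallest square grid that holds them, 2 km apart.
#' @param spacing_km Distance between successive island centers (>= 2 km).
#' @param bearing_deg Initial great-circle bearing of the chain, degrees
#'   clockwise from north (90 = eastward).
#' @param origin Numeric `c(lon, lat)` of the first island center.
#' @return A [habitat_grid()] with islands named `"I01"`, `"I02"`, ...
#' @export
make_archipelago <- function(n_islands, pixels_per_island = 4L,
                             spacing_km = 60, bearing_deg = 90,
                             origin = c(200, 20)) {
  if (n_islands < 1 || pixels_per_island < 1) stopf("counts must be positive")
  if (spacing_km < 2) stopf("spacing_km must be >= 2 km")
  side <- ceiling(sqrt(pixels_per_island))
  footprint_km <- (side - 1) * 2
  if (n_islands > 1 && spacing_km <= footprint_km * sqrt(2))
    stopf("islands would overlap: spacing %g km <= footprint %g km",
          spacing_km, footprint_km * sqrt(2))
  centers <- dest_point(origin[1], origin[2], bearing_deg,
                        (seq_len(n_islands) - 1) * spacing_km * 1000)
  # pixel offsets: compact square grid, 2 km apart, centered on the island
  ix <- (seq_len(side) - 1) - (side - 1) / 2
  off <- expand.grid(x = ix, y = ix)[seq_len(pixels_per_island), ]
  lon <- c(); lat <- c(); isl <- c()
  mpd_km <- metres_per_degree() / 1000
  for (k in seq_len(n_islands)) {
    clon <- lon360(centers[k, 1]); clat <- centers[k, 2]
    lon <- c(lon, clon + off$x * 2 / (mpd_km * cos(clat * pi / 180)))
    lat <- c(lat, clat + off$y * 2 / mpd_km)
    isl <- c(isl, rep(k, pixels_per_island))
  }
  habitat_grid(lon, lat, isl, island_name = sprintf("I%02d", isl))
}

#' Named synthetic dispersal scenarios with known expectations
#'
#' Each scenario bundles a habitat grid, a flow field, a release schedule,
#' run parameters and the analytically expected outcome, so the whole
#' pipeline can be validated end to end:
#' \describe{
#'   \item{conveyor}{`K = 0`, uniform flow tuned so each island's particles
#'     travel exactly one island spacing downstream in one pelagic larval
#'     duration: the island settlement matrix is purely superdiagonal
#'     (island k -> k+1), computable in closed form.}
#'   \item{broken_chain}{the conveyor with one inter-island gap enlarged
#'     beyond the per-PLD travel distance: zero flux across the gap — an
#'     engineered connectivity break.}
#'   \item{isolated_atoll}{a chain plus one island placed at least 10 times
#'     the 45-day advective + 3-sigma diffusive range away, under a weak
#'     retention (zero-mean) flow with diffusion: every settler at the
#'     isolated island is a self-recruit, so its self-recruitment is 1 and
#'     its source-sink index 0.}
#'   \item{diffusion_only}{zero velocity, configurable `K`: per-axis
#'     displacement variance `2*K*t` and statistically symmetric
#'     settlement.}
#' }
#'
#' @param name One of `"conveyor"`, `"broken_chain"`, `"isolated_atoll"`,
#'   `"diffusion_only"`.
#' @param n_islands Chain length (conveyor/broken chain/isolated chain).
#' @param pixels_per_island Pixels per island.
#' @param spacing_km Island spacing (conveyor-class scenarios).
#' @param params A [run_params()]; scenario-specific fields (diffusivity
#'   for the deterministic scenarios) are overridden as documented.
#' @param n_days Length of the daily release schedule.
#' @param gap_after For `broken_chain`: the gap sits after this island
#'   index (default middle of the chain).
#' @param gap_factor For `broken_chain`: the enlarged gap in units of
#'   `spacing_km` (default 3, beyond the one-spacing reach).
#' @param diffusivity For `isolated_atoll`/`diffusion_only`: K in m^2/s.
#' @return A list of class `"scenario"`: `name`, `grid`, `flow`,
#'   `schedule`, `params`, `expected` (named list of expectations with
#'   tolerances).
#' @export
scenario <- function(name = c("conveyor", "broken_chain", "isolated_atoll",
                              "diffusion_only"),
                     n_islands = 3L, pixels_per_island = 4L, spacing_km = 60,
                     params = NULL, n_days = 2L, gap_after = NULL,
                     gap_factor = 3, diffusivity = 250) {
  name <- match.arg(name)
  origin <- c(200, 20)
  schedule <- release_schedule("2011-05-01",
                               as.Date("2011-05-01") + n_days - 1)
  if (is.null(params))
    params <- run_params(particles_per_pixel_per_day = 10L, replicates = 1L)

  if (name %in% c("conveyor", "broken_chain")) {
    params$eddy_diffusivity <- 0
    gaps <- rep(spacing_km, n_islands - 1)
    if (name == "broken_chain") {
      if (is.null(gap_after)) gap_after <- max(1L, n_islands %/% 2L)
      if (gap_after < 1 || gap_after >= n_islands)
        stopf("gap_after must be in 1..%d", n_islands - 1)
      gaps[gap_after] <- gap_factor * spacing_km
      if (gap_factor <= 1.2)
        stopf("gap_factor %g leaves the gap within one-spacing reach", gap_factor)
    }
    grid <- chain_grid(n_islands, pixels_per_island, gaps, origin)
    # uniform eastward speed covering one spacing per PLD; the settlement
    # radius absorbs the small spherical-geometry curvature residual
    u0 <- spacing_km * 1000 / (params$pld_days * 86400)
    flow <- make_analytic_flow("uniform", list(u0 = u0, v0 = 0),
                               scenario_domain(grid, pad_deg = 15))
    expected <- list(
      island_pattern = if (name == "conveyor") "superdiagonal" else "superdiagonal_with_gap",
      gap_after = if (name == "broken_chain") gap_after else NA_integer_,
      settled_fraction = (n_islands - 1 - (name == "broken_chain")) / n_islands,
      tolerance = 0)
  } else if (name == "isolated_atoll") {
    params$eddy_diffusivity <- diffusivity
    grid_chain <- chain_grid(n_islands, pixels_per_island,
                             rep(spacing_km, n_islands - 1), origin)
    # isolation distance: 10 x (advective range 0 + 3 sigma of the 2-D
    # random walk over the full PLD)
    sigma_km <- sqrt(2 * diffusivity * params$pld_days * 86400) / 1000
    iso_km <- 10 * 3 * sigma_km
    iso <- dest_point(origin[1], origin[2], 180, iso_km * 1000)
    side <- ceiling(sqrt(pixels_per_island))
    mpd_km <- metres_per_degree() / 1000
    ix <- (seq_len(side) - 1) - (side - 1) / 2
    off <- expand.grid(x = ix, y = ix)[seq_len(pixels_per_island), ]
    grid <- habitat_grid(
      c(grid_chain$lon, lon360(iso[1, 1]) + off$x * 2 / (mpd_km * cos(iso[1, 2] * pi / 180))),
      c(grid_chain$lat, iso[1, 2] + off$y * 2 / mpd_km),
      c(grid_chain$island_id, rep(n_islands + 1L, pixels_per_island)),
      island_name = c(grid_chain$island_name,
                      rep("isolated", pixels_per_island)))
    flow <- make_analytic_flow("uniform", list(u0 = 0, v0 = 0),
                               scenario_domain(grid, pad_deg = 15))
    expected <- list(isolated_island = "isolated",
                     self_recruitment = 1.0, source_sink_index = 0.0,
                     tolerance = 0)   # exact, conditional on >= 1 settler
  } else {  # diffusion_only
    params$eddy_diffusivity <- diffusivity
    grid <- make_archipelago(1L, pixels_per_island, origin = origin)
    flow <- make_analytic_flow("uniform", list(u0 = 0, v0 = 0),
                               scenario_domain(grid, pad_deg = 15))
    expected <- list(displacement_variance_m2 =
                       2 * diffusivity * params$pld_days * 86400,
                     tolerance = 0.05)  # relative, at n >= 10,000
  }
  structure(list(name = name, grid = grid, flow = flow, schedule = schedule,
                 params = params, expected = expected),
            class = "scenario")
}

# great-circle destination on the package sphere; lon fed to geosphere on
# [-180, 180) to avoid its convention warnings, returned on [0, 360)
dest_point <- function(lon, lat, bearing, dist_m) {
  lon180 <- ((lon360(lon) + 180) %% 360) - 180
  p <- geosphere::destPoint(cbind(lon180, lat), b = bearing, d = dist_m,
                            a = earth_radius_km() * 1000, f = 0)
  cbind(lon360(p[, 1]), p[, 2])
}

# chain with per-gap spacings (all islands east of the previous one);
# each center is placed from the previous along the given bearing so a
# zonal conveyor stays within the settlement radius of every hop
chain_grid <- function(n_islands, pixels_per_island, gaps_km, origin,
                       bearing_deg = 90) {
  centers <- matrix(NA_real_, n_islands, 2)
  centers[1, ] <- c(lon360(origin[1]), origin[2])
  for (k in seq_len(n_islands - 1)) {
    centers[k + 1, ] <- dest_point(centers[k, 1], centers[k, 2],
                                   bearing_deg, gaps_km[k] * 1000)
  }
  side <- ceiling(sqrt(pixels_per_island))
  ix <- (seq_len(side) - 1) - (side - 1) / 2
  off <- expand.grid(x = ix, y = ix)[seq_len(pixels_per_island), ]
  mpd_km <- metres_per_degree() / 1000
  lon <- c(); lat <- c(); isl <- c()
  for (k in seq_len(n_islands)) {
    lon <- c(lon, centers[k, 1] + off$x * 2 / (mpd_km * cos(centers[k, 2] * pi / 180)))
    lat <- c(lat, centers[k, 2] + off$y * 2 / mpd_km)
    isl <- c(isl, rep(k, pixels_per_island))
  }
  habitat_grid(lon, lat, isl, island_name = sprintf("I%02d", isl))
}

scenario_domain <- function(grid, pad_deg = 15) {
  flow_domain(min(grid$lon) - pad_deg, max(grid$lon) + pad_deg,
              max(-89, min(grid$lat) - pad_deg),
              min(89, max(grid$lat) + pad_deg))
}

#' Estimate eddy diffusivity from displacement samples
#'
#' Moment estimator for the random-walk diffusivity from per-axis final
#' displacements of a zero-mean-velocity run:
#' `K_hat = (var_x + var_y) / (4 * t)`, i.e. the per-axis variance
#' estimator `var/(2t)` averaged over both axes.
#'
#' @param dx_m,dy_m Final per-axis displacements in metres (>= 100 samples).
#' @param elapsed_seconds Elapsed time of the walk (> 0).
#' @return Estimated diffusivity in m^2/s.
#' @export
estimate_diffusivity <- function(dx_m, dy_m, elapsed_seconds) {
  if (elapsed_seconds <= 0) stopf("elapsed_seconds must be positive")
  if (length(dx_m) < 100) stopf("need >= 100 displacement samples")
  (stats::var(dx_m) + stats::var(dy_m)) / (4 * elapsed_seconds)
}

#' Final displacements of a pure-diffusion ensemble, in metres
#'
#' Runs the tracker for `n` particles from one release point under the
#' scenario's flow and converts final positions to per-axis metre
#' displacements (metre/degree conversion at the release latitude; exact
#' for the zero-mean flows this is used with at sub-degree scales).
#'
#' @param sc A `"scenario"` (normally `diffusion_only`).
#' @param n Ensemble size.
#' @param seed Integer seed.
#' @return data.frame with `dx_m`, `dy_m` for particles that stayed on-grid.
#' @export
diffusion_displacements <- function(sc, n = 10000L, seed = 1L) {
  set.seed(seed)
  p0 <- c(sc$grid$lon[1], sc$grid$lat[1])
  fin <- track_particles(rep(p0[1], n), rep(p0[2], n), sc$flow, 0, sc$params)
  keep <- !fin$offgrid
  mpd <- metres_per_degree()
  dlon <- (fin$lon[keep] - p0[1] + 180) %% 360 - 180   # shortest signed arc
  data.frame(dx_m = dlon * mpd * cos(p0[2] * pi / 180),
             dy_m = (fin$lat[keep] - p0[2]) * mpd)
}

#' Brute-force connectivity oracle for deterministic (K = 0) scenarios
#'
#' Independent check of the tracker: integrates one trajectory per habitat
#' pixel with dense small-step forward-Euler advection (default dt = 60 s),
#' entirely separate from [run_experiment()]'s integrator, then applies the
#' same settlement rule and scales counts to the released totals. For K = 0
#' every particle of a pixel follows the identical path, so the resulting
#' island matrix must equal the tracker's exactly.
#'
#' @param sc A `"scenario"` with `eddy_diffusivity = 0`.
#' @param dt_seconds Dense integration step (default 60).
#' @return Island-resolution settlement matrix comparable to
#'   `bin_by_island(settlement_matrix(run_experiment(...)))`.
#' @export
brute_force_connectivity <- function(sc, dt_seconds = 60) {
  if (sc$params$eddy_diffusivity != 0)
    stopf("brute-force oracle requires a deterministic (K = 0) scenario")
  grid <- sc$grid
  n_steps <- (sc$params$pld_days * 86400) %/% dt_seconds
  mpd <- metres_per_degree()
  lon <- grid$lon; lat <- grid$lat
  lost <- rep(FALSE, length(lon))
  for (k in seq_len(n_steps)) {
    live <- !lost
    if (!any(live)) break
    s <- sample_velocity(sc$flow, lon[live], lat[live], (k - 1) * dt_seconds)
    ok <- s$status == "ok"
    coslat <- cos(lat[live] * pi / 180)
    lon[live] <- lon360(lon[live] + s$u * dt_seconds / (mpd * coslat))
    lat[live] <- lat[live] + s$v * dt_seconds / mpd
    still <- ok & in_domain(sc$flow$domain, lon[live], lat[live])
    lon[live][!still] <- NA_real_; lat[live][!still] <- NA_real_
    lost[live] <- !still
  }
  settle <- nearest_pixel(grid, lon, lat, sc$params$settle_radius_km)
  n <- nrow(grid)
  S <- matrix(0, n, n, dimnames = list(grid$pixel_id, grid$pixel_id))
  per_pixel <- sc$params$particles_per_pixel_per_day * length(sc$schedule)
  hit <- !is.na(settle)
  for (i in which(hit))
    S[i, match(settle[i], grid$pixel_id)] <-
      S[i, match(settle[i], grid$pixel_id)] + per_pixel
  attr(S, "resolution") <- "pixel"
  bin_by_island(S, grid)
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("<scenario '%s': %d pixels / %d islands, %d release days>\n",
              x$name, nrow(x$grid), n_islands(x$grid), length(x$schedule)))
  invisible(x)
}
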