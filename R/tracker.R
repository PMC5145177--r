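#' Simulation parameters for the dispersal tracker
#'
#' Defaults are the study conditions of the archipelago-scale experiment the
#' package models: a 45-day pelagic larval duration, settlement within 5 km
#' of a habitat pixel center evaluated on the last day only, scalar eddy
#' diffusivity 250 m^2/s, 50 particles per pixel per release day, and three
#' averaged replicates.
#'
#' @param pld_days Pelagic larval duration in days; settlement is evaluated
#'   once, at the end of day `pld_days`.
#' @param settle_radius_km Settlement radius around a pixel center, km.
#' @param eddy_diffusivity Horizontal eddy diffusivity K in m^2/s; the
#'   unresolved turbulence is a Gaussian random walk with per-axis variance
#'   `2*K*dt` per step.
#' @param dt_seconds Integration time step; must divide `pld_days` days
#'   evenly.
#' @param particles_per_pixel_per_day Particles released at each habitat
#'   pixel on each release day.
#' @param integrator `"rk4"` (classical 4-stage, default) or `"euler"`.
#' @param replicates Number of independent replicate runs to average.
#' @param seed Master seed; per-(replicate, cohort) streams are derived from
#'   it (see [run_experiment()]).
#' @return A list of class `"run_params"`.
#' @export
run_params <- function(pld_days = 45L, settle_radius_km = 5.0,
                       eddy_diffusivity = 250.0, dt_seconds = 3600L,
                       particles_per_pixel_per_day = 50L,
                       integrator = c("rk4", "euler"),
                       replicates = 3L, seed = 1L) {
  integrator <- match.arg(integrator)
  num <- c(pld_days = pld_days, settle_radius_km = settle_radius_km,
           dt_seconds = dt_seconds,
           particles_per_pixel_per_day = particles_per_pixel_per_day,
           replicates = replicates)
  if (any(!is.finite(num)) || any(num <= 0))
    stopf("run_params: %s must all be positive",
          paste(names(num), collapse = ", "))
  if (eddy_diffusivity < 0) stopf("eddy_diffusivity must be >= 0")
  if ((pld_days * 86400) %% dt_seconds != 0)
    stopf("dt_seconds (%d) must divide the PLD (%d days) evenly",
          dt_seconds, pld_days)
  structure(list(pld_days = as.integer(pld_days),
                 settle_radius_km = settle_radius_km,
                 eddy_diffusivity = eddy_diffusivity,
                 dt_seconds = as.integer(dt_seconds),
                 particles_per_pixel_per_day = as.integer(particles_per_pixel_per_day),
                 integrator = integrator,
                 replicates = as.integer(replicates),
                 seed = as.integer(seed)),
            class = "run_params")
}

#' Daily release schedule
#'
#' Daily release dates from `start` to `end` inclusive, optionally
#' restricted to calendar months. The default span is the five-year
#' experiment window 2009-05-02 through 2014-04-10 (1805 release days).
#'
#' @param start,end Dates (or strings coercible to `Date`), inclusive.
#' @param months Optional integer vector of calendar months (1-12) to keep.
#' @return A `Date` vector of class `c("release_schedule", "Date")`.
#' @export
release_schedule <- function(start = "2009-05-02", end = "2014-04-10",
                             months = NULL) {
  start <- as.Date(start); end <- as.Date(end)
  if (end < start) stopf("schedule end precedes start")
  dates <- seq(start, end, by = "day")
  if (!is.null(months)) {
    if (!length(months) || !all(months %in% 1:12))
      stopf("months must be a non-empty subset of 1..12")
    dates <- dates[as.integer(format(dates, "%m")) %in% months]
  }
  structure(dates, class = c("release_schedule", "Date"))
}

#' Count release events implied by a schedule
#'
#' Enumerates `length(schedule) * n_pixels * particles_per_pixel_per_day`
#' per replicate without instantiating particles.
#'
#' @param schedule A [release_schedule()].
#' @param n_pixels Number of habitat pixels.
#' @param params A [run_params()].
#' @return Named numeric vector with `per_replicate` and `total` counts.
#' @export
count_releases <- function(schedule, n_pixels, params = run_params()) {
  per <- as.numeric(length(schedule)) * n_pixels *
    params$particles_per_pixel_per_day
  c(per_replicate = per, total = per * params$replicates)
}

# degrees moved per stage, given velocities (m/s) at stage positions.
# metre->degree conversion uses the stage latitude; hard error near poles
# where the cos(lat) factor degenerates.
vel_to_deg <- function(u, v, lat) {
  coslat <- cos(lat * pi / 180)
  if (any(coslat <= 0.01, na.rm = TRUE))
    stopf("tracking poleward of +-89.4 degrees is outside the intended domain")
  mpd <- metres_per_degree()
  list(dlon = u / (mpd * coslat), dlat = v / mpd)
}

#' One advection-diffusion step for an ensemble of particles
#'
#' Advances particle positions by one time step: a deterministic advection
#' displacement from the interpolated flow (forward Euler or classical RK4
#' in lon/lat with per-stage metre-to-degree conversion at the local
#' latitude), followed by independent Gaussian random-walk increments per
#' horizontal axis with standard deviation `sqrt(2*K*dt)` metres. Any
#' particle whose stage or final position falls outside the flow domain (or
#' on a masked cell) is returned as `NA`/`"offgrid"` — the caller treats it
#' as lost. Randomness comes from R's global RNG stream; seed it (or use
#' [run_experiment()]'s derived streams) for reproducibility.
#'
#' @param lon,lat Current positions (degrees), vectorized.
#' @param flow A `"flow_field"`.
#' @param t Time at the start of the step (seconds, numeric or `POSIXct`).
#' @param params A [run_params()] (uses `dt_seconds`, `eddy_diffusivity`,
#'   `integrator`).
#' @return List with `lon`, `lat` (NA where lost) and logical `offgrid`.
#' @export
advect_diffuse_step <- function(lon, lat, flow, t, params) {
  dt <- params$dt_seconds
  K <- params$eddy_diffusivity
  n <- length(lon)
  tnum <- as.numeric(t)

  stage <- function(ln, lt, tt) {
    s <- sample_velocity(flow, ln, lt, tt)
    ok <- s$status == "ok"
    d <- vel_to_deg(s$u, s$v, lt)
    list(dlon = d$dlon, dlat = d$dlat, ok = ok)
  }

  s1 <- stage(lon, lat, tnum)
  if (params$integrator == "euler") {
    new_lon <- lon + s1$dlon * dt
    new_lat <- lat + s1$dlat * dt
    ok <- s1$ok
  } else {
    s2 <- stage(lon + s1$dlon * dt / 2, lat + s1$dlat * dt / 2, tnum + dt / 2)
    s3 <- stage(lon + s2$dlon * dt / 2, lat + s2$dlat * dt / 2, tnum + dt / 2)
    s4 <- stage(lon + s3$dlon * dt,     lat + s3$dlat * dt,     tnum + dt)
    new_lon <- lon + dt / 6 * (s1$dlon + 2 * s2$dlon + 2 * s3$dlon + s4$dlon)
    new_lat <- lat + dt / 6 * (s1$dlat + 2 * s2$dlat + 2 * s3$dlat + s4$dlat)
    ok <- s1$ok & s2$ok & s3$ok & s4$ok
  }

  if (K > 0) {
    sd_m <- sqrt(2 * K * dt)
    dx <- stats::rnorm(n, 0, sd_m)
    dy <- stats::rnorm(n, 0, sd_m)
    d <- vel_to_deg(dx, dy, new_lat)   # metres -> degrees at post-advection latitude
    new_lon <- new_lon + d$dlon
    new_lat <- new_lat + d$dlat
  }
  new_lon <- lon360(new_lon)
  inside <- ok & in_domain(flow$domain, new_lon, new_lat)
  new_lon[!inside] <- NA_real_
  new_lat[!inside] <- NA_real_
  list(lon = new_lon, lat = new_lat, offgrid = !inside)
}

#' Integrate an ensemble of particles over the full pelagic duration
#'
#' Applies [advect_diffuse_step()] for `pld_days * 86400 / dt_seconds`
#' steps. A particle that leaves the flow domain at any step stays lost (no
#' re-entry); its final position is `NA`.
#'
#' @param lon0,lat0 Release positions (degrees), vectorized.
#' @param flow A `"flow_field"`.
#' @param t0 Release time in seconds (numeric or `POSIXct`).
#' @param params A [run_params()].
#' @return List with final `lon`, `lat` (NA = lost off-grid) and logical
#'   `offgrid`.
#' @export
track_particles <- function(lon0, lat0, flow, t0, params) {
  n_steps <- (params$pld_days * 86400) %/% params$dt_seconds
  lon <- lon360(lon0); lat <- lat0
  lost <- rep(FALSE, length(lon))
  tnum <- as.numeric(t0)
  for (k in seq_len(n_steps)) {
    live <- !lost
    if (!any(live)) break
    stp <- advect_diffuse_step(lon[live], lat[live], flow,
                               tnum + (k - 1) * params$dt_seconds, params)
    lon[live] <- stp$lon
    lat[live] <- stp$lat
    lost[live] <- stp$offgrid
  }
  list(lon = lon, lat = lat, offgrid = lost)
}

#' Integrate a single particle (scalar convenience wrapper)
#'
#' @inheritParams track_particles
#' @param pos0 Numeric `c(lon, lat)` release position in degrees.
#' @return Numeric `c(lon, lat)` day-PLD position, or `c(NA, NA)` if the
#'   particle left the domain.
#' @export
integrate_particle <- function(pos0, flow, t0, params) {
  r <- track_particles(pos0[1], pos0[2], flow, t0, params)
  c(lon = r$lon, lat = r$lat)
}

#' Run one daily release cohort and evaluate settlement
#'
#' Releases `particles_per_pixel_per_day` particles at every habitat pixel
#' center at 00:00 UTC of `release_date`, integrates each over the pelagic
#' larval duration, and evaluates settlement once, on the final day: a
#' particle settles onto the nearest habitat pixel whose center is within
#' `settle_radius_km` (ties to the lowest `pixel_id`); otherwise it is lost.
#' Fates partition all released particles: `settled`, `lost_offgrid` (left
#' the flow domain), `lost_unsettled` (finished the PLD away from habitat).
#'
#' @param grid A [habitat_grid()].
#' @param flow A `"flow_field"`.
#' @param release_date A `Date` (or string coercible to one).
#' @param params A [run_params()].
#' @param replicate Integer replicate index recorded in the output.
#' @param seed Optional integer; when given, seeds the RNG for this cohort.
#' @return A `data.frame` of class `"settlement_events"` with columns
#'   `replicate, release_date, release_pixel, fate, settle_pixel,
#'   displacement_km`. `displacement_km` is release-pixel-center to
#'   settled-pixel-center for settled particles, to the final position for
#'   `lost_unsettled`, and `NA` for `lost_offgrid`.
#' @export
run_cohort <- function(grid, flow, release_date, params,
                       replicate = 1L, seed = NULL) {
  if (nrow(grid) == 0) stopf("empty habitat grid")
  if (!is.null(seed)) set.seed(seed)
  release_date <- as.Date(release_date)
  ppp <- params$particles_per_pixel_per_day
  src <- rep(seq_len(nrow(grid)), each = ppp)      # row index into grid
  t0 <- as.numeric(as.POSIXct(paste(release_date, "00:00:00"), tz = "UTC"))
  if (!flow$steady) {
    if (t0 < flow$domain$time_min ||
        t0 + params$pld_days * 86400 > flow$domain$time_max)
      stopf("release %s + PLD not covered by the flow field's time span",
            as.character(release_date))
  }
  fin <- track_particles(grid$lon[src], grid$lat[src], flow, t0, params)

  settle <- nearest_pixel(grid, fin$lon, fin$lat, params$settle_radius_km)
  fate <- ifelse(fin$offgrid, "lost_offgrid",
                 ifelse(is.na(settle), "lost_unsettled", "settled"))
  disp <- rep(NA_real_, length(src))
  uns <- fate == "lost_unsettled"
  disp[uns] <- haversine_km(grid$lon[src][uns], grid$lat[src][uns],
                            fin$lon[uns], fin$lat[uns])
  st <- fate == "settled"
  if (any(st)) {
    dst <- match(settle[st], grid$pixel_id)
    disp[st] <- haversine_km(grid$lon[src][st], grid$lat[src][st],
                             grid$lon[dst], grid$lat[dst])
  }
  ev <- data.frame(replicate = as.integer(replicate),
                   release_date = release_date,
                   release_pixel = grid$pixel_id[src],
                   fate = fate,
                   settle_pixel = settle,
                   displacement_km = disp,
                   stringsAsFactors = FALSE)
  class(ev) <- c("settlement_events", "data.frame")
  ev
}

# documented seed-derivation scheme: one independent, order-independent
# stream per (replicate, cohort); kept below 2^31 - 1
cohort_seed <- function(master, replicate, cohort_index) {
  as.integer((as.numeric(master) + 999983 * replicate + 7919 * cohort_index) %%
               2147483647)
}

#' Run the full dispersal experiment (all cohorts, all replicates)
#'
#' Runs every daily cohort of the schedule for each replicate. Each
#' (replicate, cohort) pair gets its own RNG stream derived from the master
#' seed by a fixed counter scheme, so results are deterministic for a fixed
#' seed and independent of cohort execution order. Set
#' `options(reefconn.verbose = TRUE)` for per-cohort progress messages.
#'
#' @param grid A [habitat_grid()].
#' @param flow A `"flow_field"`.
#' @param schedule A [release_schedule()].
#' @param params A [run_params()] (uses `replicates` and `seed`).
#' @return A `"settlement_events"` data.frame covering all replicates.
#' @export
run_experiment <- function(grid, flow, schedule, params = run_params()) {
  out <- vector("list", params$replicates * length(schedule))
  k <- 0L
  for (r in seq_len(params$replicates)) {
    for (ci in seq_along(schedule)) {
      k <- k + 1L
      if (isTRUE(getOption("reefconn.verbose", FALSE)))
        message(sprintf("replicate %d cohort %s (%d/%d)", r,
                        as.character(schedule[ci]), ci, length(schedule)))
      out[[k]] <- run_cohort(grid, flow, schedule[ci], params,
                             replicate = r,
                             seed = cohort_seed(params$seed, r, ci))
    }
  }
  ev <- do.call(rbind, out)
  rownames(ev) <- NULL
  class(ev) <- c("settlement_events", "data.frame")
  ev
}

#' Average settlement matrices across replicates
#'
#' @param matrices List of same-shape settlement matrices.
#' @return Elementwise mean matrix (real-valued), keeping dimnames and the
#'   `resolution` attribute of the first element.
#' @export
average_replicates <- function(matrices) {
  if (!length(matrices)) stopf("need at least one matrix")
  dims <- lapply(matrices, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    stopf("matrices must share a common shape")
  out <- Reduce(`+`, matrices) / length(matrices)
  attr(out, "resolution") <- attr(matrices[[1]], "resolution")
  out
}
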