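test_that("run_params validates positivity and dt/PLD divisibility", {
  expect_error(run_params(pld_days = 0), "positive")
  expect_error(run_params(eddy_diffusivity = -1), ">= 0")
  expect_error(run_params(pld_days = 1, dt_seconds = 7000), "divide")
  p <- run_params()
  expect_equal(p$pld_days, 45L)
  expect_equal(p$eddy_diffusivity, 250)
  expect_equal(p$settle_radius_km, 5)
  expect_equal(p$particles_per_pixel_per_day, 50L)
  expect_equal(p$replicates, 3L)
})

test_that("the default schedule enumerates the full experiment size", {
  sch <- release_schedule()
  expect_equal(length(sch), 1805L)
  expect_equal(unname(count_releases(sch, 687)["per_replicate"]), 62001750)
})

test_that("pure advection follows the closed-form displacement", {
  fl <- uniform_flow(0.5, 0)
  p1 <- run_params(pld_days = 1, dt_seconds = 86400,
                   eddy_diffusivity = 0, integrator = "euler")
  s <- advect_diffuse_step(200, 0, fl, 0, p1)
  expect_equal(s$lon, 200 + 0.5 * 86400 / (pi * 6371000 / 180),
               tolerance = 1e-12)   # 200.3885 degrees
  expect_equal(s$lat, 0)

  # zero flow, K = 0: identity
  z <- advect_diffuse_step(c(200, 210), c(0, 20), uniform_flow(0, 0), 0, p1)
  expect_equal(z$lon, c(200, 210))
  expect_equal(z$lat, c(0, 20))

  # 45 days at 0.5 m/s: 1944 km east at the equator, < 0.1% of planar form
  p45 <- run_params(eddy_diffusivity = 0)
  fin <- integrate_particle(c(200, 0), fl, 0, p45)
  expect_equal(unname(fin["lon"]), 200 + 17.48281, tolerance = 1e-4)
  expect_lt(abs(haversine_km(200, 0, fin["lon"], fin["lat"]) - 1944) / 1944,
            1e-3)
})

test_that("particles leaving the domain are lost without re-entry", {
  box <- make_analytic_flow("uniform", list(u0 = 1, v0 = 0),
                            flow_domain(200, 201, -0.5, 0.5))
  p <- run_params(pld_days = 45, eddy_diffusivity = 0)
  fin <- track_particles(200.5, 0, box, 0, p)   # exits after ~0.64 days
  expect_true(fin$offgrid)
  expect_true(is.na(fin$lon))
})

test_that("diffusion matches the 2Kt random-walk variance law", {
  fl <- uniform_flow(0, 0)
  p <- run_params(pld_days = 1, dt_seconds = 3600, eddy_diffusivity = 250)
  set.seed(99)
  n <- 10000
  fin <- track_particles(rep(200, n), rep(0, n), fl, 0, p)
  mpd <- pi * 6371000 / 180
  dx <- (fin$lon - 200) * mpd
  dy <- (fin$lat - 0) * mpd
  target <- 2 * 250 * 86400
  expect_lt(abs(var(dx) - target) / target, 0.05)
  expect_lt(abs(var(dy) - target) / target, 0.05)
  expect_lt(abs(mean(dx)) / sqrt(target / n), 4)   # mean ~ 0 within 4 SE
  expect_lt(abs(mean(dy)) / sqrt(target / n), 4)
})

test_that("rk4 positions converge under dt halving on the double gyre", {
  dom <- flow_domain(190, 210, 10, 30)
  fl <- make_analytic_flow("double_gyre", list(amplitude_ms = 0.4), dom)
  run_dt <- function(dt) {
    p <- run_params(pld_days = 45, dt_seconds = dt, eddy_diffusivity = 0)
    track_particles(c(195, 205, 199), c(15, 25, 21), fl, 0, p)
  }
  a <- run_dt(3600); b <- run_dt(1800)
  expect_lt(max(abs(a$lon - b$lon), abs(a$lat - b$lat)), 1e-3)
})

test_that("tracking near the poles is refused", {
  wide <- make_analytic_flow("uniform", list(u0 = 0, v0 = 0),
                             flow_domain(0, 359, -89.9, 89.9))
  p <- run_params(pld_days = 1, dt_seconds = 86400, eddy_diffusivity = 0)
  expect_error(advect_diffuse_step(10, 89.8, wide, 0, p), "poleward")
})

test_that("cohorts settle by geometry: retention, conveyor hop, loss", {
  p <- run_params(pld_days = 45, eddy_diffusivity = 0,
                  particles_per_pixel_per_day = 10L, replicates = 1L)
  g1 <- habitat_grid(200, 20, 1)
  still <- run_cohort(g1, uniform_flow(0, 0), "2011-05-01", p)
  expect_equal(nrow(still), 10)
  expect_true(all(still$fate == "settled"))
  expect_true(all(still$settle_pixel == 0))
  expect_true(all(still$displacement_km == 0))

  # uniform flow carrying exactly 10 km downstream in 45 d settles on the
  # downstream pixel of a 10-km-spaced pair
  mpd <- pi * 6371 / 180
  g2 <- habitat_grid(c(200, 200 + 10 / (mpd * cos(20 * pi / 180))),
                     c(20, 20), c(1, 2))
  u10 <- 10000 / (45 * 86400)
  hop <- run_cohort(g2, uniform_flow(u10, 0, test_domain()), "2011-05-01", p)
  from_up <- hop[hop$release_pixel == 0, ]
  expect_true(all(from_up$fate == "settled"))
  expect_true(all(from_up$settle_pixel == 1))
  expect_equal(from_up$displacement_km, rep(10, 10), tolerance = 1e-6)

  # flow carrying 500 km away from all habitat loses everything
  u500 <- 500000 / (45 * 86400)
  gone <- run_cohort(g1, uniform_flow(u500, 0, test_domain()), "2011-05-01", p)
  expect_true(all(gone$fate == "lost_unsettled"))
})

test_that("fates partition all released particles (conservation)", {
  sc <- scenario("isolated_atoll", n_islands = 2, pixels_per_island = 4,
                 params = run_params(particles_per_pixel_per_day = 5L,
                                     replicates = 2L, seed = 3L),
                 n_days = 2)
  ev <- run_experiment(sc$grid, sc$flow, sc$schedule, sc$params)
  expect_equal(nrow(ev),
               2 * length(sc$schedule) * nrow(sc$grid) * 5)
  expect_equal(sort(unique(ev$fate)),
               sort(intersect(c("settled", "lost_offgrid", "lost_unsettled"),
                              ev$fate)))
  expect_false(anyNA(ev$fate))
  # settled records always carry a pixel and a displacement
  st <- ev[ev$fate == "settled", ]
  expect_false(anyNA(st$settle_pixel))
  expect_false(anyNA(st$displacement_km))
})

test_that("a fixed master seed reproduces the experiment exactly", {
  sc <- scenario("diffusion_only", pixels_per_island = 2,
                 params = run_params(particles_per_pixel_per_day = 5L,
                                     replicates = 2L, seed = 42L,
                                     pld_days = 2L),
                 n_days = 2)
  ev1 <- run_experiment(sc$grid, sc$flow, sc$schedule, sc$params)
  ev2 <- run_experiment(sc$grid, sc$flow, sc$schedule, sc$params)
  expect_identical(ev1, ev2)
})

test_that("replicate averaging is the elementwise mean", {
  m1 <- matrix(2, 1, 1); m2 <- matrix(4, 1, 1)
  expect_equal(average_replicates(list(m1, m2)), matrix(3, 1, 1))
  expect_equal(average_replicates(list(m1)), m1)
  expect_equal(average_replicates(list(m2, m2, m2)), m2)
  expect_error(average_replicates(list(m1, matrix(0, 2, 2))), "shape")
})

test_that("unsteady flows reject releases outside their time span", {
  u <- array(0, c(2, 2, 2))
  t0 <- as.numeric(as.POSIXct("2011-05-01", tz = "UTC"))
  fl <- gridded_flow(c(150, 260), c(-20, 45), u, u,
                     time = c(t0, t0 + 50 * 86400))
  g <- habitat_grid(200, 20, 1)
  p <- run_params(pld_days = 2, eddy_diffusivity = 0,
                  particles_per_pixel_per_day = 2L, replicates = 1L)
  ok <- run_cohort(g, fl, "2011-05-02", p)
  expect_true(all(ok$fate == "settled"))
  expect_error(run_cohort(g, fl, "2011-06-29", p), "time span")
})
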