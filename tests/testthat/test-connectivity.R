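test_that("settlement matrices count settled particles only", {
  g <- two_pixel_grid()
  ev <- events_from_counts(data.frame(from = c(0, 0), to = c(1, 0),
                                      n = c(3, 1)))
  S <- settlement_matrix(ev, g)
  expect_equal(S["0", "1"], 3)
  expect_equal(S["0", "0"], 1)
  expect_equal(sum(S), 4)

  lost <- ev; lost$fate <- "lost_unsettled"; lost$settle_pixel <- NA
  expect_equal(sum(settlement_matrix(lost, g)), 0)

  # replicates combined without averaging sum their counts
  both <- rbind(ev, events_from_counts(data.frame(from = 0, to = 1, n = 2),
                                       replicate = 2L))
  class(both) <- class(ev)
  expect_equal(sum(settlement_matrix(both, g)), 6)
  byrep <- settlement_matrix(both, g, by_replicate = TRUE)
  expect_equal(sum(byrep[["1"]]), 4)
  expect_equal(sum(byrep[["2"]]), 2)
})

test_that("island binning sums blocks and conserves totals", {
  g <- habitat_grid(c(200, 200.02), c(20, 20), c(1, 1))   # one island
  S <- matrix(c(1, 3, 2, 4), 2, 2, dimnames = list(0:1, 0:1))
  attr(S, "resolution") <- "pixel"
  M <- bin_by_island(S, g)
  expect_equal(unname(M[1, 1]), 10)

  # identity mapping (1 pixel per island) leaves the matrix unchanged
  g2 <- two_pixel_grid()
  M2 <- bin_by_island(S, g2)
  expect_equal(unclass(M2), S, ignore_attr = TRUE)

  # conservation on a random case
  set.seed(8)
  g3 <- make_archipelago(3, 3, spacing_km = 50)
  S3 <- matrix(rpois(81, 2), 9, 9, dimnames = list(0:8, 0:8))
  attr(S3, "resolution") <- "pixel"
  expect_equal(sum(bin_by_island(S3, g3)), sum(S3))
})

test_that("rearward and forward normalizations match hand computation", {
  S <- S22()   # [[8,2],[0,4]]
  R <- rearward_probability(S)
  expect_equal(unname(R["A", ]), c(1, 0))             # receiving A: 8/8, 0/8
  expect_equal(unname(R["B", ]), c(1 / 3, 2 / 3))     # receiving B: 2/6, 4/6
  Fw <- forward_probability(S)
  expect_equal(unname(Fw["A", ]), c(0.8, 0.2))
  expect_equal(unname(Fw["B", ]), c(0, 1))
  # diagonal-only matrix maps to the identity pattern both ways
  Dg <- matrix(diag(c(5, 7)), 2, 2, dimnames = dimnames(S))
  expect_equal(unclass(rearward_probability(Dg)), diag(2), ignore_attr = TRUE)
  expect_equal(unclass(forward_probability(Dg)), diag(2), ignore_attr = TRUE)
})

test_that("probability rows sum to exactly 1 or 0, zero rows flagged", {
  set.seed(13)
  for (k in 1:20) {
    n <- sample(3:8, 1)
    S <- matrix(rpois(n * n, 1.2), n, n,
                dimnames = list(letters[1:n], letters[1:n]))
    S[, sample(n, 1)] <- 0          # force at least one empty receiver
    R <- rearward_probability(S)
    Fw <- forward_probability(S)
    expect_true(all(R >= 0 & R <= 1))
    expect_true(all(Fw >= 0 & Fw <= 1))
    rs <- rowSums(R); fs <- rowSums(Fw)
    expect_true(all(abs(rs - 1) < 1e-12 | rs == 0))
    expect_true(all(abs(fs - 1) < 1e-12 | fs == 0))
    expect_true(all(rowSums(R[attr(R, "empty"), , drop = FALSE]) == 0))
  }
})

test_that("difference matrices require a common direction tag", {
  S <- S22()
  A <- forward_probability(S)
  B <- forward_probability(t(unclass(S)) |>
                             (\(m) {dimnames(m) <- dimnames(S); m})())
  D <- matrix_difference(A, B)
  expect_equal(unclass(D), unclass(A) - unclass(B), ignore_attr = TRUE)
  expect_equal(unclass(matrix_difference(A, A)),
               matrix(0, 2, 2, dimnames = dimnames(S)), ignore_attr = TRUE)
  expect_error(matrix_difference(A, rearward_probability(S)), "forward")
})

test_that("self-recruitment equals the rearward diagonal; NA when empty", {
  S <- S22()
  expect_equal(unname(self_recruitment(S)), c(1, 2 / 3))
  expect_equal(unname(self_recruitment(S)),
               unname(diag(unclass(rearward_probability(S)))))
  # island receiving only from elsewhere has SR 0; empty receiver is NA
  S2 <- matrix(c(0, 5, 3, 0), 2, 2, dimnames = list(1:2, 1:2))
  expect_equal(unname(self_recruitment(S2)), c(0, 0))
  S3 <- matrix(c(2, 0, 0, 0), 2, 2, dimnames = list(1:2, 1:2))
  expect_true(is.na(self_recruitment(S3)[2]))
})

test_that("source-sink index spans [-1, 1] with the documented conventions", {
  # pure exporter/pure sink attain the bounds
  S <- matrix(c(0, 0, 10, 0), 2, 2, dimnames = list(1:2, 1:2))
  expect_equal(unname(source_sink_index(S)), c(1, -1))
  # balanced self-recruiter and zero-flux islands sit at 0
  S2 <- matrix(diag(c(7, 0)), 2, 2, dimnames = list(1:2, 1:2))
  expect_equal(unname(source_sink_index(S2)), c(0, 0))
  # worked example: E = (10, 4), I = (8, 6)
  expect_equal(unname(source_sink_index(S22())), c(2 / 18, -0.2))
  # antisymmetry when the only flux is between two islands
  set.seed(21)
  for (k in 1:10) {
    S3 <- matrix(0, 2, 2, dimnames = list(1:2, 1:2))
    S3[1, 2] <- rpois(1, 5) + 1
    S3[2, 1] <- rpois(1, 3)
    ssi <- source_sink_index(S3)
    expect_equal(ssi[[1]], -ssi[[2]])
    expect_true(all(abs(ssi) <= 1))
  }
})

test_that("island mean dispersal distance is the settler-weighted mean", {
  # 5 settlers at 100 km and 5 at 200 km into one island -> 150 km
  g <- habitat_grid(c(200, 201, 202), c(0, 0, 0), c(1, 2, 3))
  S <- matrix(0, 3, 3, dimnames = list(0:2, 0:2))
  S[1, 3] <- 5; S[2, 3] <- 5
  attr(S, "resolution") <- "pixel"
  D <- matrix(0, 3, 3); D[1, 3] <- 100; D[2, 3] <- 200
  D <- D + t(D)
  md <- island_mean_dispersal_distance(S, D, g)
  expect_equal(unname(md), c(NA, NA, 150))
  # all settlement on release pixels -> 0 km; bounded by contributing pairs
  S0 <- matrix(diag(3), 3, 3, dimnames = list(0:2, 0:2))
  attr(S0, "resolution") <- "pixel"
  expect_equal(unname(island_mean_dispersal_distance(S0, D, g)), c(0, 0, 0))
  expect_true(md[3] >= 100 && md[3] <= 200)
})

test_that("weighted-mean identity ties island distances to event displacements", {
  sc <- scenario("conveyor", n_islands = 3, pixels_per_island = 4, n_days = 1)
  ev <- run_experiment(sc$grid, sc$flow, sc$schedule, sc$params)
  S <- settlement_matrix(ev, sc$grid)
  D <- pixel_distance_matrix(sc$grid)
  md <- island_mean_dispersal_distance(S, D, sc$grid)
  SI <- bin_by_island(S, sc$grid)
  lhs <- sum(colSums(SI) * md, na.rm = TRUE)
  rhs <- sum(ev$displacement_km[ev$fate == "settled"])
  expect_equal(lhs, rhs, tolerance = 1e-9)
})

test_that("dispersal distance summaries match hand-computed statistics", {
  mk <- function(d) {
    ev <- data.frame(replicate = 1L, release_date = as.Date("2011-05-01"),
                     release_pixel = 0L, fate = "settled", settle_pixel = 0L,
                     displacement_km = 0)[rep(1, length(d)), , drop = FALSE]
    ev$displacement_km <- d
    class(ev) <- c("settlement_events", "data.frame"); ev
  }
  s1 <- dispersal_distance_summary(mk(100))
  expect_equal(c(s1$mean_km, s1$median_km), c(100, 100))
  expect_true(is.na(s1$se_km))
  s2 <- dispersal_distance_summary(mk(c(0, 100)))
  expect_equal(c(s2$mean_km, s2$median_km), c(50, 50))
  # right tail drives the mean above the median
  s3 <- dispersal_distance_summary(mk(c(0, 0, 0, 400)))
  expect_equal(c(s3$mean_km, s3$median_km), c(100, 0))
  expect_equal(s3$se_km, sd(c(0, 0, 0, 400)) / 2)
  expect_true(all(s3$kernel$distance_km >= 0))
  expect_error(dispersal_distance_summary(mk(numeric(0))), "no settled")
})

test_that("settlement time series attributes success to the release date", {
  g <- habitat_grid(200, 20, 1)
  sch <- release_schedule("2011-05-01", "2011-05-02")
  ev <- rbind(
    data.frame(replicate = 1L, release_date = as.Date("2011-05-01"),
               release_pixel = 0L,
               fate = c(rep("settled", 7), rep("lost_unsettled", 93)),
               settle_pixel = c(rep(0L, 7), rep(NA, 93)),
               displacement_km = 0),
    data.frame(replicate = 1L, release_date = as.Date("2011-05-02"),
               release_pixel = 0L, fate = "lost_unsettled",
               settle_pixel = NA_integer_, displacement_km = NA)[rep(1, 100), ])
  class(ev) <- c("settlement_events", "data.frame")
  ts <- settlement_time_series(ev, sch)
  expect_equal(ts$fraction, c(0.07, 0))
  # replicate averaging: 7 and 9 settlers of 100 -> 0.08
  ev2 <- ev; ev2$replicate <- 2L
  ev2$fate[1:100] <- c(rep("settled", 9), rep("lost_unsettled", 91))
  both <- rbind(ev, ev2); class(both) <- class(ev)
  expect_equal(settlement_time_series(both, sch)$fraction[1], 0.08)
})

test_that("island settlement fractions partition total settlement", {
  sc <- scenario("conveyor", n_islands = 3, pixels_per_island = 4, n_days = 1)
  ev <- run_experiment(sc$grid, sc$flow, sc$schedule, sc$params)
  fr <- island_settlement_fraction(ev, sc$grid)
  expect_equal(sum(fr), mean(ev$fate == "settled"), tolerance = 1e-12)
  # per-island-release denominator variant
  fr2 <- island_settlement_fraction(ev, sc$grid,
                                    denominator = "island_releases")
  expect_true(all(fr2 >= 0 & fr2 <= 1))
})

test_that("month filtering subsets schedules and events consistently", {
  sch <- release_schedule("2009-05-02", "2009-07-31")
  expect_equal(length(filter_by_release_months(sch, c(5, 6))), 60L)
  expect_equal(length(filter_by_release_months(sch, 1:12)), length(sch))
  g <- habitat_grid(200, 20, 1)
  ev <- data.frame(replicate = 1L, release_date = as.Date(sch),
                   release_pixel = 0L, fate = "lost_unsettled",
                   settle_pixel = NA_integer_, displacement_km = NA)
  class(ev) <- c("settlement_events", "data.frame")
  expect_equal(nrow(filter_by_release_months(ev, c(5, 6))), 60L)
  expect_equal(nrow(filter_by_release_months(ev, 2)), 0L)
  expect_error(filter_by_release_months(ev, integer(0)), "months")
})

test_that("Mantel r is exact under identity and affine maps of a matrix", {
  set.seed(31)
  A <- matrix(runif(64), 8, 8)
  self <- mantel_test(A, A, n_perm = 199, seed = 1)
  expect_equal(self$r, 1)
  expect_equal(self$p, 1 / 200)
  aff <- mantel_test(A, 2 * A + 0.3, n_perm = 99, seed = 1)
  expect_equal(aff$r, 1)
  expect_error(mantel_test(A, A[1:2, 1:2], 99), "square")
  expect_warning(m0 <- mantel_test(A, matrix(1, 8, 8), 99), "constant")
  expect_true(is.na(m0$r))
})

test_that("Mantel agrees with vegan on symmetric distance matrices", {
  skip_if_not_installed("vegan")
  set.seed(32)
  D1 <- as.matrix(dist(matrix(rnorm(30), 10, 3)))
  D2 <- as.matrix(dist(matrix(rnorm(30), 10, 3)))
  vr <- vegan::mantel(as.dist(D1), as.dist(D2), permutations = 0)$statistic
  expect_equal(mantel_test(D1, D2, n_perm = 99, seed = 1)$r, unname(vr),
               tolerance = 1e-12)
})

test_that("Mantel p-values are calibrated under the null", {
  set.seed(33)
  ps <- replicate(200, {
    A <- matrix(runif(100), 10, 10)
    B <- matrix(runif(100), 10, 10)
    mantel_test(A, B, n_perm = 199)$p
  })
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})
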