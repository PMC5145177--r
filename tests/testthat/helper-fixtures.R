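# shared fixtures: tiny grids, flows and event tables built in code

# wide steady domain around the default scenario origin
test_domain <- function() flow_domain(150, 260, -20, 45)

uniform_flow <- function(u0 = 0.5, v0 = 0, domain = test_domain())
  make_analytic_flow("uniform", list(u0 = u0, v0 = v0), domain)

# two-island, one-pixel-each grid a fixed distance apart on the equator
two_pixel_grid <- function(sep_deg = 1)
  habitat_grid(lon = c(200, 200 + sep_deg), lat = c(0, 0), island_id = c(1, 2))

# hand-built settled events: one row per particle
events_from_counts <- function(counts, replicate = 1L) {
  # counts: data.frame(from, to, n)
  rows <- do.call(rbind, lapply(seq_len(nrow(counts)), function(k) {
    data.frame(replicate = replicate,
               release_date = as.Date("2011-05-01"),
               release_pixel = counts$from[k], fate = "settled",
               settle_pixel = counts$to[k],
               displacement_km = counts$d_km[k] %||% 0)
  }))
  ev <- rows[rep(seq_len(nrow(rows)), counts$n), , drop = FALSE]
  rownames(ev) <- NULL
  class(ev) <- c("settlement_events", "data.frame")
  ev
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# the worked two-island settlement matrix used across statistic tests
S22 <- function() {
  S <- matrix(c(8, 0, 2, 4), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  attr(S, "resolution") <- "island"
  S
}

# small CSV flow snapshot on disk
write_snapshot <- function(path, lon, lat, u, v, units = "m s-1") {
  g <- expand.grid(lon = lon, lat = lat)
  g$u <- as.vector(t(u)); g$v <- as.vector(t(v))
  writeLines(c(sprintf("# units: %s", units), "lon,lat,u,v",
               sprintf("%g,%g,%g,%g", g$lon, g$lat, g$u, g$v)), path)
  path
}
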