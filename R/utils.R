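#' Spherical-Earth radius used throughout the package
#'
#' Mean Earth radius in kilometres. All great-circle math in the package
#' (distances, metre/degree conversions in the tracker) uses this single
#' constant so it can be overridden consistently.
#'
#' @return Numeric scalar, km.
#' @export
earth_radius_km <- function() getOption("reefconn.earth_radius_km", 6371.0)

#' Normalize longitudes to the [0, 360) convention
#'
#' The package stores all longitudes on [0, 360) so that domains crossing
#' the antimeridian (e.g. an archipelago spanning 175E to 150W) are
#' contiguous in coordinate space.
#'
#' @param lon Numeric vector of longitudes in degrees, any convention.
#' @return Longitudes mapped to [0, 360).
#' @export
lon360 <- function(lon) {
  out <- lon %% 360
  out[out < 0] <- out[out < 0] + 360
  out
}

# metres spanned by one degree of latitude (and of longitude at the equator)
metres_per_degree <- function() pi * earth_radius_km() * 1000 / 180

`%||%` <- function(x, y) if (is.null(x)) y else x

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
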