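#' Pixel-resolution settlement matrix from tracked events
#'
#' Builds the square count matrix `S[i, j]` of particles released at pixel
#' `i` that settled at pixel `j`. Lost particles are excluded; the grand
#' total equals the number of settled events. Events from several
#' replicates sum unless split with `by_replicate` and averaged via
#' [average_replicates()].
#'
#' @param events A `"settlement_events"` data.frame.
#' @param grid The [habitat_grid()] the events refer to.
#' @param by_replicate If `TRUE`, return a list of matrices, one per
#'   replicate present in `events`.
#' @return A matrix (or list of matrices) with dimnames = pixel ids and
#'   attribute `resolution = "pixel"`.
#' @export
settlement_matrix <- function(events, grid, by_replicate = FALSE) {
  if (by_replicate) {
    reps <- sort(unique(events$replicate))
    out <- lapply(reps, function(r)
      settlement_matrix(events[events$replicate == r, , drop = FALSE], grid))
    names(out) <- reps
    return(out)
  }
  ids <- grid$pixel_id
  st <- events[events$fate == "settled", , drop = FALSE]
  if (nrow(st) && (!all(st$release_pixel %in% ids) ||
                   !all(st$settle_pixel %in% ids)))
    stopf("events reference pixel ids absent from the habitat grid")
  f <- factor(st$release_pixel, levels = ids)
  g <- factor(st$settle_pixel, levels = ids)
  S <- unclass(table(f, g))
  dimnames(S) <- list(ids, ids)
  S <- S * 1.0
  attr(S, "resolution") <- "pixel"
  S
}

#' Bin a pixel settlement matrix by island
#'
#' Island entry (a, b) sums `S[i, j]` over pixels `i` of island `a` and
#' `j` of island `b`; the grand total is preserved. Island order is the
#' habitat grid's first-appearance order.
#'
#' @param S A pixel-resolution settlement (or product) matrix in
#'   `pixel_id` order.
#' @param grid The matching [habitat_grid()].
#' @return Island-resolution matrix with island-name dimnames and
#'   attribute `resolution = "island"`.
#' @export
bin_by_island <- function(S, grid) {
  if (identical(attr(S, "resolution"), "island"))
    stopf("matrix is already island resolution")
  if (nrow(S) != nrow(grid))
    stopf("matrix size %d does not match %d habitat pixels", nrow(S), nrow(grid))
  islands <- attr(grid, "islands")
  fac <- factor(grid$island_name[order(grid$pixel_id)], levels = islands)
  if (anyNA(fac)) stopf("pixel without island mapping")
  M <- rowsum(S, fac)                 # collapse rows
  M <- t(rowsum(t(M), fac))           # collapse columns
  M <- M[islands, islands, drop = FALSE]
  attr(M, "resolution") <- "island"
  M
}

prob_matrix <- function(P, direction, empty) {
  attr(P, "direction") <- direction
  attr(P, "empty") <- empty          # labels of all-zero (flagged) rows
  class(P) <- c("probability_matrix", class(P))
  P
}

#' Rearward (receiving-normalized) probability matrix
#'
#' Output row `r` is indexed by the RECEIVING island and holds the origin
#' composition of its settlers: entry (r, i) = `S[i, r] / sum_i' S[i', r]`.
#' Rows of islands with at least one settler sum to exactly 1; islands with
#' no settlers yield all-zero rows, flagged in the `"empty"` attribute. The
#' diagonal is each island's self-recruitment.
#'
#' @param S Square (island-resolution) settlement matrix.
#' @return A `"probability_matrix"` with `direction = "rearward"`.
#' @export
rearward_probability <- function(S) {
  if (nrow(S) != ncol(S)) stopf("settlement matrix must be square")
  colsum <- colSums(S)
  P <- t(S) / ifelse(colsum > 0, colsum, 1)   # row r of P = column r of S, normalized
  P[colsum == 0, ] <- 0
  dimnames(P) <- list(colnames(S), rownames(S))
  prob_matrix(P, "rearward", colnames(S)[colsum == 0])
}

#' Forward (source-normalized) probability matrix
#'
#' Row `s` is indexed by the SOURCE island and holds the destination
#' composition of its successful particles: entry (s, j) =
#' `S[s, j] / sum_j' S[s, j']`. Sources with no successful particles yield
#' flagged all-zero rows.
#'
#' @param S Square (island-resolution) settlement matrix.
#' @return A `"probability_matrix"` with `direction = "forward"`.
#' @export
forward_probability <- function(S) {
  if (nrow(S) != ncol(S)) stopf("settlement matrix must be square")
  rowsum_ <- rowSums(S)
  P <- S / ifelse(rowsum_ > 0, rowsum_, 1)
  P[rowsum_ == 0, ] <- 0
  prob_matrix(unclass(P), "forward", rownames(S)[rowsum_ == 0])
}

#' Difference between two probability matrices
#'
#' Elementwise `A - B`, e.g. a seasonal-release matrix minus the year-round
#' matrix. Matrices must share shape and direction tag: forward is only
#' compared with forward, rearward with rearward.
#'
#' @param A,B `"probability_matrix"` objects of the same direction.
#' @return Signed matrix `A - B` with a `direction` attribute.
#' @export
matrix_difference <- function(A, B) {
  da <- attr(A, "direction"); db <- attr(B, "direction")
  if (!is.null(da) && !is.null(db) && !identical(da, db))
    stopf("cannot subtract a %s matrix from a %s matrix", db, da)
  if (!identical(dim(A), dim(B))) stopf("matrices must share a common shape")
  D <- unclass(A) - unclass(B)
  attr(D, "direction") <- da
  attr(D, "empty") <- NULL
  D
}

#' Permutation Mantel test between two square matrices
#'
#' Pearson correlation between corresponding cells of `A` and `B`, with a
#' permutation null formed by relabeling `B`'s sites: each permutation
#' reorders `B`'s rows and columns simultaneously by one random
#' permutation, as connectivity matrices are asymmetric and row/column `k`
#' refer to the same site. The diagonal is excluded by default so
#' self-recruitment does not dominate the correlation; set
#' `include_diagonal = TRUE` for the variant that keeps it. One-sided
#' p-value: `(count of permuted r >= observed r + 1) / (n_perm + 1)`.
#'
#' @param A,B Square numeric matrices of identical size (n >= 3).
#' @param n_perm Number of permutations (>= 99; default 999).
#' @param seed Optional integer seed for the permutation stream.
#' @param include_diagonal Keep the diagonal cells in the correlation?
#' @return List with `r` (Pearson correlation; `NA` with a warning if
#'   either matrix is constant over the compared cells), `p` (permutation
#'   p-value, `NA` when r is undefined) and `n_perm`.
#' @export
mantel_test <- function(A, B, n_perm = 999L, seed = NULL,
                        include_diagonal = FALSE) {
  n <- nrow(A)
  if (n < 3 || nrow(B) != n || ncol(A) != n || ncol(B) != n)
    stopf("mantel_test needs two square matrices of equal size, n >= 3")
  if (n_perm < 99) stopf("n_perm must be >= 99")
  if (!is.null(seed)) set.seed(seed)
  keep <- if (include_diagonal) matrix(TRUE, n, n) else !diag(n)
  a <- unclass(A)[keep]; b <- unclass(B)[keep]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("constant matrix: Mantel r undefined")
    return(list(r = NA_real_, p = NA_real_, n_perm = as.integer(n_perm)))
  }
  r_obs <- stats::cor(a, b)
  Bm <- unclass(B)
  r_perm <- vapply(seq_len(n_perm), function(i) {
    p <- sample.int(n)
    stats::cor(a, Bm[p, p][keep])
  }, numeric(1))
  p_val <- (sum(r_perm >= r_obs) + 1) / (n_perm + 1)
  list(r = r_obs, p = p_val, n_perm = as.integer(n_perm))
}

#' Per-island self-recruitment
#'
#' Fraction of each island's settlers that originated from that same
#' island: `SR[a] = S[a, a] / sum_i S[i, a]`. Equals the diagonal of the
#' rearward probability matrix. Islands with no settlers are `NA`
#' (undefined), never 0.
#'
#' @param S Square (island-resolution) settlement matrix.
#' @return Named numeric vector in [0, 1] (or `NA`).
#' @export
self_recruitment <- function(S) {
  if (nrow(S) != ncol(S)) stopf("settlement matrix must be square")
  settlers <- colSums(S)
  out <- ifelse(settlers > 0, diag(as.matrix(S)) / settlers, NA_real_)
  names(out) <- colnames(S)
  out
}

#' Per-island source-sink index
#'
#' With export `E[a] = sum_j S[a, j]` (all settled particles released from
#' `a`, self-recruits included) and import `I[a] = sum_i S[i, a]` (all
#' settlers arriving at `a`, self-recruits included), the index is
#' `(E - I) / (E + I)`: +1 for a pure source, -1 for a pure sink, 0 when
#' fluxes balance — including the degenerate balanced case of an island
#' whose only settlers are its own self-recruits, and 0 (by convention)
#' when `E + I = 0`.
#'
#' @param S Square (island-resolution) settlement matrix.
#' @return Named numeric vector in [-1, 1].
#' @export
source_sink_index <- function(S) {
  if (nrow(S) != ncol(S)) stopf("settlement matrix must be square")
  E <- rowSums(S); I <- colSums(S)
  tot <- E + I
  out <- ifelse(tot > 0, (E - I) / tot, 0)
  names(out) <- rownames(S)
  out
}

#' Mean dispersal distance of settlers at each island
#'
#' Forms the pixel product matrix `P = S * D` (elementwise), bins both `P`
#' and `S` by island, and divides island column sums of the product matrix
#' by island column sums of the settlement matrix: the settler-weighted
#' mean transport distance to each receiving island. Islands with no
#' settlers are `NA`.
#'
#' @param S Pixel-resolution settlement matrix.
#' @param D Pixel-resolution great-circle [pixel_distance_matrix()].
#' @param grid The matching [habitat_grid()].
#' @return Named numeric vector of km per island.
#' @export
island_mean_dispersal_distance <- function(S, D, grid) {
  if (!identical(dim(S), dim(D)))
    stopf("settlement and distance matrices must share a common shape")
  P <- unclass(S) * D
  attr(P, "resolution") <- "pixel"
  PI <- bin_by_island(P, grid)
  SI <- bin_by_island(S, grid)
  settlers <- colSums(SI)
  out <- ifelse(settlers > 0, colSums(PI) / settlers, NA_real_)
  names(out) <- colnames(SI)
  out
}

#' Summary statistics and density kernel of dispersal distances
#'
#' Statistics over the per-particle transport distance of settled
#' particles: mean, median, standard error (`sd/sqrt(n)`, `NA` for a single
#' settler), and a Gaussian kernel density with Silverman's bandwidth on a
#' stated grid.
#'
#' @param events A `"settlement_events"` data.frame.
#' @param kernel_n Number of kernel grid points (default 512).
#' @return List with `n`, `mean_km`, `median_km`, `se_km` and a
#'   `kernel` data.frame (`distance_km`, `density`).
#' @export
dispersal_distance_summary <- function(events, kernel_n = 512L) {
  d <- events$displacement_km[events$fate == "settled"]
  if (!length(d)) stopf("no settled events")
  se <- if (length(d) > 1) stats::sd(d) / sqrt(length(d)) else NA_real_
  kern <- if (length(d) > 1 && stats::sd(d) > 0) {
    k <- stats::density(d, bw = "nrd0", n = kernel_n, from = 0)
    data.frame(distance_km = k$x, density = k$y)
  } else {
    data.frame(distance_km = d[1], density = Inf)[0, ]
  }
  list(n = length(d), mean_km = mean(d), median_km = stats::median(d),
       se_km = se, kernel = kern)
}

#' Daily settlement-success time series
#'
#' For each release date of the schedule: settled particles of that cohort
#' divided by particles released that day. Settlement is attributed to the
#' RELEASE date, so the series reflects spawning-date success. Multiple
#' replicates average (each replicate releases the same count).
#'
#' @param events A `"settlement_events"` data.frame.
#' @param schedule A [release_schedule()] covering the events.
#' @return A data.frame `release_date, released, settled, fraction`
#'   (released and settled are per-replicate means).
#' @export
settlement_time_series <- function(events, schedule) {
  dates <- as.Date(schedule)
  n_rep <- length(unique(events$replicate))
  f <- factor(as.character(events$release_date), levels = as.character(dates))
  released <- as.vector(table(f)) / n_rep
  settled <- as.vector(table(f[events$fate == "settled"])) / n_rep
  data.frame(release_date = dates, released = released, settled = settled,
             fraction = ifelse(released > 0, settled / released, 0))
}

#' Per-island settlement fraction over the whole run
#'
#' Settlers arriving at each island across the run divided by a common
#' denominator: by default every particle released archipelago-wide over
#' the period (`denominator = "all_releases"`), so the fractions over all
#' islands sum to the overall settlement fraction. The alternative
#' `"island_releases"` divides by each island's own released count.
#' Replicates average.
#'
#' @param events A `"settlement_events"` data.frame.
#' @param grid The matching [habitat_grid()].
#' @param denominator `"all_releases"` (default) or `"island_releases"`.
#' @return Named numeric vector of per-island fractions.
#' @export
island_settlement_fraction <- function(events, grid,
                                       denominator = c("all_releases",
                                                       "island_releases")) {
  denominator <- match.arg(denominator)
  islands <- attr(grid, "islands")
  n_rep <- length(unique(events$replicate))
  isl_of <- function(pix) grid$island_name[match(pix, grid$pixel_id)]
  st <- events[events$fate == "settled", , drop = FALSE]
  arr <- table(factor(isl_of(st$settle_pixel), levels = islands)) / n_rep
  denom <- if (denominator == "all_releases") {
    rep(nrow(events) / n_rep, length(islands))
  } else {
    as.vector(table(factor(isl_of(events$release_pixel), levels = islands))) / n_rep
  }
  out <- ifelse(denom > 0, as.vector(arr) / denom, 0)
  names(out) <- islands
  out
}

#' Restrict events or a schedule to given release months
#'
#' Keeps records whose release date falls in the given calendar months
#' (default May-June, the peak spawning season). All downstream metrics can
#' be recomputed on the subset — seasonal analyses are a post-hoc filter on
#' one particle set, not a separate simulation.
#'
#' @param x A `"settlement_events"` data.frame or a [release_schedule()].
#' @param months Non-empty integer subset of 1..12 (default `c(5, 6)`).
#' @return Object of the same class, filtered.
#' @export
filter_by_release_months <- function(x, months = c(5L, 6L)) {
  if (!length(months) || !all(months %in% 1:12))
    stopf("months must be a non-empty subset of 1..12")
  if (inherits(x, "release_schedule")) {
    structure(unclass(x)[as.integer(format(as.Date(x), "%m")) %in% months],
              class = c("release_schedule", "Date"))
  } else if (is.data.frame(x)) {
    keep <- as.integer(format(as.Date(x$release_date), "%m")) %in% months
    x[keep, , drop = FALSE]
  } else stopf("cannot month-filter a %s", class(x)[1])
}

#' One-table connectivity summary per island
#'
#' Convenience wrapper assembling self-recruitment, source-sink index, mean
#' dispersal distance and settlement fraction into one data.frame.
#'
#' @param events A `"settlement_events"` data.frame.
#' @param grid The matching [habitat_grid()].
#' @return data.frame with one row per island.
#' @export
connectivity_summary <- function(events, grid) {
  S <- settlement_matrix(events, grid)
  SI <- bin_by_island(S, grid)
  D <- pixel_distance_matrix(grid)
  data.frame(island = attr(grid, "islands"),
             self_recruitment = unname(self_recruitment(SI)),
             source_sink_index = unname(source_sink_index(SI)),
             mean_dispersal_km = unname(island_mean_dispersal_distance(S, D, grid)),
             settlement_fraction = unname(island_settlement_fraction(events, grid)))
}
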