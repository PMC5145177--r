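#' Write a connectivity matrix to CSV
#'
#' Island (or pixel) labels form the first row and column; a `#` comment
#' header records the direction/orientation tag so readers can refuse to
#' mix forward and rearward matrices.
#'
#' @param M Matrix with dimnames (settlement, probability or difference).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_matrix_csv <- function(M, path) {
  con <- file(path, "w")
  on.exit(close(con))
  dir_tag <- attr(M, "direction") %||% "counts"
  res_tag <- attr(M, "resolution") %||% "island"
  writeLines(sprintf("# direction: %s", dir_tag), con)
  writeLines(sprintf("# resolution: %s", res_tag), con)
  writeLines("# orientation: rows = receiving site for rearward, source site otherwise",
             con)
  utils::write.csv(as.data.frame(unclass(M)), con, row.names = TRUE)
  invisible(path)
}

#' Read a connectivity matrix written by [write_matrix_csv()]
#'
#' @param path CSV path.
#' @return Matrix with `direction` and `resolution` attributes restored.
#' @export
read_matrix_csv <- function(path) {
  if (!file.exists(path)) stopf("matrix file not found: %s", path)
  hdr <- grep("^#", readLines(path, n = 10L), value = TRUE)
  tag <- function(key, default) {
    m <- grep(sprintf("^#\\s*%s:", key), hdr, value = TRUE)
    if (length(m)) trimws(sub(sprintf("^#\\s*%s:", key), "", m[1])) else default
  }
  d <- utils::read.csv(path, comment.char = "#", row.names = 1,
                       check.names = FALSE)
  M <- as.matrix(d)
  direction <- tag("direction", "counts")
  if (direction %in% c("forward", "rearward"))
    M <- prob_matrix(M, direction, character())
  else attr(M, "direction") <- direction
  attr(M, "resolution") <- tag("resolution", "island")
  M
}

#' Write settlement events to CSV
#'
#' Stable column set `replicate, release_date, release_pixel, fate,
#' settle_pixel, displacement_km`; dates ISO-8601.
#'
#' @param events A `"settlement_events"` data.frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_events_csv <- function(events, path) {
  out <- events
  out$release_date <- format(as.Date(out$release_date), "%Y-%m-%d")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read settlement events written by [write_events_csv()]
#' @param path CSV path.
#' @return A `"settlement_events"` data.frame.
#' @export
read_events_csv <- function(path) {
  if (!file.exists(path)) stopf("events file not found: %s", path)
  ev <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("NA", ""))
  ev$release_date <- as.Date(ev$release_date)
  ev$settle_pixel <- as.integer(ev$settle_pixel)
  class(ev) <- c("settlement_events", "data.frame")
  ev
}

#' Heatmap of a connectivity matrix
#'
#' Linear color scale; cells that are exactly zero render white, so absent
#' connections are visually distinct from weak ones. Writes a PNG when
#' `path` is given, else draws on the active device.
#'
#' @param M Matrix with dimnames.
#' @param path Optional PNG output path.
#' @param main Plot title.
#' @return `path` (or `NULL`), invisibly.
#' @export
plot_matrix_heatmap <- function(M, path = NULL, main = NULL) {
  M <- unclass(M)
  if (!is.null(path)) {
    grDevices::png(path, width = 900, height = 800)
    on.exit(grDevices::dev.off())
  }
  n <- nrow(M)
  pal <- c("white", grDevices::hcl.colors(63, "YlOrRd", rev = TRUE))
  zmax <- max(M, 1e-12)
  breaks <- c(-1e-12, 1e-12, seq(1e-12, zmax, length.out = 63)[-1], zmax + 1e-9)
  op <- graphics::par(mar = c(6, 6, 3, 1))
  on.exit(graphics::par(op), add = TRUE)
  graphics::image(seq_len(n), seq_len(n), t(M[n:1, , drop = FALSE]),
                  col = pal, breaks = unique(breaks), axes = FALSE,
                  xlab = "", ylab = "", main = main)
  graphics::axis(1, at = seq_len(n), labels = colnames(M), las = 2, cex.axis = 0.7)
  graphics::axis(2, at = seq_len(n), labels = rev(rownames(M)), las = 2, cex.axis = 0.7)
  invisible(path)
}
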