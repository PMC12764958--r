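#' Detect the skin surface in a reconstructed image
#'
#' Per lateral position, the surface is the first depth at which intensity
#' exceeds an adaptive threshold (a fraction of that column's maximum, so
#' detection is invariant to global intensity scaling), median-smoothed
#' across positions. Relies on the bright superficial melanin band.
#'
#' @param image A [recon_image()] (2D).
#' @param threshold_frac Fraction of the column maximum.
#' @param median_window Lateral median filter width (odd).
#' @param detect_floor Columns whose maximum is below this fraction of the
#'   image maximum are deemed surface-free.
#' @return Object of class `skin_surface`: `row` (first-surface voxel index
#'   per column), `depth_um`, and the smoothing window used.
#' @export
detect_surface <- function(image, threshold_frac = 0.5, median_window = 7,
                           detect_floor = 0.05) {
  stopifnot(inherits(image, "recon_image"), is.matrix(image$data))
  d <- image$data
  gmax <- max(d)
  if (gmax <= 0) stop("surface detection failed: image is empty (all zero)")
  nxc <- ncol(d)
  rows <- rep(NA_integer_, nxc)
  for (j in seq_len(nxc)) {
    m <- max(d[, j])
    if (m < detect_floor * gmax) next
    rows[j] <- which(d[, j] >= threshold_frac * m)[1]
  }
  bad <- mean(is.na(rows))
  if (bad > 0.2)
    stop(sprintf("surface detection failed on %.0f%% of columns (> 20%%)", 100 * bad))
  if (any(is.na(rows))) rows[is.na(rows)] <- stats::median(rows, na.rm = TRUE)
  k <- min(median_window, nxc - (1 - nxc %% 2))
  rows <- as.integer(stats::runmed(rows, k = max(1, k)))
  structure(list(row = rows, depth_um = (rows - 0.5) * image$grid$dz_um,
                 median_window = median_window),
            class = "skin_surface")
}

#' Flatten an image to its detected skin surface
#'
#' Shifts each column so the surface maps to depth 0; voxels shifted in from
#' outside are zero. The per-column shifts are retained so [unflatten()] can
#' invert the operation (up to edge padding).
#'
#' @param image A [recon_image()] (2D).
#' @param surface A [detect_surface()] result for this image.
#' @return Flattened [recon_image()] with `$flattened = TRUE` and
#'   `$surface` retained.
#' @export
flatten <- function(image, surface) {
  stopifnot(inherits(image, "recon_image"), inherits(surface, "skin_surface"),
            length(surface$row) == ncol(image$data))
  d <- image$data; nz <- nrow(d)
  out <- matrix(0, nz, ncol(d))
  for (j in seq_len(ncol(d))) {
    s <- surface$row[j] - 1L
    if (s <= 0) out[, j] <- d[, j]
    else out[1:(nz - s), j] <- d[(s + 1):nz, j]
  }
  im <- recon_image(out, image$grid, bands = image$bands)
  im$flattened <- TRUE
  im$surface <- surface
  im
}

#' @rdname flatten
#' @export
unflatten <- function(image) {
  stopifnot(inherits(image, "recon_image"), isTRUE(image$flattened),
            !is.null(image$surface))
  d <- image$data; nz <- nrow(d)
  out <- matrix(0, nz, ncol(d))
  for (j in seq_len(ncol(d))) {
    s <- image$surface$row[j] - 1L
    if (s <= 0) out[, j] <- d[, j]
    else out[(s + 1):nz, j] <- d[1:(nz - s), j]
  }
  recon_image(out, image$grid, bands = image$bands)
}

#' Skin layer bounds in flattened coordinates
#'
#' Contiguous depth intervals: epidermis EP `[0, d_ep)`, subpapillary dermis
#' SD `[d_ep, d_ep + d_sd)`, reticular dermis RD `[d_ep + d_sd, d_max)`.
#' The whole dermal vasculature DV is SD plus RD.
#'
#' @param d_ep_um Epidermis thickness, um.
#' @param d_sd_um Subpapillary dermis thickness, um.
#' @param d_max_um Total analyzed depth, um.
#' @return Object of class `layer_bounds`.
#' @export
layer_bounds <- function(d_ep_um, d_sd_um, d_max_um) {
  if (!(d_ep_um > 0 && d_sd_um > 0 && d_max_um > d_ep_um + d_sd_um))
    stop("layer bounds must be contiguous with positive lengths")
  structure(list(d_ep_um = d_ep_um, d_sd_um = d_sd_um, d_max_um = d_max_um,
                 EP = c(0, d_ep_um), SD = c(d_ep_um, d_ep_um + d_sd_um),
                 RD = c(d_ep_um + d_sd_um, d_max_um)),
            class = "layer_bounds")
}

#' @export
print.layer_bounds <- function(x, ...) {
  cat(sprintf("layers (flattened): EP [0, %g) um | SD [%g, %g) um | RD [%g, %g) um\n",
              x$d_ep_um, x$SD[1], x$SD[2], x$RD[1], x$RD[2]))
  invisible(x)
}

#' Depth-row masks for the skin layers
#'
#' @param bounds A [layer_bounds()].
#' @param nz Number of depth voxels.
#' @param dz_um Depth voxel size, um (voxel centers at `(i - 0.5) * dz_um`).
#' @return Named list of logical row masks `EP`, `SD`, `RD`, `DV`.
#' @export
layer_masks <- function(bounds, nz, dz_um) {
  stopifnot(inherits(bounds, "layer_bounds"))
  zc <- (seq_len(nz) - 0.5) * dz_um
  m <- list(EP = zc < bounds$d_ep_um,
            SD = zc >= bounds$SD[1] & zc < bounds$SD[2],
            RD = zc >= bounds$RD[1] & zc < bounds$RD[2])
  m$DV <- m$SD | m$RD
  m
}

#' Segment a flattened image into skin layers
#'
#' The epidermis/dermis boundary is found adaptively as the first depth at
#' which the laterally-averaged intensity falls below a set fraction of its
#' superficial (melanin band) peak, bounded to a plausible range; outside
#' that range the configured default is used with a warning. The SD/RD split
#' is a fixed configurable depth below the epidermal boundary (the authors'
#' automatic layer algorithm is unpublished; these depths are honest,
#' tunable stand-ins).
#'
#' @param flat A flattened [recon_image()].
#' @param d_sd_um SD thickness below the epidermal boundary, um.
#' @param ep_range_um Plausible epidermis thickness range, um.
#' @param drop_frac Fraction of the superficial peak defining the boundary.
#' @param d_ep_default_um Fallback epidermis thickness, um.
#' @return A [layer_bounds()] with the configuration echoed in
#'   `attr(, "config")`.
#' @export
segment_layers <- function(flat, d_sd_um = 200, ep_range_um = c(60, 200),
                           drop_frac = 0.3, d_ep_default_um = 100) {
  stopifnot(inherits(flat, "recon_image"), is.matrix(flat$data))
  dz <- flat$grid$dz_um
  p <- rowMeans(flat$data)
  zc <- (seq_along(p) - 0.5) * dz
  sup <- zc <= ep_range_um[2]
  pk_i <- which.max(p[sup])
  pk <- p[sup][pk_i]
  d_ep <- NA_real_
  if (pk > 0) {
    below <- which(p < drop_frac * pk & seq_along(p) > pk_i)
    if (length(below)) d_ep <- zc[below[1]]
  }
  if (is.na(d_ep) || d_ep < ep_range_um[1] || d_ep > ep_range_um[2]) {
    warning(sprintf("epidermal boundary %s outside plausible range [%g, %g] um; using default %g um",
                    ifelse(is.na(d_ep), "undetected", sprintf("%.0f um", d_ep)),
                    ep_range_um[1], ep_range_um[2], d_ep_default_um))
    d_ep <- d_ep_default_um
  }
  b <- layer_bounds(d_ep, d_sd_um, nrow(flat$data) * dz)
  attr(b, "config") <- list(d_sd_um = d_sd_um, ep_range_um = ep_range_um,
                            drop_frac = drop_frac,
                            d_ep_default_um = d_ep_default_um)
  b
}

#' Serialize layer bounds to a JSON sidecar
#'
#' @param bounds A [layer_bounds()].
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_layer_bounds <- function(bounds, path) {
  stopifnot(inherits(bounds, "layer_bounds"))
  jsonlite::write_json(unclass(bounds), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
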