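#' Layer-mean intensity profiles from a flattened frame series
#'
#' For each frame, the mean image intensity over each layer's depth mask
#' (EP, SD, RD) and over the whole dermal vasculature DV (= SD plus RD,
#' computed over the union mask so that DV equals the voxel-count-weighted
#' combination of SD and RD).
#'
#' @param frames List of flattened [recon_image()] sharing one grid.
#' @param bounds A [layer_bounds()].
#' @param protocol A [porh_protocol()] (frame times).
#' @param layers Which profiles to return.
#' @param normalize Divide each profile by its baseline mean.
#' @return Named list of [intensity_profile()].
#' @export
layer_profile <- function(frames, bounds, protocol,
                          layers = c("EP", "SD", "RD", "DV"),
                          normalize = FALSE) {
  stopifnot(length(frames) >= 1, inherits(frames[[1]], "recon_image"))
  tt <- protocol_times(protocol)
  if (length(tt) != length(frames))
    stop("number of frames does not match the protocol's frame count")
  nz <- nrow(frames[[1]]$data)
  masks <- layer_masks(bounds, nz, frames[[1]]$grid$dz_um)
  out <- list()
  for (ly in layers) {
    m <- masks[[ly]]
    if (!any(m)) stop("empty layer mask: ", ly)
    y <- vapply(frames, function(f) mean(f$data[m, , drop = FALSE]),
                numeric(1))
    if (normalize) {
      mvb <- mean(y[tt < protocol$t_baseline_end])
      if (mvb <= 0) stop("cannot normalize: baseline mean is not positive")
      y <- y / mvb
    }
    out[[ly]] <- intensity_profile(tt, y, layer = ly, protocol = protocol,
                                   normalized = normalize)
  }
  out
}

# bilinear interpolation of matrix m at fractional (row, col)
bilinear <- function(m, r, c) {
  r <- pmin(pmax(r, 1), nrow(m)); c <- pmin(pmax(c, 1), ncol(m))
  r0 <- pmin(floor(r), nrow(m) - 1L); c0 <- pmin(floor(c), ncol(m) - 1L)
  fr <- r - r0; fc <- c - c0
  m[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    m[cbind(r0 + 1, c0)] * fr * (1 - fc) +
    m[cbind(r0, c0 + 1)] * (1 - fr) * fc +
    m[cbind(r0 + 1, c0 + 1)] * fr * fc
}

#' Vessel diameter as full width at half maximum
#'
#' Extracts a 1D intensity profile through a vessel's local maximum along a
#' given direction and returns the distance between the half-maximum
#' crossings nearest the peak, with linear sub-sample interpolation.
#' Background is the median of the profile's outer edges. The seed point is
#' first refined to the brightest voxel in a small neighborhood.
#'
#' @param image A [recon_image()] (2D) or matrix.
#' @param seed_point `c(row, col)` voxel indices near the vessel center.
#' @param direction `"lateral"` (along x), `"axial"` (along z), or a numeric
#'   `c(dz, dx)` unit direction in voxel space.
#' @param voxel_um Physical step per voxel along the direction; taken from
#'   the image grid for the named directions.
#' @param window_um Half-length of the extracted profile, um.
#' @param refine_vox Neighborhood radius (voxels) for peak refinement.
#' @param edge_frac Fraction of profile ends used for the background median.
#' @return FWHM in um, or `NA` (with attribute `reason`) when no
#'   half-maximum crossing lies within the window.
#' @examples
#' # Gaussian cross-section of sd 30 um on a 5 um grid: FWHM ~ 2.3548 * 30
#' x <- seq(-300, 300, by = 5)
#' img <- recon_image(outer(rep(1, 11), exp(-x^2 / (2 * 30^2))),
#'                    recon_grid(nx = length(x), nz = 11, dx_um = 5, dz_um = 5))
#' vessel_fwhm(img, c(6, 61), "lateral")
#' @export
vessel_fwhm <- function(image, seed_point, direction = "lateral",
                        voxel_um = NULL, window_um = 250, refine_vox = 3,
                        edge_frac = 0.15) {
  m <- if (inherits(image, "recon_image")) image$data else image
  if (is.character(direction)) {
    direction <- match.arg(direction, c("lateral", "axial"))
    dvec <- if (direction == "lateral") c(0, 1) else c(1, 0)
    if (is.null(voxel_um) && inherits(image, "recon_image"))
      voxel_um <- if (direction == "lateral") image$grid$dx_um else image$grid$dz_um
  } else {
    dvec <- direction / sqrt(sum(direction^2))
    if (is.null(voxel_um) && inherits(image, "recon_image"))
      voxel_um <- sqrt((dvec[1] * image$grid$dz_um)^2 +
                       (dvec[2] * image$grid$dx_um)^2)
  }
  if (is.null(voxel_um)) stop("voxel_um required when image carries no grid")
  # refine the seed to the local maximum
  r0 <- max(1, seed_point[1] - refine_vox):min(nrow(m), seed_point[1] + refine_vox)
  c0 <- max(1, seed_point[2] - refine_vox):min(ncol(m), seed_point[2] + refine_vox)
  sub <- m[r0, c0, drop = FALSE]
  pk <- which(sub == max(sub), arr.ind = TRUE)[1, ]
  ctr <- c(r0[pk[1]], c0[pk[2]])
  nstep <- ceiling(window_um / voxel_um)
  s <- seq(-nstep, nstep)
  prof <- bilinear(m, ctr[1] + s * dvec[1], ctr[2] + s * dvec[2])
  n <- length(prof)
  ne <- max(1, floor(edge_frac * n))
  bg <- stats::median(c(prof[1:ne], prof[(n - ne + 1):n]))
  ipk <- which.max(prof)
  half <- bg + (prof[ipk] - bg) / 2
  cross <- function(idx_seq) {
    for (i in idx_seq) {
      a <- prof[i]; b <- prof[i + 1]
      if ((a - half) * (b - half) <= 0 && a != b)
        return(i + (half - a) / (b - a))
    }
    NA_real_
  }
  left <- cross(rev(seq_len(ipk - 1)))
  right <- cross(seq(ipk, n - 1))
  if (is.na(left) || is.na(right)) {
    out <- NA_real_
    attr(out, "reason") <- "no half-maximum crossing within window"
    return(out)
  }
  (right - left) * voxel_um
}

#' Total blood volume above an adaptive threshold
#'
#' The blood volume in each dermal layer is the number of voxels whose
#' intensity exceeds an adaptive threshold, times the voxel volume. The
#' threshold is `median + threshold_mult * mad` of the deepest image rows
#' (a robust background estimate), so the measure is invariant to global
#' intensity scaling. Optionally intensity-weighted instead of counted.
#'
#' @param volume A flattened [recon_image()] (2D matrix or 3D array).
#' @param bounds A [layer_bounds()].
#' @param threshold_mult Multiples of the robust background scale.
#' @param background_frac Fraction of the deepest rows used for background.
#' @param weighted If `TRUE`, sum intensities above threshold instead of
#'   counting voxels.
#' @return Named numeric: `SD`, `RD`, `DV` volumes (um^3; a.u. when
#'   `weighted`). DV = SD + RD by construction.
#' @export
total_blood_volume <- function(volume, bounds, threshold_mult = 3,
                               background_frac = 0.1, weighted = FALSE) {
  stopifnot(inherits(volume, "recon_image"))
  d <- volume$data
  if (is.matrix(d)) d <- array(d, c(dim(d), 1))
  nz <- dim(d)[1]
  masks <- layer_masks(bounds, nz, volume$grid$dz_um)
  if (!any(masks$DV)) stop("empty dermal mask")
  nbg <- max(1, floor(background_frac * nz))
  bg <- d[(nz - nbg + 1):nz, , , drop = FALSE]
  thr <- stats::median(bg) + threshold_mult * stats::mad(bg)
  vox_vol <- volume$grid$dz_um * volume$grid$dx_um * volume$grid$dy_um
  one <- function(mask) {
    sl <- d[mask, , , drop = FALSE]
    if (weighted) sum(sl[sl > thr]) else sum(sl > thr) * vox_vol
  }
  sd_v <- one(masks$SD); rd_v <- one(masks$RD)
  c(SD = sd_v, RD = rd_v, DV = sd_v + rd_v)
}

#' Depth-resolved time-to-peak
#'
#' Splits the dermis (below the epidermal boundary) into depth bins, computes
#' the mean-intensity profile of each bin across the frame series, and
#' extracts each bin's time-to-peak with the same window machinery as
#' [compute_biomarkers()]. Resolves how much earlier or later vessels at
#' different depths reach peak hyperemia.
#'
#' @param frames List of flattened [recon_image()].
#' @param bounds A [layer_bounds()].
#' @param protocol A [porh_protocol()].
#' @param n_bins Number of equal depth bins over the dermis (used when
#'   `depth_bin_um` is `NULL`).
#' @param depth_bin_um Bin height, um (overrides `n_bins`).
#' @param smooth_peak See [compute_biomarkers()].
#' @return `data.frame(bin, depth_lo_um, depth_hi_um, tp_min)`.
#' @export
depth_resolved_tp <- function(frames, bounds, protocol, n_bins = 2,
                              depth_bin_um = NULL, smooth_peak = 9) {
  stopifnot(inherits(bounds, "layer_bounds"))
  dz <- frames[[1]]$grid$dz_um
  nz <- nrow(frames[[1]]$data)
  d_lo <- bounds$d_ep_um
  d_hi <- min(bounds$d_max_um, nz * dz)
  extent <- d_hi - d_lo
  if (!is.null(depth_bin_um)) {
    if (depth_bin_um > extent)
      stop("depth bin larger than the dermis extent")
    edges <- seq(d_lo, d_hi, by = depth_bin_um)
    if (edges[length(edges)] < d_hi) edges <- c(edges, d_hi)
  } else {
    edges <- seq(d_lo, d_hi, length.out = n_bins + 1)
  }
  tt <- protocol_times(protocol)
  if (length(tt) != length(frames))
    stop("number of frames does not match the protocol's frame count")
  zc <- (seq_len(nz) - 0.5) * dz
  out <- data.frame(bin = integer(0), depth_lo_um = numeric(0),
                    depth_hi_um = numeric(0), tp_min = numeric(0))
  for (b in seq_len(length(edges) - 1)) {
    m <- zc >= edges[b] & zc < edges[b + 1]
    if (!any(m)) next
    y <- vapply(frames, function(f) mean(f$data[m, , drop = FALSE]),
                numeric(1))
    prof <- intensity_profile(tt, y, layer = sprintf("bin%d", b),
                              protocol = protocol)
    bm <- compute_biomarkers(prof, smooth_peak)
    out <- rbind(out, data.frame(bin = b, depth_lo_um = edges[b],
                                 depth_hi_um = edges[b + 1],
                                 tp_min = bm$TP))
  }
  out
}
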