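#' Skin vascular phantom specification
#'
#' Describes a simple skin block: an absorbing melanin layer near the surface
#' (the epidermal reference band) and a set of vessels, modeled as cylinders
#' running along the slow axis, placed at epidermal/subpapillary/reticular
#' depths. Coordinates: x lateral (fast axis), y slow axis, z depth below the
#' surface, all in um inside a `lateral_mm` x `slow_mm` x `depth_mm` block.
#'
#' @param lateral_mm,depth_mm,slow_mm Block extents, mm.
#' @param melanin `c(depth_offset_um, thickness_um, absorption)`.
#' @param vessels `data.frame` with columns `x_um`, `y_um`, `z_um` (center),
#'   `radius_um`, `absorption`, `layer` (e.g. `"SD"`, `"RD"`).
#' @param seed Integer seed (kept with the spec for provenance).
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(lateral_mm = 1, depth_mm = 1, slow_mm = lateral_mm,
                         melanin = c(30, 60, 1),
                         vessels = NULL, seed = 1L) {
  if (is.null(vessels))
    vessels <- data.frame(x_um = numeric(0), y_um = numeric(0),
                          z_um = numeric(0), radius_um = numeric(0),
                          absorption = numeric(0), layer = character(0))
  stopifnot(all(c("x_um", "z_um", "radius_um", "absorption") %in% names(vessels)))
  if (!"y_um" %in% names(vessels)) vessels$y_um <- slow_mm * 500
  if (!"layer" %in% names(vessels)) vessels$layer <- "DV"
  if (length(melanin) != 3 || melanin[2] <= 0)
    stop("melanin must be c(depth_offset_um, thickness_um > 0, absorption)")
  if (nrow(vessels) > 0) {
    if (any(vessels$radius_um <= 0)) stop("vessel radii must be positive")
    lx <- lateral_mm * 1000; lz <- depth_mm * 1000
    bad <- which(vessels$x_um - vessels$radius_um < 0 |
                 vessels$x_um + vessels$radius_um > lx |
                 vessels$z_um - vessels$radius_um < 0 |
                 vessels$z_um + vessels$radius_um > lz)
    if (length(bad))
      stop("vessel(s) outside the phantom volume: ",
           paste(bad, collapse = ", "))
  }
  structure(list(lateral_mm = lateral_mm, depth_mm = depth_mm,
                 slow_mm = slow_mm, melanin = melanin, vessels = vessels,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Voxelize a phantom specification
#'
#' Deterministic rendering of a [phantom_spec()] onto a voxel lattice:
#' returns the absorption map, a per-voxel label array (`"none"`,
#' `"melanin"`, or the vessel's layer label) and the vessel metadata.
#' Vessels are cylinders along the slow (y) axis spanning the block.
#'
#' @param spec A [phantom_spec()].
#' @param voxel_um Isotropic voxel size, um.
#' @return Object of class `phantom`: list with `absorption` and `labels`
#'   (arrays `[nz, nx, ny]`), `voxel_um`, `spec`.
#' @export
generate_phantom <- function(spec, voxel_um = 10) {
  stopifnot(inherits(spec, "phantom_spec"), voxel_um > 0)
  nx <- max(1L, round(spec$lateral_mm * 1000 / voxel_um))
  ny <- max(1L, round(spec$slow_mm * 1000 / voxel_um))
  nz <- max(1L, round(spec$depth_mm * 1000 / voxel_um))
  zc <- (seq_len(nz) - 0.5) * voxel_um
  xc <- (seq_len(nx) - 0.5) * voxel_um
  a <- array(0, c(nz, nx, ny))
  lab <- array("none", c(nz, nx, ny))
  mz <- zc >= spec$melanin[1] & zc < spec$melanin[1] + spec$melanin[2]
  if (any(mz)) {
    a[mz, , ] <- spec$melanin[3]
    lab[mz, , ] <- "melanin"
  }
  if (nrow(spec$vessels) > 0) {
    for (i in seq_len(nrow(spec$vessels))) {
      v <- spec$vessels[i, ]
      inside <- outer((zc - v$z_um)^2, (xc - v$x_um)^2, "+") <= v$radius_um^2
      if (any(inside)) {
        idx <- which(inside)
        for (y in seq_len(ny)) {
          sl_a <- a[, , y]; sl_l <- lab[, , y]
          sl_a[idx] <- sl_a[idx] + v$absorption
          sl_l[idx] <- v$layer
          a[, , y] <- sl_a; lab[, , y] <- sl_l
        }
      }
    }
  }
  structure(list(absorption = a, labels = lab, voxel_um = voxel_um,
                 spec = spec), class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  d <- dim(x$absorption)
  cat(sprintf("phantom: %d x %d x %d voxels (%g um), %d vessel(s)\n",
              d[1], d[2], d[3], x$voxel_um, nrow(x$spec$vessels)))
  invisible(x)
}

#' Spherical-source decomposition of a phantom cross-section
#'
#' Converts a [phantom_spec()] into the spherical sources consumed by
#' [simulate_raw_scan()] for a cross-sectional (y = mid-plane) line scan:
#' each vessel intersecting the plane becomes one sphere of its radius; the
#' melanin layer becomes a row of small spheres along x.
#'
#' @param spec A [phantom_spec()].
#' @param melanin_spacing_um Spacing of the melanin surface sources, um.
#' @return `data.frame(x_um, y_um, z_um, radius_um, absorption, label)`.
#' @export
phantom_sources <- function(spec, melanin_spacing_um = 30) {
  stopifnot(inherits(spec, "phantom_spec"))
  lx <- spec$lateral_mm * 1000
  mr <- spec$melanin[2] / 2
  mx <- seq(melanin_spacing_um / 2, lx - melanin_spacing_um / 2,
            by = melanin_spacing_um)
  mel <- data.frame(x_um = mx, y_um = 0, z_um = spec$melanin[1] + mr,
                    radius_um = mr, absorption = spec$melanin[3],
                    label = "melanin")
  if (nrow(spec$vessels) > 0) {
    ves <- data.frame(x_um = spec$vessels$x_um, y_um = 0,
                      z_um = spec$vessels$z_um,
                      radius_um = spec$vessels$radius_um,
                      absorption = spec$vessels$absorption,
                      label = spec$vessels$layer)
    rbind(mel, ves)
  } else mel
}

#' Simulate a PORH cross-sectional frame series
#'
#' Renders the raw-scan time series of a phantom whose vascular sources are
#' modulated by per-layer [hemodynamic_modulation()] curves. The forward
#' model is linear in absorption, so the series is built exactly as a
#' superposition: one static base sinogram per source group (melanin, and
#' each vascular layer), scaled per frame by its modulation factor, plus
#' fresh per-frame Gaussian noise. Frames are materialized lazily by
#' [frame_sinogram()] / reconstructed by [reconstruct_frames()].
#'
#' @param params Named list of [hemodynamic_params()], one per vascular layer
#'   label occurring in the sources (e.g. `list(SD = ..., RD = ...)`).
#' @param protocol A [porh_protocol()].
#' @param geometry An [acquisition_geometry()].
#' @param sources Spherical source table (see [phantom_sources()]); default:
#'   a built-in two-layer phantom with vessels in SD and RD.
#' @param positions_um Detector positions; default spans the source extent at
#'   the geometry's fast-axis step.
#' @param nt Samples per A-line.
#' @param noise_sd Per-frame additive Gaussian noise sd on the sinogram.
#' @param seed Integer seed (noise is `seed + frame` for frame reproducibility).
#' @return Object of class `frame_series`.
#' @export
simulate_frame_series <- function(params, protocol,
                                  geometry = acquisition_geometry(),
                                  sources = NULL, positions_um = NULL,
                                  nt = 1024, noise_sd = 0.01, seed) {
  stopifnot(inherits(protocol, "porh_protocol"))
  if (missing(seed)) stop("seed must be given explicitly")
  if (is.null(sources)) sources <- phantom_sources(default_porh_phantom())
  if (is.null(positions_um))
    positions_um <- seq(min(sources$x_um), max(sources$x_um),
                        by = geometry$step_fast_um)
  groups <- list(static = simulate_raw_scan(
    sources[!sources$label %in% names(params), , drop = FALSE],
    geometry, positions_um, nt))
  for (ly in names(params)) {
    stopifnot(inherits(params[[ly]], "hemo_params"))
    groups[[ly]] <- simulate_raw_scan(
      sources[sources$label == ly, , drop = FALSE],
      geometry, positions_um, nt)
  }
  tt <- protocol_times(protocol)
  scales <- sapply(names(params), function(ly)
    hemodynamic_modulation(params[[ly]], protocol, tt))
  structure(list(protocol = protocol, geometry = geometry,
                 positions_um = positions_um, nt = nt, groups = groups,
                 scales = as.matrix(scales), t_min = tt,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 params = params, sources = sources),
            class = "frame_series")
}

#' @export
print.frame_series <- function(x, ...) {
  cat(sprintf("PORH frame series: %d frames, %d positions x %d samples, layers %s\n",
              length(x$t_min), length(x$positions_um), x$nt,
              paste(colnames(x$scales), collapse = "/")))
  invisible(x)
}

#' Built-in two-layer PORH phantom
#'
#' A 2 mm x 1.2 mm skin block with a melanin band and four vessels each in
#' the subpapillary (SD, 150--280 um) and reticular (RD, 680--820 um) depth
#' ranges, radii 25--50 um.
#'
#' @return A [phantom_spec()].
#' @export
default_porh_phantom <- function() {
  phantom_spec(
    lateral_mm = 2, depth_mm = 1.2,
    melanin = c(30, 60, 1.2),
    vessels = data.frame(
      x_um = c(300, 750, 1250, 1700, 400, 900, 1350, 1650),
      z_um = c(170, 220, 180, 250, 720, 820, 680, 760),
      radius_um = c(25, 30, 28, 35, 45, 50, 40, 48),
      absorption = 1,
      layer = rep(c("SD", "RD"), each = 4)))
}

#' Materialize one raw-scan frame of a series
#'
#' @param series A `frame_series`.
#' @param i Frame index.
#' @return A `raw_scan` for frame `i` (modulated superposition plus noise).
#' @export
frame_sinogram <- function(series, i) {
  stopifnot(inherits(series, "frame_series"),
            i >= 1, i <= length(series$t_min))
  sino <- series$groups$static$sinogram
  for (ly in colnames(series$scales))
    sino <- sino + series$scales[i, ly] * series$groups[[ly]]$sinogram
  if (series$noise_sd > 0) {
    set.seed(series$seed + i)
    sino <- sino + matrix(stats::rnorm(length(sino), 0, series$noise_sd),
                          nrow(sino), ncol(sino))
  }
  structure(list(sinogram = sino, positions_um = series$positions_um,
                 geometry = series$geometry), class = "raw_scan")
}

#' Reconstruct every frame of a series
#'
#' Band-filters and beamforms each frame on a shared grid, reusing one
#' precomputed [beamform_operator()].
#'
#' @param series A `frame_series`.
#' @param grid A [recon_grid()].
#' @param band Filter band, MHz.
#' @return List of [recon_image()], one per frame.
#' @export
reconstruct_frames <- function(series, grid, band = c(10, 120)) {
  op <- beamform_operator(series$geometry, series$positions_um, grid,
                          series$nt)
  lapply(seq_along(series$t_min), function(i)
    beamform(bandpass(frame_sinogram(series, i), band), grid, op))
}
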