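#' Acquisition geometry of the raster-scan optoacoustic system
#'
#' Physical constants of the scanning focused-detector system: a broadband
#' transducer (50 MHz center frequency, 10--120 MHz band, 3 mm element,
#' 60-degree detection aperture i.e. 30-degree acceptance half-angle)
#' raster-scanned with a 15 um fast-axis step at a 500 Hz laser repetition
#' rate. Speed of sound and sampling rate are configurable; defaults are the
#' standard soft-tissue 1540 m/s and 500 MS/s (>= 4x the 120 MHz band edge).
#' The detector is modeled as a point at height `focal_depth` above the skin
#' surface plane (z = 0, z increasing downward).
#'
#' @param center_freq_mhz Transducer center frequency, MHz.
#' @param band_mhz Full detection band `c(low, high)`, MHz.
#' @param element_diameter_mm Active element diameter, mm.
#' @param half_angle_deg Acceptance half-angle, degrees (in (0, 90)).
#' @param focal_depth_mm Detector standoff above the skin surface, mm.
#' @param step_fast_um,step_slow_um Scan step sizes, um.
#' @param prf_hz Laser repetition rate, Hz.
#' @param c_m_s Speed of sound, m/s.
#' @param fs_msps Sampling rate, megasamples per second.
#' @return Object of class `acq_geometry`. Derived: `c_um_us` (um/us),
#'   `dt_us`, `nyquist_mhz`.
#' @export
acquisition_geometry <- function(center_freq_mhz = 50, band_mhz = c(10, 120),
                                 element_diameter_mm = 3, half_angle_deg = 30,
                                 focal_depth_mm = 2.5, step_fast_um = 15,
                                 step_slow_um = 15, prf_hz = 500,
                                 c_m_s = 1540, fs_msps = 500) {
  if (!(band_mhz[1] > 0 && band_mhz[1] < band_mhz[2]))
    stop("band must satisfy 0 < low < high")
  if (!(half_angle_deg > 0 && half_angle_deg < 90))
    stop("acceptance half-angle must lie in (0, 90) degrees")
  vals <- c(center_freq_mhz, element_diameter_mm, focal_depth_mm,
            step_fast_um, step_slow_um, prf_hz, c_m_s, fs_msps)
  if (any(vals <= 0)) stop("all physical quantities must be positive")
  structure(list(center_freq_mhz = center_freq_mhz, band_mhz = band_mhz,
                 element_diameter_mm = element_diameter_mm,
                 half_angle_deg = half_angle_deg,
                 focal_depth_mm = focal_depth_mm,
                 step_fast_um = step_fast_um, step_slow_um = step_slow_um,
                 prf_hz = prf_hz, c_m_s = c_m_s, fs_msps = fs_msps,
                 c_um_us = c_m_s, dt_us = 1 / fs_msps,
                 nyquist_mhz = fs_msps / 2),
            class = "acq_geometry")
}

#' @export
print.acq_geometry <- function(x, ...) {
  cat(sprintf("acquisition geometry: %g MHz center, band %g-%g MHz, +/-%g deg cone, fs %g MS/s, c %g m/s\n",
              x$center_freq_mhz, x$band_mhz[1], x$band_mhz[2],
              x$half_angle_deg, x$fs_msps, x$c_m_s))
  invisible(x)
}

#' Band-limited optoacoustic pulse kernel for a spherical absorber
#'
#' Time-domain signature of a uniform sphere: the bipolar N-shaped wave of
#' half-duration `radius / c`, band-limited by a Gaussian transducer impulse
#' response centered at the transducer frequency. Built on an 8x oversampled
#' grid and decimated to the acquisition sampling rate. Normalized to unit
#' peak magnitude.
#'
#' @param radius_um Sphere radius, um.
#' @param geometry An [acquisition_geometry()].
#' @param sigma_f_mhz Gaussian bandwidth (sd) of the transducer response, MHz.
#' @return List: `kernel` (numeric), `offsets` (sample offsets relative to
#'   the time-of-flight sample).
#' @export
oa_pulse_kernel <- function(radius_um, geometry, sigma_f_mhz = 30) {
  ov <- 8L
  dtf <- geometry$dt_us / ov                       # us
  Tn <- radius_um / geometry$c_um_us               # N-wave half-duration, us
  sigma_t <- 1 / (2 * pi * sigma_f_mhz)            # us
  half <- max(Tn, 1e-6) + 4 * sigma_t
  tf <- seq(-half, half, by = dtf)
  n_wave <- ifelse(abs(tf) <= Tn, -tf / max(Tn, dtf), 0)
  if (all(n_wave == 0)) n_wave[which.min(abs(tf))] <- 1  # point-like source
  h <- exp(-tf^2 / (2 * sigma_t^2)) *
    cos(2 * pi * geometry$center_freq_mhz * tf)
  k_f <- stats::convolve(n_wave, rev(h), type = "open")
  # center of the open convolution corresponds to zero lag
  mid <- (length(k_f) + 1L) %/% 2L
  nside <- (mid - 1L) %/% ov
  off <- -nside:nside
  k <- k_f[mid + off * ov]
  k <- k / max(abs(k))
  keep <- abs(k) > 1e-4
  list(kernel = k[keep], offsets = off[keep])
}

#' Simulate a raw optoacoustic line scan of spherical sources
#'
#' Linear forward model: each spherical absorber contributes its band-limited
#' N-shaped pulse ([oa_pulse_kernel()]) to every scan position whose angle to
#' the source lies inside the acceptance cone, centered at the time of flight
#' `distance / c`, with amplitude proportional to absorption times radius,
#' attenuated by spherical spreading (`focal_depth / distance`) and a cosine
#' directivity apodization that falls to zero at the cone edge. Additive
#' white Gaussian noise completes the measurement model. An empty source
#' table yields a noise-only sinogram.
#'
#' @param sources `data.frame` with columns `x_um`, `z_um` (depth below the
#'   skin plane), `radius_um`, `absorption`; optional `y_um` (default 0) and
#'   `label`.
#' @param geometry An [acquisition_geometry()].
#' @param positions_um Detector x positions along the fast axis, um.
#' @param nt Number of time samples per A-line.
#' @param noise_sd Gaussian noise sd (a.u.).
#' @param seed Optional integer seed for the noise.
#' @return Object of class `raw_scan`: `sinogram` (positions x samples),
#'   `positions_um`, `geometry`.
#' @export
simulate_raw_scan <- function(sources, geometry, positions_um, nt = 2048,
                              noise_sd = 0, seed = NULL) {
  stopifnot(inherits(geometry, "acq_geometry"))
  if (is.null(sources)) sources <- data.frame(x_um = numeric(0),
                                              z_um = numeric(0),
                                              radius_um = numeric(0),
                                              absorption = numeric(0))
  if (nrow(sources) > 0 && !"y_um" %in% names(sources)) sources$y_um <- 0
  npos <- length(positions_um)
  sino <- matrix(0, npos, nt)
  live <- if (nrow(sources)) sources[sources$absorption != 0, , drop = FALSE] else sources
  if (nrow(live) > 0) {
    standoff <- geometry$focal_depth_mm * 1000
    thmax <- geometry$half_angle_deg * pi / 180
    fs_us <- geometry$fs_msps
    trip_i <- list(); trip_j <- list(); trip_x <- list(); b <- 0L
    for (r in unique(live$radius_um)) {
      kern <- oa_pulse_kernel(r, geometry)
      sl <- live[live$radius_um == r, , drop = FALSE]
      dx <- outer(sl$x_um, positions_um, "-")          # nsrc x npos
      dz <- sl$z_um + standoff
      dist <- sqrt(dx^2 + sl$y_um^2 + dz^2)
      theta <- acos(pmin(dz / dist, 1))
      ok <- theta <= thmax
      if (!any(ok)) next
      w <- cos(pi / 2 * theta / thmax) * (standoff / dist)
      amp <- (sl$absorption * r) * w                   # recycled by column
      s0 <- round(dist / geometry$c_um_us * fs_us) + 1L
      pos_idx <- matrix(rep(seq_len(npos), each = nrow(sl)), nrow(sl))
      for (k in seq_along(kern$kernel)) {
        s <- s0[ok] + kern$offsets[k]
        valid <- s >= 1L & s <= nt
        if (!any(valid)) next
        b <- b + 1L
        trip_i[[b]] <- pos_idx[ok][valid]
        trip_j[[b]] <- s[valid]
        trip_x[[b]] <- amp[ok][valid] * kern$kernel[k]
      }
    }
    if (b > 0L) {
      sm <- Matrix::sparseMatrix(i = unlist(trip_i), j = unlist(trip_j),
                                 x = unlist(trip_x), dims = c(npos, nt))
      sino <- as.matrix(sm)
    }
  }
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    sino <- sino + matrix(stats::rnorm(npos * nt, 0, noise_sd), npos, nt)
  }
  structure(list(sinogram = sino, positions_um = positions_um,
                 geometry = geometry), class = "raw_scan")
}

#' @export
print.raw_scan <- function(x, ...) {
  cat(sprintf("raw scan: %d positions x %d samples (fs %g MS/s, step %g um)\n",
              nrow(x$sinogram), ncol(x$sinogram), x$geometry$fs_msps,
              if (length(x$positions_um) > 1) diff(x$positions_um[1:2]) else NA))
  invisible(x)
}

#' Write / read a raw scan in the package's plain-text layout
#'
#' The sinogram is stored as a headerless CSV (one row per scan position) next
#' to a JSON sidecar holding positions and acquisition geometry.
#'
#' @param raw A `raw_scan`.
#' @param stem Path stem; writes `<stem>_sinogram.csv` and `<stem>_meta.json`.
#' @return `write_raw_scan`: invisibly, the paths written.
#' @export
write_raw_scan <- function(raw, stem) {
  stopifnot(inherits(raw, "raw_scan"))
  f1 <- paste0(stem, "_sinogram.csv"); f2 <- paste0(stem, "_meta.json")
  utils::write.table(raw$sinogram, f1, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  meta <- list(positions_um = raw$positions_um,
               geometry = unclass(raw$geometry))
  jsonlite::write_json(meta, f2, auto_unbox = TRUE, digits = NA)
  invisible(c(f1, f2))
}

#' @rdname write_raw_scan
#' @param stem Path stem used at write time.
#' @return `read_raw_scan`: the reconstructed `raw_scan` object.
#' @export
read_raw_scan <- function(stem) {
  sino <- as.matrix(utils::read.table(paste0(stem, "_sinogram.csv"), sep = ","))
  dimnames(sino) <- NULL
  meta <- jsonlite::read_json(paste0(stem, "_meta.json"), simplifyVector = TRUE)
  g <- meta$geometry
  geometry <- acquisition_geometry(g$center_freq_mhz, g$band_mhz,
                                   g$element_diameter_mm, g$half_angle_deg,
                                   g$focal_depth_mm, g$step_fast_um,
                                   g$step_slow_um, g$prf_hz, g$c_m_s, g$fs_msps)
  structure(list(sinogram = sino, positions_um = meta$positions_um,
                 geometry = geometry), class = "raw_scan")
}
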