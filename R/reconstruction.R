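#' Reconstruction grid
#'
#' Voxel lattice for delay-and-sum reconstruction. Depth `z` is 0 at the
#' membrane/skin surface and increases downward; voxel centers are at
#' `(i - 0.5) * voxel`. The standard grid voxel is 12 x 12 x 3 um (x, y, z).
#'
#' @param nx,nz,ny Grid size in voxels (ny = 1 for cross-sectional frames).
#' @param dx_um,dz_um,dy_um Voxel size, um.
#' @param x0_um Lateral coordinate of the grid's left edge, um.
#' @return Object of class `recon_grid` with coordinate vectors `x_um`,
#'   `z_um` (`y_um` when 3D).
#' @export
recon_grid <- function(nx, nz, dx_um = 12, dz_um = 3, ny = 1, dy_um = 12,
                       x0_um = 0) {
  if (any(c(dx_um, dz_um, dy_um) <= 0)) stop("voxel sizes must be positive")
  structure(list(nx = nx, nz = nz, ny = ny,
                 dx_um = dx_um, dz_um = dz_um, dy_um = dy_um,
                 x_um = x0_um + (seq_len(nx) - 0.5) * dx_um,
                 z_um = (seq_len(nz) - 0.5) * dz_um,
                 y_um = (seq_len(ny) - 0.5) * dy_um),
            class = "recon_grid")
}

#' Reconstructed image container
#'
#' @param data Matrix `[nz x nx]` (or array `[nz, nx, ny]`) of nonnegative
#'   envelope intensities.
#' @param grid A [recon_grid()].
#' @param bands Optional named list of per-band envelope images
#'   (`low` = 10--40 MHz, `high` = 40--120 MHz).
#' @param pre_envelope Optional summed RF image before envelope extraction.
#' @return Object of class `recon_image`.
#' @export
recon_image <- function(data, grid, bands = NULL, pre_envelope = NULL) {
  if (any(data < 0)) stop("recon_image intensities must be nonnegative")
  structure(list(data = data, grid = grid, bands = bands,
                 pre_envelope = pre_envelope, flattened = FALSE),
            class = "recon_image")
}

#' @export
print.recon_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("recon image: %s voxels (dz %g um, dx %g um)%s%s\n",
              paste(d, collapse = " x "), x$grid$dz_um, x$grid$dx_um,
              if (!is.null(x$bands)) ", dual-band" else "",
              if (isTRUE(x$flattened)) ", flattened" else ""))
  invisible(x)
}

# analytic-signal magnitude along a vector (FFT Hilbert transformer)
analytic_envelope <- function(x) {
  n <- length(x)
  if (n < 4) return(abs(x))
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(X * h, inverse = TRUE) / n)
}

envelope_columns <- function(m) apply(m, 2, analytic_envelope)

#' Zero-phase band-pass filter of a raw scan
#'
#' 4th-order Butterworth applied forward-backward (`signal::filtfilt`) to
#' each A-line: zero phase, ripple-free pass band, about 48 dB/octave
#' stop-band rolloff. Also removes any DC offset.
#'
#' @param raw A `raw_scan`.
#' @param band `c(low, high)` in MHz; must lie inside (0, Nyquist).
#' @return Filtered `raw_scan`.
#' @export
bandpass <- function(raw, band) {
  stopifnot(inherits(raw, "raw_scan"))
  nyq <- raw$geometry$nyquist_mhz
  if (!(band[1] > 0 && band[1] < band[2])) stop("band must satisfy 0 < low < high")
  if (band[2] >= nyq)
    stop(sprintf("band high (%g MHz) must be below Nyquist (%g MHz)", band[2], nyq))
  bf <- signal::butter(4, band / nyq, type = "pass")
  out <- t(apply(raw$sinogram, 1, function(x) signal::filtfilt(bf, x)))
  structure(list(sinogram = out, positions_um = raw$positions_um,
                 geometry = raw$geometry), class = "raw_scan")
}

#' Sparse delay-and-sum beamforming operator
#'
#' Precomputes the linear map from a sinogram (vectorized position-major) to
#' the summed RF image on a grid: each voxel accumulates, over all scan
#' positions with the voxel inside the acceptance cone, the A-line sample at
#' the voxel's time of flight, weighted by the simulated transducer
#' sensitivity field (Gaussian focal beam, normalized to unit maximum) and a
#' cosine cone apodization. Reuse the operator to reconstruct many frames
#' sharing one geometry.
#'
#' @param geometry An [acquisition_geometry()].
#' @param positions_um Detector positions, um.
#' @param grid A [recon_grid()] (2D: ny = 1).
#' @param nt Number of time samples per A-line.
#' @return A `dgCMatrix` of dimension `(nz * nx) x (npos * nt)`.
#' @export
beamform_operator <- function(geometry, positions_um, grid, nt) {
  stopifnot(inherits(geometry, "acq_geometry"), inherits(grid, "recon_grid"))
  standoff <- geometry$focal_depth_mm * 1000
  thmax <- geometry$half_angle_deg * pi / 180
  nx <- grid$nx; nz <- grid$nz
  Z <- matrix(grid$z_um, nz, nx)
  X <- matrix(grid$x_um, nz, nx, byrow = TRUE)
  vox <- seq_len(nz * nx)
  ii <- list(); jj <- list(); xx <- list()
  for (p in seq_along(positions_um)) {
    dxm <- X - positions_um[p]
    dzm <- Z + standoff
    dist <- sqrt(dxm^2 + dzm^2)
    theta <- acos(pmin(dzm / dist, 1))
    s <- as.integer(round(dist / geometry$c_um_us * geometry$fs_msps)) + 1L
    ok <- theta <= thmax & s >= 1L & s <= nt
    if (!any(ok)) next
    w <- cos(pi / 2 * theta[ok] / thmax) *
      sensitivity_field(dxm[ok], Z[ok], geometry)
    ii[[p]] <- vox[ok]
    jj[[p]] <- (p - 1L) * nt + s[ok]
    xx[[p]] <- w
  }
  iv <- unlist(ii); jv <- unlist(jj); xv <- unlist(xx)
  if (length(iv) == 0) {
    warning("reconstruction grid entirely outside the insonified region")
    iv <- integer(0); jv <- integer(0); xv <- numeric(0)
  }
  Matrix::sparseMatrix(i = iv, j = jv, x = xv,
                       dims = c(nz * nx, length(positions_um) * nt))
}

#' Simulated transducer sensitivity field
#'
#' Gaussian focal beam of the focused detector: lateral sensitivity falls off
#' with a Gaussian whose width grows away from the focus (at the skin
#' surface) according to the stated aperture; normalized to unit maximum.
#'
#' @param dx_um Lateral offset from the beam axis, um.
#' @param z_um Depth below the surface, um.
#' @param geometry An [acquisition_geometry()].
#' @return Sensitivity weights in (0, 1].
#' @export
sensitivity_field <- function(dx_um, z_um, geometry) {
  f_um <- geometry$focal_depth_mm * 1000
  d_um <- geometry$element_diameter_mm * 1000
  # diffraction-limited waist at focus, geometric growth with defocus
  lambda <- geometry$c_um_us / geometry$center_freq_mhz   # um
  w0 <- 0.61 * lambda * f_um / (d_um / 2)
  w <- sqrt(w0^2 + (z_um * d_um / (2 * f_um))^2)
  exp(-dx_um^2 / (2 * w^2))
}

#' Delay-and-sum reconstruction of a raw scan
#'
#' Sensitivity-weighted delay-and-sum ([beamform_operator()]) followed by
#' envelope extraction: the magnitude of the analytic signal along depth for
#' each lateral position, yielding a nonnegative intensity image.
#'
#' @param raw A `raw_scan` (band-filtered).
#' @param grid A [recon_grid()].
#' @param operator Optional precomputed [beamform_operator()] for this
#'   geometry/grid (built on the fly otherwise).
#' @return A [recon_image()]; the pre-envelope RF image is retained in
#'   `$pre_envelope`.
#' @export
beamform <- function(raw, grid, operator = NULL) {
  stopifnot(inherits(raw, "raw_scan"), inherits(grid, "recon_grid"))
  nt <- ncol(raw$sinogram)
  if (is.null(operator))
    operator <- beamform_operator(raw$geometry, raw$positions_um, grid, nt)
  rf <- matrix(as.numeric(operator %*% as.numeric(t(raw$sinogram))),
               grid$nz, grid$nx)
  recon_image(envelope_columns(rf), grid, pre_envelope = rf)
}

#' Dual-band reconstruction
#'
#' Band-splits the raw scan into the low (10--40 MHz, larger structures) and
#' high (40--120 MHz, smaller structures) bands, reconstructs each
#' independently and returns both channels; `composite_rgb()` renders them as
#' the conventional red (low) / green (high) overlay with per-channel
#' percentile normalization.
#'
#' @param raw A `raw_scan`.
#' @param grid A [recon_grid()].
#' @param low_mhz,high_mhz The two bands, MHz.
#' @param operator Optional precomputed beamforming operator.
#' @return A [recon_image()] whose `data` is the summed band envelope and
#'   whose `bands` list holds the per-band images.
#' @export
dual_band_reconstruct <- function(raw, grid, low_mhz = c(10, 40),
                                  high_mhz = c(40, 120), operator = NULL) {
  if (is.null(operator))
    operator <- beamform_operator(raw$geometry, raw$positions_um, grid,
                                  ncol(raw$sinogram))
  lo <- beamform(bandpass(raw, low_mhz), grid, operator)
  hi <- beamform(bandpass(raw, high_mhz), grid, operator)
  recon_image(lo$data + hi$data, grid,
              bands = list(low = lo$data, high = hi$data))
}

#' Render a dual-band image as a red/green composite
#'
#' @param image A dual-band [recon_image()].
#' @param prob Percentile used for per-channel normalization.
#' @return Array `[nz, nx, 3]` of values in `[0, 1]` (red = low band,
#'   green = high band).
#' @export
composite_rgb <- function(image, prob = 0.99) {
  stopifnot(inherits(image, "recon_image"), !is.null(image$bands))
  norm1 <- function(m) {
    q <- stats::quantile(m, prob)
    if (q <= 0) q <- max(m, 1e-12)
    pmin(m / q, 1)
  }
  out <- array(0, c(dim(image$bands$low), 3))
  out[, , 1] <- norm1(image$bands$low)
  out[, , 2] <- norm1(image$bands$high)
  out
}

#' Maximum intensity projection
#'
#' @param image A [recon_image()] (matrix `[nz, nx]` treated as a thin volume,
#'   or array `[nz, nx, ny]`).
#' @param axis `"slow"` (project over y, giving a z-x image) or `"depth"`
#'   (project over z, giving an x-y image).
#' @return Matrix of per-pixel maxima.
#' @export
mip <- function(image, axis = c("slow", "depth")) {
  axis <- match.arg(axis)
  d <- if (inherits(image, "recon_image")) image$data else image
  if (is.matrix(d)) d <- array(d, c(dim(d), 1))
  if (axis == "slow") apply(d, c(1, 2), max) else apply(d, c(2, 3), max)
}

#' Surface-tracking motion correction
#'
#' Self-contained substitute for full optoacoustic motion correction: the
#' first-arrival (skin surface) sample of each A-line is detected on its
#' envelope, a smooth reference surface is obtained by median filtering
#' across positions, and each A-line is shifted by an integer number of
#' samples (bounded by `max_shift`) so its arrival matches the reference.
#'
#' @param raw A `raw_scan`.
#' @param max_shift Maximum per-line shift, samples.
#' @param threshold Fraction of each line's envelope maximum defining the
#'   first arrival.
#' @param detect_floor A line is deemed surface-free when its envelope
#'   maximum falls below this fraction of the scan-wide maximum.
#' @param median_window Width (positions) of the lateral median filter that
#'   defines the smooth reference surface.
#' @param passes Number of detect-and-shift iterations (one normally
#'   suffices: the arrival is the first envelope peak, which is stable
#'   against per-line gain differences).
#' @return Corrected `raw_scan` with the integer `shifts` applied attached as
#'   an attribute.
#' @export
motion_correct <- function(raw, max_shift = 50, threshold = 0.5,
                           detect_floor = 0.1, median_window = 15,
                           passes = 1) {
  stopifnot(inherits(raw, "raw_scan"))
  sino <- raw$sinogram
  npos <- nrow(sino); nt <- ncol(sino)
  k <- min(median_window, npos - (1 - npos %% 2))
  total <- integer(npos)
  shift_lines <- function(m, shifts) {
    for (i in seq_len(npos)) {
      s <- shifts[i]
      if (s == 0) next
      line <- numeric(nt)
      if (s > 0) line[(1 + s):nt] <- m[i, 1:(nt - s)]
      else line[1:(nt + s)] <- m[i, (1 - s):nt]
      m[i, ] <- line
    }
    m
  }
  cur <- sino
  for (p in seq_len(passes)) {
    env <- t(apply(cur, 1, analytic_envelope))
    gmax <- max(env)
    if (gmax <= 0)
      stop("motion correction refused: no surface detectable (all-zero scan)")
    arrivals <- rep(NA_integer_, npos)
    for (i in seq_len(npos)) {
      m <- max(env[i, ])
      if (m < detect_floor * gmax) next
      j <- which(env[i, ] >= threshold * m)[1]
      # refine to the first local envelope maximum (the surface echo peak),
      # which is insensitive to per-line gain differences
      while (j < nt && env[i, j + 1] > env[i, j]) j <- j + 1L
      arrivals[i] <- j
    }
    bad <- mean(is.na(arrivals))
    if (bad > 0.2)
      stop(sprintf("motion correction refused: surface undetectable on %.0f%% of A-lines (> 20%%)",
                   100 * bad))
    if (any(is.na(arrivals)))
      arrivals[is.na(arrivals)] <- stats::median(arrivals, na.rm = TRUE)
    ref <- as.integer(stats::runmed(arrivals, k = max(1, k),
                                    endrule = "constant"))
    shifts <- ref - arrivals
    total <- pmax(pmin(total + shifts, max_shift), -max_shift)
    cur <- shift_lines(sino, total)
    if (all(shifts == 0)) break
  }
  res <- structure(list(sinogram = cur, positions_um = raw$positions_um,
                        geometry = raw$geometry), class = "raw_scan")
  attr(res, "shifts") <- total
  res
}

#' Write a reconstructed image (or frame series) as 32-bit float TIFF
#'
#' @param images A `recon_image` or list of them (frames of a series).
#' @param path Output TIFF path (multi-page for a series).
#' @return Invisibly, `path`.
#' @export
write_recon_tiff <- function(images, path) {
  if (inherits(images, "recon_image")) images <- list(images)
  gmax <- max(vapply(images, function(im) max(im$data), numeric(1)), 1e-12)
  pages <- lapply(images, function(im) im$data / gmax)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  invisible(path)
}
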