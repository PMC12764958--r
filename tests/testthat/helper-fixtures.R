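# shared fixtures: small geometries and profile builders (all generated in code)

# compact acquisition geometry for fast forward/recon tests
test_geometry <- function(...) acquisition_geometry(...)

# ideal (noise-free) normalized profile for given truths
make_profile <- function(mvc, hr, tp, protocol = porh_protocol("long"),
                         noise_sd = 0, seed = NULL, ...) {
  tt <- protocol_times(protocol)
  par <- hemodynamic_params(mvc, hr, tp, ...)
  y <- hemodynamic_modulation(par, protocol, tt)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    y <- pmax(y + rnorm(length(tt), 0, noise_sd), 0)
  }
  intensity_profile(tt, y, protocol = protocol, normalized = TRUE)
}

# flat melanin-slab sinogram with sources aligned to the detector positions,
# so the true first-arrival is identical on every A-line
aligned_slab_scan <- function(geom = test_geometry(), step_um = 15,
                              n_pos = 48, z_um = 200, radius_um = 25,
                              nt = 1200, vessels = NULL) {
  pos <- seq(step_um, by = step_um, length.out = n_pos)
  src <- data.frame(x_um = pos, y_um = 0, z_um = z_um, radius_um = radius_um,
                    absorption = 1, label = "melanin")
  if (!is.null(vessels)) src <- rbind(src, vessels)
  simulate_raw_scan(src, geom, pos, nt = nt)
}

# independent brute-force delay-and-sum oracle (plain loops, same weighting
# definition as the documented beamformer contract)
das_oracle <- function(raw, grid) {
  geom <- raw$geometry
  standoff <- geom$focal_depth_mm * 1000
  thmax <- geom$half_angle_deg * pi / 180
  nt <- ncol(raw$sinogram)
  rf <- matrix(0, grid$nz, grid$nx)
  for (iz in seq_len(grid$nz)) for (ix in seq_len(grid$nx)) {
    acc <- 0
    for (p in seq_along(raw$positions_um)) {
      dx <- grid$x_um[ix] - raw$positions_um[p]
      dz <- grid$z_um[iz] + standoff
      dist <- sqrt(dx^2 + dz^2)
      theta <- acos(min(dz / dist, 1))
      if (theta > thmax) next
      s <- round(dist / geom$c_um_us * geom$fs_msps) + 1
      if (s < 1 || s > nt) next
      w <- cos(pi / 2 * theta / thmax) *
        sensitivity_field(dx, grid$z_um[iz], geom)
      acc <- acc + w * raw$sinogram[p, s]
    }
    rf[iz, ix] <- acc
  }
  rf
}

# synthetic flattened frame list with intensity proportional to a per-layer
# modulation (bypasses the acoustic chain; for layer-profile/metrics tests)
make_layer_frames <- function(protocol, nz = 60, nx = 16, dz_um = 10,
                              ep_rows = 1:8, sd_rows = 9:30, rd_rows = 31:60,
                              sd_scale = NULL, rd_scale = NULL) {
  tt <- protocol_times(protocol)
  grid <- recon_grid(nx = nx, nz = nz, dx_um = 10, dz_um = dz_um)
  if (is.null(sd_scale)) sd_scale <- rep(1, length(tt))
  if (is.null(rd_scale)) rd_scale <- rep(1, length(tt))
  lapply(seq_along(tt), function(i) {
    m <- matrix(0, nz, nx)
    m[ep_rows, ] <- 2
    m[sd_rows, ] <- sd_scale[i]
    m[rd_rows, ] <- rd_scale[i]
    im <- recon_image(m, grid)
    im$flattened <- TRUE
    im
  })
}
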