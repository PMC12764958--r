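test_that("layer profiles isolate their masks and DV is the weighted union", {
  prot <- porh_protocol("short", frame_interval = 30)
  tt <- protocol_times(prot)
  nz <- 60; dz <- 10
  bounds <- layer_bounds(80, 220, nz * dz)
  sd_scale <- seq(1, 2, length.out = length(tt))
  frames <- make_layer_frames(prot, nz = nz, dz_um = dz, ep_rows = 1:8,
                              sd_rows = 9:30, rd_rows = 31:60,
                              sd_scale = sd_scale)
  profs <- layer_profile(frames, bounds, prot)
  # constant layers give constant profiles
  expect_equal(unique(profs$RD$intensity), 1)
  expect_equal(unique(profs$EP$intensity), 2)
  # SD follows its injected modulation
  expect_equal(profs$SD$intensity, sd_scale)
  # EP changes do not leak into dermal profiles
  frames2 <- make_layer_frames(prot, nz = nz, dz_um = dz, ep_rows = 1:8,
                               sd_rows = 9:30, rd_rows = 31:60,
                               sd_scale = sd_scale,
                               rd_scale = rep(1, length(tt)))
  for (i in seq_along(frames2)) frames2[[i]]$data[1:8, ] <- 99
  profs2 <- layer_profile(frames2, bounds, prot)
  expect_equal(profs2$SD$intensity, profs$SD$intensity)
  expect_equal(profs2$RD$intensity, profs$RD$intensity)
  # DV additivity: voxel-count-weighted mean of SD and RD
  masks <- layer_masks(bounds, nz, dz)
  w_sd <- sum(masks$SD); w_rd <- sum(masks$RD)
  expect_equal(profs$DV$intensity,
               (w_sd * profs$SD$intensity + w_rd * profs$RD$intensity) /
                 (w_sd + w_rd), tolerance = 1e-12)
  # doubling one frame's dermis doubles the profile at that frame only
  frames3 <- frames
  frames3[[4]]$data[9:60, ] <- 2 * frames3[[4]]$data[9:60, ]
  profs3 <- layer_profile(frames3, bounds, prot)
  expect_equal(profs3$DV$intensity[4], 2 * profs$DV$intensity[4])
  expect_equal(profs3$DV$intensity[-4], profs$DV$intensity[-4])
  expect_error(layer_profile(frames[1:3], bounds, prot), "frame count")
})

test_that("FWHM matches closed forms for Gaussian and top-hat sections", {
  dx <- 5
  x <- seq(-300, 300, by = dx)
  grid <- recon_grid(nx = length(x), nz = 11, dx_um = dx, dz_um = dx)
  gauss <- outer(exp(-((1:11) - 6)^2 / 8), exp(-x^2 / (2 * 30^2)))
  img <- recon_image(gauss, grid)
  f <- vessel_fwhm(img, c(6, which(x == 0)), "lateral")
  expect_equal(f, 2.3548 * 30, tolerance = 0.02)
  # top-hat of width 80 um
  th <- outer(rep(1, 11), as.numeric(abs(x) <= 40))
  f2 <- vessel_fwhm(recon_image(th, grid), c(6, which(x == 0)), "lateral")
  expect_equal(f2, 85, tolerance = dx / 80)  # edges at +/-42.5 on a 5 um lattice
  # axial direction works the same way
  gz <- outer(exp(-((1:121) - 61)^2 * dx^2 / (2 * 25^2)), rep(1, 11))
  gridz <- recon_grid(nx = 11, nz = 121, dx_um = dx, dz_um = dx)
  fz <- vessel_fwhm(recon_image(gz, gridz), c(61, 6), "axial")
  expect_equal(fz, 2.3548 * 25, tolerance = 0.02)
})

test_that("FWHM of a blurred cylinder matches a 1D convolution oracle", {
  dx <- 2
  x <- seq(-300, 300, by = dx)
  r <- 30
  chord <- 2 * sqrt(pmax(r^2 - x^2, 0))   # projected disk
  psf_sd <- 18 / 2.3548
  psf <- exp(-x^2 / (2 * psf_sd^2))
  prof <- stats::convolve(chord, psf / sum(psf), type = "open")
  prof <- pmax(prof[seq_along(x) + (length(x) - 1) / 2], 0)
  # oracle FWHM by direct crossing search on the convolved profile
  half <- max(prof) / 2
  above <- which(prof >= half)
  oracle <- (max(above) - min(above)) * dx
  img <- recon_image(outer(rep(1, 9), prof),
                     recon_grid(nx = length(x), nz = 9, dx_um = dx, dz_um = dx))
  f <- vessel_fwhm(img, c(5, which.max(prof)), "lateral")
  expect_equal(f, oracle, tolerance = 0.05)
})

test_that("FWHM is flagged undefined when no crossing is in the window", {
  img <- recon_image(matrix(1, 20, 20), recon_grid(nx = 20, nz = 20))
  f <- vessel_fwhm(img, c(10, 10), "lateral", window_um = 50)
  expect_true(is.na(f))
  expect_match(attr(f, "reason"), "half-maximum")
})

test_that("total blood volume counts voxels above a relative threshold", {
  nz <- 100; nx <- 30
  grid <- recon_grid(nx = nx, nz = nz, dx_um = 10, dz_um = 10, dy_um = 1)
  bounds <- layer_bounds(100, 300, 1000)
  m <- matrix(0, nz, nx)
  m[15:20, 5:10] <- 5    # SD vessel: 36 voxels
  m[55:60, 5:14] <- 5    # RD vessel: 60 voxels
  im <- recon_image(m, grid)
  v <- total_blood_volume(im, bounds)
  vox <- 10 * 10 * 1
  expect_equal(unname(v["SD"]), 36 * vox)
  expect_equal(unname(v["RD"]), 60 * vox)
  expect_equal(unname(v["DV"]), unname(v["SD"] + v["RD"]))
  # scale equivariance: threshold is relative to the background
  v2 <- total_blood_volume(recon_image(7.3 * m, grid), bounds)
  expect_equal(v2, v)
  # empty volume -> zero
  v0 <- total_blood_volume(recon_image(matrix(0, nz, nx), grid), bounds)
  expect_equal(unname(v0["DV"]), 0)
  shallow <- recon_image(matrix(1, 5, nx),
                         recon_grid(nx = nx, nz = 5, dx_um = 10, dz_um = 10))
  expect_error(total_blood_volume(shallow, bounds), "empty dermal mask")
})

test_that("depth-resolved TP recovers per-depth peak timing", {
  prot <- porh_protocol("long", frame_interval = 5)
  tt <- protocol_times(prot)
  nz <- 60; dz <- 10
  bounds <- layer_bounds(80, 220, nz * dz)
  p_sup <- hemodynamic_params(0.4, 0.15, 1.5)
  p_deep <- hemodynamic_params(0.4, 0.15, 1.5 - 15 / 60)
  frames <- make_layer_frames(prot, nz = nz, dz_um = dz, ep_rows = 1:8,
                              sd_rows = 9:30, rd_rows = 31:60,
                              sd_scale = hemodynamic_modulation(p_sup, prot, tt),
                              rd_scale = hemodynamic_modulation(p_deep, prot, tt))
  tpb <- depth_resolved_tp(frames, bounds, prot, n_bins = 2, smooth_peak = 0)
  lag_s <- 60 * (tpb$tp_min[1] - tpb$tp_min[2])
  expect_equal(lag_s, 15, tolerance = 5 + 1e-9)
  # zero offset: all bins agree within one frame interval
  frames0 <- make_layer_frames(prot, nz = nz, dz_um = dz, ep_rows = 1:8,
                               sd_rows = 9:30, rd_rows = 31:60,
                               sd_scale = hemodynamic_modulation(p_sup, prot, tt),
                               rd_scale = hemodynamic_modulation(p_sup, prot, tt))
  tp0 <- depth_resolved_tp(frames0, bounds, prot, n_bins = 3, smooth_peak = 0)
  expect_lte(diff(range(tp0$tp_min)), 5 / 60 + 1e-9)
  # a single bin reproduces the layer-level DV time-to-peak
  tp1 <- depth_resolved_tp(frames, bounds, prot, n_bins = 1, smooth_peak = 0)
  dv <- compute_biomarkers(layer_profile(frames, bounds, prot)$DV,
                           smooth_peak = 0)
  expect_equal(tp1$tp_min, dv$TP)
  expect_error(depth_resolved_tp(frames, bounds, prot, depth_bin_um = 9999),
               "larger than")
})
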