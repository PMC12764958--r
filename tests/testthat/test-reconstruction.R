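test_that("bandpass preserves the pass band and rejects out-of-band tones", {
  geom <- test_geometry()
  t_us <- (0:2047) * geom$dt_us
  tone <- function(f_mhz) sin(2 * pi * f_mhz * t_us)
  mk <- function(x) structure(list(sinogram = rbind(x, x),
                                   positions_um = c(0, 15), geometry = geom),
                              class = "raw_scan")
  inb <- bandpass(mk(tone(25)), c(10, 40))$sinogram[1, 200:1800]
  expect_gt(max(abs(inb)), 10^(-1 / 20))                    # < 1 dB loss
  outb <- bandpass(mk(tone(25)), c(40, 120))$sinogram[1, 200:1800]
  expect_lt(max(abs(outb)), 10^(-40 / 20))                  # >= 40 dB down
  dc <- bandpass(mk(tone(25) + 3), c(10, 120))$sinogram[1, 200:1800]
  expect_lt(abs(mean(dc)), 1e-3)                            # offset removed
  expect_error(bandpass(mk(tone(25)), c(10, 300)), "Nyquist")
})

test_that("band split approximately conserves broadband pulse energy", {
  geom <- test_geometry()
  for (r in c(5, 15, 40)) {
    k <- oa_pulse_kernel(r, geom)
    x <- numeric(1024); x[500 + k$offsets] <- k$kernel
    mk <- structure(list(sinogram = rbind(x, x), positions_um = c(0, 15),
                         geometry = geom), class = "raw_scan")
    full <- sum(bandpass(mk, c(10, 120))$sinogram[1, ]^2)
    lo <- sum(bandpass(mk, c(10, 40))$sinogram[1, ]^2)
    hi <- sum(bandpass(mk, c(40, 120))$sinogram[1, ]^2)
    expect_gte((lo + hi) / full, 0.8)
    expect_lte((lo + hi) / full, 1.05)
  }
})

test_that("fast beamformer equals the brute-force delay-and-sum oracle", {
  geom <- test_geometry()
  pos <- seq(100, 550, by = 30)          # 16 positions
  src <- data.frame(x_um = c(300, 420), z_um = c(250, 400),
                    radius_um = c(10, 20), absorption = c(1, 0.8))
  raw <- bandpass(simulate_raw_scan(src, geom, pos, nt = 1200), c(10, 120))
  grid <- recon_grid(nx = 24, nz = 24, dx_um = 20, dz_um = 20, x0_um = 120)
  fast <- beamform(raw, grid)
  rf_oracle <- das_oracle(raw, grid)
  expect_lt(max(abs(fast$pre_envelope - rf_oracle)), 1e-6 * max(abs(rf_oracle)))
})

test_that("point sources localize within one axial / two lateral voxels", {
  geom <- test_geometry()
  pos <- seq(0, 1500, by = 15)
  grid <- recon_grid(nx = 64, nz = 80, dx_um = 15, dz_um = 15, x0_um = 270)
  set.seed(42)
  for (k in 1:10) {
    x0 <- runif(1, 500, 1000); z0 <- runif(1, 300, 900)
    src <- data.frame(x_um = x0, z_um = z0, radius_um = 5, absorption = 1)
    raw <- simulate_raw_scan(src, geom, pos, nt = 1600)
    img <- beamform(bandpass(raw, c(10, 120)), grid)
    pk <- which(img$data == max(img$data), arr.ind = TRUE)[1, ]
    expect_lte(abs(grid$z_um[pk[1]] - z0) / 15, 1)
    expect_lte(abs(grid$x_um[pk[2]] - x0) / 15, 2)
  }
})

test_that("two absorbers 200 um apart produce two local maxima at truth", {
  geom <- test_geometry()
  pos <- seq(0, 1500, by = 15)
  src <- data.frame(x_um = c(650, 850), z_um = 500, radius_um = c(20, 20),
                    absorption = 1)
  raw <- simulate_raw_scan(src, geom, pos, nt = 1400)
  grid <- recon_grid(nx = 64, nz = 48, dx_um = 15, dz_um = 15, x0_um = 270)
  img <- beamform(bandpass(raw, c(10, 120)), grid)
  prof <- apply(img$data, 2, max)
  locmax <- which(diff(sign(diff(prof))) == -2) + 1
  # prominent local maxima exist within two voxels of both true positions
  locmax <- locmax[prof[locmax] > 0.5 * max(prof)]
  expect_true(any(abs(grid$x_um[locmax] - 650) <= 30))
  expect_true(any(abs(grid$x_um[locmax] - 850) <= 30))
})

test_that("all-zero sinograms reconstruct to all-zero images", {
  geom <- test_geometry()
  raw <- simulate_raw_scan(NULL, geom, seq(0, 300, 30), nt = 1024)
  grid <- recon_grid(nx = 10, nz = 12, dx_um = 30, dz_um = 20)
  img <- beamform(raw, grid)
  expect_true(all(img$data == 0))
  db <- dual_band_reconstruct(raw, grid)
  expect_true(all(db$bands$low == 0) && all(db$bands$high == 0))
})

test_that("reconstruction is linear before envelope extraction", {
  geom <- test_geometry()
  pos <- seq(100, 550, 30)
  a <- simulate_raw_scan(data.frame(x_um = 300, z_um = 250, radius_um = 10,
                                    absorption = 1), geom, pos, nt = 1200)
  b <- simulate_raw_scan(data.frame(x_um = 400, z_um = 380, radius_um = 15,
                                    absorption = 1), geom, pos, nt = 1200)
  ab <- a; ab$sinogram <- a$sinogram + b$sinogram
  grid <- recon_grid(nx = 20, nz = 20, dx_um = 25, dz_um = 25, x0_um = 150)
  ra <- beamform(a, grid); rb <- beamform(b, grid); rab <- beamform(ab, grid)
  expect_equal(rab$pre_envelope, ra$pre_envelope + rb$pre_envelope,
               tolerance = 1e-10)
})

test_that("dual-band channels separate large from small absorbers", {
  geom <- test_geometry()
  pos <- seq(0, 1500, 15)
  grid <- recon_grid(nx = 32, nz = 48, dx_um = 20, dz_um = 15, x0_um = 430)
  energies <- sapply(c(50, 5), function(r) {
    raw <- simulate_raw_scan(data.frame(x_um = 750, z_um = 500,
                                        radius_um = r, absorption = 1),
                             geom, pos, nt = 1200)
    db <- dual_band_reconstruct(raw, grid)
    c(low = sum(db$bands$low^2), high = sum(db$bands$high^2))
  })
  expect_gt(energies["low", 1], energies["high", 1])   # 50 um: low dominates
  expect_gt(energies["high", 2], energies["low", 2])   # 5 um: high dominates
  rgb_img <- composite_rgb(dual_band_reconstruct(
    simulate_raw_scan(data.frame(x_um = 750, z_um = 500, radius_um = 20,
                                 absorption = 1), geom, pos, nt = 1200), grid))
  expect_true(all(rgb_img >= 0 & rgb_img <= 1))
})

test_that("maximum intensity projections satisfy their defining properties", {
  set.seed(1)
  vol <- array(runif(6 * 5 * 4), c(6, 5, 4))
  im <- recon_image(vol, recon_grid(nx = 5, nz = 6, ny = 4))
  m_slow <- mip(im, "slow"); m_depth <- mip(im, "depth")
  for (y in 1:4) expect_true(all(m_slow >= vol[, , y]))
  for (z in 1:6) expect_true(all(m_depth >= vol[z, , ]))
  # positive homogeneity
  im2 <- recon_image(3 * vol, im$grid)
  expect_equal(mip(im2, "slow"), 3 * m_slow)
  # single hot voxel appears unchanged at its projected location
  v0 <- array(0, c(6, 5, 4)); v0[3, 2, 2] <- 7
  expect_equal(mip(recon_image(v0, im$grid), "slow")[3, 2], 7)
  expect_equal(max(mip(recon_image(v0, im$grid), "slow")), 7)
  # two-slab volume projects to the elementwise slab maximum
  expect_equal(mip(recon_image(vol[, , 1:2], im$grid), "slow"),
               pmax(vol[, , 1], vol[, , 2]))
  expect_error(mip(im, "sideways"))
})

test_that("surface-jitter motion correction inverts known shifts", {
  geom <- test_geometry()
  raw <- aligned_slab_scan(geom)
  set.seed(7)
  # median-zero jitter: the smooth reference surface is then recoverable
  half <- sample(0:5, nrow(raw$sinogram) / 2, replace = TRUE)
  jit <- as.integer(rbind(half, -half))
  nt <- ncol(raw$sinogram)
  sj <- raw$sinogram
  for (i in seq_len(nrow(sj))) {
    s <- jit[i]; line <- numeric(nt)
    if (s > 0) line[(1 + s):nt] <- raw$sinogram[i, 1:(nt - s)]
    else if (s < 0) line[1:(nt + s)] <- raw$sinogram[i, (1 - s):nt]
    else line <- raw$sinogram[i, ]
    sj[i, ] <- line
  }
  rj <- structure(list(sinogram = sj, positions_um = raw$positions_um,
                       geometry = geom), class = "raw_scan")
  mc <- motion_correct(rj, max_shift = 10, median_window = 47)
  expect_lte(max(abs(attr(mc, "shifts") + jit)), 1)
  # jitter-free scan: identity
  mc0 <- motion_correct(raw, max_shift = 10)
  expect_true(all(attr(mc0, "shifts") == 0))
  expect_equal(mc0$sinogram, raw$sinogram)
  # degenerate input: no surface
  z <- structure(list(sinogram = matrix(0, 8, 128),
                      positions_um = seq(0, 105, 15), geometry = geom),
                 class = "raw_scan")
  expect_error(motion_correct(z), "no surface")
})
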