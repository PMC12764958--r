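test_that("A-line envelope peaks at the time of flight for an on-axis source", {
  geom <- test_geometry()
  pos <- seq(0, 1500, by = 15)
  src <- data.frame(x_um = 750, z_um = 1000, radius_um = 5, absorption = 1)
  raw <- simulate_raw_scan(src, geom, pos, nt = 2048)
  i <- which.min(abs(pos - 750))
  env <- abs(raw$sinogram[i, ])
  # Hilbert envelope for sub-sample peak stability
  env <- porhmeso:::analytic_envelope(raw$sinogram[i, ])
  expected <- round((1000 + geom$focal_depth_mm * 1000) /
                      geom$c_um_us * geom$fs_msps) + 1
  expect_lte(abs(which.max(env) - expected), 1)
})

test_that("zero-absorption phantom yields an all-zero (or noise-only) sinogram", {
  geom <- test_geometry()
  raw <- simulate_raw_scan(NULL, geom, seq(0, 300, 15), nt = 256)
  expect_true(all(raw$sinogram == 0))
  src0 <- data.frame(x_um = 100, z_um = 200, radius_um = 10, absorption = 0)
  raw0 <- simulate_raw_scan(src0, geom, seq(0, 300, 15), nt = 256)
  expect_true(all(raw0$sinogram == 0))
  rn <- simulate_raw_scan(NULL, geom, seq(0, 300, 15), nt = 256,
                          noise_sd = 0.5, seed = 3)
  expect_equal(sd(as.vector(rn$sinogram)), 0.5, tolerance = 0.05)
})

test_that("sources beyond the 30-degree half-angle contribute nothing", {
  geom <- test_geometry()
  # dz = z + standoff = 2600; need dx > tan(30 deg) * 2600 = 1501
  src <- data.frame(x_um = 0, z_um = 100, radius_um = 20, absorption = 1)
  raw <- simulate_raw_scan(src, geom, c(1600, 1700), nt = 2048)
  expect_true(all(raw$sinogram == 0))
  # same source inside the cone does contribute
  raw_in <- simulate_raw_scan(src, geom, c(200, 300), nt = 2048)
  expect_gt(max(abs(raw_in$sinogram)), 0)
})

test_that("forward model is linear in absorption and seed-deterministic", {
  geom <- test_geometry()
  pos <- seq(0, 600, 30)
  a <- data.frame(x_um = 200, z_um = 300, radius_um = 20, absorption = 1)
  b <- data.frame(x_um = 400, z_um = 500, radius_um = 30, absorption = 0.7)
  ra <- simulate_raw_scan(a, geom, pos, nt = 1024)
  rb <- simulate_raw_scan(b, geom, pos, nt = 1024)
  rab <- simulate_raw_scan(rbind(a, b), geom, pos, nt = 1024)
  expect_equal(rab$sinogram, ra$sinogram + rb$sinogram, tolerance = 1e-12)
  n1 <- simulate_raw_scan(a, geom, pos, nt = 1024, noise_sd = 0.1, seed = 11)
  n2 <- simulate_raw_scan(a, geom, pos, nt = 1024, noise_sd = 0.1, seed = 11)
  expect_identical(n1$sinogram, n2$sinogram)
})

test_that("pulse kernels shift spectral weight with source size", {
  geom <- test_geometry()
  spec_centroid <- function(r) {
    k <- oa_pulse_kernel(r, geom)
    n <- 2048
    x <- numeric(n); x[1024 + k$offsets] <- k$kernel
    f <- seq(0, geom$fs_msps / 2, length.out = n / 2)
    a2 <- Mod(fft(x))[1:(n / 2)]^2
    sum(f * a2) / sum(a2)
  }
  expect_gt(spec_centroid(5), spec_centroid(50))
})

test_that("raw scans round-trip through the plain-text layout", {
  geom <- test_geometry()
  src <- data.frame(x_um = 150, z_um = 250, radius_um = 15, absorption = 1)
  raw <- simulate_raw_scan(src, geom, seq(0, 300, 30), nt = 1200)
  expect_gt(max(abs(raw$sinogram)), 0)
  stem <- file.path(tempdir(), "scan_rt")
  write_raw_scan(raw, stem)
  back <- read_raw_scan(stem)
  expect_equal(back$sinogram, raw$sinogram, tolerance = 1e-12)
  expect_equal(back$positions_um, raw$positions_um)
  expect_equal(back$geometry$fs_msps, raw$geometry$fs_msps)
})
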