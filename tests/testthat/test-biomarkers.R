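test_that("window statistics reproduce the worked group-shaped example", {
  # normalized profile: baseline 1.0, occlusion plateau 0.66,
  # post-release peak 1.2560 at 8.42 min under the long protocol
  prot <- porh_protocol("long")
  tt <- protocol_times(prot)
  y <- numeric(length(tt))
  y[tt < 2] <- 1
  y[tt >= 2 & tt < 7] <- 0.66
  post <- tt >= 7
  y[post] <- 1 + (1.2560 - 1) * exp(-((tt[post] - 8.42) / 0.45)^2)
  prof <- intensity_profile(tt, y, protocol = prot, normalized = TRUE)
  bm <- compute_biomarkers(prof, smooth_peak = 0)
  expect_equal(bm$MVC, 0.34, tolerance = 1e-6)
  expect_equal(bm$HR, 20.38, tolerance = 0.01)
  expect_equal(bm$TP, 1.42, tolerance = 1 / 60 + 1e-9)
})

test_that("a constant profile gives zero biomarkers with earliest-tie peak", {
  prot <- porh_protocol("long")
  tt <- protocol_times(prot)
  prof <- intensity_profile(tt, rep(1, length(tt)), protocol = prot)
  bm <- compute_biomarkers(prof)
  expect_equal(bm$MVC, 0)
  expect_equal(bm$HR, 0)
  expect_equal(bm$TP, 0)   # earliest tie: the release sample itself
})

test_that("biomarker identities hold exactly on random profiles", {
  set.seed(101)
  prot_long <- porh_protocol("long", frame_interval = 5)
  prot_short <- porh_protocol("short", frame_interval = 5)
  for (k in 1:1000) {
    prot <- if (k %% 2) prot_long else prot_short
    tt <- protocol_times(prot)
    prof <- intensity_profile(tt, runif(length(tt), 0, 2), protocol = prot)
    bm <- compute_biomarkers(prof, smooth_peak = sample(c(0, 9), 1))
    expect_identical(bm$MVC, bm$MVB - bm$MVIC)
    expect_identical(bm$HR, 100 * (bm$PIV - bm$MVB) / bm$PIV)
    expect_identical(bm$TP, bm$t_PIV - prot$t_release)
    expect_gte(bm$TP, 0)
  }
})

test_that("HR and TP are invariant under positive rescaling; MVC scales", {
  base <- make_profile(0.4, 0.15, 1.3, noise_sd = 0.01, seed = 5)
  prof <- intensity_profile(base$t_min, base$intensity,
                            protocol = base$protocol)  # raw-scale view
  bm1 <- compute_biomarkers(prof)
  for (c0 in c(0.2, 3, 1700)) {
    prof2 <- intensity_profile(prof$t_min, c0 * prof$intensity,
                               protocol = prof$protocol)
    bm2 <- compute_biomarkers(prof2)
    expect_equal(bm2$HR, bm1$HR, tolerance = 1e-9)
    expect_equal(bm2$TP, bm1$TP)
    expect_equal(bm2$MVC, c0 * bm1$MVC, tolerance = 1e-9)
    # normalized fit is fully scale-invariant
    expect_equal(coef(porh_fit(prof2)), coef(porh_fit(prof)),
                 tolerance = 1e-9)
  }
})

test_that("noise-free profiles with fast decay recover generator truths", {
  cases <- list(c(0.34, 0.0954, 1.89), c(0.48, 0.2038, 1.42),
                c(0.16, 0.0713, 2.18))
  for (cs in cases) {
    prot <- porh_protocol("long")
    prof <- make_profile(cs[1], cs[2], cs[3], prot,
                         occlusion_tau = 1e-4)
    cf <- coef(porh_fit(prof, smooth_peak = 0))
    # the release-boundary sample leaves a mvc/n_occ quantization residue
    expect_equal(cf[["MVC"]], cs[1], tolerance = 0.01)
    expect_equal(cf[["HR_pct"]], 100 * cs[2], tolerance = 0.01)
    expect_equal(cf[["TP_min"]], cs[3], tolerance = (1 / 60 + 1e-9) / cs[3])
  }
})

test_that("profiles missing post-release samples are rejected", {
  prot <- porh_protocol("long")
  tt <- seq(0, 6.5, by = 1 / 60)
  expect_error(intensity_profile(tt, rep(1, length(tt)), protocol = prot),
               "cover")
})

test_that("porh_fit methods are mutually consistent", {
  prof <- make_profile(0.45, 0.18, 1.5, noise_sd = 0.02, seed = 21)
  fit <- porh_fit(prof)
  expect_s3_class(fit, "porh_fit")
  cf <- coef(fit)
  expect_named(cf, c("MVB", "MVIC", "PIV", "MVC", "HR_pct", "TP_min"))
  expect_equal(unname(cf["MVC"]), fit$biomarkers$MVC)
  expect_length(predict(fit), length(prof$t_min))
  expect_equal(residuals(fit), fit$profile$intensity - fitted(fit))
  expect_lt(sd(residuals(fit)), 0.05)
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(length(prof$t_min), 4L))
  expect_identical(simulate(fit, nsim = 2, seed = 9),
                   simulate(fit, nsim = 2, seed = 9))
  expect_output(print(summary(fit)), "residual sd")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
  # refit of the model's own prediction recovers the same parameters
  # (the occlusion transient of the canonical decay constant shaves ~5%)
  refit <- porh_fit(prof$t_min, predict(fit), protocol = prof$protocol)
  expect_equal(coef(refit)[["MVC"]], cf[["MVC"]], tolerance = 0.08)
  expect_equal(coef(refit)[["TP_min"]], cf[["TP_min"]], tolerance = 2 / 60)
})

test_that("percent increment matches the worked vessel examples", {
  expect_equal(percent_increment(27, 33), 22)
  expect_equal(percent_increment(50, 60), 20)
  expect_equal(percent_increment(40, 40), 0)
  expect_equal(percent_increment(58, 69, digits = NULL), 100 * 11 / 58)
  expect_error(percent_increment(0, 10), "positive")
})
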