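#' Cohort preset: per-layer biomarker distributions for one subject group
#'
#' A preset names a group and gives, per skin layer (DV, SD, RD), the normal
#' distribution (mean, sd) from which subject-level ground truths for MVC,
#' HR and TP are drawn. HR is stored as a fraction, TP in minutes.
#'
#' @param name Group label.
#' @param layers Named list (`DV`, `SD`, `RD`, any subset) of lists with
#'   elements `mvc`, `hr`, `tp`, each `c(mean, sd)`; `hr` as a fraction.
#' @param n_subjects Default cohort size (>= 1).
#' @param protocol Default protocol name for this group (`"long"`/`"short"`).
#' @return Object of class `cohort_preset`.
#' @export
cohort_preset <- function(name, layers, n_subjects = 10, protocol = "long") {
  stopifnot(is.character(name), is.list(layers), length(layers) >= 1)
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  for (ly in names(layers)) {
    l <- layers[[ly]]
    stopifnot(all(c("mvc", "hr", "tp") %in% names(l)))
    for (f in c("mvc", "hr", "tp")) {
      v <- l[[f]]
      if (length(v) != 2L || v[2] < 0) stop("each field must be c(mean, sd) with sd >= 0")
    }
    if (l$mvc[1] <= 0 || l$mvc[1] >= 1) stop("mvc mean must lie in (0,1)")
    if (l$hr[1] < 0 || l$hr[1] >= 1) stop("hr mean (fraction) must lie in [0,1)")
    if (l$tp[1] <= 0) stop("tp mean must be positive")
  }
  structure(list(name = name, layers = layers, n_subjects = n_subjects,
                 protocol = protocol), class = "cohort_preset")
}

#' Built-in group presets
#'
#' Per-layer MVC / HR / TP means and standard deviations for the four study
#' groups: smokers and age-matched non-smokers (10-min long protocol) and
#' CVD patients with age-matched healthy volunteers (6-min short protocol).
#' HR is stored as a fraction (printed percentages divided by 100).
#'
#' @return Named list of [cohort_preset()] objects:
#'   `smoker`, `nonsmoker`, `cvd`, `hv_matched`.
#' @examples
#' cohort_presets()$smoker$layers$DV
#' @export
cohort_presets <- function() {
  list(
    smoker = cohort_preset("smoker", list(
      DV = list(mvc = c(0.34, 0.082), hr = c(0.0954, 0.0437), tp = c(1.89, 0.38)),
      SD = list(mvc = c(0.26, 0.095), hr = c(0.0767, 0.0352), tp = c(1.77, 0.38)),
      RD = list(mvc = c(0.38, 0.079), hr = c(0.1052, 0.0283), tp = c(2.01, 0.41))
    ), n_subjects = 10, protocol = "long"),
    nonsmoker = cohort_preset("nonsmoker", list(
      DV = list(mvc = c(0.48, 0.062), hr = c(0.2038, 0.0443), tp = c(1.42, 0.40)),
      SD = list(mvc = c(0.44, 0.054), hr = c(0.1965, 0.0484), tp = c(1.29, 0.40)),
      RD = list(mvc = c(0.49, 0.063), hr = c(0.2062, 0.0794), tp = c(1.46, 0.37))
    ), n_subjects = 10, protocol = "long"),
    cvd = cohort_preset("cvd", list(
      DV = list(mvc = c(0.16, 0.048), hr = c(0.0713, 0.0341), tp = c(2.18, 0.20)),
      SD = list(mvc = c(0.11, 0.024), hr = c(0.0491, 0.0304), tp = c(2.05, 0.16)),
      RD = list(mvc = c(0.21, 0.073), hr = c(0.0916, 0.0345), tp = c(2.36, 0.20))
    ), n_subjects = 10, protocol = "short"),
    hv_matched = cohort_preset("hv_matched", list(
      DV = list(mvc = c(0.38, 0.068), hr = c(0.1638, 0.0299), tp = c(1.69, 0.27)),
      SD = list(mvc = c(0.34, 0.050), hr = c(0.1513, 0.0321), tp = c(1.53, 0.26)),
      RD = list(mvc = c(0.40, 0.048), hr = c(0.1748, 0.0369), tp = c(1.78, 0.31))
    ), n_subjects = 10, protocol = "short")
  )
}

# truncated normal by inverse-CDF; exact, no rejection loop
rtruncnorm <- function(n, mean, sd, lower, upper) {
  if (sd == 0) return(rep(min(max(mean, lower), upper), n))
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

#' Draw subject-level ground truths for one layer of a preset
#'
#' Truths are drawn from truncated normal distributions so that MVC stays in
#' (0, 1), HR in \[0, 1) and TP > 0 regardless of the configured mean/sd.
#'
#' @param preset A [cohort_preset()].
#' @param layer Layer label present in the preset (`"DV"`, `"SD"`, `"RD"`).
#' @param n Number of subjects (default: preset's `n_subjects`).
#' @param seed Integer seed (required for reproducibility).
#' @return `data.frame(subject_id, layer, mvc_true, hr_true, tp_true)`.
#' @export
draw_cohort_truths <- function(preset, layer = "DV", n = preset$n_subjects,
                               seed) {
  stopifnot(inherits(preset, "cohort_preset"))
  if (!layer %in% names(preset$layers)) stop("layer not in preset: ", layer)
  if (n < 1) stop("n_subjects must be >= 1")
  if (missing(seed)) stop("seed must be given explicitly")
  l <- preset$layers[[layer]]
  set.seed(seed)
  eps <- 1e-4
  data.frame(
    subject_id = sprintf("%s_%02d", preset$name, seq_len(n)),
    layer = layer,
    mvc_true = rtruncnorm(n, l$mvc[1], l$mvc[2], eps, 1 - eps),
    hr_true = rtruncnorm(n, l$hr[1], l$hr[2], 0, 1 - eps),
    tp_true = rtruncnorm(n, l$tp[1], l$tp[2], eps, Inf),
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic PORH cohort with known ground truth
#'
#' Profile-level mode draws per-subject biomarker truths from the preset and
#' emits baseline-normalized layer intensity profiles: the ideal
#' [hemodynamic_modulation()] curve sampled at the protocol's frame times
#' plus additive Gaussian noise. Image-level mode additionally renders each
#' subject as a cross-sectional frame series of a vascular phantom via
#' [simulate_frame_series()] (slow; intended for small cohorts).
#'
#' @param preset A [cohort_preset()].
#' @param layer Layer to generate (`"DV"`, `"SD"`, `"RD"`).
#' @param protocol A [porh_protocol()]; default: the preset's protocol name
#'   at 1 s frame interval.
#' @param noise_sd Additive Gaussian noise sd on the normalized profile.
#' @param seed Integer seed.
#' @param mode `"profile"` or `"image"`.
#' @param n Number of subjects (default from the preset).
#' @param ... Passed to [simulate_frame_series()] in image mode.
#' @return List with `truths` (data.frame), `profiles` (list of
#'   `intensity_profile`), `protocol`, and in image mode `frames`
#'   (per-subject frame series).
#' @export
generate_cohort <- function(preset, layer = "DV", protocol = NULL,
                            noise_sd = 0.02, seed, mode = c("profile", "image"),
                            n = preset$n_subjects, ...) {
  mode <- match.arg(mode)
  if (missing(seed)) stop("seed must be given explicitly")
  if (is.null(protocol)) protocol <- porh_protocol(preset$protocol)
  truths <- draw_cohort_truths(preset, layer, n, seed)
  tt <- protocol_times(protocol)
  set.seed(seed + 1L)
  profiles <- vector("list", n)
  frames <- if (mode == "image") vector("list", n) else NULL
  for (i in seq_len(n)) {
    par <- hemodynamic_params(truths$mvc_true[i], truths$hr_true[i],
                              truths$tp_true[i])
    ideal <- hemodynamic_modulation(par, protocol, tt)
    y <- ideal + stats::rnorm(length(tt), 0, noise_sd)
    profiles[[i]] <- intensity_profile(tt, pmax(y, 0), layer = layer,
                                       protocol = protocol, normalized = TRUE)
    if (mode == "image") {
      frames[[i]] <- simulate_frame_series(
        params = list(SD = par, RD = par), protocol = protocol,
        seed = seed + 1000L + i, ...)
    }
  }
  out <- list(truths = truths, profiles = profiles, protocol = protocol,
              layer = layer, noise_sd = noise_sd, seed = seed, mode = mode)
  if (mode == "image") out$frames <- frames
  class(out) <- "porh_cohort"
  out
}

#' @export
print.porh_cohort <- function(x, ...) {
  cat(sprintf("PORH cohort: %d subjects, layer %s, %s-level, noise sd %g\n",
              nrow(x$truths), x$layer, x$mode, x$noise_sd))
  invisible(x)
}

#' Fit every subject of a cohort and tabulate recovered biomarkers
#'
#' Runs [porh_fit()] on each subject's profile and returns the recovered
#' biomarkers next to the generator's ground truths, ready for recovery
#' checks or group statistics.
#'
#' @param cohort A `porh_cohort` from [generate_cohort()].
#' @param ... Passed to [porh_fit()].
#' @return `data.frame` with one row per subject: recovered `MVB`, `MVIC`,
#'   `PIV`, `MVC`, `HR_pct`, `TP_min` and the `*_true` columns.
#' @export
cohort_biomarkers <- function(cohort, ...) {
  stopifnot(inherits(cohort, "porh_cohort"))
  rows <- lapply(seq_along(cohort$profiles), function(i) {
    cf <- coef(porh_fit(cohort$profiles[[i]], ...))
    data.frame(subject_id = cohort$truths$subject_id[i],
               layer = cohort$layer,
               MVB = cf[["MVB"]], MVIC = cf[["MVIC"]], PIV = cf[["PIV"]],
               MVC = cf[["MVC"]], HR_pct = cf[["HR_pct"]],
               TP_min = cf[["TP_min"]],
               mvc_true = cohort$truths$mvc_true[i],
               hr_true_pct = 100 * cohort$truths$hr_true[i],
               tp_true_min = cohort$truths$tp_true[i])
  })
  do.call(rbind, rows)
}

#' Write cohort truths and profiles to CSV
#'
#' Long-format CSV with columns `subject_id, layer, t_min, intensity`, plus a
#' companion `<stem>_truths.csv`.
#'
#' @param cohort A `porh_cohort`.
#' @param stem Output path stem (without extension).
#' @return Invisibly, the two file paths written.
#' @export
write_cohort_csv <- function(cohort, stem) {
  stopifnot(inherits(cohort, "porh_cohort"))
  prof <- do.call(rbind, lapply(seq_along(cohort$profiles), function(i) {
    p <- cohort$profiles[[i]]
    data.frame(subject_id = cohort$truths$subject_id[i], layer = p$layer,
               t_min = p$t_min, intensity = p$intensity)
  }))
  f1 <- paste0(stem, "_profiles.csv"); f2 <- paste0(stem, "_truths.csv")
  utils::write.csv(prof, f1, row.names = FALSE)
  utils::write.csv(cohort$truths, f2, row.names = FALSE)
  invisible(c(f1, f2))
}
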