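#' Layer intensity profile
#'
#' A time series of mean image intensity within one skin layer over a PORH
#' test, annotated with its protocol.
#'
#' @param t_min Time stamps, minutes, strictly increasing, covering
#'   `[0, t_total]`.
#' @param intensity Nonnegative intensities (a.u.), same length.
#' @param layer Layer label: `"EP"`, `"SD"`, `"RD"` or `"DV"`.
#' @param protocol A [porh_protocol()].
#' @param normalized Logical; `TRUE` if already divided by its baseline mean.
#' @return Object of class `intensity_profile`.
#' @export
intensity_profile <- function(t_min, intensity, layer = "DV", protocol,
                              normalized = FALSE) {
  stopifnot(inherits(protocol, "porh_protocol"),
            length(t_min) == length(intensity))
  if (any(diff(t_min) <= 0)) stop("time stamps must be strictly increasing")
  if (any(intensity < 0)) stop("intensities must be nonnegative")
  if (t_min[1] > 0 || t_min[length(t_min)] < protocol$t_total - 1e-9)
    stop("profile must cover [0, t_total]")
  structure(list(t_min = t_min, intensity = intensity, layer = layer,
                 protocol = protocol, normalized = normalized),
            class = "intensity_profile")
}

#' @export
print.intensity_profile <- function(x, ...) {
  cat(sprintf("intensity profile: layer %s, %d frames over %g min%s\n",
              x$layer, length(x$t_min), max(x$t_min),
              if (x$normalized) " (baseline-normalized)" else ""))
  invisible(x)
}

# centered moving average; width w samples (w <= 1 is identity)
moving_average <- function(y, w) {
  if (w <= 1) return(y)
  w <- as.integer(w); if (w %% 2L == 0L) w <- w + 1L
  k <- (w - 1L) %/% 2L
  n <- length(y)
  cs <- cumsum(c(0, y))
  lo <- pmax(seq_len(n) - k, 1L); hi <- pmin(seq_len(n) + k, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Window-statistic endothelial-function biomarkers from a PORH profile
#'
#' Computes the biomarker set from a layer intensity profile: `MVB`, the mean
#' over the baseline window `[0, t_baseline_end)`; `MVIC`, the mean over the
#' full occlusion window `[t_baseline_end, t_release)`; `PIV` and `t_PIV`,
#' the peak value and its (earliest) time at or after cuff release; and the
#' derived biomarkers `MVC = MVB - MVIC`, `HR = 100 (PIV - MVB) / PIV` (%),
#' `TP = t_PIV - t_release` (min).
#'
#' Peak picking uses a lightly smoothed copy of the profile (centered moving
#' average, `smooth_peak` samples) because the raw maximum of a noisy series
#' is biased upward by extreme noise values; the window means are always
#' computed on the raw profile. Set `smooth_peak = 0` for the raw maximum.
#'
#' @param profile An [intensity_profile()].
#' @param smooth_peak Moving-average width (samples) for peak detection;
#'   default 9 (9 s at the 1 s frame interval), 0 disables.
#' @return Object of class `biomarker_set`: named list with `MVB`, `MVIC`,
#'   `PIV`, `t_PIV`, `MVC`, `HR` (percent), `TP` (min) and `layer`.
#' @examples
#' prot <- porh_protocol("long")
#' tt <- protocol_times(prot)
#' p <- hemodynamic_params(0.34, 0.2038, 1.42)
#' prof <- intensity_profile(tt, hemodynamic_modulation(p, prot, tt),
#'                           protocol = prot, normalized = TRUE)
#' compute_biomarkers(prof)
#' @export
compute_biomarkers <- function(profile, smooth_peak = 9) {
  stopifnot(inherits(profile, "intensity_profile"))
  pr <- profile$protocol
  t <- profile$t_min; y <- profile$intensity
  post <- t >= pr$t_release
  if (!any(post)) stop("profile has no samples at or after cuff release")
  mvb <- mean(y[t < pr$t_baseline_end])
  mvic <- mean(y[t >= pr$t_baseline_end & t < pr$t_release])
  ys <- moving_average(y, smooth_peak)
  ypost <- ys[post]; tpost <- t[post]
  i <- which.max(ypost)           # which.max takes the earliest tie
  piv <- ypost[i]; t_piv <- tpost[i]
  structure(list(MVB = mvb, MVIC = mvic, PIV = piv, t_PIV = t_piv,
                 MVC = mvb - mvic, HR = 100 * (piv - mvb) / piv,
                 TP = t_piv - pr$t_release, layer = profile$layer),
            class = "biomarker_set")
}

#' @export
print.biomarker_set <- function(x, ...) {
  cat(sprintf("biomarkers [%s]: MVB %.4f | MVIC %.4f | PIV %.4f @ %.2f min\n",
              x$layer, x$MVB, x$MVIC, x$PIV, x$t_PIV))
  cat(sprintf("  MVC %.4f  HR %.2f%%  TP %.3f min\n", x$MVC, x$HR, x$TP))
  invisible(x)
}

#' Fit the PORH response model to a layer intensity profile
#'
#' The central model fit. The PORH response is described by the idealized
#' piecewise curve of [hemodynamic_modulation()] on the baseline-normalized
#' scale; its three parameters are the endothelial-function biomarkers MVC
#' (occlusion drop), HR (hyperemic overshoot fraction) and TP (time from
#' release to peak). `porh_fit` estimates them by window statistics
#' ([compute_biomarkers()]) after normalizing the profile by its baseline
#' mean, and returns a classed object supporting `print`, `summary`, `coef`,
#' `plot`, `predict`, `fitted`, `residuals` and `simulate`.
#'
#' @param x An [intensity_profile()], or a numeric time vector (minutes).
#' @param intensity Numeric intensities when `x` is a time vector.
#' @param protocol A [porh_protocol()] (required when `x` is numeric).
#' @param layer Layer label (when `x` is numeric).
#' @param normalize Divide by the baseline mean before fitting (default TRUE;
#'   HR and TP are invariant to this, MVC becomes dimensionless in (0, 1]).
#' @param smooth_peak See [compute_biomarkers()].
#' @param ... Unused.
#' @return Object of class `porh_fit` with elements `profile` (normalized),
#'   `raw_profile`, `biomarkers` (a `biomarker_set`), `params`
#'   (a [hemodynamic_params()] built from the estimates, for prediction)
#'   and `sigma` (residual sd).
#' @examples
#' prot <- porh_protocol("long")
#' tt <- protocol_times(prot)
#' truth <- hemodynamic_params(0.48, 0.20, 1.4)
#' y <- hemodynamic_modulation(truth, prot, tt) + rnorm(length(tt), 0, 0.02)
#' fit <- porh_fit(tt, pmax(y, 0), protocol = prot)
#' coef(fit)
#' @export
porh_fit <- function(x, ...) UseMethod("porh_fit")

#' @rdname porh_fit
#' @export
porh_fit.intensity_profile <- function(x, normalize = TRUE, smooth_peak = 9,
                                       ...) {
  raw <- x
  bm0 <- compute_biomarkers(x, smooth_peak)
  if (normalize && !x$normalized) {
    if (bm0$MVB <= 0) stop("cannot normalize: baseline mean is not positive")
    x <- intensity_profile(x$t_min, x$intensity / bm0$MVB, x$layer,
                           x$protocol, normalized = TRUE)
  }
  bm <- compute_biomarkers(x, smooth_peak)
  # parameter estimates on the normalized scale, clamped to the model's domain
  eps <- 1e-6
  mvc_hat <- min(max(bm$MVC / bm$MVB, eps), 1 - eps)
  hr_hat <- min(max(bm$HR / 100, 0), 1 - eps)
  tp_hat <- max(bm$TP, eps)
  par <- hemodynamic_params(mvc_hat, hr_hat, tp_hat)
  fitted_vals <- hemodynamic_modulation(par, x$protocol, x$t_min)
  res <- x$intensity / mean(x$intensity[x$t_min < x$protocol$t_baseline_end]) -
    fitted_vals
  structure(list(profile = x, raw_profile = raw, biomarkers = bm,
                 params = par, sigma = stats::sd(res),
                 smooth_peak = smooth_peak),
            class = "porh_fit")
}

#' @rdname porh_fit
#' @export
porh_fit.numeric <- function(x, intensity, protocol, layer = "DV",
                             normalize = TRUE, smooth_peak = 9, ...) {
  porh_fit(intensity_profile(x, intensity, layer, protocol),
           normalize = normalize, smooth_peak = smooth_peak)
}

#' @export
coef.porh_fit <- function(object, ...) {
  b <- object$biomarkers
  c(MVB = b$MVB, MVIC = b$MVIC, PIV = b$PIV, MVC = b$MVC,
    HR_pct = b$HR, TP_min = b$TP)
}

#' @export
print.porh_fit <- function(x, ...) {
  cat(sprintf("PORH response fit (layer %s, %s protocol)\n",
              x$profile$layer, x$profile$protocol$name))
  print(x$biomarkers)
  invisible(x)
}

#' @export
summary.porh_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.porh_fit")
}

#' @export
print.summary.porh_fit <- function(x, ...) {
  f <- x$fit; pr <- f$profile$protocol; b <- f$biomarkers
  print(f)
  cat(sprintf("  windows: baseline [0, %g) min, occlusion [%g, %g) min, peak search >= %g min\n",
              pr$t_baseline_end, pr$t_baseline_end, pr$t_release, pr$t_release))
  cat(sprintf("  residual sd %.4f over %d frames; peak smoothing %d samples\n",
              f$sigma, length(f$profile$t_min), f$smooth_peak))
  invisible(x)
}

#' @export
predict.porh_fit <- function(object, t = object$profile$t_min, ...) {
  hemodynamic_modulation(object$params, object$profile$protocol, t)
}

#' @export
fitted.porh_fit <- function(object, ...) predict(object)

#' @export
residuals.porh_fit <- function(object, ...) {
  object$profile$intensity - predict(object)
}

#' @export
simulate.porh_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- predict(object)
  out <- replicate(nsim, pmax(mu + stats::rnorm(length(mu), 0, object$sigma), 0))
  colnames(out) <- paste0("sim_", seq_len(nsim))
  data.frame(t_min = object$profile$t_min, out)
}

#' @export
plot.porh_fit <- function(x, ...) {
  pr <- x$profile$protocol; b <- x$biomarkers
  graphics::plot(x$profile$t_min, x$profile$intensity, type = "l",
                 xlab = "time (min)", ylab = "normalized intensity (a.u.)",
                 main = sprintf("PORH response, layer %s", x$profile$layer), ...)
  graphics::abline(v = c(pr$t_baseline_end, pr$t_release), lty = 2, col = "grey40")
  graphics::lines(x$profile$t_min, predict(x), col = "firebrick", lwd = 2)
  graphics::points(b$t_PIV, b$PIV, pch = 19, col = "firebrick")
  graphics::legend("topleft", bty = "n",
                   legend = c(sprintf("MVC %.3f", b$MVC),
                              sprintf("HR %.1f%%", b$HR),
                              sprintf("TP %.2f min", b$TP)))
  invisible(x)
}

#' Percent increment between baseline and peak vessel diameter
#'
#' @param d_baseline Baseline diameter, must be positive.
#' @param d_peak Peak diameter (same units).
#' @param digits Rounding for reporting (default nearest integer); `NULL`
#'   returns the unrounded value.
#' @return Percent increase `100 (d_peak - d_baseline) / d_baseline`.
#' @examples
#' percent_increment(27, 33)  # 22
#' @export
percent_increment <- function(d_baseline, d_peak, digits = 0) {
  if (any(d_baseline <= 0)) stop("baseline diameter must be positive")
  v <- 100 * (d_peak - d_baseline) / d_baseline
  if (is.null(digits)) v else round(v, digits)
}
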