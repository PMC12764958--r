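#' Ground-truth hemodynamic parameters for one subject
#'
#' Parameterizes the idealized layer-mean intensity response to a PORH test
#' on the baseline-normalized scale. The three endothelial-function
#' biomarkers appear directly: `mvc` is the depth of the occlusion-induced
#' signal drop (the curve decays from 1 toward the floor `1 - mvc`), `hr` is
#' the relative hyperemic overshoot (the post-release peak equals
#' `1 / (1 - hr)`, so that `(peak - 1) / peak = hr`), and `tp` is the time
#' from cuff release to that peak.
#'
#' @param mvc Maximum volume change, dimensionless in (0, 1).
#' @param hr Hyperemia ratio as a fraction in \[0, 1) (not percent).
#' @param tp Time-to-peak after cuff release, minutes (> 0).
#' @param occlusion_tau Exponential time constant of the occlusion decay,
#'   minutes. Default 0.25 min: under a suprasystolic cuff, arterial inflow
#'   stops within seconds and the optoacoustic vessel signal empties over a
#'   few tens of seconds, so the occlusion plateau dominates the occlusion
#'   window.
#' @param recovery_tau Exponential time constant of the post-peak relaxation
#'   toward baseline, minutes.
#' @param rise_shape Shape parameter (alpha) of the gamma-variate post-release
#'   rise; larger values sharpen the hyperemic peak. Default 9 gives a rise
#'   width of about `tp / 3`, matching the sharp overshoot seen in reactive
#'   hyperemia recordings.
#' @return Object of class `hemo_params`. Derived fields: `piv = 1/(1 - hr)`
#'   (peak value) and `floor = 1 - mvc` (occlusion plateau).
#' @seealso [hemodynamic_modulation()]
#' @export
hemodynamic_params <- function(mvc, hr, tp, occlusion_tau = 0.25,
                               recovery_tau = 1.0, rise_shape = 9) {
  stopifnot(length(mvc) == 1L, length(hr) == 1L, length(tp) == 1L)
  if (!(mvc > 0 && mvc < 1)) stop("mvc must lie in (0, 1)")
  if (!(hr >= 0 && hr < 1)) stop("hr must lie in [0, 1)")
  if (tp <= 0) stop("tp must be positive (minutes)")
  if (occlusion_tau <= 0 || recovery_tau <= 0) stop("time constants must be positive")
  if (rise_shape <= 0) stop("rise_shape must be positive")
  structure(list(mvc = mvc, hr = hr, tp = tp,
                 occlusion_tau = occlusion_tau, recovery_tau = recovery_tau,
                 rise_shape = rise_shape,
                 piv = 1 / (1 - hr), floor = 1 - mvc),
            class = "hemo_params")
}

#' @export
print.hemo_params <- function(x, ...) {
  cat(sprintf("hemodynamic truth: MVC = %.3f, HR = %.2f%%, TP = %.2f min (peak %.4f, floor %.3f)\n",
              x$mvc, 100 * x$hr, x$tp, x$piv, x$floor))
  invisible(x)
}

#' Idealized PORH modulation curve
#'
#' Dimensionless scale factor applied to vascular signal over a PORH test.
#' Piecewise: constant 1 during baseline; exponential decay toward the floor
#' `1 - mvc` during occlusion; after release, a gamma-variate-shaped rise
#' from the end-of-occlusion value that attains its maximum `1/(1 - hr)`
#' exactly at `t_release + tp`; then exponential relaxation toward 1. The
#' curve is continuous in `t`, and the three biomarker truths are closed
#' form: ideal baseline mean 1, occlusion floor `1 - mvc`, peak `1/(1 - hr)`
#' at `tp` after release.
#'
#' If `tp` exceeds the post-release window the curve is still rising at
#' `t_total` (the peak falls outside the recording, as happens for slow
#' responders under a short protocol).
#'
#' @param params A [hemodynamic_params()] object.
#' @param protocol A [porh_protocol()].
#' @param t Time(s) in minutes; must lie within `[0, t_total]`.
#' @return Numeric vector of scale factors, same length as `t`.
#' @examples
#' p <- hemodynamic_params(mvc = 0.34, hr = 0.2038, tp = 1.42)
#' prot <- porh_protocol("long")
#' hemodynamic_modulation(p, prot, c(0, 6.99, 7 + 1.42))
#' @export
hemodynamic_modulation <- function(params, protocol, t) {
  stopifnot(inherits(params, "hemo_params"), inherits(protocol, "porh_protocol"))
  if (any(t < 0 | t > protocol$t_total))
    stop(sprintf("t outside protocol range [0, %g] min", protocol$t_total))
  tb <- protocol$t_baseline_end; tr <- protocol$t_release
  fl <- params$floor; mvc <- params$mvc
  ot <- params$occlusion_tau; rt <- params$recovery_tau
  piv <- params$piv; tp <- params$tp; a <- params$rise_shape

  v <- numeric(length(t))
  bas <- t < tb
  occ <- t >= tb & t < tr
  rec <- t >= tr
  v[bas] <- 1
  v[occ] <- fl + mvc * exp(-(t[occ] - tb) / ot)
  if (any(rec)) {
    v0 <- fl + mvc * exp(-(tr - tb) / ot)  # continuity at release
    tau <- t[rec] - tr
    u <- tau / tp
    rise <- u <= 1
    out <- numeric(length(tau))
    # gamma-variate, monotone increasing on [0, tp], unit peak at tp
    g <- (u[rise])^a * exp(a * (1 - u[rise]))
    out[rise] <- v0 + (piv - v0) * g
    out[!rise] <- 1 + (piv - 1) * exp(-(tau[!rise] - tp) / rt)
    v[rec] <- out
  }
  v
}
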