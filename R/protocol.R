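#' PORH cuff protocol
#'
#' Defines the timing of a post-occlusive reactive hyperemia (PORH) test:
#' a resting baseline with the cuff deflated, an arterial occlusion with the
#' cuff inflated above systolic pressure, and a post-release recovery window.
#' Two standard protocols are provided: `"long"` (2 min baseline, 5 min
#' occlusion, 3 min recovery; marks at 2/7/10 min) and `"short"`
#' (1 min baseline, 3 min occlusion, 2 min recovery; marks at 1/4/6 min).
#'
#' @param name `"long"`, `"short"`, or `"custom"`.
#' @param t_baseline_end End of baseline / start of occlusion, minutes.
#' @param t_release Cuff release time, minutes.
#' @param t_total Total recording time, minutes.
#' @param frame_interval Imaging frame interval, seconds (1 s default; the
#'   line-scan mode supports 0.5 s).
#' @return An object of class `porh_protocol` with fields `t_baseline_end`,
#'   `t_release`, `t_total` (minutes) and `frame_interval` (seconds).
#' @examples
#' porh_protocol("long")
#' porh_protocol("custom", 1, 4, 6, frame_interval = 0.5)
#' @export
porh_protocol <- function(name = c("long", "short", "custom"),
                          t_baseline_end = NULL, t_release = NULL,
                          t_total = NULL, frame_interval = 1) {
  name <- match.arg(name)
  if (name == "long") {
    t_baseline_end <- t_baseline_end %||% 2
    t_release <- t_release %||% 7
    t_total <- t_total %||% 10
  } else if (name == "short") {
    t_baseline_end <- t_baseline_end %||% 1
    t_release <- t_release %||% 4
    t_total <- t_total %||% 6
  } else if (is.null(t_baseline_end) || is.null(t_release) || is.null(t_total)) {
    stop("custom protocol requires t_baseline_end, t_release and t_total")
  }
  stopifnot(is.numeric(frame_interval), length(frame_interval) == 1L)
  if (!(0 < t_baseline_end && t_baseline_end < t_release && t_release < t_total))
    stop("protocol times must satisfy 0 < t_baseline_end < t_release < t_total")
  if (frame_interval <= 0) stop("frame_interval must be positive")
  structure(list(name = name, t_baseline_end = t_baseline_end,
                 t_release = t_release, t_total = t_total,
                 frame_interval = frame_interval),
            class = "porh_protocol")
}

#' @export
print.porh_protocol <- function(x, ...) {
  cat(sprintf("PORH protocol ('%s'): baseline [0, %g) min, occlusion [%g, %g) min, recovery [%g, %g] min; frame every %g s\n",
              x$name, x$t_baseline_end, x$t_baseline_end, x$t_release,
              x$t_release, x$t_total, x$frame_interval))
  invisible(x)
}

#' Frame time stamps of a protocol
#'
#' @param protocol A [porh_protocol()].
#' @return Numeric vector of frame times in minutes, from 0 to `t_total`.
#' @export
protocol_times <- function(protocol) {
  stopifnot(inherits(protocol, "porh_protocol"))
  seq(0, protocol$t_total, by = protocol$frame_interval / 60)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
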