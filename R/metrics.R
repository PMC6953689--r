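# Timing and energy metrics of sampled impulse traces, and the standard
# lightning-current taxonomy.

validate_trace <- function(trace) {
  if (!is.data.frame(trace) || !all(c("time_us", "current_ka") %in% names(trace)))
    stop("trace must have columns `time_us` and `current_ka`", call. = FALSE)
  t <- trace$time_us
  if (nrow(trace) < 3) stop("trace too short", call. = FALSE)
  dt <- diff(t)
  if (any(dt <= 0)) stop("`time_us` must be strictly increasing", call. = FALSE)
  if (max(dt) - min(dt) > 1e-9 * max(dt))
    stop("`time_us` must have a uniform step", call. = FALSE)
  if ("voltage_kv" %in% names(trace) && length(trace$voltage_kv) != length(t))
    stop("voltage channel length mismatch", call. = FALSE)
  invisible(trace)
}

# linear interpolation of the time where |i| crosses `level`, between sample
# indices j and j+1
cross_time <- function(t, a, j, level) {
  t[j] + (level - a[j]) * (t[j + 1] - t[j]) / (a[j + 1] - a[j])
}

#' Extract timing and energy metrics from a waveform trace
#'
#' Measures the quantities the ignition experiments report for each discharge:
#' peak current \eqn{I_p}, front time \eqn{t_f} (1.25 x the interpolated
#' 10--90% rise interval), half-wave time \eqn{t_h} (virtual origin to the
#' first 50% decay crossing), the action integral \eqn{\int I^2 dt} in
#' A\eqn{^2}s, and, when a voltage channel is present, the trapezoidal energy
#' \eqn{\int U I dt} in J.
#'
#' @param trace A `waveform_trace` tibble (columns `time_us`, `current_ka`,
#'   optionally `voltage_kv`) on a uniform time grid.
#'
#' @return A one-row tibble with columns `peak_ka`, `front_us`, `half_us`,
#'   `action_integral_a2s` and (if voltage present) `energy_j`.
#' @export
extract_metrics <- function(trace) {
  validate_trace(trace)
  t <- trace$time_us
  a <- abs(trace$current_ka)

  pk <- max(a)
  if (pk == 0) stop("no impulse detected: trace is identically zero", call. = FALSE)
  ip <- which.max(a)
  if (ip == 1 || ip == length(a))
    stop("no impulse detected: peak lies on the grid boundary", call. = FALSE)

  # rising edge: last upward crossings of 10% and 90% before the peak
  rise_cross <- function(level) {
    below <- which(a[seq_len(ip - 1)] < level & a[2:ip] >= level)
    if (length(below) == 0)
      stop("no impulse detected: rising edge never crosses ", level / pk * 100,
           "% of peak", call. = FALSE)
    j <- max(below)
    cross_time(t, a, j, level)
  }
  t10 <- rise_cross(0.1 * pk)
  t90 <- rise_cross(0.9 * pk)

  # falling edge: first downward crossing of 50% after the peak
  post <- seq(ip, length(a) - 1)
  down <- post[a[post] >= 0.5 * pk & a[post + 1] < 0.5 * pk]
  if (length(down) == 0)
    stop("no impulse detected: tail never decays to 50% of peak", call. = FALSE)
  j <- min(down)
  t50 <- cross_time(t, a, j, 0.5 * pk)

  front <- 1.25 * (t90 - t10)
  origin <- t10 - 0.25 * (t90 - t10)

  # kA^2 us -> A^2 s : (1e3)^2 * 1e-6 = 1
  action <- pracma::trapz(t, (trace$current_ka)^2)

  out <- tibble::tibble(
    peak_ka = pk,
    front_us = front,
    half_us = t50 - origin,
    action_integral_a2s = action
  )
  if ("voltage_kv" %in% names(trace)) {
    # kV * kA * us -> J : 1e3 * 1e3 * 1e-6 = 1
    out$energy_j <- pracma::trapz(t, trace$voltage_kv * trace$current_ka)
  }
  out
}

# Approximate current/duration windows for the four components of the standard
# lightning waveform. Only partial bounds are standardized (maxima for the
# strokes, an average for the intermediate current); the remaining edges are
# package conventions. Precedence A > D > B > C so larger-current classes win;
# the duration floor on the first return stroke is what makes the (faster)
# subsequent stroke reachable.
WAVEFORM_PART_WINDOWS <- list(
  first_return_stroke = list(peak = c(1, 200), dur = c(50, 500)),          # us
  subsequent          = list(peak = c(1, 100), dur = c(0, 500)),           # us
  intermediate        = list(peak = c(0.8, 5), dur = c(500, 5e3)),         # <5 ms
  long_continuing     = list(peak = c(0.2, 0.8), dur = c(0.25e6, 1e6))     # 0.25-1 s
)

#' Classify a current pulse against the standard lightning-waveform taxonomy
#'
#' Assigns a (peak current, duration) pair to one of the four canonical
#' components of a lightning flash: first return stroke (up to 200 kA,
#' < 500 us), intermediate current (~2 kA, < 5 ms), long continuing current
#' (200--800 A for 0.25--1 s) or subsequent stroke (up to 100 kA, < 500 us).
#' Overlaps resolve in that precedence order; values outside every window
#' return `"unclassified"`.
#'
#' @param peak_ka Peak current in kA (positive).
#' @param duration_us Pulse duration in microseconds (positive).
#'
#' @return A character vector over the recycled inputs.
#' @examples
#' classify_waveform_part(0.5, 5e5)  # 500 A for 0.5 s -> long_continuing
#' @export
classify_waveform_part <- function(peak_ka, duration_us) {
  stopifnot(is.numeric(peak_ka), is.numeric(duration_us))
  n <- max(length(peak_ka), length(duration_us))
  peak_ka <- rep_len(peak_ka, n)
  duration_us <- rep_len(duration_us, n)
  if (any(!is.finite(peak_ka)) || any(peak_ka <= 0) ||
      any(!is.finite(duration_us)) || any(duration_us <= 0))
    stop("`peak_ka` and `duration_us` must be positive", call. = FALSE)
  vapply(seq_len(n), function(i) {
    for (part in names(WAVEFORM_PART_WINDOWS)) {
      w <- WAVEFORM_PART_WINDOWS[[part]]
      if (peak_ka[i] >= w$peak[1] && peak_ka[i] <= w$peak[2] &&
          duration_us[i] >= w$dur[1] && duration_us[i] <= w$dur[2])
        return(part)
    }
    "unclassified"
  }, character(1))
}
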