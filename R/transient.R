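#' Ca2+ transient kernel
#'
#' Difference-of-exponentials transient shape, peak-normalized so that the
#' maximum over time equals `amplitude` exactly. This is the standard
#' phenomenological shape for indicator-reported Ca2+ release: a fast rise
#' (IP3R opening) followed by a slower decay (reuptake/extrusion).
#'
#' The kernel is zero for `t < t0`; its analytic peak time is
#' `t0 + rise_tau_s * decay_tau_s / (decay_tau_s - rise_tau_s) *
#' log(decay_tau_s / rise_tau_s)`.
#'
#' @param t Time(s) in seconds (vectorized).
#' @param t0 Event onset time, s.
#' @param amplitude Peak height in dF/F0 units.
#' @param rise_tau_s,decay_tau_s Rise and decay time constants, s; must
#'   satisfy `decay_tau_s > rise_tau_s > 0`.
#' @return Kernel values at `t`, same length as `t`.
#' @export
transient_kernel <- function(t, t0, amplitude, rise_tau_s = 0.3,
                             decay_tau_s = 3) {
  if (!(rise_tau_s > 0) || !(decay_tau_s > rise_tau_s)) {
    stop("time constants must satisfy decay_tau_s > rise_tau_s > 0")
  }
  u <- t - t0
  h <- numeric(length(t))
  on <- u >= 0
  h[on] <- exp(-u[on] / decay_tau_s) - exp(-u[on] / rise_tau_s)
  tp <- transient_peak_time(0, rise_tau_s, decay_tau_s)
  hmax <- exp(-tp / decay_tau_s) - exp(-tp / rise_tau_s)
  amplitude * h / hmax
}

#' Analytic peak time of the transient kernel
#'
#' @inheritParams transient_kernel
#' @return Time of the kernel maximum, s.
#' @export
transient_peak_time <- function(t0, rise_tau_s = 0.3, decay_tau_s = 3) {
  t0 + rise_tau_s * decay_tau_s / (decay_tau_s - rise_tau_s) *
    log(decay_tau_s / rise_tau_s)
}
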