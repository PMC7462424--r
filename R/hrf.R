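#' Canonical double-gamma haemodynamic response function
#'
#' Difference of two gamma densities (unit scale): a response peaking near
#' `peak` seconds minus an undershoot peaking near `undershoot` seconds,
#' scaled by `ratio`. The same kernel is used by the cohort simulator and by
#' the LS-S design builder, so trial-level estimates are unbiased with
#' respect to the simulated response shape.
#'
#' @param t time in seconds (vector); values at `t <= 0` return 0.
#' @param peak shape of the response gamma (delay of the peak, seconds).
#' @param undershoot shape of the undershoot gamma (seconds).
#' @param ratio relative amplitude of the undershoot.
#' @return numeric vector of kernel values, unit peak-gamma mass.
#' @export
hrf_double_gamma <- function(t, peak = 6, undershoot = 16, ratio = 1 / 6) {
  h <- numeric(length(t))
  pos <- t > 0
  h[pos] <- dgamma(t[pos], shape = peak, rate = 1) -
    ratio * dgamma(t[pos], shape = undershoot, rate = 1)
  h
}

#' Volumes spanned by a single trial response
#'
#' The haemodynamic response to one trial lasts about `response_dur` seconds
#' (13.1 s by default), so at TR = 2 s a trial spans 6 or 7 volumes depending
#' on its onset phase: indices `floor(onset/tr) + 1` through
#' `ceiling((onset + response_dur)/tr)` (1-based), clipped to the run length.
#'
#' @param onset trial onset in seconds.
#' @param tr repetition time in seconds.
#' @param n_volumes number of volumes in the run.
#' @param response_dur response duration in seconds.
#' @return integer vector of volume indices.
#' @export
trial_response_span <- function(onset, tr, n_volumes, response_dur = 13.1) {
  from <- floor(onset / tr) + 1
  to <- ceiling((onset + response_dur) / tr)
  seq.int(max(1L, from), min(as.integer(n_volumes), to))
}
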