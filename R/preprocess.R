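#' @title Zero-phase band-pass prefiltering
#' @name preprocess
#' @description
#' Abdominal and scalp ECG recordings carry baseline wander below 0.5 Hz and
#' muscle/powerline interference above 45 Hz, bands where no maternal or
#' fetal electrocardiographic energy is expected. Prefiltering removes both
#' before any beat-based processing; the in-band (0.5-45 Hz) noise is what
#' the template denoiser must deal with.
NULL

# Squared magnitude response of an order-n analog Butterworth band-pass
# realized as high-pass(low_hz) * low-pass(high_hz). The square is the
# response of forward-backward filtering.
butter_bandpass_mag2 <- function(f, low_hz, high_hz, order) {
  lp <- 1 / (1 + (f / high_hz)^(2 * order))
  hp <- ifelse(f <= 0, 0, 1 / (1 + (low_hz / pmax(f, .Machine$double.xmin))^(2 * order)))
  lp * hp
}

# Zero-phase filtering by spectral multiplication with a real, even gain.
# The signal is mirrored (even extension, as in DCT filtering) so the
# implicit circular continuation is continuous at both joins and
# wrap-around leakage is second order (derivative kinks only).
fft_zero_phase <- function(x, fs, gain_fun) {
  n <- length(x)
  xe <- c(x, rev(x))
  m <- 2L * n
  f <- c(seq(0L, floor(m / 2)), seq(-ceiling(m / 2) + 1L, -1L)) * fs / m
  g <- gain_fun(abs(f))
  y <- Re(stats::fft(stats::fft(xe) * g, inverse = TRUE)) / m
  y[seq_len(n)]
}

#' Band-pass prefilter a trace (0.5-45 Hz by default)
#'
#' Applies a zero-phase band-pass with the squared magnitude response of an
#' order-`order` Butterworth band-pass (the response a forward-backward
#' time-domain filter would have). Realized by spectral multiplication on a
#' mirrored (even-extended) copy of the signal, so the phase is exactly
#' zero, R-peak positions are preserved, and the operator is exactly
#' linear.
#'
#' @param tr input `Trace`.
#' @param low_hz lower cut-off in Hz (default 0.5).
#' @param high_hz upper cut-off in Hz (default 45).
#' @param order Butterworth order of each (high-pass, low-pass) section,
#'   default 12 (steep enough that 50 Hz powerline is attenuated by more
#'   than 20 dB while the sub-40 Hz ECG band is untouched; see the
#'   passband flat; see the methods vignette).
#' @return a `Trace` of the same length and sampling rate.
#' @examples
#' tr <- trace(sin(2 * pi * 10 * seq(0, 5, by = 1e-3)) + 100, fs = 1000)
#' filt <- bandpass_prefilter(tr)   # DC offset removed, 10 Hz kept
#' @export
bandpass_prefilter <- function(tr, low_hz = 0.5, high_hz = 45, order = 12) {
  stopifnot_trace(tr)
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < tr$fs / 2))
    stop("bandpass_prefilter: need 0 < low_hz < high_hz < fs/2, got low_hz=",
         low_hz, ", high_hz=", high_hz, ", fs=", tr$fs)
  if (order < 1) stop("bandpass_prefilter: order must be >= 1")
  y <- fft_zero_phase(tr$samples, tr$fs, function(f)
    butter_bandpass_mag2(f, low_hz, high_hz, order))
  trace(y, tr$fs, label = tr$label)
}

#' Designed prefilter gain at given frequencies
#'
#' The (squared-Butterworth) amplitude gain the zero-phase prefilter applies
#' at frequency `f_hz`. Exposed so that filter behaviour can be checked
#' against its own design response.
#'
#' @param f_hz frequencies in Hz.
#' @param low_hz,high_hz,order as in [bandpass_prefilter()].
#' @return amplitude gain (dimensionless) at each frequency.
#' @export
prefilter_gain <- function(f_hz, low_hz = 0.5, high_hz = 45, order = 12) {
  butter_bandpass_mag2(f_hz, low_hz, high_hz, order)
}

# internal band-pass on a bare numeric vector (used by Pan-Tompkins and the
# synthetic noise shaping); same realization as bandpass_prefilter
bandpass_vec <- function(x, fs, low_hz, high_hz, order = 2) {
  fft_zero_phase(x, fs, function(f) butter_bandpass_mag2(f, low_hz, high_hz, order))
}

lowpass_vec <- function(x, fs, high_hz, order = 2) {
  fft_zero_phase(x, fs, function(f) 1 / (1 + (f / high_hz)^(2 * order)))
}
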