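#' @title Synthetic maternal + fetal ECG generator
#' @name synthgen
#' @description
#' Generates direct (scalp) and abdominal recordings with exact ground
#' truth so that every stage of the extraction cascade is testable without
#' clinical data. Beats are rendered as sums of Gaussian kernels (P, Q, R,
#' S, T) on a beat-phase variable — the standard dynamical ECG
#' construction — with RR intervals drawn from a first-order
#' autoregressive process. T-wave position and width scale with sqrt(RR),
#' creating exactly the beat-to-beat repolarization-length variability the
#' segmented-beat modulation is designed to track. Abdominal channels mix
#' a dominant maternal ECG, a small fetal ECG and three noise classes:
#' low-frequency baseline wander (< 0.5 Hz), powerline + EMG-like
#' high/in-band noise, and broadband Gaussian noise.
NULL

# Gaussian-kernel beat morphology. Offsets/widths in seconds relative to
# the R peak; T (and P, which precedes the NEXT R) scale with sqrt(RR).
# Amplitudes chosen so the QRS peak-to-peak excursion is ~1.
.default_shape <- list(
  p = list(amp = 0.15, off = -0.17, width = 0.025, scale_rr = TRUE),
  q = list(amp = -0.12, off = -0.025, width = 0.010, scale_rr = FALSE),
  r = list(amp = 0.80, off = 0.000, width = 0.012, scale_rr = FALSE),
  s = list(amp = -0.20, off = 0.025, width = 0.010, scale_rr = FALSE),
  t = list(amp = 0.30, off = 0.300, width = 0.055, scale_rr = TRUE)
)

#' Generate a quasi-periodic ECG beat train
#'
#' RR intervals follow a first-order autoregressive process (lag-1
#' correlation 0.8) with mean `60 / hr_bpm` s and standard deviation
#' derived from `hr_sd_bpm`, floored at 250 ms. Each beat is a sum of
#' Gaussian kernels; kernels marked `scale_rr` have their offset and width
#' multiplied by `sqrt(RR / RR_mean)`, so the repolarization segment
#' lengthens and shortens with the heart rate. The unit-amplitude train is
#' scaled by the caller.
#'
#' @param hr_bpm mean heart rate, 30-250 bpm.
#' @param hr_sd_bpm beat-to-beat heart-rate SD in bpm.
#' @param duration_s record length in seconds.
#' @param fs sampling rate in Hz.
#' @param seed integer seed; same seed, same output.
#' @param beat_shape kernel list (see the package default) — each entry
#'   has `amp` (relative), `off` and `width` (seconds), `scale_rr`.
#' @return list: `tr` (`Trace`, unit QRS amplitude), `rpeaks`
#'   (`RPeakSeries`, `source = "synthetic_truth"`), `rr_s` (RR intervals in
#'   seconds).
#' @export
gen_beat_train <- function(hr_bpm, hr_sd_bpm = 0, duration_s = 60, fs = 1000,
                           seed = 1L, beat_shape = NULL) {
  if (hr_bpm < 30 || hr_bpm > 250)
    stop("gen_beat_train: hr_bpm must be in [30, 250]")
  if (hr_sd_bpm < 0) stop("gen_beat_train: hr_sd_bpm must be >= 0")
  if (is.null(beat_shape)) beat_shape <- .default_shape
  set.seed(as.integer(seed))
  rr_mean <- 60 / hr_bpm
  rr_sd <- 60 * hr_sd_bpm / hr_bpm^2     # delta method: d(60/hr)/dhr
  phi <- 0.8
  n_guess <- ceiling(duration_s / rr_mean) + 10L
  innov <- stats::rnorm(n_guess, 0, rr_sd * sqrt(1 - phi^2))
  rr <- numeric(n_guess)
  rr[1L] <- rr_mean + stats::rnorm(1, 0, rr_sd)
  for (i in 2:n_guess) rr[i] <- rr_mean + phi * (rr[i - 1L] - rr_mean) + innov[i]
  rr <- pmax(rr, 0.25)
  r_times <- cumsum(c(rr_mean * 0.6, rr))     # first R ~0.6 RR into the record
  keep <- r_times < duration_s - 0.05
  r_times <- r_times[keep]
  if (length(r_times) < 2L)
    stop("gen_beat_train: record too short for two beats")
  rr_each <- diff(c(r_times, r_times[length(r_times)] + rr_mean))

  n <- as.integer(round(duration_s * fs))
  t <- (seq_len(n) - 1L) / fs
  x <- numeric(n)
  for (k in seq_along(r_times)) {
    sc <- sqrt(rr_each[k] / rr_mean)
    for (kern in beat_shape) {
      off <- if (isTRUE(kern$scale_rr)) kern$off * sc else kern$off
      wid <- if (isTRUE(kern$scale_rr)) kern$width * sc else kern$width
      c0 <- r_times[k] + off
      lo <- max(1L, as.integer(floor((c0 - 5 * wid) * fs)) + 1L)
      hi <- min(n, as.integer(ceiling((c0 + 5 * wid) * fs)) + 1L)
      if (lo <= hi) {
        idx <- lo:hi
        x[idx] <- x[idx] + kern$amp * exp(-0.5 * ((t[idx] - c0) / wid)^2)
      }
    }
  }
  ridx <- as.integer(round(r_times * fs)) + 1L
  ridx <- ridx[ridx >= 1L & ridx <= n]
  list(tr = trace(x, fs, label = "beat_train"),
       rpeaks = rpeak_series(ridx, fs, source = "synthetic_truth", n_samples = n),
       rr_s = rr_each)
}

#' Default synthetic-record configuration
#'
#' Amplitudes mirror the clinical scales of labor recordings: direct fetal
#' ECG ~150 uV QRS peak-to-peak on the scalp, fetal ~20 uV on the abdomen
#' against a dominant ~200 uV maternal ECG (ten-fold ratio), with baseline
#' wander, 50 Hz powerline, broadband and EMG-band noise.
#'
#' @param duration_s,fs record length (s) and sampling rate (Hz).
#' @param seed integer seed.
#' @param n_abdominal_channels 1-4 abdominal channels.
#' @return a `SynthConfig` list; override fields before passing to
#'   [gen_record_set()].
#' @export
synth_config <- function(duration_s = 60, fs = 1000, seed = 1L,
                         n_abdominal_channels = 4L) {
  list(
    duration_s = duration_s, fs = fs, seed = as.integer(seed),
    n_abdominal_channels = as.integer(n_abdominal_channels),
    maternal = list(mean_hr_bpm = 80, hr_sd_bpm = 3, amplitude_uv = 200,
                    beat_shape = NULL),
    fetal = list(mean_hr_bpm = 140, hr_sd_bpm = 5,
                 amplitude_direct_uv = 150, amplitude_abdominal_uv = 20,
                 beat_shape = NULL),
    noise = list(baseline_uv = 50, powerline_uv = 20, powerline_hz = 50,
                 broadband_uv = 10, emg_uv = 10),
    # per-channel gains applied to the maternal and fetal components;
    # sign flips emulate arbitrary abdominal lead polarity
    channel_gain_maternal = c(1, 0.85, -0.7, 0.9),
    channel_gain_fetal = c(1, 0.8, 0.6, -0.7)
  )
}

.gen_noise <- function(n, fs, cfg_noise, seed) {
  set.seed(as.integer(seed))
  t <- (seq_len(n) - 1L) / fs
  out <- numeric(n)
  if (cfg_noise$baseline_uv > 0) {
    bw <- lowpass_vec(cumsum(stats::rnorm(n)), fs, high_hz = 0.3, order = 2)
    s <- stats::sd(bw)
    if (s > 0) out <- out + cfg_noise$baseline_uv * bw / s
  }
  if (cfg_noise$powerline_uv > 0) {
    # mains frequency is stable to ~0.05 Hz; the phase wanders slowly
    drift <- lowpass_vec(cumsum(stats::rnorm(n, 0, 0.01)), fs, 0.1, 2)
    phase <- 2 * pi * cfg_noise$powerline_hz * t + drift
    out <- out + cfg_noise$powerline_uv * sin(phase)
  }
  if (cfg_noise$broadband_uv > 0)
    out <- out + stats::rnorm(n, 0, cfg_noise$broadband_uv)
  if (cfg_noise$emg_uv > 0) {
    emg <- bandpass_vec(stats::rnorm(n), fs, 20, 45, order = 2)
    s <- stats::sd(emg)
    if (s > 0) out <- out + cfg_noise$emg_uv * emg / s
  }
  out
}

#' Generate a synthetic record set with ground truth
#'
#' Realizes the additive recording model literally: the direct trace is the
#' scaled fetal beat train plus direct-channel noise; every abdominal
#' channel is a gain-scaled maternal train plus the scaled fetal train plus
#' channel noise. All truth components are stored exactly, so
#' `maternal + fetal + noise == recorded` holds bit-level per channel.
#'
#' @param cfg a [synth_config()] list (possibly with fields overridden).
#' @return list of class `fecg_synth_record`:
#'   `recordset` — list with `direct` (`Trace`), `abdominal` (list of
#'   `Trace`s), `fetal_rpeaks`, `maternal_rpeaks`, `metadata`;
#'   `truth` — `fetal_direct`, and per abdominal channel `fetal`,
#'   `maternal`, `noise` (numeric vectors in uV), plus `noise_direct`.
#' @export
gen_record_set <- function(cfg = synth_config()) {
  if (any(unlist(cfg$noise[c("baseline_uv", "powerline_uv", "broadband_uv", "emg_uv")]) < 0))
    stop("gen_record_set: noise amplitudes must be >= 0")
  if (cfg$fetal$mean_hr_bpm <= cfg$maternal$mean_hr_bpm)
    stop("gen_record_set: fetal mean HR must exceed maternal mean HR")
  nch <- cfg$n_abdominal_channels
  if (nch < 1L || nch > 4L) stop("gen_record_set: 1-4 abdominal channels")
  fs <- cfg$fs
  n <- as.integer(round(cfg$duration_s * fs))

  fet <- gen_beat_train(cfg$fetal$mean_hr_bpm, cfg$fetal$hr_sd_bpm,
                        cfg$duration_s, fs, seed = cfg$seed,
                        beat_shape = cfg$fetal$beat_shape)
  mat <- gen_beat_train(cfg$maternal$mean_hr_bpm, cfg$maternal$hr_sd_bpm,
                        cfg$duration_s, fs, seed = cfg$seed + 104729L,
                        beat_shape = cfg$maternal$beat_shape)

  fetal_direct <- cfg$fetal$amplitude_direct_uv * fet$tr$samples
  noise_direct <- .gen_noise(n, fs, cfg$noise, seed = cfg$seed + 7L)
  direct <- trace(fetal_direct + noise_direct, fs, label = "DREC")

  gm <- rep_len(cfg$channel_gain_maternal, nch)
  gf <- rep_len(cfg$channel_gain_fetal, nch)
  abdominal <- vector("list", nch)
  truth_ch <- vector("list", nch)
  for (j in seq_len(nch)) {
    m <- gm[j] * cfg$maternal$amplitude_uv * mat$tr$samples
    f <- gf[j] * cfg$fetal$amplitude_abdominal_uv * fet$tr$samples
    e <- .gen_noise(n, fs, cfg$noise, seed = cfg$seed + 100L + j)
    abdominal[[j]] <- trace(m + f + e, fs, label = sprintf("IREC_ch%d", j))
    truth_ch[[j]] <- list(maternal = m, fetal = f, noise = e)
  }
  structure(list(
    recordset = list(direct = direct, abdominal = abdominal,
                     fetal_rpeaks = fet$rpeaks, maternal_rpeaks = mat$rpeaks,
                     metadata = list(seed = cfg$seed, fs = fs,
                                     duration_s = cfg$duration_s)),
    truth = list(fetal_direct = fetal_direct, noise_direct = noise_direct,
                 channels = truth_ch),
    cfg = cfg
  ), class = "fecg_synth_record")
}
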