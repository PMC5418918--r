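#' @title Pan-Tompkins QRS detection
#' @name peak_detect
#' @description
#' Classical Pan-Tompkins detector used to locate the maternal R peaks on
#' abdominal channels, where the maternal ECG is the dominant component.
#' Stages: band-pass (5-15 Hz), five-point derivative, squaring,
#' moving-window integration (150 ms), adaptive dual-threshold peak
#' classification with a 200 ms refractory period, T-wave slope
#' discrimination and search-back at half threshold when an expected beat
#' is missed. Band-pass, derivative and integration are implemented
#' zero-phase (centered), so integrated peaks stay aligned with the R peak
#' and detections are refined to the extremum of |band-passed signal|
#' within +/-50 ms without a group-delay correction.
NULL

# centered moving average, zero-padded at the edges
.mwi <- function(x, w) {
  k <- stats::filter(x, rep(1 / w, w), sides = 2)
  k[is.na(k)] <- 0
  as.numeric(k)
}

# centered five-point derivative (zero-phase variant of the classical
# 1/8 * (2x[n] + x[n-1] - x[n-3] - 2x[n-4]) kernel)
.deriv5 <- function(x) {
  k <- stats::filter(x, c(2, 1, 0, -1, -2) / 8, sides = 2)
  k[is.na(k)] <- 0
  as.numeric(k)
}

# local maxima of v with at least min_dist samples between kept peaks
.local_maxima <- function(v, min_dist) {
  n <- length(v)
  if (n < 3L) return(integer())
  cand <- which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n]) + 1L
  cand <- cand[v[cand] > 0]
  if (!length(cand)) return(integer())
  keep <- integer()
  last <- -Inf
  for (i in cand) {
    if (i - last >= min_dist) {
      keep <- c(keep, i); last <- i
    } else if (v[i] > v[keep[length(keep)]]) {
      keep[length(keep)] <- i; last <- i
    }
  }
  keep
}

#' Detect R peaks with the Pan-Tompkins algorithm
#'
#' @param tr `Trace`, at least 2 s long, sampled at 200 Hz or more.
#' @param bandpass_low_hz,bandpass_high_hz QRS-enhancement band (defaults
#'   5 and 15 Hz).
#' @param integration_ms moving-window integration width (default 150 ms).
#' @param refractory_ms minimum distance between detections (default 200 ms).
#' @param refine_ms half-width of the window in which each detection is
#'   moved to the extremum of |band-passed signal| (default 50 ms).
#' @return `RPeakSeries` with `source = "pan_tompkins"`. Empty when no QRS
#'   energy is found (e.g. a flat trace). Thresholds adapt with running
#'   signal/noise estimates (0.125 update factor,
#'   `threshold = noise + 0.25 (signal - noise)`), so detections are
#'   invariant to amplitude scaling; lead polarity is handled by refining
#'   on the absolute band-passed signal.
#' @export
pan_tompkins <- function(tr, bandpass_low_hz = 5, bandpass_high_hz = 15,
                         integration_ms = 150, refractory_ms = 200,
                         refine_ms = 50) {
  stopifnot_trace(tr)
  fs <- tr$fs
  n <- length(tr$samples)
  if (fs < 200) stop("pan_tompkins: sampling rate must be >= 200 Hz")
  if (n < 2 * fs) stop("pan_tompkins: trace must be at least 2 s long")

  bp <- bandpass_vec(tr$samples, fs, bandpass_low_hz, bandpass_high_hz, order = 2)
  mwi <- .mwi(.deriv5(bp)^2, max(3L, as.integer(round(integration_ms * fs / 1000))))
  if (max(mwi) <= 0)
    return(rpeak_series(integer(), fs, source = "pan_tompkins"))

  refract <- as.integer(round(refractory_ms * fs / 1000))
  peaks <- .local_maxima(mwi, refract)
  if (!length(peaks)) return(rpeak_series(integer(), fs, source = "pan_tompkins"))

  # learning phase: first 2 s initialize the running estimates
  init <- mwi[seq_len(min(n, as.integer(2 * fs)))]
  spki <- 0.5 * max(init)
  npki <- 0.5 * mean(init)
  thr1 <- function() npki + 0.25 * (spki - npki)

  qrs <- integer()
  noise_peaks <- integer()
  rr_hist <- numeric()
  twave_win <- as.integer(round(0.36 * fs))
  slope_at <- function(i) {
    lo <- max(1L, i - refract %/% 2L); hi <- min(n, i + refract %/% 2L)
    max(abs(diff(mwi[lo:hi])))
  }

  accept <- function(i) {
    spki <<- 0.125 * mwi[i] + 0.875 * spki
    if (length(qrs)) rr_hist <<- c(rr_hist, i - qrs[length(qrs)])
    if (length(rr_hist) > 8L) rr_hist <<- rr_hist[(length(rr_hist) - 7L):length(rr_hist)]
    qrs <<- c(qrs, i)
  }

  for (p in peaks) {
    is_qrs <- FALSE
    if (mwi[p] > thr1()) {
      is_qrs <- TRUE
      # T-wave discrimination: close to the previous beat and much flatter
      if (length(qrs) && (p - qrs[length(qrs)]) < twave_win &&
          slope_at(p) < 0.5 * slope_at(qrs[length(qrs)]))
        is_qrs <- FALSE
    }
    if (is_qrs) {
      accept(p)
    } else {
      noise_peaks <- c(noise_peaks, p)
      npki <- 0.125 * mwi[p] + 0.875 * npki
    }
    # search-back: expected beat missed -> recheck skipped peaks at thr/2
    if (length(qrs) && length(rr_hist) >= 2L) {
      rr_avg <- mean(rr_hist)
      if ((p - qrs[length(qrs)]) > 1.66 * rr_avg && length(noise_peaks)) {
        cand <- noise_peaks[noise_peaks > qrs[length(qrs)] + refract &
                              noise_peaks < p]
        cand <- cand[mwi[cand] > 0.5 * thr1()]
        if (length(cand)) {
          best <- cand[which.max(mwi[cand])]
          spki <- 0.25 * mwi[best] + 0.75 * spki
          qrs <- sort(c(qrs, best))
          noise_peaks <- setdiff(noise_peaks, best)
        }
      }
    }
  }
  if (!length(qrs)) return(rpeak_series(integer(), fs, source = "pan_tompkins"))

  # refine to the extremum of |bp| within +/- refine_ms
  w <- as.integer(round(refine_ms * fs / 1000))
  refined <- vapply(qrs, function(i) {
    lo <- max(1L, i - w); hi <- min(n, i + w)
    lo + which.max(abs(bp[lo:hi])) - 1L
  }, integer(1))
  refined <- sort(unique(refined))
  # enforce the refractory distance post-refinement, keeping the stronger peak
  if (length(refined) > 1L) {
    keep <- refined[1L]
    for (i in refined[-1L]) {
      if (i - keep[length(keep)] >= refract) keep <- c(keep, i)
      else if (abs(bp[i]) > abs(bp[keep[length(keep)]])) keep[length(keep)] <- i
    }
    refined <- keep
  }
  rpeak_series(refined, fs, source = "pan_tompkins", n_samples = n)
}

#' Match detected peaks against a reference
#'
#' Greedy one-to-one matching within a tolerance window; the standard way
#' QRS detectors are scored.
#'
#' @param detected,reference `RPeakSeries` on the same sampling grid.
#' @param tol_ms matching window half-width in milliseconds.
#' @return list with counts `tp`, `fp`, `fn`, `sensitivity`
#'   (`tp / (tp + fn)`) and `ppv` (`tp / (tp + fp)`).
#' @export
match_peaks <- function(detected, reference, tol_ms = 50) {
  if (!is_rpeaks(detected) || !is_rpeaks(reference))
    stop("match_peaks: both arguments must be RPeakSeries")
  tol <- round(tol_ms * reference$fs / 1000)
  det <- detected$indices; ref <- reference$indices
  used <- logical(length(det))
  tp <- 0L
  for (r in ref) {
    ok <- which(!used & abs(det - r) <= tol)
    if (length(ok)) {
      used[ok[which.min(abs(det[ok] - r))]] <- TRUE
      tp <- tp + 1L
    }
  }
  fp <- sum(!used); fn <- length(ref) - tp
  list(tp = tp, fp = fp, fn = fn,
       sensitivity = if (length(ref)) tp / (tp + fn) else NA_real_,
       ppv = if (length(det)) tp / (tp + fp) else NA_real_)
}
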