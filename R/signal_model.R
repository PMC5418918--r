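#' @title Domain types for fetal-ECG extraction
#' @name signal_model
#' @description
#' The pipeline's common currency is a uniformly sampled voltage trace in
#' microvolts. Direct (scalp) recordings decompose additively into a fetal
#' ECG estimate and in-band noise; abdominal recordings additionally carry
#' the maternal ECG. All decompositions conserve the input sample-by-sample.
#'
#' Conventions: samples are stored in microvolts; sample indexing is 1-based
#' at the R surface (printed and returned indices), with half-open beat
#' intervals `[start, end)` used internally for segmentation arithmetic.
NULL

#' Construct a Trace
#'
#' A `Trace` is a uniformly sampled voltage signal in microvolts with a
#' sampling rate in Hz and a free-text label.
#'
#' @param samples numeric vector of voltages in microvolts; all finite,
#'   length at least 2.
#' @param fs sampling rate in Hz, positive.
#' @param label free-text channel label.
#' @return an object of class `fecg_trace` with fields `samples`, `fs`,
#'   `label`.
#' @export
trace <- function(samples, fs, label = "") {
  samples <- as.numeric(samples)
  if (length(samples) < 2L)
    stop("trace: need at least 2 samples, got ", length(samples))
  if (!all(is.finite(samples)))
    stop("trace: all samples must be finite")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("trace: fs must be a single positive number")
  structure(list(samples = samples, fs = as.numeric(fs),
                 label = as.character(label)[1L]),
            class = "fecg_trace")
}

#' @export
print.fecg_trace <- function(x, ...) {
  cat(sprintf("<Trace '%s': %d samples @ %g Hz (%.1f s), range [%.1f, %.1f] uV>\n",
              x$label, length(x$samples), x$fs,
              length(x$samples) / x$fs,
              min(x$samples), max(x$samples)))
  invisible(x)
}

#' @export
length.fecg_trace <- function(x) length(x$samples)

is_trace <- function(x) inherits(x, "fecg_trace")

stopifnot_trace <- function(x, what = "trace") {
  if (!is_trace(x)) stop(what, " must be a Trace (see trace())")
  invisible(x)
}

#' Construct an R-peak series
#'
#' Strictly increasing sample indices (1-based) of R peaks annotating a
#' trace sampled at `fs` Hz.
#'
#' @param indices integer sample positions, strictly increasing.
#' @param fs sampling rate of the annotated trace in Hz.
#' @param source one of `"reference"` (expert/database markers),
#'   `"pan_tompkins"` (detector output), `"synthetic_truth"` (generator
#'   ground truth).
#' @param n_samples optional trace length; when given, indices must lie in
#'   `[1, n_samples]`.
#' @return an object of class `fecg_rpeaks` with fields `indices`, `fs`,
#'   `source`.
#' @export
rpeak_series <- function(indices, fs,
                         source = c("reference", "pan_tompkins", "synthetic_truth"),
                         n_samples = NULL) {
  source <- match.arg(source)
  indices <- as.integer(round(indices))
  if (length(indices) && any(diff(indices) <= 0L))
    stop("rpeak_series: indices must be strictly increasing")
  if (length(indices) && indices[1L] < 1L)
    stop("rpeak_series: indices must be >= 1")
  if (!is.null(n_samples) && length(indices) && indices[length(indices)] > n_samples)
    stop("rpeak_series: index ", indices[length(indices)],
         " beyond trace length ", n_samples)
  if (!is.numeric(fs) || fs <= 0) stop("rpeak_series: fs must be positive")
  structure(list(indices = indices, fs = as.numeric(fs), source = source),
            class = "fecg_rpeaks")
}

#' @export
print.fecg_rpeaks <- function(x, ...) {
  cat(sprintf("<RPeakSeries: %d peaks @ %g Hz, source=%s>\n",
              length(x$indices), x$fs, x$source))
  invisible(x)
}

#' @export
length.fecg_rpeaks <- function(x) length(x$indices)

is_rpeaks <- function(x) inherits(x, "fecg_rpeaks")

check_rpeaks_for <- function(rpeaks, tr, min_peaks = 2L) {
  if (!is_rpeaks(rpeaks)) stop("rpeaks must be an RPeakSeries (see rpeak_series())")
  stopifnot_trace(tr)
  if (abs(rpeaks$fs - tr$fs) > 1e-9)
    stop("rpeaks fs (", rpeaks$fs, ") does not match trace fs (", tr$fs, ")")
  n <- length(tr$samples)
  if (length(rpeaks$indices) && rpeaks$indices[length(rpeaks$indices)] > n)
    stop("rpeaks index beyond trace length ", n)
  if (length(rpeaks$indices) < min_peaks)
    stop("need at least ", min_peaks, " R peaks, got ", length(rpeaks$indices))
  invisible(rpeaks)
}

.check_same_grid <- function(..., what = "decomposition") {
  trs <- list(...)
  fs <- vapply(trs, function(t) t$fs, 0)
  n  <- vapply(trs, function(t) length(t$samples), 0L)
  if (any(abs(fs - fs[1L]) > 1e-9) || any(n != n[1L]))
    stop(what, ": all component traces must share fs and length")
  invisible(TRUE)
}

# conservation tolerance shared by the decomposition constructors (uV)
CONSERVATION_TOL <- 1e-6

#' Direct-recording decomposition
#'
#' Additive split of a prefiltered direct (scalp) recording into the fetal
#' ECG estimate and the in-band noise residual:
#' `input = dfecg + dn`, conserved sample-by-sample.
#'
#' @param input prefiltered direct recording (`Trace`).
#' @param dfecg extracted fetal ECG (`Trace`).
#' @param dn in-band noise residual (`Trace`).
#' @return object of class `fecg_direct_decomp`.
#' @export
direct_decomposition <- function(input, dfecg, dn) {
  stopifnot_trace(input, "input"); stopifnot_trace(dfecg, "dfecg")
  stopifnot_trace(dn, "dn")
  .check_same_grid(input, dfecg, dn, what = "direct_decomposition")
  dev <- max(abs(dfecg$samples + dn$samples - input$samples))
  if (dev > CONSERVATION_TOL)
    stop("direct_decomposition: dfecg + dn != input (max |dev| = ", dev, " uV)")
  structure(list(input = input, dfecg = dfecg, dn = dn),
            class = "fecg_direct_decomp")
}

#' Abdominal-recording decomposition
#'
#' Additive split of a prefiltered abdominal (indirect) channel:
#' `input = mecg + ifecg_noisy` and `ifecg_noisy = ifecg + in_noise`,
#' each conserved sample-by-sample.
#'
#' @param input prefiltered abdominal channel (`Trace`).
#' @param mecg estimated maternal ECG (`Trace`).
#' @param ifecg_noisy input minus mecg, i.e. fetal ECG plus in-band noise.
#' @param ifecg denoised fetal ECG estimate.
#' @param in_noise in-band noise residual.
#' @param extra optional named list of auxiliary results (e.g. detected
#'   maternal peaks, template noise estimates) carried for reporting.
#' @return object of class `fecg_abdominal_decomp`.
#' @export
abdominal_decomposition <- function(input, mecg, ifecg_noisy, ifecg, in_noise,
                                    extra = list()) {
  for (nm in c("input", "mecg", "ifecg_noisy", "ifecg", "in_noise"))
    stopifnot_trace(get(nm), nm)
  .check_same_grid(input, mecg, ifecg_noisy, ifecg, in_noise,
                   what = "abdominal_decomposition")
  dev1 <- max(abs(mecg$samples + ifecg_noisy$samples - input$samples))
  dev2 <- max(abs(ifecg$samples + in_noise$samples - ifecg_noisy$samples))
  if (dev1 > CONSERVATION_TOL)
    stop("abdominal_decomposition: mecg + ifecg_noisy != input (", dev1, " uV)")
  if (dev2 > CONSERVATION_TOL)
    stop("abdominal_decomposition: ifecg + in_noise != ifecg_noisy (", dev2, " uV)")
  structure(c(list(input = input, mecg = mecg, ifecg_noisy = ifecg_noisy,
                   ifecg = ifecg, in_noise = in_noise), extra),
            class = "fecg_abdominal_decomp")
}

#' Signal-to-noise report
#'
#' Carrier for one SNR evaluation: the beat-based signal amplitude, the
#' 4-sigma noise amplitude and their ratio in dB,
#' `snr_db = 10 log10(signal_amplitude / noise_amplitude)`.
#'
#' @param signal_amplitude microvolts, non-negative.
#' @param noise_amplitude microvolts, non-negative.
#' @param kind one of `"DSNR"`, `"ISNR1"`, `"ISNR2"`.
#' @return object of class `fecg_snr_report` with the dB value in `snr_db`.
#' @export
snr_report <- function(signal_amplitude, noise_amplitude,
                       kind = c("DSNR", "ISNR1", "ISNR2")) {
  kind <- match.arg(kind)
  structure(list(signal_amplitude = signal_amplitude,
                 noise_amplitude = noise_amplitude,
                 snr_db = snr_db(signal_amplitude, noise_amplitude),
                 kind = kind),
            class = "fecg_snr_report")
}

#' @export
print.fecg_snr_report <- function(x, ...) {
  cat(sprintf("<%s: signal %.1f uV / noise %.1f uV = %.1f dB>\n",
              x$kind, x$signal_amplitude, x$noise_amplitude, x$snr_db))
  invisible(x)
}
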