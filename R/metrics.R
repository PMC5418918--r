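#' @title Signal-quality metrics
#' @name metrics
#' @description
#' Quality of an extracted fetal ECG is quantified the way the field does
#' for pseudo-periodic signals: the deterministic component's amplitude is
#' the mean per-beat peak-to-peak excursion; a Gaussian-like noise
#' residual's amplitude is 4 standard deviations (covering ~95% of its
#' excursions); their ratio in dB is the SNR. Distributions over records
#' and channels are summarized as median [25th; 75th] percentiles and
#' compared with the Wilcoxon rank-sum test; morphological correspondence
#' between two extractions of the same fetal heart is measured with
#' Pearson's correlation.
NULL

#' Beat-based signal amplitude
#'
#' Mean over complete beats of the within-beat max-minus-min excursion.
#' Beats are defined exactly as in [segment_beats()], so edge samples
#' outside complete beats are excluded.
#'
#' @param tr `Trace`.
#' @param rpeaks `RPeakSeries` (at least 2 peaks).
#' @param qrs_pre_ms,qrs_post_ms beat-window convention, see
#'   [segment_beats()].
#' @return amplitude in microvolts.
#' @export
signal_amplitude <- function(tr, rpeaks, qrs_pre_ms = 100, qrs_post_ms = 100) {
  seg <- segment_beats(tr, rpeaks, qrs_pre_ms, qrs_post_ms)
  x <- tr$samples
  p2p <- vapply(seq_len(nrow(seg)), function(i) {
    b <- x[seg$beat_start[i]:(seg$tu_end[i] - 1L)]
    max(b) - min(b)
  }, numeric(1))
  mean(p2p)
}

#' Noise amplitude as 4 standard deviations
#'
#' For a zero-mean, approximately Gaussian residual, 4 SD spans about 95%
#' of the excursions and is the conventional amplitude proxy. Computed over
#' the entire trace with the sample (n-1) standard deviation.
#'
#' @param tr `Trace`.
#' @return amplitude in microvolts.
#' @export
noise_amplitude <- function(tr) {
  stopifnot_trace(tr)
  4 * stats::sd(tr$samples)
}

#' Signal-to-noise ratio in dB
#'
#' `10 * log10(signal_amplitude / noise_amplitude)`.
#'
#' @param signal_amplitude,noise_amplitude amplitudes in the same units,
#'   both strictly positive.
#' @return SNR in dB.
#' @export
snr_db <- function(signal_amplitude, noise_amplitude) {
  if (any(signal_amplitude <= 0) || any(noise_amplitude <= 0))
    stop("snr_db: amplitudes must be strictly positive")
  10 * log10(signal_amplitude / noise_amplitude)
}

#' Pearson correlation between two traces
#'
#' Product-moment correlation with the two-sided p-value from the
#' t-transform on n-2 degrees of freedom.
#'
#' @param x,y `Trace`s (or bare numeric vectors) of equal length >= 3.
#' @return list of class `fecg_correlation`: `rho`, `p_value`, `n`.
#' @export
pearson <- function(x, y) {
  xv <- if (is_trace(x)) x$samples else as.numeric(x)
  yv <- if (is_trace(y)) y$samples else as.numeric(y)
  n <- length(xv)
  if (length(yv) != n) stop("pearson: traces must have equal length")
  if (n < 3L) stop("pearson: need at least 3 paired samples")
  if (stats::sd(xv) == 0 || stats::sd(yv) == 0)
    stop("pearson: zero-variance input")
  r <- sum((xv - mean(xv)) * (yv - mean(yv))) /
    ((n - 1) * stats::sd(xv) * stats::sd(yv))
  r <- max(-1, min(1, r))
  p <- if (abs(r) == 1) 0 else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  structure(list(rho = r, p_value = p, n = n), class = "fecg_correlation")
}

#' @export
print.fecg_correlation <- function(x, ...) {
  cat(sprintf("<rho = %.3f, p = %.3g, n = %d>\n", x$rho, x$p_value, x$n))
  invisible(x)
}

# exact two-sided rank-sum p by enumeration of all C(N, n_small) subsets
.ranksum_exact <- function(a, b) {
  if (length(a) > length(b)) { tmp <- a; a <- b; b <- tmp }
  na <- length(a); N <- na + length(b)
  ranks <- rank(c(a, b))
  w_obs <- sum(ranks[seq_len(na)])
  combos <- utils::combn(N, na)
  allr <- seq_len(N)  # no ties by precondition, ranks are 1..N
  w_all <- colSums(matrix(allr[combos], nrow = na))
  mu <- na * (N + 1) / 2
  p <- mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
  min(1, p)
}

# normal approximation with tie correction and continuity correction
.ranksum_normal <- function(a, b) {
  na <- length(a); nb <- length(b); N <- na + nb
  ranks <- rank(c(a, b))
  w <- sum(ranks[seq_len(na)])
  mu <- na * (N + 1) / 2
  tie_tab <- table(c(a, b))
  tie_term <- sum(tie_tab^3 - tie_tab) / (N * (N - 1))
  sigma2 <- na * nb / 12 * ((N + 1) - tie_term)
  if (sigma2 <= 0) return(1)
  z <- (abs(w - mu) - 0.5) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-max(z, 0)))
}

#' Wilcoxon rank-sum test for equal medians
#'
#' Two-sided p-value. Uses the exact null distribution (full enumeration of
#' rank assignments) when the smaller sample has at most 10 values and the
#' pooled sample has no ties; otherwise the normal approximation with tie
#' and continuity corrections.
#'
#' @param a,b numeric vectors, both non-empty.
#' @param exact force (`TRUE`) or forbid (`FALSE`) enumeration; default
#'   `NULL` applies the rule above. Forcing `exact = TRUE` with ties is an
#'   error.
#' @return two-sided p-value.
#' @export
ranksum <- function(a, b, exact = NULL) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (!length(a) || !length(b)) stop("ranksum: both samples must be non-empty")
  ties <- anyDuplicated(c(a, b)) > 0
  if (is.null(exact)) exact <- min(length(a), length(b)) <= 10 && !ties
  if (exact && ties) stop("ranksum: exact enumeration requires no ties")
  if (exact) .ranksum_exact(a, b) else .ranksum_normal(a, b)
}

#' Median and quartile summary
#'
#' Summarizes a set of values as median, 25th and 75th percentiles using
#' midpoint-position linear interpolation (the p-th percentile interpolates
#' between order statistics placed at positions `100 (i - 0.5) / n`;
#' `quantile(type = 5)`). `mode = "per_record_median"` first collapses each
#' record to its median and then summarizes the per-record medians — the
#' natural aggregation when channels within a record are not independent.
#'
#' @param values numeric vector, non-empty.
#' @param mode `"pooled"` or `"per_record_median"`.
#' @param record_ids record identifier per value; required for
#'   `"per_record_median"`.
#' @return list of class `fecg_summary`: `median`, `p25`, `p75`, `n`.
#' @export
summarize_values <- function(values, mode = c("pooled", "per_record_median"),
                             record_ids = NULL) {
  mode <- match.arg(mode)
  values <- as.numeric(values)
  if (!length(values) || any(!is.finite(values)))
    stop("summarize_values: need at least one finite value")
  if (mode == "per_record_median") {
    if (is.null(record_ids) || length(record_ids) != length(values))
      stop("summarize_values: record_ids required for per_record_median")
    values <- as.numeric(tapply(values, record_ids, stats::median))
  }
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 5, names = FALSE)
  structure(list(median = q[2L], p25 = q[1L], p75 = q[3L],
                 n = length(values)),
            class = "fecg_summary")
}

#' @export
print.fecg_summary <- function(x, ...) {
  cat(sprintf("<median %.4g [%.4g; %.4g], n = %d>\n",
              x$median, x$p25, x$p75, x$n))
  invisible(x)
}
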