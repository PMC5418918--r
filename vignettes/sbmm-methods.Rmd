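---
title: "Methods: segmented-beat modulation for fetal ECG extraction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segmented-beat modulation for fetal ECG extraction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sbmmfecg)
```

## The problem

Fetal electrocardiography comes in two flavours. A *direct* recording
(DREC), taken with a scalp electrode during labor, is essentially a noisy
fetal ECG: `DREC = DFECG + DN`, where `DN` is in-band noise. An *indirect*
recording (IREC), taken from electrodes on the maternal abdomen, is
noninvasive and usable from roughly the 38th week of gestation (once the
vernix caseosa stops shielding the fetus electrically) but is dominated by
the maternal ECG: `IREC = IFECG + MECG + IN`, with the fetal component an
order of magnitude smaller than the maternal one (tens of µV against
hundreds). Extracting a clinically usable IFECG is therefore a denoising
problem with two stages: cancel MECG, then suppress IN.

Both recordings are prefiltered to 0.5–45 Hz before any beat-based
processing: below 0.5 Hz there is only baseline wander, above 45 Hz only
muscle noise and powerline interference; neither band carries maternal or
fetal electrocardiographic energy.

## The denoiser

The segmented-beat modulation method (SBMM) is a template-based denoiser
that assumes R-peak positions are known. Each beat is split into

* a **QRS segment** of fixed duration around the R peak (the QRS complex
  does not change duration with heart rate), and
* a **TU segment** — everything from the end of the QRS window to the
  start of the next beat's QRS window. Its length varies beat to beat with
  the RR interval, because the repolarization (T wave) stretches and
  compresses with heart rate. The P wave of the *next* beat lies at the
  end of the current TU segment and is modulated with it.

The TU segments are *modulated*: each is resampled onto the reference TU
length (the median of the per-beat TU lengths). In this common domain a
pointwise template is estimated — the median across beats by default
(robust to transient artifacts; the mean is available and makes the
`sd/sqrt(N)` averaging property exact). Reconstruction *demodulates*: each
beat emits the QRS template followed by the TU template resampled back to
that beat's own TU length. The residual is the input minus the
reconstruction — a pure subtraction, so the decomposition conserves the
input (to one floating-point rounding when re-added; the package's
decomposition constructors enforce conservation to 1e-6 µV).

The modulation step is the whole point. A fixed-length average beat pasted
at each R peak misaligns T waves whenever the heart rate varies, leaving
repolarization-shaped artifacts in the residual. The package ships this
ablation (`sbmm_denoise_fixed()`) precisely so the claim is testable: on
synthetic ECG whose TU length varies ±15 % beat to beat, the SBMM residual
RMS is strictly smaller than the ablation's (a property test and an
acceptance criterion).

### Extraction cascades

* **Direct** (`extract_direct`): prefilter → SBMM with the reference fetal
  R peaks → `DFECG`; `DN` by subtraction.
* **Indirect** (`extract_indirect`): prefilter → Pan-Tompkins detects the
  *maternal* R peaks (MECG dominates, so the adult-ECG detector applies)
  → SBMM with maternal QRS windows gives `MECG` → subtract → SBMM with the
  *fetal* R peaks and fetal QRS windows gives `IFECG`; `IN` by
  subtraction. Fetal R peaks are an input throughout: fetal peak
  detection is a separate problem and out of scope here.

## Parameters that matter

| parameter | default | why |
|---|---|---|
| prefilter band | 0.5–45 Hz | the ECG band; fixed by the problem |
| prefilter order | 12 | see below |
| maternal QRS window | 100 + 100 ms | contains the adult QRS with margin |
| fetal QRS window | 50 + 50 ms | the fetal QRS is much narrower; a wide window would steal modulable TU samples |
| template statistic | median | robust to single-beat artifacts |
| interpolation | cubic (natural spline), linear below 4 samples | smooth repolarization waves; linear mode is interpolation-exact on ramps |
| reference TU length | median of per-beat TU lengths | minimizes average stretch distortion |
| Pan-Tompkins constants | published recipe (5–15 Hz, 150 ms integration, 0.125 update, 200 ms refractory) | reference algorithm, used as cited |

**Filter realization.** No DSP package is available in the target R
environment, so the zero-phase band-pass is realized spectrally: the
signal is mirrored (even extension, as in DCT filtering, so the circular
continuation has no jumps), its spectrum is multiplied by the *squared*
magnitude response of an order-*n* analog Butterworth band-pass — exactly
the response a forward-backward time-domain filter would have — and the
first half is kept. The operator is exactly linear and exactly zero-phase,
which SBMM needs: R-peak indices must stay aligned through the filter.

**Filter order.** The conventional choice would be order 4, but its
forward-backward gain at 50 Hz from a 45 Hz cutoff is 0.30 — a 10 dB
suppression, not enough for the prefilter to *remove* powerline
interference, which this pipeline requires since a separate notch is
deliberately out of scope. Order 12 puts the 50 Hz gain at 0.074
(22.6 dB) while leaving the band below 40 Hz untouched. With the spectral
realization a steep order costs nothing numerically (there is no
time-domain recursion to go unstable).

**ISNR2's denominator.** SNR is evaluated twice on the indirect cascade:
after MECG subtraction (ISNR1) and after the final denoising (ISNR2). Both
use the same signal amplitude — the mean per-beat peak-to-peak excursion
of the denoised `ifecg`, the only available estimate of the fetal
amplitude. ISNR1's noise amplitude is `4 × SD(ifecg_noisy − ifecg)`, the
in-band noise present before denoising. ISNR2 measures the quality of the
final trace, whose residual noise is *inside* the reconstruction and not
directly observable; the package estimates it as 4 × the RMS pointwise
standard error of the beat template (between-beat SD divided by √N). This
is the design choice resolving an ambiguity in how a pre-denoising fetal
amplitude could be measured at all; it scales as σ/√N, which for the
~140 fetal beats of a one-minute record predicts the ~12 dB gap between
ISNR1 and ISNR2 that clinical benchmarks report, and it makes
`ISNR2 > ISNR1` a structural property whenever at least two beats are
averaged — which is exactly the claim the denoiser makes.

**Statistics conventions.** Percentiles use midpoint-position linear
interpolation (`quantile(type = 5)`): it is the convention that reproduces
the published quartile brackets of the benchmark table (e.g. a 75th
percentile of 157 µV from the five direct amplitudes
{104, 87, 89, 208, 140}), which fixes the convention empirically. Summary
aggregation is explicit (`pooled` vs `per_record_median`) because the
benchmark's own medians mix the two: the 22 µV fetal abdominal amplitude
is a per-record-median figure while the −2.3 dB ISNR1 median is pooled
over all 20 channels. The rank-sum test enumerates the exact null when the
smaller sample has ≤ 10 values and there are no ties, and otherwise uses
the normal approximation with tie and continuity corrections — the variant
that reproduces the benchmark's published P = 7.66·10⁻⁴ for 5 direct vs 20
abdominal amplitudes (the exact enumeration would give 2/C(25,5) ≈
3.8·10⁻⁵ there, since the samples do not overlap; the published value
identifies the approximate test).

## The synthetic world

The generator (`gen_record_set`) realizes the additive recording model
literally, with exact ground truth per channel. Beats are sums of Gaussian
kernels (P, Q, R, S, T) placed on a beat-phase variable — the standard
dynamical ECG construction. RR intervals follow a first-order
autoregressive process (lag-1 correlation 0.8) floored at 250 ms. T and P
kernel offsets and widths scale with √RR, which creates exactly the
repolarization-length variability the modulation step exists to track.
Defaults state the clinical scales: maternal 80 bpm (SD 3) at 200 µV on
the abdomen, fetal 140 bpm (SD 5) at 150 µV on the scalp and 20 µV on the
abdomen; per-channel gains include sign flips (abdominal lead polarity is
arbitrary); noise is baseline wander (< 0.5 Hz random walk, 50 µV),
powerline (50 Hz, slow phase drift bounded by mains stability, 20 µV),
broadband Gaussian (10 µV) and EMG-band 20–45 Hz noise (10 µV).

What the generator does *not* emulate: electrode motion artifacts, uterine
contraction bursts, fetal movement re-orienting the cardiac vector,
ectopic beats, and any nonlinear volume-conductor geometry. A green test
therefore establishes that the pipeline is correct *for quasi-periodic
sources in additive stationary noise* — the model the method itself
assumes — not that it survives every clinical pathology.

One deliberate property: beats are rendered in continuous time and
sampled, so when the RR interval is not an integer number of samples the
beats carry sub-sample phase jitter, exactly as real sampled ECG does.
This alone leaves a residual of a few percent of the peak-to-peak
amplitude (the template is sample-locked to the rounded R index). The
noise-free identity tests pin the heart rate to a sample-commensurate RR
(150 bpm at 500 Hz) to isolate the denoiser's own error; the jitter floor
is a measurement-model limitation, not a denoiser defect.

## Numerical choices and degenerate inputs

* Indexing is 1-based (the R convention) with half-open beat intervals
  `[start, end)`; every boundary in the package uses this single
  convention.
* Modulation pins segment endpoints exactly; a segment resampled to its
  own length is returned unchanged.
* Reference TU length rounding uses banker's rounding (half-sample ties to
  the nearest even length).
* Beats that would extend outside the trace are dropped; samples outside
  complete beats pass through to the clean estimate unchanged (zero
  residual there) and are excluded from template estimation and beat-based
  amplitudes.
* Segmentation refuses any RR interval not longer than the QRS window,
  naming the offending beat. Fewer than two complete beats is an error —
  there is nothing to average.
* A flat trace yields an empty Pan-Tompkins result; the indirect cascade
  turns that into a "no maternal rhythm" error rather than guessing.
* `snr_db` requires strictly positive amplitudes; equal amplitudes give
  exactly 0 dB.

## Known limitations

* Performance at clinical scale on the real 5-record database is not
  asserted numerically by the test suite: those values depend on the
  PhysioNet accession and unpublished implementation constants of the
  original processing chain. The WFDB reader and `evaluate_record()` make
  the integration check a one-liner once the records are downloaded.
* Single-channel processing only; the four abdominal channels are never
  fused.
* No beat-class handling: an ectopic beat contaminates (mildly, under the
  median) the single template rather than getting its own.
* The residual-noise estimate behind ISNR2 assumes independent noise
  across beats; correlated in-band noise (e.g. residual powerline) would
  make it optimistic.

## Reproducing the acceptance report

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes, from scratch: the SNR arithmetic and every summary statistic
of the published benchmark table (shipped as
`inst/extdata/benchmark_table1.csv`), Pan-Tompkins sensitivity/PPV at
10 dB, SBMM white-noise recovery correlation, and the 27-mixture indirect
extraction grid (ISNR2 > ISNR1 fraction and correlation at the noise
extremes). All randomness derives from `--seed`.
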