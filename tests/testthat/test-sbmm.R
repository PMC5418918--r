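test_that("segmentation arithmetic follows the QRS/TU window convention", {
  fs <- 1000
  tr <- trace(rnorm(3000), fs)

  seg <- segment_beats(tr, rpeak_series(c(500, 1500, 2500), fs), 100, 100)
  expect_equal(nrow(seg), 2)
  expect_equal(rep(attr(seg, "qrs_len"), 2), seg$qrs_end - seg$qrs_start)
  expect_equal(seg$qrs_end - seg$qrs_start, c(200, 200))
  expect_equal(seg$tu_len, c(800, 800))

  seg2 <- segment_beats(tr, rpeak_series(c(500, 1300, 2500), fs), 100, 100)
  expect_equal(seg2$tu_len, c(600, 1000))

  expect_error(
    segment_beats(trace(rnorm(1000), fs), rpeak_series(c(500, 650), fs), 100, 100),
    "RR interval of beat 1")
})

test_that("modulation resamples exactly and preserves endpoints", {
  ramp <- c(0, 1, 2, 3, 4)
  expect_equal(modulate_segment(ramp, 9, method = "linear"),
               seq(0, 4, by = 0.5))
  # identity when target length equals own length
  set.seed(1); seg <- rnorm(37)
  expect_identical(modulate_segment(seg, 37), seg)
  expect_error(modulate_segment(c(1), 5), "at least 2")
  expect_error(modulate_segment(ramp, 1), "target_len")
})

test_that("modulation round trip on band-limited segments is near-lossless", {
  # oracle: the original samples; L -> M -> L must come back for M >= L/2
  x <- seq(0, 1, length.out = 200)
  seg <- sin(2 * pi * 2 * x) + 0.4 * cos(2 * pi * 5 * x)
  p2p <- diff(range(seg))
  for (M in c(100, 150, 200, 317, 400)) {
    back <- modulate_segment(modulate_segment(seg, M), 200)
    expect_lt(max(abs(back - seg)), 0.01 * p2p)
  }
})

test_that("template of identical constant-RR beats is one beat, exactly", {
  g <- periodic_ecg(duration_s = 20, fs = 500)
  seg <- segment_beats(g$tr, g$rpeaks, 100, 100)
  tmpl <- build_template(g$tr, seg, stat = "median")
  beat1 <- g$tr$samples[seg$beat_start[2]:(seg$tu_end[2] - 1L)]
  expect_equal(c(tmpl$qrs_template, tmpl$tu_template), beat1,
               tolerance = 1e-10)
  expect_equal(tmpl$n_beats_used, nrow(seg))
  expect_error(build_template(g$tr, seg[1, ]), "at least 2")
})

test_that("mean-template noise scales as sigma/sqrt(N) (Monte-Carlo)", {
  # 600 seeded trials (scaled from 1000 for CPU budget; SD estimate
  # precision ~3%, assertion band 12%)
  fs <- 200; sigma <- 1
  g <- periodic_ecg(duration_s = 14, fs = fs, hr_bpm = 75)
  seg <- segment_beats(g$tr, g$rpeaks, 100, 100)
  N <- nrow(seg)
  set.seed(99)
  trials <- replicate(600, {
    noisy <- trace(g$tr$samples + rnorm(length(g$tr$samples), 0, sigma), fs)
    tmpl <- build_template(noisy, seg, stat = "mean")
    c(tmpl$qrs_template, tmpl$tu_template)
  })
  err_sd <- mean(apply(trials, 1, sd))
  expect_equal(err_sd, sigma / sqrt(N), tolerance = 0.12)
})

test_that("TU template matches the reference-length version of a stretched wave", {
  # three beats whose TU is the same smooth wave at lengths 700/800/900;
  # oracle: the length-800 rendering of that wave
  fs <- 1000; pre <- 100; post <- 100
  wave <- function(L) {
    x <- seq(0, 1, length.out = L)
    0.3 * exp(-0.5 * ((x - 0.3) / 0.1)^2) + 0.1 * sin(pi * x)
  }
  qrs <- exp(-0.5 * ((seq_len(200) - 100) / 12)^2)
  beats <- lapply(c(700, 800, 900), function(L) c(qrs, wave(L)))
  samples <- c(rep(0, 50), unlist(beats), qrs, rep(0, 800))
  rpk <- cumsum(c(51 + pre, 900, 1000, 1100))  # beats start at sample 51
  tr <- trace(samples, fs)
  seg <- segment_beats(tr, rpeak_series(rpk, fs), pre, post)
  tmpl <- build_template(tr, seg, reference_tu_len = 800, stat = "mean")
  oracle <- wave(800)
  expect_lt(max(abs(tmpl$tu_template - oracle)), 0.01 * diff(range(oracle)))
  # default reference length is the median TU length
  expect_equal(build_template(tr, seg)$reference_tu_len, 800)
})

test_that("denoising a noise-free periodic ECG reproduces it", {
  g <- periodic_ecg(duration_s = 30, fs = 500)
  fit <- sbmm_denoise(g$tr, g$rpeaks, 100, 100)
  sup <- beat_support(fit$segmentation)
  p2p <- diff(range(g$tr$samples))
  expect_lt(max(abs(fit$residual$samples[sup])), 0.01 * p2p)
  # conservation by construction (residual is a pure subtraction; exact to
  # one rounding of the re-addition)
  expect_lt(max(abs(fit$clean$samples + fit$residual$samples - g$tr$samples)),
            1e-12 * max(1, max(abs(g$tr$samples))))
  # head/tail pass-through: residual is exactly zero outside full beats
  outside <- setdiff(seq_along(g$tr$samples), sup)
  expect_identical(unique(fit$residual$samples[outside]), 0)
})

test_that("white-noise recovery: residual SD tracks sigma, clean tracks truth", {
  fs <- 500
  g <- gen_beat_train(80, 2, duration_s = 48, fs = fs, seed = 5)  # ~60 beats
  sigma <- 0.1 * diff(range(g$tr$samples))
  set.seed(11)
  noisy <- trace(g$tr$samples + rnorm(length(g$tr$samples), 0, sigma), fs)
  fit <- sbmm_denoise(noisy, g$rpeaks, 100, 100)
  sup <- beat_support(fit$segmentation)
  expect_equal(sd(fit$residual$samples[sup]), sigma, tolerance = 0.1)
  expect_gte(cor(fit$clean$samples[sup], g$tr$samples[sup]), 0.99)
})

test_that("identity limit: residual shrinks monotonically as noise vanishes", {
  fs <- 500
  g <- periodic_ecg(duration_s = 20, fs = fs)
  rms <- vapply(c(0.2, 0.05, 0.0125), function(sigma) {
    set.seed(3)
    noisy <- trace(g$tr$samples + rnorm(length(g$tr$samples), 0, sigma), fs)
    fit <- sbmm_denoise(noisy, g$rpeaks, 100, 100)
    sup <- beat_support(fit$segmentation)
    sqrt(mean(fit$residual$samples[sup]^2))
  }, numeric(1))
  expect_true(all(diff(rms) < 0))
})

test_that("modulation beats the fixed-template ablation under HRV", {
  # TU lengths vary ~+/-15% beat to beat; the unmodulated average beat
  # misaligns T waves and must leave a larger residual
  fs <- 500
  g <- hrv_ecg(duration_s = 40, fs = fs, hr_bpm = 80, hr_sd_bpm = 6, seed = 7)
  expect_gt(max(abs(diff(g$rr_s))) / mean(g$rr_s), 0.1)  # HRV present
  fit_mod <- sbmm_denoise(g$tr, g$rpeaks, 100, 100)
  fit_fix <- sbmm_denoise_fixed(g$tr, g$rpeaks, 100, 100)
  sup <- beat_support(fit_mod$segmentation)
  rms_mod <- sqrt(mean(fit_mod$residual$samples[sup]^2))
  rms_fix <- sqrt(mean(fit_fix$residual$samples[sup]^2))
  expect_lt(rms_mod, rms_fix)
})

test_that("median template shrugs off a single large artifact beat", {
  fs <- 500
  g <- periodic_ecg(duration_s = 30, fs = fs)
  x <- g$tr$samples
  amp <- 10 * diff(range(x))
  # drop a wide spike into one mid-record beat
  k <- g$rpeaks$indices[8] + 120
  x2 <- x
  x2[(k - 15):(k + 15)] <- x2[(k - 15):(k + 15)] + amp
  fit0 <- sbmm_denoise(g$tr, g$rpeaks, 100, 100, stat = "median")
  fit1 <- sbmm_denoise(trace(x2, fs), g$rpeaks, 100, 100, stat = "median")
  t0 <- c(fit0$template$qrs_template, fit0$template$tu_template)
  t1 <- c(fit1$template$qrs_template, fit1$template$tu_template)
  expect_lt(max(abs(t1 - t0)), amp / 2)
  # clean output over unaffected beats is unchanged within tolerance
  seg <- fit0$segmentation
  other <- seg$beat_start[3]:(seg$tu_end[5] - 1L)
  expect_lt(max(abs(fit1$clean$samples[other] - fit0$clean$samples[other])),
            0.02 * diff(range(x)))
})
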