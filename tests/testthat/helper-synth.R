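# Shared fixtures, all generated in code.

# strictly periodic unit-amplitude ECG with known R peaks
periodic_ecg <- function(duration_s = 30, fs = 500, hr_bpm = 80, seed = 1) {
  gen_beat_train(hr_bpm, hr_sd_bpm = 0, duration_s = duration_s, fs = fs,
                 seed = seed)
}

# ECG with heart-rate variability (TU lengths vary with RR)
hrv_ecg <- function(duration_s = 30, fs = 500, hr_bpm = 80, hr_sd_bpm = 6,
                    seed = 1) {
  gen_beat_train(hr_bpm, hr_sd_bpm = hr_sd_bpm, duration_s = duration_s,
                 fs = fs, seed = seed)
}

# full-beat support of a segmentation (samples covered by complete beats)
beat_support <- function(seg) seg$beat_start[1]:(seg$tu_end[nrow(seg)] - 1L)

# small synthetic record config for pipeline tests (scaled down from the
# 60 s / 1000 Hz clinical format for CPU budget; all properties are
# scale-free)
test_synth_config <- function(seed = 1, duration_s = 30, fs = 500,
                              n_channels = 2L) {
  synth_config(duration_s = duration_s, fs = fs, seed = seed,
               n_abdominal_channels = n_channels)
}
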