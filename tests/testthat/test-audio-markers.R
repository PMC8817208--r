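# Vocal acoustic marker extraction: framing, pitch, jitter, HNR,
# intensity, voice activity and the orchestrated marker set.

test_that("framing yields floor((N - L)/H) + 1 frames and drops the tail", {
  sig <- audio_signal(numeric(16000), 16000)
  expect_equal(ncol(frame_signal(sig, 0.04, 0.01)$frames), 97)
  short <- audio_signal(numeric(300), 16000)
  expect_equal(ncol(frame_signal(short, 0.04, 0.01)$frames), 0)
  exact <- audio_signal(numeric(1920), 16000)
  fr <- frame_signal(exact, 0.04, 0.04)
  expect_equal(ncol(fr$frames), 1920 / 640)
})

test_that("steady tones are tracked within 1% with near-zero F0 spread", {
  for (freq in c(100, 150, 250, 400)) {
    track <- estimate_f0_track(pure_tone(freq))
    expect_gt(mean(track$voiced), 0.9)
    s <- f0_summary(track)
    expect_lt(abs(s$f0_mean$value - freq) / freq, 0.01)
    expect_lt(s$f0_stdev$value, 2)
  }
})

test_that("noise and silence are not voiced; infeasible bands error", {
  set.seed(71)
  noise <- audio_signal(0.1 * rnorm(16000), 16000)
  expect_lt(mean(estimate_f0_track(noise)$voiced), 0.10)
  silence <- audio_signal(numeric(16000), 16000)
  expect_equal(sum(estimate_f0_track(silence)$voiced), 0)
  expect_error(estimate_f0_track(silence, f_min = 75, f_max = 9000),
               "infeasible")
})

test_that("f0 summary averages voiced frames only and degrades to missing", {
  tr <- frame_track(seq(0.02, 0.10, by = 0.01), rep(150, 9),
                    voiced = rep(TRUE, 9))
  s <- f0_summary(tr)
  expect_equal(s$f0_mean$value, 150)
  expect_equal(s$f0_stdev$value, 0)
  tr0 <- frame_track(seq(0.02, 0.05, by = 0.01), rep(NA_real_, 4))
  s0 <- f0_summary(tr0)
  expect_true(is_missing_marker(s0$f0_mean))
  expect_equal(s0$f0_mean$missing_reason, "unvoiced")
  glide <- synth_voiced_audio(voice_params(f0 = 100, f0_end = 200,
                                           duration = 2, seed = 3))
  sg <- f0_summary(estimate_f0_track(glide$signal))
  expect_lt(abs(sg$f0_mean$value - 150), 5)
})

test_that("cycle marks recover programmed glottal periods to sub-sample", {
  v <- synth_voiced_audio(voice_params(f0 = 100, jitter_target = 0,
                                       duration = 1, seed = 1))
  p <- extract_periods(v$signal, estimate_f0_track(v$signal))
  expect_gt(length(p), 80)
  expect_lt(max(abs(p - 0.010)), 1e-4)
  # programmed +/-2% perturbation reproduced within one sample
  v2 <- synth_voiced_audio(voice_params(f0 = 100, jitter_target = 2,
                                        duration = 2, seed = 3))
  p2 <- extract_periods(v2$signal, estimate_f0_track(v2$signal))
  tp <- v2$truth$periods
  n <- min(length(p2), length(tp))
  expect_gt(n, length(tp) - 3)
  expect_lt(max(abs(p2[seq_len(n)] - tp[seq_len(n)])), 1 / 16000)
  # silence yields an empty sequence
  silence <- audio_signal(numeric(16000), 16000)
  expect_length(extract_periods(silence, estimate_f0_track(silence)), 0)
})

test_that("local jitter follows the Praat convention and handles degeneracy", {
  expect_equal(jitter_local(c(0.010, 0.010, 0.010))$value, 0)
  expect_equal(jitter_local(c(0.010, 0.011, 0.010))$value,
               100 * 0.001 / (0.031 / 3), tolerance = 1e-9)
  expect_equal(round(jitter_local(c(0.010, 0.011, 0.010))$value, 3), 9.677)
  single <- jitter_local(0.010)
  expect_true(is_missing_marker(single))
})

test_that("programmed jitter is recovered within 25% and monotonically", {
  est <- vapply(c(1, 2, 4), function(j) {
    v <- synth_voiced_audio(voice_params(f0 = 150, jitter_target = j,
                                         duration = 3, seed = 11))
    jitter_local(extract_periods(v$signal,
                                 estimate_f0_track(v$signal)))$value
  }, 0)
  zero <- synth_voiced_audio(voice_params(f0 = 150, jitter_target = 0,
                                          duration = 3, seed = 11))
  e0 <- jitter_local(extract_periods(zero$signal,
                                     estimate_f0_track(zero$signal)))$value
  expect_true(all(diff(c(e0, est)) > 0))
  expect_lt(max(abs(est - c(1, 2, 4)) / c(1, 2, 4)), 0.25)
})

test_that("HNR tracks injected harmonic-to-noise ratios", {
  est <- vapply(c(5, 10, 20), function(h) {
    v <- synth_voiced_audio(voice_params(f0 = 150, hnr_target = h,
                                         duration = 3, seed = 7))
    hnr_db(v$signal, estimate_f0_track(v$signal))$value
  }, 0)
  expect_lt(max(abs(est - c(5, 10, 20))), 2)
  expect_true(all(diff(est) > 0))
  eq <- synth_voiced_audio(voice_params(f0 = 150, hnr_target = 0,
                                        duration = 3, seed = 7))
  expect_lt(abs(hnr_db(eq$signal, estimate_f0_track(eq$signal))$value), 1.5)
  clean <- synth_voiced_audio(voice_params(f0 = 150, duration = 3, seed = 7))
  expect_gt(hnr_db(clean$signal, estimate_f0_track(clean$signal))$value, 25)
  silence <- audio_signal(numeric(16000), 16000)
  expect_true(is_missing_marker(hnr_db(silence,
                                       estimate_f0_track(silence))))
})

test_that("intensity matches the closed form and scales in dB", {
  sine <- pure_tone(220, amp = 1.0)
  m <- intensity_db(sine)
  expect_equal(m$value, 20 * log10(sqrt(0.5) / 2e-5), tolerance = 1e-4)
  expect_equal(round(m$value, 2), 90.97)
  half <- intensity_db(audio_signal(0.5 * sine$samples, 16000))
  expect_equal(m$value - half$value, 6.02, tolerance = 0.1)
  for (k in c(0.1, 0.25, 0.7)) {
    mk <- intensity_db(audio_signal(k * sine$samples, 16000))
    expect_equal(mk$value - m$value, 20 * log10(k), tolerance = 0.1)
  }
  expect_true(is_missing_marker(intensity_db(audio_signal(numeric(8000),
                                                          16000))))
})

test_that("speech detection flags the voiced segment and nothing else", {
  fs <- 16000
  x <- c(numeric(fs), 0.6 * sin(2 * pi * 150 * (0:(2 * fs - 1)) / fs),
         numeric(fs))
  sig <- audio_signal(x, fs)
  track <- estimate_f0_track(sig)
  flags <- detect_speech_frames(sig, track)
  on <- which(flags$values)
  # transitions within one analysis frame of the construction boundaries
  frame_s <- track$frame_len_samples / fs
  expect_lt(abs(flags$frame_times[min(on)] - (1 + frame_s / 2)), frame_s)
  expect_lt(abs(flags$frame_times[max(on)] - (3 - frame_s / 2)), frame_s)
  silence <- audio_signal(numeric(fs), fs)
  expect_equal(sum(detect_speech_frames(silence,
                                        estimate_f0_track(silence))$values),
               0)
  tone <- pure_tone(150, duration = 1)
  tone_tr <- estimate_f0_track(tone)
  expect_true(all(detect_speech_frames(tone, tone_tr)$values))
})

test_that("speech prevalence is the flagged-frame percentage", {
  expect_equal(speech_prevalence(c(rep(TRUE, 60), rep(FALSE, 40)))$value, 60)
  expect_equal(speech_prevalence(rep(FALSE, 50))$value, 0)
  expect_true(is_missing_marker(speech_prevalence(logical(0))))
  v <- synth_voiced_audio(voice_params(f0 = 150, voiced_fraction = 0.6,
                                       hnr_target = 30, duration = 4,
                                       seed = 2))
  sp <- speech_prevalence(detect_speech_frames(v$signal,
                                               estimate_f0_track(v$signal)))
  expect_lt(abs(sp$value - 60), 5)
})

test_that("prevalence of a concatenation is the frame-weighted mean", {
  v1 <- synth_voiced_audio(voice_params(f0 = 150, voiced_fraction = 0.8,
                                        hnr_target = 30, duration = 2,
                                        seed = 5))
  v2 <- synth_voiced_audio(voice_params(f0 = 150, voiced_fraction = 0.3,
                                        hnr_target = 30, duration = 2,
                                        seed = 6))
  prev <- function(sig) {
    speech_prevalence(detect_speech_frames(sig,
                                           estimate_f0_track(sig)))$value
  }
  cat12 <- audio_signal(c(v1$signal$samples, v2$signal$samples), 16000)
  p_cat <- prev(cat12)
  p_mean <- (prev(v1$signal) + prev(v2$signal)) / 2
  n_frames <- length(estimate_f0_track(cat12)$values)
  expect_lt(abs(p_cat - p_mean), 100 * 4 / n_frames) # edge-frame slack
})

test_that("the orchestrated marker set round-trips generator ground truth", {
  v <- synth_voiced_audio(voice_params(f0 = 150, jitter_target = 1,
                                       hnr_target = 15,
                                       voiced_fraction = 0.7,
                                       duration = 3, seed = 8))
  m <- extract_vocal_markers(v$signal, vocal_config(enhance = FALSE))
  expect_lt(abs(m$f0_mean$value - 150), 1.5)
  expect_lt(m$f0_stdev$value, 3)
  # additive noise inflates cycle-mark jitter upward of the programmed 1%
  expect_gt(m$jitter_local$value, 0.5)
  expect_lt(m$jitter_local$value, 2)
  expect_lt(abs(m$hnr$value - 15), 3)
  expect_lt(abs(m$speech_prevalence$value - 70), 7)
  expect_false(is_missing_marker(m$vocal_intensity))
  # enhancement raises, never lowers, measured HNR on noisy input
  me <- extract_vocal_markers(v$signal)
  expect_gt(me$hnr$value, m$hnr$value)
  expect_identical(me, extract_vocal_markers(v$signal))
})

test_that("pure silence yields prevalence 0 and missing voiced markers", {
  m <- extract_vocal_markers(audio_signal(numeric(32000), 16000))
  expect_equal(m$speech_prevalence$value, 0)
  for (f in c("f0_mean", "f0_stdev", "jitter_local", "hnr",
              "vocal_intensity")) {
    expect_true(is_missing_marker(m[[f]]))
  }
})

test_that("markers are stable under 44.1 kHz to 16 kHz resampling", {
  p44 <- voice_params(f0 = 150, jitter_target = 1, voiced_fraction = 0.8,
                      duration = 3, sample_rate = 44100, seed = 9)
  p16 <- voice_params(f0 = 150, jitter_target = 1, voiced_fraction = 0.8,
                      duration = 3, sample_rate = 16000, seed = 9)
  m44 <- extract_vocal_markers(synth_voiced_audio(p44)$signal,
                               vocal_config(enhance = FALSE))
  m16 <- extract_vocal_markers(synth_voiced_audio(p16)$signal,
                               vocal_config(enhance = FALSE))
  expect_lt(abs(m44$f0_mean$value - m16$f0_mean$value), 1.5)
  expect_lt(abs(m44$jitter_local$value - m16$jitter_local$value), 0.25)
  expect_lt(abs(m44$speech_prevalence$value - m16$speech_prevalence$value), 5)
  expect_lt(abs(m44$vocal_intensity$value - m16$vocal_intensity$value), 1)
})

test_that("WAV round trip preserves samples and downmixes stereo", {
  v <- synth_voiced_audio(voice_params(duration = 0.5, seed = 4))
  path <- tempfile(fileext = ".wav")
  write_wav(v$signal, path)
  back <- read_wav(path)
  expect_equal(back$sample_rate, 16000)
  expect_lt(max(abs(back$samples - v$signal$samples)), 1 / 32767)
  unlink(path)
})
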