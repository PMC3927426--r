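# Ground-truth generators: song audio, membrane traces, trials, WAV I/O

test_that("song generation is deterministic and annotation-consistent", {
  m <- tiny_song_model()
  s1 <- generate_song(m, 3, seed = 9)
  s2 <- generate_song(m, 3, seed = 9)
  expect_identical(s1$x, s2$x)
  expect_identical(s1$annotation, s2$annotation)
  s3 <- generate_song(m, 3, seed = 10)
  expect_false(identical(s1$x, s3$x))

  dur <- length(s1$x) / s1$fs * 1000
  expect_true(all(s1$annotation$onset_ms >= 0))
  expect_true(all(s1$annotation$offset_ms <= dur))
  expect_true(all(s1$annotation$offset_ms > s1$annotation$onset_ms))
  # realized fundamental within 1% of the template
  for (i in seq_len(nrow(s1$annotation))) {
    tpl <- m$syllables[[s1$annotation$label[i]]]
    expect_lt(abs(s1$annotation$f0_hz[i] - tpl$fundamental_hz) /
                tpl$fundamental_hz, 0.01)
  }
})

test_that("zero tempo jitter gives gaps exactly at template values", {
  m <- tiny_song_model(jitter = 0)
  s <- generate_song(m, 2, seed = 1, inter_motif_gap_ms = 300)
  ann <- s$annotation
  gap_ab <- ann$onset_ms[2] - ann$offset_ms[1]
  # gap quantized to the sample grid
  expect_equal(gap_ab, m$syllables[["a"]]$gap_ms, tolerance = 1 / s$fs * 1000)
  gap_ab2 <- ann$onset_ms[4] - ann$offset_ms[3]
  expect_equal(gap_ab, gap_ab2)
})

test_that("song model validation rejects malformed inputs", {
  expect_error(syllable_template("a", duration_ms = -5, fundamental_hz = 500))
  expect_error(song_model(list(syllable_template("a", 50, 500)), "b"),
               "unknown syllable")
  expect_error(song_model(list(syllable_template("a", 50, 500)),
                          character(0)), "non-empty")
  expect_error(song_model(list(syllable_template("a", 50, 500)), "a",
                          sample_rate_hz = 8000), "44100 or 22050")
})

test_that("pure-tone syllables are entropic opposites of noise", {
  tone_m <- song_model(list(syllable_template("t", 100, 2000,
                                              n_harmonics = 1,
                                              entropy_target = 0)),
                       "t", noise_floor_db = -80)
  noise_m <- song_model(list(syllable_template("n", 100, 2000,
                                               n_harmonics = 1,
                                               entropy_target = 1)),
                        "n", noise_floor_db = -80)
  st <- generate_song(tone_m, 1, seed = 2)
  sn <- generate_song(noise_m, 1, seed = 2)
  in_syl <- function(s) {
    f <- song_features(s$x, s$fs)
    a <- s$annotation
    f$wiener_entropy[f$t_ms > a$onset_ms[1] + 10 &
                       f$t_ms < a$offset_ms[1] - 10]
  }
  expect_lt(median(in_syl(st)), -5)   # pure tone: strongly negative
  expect_gt(median(in_syl(sn)), -0.6) # noise: near the flat-spectrum limit
})

test_that("WAV round trip preserves the waveform at 16-bit precision", {
  set.seed(4)
  x <- runif(2000, -0.9, 0.9)
  p <- file.path(tempdir(), "songgate-test.wav")
  write_wav(x, 22050, p)
  w <- read_wav(p)
  expect_identical(w$fs, 22050L)
  expect_equal(w$x, x, tolerance = 1 / 32767)
  unlink(p)
})

test_that("trial sets reproduce their design probabilities", {
  expect_error(generate_trial_set(10, p_catch = 1.5))
  tr0 <- generate_trial_set(50, p_catch = 1, seed = 3)
  expect_identical(sum(tr0$condition == "hit"), 0L)

  tr <- generate_trial_set(1e4, p_catch = 0.5, seed = 5)
  hit_frac <- mean(tr$condition == "hit")
  expect_lt(abs(hit_frac - 0.5), 3 * sqrt(0.25 / 1e4))   # 3 binomial SE

  hits <- tr[tr$condition == "hit", ]
  expect_true(all(hits$daf_onset_ms - hits$target_onset_ms >= 8))
  expect_true(all(hits$daf_onset_ms - hits$target_onset_ms <= 10))
  expect_true(all(is.na(tr$daf_onset_ms[tr$condition == "catch"])))

  trd <- generate_trial_set(4000, p_catch = 0.5,
                            outcome_rates = list(truncated = 0,
                                                 delayed = 0.2), seed = 6)
  d_frac <- mean(trd$outcome[trd$condition == "hit"] == "delayed")
  expect_lt(abs(d_frac - 0.2), 3 * sqrt(0.2 * 0.8 / sum(trd$condition ==
                                                          "hit")))
})

test_that("noiseless membrane traces expose their ground truth exactly", {
  m <- tiny_song_model()
  song <- generate_song(m, 2, seed = 3, inter_motif_gap_ms = 1500)
  cell <- cell_model(noise_sd_mv = 0, tonic_rate_hz = 0,
                     spike_threshold_mv = 0)   # no spikes
  tr <- generate_membrane_trace(cell, song$annotation, seed = 1)
  # one dPSP 25 ms before each syllable onset
  expect_equal(tr$truth$dpsp_onsets_ms,
               sort(song$annotation$onset_ms - 25))
  # trace deviates from the state baseline only at scheduled dPSPs
  flat_before <- tr$vm_mv[tr$t_ms < min(tr$truth$dpsp_onsets_ms) - 400]
  expect_true(all(flat_before == cell$rest_mv))
  # dPSP onsets recoverable exactly from the noiseless trace
  d <- despike(tr)
  det <- detect_dpsp_onsets(d, tr$fs, c_sd = 1.0)
  det <- det[det > 100]   # skip the singing-state ramp
  for (o in tr$truth$dpsp_onsets_ms)
    expect_true(min(abs(det - o)) <= 2)
})

test_that("scheduled spikes are constructed and counted faithfully", {
  ann <- data.frame(onset_ms = seq(2000, 6000, by = 400),
                    offset_ms = seq(2000, 6000, by = 400) + 100,
                    label = "a")
  cell <- cell_model(noise_sd_mv = 0, tonic_rate_hz = 0,
                     singing_offset_mv = 0,
                     dpsp_schedule = list(list(label = "a", lead_ms = 25,
                                               amplitude_mv = 20, rise_ms = 2,
                                               decay_ms = 12)),
                     spike_threshold_mv = -45)   # every dPSP crosses
  tr <- generate_membrane_trace(cell, ann, seed = 2)
  expect_identical(length(tr$truth$spike_times_ms), nrow(ann))
  sp <- detect_spikes(tr)
  expect_identical(length(sp), nrow(ann))
  expect_true(all(abs(sp - tr$truth$spike_times_ms) <= 1))
})

test_that("trials outside the trace span raise an alignment error", {
  ann <- data.frame(onset_ms = 1500, offset_ms = 1600, label = "a")
  trials <- generate_trial_set(5, p_catch = 0, seed = 1,
                               start_ms = 50000, isi_ms = 1000)
  expect_error(generate_membrane_trace(cell_model(), ann, trials = trials,
                                       duration_ms = 3000, seed = 1),
               "outside the trace span")
})

test_that("every generated event appears exactly once in the truth tables", {
  m <- default_song_model()
  s <- generate_song(m, 3, seed = 8)
  # one annotation row per motif syllable
  expect_identical(nrow(s$annotation), 3L * length(m$motif_order))
  expect_identical(anyDuplicated(s$annotation[, c("onset_ms", "label")]), 0L)

  cell <- cell_model(noise_sd_mv = 0, tonic_rate_hz = 0,
                     spike_threshold_mv = 0)
  tr <- generate_membrane_trace(cell, s$annotation, seed = 1)
  expect_identical(length(tr$truth$dpsp_onsets_ms), nrow(s$annotation))
  expect_identical(anyDuplicated(tr$truth$dpsp_onsets_ms), 0L)
})
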