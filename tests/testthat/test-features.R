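# Multitaper spectra and frame-wise acoustic features

test_that("DPSS tapers match the Slepian reference and are orthonormal", {
  H <- dpss_tapers(64, 2, 4)
  # frozen oracle: scipy.signal.windows.dpss(64, 4, 2), first 3 values
  expect_equal(H[1:3, 1], c(3.1063683007e-05, 9.9773976937e-05,
                            2.3921405632e-04), tolerance = 1e-8)
  expect_equal(H[1:3, 2], c(0.0002471115, 0.0007000894, 0.0015289538),
               tolerance = 1e-5)
  expect_equal(max(H[, 1]), 0.2473371865596641, tolerance = 1e-10)
  expect_equal(crossprod(H), diag(2), ignore_attr = TRUE, tolerance = 1e-10)
})

test_that("multitaper spectrum handles null input, locates tones, and is
           Parseval-consistent", {
  fs <- 44100
  n <- round(0.005 * fs)
  expect_equal(multitaper_spectrum(rep(0, n), fs)$power, rep(0, 257))
  expect_error(multitaper_spectrum(numeric(1), fs), "2 samples")

  t <- (0:(n - 1)) / fs
  x <- sin(2 * pi * 2000 * t)
  sp <- multitaper_spectrum(x, fs)
  # peak within the multitaper bandwidth (W = NW/N * fs) of the tone
  W <- 4 / n * fs
  expect_lt(abs(sp$freq[which.max(sp$power)] - 2000), W)
  # oracle: single rectangular taper's argmax equals the FFT periodogram's
  spr <- multitaper_spectrum(x, fs, taper = "rect")
  pg <- (Mod(fft(c(x, rep(0, 512 - n)))))^2
  expect_equal(which.max(spr$power), which.max(pg[1:257]))
  expect_equal(spr$freq[which.max(spr$power)], 2000,
               tolerance = (fs / 512) / 2000)

  # Parseval: sum of one-sided power equals mean tapered-window energy
  H <- dpss_tapers(n, 2, 4)
  energy <- mean(colSums((H * x)^2))
  expect_equal(sum(sp$power), energy, tolerance = 1e-10)
})

test_that("one rectangular taper reproduces the plain periodogram", {
  set.seed(7)
  fs <- 22050
  x <- rnorm(110)
  sp <- multitaper_spectrum(x, fs, taper = "rect", nfft = 256)
  X <- fft(c(x / sqrt(110), rep(0, 256 - 110)))
  pg <- Mod(X[1:129])^2
  pg[2:128] <- 2 * pg[2:128]
  expect_equal(sp$power, pg / 256, tolerance = 1e-12)
})

test_that("averaging two tapers reduces the variance of the estimate", {
  set.seed(11)
  fs <- 44100
  n <- 220
  bin <- 30
  p1 <- p2 <- numeric(500)
  for (i in 1:500) {
    x <- rnorm(n)
    p1[i] <- multitaper_spectrum(x, fs, n_tapers = 1)$power[bin]
    p2[i] <- multitaper_spectrum(x, fs, n_tapers = 2)$power[bin]
  }
  expect_lt(var(p2), var(p1))
})

test_that("frame features obey the entropy bound and closed-form cases", {
  fs <- 44100
  freq <- (0:256) * fs / 512
  mk <- function(power) list(freq = freq, power = power, fs = fs, nfft = 512)

  # flat spectrum: AM-GM equality
  flat <- frame_features(mk(rep(2, 257)))
  expect_identical(flat$wiener_entropy, 0)

  # single nonzero bin at ~3 kHz: centroid at the bin, entropy at the cap
  p <- rep(0, 257)
  i3k <- which.min(abs(freq - 3000))
  p[i3k] <- 5
  one <- frame_features(mk(p))
  expect_equal(one$mean_freq_hz, freq[i3k])
  expect_equal(one$wiener_entropy, -25)

  # two equal bins at 2 and 4 kHz: centroid at 3 kHz
  p <- rep(0, 257)
  p[which.min(abs(freq - 2000))] <- 1
  p[which.min(abs(freq - 4000))] <- 1
  two <- frame_features(mk(p))
  expect_equal(two$mean_freq_hz,
               mean(freq[c(which.min(abs(freq - 2000)),
                           which.min(abs(freq - 4000)))]))

  # all-zero spectrum: amplitude floor, features undefined
  z <- frame_features(mk(rep(0, 257)))
  expect_equal(z$amplitude_db, -120)
  expect_true(is.na(z$mean_freq_hz) && is.na(z$pitch_hz))

  expect_error(frame_features(mk(rep(-1, 257))), "non-negative")

  # property: entropy <= 0 on random spectra
  set.seed(3)
  for (i in 1:50) {
    f <- frame_features(mk(runif(257)^2))
    expect_lte(f$wiener_entropy, 0)
  }
})

test_that("tonal and noisy signals separate in Wiener entropy", {
  fs <- 22050
  set.seed(5)
  t <- (0:(fs / 2 - 1)) / fs
  tone <- song_features(sin(2 * pi * 2000 * t), fs)
  noise <- song_features(rnorm(length(t)) * 0.1, fs)
  expect_lt(median(tone$wiener_entropy, na.rm = TRUE), -4)
  expect_gt(median(noise$wiener_entropy, na.rm = TRUE), -1)
})

test_that("autocorrelation pitch recovers harmonic-stack fundamentals", {
  fs <- 22050
  t <- (0:(fs / 4 - 1)) / fs
  for (f0 in c(450, 700, 1500)) {
    x <- rowSums(sapply(1:6, function(k)
      if (k * f0 < fs / 2) sin(2 * pi * k * f0 * t) / k else 0 * t))
    f <- song_features(x / max(abs(x)), fs)
    expect_equal(median(f$pitch_hz, na.rm = TRUE), f0, tolerance = 0.02)
    expect_gt(median(f$goodness, na.rm = TRUE), 0.8)
  }
})

test_that("event detection finds maximal supra-threshold runs", {
  mkframes <- function(amp) data.frame(
    t_ms = seq_along(amp), amplitude_db = amp,
    mean_freq_hz = 1000, wiener_entropy = -1, fm = 0.5,
    pitch_hz = 800, goodness = 0.1)

  expect_identical(nrow(detect_sound_events(mkframes(rep(-60, 50)),
                                            threshold_db = -40)), 0L)
  expect_identical(nrow(detect_sound_events(mkframes(-60)[0, ],
                                            threshold_db = -40)), 0L)

  # one 80-frame supra-threshold run at 1-ms hop: a single 80-ms event
  amp <- c(rep(-60, 20), rep(-20, 80), rep(-60, 20))
  ev <- detect_sound_events(mkframes(amp), threshold_db = -40)
  expect_identical(nrow(ev), 1L)
  expect_equal(ev$duration_ms, 80)

  # run still open at stream end is closed there
  ev2 <- detect_sound_events(mkframes(c(rep(-60, 5), rep(-20, 10))),
                             threshold_db = -40)
  expect_identical(ev2$last_frame, 15L)
})

test_that("events partition the frame timeline without overlap", {
  song <- generate_song(default_song_model(), 2, seed = 21)
  frames <- song_features(song$x, song$fs)
  ev <- detect_sound_events(frames)
  # no frame belongs to two events; events ordered and disjoint
  claimed <- unlist(mapply(seq, ev$first_frame, ev$last_frame))
  expect_identical(anyDuplicated(claimed), 0L)
  expect_true(all(diff(ev$first_frame) > 0))
  expect_true(all(ev$onset_ms < ev$offset_ms))
  # event count matches the ground-truth annotation
  expect_identical(nrow(ev), nrow(song$annotation))
})

test_that("event summaries match closed forms", {
  n <- 11
  a0 <- -30; d <- 0.5
  frames <- data.frame(t_ms = 1:n, amplitude_db = a0 + d * (0:(n - 1)),
                       mean_freq_hz = 1500, wiener_entropy = -2,
                       fm = 0.3, pitch_hz = c(800, rep(NA, n - 1)),
                       goodness = 0.2)
  ev <- data.frame(first_frame = 1L, last_frame = n,
                   duration_ms = n)
  s <- summarize_event(frames, ev)
  # arithmetic-ramp closed forms (population variance)
  expect_equal(s$amplitude_mean, a0 + d * (n - 1) / 2)
  expect_equal(s$amplitude_var, d^2 * (n^2 - 1) / 12)
  expect_equal(s$mean_freq_var, 0)
  expect_equal(s$mean_freq_mean, 1500)
  # undefined-pitch frames excluded
  expect_equal(s$pitch_mean, 800)
  expect_equal(s$pitch_var, 0)

  single <- summarize_event(frames, data.frame(first_frame = 3L,
                                               last_frame = 3L,
                                               duration_ms = 1))
  expect_equal(single$amplitude_var, 0)
})
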