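# Intracellular analyses: despiking, spike detection, state statistics,
# hit-minus-catch membrane-potential differences

test_that("despiking equals a brute-force sliding median", {
  fs <- 1000   # 5-ms window -> 5 samples
  expect_equal(despike(rep(-60, 100), fs), rep(-60, 100))

  x <- rep(-60, 50)
  x[25] <- 10   # single-sample spike
  expect_equal(despike(x, fs), rep(-60, 50))

  # direct oracle on a hand-sized vector, including the edges
  v <- c(3, -1, 4, 1, 5, 9, 2)
  oracle <- vapply(seq_along(v), function(i)
    median(v[max(1, i - 2):min(7, i + 2)]), 0)
  expect_equal(despike(v, fs), oracle)

  expect_error(despike(1:10, fs, window_ms = 0.5), "window too short")
})

test_that("spike detection sees fast deflections and ignores slow ramps", {
  fs <- 10000
  expect_identical(detect_spikes(rep(-60, fs), fs), numeric(0))

  # slow 20-mV ramp: rejected by the high-pass stage
  ramp <- seq(-70, -50, length.out = fs)
  expect_identical(detect_spikes(ramp, fs), numeric(0))

  # 12 scheduled spikes recovered within 1 ms
  ann <- data.frame(onset_ms = seq(1500, 5900, by = 400),
                    offset_ms = seq(1500, 5900, by = 400) + 80, label = "a")
  cell <- cell_model(noise_sd_mv = 0.3, tonic_rate_hz = 0,
                     singing_offset_mv = 0,
                     dpsp_schedule = list(list(label = "a", lead_ms = 20,
                                               amplitude_mv = 18,
                                               rise_ms = 2, decay_ms = 10)),
                     spike_threshold_mv = -45)
  tr <- generate_membrane_trace(cell, ann, seed = 3)
  expect_identical(length(tr$truth$spike_times_ms), 12L)
  sp <- detect_spikes(tr)
  expect_identical(length(sp), 12L)
  expect_true(all(abs(sp - tr$truth$spike_times_ms) <= 1))

  # both readings of the criterion agree on this trace
  sp2 <- detect_spikes(tr$vm_mv, tr$fs, method = "complement")
  expect_identical(length(sp2), 12L)
})

test_that("singing-state statistics recover the generator's regime", {
  m <- tiny_song_model()
  song <- generate_song(m, 6, seed = 12, inter_motif_gap_ms = 2500,
                        lead_ms = 1500)
  cell <- cell_model(rest_mv = -58, singing_offset_mv = -4,
                     tonic_rate_hz = 8, noise_sd_mv = 0.2,
                     spike_threshold_mv = 0)  # only tonic spikes
  tr <- generate_membrane_trace(cell, song$annotation, seed = 13)
  st <- singing_state_stats(tr)
  expect_identical(st$n_bouts_used, 6L)
  # tonic firing before song, silenced during song
  expect_gt(st$rate_pre_hz, 3)
  expect_lt(st$rate_sing_hz, st$rate_pre_hz)
  # hyperpolarization during singing close to the generator offset
  expect_equal(st$vm_sing_mv - st$vm_pre_mv, -4, tolerance = 0.15)

  # bout cap: only the first 50 bouts enter
  onsets <- seq(2000, by = 2000, length.out = 60)
  fake <- rep(-60, (max(onsets) + 1000) * 1000 / 1000)  # 1-kHz flat trace
  st2 <- singing_state_stats(fake, fs = 1000, bout_onsets_ms = onsets)
  expect_identical(st2$n_bouts_used, 50L)
})

test_that("delta Vm vanishes for identical trial sets and finds injected
           offsets", {
  set.seed(21)
  fs <- 1000
  t_ms <- seq(-200, 249.9, by = 1)
  n <- length(t_ms)
  mk <- function(rows) matrix(rnorm(rows * n, -60, 1), rows, n)
  hit <- mk(10)
  attr(hit, "t_ms") <- t_ms

  dv0 <- delta_vm(hit, hit)
  expect_true(all(dv0$delta == 0))
  expect_identical(dv0$windows$p_value, c(1, 1))
  expect_identical(dv0$min_p, 1)

  # +2 mV boxcar on hits over 20-60 ms: fast window recovers it, slow ~0
  catch <- mk(200)
  hit2 <- mk(200)
  hit2[, t_ms >= 20 & t_ms < 60] <- hit2[, t_ms >= 20 & t_ms < 60] + 2
  attr(hit2, "t_ms") <- t_ms
  dv <- delta_vm(hit2, catch)
  expect_equal(dv$windows$diff[dv$windows$window == "fast"], 2,
               tolerance = 0.1)
  expect_lt(abs(dv$windows$diff[dv$windows$window == "slow"]), 0.1)
  expect_lt(dv$windows$p_value[1], 1e-6)
})

test_that("delta Vm is antisymmetric and baseline-invariant", {
  set.seed(22)
  t_ms <- seq(-200, 249, by = 1)
  n <- length(t_ms)
  hit <- matrix(rnorm(8 * n, -62, 1.5), 8, n)
  catch <- matrix(rnorm(9 * n, -61, 1.5), 9, n)
  a <- delta_vm(hit, catch, t_ms = t_ms)
  b <- delta_vm(catch, hit, t_ms = t_ms)
  expect_equal(a$delta, -b$delta)
  expect_equal(a$windows$p_value, b$windows$p_value, tolerance = 1e-12)

  # adding a per-trial constant changes nothing (baseline subtraction)
  hit_shift <- hit + matrix(rnorm(8, 0, 10), 8, n)
  c_ <- delta_vm(hit_shift, catch, t_ms = t_ms)
  expect_equal(a$delta, c_$delta)
})

test_that("groups below the motif minimum are excluded with a reason", {
  set.seed(23)
  t_ms <- seq(-200, 249, by = 1)
  n <- length(t_ms)
  hit <- matrix(rnorm(5 * n, -60, 0.5), 5, n)
  catch <- matrix(rnorm(5 * n, -60, 0.5), 5, n)
  expect_error(delta_vm(hit, catch, t_ms = t_ms), "fewer than 14")

  # grouped analysis: a -78 mV hyperpolarized pair forms an excluded group
  hit2 <- rbind(matrix(rnorm(9 * n, -58, 0.5), 9, n),
                matrix(rnorm(1 * n, -78, 0.5), 1, n))
  catch2 <- rbind(matrix(rnorm(8 * n, -58, 0.5), 8, n),
                  matrix(rnorm(1 * n, -78, 0.5), 1, n))
  g <- delta_vm(hit2, catch2, t_ms = t_ms, group_bin_mv = 5)
  expect_s3_class(g, "delta_vm_groups")
  expect_identical(length(g$groups), 1L)
  expect_identical(nrow(g$excluded), 1L)
  expect_match(g$excluded$reason, "fewer than 14")
})

test_that("windowed tests hold their nominal size under the DAF-null
           generator", {
  # 200 replicate null sessions; reject if min over the two windows of the
  # Welch p-value < alpha in each, count per-window rejections
  set.seed(24)
  t_ms <- seq(-200, 249, by = 1)
  n <- length(t_ms)
  alpha <- 0.05
  rej_fast <- rej_slow <- logical(200)
  for (i in 1:200) {
    hit <- matrix(rnorm(10 * n, -60, 1), 10, n)
    catch <- matrix(rnorm(10 * n, -60, 1), 10, n)
    dv <- delta_vm(hit, catch, t_ms = t_ms)
    rej_fast[i] <- dv$windows$p_value[1] < alpha
    rej_slow[i] <- dv$windows$p_value[2] < alpha
  }
  # binomial 99% band around alpha at 200 replicates
  band <- 2.58 * sqrt(alpha * (1 - alpha) / 200)
  expect_lt(abs(mean(rej_fast) - alpha), band + 1e-9)
  expect_lt(abs(mean(rej_slow) - alpha), band + 1e-9)
})
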