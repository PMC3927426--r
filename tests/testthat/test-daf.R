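# Closed-loop controller: arming, triggering, hit/catch, outcomes,
# contingency, latency-matched resampling

test_that("persistence-gated triggering obeys its latency contract", {
  t_ms <- 0:200

  # criteria never satisfied within the timeout
  r <- detect_target_and_trigger(t_ms, rep(FALSE, 201), armed_at_ms = 0)
  expect_true(r$timed_out)
  expect_true(is.na(r$trigger_ms))

  # satisfied for only 2 ms, then broken: persistence not met
  sat <- t_ms >= 50 & t_ms <= 52
  r2 <- detect_target_and_trigger(t_ms, sat, armed_at_ms = 0)
  expect_true(r2$timed_out)

  # satisfied continuously from arming: trigger after >= 3 ms
  sat3 <- t_ms >= 50
  r3 <- detect_target_and_trigger(t_ms, sat3, armed_at_ms = 40)
  expect_equal(r3$trigger_ms, 53)

  # latency over all sub-frame phases of criteria onset lies in [3, 4)
  for (phase in seq(0, 0.99, by = 0.07)) {
    onset <- 50 + phase
    sat_p <- t_ms >= onset
    rp <- detect_target_and_trigger(t_ms, sat_p, armed_at_ms = 0)
    lat <- rp$trigger_ms - onset
    expect_gte(lat, 3)
    expect_lt(lat, 4)
  }
})

test_that("hit/catch assignment respects its probabilities and delays", {
  set.seed(1)
  all_hit <- assign_hit_catch(1:50, p_catch = 0)
  expect_true(all(all_hit$condition == "hit"))

  set.seed(2)
  tr <- assign_hit_catch(seq_len(1e4), p_catch = 0.5)
  expect_lt(abs(mean(tr$condition == "hit") - 0.5), 3 * sqrt(0.25 / 1e4))
  d <- tr$daf_onset_ms - tr$trigger_ms
  d <- d[!is.na(d)]
  expect_true(all(d >= 8 & d <= 10))
  expect_true(all(is.na(tr$daf_onset_ms[tr$condition == "catch"])))
})

test_that("the contingent gate plays strictly on the non-escape side", {
  rule <- contingency_rule("mean_freq_hz", threshold = 5000,
                           direction = "below", window_ms = 10)
  expect_identical(contingent_gate(5200, rule), "play")
  expect_identical(contingent_gate(4800, rule), "escape")
  expect_identical(contingent_gate(5000, rule), "escape")  # ties escape
  expect_identical(contingent_gate(NA, rule), "play")      # default
  up <- contingency_rule("mean_freq_hz", 5800, direction = "above")
  expect_identical(contingent_gate(5600, up), "play")
  expect_identical(contingent_gate(5800, up), "escape")
})

test_that("escape rate grows monotonically as a population drifts past the
           threshold", {
  rule <- contingency_rule("mean_freq_hz", threshold = 5000,
                           direction = "below")
  set.seed(3)
  esc <- vapply(c(5400, 5200, 5000, 4800), function(mu) {
    v <- rnorm(400, mu, 150)
    mean(vapply(v, function(x) contingent_gate(x, rule), "") == "escape")
  }, 0)
  expect_true(all(diff(esc) > 0))
})

test_that("trial outcomes follow the truncation and delay rules", {
  set.seed(4)
  catch_tau <- rnorm(500, 60, 5)
  # missing next syllable: truncated
  expect_identical(classify_trial_outcome(NA, catch_tau), "truncated")
  # tau at the catch median: normal
  expect_identical(classify_trial_outcome(median(catch_tau), catch_tau),
                   "normal")
  # tau beyond the 99th catch percentile: delayed, however late
  q99 <- quantile(catch_tau, 0.99)
  expect_identical(classify_trial_outcome(q99 + 1, catch_tau), "delayed")
  expect_identical(classify_trial_outcome(median(catch_tau) +
                                            8 * sd(catch_tau), catch_tau),
                   "delayed")
})

test_that("annotation-based outcome classification matches the generator", {
  trials <- generate_trial_set(400, p_catch = 0.5,
                               outcome_rates = list(truncated = 0.1,
                                                    delayed = 0.15),
                               seed = 5)
  # build an annotation carrying the generator's tau ground truth
  ref <- ifelse(is.na(trials$daf_onset_ms), trials$virtual_daf_onset_ms,
                trials$daf_onset_ms)
  keep <- !is.na(trials$tau_ms)
  ann <- data.frame(onset_ms = ref[keep] + trials$tau_ms[keep],
                    offset_ms = ref[keep] + trials$tau_ms[keep] + 50,
                    label = "c")
  out <- classify_trial_outcomes(trials, ann, next_label = "c")
  truth <- trials$outcome[trials$condition == "hit"]
  est <- out$outcome[out$condition == "hit"]
  expect_identical(est[truth == "truncated"],
                   rep("truncated", sum(truth == "truncated")))
  # delayed trials are shifted +40 ms >> q99 of catch: all flagged
  expect_gte(mean(est[truth == "delayed"] == "delayed"), 0.9)
  expect_gte(mean(est[truth == "normal"] == "normal"), 0.95)
})

test_that("latency-matched resampling equalizes hit and catch", {
  set.seed(6)
  # same distribution: near-complete retention
  hit <- rnorm(2000, 60, 6)
  catch <- rnorm(2000, 60, 6)
  keep <- resample_delayed_hits(hit, catch, seed = 7)
  expect_gt(mean(keep), 0.85)

  # single hit in an empty catch bin is rejected
  expect_false(resample_delayed_hits(1000, catch, seed = 8))

  # shifted hits: retained subset closer to catch in KS distance
  ks_stat <- function(a, b) suppressWarnings(
    stats::ks.test(a, b)$statistic)
  improved <- vapply(1:60, function(i) {
    set.seed(100 + i)
    h <- rnorm(400, 80, 6)   # +20 ms shift
    c_ <- rnorm(400, 60, 6)
    k <- resample_delayed_hits(h, c_, seed = 200 + i)
    if (sum(k) < 5) return(TRUE)
    ks_stat(h[k], c_) < ks_stat(h, c_)
  }, TRUE)
  expect_gte(mean(improved), 0.95)

  # retained histograms agree bin-wise within binomial error
  set.seed(9)
  h <- c(rnorm(3000, 60, 5), rnorm(1500, 90, 8))
  c_ <- rnorm(3000, 60, 5)
  k <- resample_delayed_hits(h, c_, seed = 10)
  br <- seq(30, 130, by = 5)
  ph <- hist(pmin(pmax(h[k], 31), 129), breaks = br, plot = FALSE)$density
  pc <- hist(pmin(pmax(c_, 31), 129), breaks = br, plot = FALSE)$density
  expect_lt(max(abs(ph - pc)), 0.02)
})

test_that("pre-target detection fires once per event, at event offsets", {
  cl <- trained_default_classifier()
  te <- generate_labeled_events(default_song_model(), 6, seed = 31)
  det <- detect_pretarget(te$summaries, cl, "a")
  expect_identical(length(det), 6L)  # one per motif
  expect_true(all(det %in% te$summaries$offset_ms))

  # stream without the pre-target syllable: no detections
  noise_only <- generate_labeled_events(default_song_model(), 2, seed = 32)
  b_only <- noise_only$summaries[noise_only$labels == "b", , drop = FALSE]
  expect_identical(length(detect_pretarget(b_only, cl, "a")), 0L)
})

test_that("the closed-loop simulation operates in the reported band", {
  cl <- trained_default_classifier()
  sess <- simulate_daf_session(default_song_model(), cl, 150,
                               pretarget_label = "a", target_label = "b",
                               p_catch = 0.5, seed = 21)
  expect_gte(sess$hit_rate_percent, 30)
  expect_lte(sess$hit_rate_percent, 70)
  # triggers land on the target syllable and plays only on hits
  tr <- sess$trials
  expect_true(all(tr$played <= (tr$condition == "hit"), na.rm = TRUE))
})
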