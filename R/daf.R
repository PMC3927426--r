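#' Detect the pre-target syllable in an event stream
#'
#' Classifies each completed sound event and emits a detection at the
#' event's offset whenever the predicted label matches the pre-target
#' label: detections can only occur at event offsets, at most one per
#' event (the online detector evaluates a rendition when its event closes).
#'
#' @param summaries Event summaries (with `offset_ms`) from
#'   [summarize_events()].
#' @param model A deployable [train_syllable_classifier()] model.
#' @param pretarget_label Label that arms the target detector.
#' @return Numeric vector of detection times (the matching events'
#'   `offset_ms`).
#' @export
detect_pretarget <- function(summaries, model, pretarget_label) {
  stopifnot(inherits(model, "syllable_classifier"))
  if (!model$deployable)
    stop("classifier is not deployable (cv accuracy below floor)")
  if (nrow(summaries) == 0) return(numeric(0))
  pred <- predict(model, summaries)
  summaries$offset_ms[pred$label == pretarget_label]
}

#' Persistence-gated target-onset detection
#'
#' Once armed by a pre-target detection, the detector samples its criteria
#' on the 1-ms frame clock and issues the trigger at the first frame by
#' which the criteria have held continuously for at least `persistence_ms`
#' (guarding against triggering on momentary feature fluctuations). If the
#' criteria are never satisfied that long within `timeout_ms` of arming,
#' the detector disarms and reports a timeout.
#'
#' With a hop of 1 ms and 3-ms persistence the latency from the first
#' (continuous-time) criteria satisfaction to the trigger is in `[3, 4)`
#' ms, depending on the phase of criteria onset relative to the frame
#' clock.
#'
#' @param t_ms Frame times (ms), strictly increasing (approx. 1-ms hop).
#' @param satisfied Logical vector: criteria satisfied at each frame.
#' @param armed_at_ms Arming time; only frames at or after it are used.
#' @param persistence_ms Required continuous satisfaction (ms).
#' @param timeout_ms Disarm deadline after arming (ms).
#' @return List with `trigger_ms` (`NA` on timeout) and `timed_out`.
#' @export
detect_target_and_trigger <- function(t_ms, satisfied, armed_at_ms = -Inf,
                                      persistence_ms = 3, timeout_ms = 100) {
  stopifnot(length(t_ms) == length(satisfied))
  use <- t_ms >= armed_at_ms & t_ms <= armed_at_ms + timeout_ms
  tt <- t_ms[use]
  ss <- satisfied[use]
  if (!length(tt) || !any(ss))
    return(list(trigger_ms = NA_real_, timed_out = TRUE))
  r <- rle(ss)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in which(r$values)) {
    run_t <- tt[starts[k]:ends[k]]
    hold <- run_t - run_t[1]
    hit <- which(hold >= persistence_ms)
    if (length(hit))
      return(list(trigger_ms = run_t[hit[1]], timed_out = FALSE))
  }
  list(trigger_ms = NA_real_, timed_out = TRUE)
}

#' Randomized hit/catch assignment for a triggered trial
#'
#' Each trigger is independently assigned to the catch condition with
#' probability `p_catch` (DAF suppressed); hits receive a DAF onset drawn
#' uniformly from `trigger + delay_range_ms` (the processing/playback
#' delay).
#'
#' @param trigger_ms Trigger time(s), one per trial.
#' @param p_catch Catch probability in `[0, 1]`.
#' @param delay_range_ms Length-2 trigger-to-DAF delay bounds (ms).
#' @param daf_duration_ms DAF stimulus duration (ms).
#' @return `data.frame` with `trial_id`, `trigger_ms`, `condition`,
#'   `daf_onset_ms` (`NA` for catches), `daf_duration_ms`.
#' @export
assign_hit_catch <- function(trigger_ms, p_catch = 0.5,
                             delay_range_ms = c(8, 10),
                             daf_duration_ms = 100) {
  stopifnot(p_catch >= 0, p_catch <= 1)
  n <- length(trigger_ms)
  is_catch <- runif(n) < p_catch
  delay <- runif(n, delay_range_ms[1], delay_range_ms[2])
  data.frame(trial_id = seq_len(n), trigger_ms = trigger_ms,
             condition = ifelse(is_catch, "catch", "hit"),
             daf_onset_ms = ifelse(is_catch, NA_real_, trigger_ms + delay),
             daf_duration_ms = daf_duration_ms)
}

#' Contingency rule for feature-contingent (escapable) DAF
#'
#' @param feature Feature name measured in the post-onset window (e.g.
#'   `"mean_freq_hz"`).
#' @param threshold Escape threshold in the feature's units.
#' @param direction `"below"`: values strictly below the threshold escape
#'   DAF; `"above"`: values strictly above it escape.
#' @param window_ms Measurement window from target onset (> 0, ms).
#' @return A `contingency_rule` object.
#' @export
contingency_rule <- function(feature = "mean_freq_hz", threshold,
                             direction = c("below", "above"),
                             window_ms = 10) {
  direction <- match.arg(direction)
  stopifnot(window_ms > 0)
  structure(list(feature = feature, threshold = threshold,
                 direction = direction, window_ms = window_ms),
            class = "contingency_rule")
}

#' Apply a contingency rule to a measured feature value
#'
#' Returns `"play"` when the measured value lies strictly on the non-escape
#' side of the threshold; values on the escape side, or exactly at the
#' threshold, escape. An unmeasurable (`NA`) feature falls back to
#' `default` (play, by default).
#'
#' @param value Measured feature value (e.g. mean frequency over the rule's
#'   window).
#' @param rule A [contingency_rule()].
#' @param default Action when `value` is `NA`.
#' @return `"play"` or `"escape"`.
#' @export
contingent_gate <- function(value, rule, default = "play") {
  stopifnot(inherits(rule, "contingency_rule"))
  if (is.na(value)) return(default)
  play <- if (rule$direction == "below") value > rule$threshold
          else value < rule$threshold
  if (play) "play" else "escape"
}

#' Classify a trial's vocal-motor outcome
#'
#' A hit trial is `truncated` when the expected next syllable is absent
#' (the song stopped: `tau_ms = NA`, i.e. no onset within the search
#' horizon), `delayed` when the syllable occurred but its latency exceeds
#' the `delayed_q` quantile of the catch-trial latency distribution, and
#' `normal` otherwise.
#'
#' @param tau_ms Next expected-syllable onset latency relative to DAF onset
#'   (ms); `NA` if the syllable never occurred.
#' @param catch_tau_ms Latencies from catch trials (reference
#'   distribution).
#' @param delayed_q Quantile of the catch distribution defining "delayed".
#' @return Character vector of outcomes (`"truncated"`, `"delayed"`,
#'   `"normal"`), same length as `tau_ms`.
#' @export
classify_trial_outcome <- function(tau_ms, catch_tau_ms, delayed_q = 0.99) {
  if (!length(catch_tau_ms)) stop("catch latency distribution is empty")
  qd <- quantile(catch_tau_ms, delayed_q, names = FALSE)
  out <- rep("normal", length(tau_ms))
  out[!is.na(tau_ms) & tau_ms > qd] <- "delayed"
  out[is.na(tau_ms)] <- "truncated"
  out
}

#' Classify trial outcomes from an annotation table
#'
#' Convenience wrapper: for each trial, finds the first onset of the
#' expected next syllable within `search_limit_ms` after the trial's
#' (actual or virtual) DAF onset and classifies the outcome with
#' [classify_trial_outcome()]. The search horizon bounds the absence
#' decision -- it must comfortably exceed any plausible within-motif
#' syllable latency while staying below the inter-rendition interval.
#'
#' @param trials Trial table with `daf_onset_ms` / `virtual_daf_onset_ms`
#'   and `condition`.
#' @param annotation Syllable annotation (`onset_ms`, `label`).
#' @param next_label Expected next syllable label (from the motif grammar).
#' @param search_limit_ms Absence horizon after DAF onset (ms).
#' @inheritParams classify_trial_outcome
#' @return `trials` with added `tau_ms` and `outcome` columns.
#' @export
classify_trial_outcomes <- function(trials, annotation, next_label,
                                    delayed_q = 0.99,
                                    search_limit_ms = 500) {
  if (is.null(annotation) || !nrow(annotation))
    stop("annotation table is required")
  ref <- ifelse(is.na(trials$daf_onset_ms),
                trials$virtual_daf_onset_ms, trials$daf_onset_ms)
  onsets <- annotation$onset_ms[annotation$label == next_label]
  tau <- vapply(ref, function(r) {
    nxt <- onsets[onsets >= r & onsets < r + search_limit_ms]
    if (length(nxt)) nxt[1] - r else NA_real_
  }, 0)
  catch_tau <- tau[trials$condition == "catch" & !is.na(tau)]
  trials$tau_ms <- tau
  trials$outcome <- classify_trial_outcome(tau, catch_tau, delayed_q)
  trials$outcome[trials$condition == "catch"] <- "normal"
  trials
}

#' Resample hit trials to match the catch latency distribution
#'
#' DAF can acutely delay upcoming syllables, biasing hit-catch
#' comparisons. Hits are retained with probability
#' `min(1, p(tau | catch) / p(tau | hit))`, with both densities estimated
#' by histograms on a common `bin_ms` grid, which equalizes the
#' next-syllable latency distributions of the retained hits and the
#' catches. A hit whose latency falls in an empty catch bin is always
#' rejected.
#'
#' @param hit_tau_ms,catch_tau_ms Next-syllable latencies (ms), non-empty.
#' @param bin_ms Histogram bin width (ms).
#' @param seed Integer seed.
#' @return Logical vector: which hits are retained.
#' @export
resample_delayed_hits <- function(hit_tau_ms, catch_tau_ms, bin_ms = 5,
                                  seed = 1) {
  if (!length(hit_tau_ms) || !length(catch_tau_ms))
    stop("both latency lists must be non-empty")
  set.seed(seed)
  lo <- floor(min(hit_tau_ms, catch_tau_ms) / bin_ms) * bin_ms
  hi <- ceiling(max(hit_tau_ms, catch_tau_ms) / bin_ms) * bin_ms
  breaks <- seq(lo, hi + bin_ms, by = bin_ms)
  bin_of <- function(x) findInterval(x, breaks, rightmost.closed = TRUE)
  p_hit <- tabulate(bin_of(hit_tau_ms), length(breaks)) / length(hit_tau_ms)
  p_catch <- tabulate(bin_of(catch_tau_ms), length(breaks)) /
    length(catch_tau_ms)
  b <- bin_of(hit_tau_ms)
  ratio <- ifelse(p_hit[b] > 0, p_catch[b] / p_hit[b], 0)
  runif(length(hit_tau_ms)) < pmin(1, ratio)
}
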