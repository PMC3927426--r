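#' Generate a labeled event-summary training set from a song model
#'
#' Renders motifs of the model (plus optional broadband cage-noise events),
#' runs the feature/event pipeline, and labels each detected event by the
#' annotated syllable it overlaps. Used to train the syllable classifier
#' the way the online detector is trained: on clean, manually-labeled
#' renditions.
#'
#' @param model A [song_model()].
#' @param n_motifs Number of motif renditions.
#' @param seed Integer seed.
#' @param cage_noise_events Number of cage-noise (broadband burst) events
#'   appended, labeled `"noise"`.
#' @param ... Passed to [song_features()].
#' @return List with `summaries` (event summaries), `labels`, and the
#'   underlying `frames`/`events`.
#' @export
generate_labeled_events <- function(model, n_motifs, seed = 1,
                                    cage_noise_events = 0, ...) {
  song <- generate_song(model, n_motifs, seed = seed)
  frames <- song_features(song$x, song$fs, ...)
  floor_db <- estimate_noise_floor(
    frames[frames$t_ms <= 200, , drop = FALSE])
  events <- detect_sound_events(frames, noise_floor_db = floor_db)
  summaries <- summarize_events(frames, events)
  lab <- vapply(seq_len(nrow(events)), function(i) {
    mid <- (events$onset_ms[i] + events$offset_ms[i]) / 2
    hit <- song$annotation$onset_ms <= mid & song$annotation$offset_ms > mid
    if (any(hit)) song$annotation$label[which(hit)[1]] else NA_character_
  }, "")
  keep <- !is.na(lab)
  summaries <- summaries[keep, , drop = FALSE]
  lab <- lab[keep]
  if (cage_noise_events > 0) {
    noise_tpl <- syllable_template("noise", duration_ms = 80,
                                   fundamental_hz = 1500, n_harmonics = 1,
                                   amplitude_db = -14, entropy_target = 0.97,
                                   gap_ms = 120)
    nm <- song_model(list(noise_tpl), "noise",
                     noise_floor_db = model$noise_floor_db,
                     sample_rate_hz = model$sample_rate_hz)
    nsong <- generate_song(nm, cage_noise_events, seed = seed + 1)
    nframes <- song_features(nsong$x, nsong$fs, ...)
    nevents <- detect_sound_events(nframes, noise_floor_db = floor_db)
    nsum <- summarize_events(nframes, nevents)
    summaries <- rbind(summaries, nsum)
    lab <- c(lab, rep("noise", nrow(nsum)))
  }
  list(summaries = summaries, labels = lab, frames = frames,
       events = events)
}

.feature_cols <- c("amplitude_mean", "amplitude_var", "mean_freq_mean",
                   "mean_freq_var", "entropy_mean", "entropy_var",
                   "fm_mean", "fm_var", "pitch_mean", "pitch_var",
                   "duration_ms")

#' Simulate a closed-loop DAF session end to end
#'
#' Runs the full online chain on synthetic song, one target-syllable
#' rendition per motif: feature extraction at the 1-kHz frame clock,
#' amplitude-threshold event detection, SVM identification of the
#' pre-target syllable at event offsets, persistence-gated
#' amplitude-threshold target-onset triggering, randomized hit/catch
#' assignment, and (optionally) a feature-contingent escape rule. Event
#' features seen by the online classifier are perturbed by additive
#' Gaussian noise of `detection_noise_sd` (in training-set SD units),
#' emulating the acoustic variability and sensor noise that made the
#' deployed detector miss a fraction of renditions.
#'
#' @param model A [song_model()]; the motif must contain `pretarget_label`
#'   followed by `target_label`.
#' @param classifier A deployable [train_syllable_classifier()] model.
#' @param n_renditions Number of simulated motif renditions.
#' @param pretarget_label,target_label Labels of the pre-target and target
#'   syllables.
#' @param p_catch Catch probability.
#' @param detection_noise_sd SD of the feature noise injected before
#'   online classification (training-SD units).
#' @param persistence_ms,timeout_ms Target-detector parameters, see
#'   [detect_target_and_trigger()].
#' @param delay_range_ms Trigger-to-DAF delay bounds (ms).
#' @param rule Optional [contingency_rule()] applied to hits.
#' @param seed Integer seed.
#' @return Object of class `daf_session`: `trials` (one row per rendition:
#'   `rendition`, `detected`, `trigger_ms`, `trigger_on_target`,
#'   `condition`, `played`), and summary fields `hit_rate_percent`
#'   (plays on target / renditions), `detection_rate`, `n_renditions`.
#' @export
simulate_daf_session <- function(model, classifier, n_renditions,
                                 pretarget_label = "a", target_label = "b",
                                 p_catch = 0.5, detection_noise_sd = 1.0,
                                 persistence_ms = 3, timeout_ms = 100,
                                 delay_range_ms = c(8, 10), rule = NULL,
                                 seed = 1) {
  stopifnot(inherits(model, "song_model"),
            inherits(classifier, "syllable_classifier"))
  if (!classifier$deployable)
    stop("classifier is not deployable (cv accuracy below floor)")
  set.seed(seed)
  rend_seeds <- sample.int(2^30, n_renditions)
  noise_cols <- intersect(.feature_cols, classifier$feature_names)
  sdv <- classifier$scale[noise_cols]
  rows <- vector("list", n_renditions)
  for (r in seq_len(n_renditions)) {
    song <- generate_song(model, 1, seed = rend_seeds[r])
    frames <- song_features(song$x, song$fs)
    floor_db <- estimate_noise_floor(
      frames[frames$t_ms <= 150, , drop = FALSE])
    threshold_db <- floor_db + 20
    events <- detect_sound_events(frames, threshold_db = threshold_db)
    summaries <- summarize_events(frames, events)
    out <- list(rendition = r, detected = FALSE, trigger_ms = NA_real_,
                trigger_on_target = FALSE, condition = NA_character_,
                played = FALSE, timed_out = FALSE)
    if (nrow(summaries)) {
      noisy <- summaries
      noisy[noise_cols] <- noisy[noise_cols] +
        matrix(rnorm(nrow(noisy) * length(noise_cols)), nrow(noisy)) *
        rep(sdv * detection_noise_sd, each = nrow(noisy))
      det <- detect_pretarget(noisy, classifier, pretarget_label)
      if (length(det)) {
        out$detected <- TRUE
        armed_at <- det[1]
        satisfied <- frames$amplitude_db > threshold_db &
          frames$t_ms > armed_at
        trig <- detect_target_and_trigger(frames$t_ms, satisfied,
                                          armed_at_ms = armed_at,
                                          persistence_ms = persistence_ms,
                                          timeout_ms = timeout_ms)
        out$timed_out <- trig$timed_out
        if (!is.na(trig$trigger_ms)) {
          out$trigger_ms <- trig$trigger_ms
          tgt <- song$annotation[song$annotation$label == target_label, ]
          out$trigger_on_target <- any(trig$trigger_ms >= tgt$onset_ms &
                                         trig$trigger_ms < tgt$offset_ms)
          tr <- assign_hit_catch(trig$trigger_ms, p_catch = p_catch,
                                 delay_range_ms = delay_range_ms)
          out$condition <- tr$condition
          play <- tr$condition == "hit"
          if (play && !is.null(rule)) {
            wsel <- frames$t_ms >= trig$trigger_ms &
              frames$t_ms < trig$trigger_ms + rule$window_ms
            val <- mean(frames[[rule$feature]][wsel], na.rm = TRUE)
            play <- contingent_gate(ifelse(is.nan(val), NA, val),
                                    rule) == "play"
          }
          out$played <- play
        }
      }
    }
    rows[[r]] <- as.data.frame(out)
  }
  trials <- do.call(rbind, rows)
  on_target_plays <- sum(trials$played & trials$trigger_on_target)
  structure(list(trials = trials, n_renditions = n_renditions,
                 p_catch = p_catch,
                 detection_rate = mean(trials$trigger_on_target),
                 hit_rate_percent = 100 * on_target_plays / n_renditions),
            class = "daf_session")
}

#' @export
print.daf_session <- function(x, ...) {
  cat(sprintf(paste0("Closed-loop DAF session: %d renditions, catch ",
                     "probability %.2f\n"), x$n_renditions, x$p_catch))
  cat(sprintf("  target detection rate: %.1f%%\n", 100 * x$detection_rate))
  cat(sprintf("  observed hit rate (playbacks / renditions): %.1f%%\n",
              x$hit_rate_percent))
  invisible(x)
}
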