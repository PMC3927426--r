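#' Generate a synthetic DAF trial set with known ground truth
#'
#' Emulates the trial structure of a closed-loop distorted-auditory-feedback
#' (DAF) experiment: each target-syllable rendition is assigned
#' independently to the catch condition with probability `p_catch`;
#' hits receive a DAF onset drawn uniformly 8-10 ms after target onset
#' (the trigger-to-playback delay). Among hits, acute motor outcomes
#' (song truncation, delayed next syllable) occur at the configured rates;
#' catch trials are always `normal`. The latency `tau_ms` of the next
#' expected syllable relative to (actual or virtual) DAF onset is drawn
#' from a Gaussian; delayed trials get an extra positive shift and
#' truncated trials have `tau_ms = NA`.
#'
#' @param n_targets Number of target renditions (>= 1).
#' @param p_catch Catch probability in `[0, 1]`.
#' @param outcome_rates List with `truncated` and `delayed` probabilities
#'   (applied to hit trials; their sum must be <= 1).
#' @param seed Integer seed.
#' @param start_ms Onset of the first target (ms).
#' @param isi_ms Inter-target interval (ms).
#' @param daf_delay_ms Length-2 bounds of the trigger-to-DAF delay (ms).
#' @param daf_duration_ms DAF stimulus duration (ms).
#' @param tau_mean_ms,tau_sd_ms Next-syllable latency distribution (ms).
#' @param delay_shift_ms Extra latency added on `delayed` trials (ms).
#' @return `data.frame` with columns `trial_id`, `target_onset_ms`,
#'   `condition` (`"hit"`/`"catch"`), `daf_onset_ms` (`NA` on catch),
#'   `daf_duration_ms`, `outcome`, `tau_ms`. On catch trials `tau_ms` is
#'   referenced to a virtual DAF onset at the mean delay.
#' @export
generate_trial_set <- function(n_targets, p_catch = 0.5,
                               outcome_rates = list(truncated = 0, delayed = 0),
                               seed = 1, start_ms = 1000, isi_ms = 1000,
                               daf_delay_ms = c(8, 10), daf_duration_ms = 100,
                               tau_mean_ms = 60, tau_sd_ms = 6,
                               delay_shift_ms = 40) {
  stopifnot(n_targets >= 1, p_catch >= 0, p_catch <= 1)
  pr_t <- outcome_rates$truncated %||% 0
  pr_d <- outcome_rates$delayed %||% 0
  stopifnot(pr_t >= 0, pr_d >= 0, pr_t + pr_d <= 1)
  set.seed(seed)
  onset <- start_ms + (seq_len(n_targets) - 1) * isi_ms
  is_catch <- runif(n_targets) < p_catch
  delay <- runif(n_targets, daf_delay_ms[1], daf_delay_ms[2])
  daf_onset <- ifelse(is_catch, NA_real_, onset + delay)
  virtual_daf <- ifelse(is_catch, onset + mean(daf_delay_ms), daf_onset)
  u <- runif(n_targets)
  outcome <- rep("normal", n_targets)
  outcome[!is_catch & u < pr_t] <- "truncated"
  outcome[!is_catch & u >= pr_t & u < pr_t + pr_d] <- "delayed"
  tau <- rnorm(n_targets, tau_mean_ms, tau_sd_ms)
  tau[outcome == "delayed"] <- tau[outcome == "delayed"] + delay_shift_ms
  tau[outcome == "truncated"] <- NA_real_
  data.frame(trial_id = seq_len(n_targets), target_onset_ms = onset,
             condition = ifelse(is_catch, "catch", "hit"),
             daf_onset_ms = daf_onset, virtual_daf_onset_ms = virtual_daf,
             daf_duration_ms = daf_duration_ms,
             outcome = outcome, tau_ms = tau)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
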