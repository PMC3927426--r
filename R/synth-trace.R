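#' Define a model HVC projection-neuron membrane-potential generator
#'
#' Captures the stereotyped intracellular phenomenology of song-premotor
#' projection neurons: tonic regular firing at rest, a hyperpolarized state
#' entered a few hundred milliseconds before song onset, and a stereotyped
#' sequence of sharp-rising depolarizing postsynaptic potentials (dPSPs)
#' leading each linked syllable onset. dPSPs are difference-of-exponential
#' waveforms; noise is additive Gaussian.
#'
#' @param rest_mv Resting potential (mV).
#' @param singing_offset_mv Vm offset during singing (mV; negative =
#'   hyperpolarization).
#' @param dpsp_schedule List of entries `list(label=, lead_ms=,
#'   amplitude_mv=, rise_ms=, decay_ms=)`; one dPSP is injected `lead_ms`
#'   before every onset of syllable `label` (`label = NULL` links to all
#'   syllables). `rise_ms < decay_ms` is required.
#' @param spike_threshold_mv Threshold above which a spike waveform is
#'   inserted (mV).
#' @param spike_amp_mv Spike height above threshold crossing (mV).
#' @param tonic_rate_hz Poisson rate of tonic spiking outside song (Hz).
#' @param noise_sd_mv SD of additive Gaussian noise (mV, >= 0).
#' @param sample_rate_hz Trace sample rate (Hz).
#' @return A `cell_model` object.
#' @export
cell_model <- function(rest_mv = -58.5, singing_offset_mv = -3.8,
                       dpsp_schedule = default_dpsp_schedule(),
                       spike_threshold_mv = -40, spike_amp_mv = 70,
                       tonic_rate_hz = 8, noise_sd_mv = 0.5,
                       sample_rate_hz = 10000) {
  stopifnot(noise_sd_mv >= 0, sample_rate_hz > 0, tonic_rate_hz >= 0)
  for (d in dpsp_schedule)
    if (!(d$rise_ms < d$decay_ms))
      stop("dPSP rise_ms must be smaller than decay_ms")
  structure(list(rest_mv = rest_mv, singing_offset_mv = singing_offset_mv,
                 dpsp_schedule = dpsp_schedule,
                 spike_threshold_mv = spike_threshold_mv,
                 spike_amp_mv = spike_amp_mv, tonic_rate_hz = tonic_rate_hz,
                 noise_sd_mv = noise_sd_mv, sample_rate_hz = sample_rate_hz),
            class = "cell_model")
}

#' Default dPSP schedule: one dPSP leading each syllable onset by 25 ms
#' @param lead_ms Lead of the dPSP onset before the syllable onset (ms).
#' @param amplitude_mv dPSP amplitude (mV).
#' @return List of schedule entries for [cell_model()].
#' @export
default_dpsp_schedule <- function(lead_ms = 25, amplitude_mv = 6) {
  list(list(label = NULL, lead_ms = lead_ms, amplitude_mv = amplitude_mv,
            rise_ms = 2, decay_ms = 12))
}

.dpsp_kernel <- function(rise_ms, decay_ms, amplitude_mv, fs, span_ms = NULL) {
  if (is.null(span_ms)) span_ms <- decay_ms * 6
  t <- seq(0, span_ms / 1000, by = 1 / fs)
  k <- exp(-t / (decay_ms / 1000)) - exp(-t / (rise_ms / 1000))
  k / max(k) * amplitude_mv
}

#' Generate a synthetic membrane-potential trace with known ground truth
#'
#' Builds a Vm trace aligned to a song annotation: resting potential, a
#' smooth transition into the hyperpolarized singing state starting
#' `pre_song_ramp_ms` before each bout onset, scheduled dPSPs before linked
#' syllable onsets, spikes wherever the deterministic trace crosses the
#' spike threshold plus tonic Poisson spikes outside song, and additive
#' Gaussian noise. With `noise_sd_mv = 0` the trace deviates from the state
#' baseline only at scheduled dPSPs and spikes, and all injected event
#' times are recoverable exactly.
#'
#' No DAF-evoked synaptic response is generated unless `daf_effect_mv` is
#' nonzero: by construction hit and catch epochs are then statistically
#' identical (the DAF-null regime). A nonzero `daf_effect_mv` adds a boxcar
#' of that height over `daf_effect_window_ms` (relative to DAF onset) on
#' hit trials only, for power/recovery studies.
#'
#' @param cell A [cell_model()].
#' @param annotation Syllable annotation (`onset_ms`, `offset_ms`, `label`),
#'   e.g. from [generate_song()].
#' @param trials Optional trial table from [generate_trial_set()]; DAF
#'   onsets must lie within the trace span.
#' @param duration_ms Trace duration; defaults to covering the annotation
#'   plus 1 s.
#' @param seed Integer seed.
#' @param pre_song_ramp_ms Onset of the pre-song hyperpolarization ramp
#'   before each bout onset (ms).
#' @param daf_effect_mv,daf_effect_window_ms Optional injected DAF response
#'   on hit trials (see above).
#' @return A `membrane_trace` object: `vm_mv`, `fs`, `anchors` (list with
#'   `syllable_onsets_ms`, `syllable_offsets_ms`, `bout_onsets_ms`, and per
#'   trial DAF anchors if `trials` given) and `truth` (list with
#'   `dpsp_onsets_ms`, `spike_times_ms`).
#' @export
generate_membrane_trace <- function(cell, annotation, trials = NULL,
                                    duration_ms = NULL, seed = 1,
                                    pre_song_ramp_ms = 300,
                                    daf_effect_mv = 0,
                                    daf_effect_window_ms = c(20, 60)) {
  stopifnot(inherits(cell, "cell_model"))
  set.seed(seed)
  fs <- cell$sample_rate_hz
  if (is.null(duration_ms))
    duration_ms <- max(annotation$offset_ms) + 1000
  if (!is.null(trials)) {
    daf <- trials$daf_onset_ms[!is.na(trials$daf_onset_ms)]
    if (any(daf < 0 | daf > duration_ms))
      stop("trial DAF onsets fall outside the trace span")
  }
  n <- round(duration_ms * fs / 1000)
  t_ms <- (0:(n - 1)) / fs * 1000

  # bout onsets: first syllable preceded by >= 1 s of silence
  if (nrow(annotation)) {
    on <- annotation$onset_ms
    off <- annotation$offset_ms
    gap_before <- c(Inf, on[-1] - off[-length(off)])
    bout_onsets <- on[gap_before >= 1000]
    bout_offsets <- vapply(bout_onsets, function(b) {
      later_start <- on[gap_before >= 1000 & on > b]
      if (length(later_start)) max(off[on < min(later_start)])
      else max(off[on >= b])
    }, 0)
  } else {
    bout_onsets <- bout_offsets <- numeric(0)
  }

  vm <- rep(cell$rest_mv, n)
  singing <- rep(FALSE, n)
  for (b in seq_along(bout_onsets)) {
    ramp0 <- bout_onsets[b] - pre_song_ramp_ms
    i0 <- max(1L, round(ramp0 * fs / 1000) + 1L)
    i1 <- max(1L, round(bout_onsets[b] * fs / 1000) + 1L)
    i2 <- min(n, round((bout_offsets[b] + 200) * fs / 1000) + 1L)
    if (i1 > i0)
      vm[i0:i1] <- vm[i0:i1] +
        cell$singing_offset_mv * seq(0, 1, length.out = i1 - i0 + 1)
    if (i2 > i1) vm[(i1 + 1):i2] <- vm[(i1 + 1):i2] + cell$singing_offset_mv
    # smooth recovery back to rest (no artificial sharp rise)
    i3 <- min(n, i2 + round(0.3 * fs))
    if (i3 > i2)
      vm[(i2 + 1):i3] <- vm[(i2 + 1):i3] +
        cell$singing_offset_mv * seq(1, 0, length.out = i3 - i2 + 1)[-1]
    singing[i0:i2] <- TRUE
  }

  # scheduled dPSPs
  dpsp_onsets <- numeric(0)
  for (sch in cell$dpsp_schedule) {
    link <- if (is.null(sch$label)) rep(TRUE, nrow(annotation))
            else annotation$label == sch$label
    onsets <- annotation$onset_ms[link] - sch$lead_ms
    onsets <- onsets[onsets >= 0 & onsets < duration_ms]
    ker <- .dpsp_kernel(sch$rise_ms, sch$decay_ms, sch$amplitude_mv, fs)
    for (o in onsets) {
      i0 <- round(o * fs / 1000) + 1L
      i1 <- min(n, i0 + length(ker) - 1L)
      vm[i0:i1] <- vm[i0:i1] + ker[seq_len(i1 - i0 + 1L)]
    }
    dpsp_onsets <- c(dpsp_onsets, onsets)
  }
  dpsp_onsets <- sort(dpsp_onsets)

  # injected DAF effect (hit trials only)
  if (daf_effect_mv != 0 && !is.null(trials)) {
    hits <- trials$daf_onset_ms[trials$condition == "hit"]
    hits <- hits[!is.na(hits)]
    for (h in hits) {
      i0 <- max(1L, round((h + daf_effect_window_ms[1]) * fs / 1000) + 1L)
      i1 <- min(n, round((h + daf_effect_window_ms[2]) * fs / 1000))
      if (i1 >= i0) vm[i0:i1] <- vm[i0:i1] + daf_effect_mv
    }
  }

  # spikes: deterministic threshold crossings plus tonic spiking at rest
  spike_ker <- .spike_kernel(cell$spike_amp_mv, fs)
  cross <- which(vm[-1] >= cell$spike_threshold_mv &
                 vm[-n] < cell$spike_threshold_mv)
  spike_idx <- cross + 1L
  if (cell$tonic_rate_hz > 0) {
    n_tonic <- rpois(1, cell$tonic_rate_hz * duration_ms / 1000)
    cand <- sort(runif(n_tonic, 0, duration_ms))
    ti <- round(cand * fs / 1000) + 1L
    ti <- ti[ti >= 1 & ti <= n & !singing[pmin(ti, n)]]
    spike_idx <- sort(unique(c(spike_idx, ti)))
  }
  # 5-ms refractoriness between inserted spikes
  if (length(spike_idx) > 1) {
    keep <- c(TRUE, diff(spike_idx) >= round(0.005 * fs))
    while (!all(keep)) {
      spike_idx <- spike_idx[keep]
      keep <- c(TRUE, diff(spike_idx) >= round(0.005 * fs))
    }
  }
  for (si in spike_idx) {
    i1 <- min(n, si + length(spike_ker) - 1L)
    vm[si:i1] <- vm[si:i1] + spike_ker[seq_len(i1 - si + 1L)]
  }

  if (cell$noise_sd_mv > 0) vm <- vm + rnorm(n, 0, cell$noise_sd_mv)

  anchors <- list(syllable_onsets_ms = annotation$onset_ms,
                  syllable_offsets_ms = annotation$offset_ms,
                  bout_onsets_ms = bout_onsets,
                  bout_offsets_ms = bout_offsets)
  if (!is.null(trials)) anchors$trials <- trials
  structure(list(vm_mv = vm, fs = fs, t_ms = t_ms, anchors = anchors,
                 truth = list(dpsp_onsets_ms = dpsp_onsets,
                              spike_times_ms = (spike_idx - 1L) / fs * 1000),
                 cell = cell),
            class = "membrane_trace")
}

.spike_kernel <- function(amp_mv, fs, width_ms = 1) {
  half <- max(1L, round(width_ms / 2 * fs / 1000))
  c(seq(0, amp_mv, length.out = half + 1)[-1],
    seq(amp_mv, 0, length.out = half + 1)[-1])
}

#' @export
print.membrane_trace <- function(x, ...) {
  cat("Membrane trace:", length(x$vm_mv), "samples at", x$fs, "Hz (",
      round(length(x$vm_mv) / x$fs, 2), "s );",
      length(x$truth$dpsp_onsets_ms), "true dPSPs,",
      length(x$truth$spike_times_ms), "true spikes,",
      length(x$anchors$bout_onsets_ms), "bout(s)\n")
  invisible(x)
}

#' Extract trial-aligned Vm segments as a matrix
#'
#' Cuts windows around anchor times on a common relative-time grid; one row
#' per anchor. Anchors whose window falls outside the trace are dropped
#' (with a warning).
#'
#' @param vm Numeric Vm vector, or a `membrane_trace`.
#' @param fs Sample rate (Hz); ignored if `vm` is a `membrane_trace`.
#' @param anchors_ms Anchor times (ms).
#' @param window_ms Length-2 window relative to the anchor (ms, half-open).
#' @return Matrix (anchors x samples) with attribute `t_ms`, the relative
#'   time of each column.
#' @export
align_trials <- function(vm, fs = NULL, anchors_ms, window_ms = c(-200, 200)) {
  if (inherits(vm, "membrane_trace")) {
    fs <- vm$fs
    vm <- vm$vm_mv
  }
  stopifnot(!is.null(fs), window_ms[1] < window_ms[2])
  rel_idx <- seq(round(window_ms[1] * fs / 1000),
                 round(window_ms[2] * fs / 1000) - 1L)
  t_ms <- rel_idx / fs * 1000
  rows <- lapply(anchors_ms, function(a) {
    idx <- round(a * fs / 1000) + 1L + rel_idx
    if (any(idx < 1 | idx > length(vm))) return(NULL)
    vm[idx]
  })
  drop <- vapply(rows, is.null, TRUE)
  if (any(drop)) warning(sum(drop), " anchor(s) outside the trace span dropped")
  m <- do.call(rbind, rows[!drop])
  attr(m, "t_ms") <- t_ms
  m
}
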