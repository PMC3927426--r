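#' Define a syllable template for song synthesis
#'
#' Syllables are synthesized as harmonic stacks (amplitude-weighted
#' harmonics of a fundamental) under a raised-cosine envelope; spectral
#' entropy is controlled by mixing in a white-noise component.
#'
#' @param label Syllable label (single string).
#' @param duration_ms Syllable duration (> 0, ms).
#' @param fundamental_hz Fundamental frequency (Hz).
#' @param n_harmonics Number of harmonics in the stack.
#' @param amplitude_db Syllable RMS level in dB re full scale.
#' @param entropy_target Fraction of syllable power carried by the white
#'   noise component, in `[0, 1]` (0 = pure harmonic stack, 1 = pure noise).
#' @param gap_ms Silent gap following the syllable (ms).
#' @return A `syllable_template` list.
#' @export
syllable_template <- function(label, duration_ms, fundamental_hz,
                              n_harmonics = 8, amplitude_db = -10,
                              entropy_target = 0.05, gap_ms = 40) {
  stopifnot(duration_ms > 0, fundamental_hz > 0, n_harmonics >= 1,
            entropy_target >= 0, entropy_target <= 1, gap_ms >= 0)
  structure(list(label = label, duration_ms = duration_ms,
                 fundamental_hz = fundamental_hz, n_harmonics = n_harmonics,
                 amplitude_db = amplitude_db, entropy_target = entropy_target,
                 gap_ms = gap_ms),
            class = "syllable_template")
}

#' Define a song model
#'
#' A stereotyped zebra-finch-like song: a motif is a fixed sequence of
#' syllable templates (introductory note plus syllables), repeated with
#' optional Gaussian jitter on the inter-syllable gaps.
#'
#' @param syllables Named list of [syllable_template()]s.
#' @param motif_order Character vector of template labels (non-empty),
#'   including the introductory-note label.
#' @param tempo_jitter_sd_ms SD of the Gaussian jitter added to each gap.
#' @param noise_floor_db Background noise level in dB re full scale.
#' @param sample_rate_hz Sample rate; 44100 or 22050 Hz.
#' @return A `song_model` object.
#' @export
song_model <- function(syllables, motif_order,
                       tempo_jitter_sd_ms = 0, noise_floor_db = -60,
                       sample_rate_hz = 22050) {
  if (!sample_rate_hz %in% c(44100, 22050))
    stop("sample_rate_hz must be 44100 or 22050")
  if (length(motif_order) < 1) stop("motif_order must be non-empty")
  labs <- vapply(syllables, `[[`, "", "label")
  names(syllables) <- labs
  if (!all(motif_order %in% labs))
    stop("motif_order refers to unknown syllable labels")
  stopifnot(tempo_jitter_sd_ms >= 0)
  structure(list(syllables = syllables, motif_order = motif_order,
                 tempo_jitter_sd_ms = tempo_jitter_sd_ms,
                 noise_floor_db = noise_floor_db,
                 sample_rate_hz = sample_rate_hz),
            class = "song_model")
}

#' A default five-element zebra-finch-like song model
#'
#' Introductory note `i` followed by four harmonic-stack syllables `a`-`d`
#' with distinct fundamentals, durations and entropy, in the motif order
#' `i a b c d`.
#'
#' @param sample_rate_hz Sample rate (Hz).
#' @param tempo_jitter_sd_ms Gap jitter SD (ms).
#' @param noise_floor_db Background noise level (dB re full scale).
#' @return A [song_model()].
#' @export
default_song_model <- function(sample_rate_hz = 22050, tempo_jitter_sd_ms = 2,
                               noise_floor_db = -60) {
  song_model(
    syllables = list(
      syllable_template("i", 45, 650, n_harmonics = 4, amplitude_db = -16,
                        entropy_target = 0.10, gap_ms = 30),
      syllable_template("a", 90, 520, n_harmonics = 10, amplitude_db = -10,
                        entropy_target = 0.05, gap_ms = 35),
      syllable_template("b", 70, 780, n_harmonics = 7, amplitude_db = -8,
                        entropy_target = 0.25, gap_ms = 30),
      syllable_template("c", 120, 430, n_harmonics = 12, amplitude_db = -12,
                        entropy_target = 0.02, gap_ms = 40),
      syllable_template("d", 60, 940, n_harmonics = 5, amplitude_db = -9,
                        entropy_target = 0.45, gap_ms = 50)),
    motif_order = c("i", "a", "b", "c", "d"),
    tempo_jitter_sd_ms = tempo_jitter_sd_ms,
    noise_floor_db = noise_floor_db,
    sample_rate_hz = sample_rate_hz)
}

.synth_syllable <- function(tpl, fs) {
  n <- max(2L, round(tpl$duration_ms * fs / 1000))
  t <- (0:(n - 1)) / fs
  harm <- rep(0, n)
  for (k in seq_len(tpl$n_harmonics)) {
    f <- k * tpl$fundamental_hz
    if (f >= fs / 2) break
    harm <- harm + sin(2 * pi * f * t) / k
  }
  if (sd(harm) > 0) harm <- harm / sqrt(mean(harm^2))
  noise <- rnorm(n)
  noise <- noise / sqrt(mean(noise^2))
  e <- tpl$entropy_target
  x <- sqrt(1 - e) * harm + sqrt(e) * noise
  env <- 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))   # raised cosine
  x <- x * env
  x <- x / sqrt(mean(x^2)) * 10^(tpl$amplitude_db / 20)
  x
}

#' Generate synthetic song audio with a ground-truth annotation
#'
#' Renders `n_motifs` repetitions of the model's motif, separated by
#' `inter_motif_gap_ms` of silence, over a Gaussian background at the
#' model's noise floor. A leading `lead_ms` of background-only audio is
#' included for noise-floor calibration.
#'
#' @param model A [song_model()].
#' @param n_motifs Number of motif renditions (>= 1).
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @param inter_motif_gap_ms Silence between motifs (ms).
#' @param lead_ms Leading background-only segment (ms).
#' @return A list of class `synthetic_song`: `x` (waveform), `fs`, and
#'   `annotation`, a `data.frame` with one row per rendered syllable
#'   (`onset_ms`, `offset_ms` half-open, `label`, `motif`, `f0_hz`).
#' @export
generate_song <- function(model, n_motifs, seed = 1,
                          inter_motif_gap_ms = 300, lead_ms = 200) {
  stopifnot(inherits(model, "song_model"), n_motifs >= 1)
  set.seed(seed)
  fs <- model$sample_rate_hz
  pieces <- list()
  ann <- list()
  cursor <- round(lead_ms * fs / 1000)   # samples of silence so far
  pieces[[1]] <- rep(0, cursor)
  pi_ <- 2L
  for (m in seq_len(n_motifs)) {
    for (lab in model$motif_order) {
      tpl <- model$syllables[[lab]]
      syl <- .synth_syllable(tpl, fs)
      gap_ms <- tpl$gap_ms
      if (model$tempo_jitter_sd_ms > 0)
        gap_ms <- max(0, gap_ms + rnorm(1, 0, model$tempo_jitter_sd_ms))
      gap_n <- round(gap_ms * fs / 1000)
      ann[[length(ann) + 1L]] <- data.frame(
        onset_ms = cursor / fs * 1000,
        offset_ms = (cursor + length(syl)) / fs * 1000,
        label = lab, motif = m, f0_hz = tpl$fundamental_hz)
      pieces[[pi_]] <- syl; pi_ <- pi_ + 1L
      pieces[[pi_]] <- rep(0, gap_n); pi_ <- pi_ + 1L
      cursor <- cursor + length(syl) + gap_n
    }
    if (m < n_motifs) {
      gn <- round(inter_motif_gap_ms * fs / 1000)
      pieces[[pi_]] <- rep(0, gn); pi_ <- pi_ + 1L
      cursor <- cursor + gn
    }
  }
  x <- unlist(pieces, use.names = FALSE)
  x <- x + rnorm(length(x)) * 10^(model$noise_floor_db / 20)
  annotation <- do.call(rbind, ann)
  rownames(annotation) <- NULL
  structure(list(x = x, fs = fs, annotation = annotation, model = model),
            class = "synthetic_song")
}

#' @export
print.synthetic_song <- function(x, ...) {
  cat("Synthetic song:", length(x$x), "samples at", x$fs, "Hz (",
      round(length(x$x) / x$fs, 2), "s ),", nrow(x$annotation),
      "annotated syllables in", max(x$annotation$motif), "motif(s)\n")
  invisible(x)
}
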