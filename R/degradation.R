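#' Wiener entropy and entropy variance of a syllable
#'
#' Mean and variance of the frame-wise Wiener entropy over a syllable's
#' audio segment, the two spectral features most sensitive to the loss of
#' harmonic structure after deafening. Entropy variance (EV) here is the
#' variance of the frame-wise entropy across the frames of the syllable.
#'
#' @param x Audio segment of one syllable rendition.
#' @param fs Sample rate (Hz).
#' @param silence_floor_db Frames below this amplitude are treated as
#'   silent and excluded.
#' @param ... Passed to [song_features()].
#' @return List with `entropy` (mean, <= 0), `ev` (variance, >= 0), and
#'   `n_frames`. Both are `NA` (flagged by `n_frames = 0`) for a silent
#'   segment.
#' @export
syllable_entropy_ev <- function(x, fs, silence_floor_db = -70, ...) {
  f <- song_features(x, fs, ...)
  if (nrow(f) < 2) stop("segment must span at least 2 frames")
  keep <- f$amplitude_db > silence_floor_db & !is.na(f$wiener_entropy)
  if (!any(keep))
    return(list(entropy = NA_real_, ev = NA_real_, n_frames = 0L))
  e <- f$wiener_entropy[keep]
  list(entropy = mean(e), ev = var(e), n_frames = length(e))
}

#' Entropy/EV records for every annotated syllable of a song
#'
#' @param song A [generate_song()] object (or list with `x`, `fs`,
#'   `annotation`).
#' @param day Day label attached to the records.
#' @param ... Passed to [syllable_entropy_ev()].
#' @return `data.frame` with `syllable_id`, `day`, `rendition_id`,
#'   `entropy`, `ev`.
#' @export
syllable_spectral_records <- function(song, day = 0, ...) {
  ann <- song$annotation
  out <- lapply(seq_len(nrow(ann)), function(i) {
    i0 <- max(1L, round(ann$onset_ms[i] * song$fs / 1000) + 1L)
    i1 <- min(length(song$x), round(ann$offset_ms[i] * song$fs / 1000))
    r <- syllable_entropy_ev(song$x[i0:i1], song$fs, ...)
    data.frame(syllable_id = ann$label[i], day = day,
               rendition_id = i, entropy = r$entropy, ev = r$ev)
  })
  do.call(rbind, out)
}

#' Detect the onset day of song degradation
#'
#' For each syllable and each feature (entropy, EV), daily distributions
#' are compared with the pooled baseline distribution (the first
#' `baseline_days` days) by one-way ANOVA. A day `d` is a degradation
#' onset for that syllable/feature if its distribution differs
#' significantly from baseline (p < `alpha`) *and stays significantly
#' different on every subsequent day* -- a transient single-day deviation
#' never yields an onset. Because persistence cannot be assessed without
#' at least one subsequent day, the final observed day is never an onset
#' candidate by itself (it only serves as evidence of persistence for
#' earlier days). The bird-level onset is the earliest onset over all
#' syllables and features.
#'
#' @param records `data.frame` with `syllable_id`, `day`, `entropy`, `ev`
#'   (e.g. rbind-ed [syllable_spectral_records()] across days; typically
#'   ~30 renditions per syllable per day).
#' @param baseline_days Number of leading days pooled into the baseline
#'   (>= 2).
#' @param alpha ANOVA significance level.
#' @return Object of class `degradation_onset`: `onset_day` (`NA` if
#'   none), and `table` with one row per syllable/feature giving its
#'   onset day.
#' @export
degradation_onset <- function(records, baseline_days = 2, alpha = 0.05) {
  stopifnot(baseline_days >= 2)
  days <- sort(unique(records$day))
  if (length(days) < baseline_days + 1)
    stop("need at least one post-baseline day")
  base_days <- days[seq_len(baseline_days)]
  post_days <- days[-seq_len(baseline_days)]
  rows <- list()
  for (syl in unique(records$syllable_id)) {
    rs <- records[records$syllable_id == syl, ]
    for (feat in c("entropy", "ev")) {
      base_v <- rs[[feat]][rs$day %in% base_days]
      base_v <- base_v[!is.na(base_v)]
      sig <- vapply(post_days, function(d) {
        v <- rs[[feat]][rs$day == d]
        v <- v[!is.na(v)]
        if (length(v) < 2 || length(base_v) < 2) return(NA)
        vals <- c(base_v, v)
        grp <- factor(rep(c("base", "day"), c(length(base_v), length(v))))
        if (var(vals) == 0) return(FALSE)
        anova(lm(vals ~ grp))[["Pr(>F)"]][1] < alpha
      }, TRUE)
      onset <- NA_real_
      avail <- !is.na(sig)
      np <- length(post_days)
      for (j in seq_len(max(0L, np - 1L))) {   # last day: no persistence info
        later <- avail & seq_len(np) >= j
        if (avail[j] && sig[j] && sum(later) >= 2 && all(sig[later])) {
          onset <- post_days[j]
          break
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        syllable_id = syl, feature = feat, onset_day = onset)
    }
  }
  tab <- do.call(rbind, rows)
  onset_day <- if (all(is.na(tab$onset_day))) NA_real_
               else min(tab$onset_day, na.rm = TRUE)
  structure(list(onset_day = onset_day, table = tab,
                 baseline_days = base_days, alpha = alpha),
            class = "degradation_onset")
}

#' @export
print.degradation_onset <- function(x, ...) {
  if (is.na(x$onset_day)) cat("No song-degradation onset detected\n")
  else cat("Song degradation onset: day", x$onset_day, "\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}
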