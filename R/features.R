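#' Discrete prolate spheroidal (Slepian) tapers
#'
#' First `k` DPSS tapers of length `n` with time-bandwidth product `nw`,
#' computed from the symmetric tridiagonal eigenproblem. Tapers are
#' orthonormal (unit energy); signs follow the usual convention (symmetric
#' tapers have positive mean, antisymmetric tapers positive initial slope).
#'
#' @param n Taper length in samples.
#' @param k Number of tapers.
#' @param nw Time-bandwidth parameter.
#' @return An `n x k` matrix, one taper per column.
#' @export
dpss_tapers <- function(n, k = 2, nw = 4) {
  stopifnot(n >= 2, k >= 1, k <= n, nw > 0)
  key <- paste0("dpss_", n, "_", k, "_", nw)
  cached <- .songgate_cache[[key]]
  if (!is.null(cached)) return(cached)
  w <- nw / n
  tt <- 0:(n - 1)
  A <- diag(((n - 1 - 2 * tt) / 2)^2 * cos(2 * pi * w))
  off <- (1:(n - 1)) * (n - (1:(n - 1))) / 2
  A[cbind(1:(n - 1), 2:n)] <- off
  A[cbind(2:n, 1:(n - 1))] <- off
  v <- eigen(A, symmetric = TRUE)$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    v[, j] <- v[, j] / sqrt(sum(v[, j]^2))
    flip <- if (j %% 2 == 1) sum(v[, j]) < 0 else (v[2, j] - v[1, j]) < 0
    if (flip) v[, j] <- -v[, j]
  }
  .songgate_cache[[key]] <- v
  v
}

#' Multitaper power-spectrum estimate of a short sound segment
#'
#' Averages per-taper periodograms over the first `n_tapers` Slepian
#' sequences (or a single rectangular taper). The one-sided spectrum is
#' scaled so that `sum(power)` equals the mean tapered-signal energy
#' (Parseval-consistent).
#'
#' @param x Numeric vector, one analysis window of samples.
#' @param fs Sample rate (Hz).
#' @param n_tapers Number of tapers to average.
#' @param nw DPSS time-bandwidth parameter.
#' @param nfft FFT length (zero-padded); enlarged automatically if
#'   `length(x) > nfft`.
#' @param taper `"dpss"` or `"rect"` (single rectangular taper, i.e. the
#'   plain periodogram).
#' @return A list with `freq` (Hz), `power` (one-sided), `fs`, `nfft`.
#' @export
multitaper_spectrum <- function(x, fs, n_tapers = 2, nw = 4, nfft = 512,
                                taper = c("dpss", "rect")) {
  taper <- match.arg(taper)
  n <- length(x)
  if (n < 2) stop("window must contain at least 2 samples")
  stopifnot(n_tapers >= 1)
  if (n > nfft) nfft <- 2^ceiling(log2(n))
  H <- if (taper == "rect") {
    matrix(1 / sqrt(n), n, 1)
  } else {
    dpss_tapers(n, n_tapers, nw)
  }
  P <- .mt_power(matrix(x, ncol = 1), H, nfft)[, 1]
  nb <- nfft %/% 2 + 1
  list(freq = (0:(nb - 1)) * fs / nfft, power = P, fs = fs, nfft = nfft)
}

# one-sided multitaper power of a (win x nframes) matrix of windows
.mt_power <- function(frames, H, nfft) {
  n <- nrow(frames)
  nf <- ncol(frames)
  nb <- nfft %/% 2 + 1
  acc <- matrix(0, nb, nf)
  pad <- matrix(0, nfft - n, nf)
  for (j in seq_len(ncol(H))) {
    X <- mvfft(rbind(frames * H[, j], pad))
    p2 <- Mod(X[seq_len(nb), , drop = FALSE])^2
    # fold: double interior bins so sum(one-sided) == sum(two-sided)
    if (nb > 2) p2[2:(nb - 1), ] <- 2 * p2[2:(nb - 1), ]
    if (nfft %% 2 == 1) p2[nb, ] <- 2 * p2[nb, ]
    acc <- acc + p2 / nfft
  }
  acc / ncol(H)
}

#' Acoustic features of one spectral frame
#'
#' Computes the per-frame features used by the online song detector:
#' amplitude (dB re full scale), power-weighted mean frequency, Wiener
#' entropy (log of geometric over arithmetic mean of in-band power, `<= 0`),
#' frequency modulation (angle between temporal and spectral derivatives of
#' the log spectrum), and pitch with its salience ("goodness"). Pitch is
#' the first strong peak of the normalized autocorrelation of the raw
#' analysis window within the search band (parabolically interpolated);
#' goodness is that peak's correlation value in `[0, 1]`. Pitch therefore
#' requires the time-domain `window`; without it pitch and goodness are
#' `NA`.
#'
#' @param spectrum A spectrum as returned by [multitaper_spectrum()].
#' @param prev_spectrum Previous frame's spectrum, for the FM feature
#'   (`NULL` gives `fm = NA`).
#' @param window Raw samples of the same analysis window (for pitch).
#' @param band Analysis band (Hz) for centroid/entropy/FM.
#' @param pitch_band Pitch search band (Hz).
#' @param entropy_floor Cap used when the geometric mean underflows
#'   (degenerate, near-line spectra); log units.
#' @param amp_floor_db Amplitude reported for an all-zero spectrum.
#' @return One-row `data.frame` with columns `amplitude_db, mean_freq_hz,
#'   wiener_entropy, fm, pitch_hz, goodness`.
#' @export
frame_features <- function(spectrum, prev_spectrum = NULL, window = NULL,
                           band = c(500, 10000), pitch_band = c(400, 6000),
                           entropy_floor = -25, amp_floor_db = -120) {
  P <- matrix(spectrum$power, ncol = 1)
  Pprev <- if (is.null(prev_spectrum)) NULL else
    matrix(prev_spectrum$power, ncol = 1)
  W <- if (is.null(window)) NULL else matrix(window, ncol = 1)
  out <- .frame_features_mat(P, spectrum$freq, spectrum$fs, spectrum$nfft,
                             Pprev, band, pitch_band, entropy_floor,
                             amp_floor_db, frames = W)
  as.data.frame(out)
}

# vectorized feature computation over columns of a one-sided power matrix;
# `frames` (win x nf raw windows) enables time-domain pitch
.frame_features_mat <- function(P, freq, fs, nfft, Pprev, band, pitch_band,
                                entropy_floor, amp_floor_db, frames = NULL) {
  if (any(P < 0)) stop("power spectrum must be non-negative")
  nf <- ncol(P)
  tot <- colSums(P)
  silent <- tot <= 0
  amplitude_db <- ifelse(silent, amp_floor_db,
                         pmax(10 * log10(tot + 1e-300), amp_floor_db))

  inb <- freq >= band[1] & freq <= band[2]
  Pb <- P[inb, , drop = FALSE]
  bsum <- colSums(Pb)
  bzero <- bsum <= 0
  mean_freq_hz <- ifelse(bzero, NA_real_, colSums(freq[inb] * Pb) / bsum)

  # Wiener entropy: log(geometric mean) - log(arithmetic mean), <= 0
  logPb <- suppressWarnings(log(Pb))
  we <- colMeans(logPb) - log(colMeans(Pb))
  we[!is.finite(we)] <- entropy_floor
  we <- pmin(pmax(we, entropy_floor), 0)
  we[bzero] <- NA_real_

  # FM: angle of temporal vs spectral derivative magnitude of log spectrum
  fm <- rep(NA_real_, nf)
  eps <- 1e-12
  L <- log(Pb + eps)
  nbnd <- nrow(L)
  D <- L[-1, , drop = FALSE] - L[-nbnd, , drop = FALSE]
  dfreq <- sqrt(colMeans(D^2))
  if (!is.null(Pprev)) {
    Lp <- log(Pprev[inb, , drop = FALSE] + eps)
    dtime <- sqrt(colMeans((L - Lp)^2))
    fm <- atan2(dtime, dfreq)
  } else if (nf > 1) {
    dtime <- c(NA_real_, sqrt(colMeans((L[, -1, drop = FALSE] -
                                          L[, -nf, drop = FALSE])^2)))
    fm <- atan2(dtime, dfreq)
  }
  fm[bzero] <- NA_real_

  # pitch from the raw window's normalized autocorrelation
  pitch_hz <- rep(NA_real_, nf)
  goodness <- rep(NA_real_, nf)
  if (!is.null(frames)) {
    pg <- .pitch_acf(frames, fs, pitch_band)
    ok <- !silent & !bzero & !is.na(pg$pitch_hz)
    pitch_hz[ok] <- pg$pitch_hz[ok]
    goodness[ok] <- pg$goodness[ok]
  }
  list(amplitude_db = amplitude_db, mean_freq_hz = mean_freq_hz,
       wiener_entropy = we, fm = fm, pitch_hz = pitch_hz,
       goodness = goodness)
}

# pitch per frame: first local maximum of the normalized autocorrelation
# within the lag band that reaches `rel` of the global in-band maximum and
# at least `min_peak`; parabolic interpolation refines the lag.
.pitch_acf <- function(frames, fs, pitch_band, min_peak = 0.3, rel = 0.85) {
  win <- nrow(frames)
  nf <- ncol(frames)
  lag_lo <- max(2L, round(fs / pitch_band[2]))
  lag_hi <- min(win - 2L, round(fs / pitch_band[1]))
  out <- list(pitch_hz = rep(NA_real_, nf), goodness = rep(NA_real_, nf))
  if (lag_hi <= lag_lo) return(out)
  lags <- (lag_lo - 1L):(lag_hi + 1L)   # pad one lag each side for peaks
  A <- matrix(NA_real_, length(lags), nf)
  for (i in seq_along(lags)) {
    L <- lags[i]
    a <- frames[1:(win - L), , drop = FALSE]
    b <- frames[(1 + L):win, , drop = FALSE]
    den <- sqrt(colSums(a^2) * colSums(b^2))
    A[i, ] <- ifelse(den > 0, colSums(a * b) / den, NA_real_)
  }
  nl <- nrow(A)
  core <- 2:(nl - 1)
  locmax <- A[core, , drop = FALSE] >= A[core - 1, , drop = FALSE] &
    A[core, , drop = FALSE] > A[core + 1, , drop = FALSE]
  gmax <- suppressWarnings(apply(A[core, , drop = FALSE], 2, max,
                                 na.rm = TRUE))
  thr <- pmax(rel * gmax, min_peak)
  cand <- locmax & sweep(A[core, , drop = FALSE], 2, thr, ">=")
  cand[is.na(cand)] <- FALSE
  has <- colSums(cand) > 0
  if (!any(has)) return(out)
  first <- max.col(t(cand), ties.method = "first")   # first TRUE per column
  j <- which(has)
  i0 <- first[j] + 1L   # index into lags
  cm <- A[cbind(i0 - 1L, j)]
  c0 <- A[cbind(i0, j)]
  cp <- A[cbind(i0 + 1L, j)]
  den <- cm - 2 * c0 + cp
  shift <- ifelse(is.finite(den) & abs(den) > 1e-30,
                  pmax(-0.5, pmin(0.5, 0.5 * (cm - cp) / den)), 0)
  lag_f <- lags[i0] + shift
  out$pitch_hz[j] <- fs / lag_f
  out$goodness[j] <- pmin(1, pmax(0, c0))
  out
}

#' Frame-wise acoustic features of a waveform
#'
#' Slides a short multitaper analysis window along the signal (5-ms window,
#' 1-ms hop by default, i.e. a 1-kHz feature update rate) and computes the
#' features of [frame_features()] for every frame. Frame time `t_ms` is the
#' end of the analysis window.
#'
#' @param x Waveform (numeric, `[-1, 1]` nominal full scale).
#' @param fs Sample rate (Hz).
#' @param window_ms,hop_ms Analysis window length and hop (ms).
#' @param n_tapers,nw,nfft Multitaper parameters, see
#'   [multitaper_spectrum()]; by default the FFT length scales with the
#'   sample rate (512 points at 44.1 kHz, 256 at 22.05 kHz) so the
#'   frequency bin width is rate-independent.
#' @inheritParams frame_features
#' @return A `data.frame` with `t_ms` plus the [frame_features()] columns;
#'   `t_ms` is strictly increasing.
#' @export
song_features <- function(x, fs, window_ms = 5, hop_ms = 1, n_tapers = 2,
                          nw = 4, nfft = NULL, band = c(500, 10000),
                          pitch_band = c(400, 6000), entropy_floor = -25,
                          amp_floor_db = -120) {
  win <- max(2L, round(window_ms * fs / 1000))
  hop <- max(1L, round(hop_ms * fs / 1000))
  if (is.null(nfft)) nfft <- max(64L, 2^round(log2(512 * fs / 44100)))
  if (length(x) < win) {
    return(data.frame(t_ms = numeric(0), amplitude_db = numeric(0),
                      mean_freq_hz = numeric(0), wiener_entropy = numeric(0),
                      fm = numeric(0), pitch_hz = numeric(0),
                      goodness = numeric(0)))
  }
  if (win > nfft) nfft <- 2^ceiling(log2(win))
  starts <- seq(1L, length(x) - win + 1L, by = hop)
  H <- dpss_tapers(win, n_tapers, nw)
  nb <- nfft %/% 2 + 1
  freq <- (0:(nb - 1)) * fs / nfft
  chunk <- 4096L
  res <- vector("list", ceiling(length(starts) / chunk))
  prev_last <- NULL
  for (ci in seq_along(res)) {
    sel <- starts[((ci - 1L) * chunk + 1L):min(ci * chunk, length(starts))]
    frames <- matrix(x[outer(0:(win - 1L), sel, "+")], nrow = win)
    P <- .mt_power(frames, H, nfft)
    Pwithprev <- if (is.null(prev_last)) P else cbind(prev_last, P)
    Fwithprev <- if (is.null(prev_last)) frames else
      cbind(NA_real_ * frames[, 1], frames)
    f <- .frame_features_mat(Pwithprev, freq, fs, nfft, NULL, band,
                             pitch_band, entropy_floor, amp_floor_db,
                             frames = Fwithprev)
    keep <- if (is.null(prev_last)) seq_len(ncol(P)) else 1L + seq_len(ncol(P))
    res[[ci]] <- cbind(t_ms = (sel + win - 1L) / fs * 1000,
                       amplitude_db = f$amplitude_db[keep],
                       mean_freq_hz = f$mean_freq_hz[keep],
                       wiener_entropy = f$wiener_entropy[keep],
                       fm = f$fm[keep],
                       pitch_hz = f$pitch_hz[keep],
                       goodness = f$goodness[keep])
    prev_last <- P[, ncol(P), drop = FALSE]
  }
  out <- as.data.frame(do.call(rbind, res))
  rownames(out) <- NULL
  out
}

#' Estimate the baseline noise floor of a feature stream
#'
#' Median amplitude of the lowest-amplitude decile of frames, intended to be
#' applied to a leading calibration segment containing background noise.
#'
#' @param frames Feature frame `data.frame` from [song_features()].
#' @return Noise floor estimate in dB.
#' @export
estimate_noise_floor <- function(frames) {
  a <- frames$amplitude_db
  if (length(a) == 0) stop("empty frame stream")
  dec <- quantile(a, 0.1, names = FALSE, type = 7)
  median(a[a <= dec])
}

#' Detect sound events by amplitude thresholding
#'
#' A sound event is a maximal run of contiguous frames whose amplitude
#' exceeds the detection threshold (10 times the baseline noise amplitude,
#' i.e. `noise_floor_db + 20` dB, by default). Events still above threshold
#' at the end of the stream are closed there.
#'
#' @param frames Feature frames from [song_features()].
#' @param noise_floor_db Baseline noise floor (dB); see
#'   [estimate_noise_floor()].
#' @param threshold_db Detection threshold (dB); default
#'   `noise_floor_db + 20`.
#' @param min_dur_ms Minimum event duration to keep (ms).
#' @return A `data.frame` with one row per event: `onset_ms`, `offset_ms`
#'   (half-open interval), `first_frame`, `last_frame` (row indices into
#'   `frames`), `n_frames`, `duration_ms`.
#' @export
detect_sound_events <- function(frames, noise_floor_db = NULL,
                                threshold_db = NULL, min_dur_ms = 0) {
  empty <- data.frame(onset_ms = numeric(0), offset_ms = numeric(0),
                      first_frame = integer(0), last_frame = integer(0),
                      n_frames = integer(0), duration_ms = numeric(0))
  if (nrow(frames) == 0) return(empty)
  if (is.null(threshold_db)) {
    if (is.null(noise_floor_db)) noise_floor_db <- estimate_noise_floor(frames)
    threshold_db <- noise_floor_db + 20
  }
  above <- frames$amplitude_db > threshold_db
  if (!any(above)) return(empty)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  i1 <- starts[keep]
  i2 <- ends[keep]
  hop <- if (nrow(frames) > 1) median(diff(frames$t_ms)) else 1
  out <- data.frame(onset_ms = frames$t_ms[i1] - hop,
                    offset_ms = frames$t_ms[i2],
                    first_frame = i1, last_frame = i2,
                    n_frames = i2 - i1 + 1L)
  out$duration_ms <- out$offset_ms - out$onset_ms
  out <- out[out$duration_ms >= min_dur_ms, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarize spectral features over one sound event
#'
#' Mean and variance (population variance, so a single-frame event has
#' variance 0) of amplitude, mean frequency, Wiener entropy, FM, and pitch
#' over the member frames of an event, plus its duration. Frames with
#' undefined pitch are excluded from the pitch statistics.
#'
#' @param frames Feature frames from [song_features()].
#' @param event One row of the [detect_sound_events()] table.
#' @return One-row `data.frame` with 11 columns: `*_mean`, `*_var` for the 5
#'   features plus `duration_ms`.
#' @export
summarize_event <- function(frames, event) {
  idx <- event$first_frame:event$last_frame
  if (length(idx) < 1) stop("event must contain at least one frame")
  f <- frames[idx, , drop = FALSE]
  pv <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0) return(c(NA_real_, NA_real_))
    c(mean(x), mean((x - mean(x))^2))
  }
  a <- pv(f$amplitude_db); m <- pv(f$mean_freq_hz); e <- pv(f$wiener_entropy)
  fm <- pv(f$fm); p <- pv(f$pitch_hz)
  data.frame(amplitude_mean = a[1], amplitude_var = a[2],
             mean_freq_mean = m[1], mean_freq_var = m[2],
             entropy_mean = e[1], entropy_var = e[2],
             fm_mean = fm[1], fm_var = fm[2],
             pitch_mean = p[1], pitch_var = p[2],
             duration_ms = event$duration_ms)
}

#' Summarize all detected events of a stream
#'
#' @inheritParams summarize_event
#' @param events Event table from [detect_sound_events()].
#' @return `data.frame`, one row per event, the [summarize_event()] columns
#'   plus `onset_ms` and `offset_ms`.
#' @export
summarize_events <- function(frames, events) {
  if (nrow(events) == 0) {
    s <- summarize_event(data.frame(amplitude_db = 0, mean_freq_hz = 0,
                                    wiener_entropy = 0, fm = 0, pitch_hz = 0),
                         data.frame(first_frame = 1, last_frame = 1,
                                    duration_ms = 0))
    return(cbind(onset_ms = numeric(0), offset_ms = numeric(0), s[0, ]))
  }
  out <- do.call(rbind, lapply(seq_len(nrow(events)), function(i)
    summarize_event(frames, events[i, ])))
  cbind(onset_ms = events$onset_ms, offset_ms = events$offset_ms, out)
}
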