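#' Remove spikes from a Vm trace by sliding median filtering
#'
#' Sliding median with a 5-ms window (the window shrinks symmetrically at
#' the trace edges). Output has the same length as the input; constant
#' segments pass through unchanged and single-sample spikes are removed.
#'
#' @param vm Numeric Vm vector (mV), or a `membrane_trace`.
#' @param fs Sample rate (Hz); ignored for a `membrane_trace`.
#' @param window_ms Filter window (ms); must map to >= 3 samples.
#' @return Filtered numeric vector.
#' @export
despike <- function(vm, fs = NULL, window_ms = 5) {
  if (inherits(vm, "membrane_trace")) {
    fs <- vm$fs
    vm <- vm$vm_mv
  }
  stopifnot(!is.null(fs))
  k <- round(window_ms * fs / 1000)
  if (k %% 2 == 0) k <- k + 1L
  if (k < 3) stop("window too short: must span at least 3 samples")
  n <- length(vm)
  if (n < k) return(vapply(seq_len(n), function(i)
    median(vm[max(1, i - k %/% 2):min(n, i + k %/% 2)]), 0))
  y <- runmed(vm, k, endrule = "keep")
  h <- k %/% 2
  for (i in seq_len(h)) {
    y[i] <- median(vm[1:(i + h)])
    y[n - i + 1L] <- median(vm[(n - i + 1L - h):n])
  }
  as.numeric(y)
}

#' Detect action potentials in a Vm trace
#'
#' Spikes are fast, large positive deflections: the trace is high-pass
#' filtered above `hp_cutoff_hz` (4th-order Butterworth, zero-phase) and a
#' spike is registered for every contiguous excursion of the fast
#' component above `threshold_mv`, timed at the excursion's peak. The
#' `"complement"` method implements the alternative reading of the same
#' criterion -- the deviation of the raw trace from its low-passed version
#' exceeding the threshold -- which differs only in the filter's complement
#' band.
#'
#' @param vm Vm vector (mV) or `membrane_trace`.
#' @param fs Sample rate (Hz); must exceed twice the cutoff.
#' @param hp_cutoff_hz High-pass cutoff (Hz).
#' @param threshold_mv Detection threshold on the fast component (mV).
#' @param method `"highpass"` or `"complement"` (see above).
#' @return Sorted spike times (ms).
#' @export
detect_spikes <- function(vm, fs = NULL, hp_cutoff_hz = 400,
                          threshold_mv = 30,
                          method = c("highpass", "complement")) {
  method <- match.arg(method)
  if (inherits(vm, "membrane_trace")) {
    fs <- vm$fs
    vm <- vm$vm_mv
  }
  stopifnot(!is.null(fs))
  if (fs <= 2 * hp_cutoff_hz)
    stop("sample rate must exceed twice the high-pass cutoff")
  fast <- if (method == "highpass") {
    bf <- signal::butter(4, hp_cutoff_hz / (fs / 2), type = "high")
    signal::filtfilt(bf, vm)
  } else {
    bf <- signal::butter(4, hp_cutoff_hz / (fs / 2), type = "low")
    vm - signal::filtfilt(bf, vm)
  }
  above <- fast > threshold_mv
  if (!any(above)) return(numeric(0))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  idx <- vapply(which(r$values), function(k) {
    seg <- starts[k]:ends[k]
    seg[which.max(fast[seg])]
  }, 0L)
  sort((idx - 1L) / fs * 1000)
}

#' Firing-rate and Vm statistics before and during singing
#'
#' For each song bout (up to the first `max_bouts`), compares a 0.5-s
#' pre-song window (-1 to -0.5 s before bout onset) with a 0.5-s singing
#' window (0 to 0.5 s after onset); the transition period (-0.5 to 0 s) is
#' excluded from both. Rates come from [detect_spikes()] on the raw trace;
#' Vm means from the despiked trace. Bouts without 1 s of preceding data
#' are skipped.
#'
#' @param trace A `membrane_trace`, or a numeric Vm vector (then give
#'   `fs` and `bout_onsets_ms`).
#' @param fs,bout_onsets_ms Used when `trace` is a plain vector.
#' @param max_bouts Maximum number of bouts used.
#' @return List with `rate_pre_hz`, `rate_sing_hz`, `vm_pre_mv`,
#'   `vm_sing_mv`, `n_bouts_used`.
#' @export
singing_state_stats <- function(trace, fs = NULL, bout_onsets_ms = NULL,
                                max_bouts = 50) {
  if (inherits(trace, "membrane_trace")) {
    fs <- trace$fs
    bout_onsets_ms <- trace$anchors$bout_onsets_ms
    vm <- trace$vm_mv
  } else vm <- trace
  stopifnot(!is.null(fs), !is.null(bout_onsets_ms))
  if (!length(bout_onsets_ms)) stop("at least one bout onset is required")
  bouts <- head(sort(bout_onsets_ms), max_bouts)
  bouts <- bouts[bouts >= 1000]
  if (!length(bouts)) stop("no bout has 1 s of preceding data")
  spikes <- detect_spikes(vm, fs)
  dsp <- despike(vm, fs)
  dur_ms <- length(vm) / fs * 1000
  win_stats <- function(b, rel) {
    lo <- b + rel[1]; hi <- b + rel[2]
    if (lo < 0 || hi > dur_ms) return(c(NA, NA))
    i <- (round(lo * fs / 1000) + 1L):min(length(vm), round(hi * fs / 1000))
    c(sum(spikes >= lo & spikes < hi) / ((rel[2] - rel[1]) / 1000),
      mean(dsp[i]))
  }
  pre <- vapply(bouts, win_stats, c(0, 0), rel = c(-1000, -500))
  sing <- vapply(bouts, win_stats, c(0, 0), rel = c(0, 500))
  ok <- !is.na(pre[1, ]) & !is.na(sing[1, ])
  list(rate_pre_hz = mean(pre[1, ok]), rate_sing_hz = mean(sing[1, ok]),
       vm_pre_mv = mean(pre[2, ok]), vm_sing_mv = mean(sing[2, ok]),
       n_bouts_used = sum(ok))
}

#' Hit-minus-catch baseline-subtracted membrane-potential difference
#'
#' For DAF-aligned trial matrices, computes per trial the baseline (mean
#' Vm over the `baseline_ms` pre-DAF window) and the trial-averaged
#' baseline-subtracted difference
#' `delta(t) = mean_hits(Vm_i(t) - baseline_i) - mean_catch(Vm_j(t) -
#' baseline_j)`. Per-trial means over the fast (20-60 ms) and slow
#' (60-200 ms) post-DAF windows are compared between conditions with
#' two-sample Welch t-tests; `min_p` is the smaller of the two window
#' p-values. Trials may first be split into similar-baseline voltage
#' groups (`group_bin_mv`); any group with fewer than `min_motifs` total
#' trials is excluded (with the reason recorded).
#'
#' @param hit,catch Matrices (trials x samples) on a common DAF-relative
#'   time grid, e.g. from [align_trials()]; rows are despiked trials.
#' @param t_ms Column times (ms, relative to DAF onset); defaults to the
#'   matrices' `t_ms` attribute.
#' @param baseline_ms,fast_ms,slow_ms Half-open analysis windows (ms).
#' @param group_bin_mv Optional width of baseline-voltage grouping bins
#'   (mV); `NULL` analyzes all trials as one group.
#' @param min_motifs Minimum total trials (hit + catch) per group.
#' @return For a single group, an object of class `delta_vm` with
#'   elements `delta`, `t_ms`, `M`, `N`, `baseline_hit`, `baseline_catch`,
#'   `windows` (per-window stats and p-values) and `min_p`. With grouping,
#'   a list of class `delta_vm_groups` with one `delta_vm` per retained
#'   group plus an `excluded` table.
#' @export
delta_vm <- function(hit, catch, t_ms = NULL, baseline_ms = c(-200, 0),
                     fast_ms = c(20, 60), slow_ms = c(60, 200),
                     group_bin_mv = NULL, min_motifs = 14) {
  if (is.null(t_ms)) t_ms <- attr(hit, "t_ms")
  if (is.null(t_ms)) stop("t_ms must be supplied (or attached to `hit`)")
  stopifnot(ncol(hit) == length(t_ms), ncol(catch) == length(t_ms))
  bsel <- t_ms >= baseline_ms[1] & t_ms < baseline_ms[2]
  if (!any(bsel)) stop("baseline window contains no samples")
  base_h <- rowMeans(hit[, bsel, drop = FALSE])
  base_c <- rowMeans(catch[, bsel, drop = FALSE])

  if (!is.null(group_bin_mv)) {
    gb_h <- floor(base_h / group_bin_mv)
    gb_c <- floor(base_c / group_bin_mv)
    groups <- sort(unique(c(gb_h, gb_c)))
    res <- list()
    excluded <- data.frame(group_mv = numeric(0), n_hit = integer(0),
                           n_catch = integer(0), reason = character(0))
    for (g in groups) {
      hi <- gb_h == g; ci <- gb_c == g
      if (sum(hi) + sum(ci) < min_motifs || sum(hi) < 1 || sum(ci) < 1) {
        excluded <- rbind(excluded, data.frame(
          group_mv = g * group_bin_mv, n_hit = sum(hi), n_catch = sum(ci),
          reason = sprintf("fewer than %d motifs (or empty condition)",
                           min_motifs)))
        next
      }
      res[[as.character(g * group_bin_mv)]] <-
        delta_vm(hit[hi, , drop = FALSE], catch[ci, , drop = FALSE],
                 t_ms = t_ms, baseline_ms = baseline_ms, fast_ms = fast_ms,
                 slow_ms = slow_ms, min_motifs = min_motifs)
    }
    return(structure(list(groups = res, excluded = excluded,
                          group_bin_mv = group_bin_mv),
                     class = "delta_vm_groups"))
  }

  if (nrow(hit) + nrow(catch) < min_motifs)
    stop(sprintf("fewer than %d motifs in total", min_motifs))
  hb <- hit - base_h
  cb <- catch - base_c
  delta <- colMeans(hb) - colMeans(cb)
  win_test <- function(w, name) {
    sel <- t_ms >= w[1] & t_ms < w[2]
    th <- rowMeans(hb[, sel, drop = FALSE])
    tc <- rowMeans(cb[, sel, drop = FALSE])
    p <- if (isTRUE(all.equal(var(th) + var(tc), 0)) ||
             var(th) + var(tc) == 0) {
      if (isTRUE(all.equal(mean(th), mean(tc)))) 1 else 0
    } else if (length(th) == length(tc) && isTRUE(all.equal(sort(th),
                                                            sort(tc)))) {
      1   # identical trial sets: no difference by symmetry
    } else {
      t.test(th, tc)$p.value
    }
    data.frame(window = name, lo_ms = w[1], hi_ms = w[2],
               hit_mean = mean(th), catch_mean = mean(tc),
               diff = mean(th) - mean(tc), p_value = p)
  }
  windows <- rbind(win_test(fast_ms, "fast"), win_test(slow_ms, "slow"))
  structure(list(delta = delta, t_ms = t_ms, M = nrow(hit), N = nrow(catch),
                 baseline_hit = base_h, baseline_catch = base_c,
                 windows = windows, min_p = min(windows$p_value)),
            class = "delta_vm")
}

#' @export
print.delta_vm <- function(x, ...) {
  cat(sprintf("Hit-minus-catch ΔVm: %d hit / %d catch trials\n",
              x$M, x$N))
  print(x$windows, row.names = FALSE, digits = 3)
  cat(sprintf("min p across windows: %.3g\n", x$min_p))
  invisible(x)
}

#' @export
print.delta_vm_groups <- function(x, ...) {
  cat(sprintf("ΔVm by %g-mV baseline voltage group: %d group(s), %d excluded\n",
              x$group_bin_mv, length(x$groups), nrow(x$excluded)))
  for (nm in names(x$groups)) {
    cat("-- group near", nm, "mV --\n")
    print(x$groups[[nm]])
  }
  invisible(x)
}

#' @export
plot.delta_vm <- function(x, ...) {
  plot(x$t_ms, x$delta, type = "l", xlab = "time from DAF onset (ms)",
       ylab = expression(Delta * V[m] ~ "(mV)"), ...)
  abline(h = 0, lty = 3)
  abline(v = c(20, 60, 200), lty = 2, col = "grey60")
  invisible(x)
}
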