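#' Detect depolarizing-PSP onsets by a dV/dt threshold
#'
#' On a despiked Vm segment, computes the forward-difference slope
#' `dV/dt = (V(t + dt) - V(t)) / dt` and marks an onset at every upward
#' crossing of a threshold set at `c_sd` times the SD of `dV/dt` over the
#' segment. Onsets closer than `refractory_ms` to the previous accepted
#' onset are suppressed. The threshold is deliberately high, so only
#' sharp-rising dPSPs are detected; a zero-variance segment yields no
#' onsets. Before differencing, the trace is locally averaged over
#' `smooth_ms` (half the difference interval by default): the slope is
#' then a difference of local means, which suppresses sample noise without
#' blurring rises on the `dt` scale.
#'
#' @param vm Despiked Vm segment (mV).
#' @param fs Sample rate (Hz).
#' @param dt_ms Forward-difference interval (ms).
#' @param c_sd Threshold in units of the slope SD (conventionally within
#'   0.8-1.5).
#' @param refractory_ms Minimum inter-onset interval (ms).
#' @param smooth_ms Local-mean window applied before differencing (ms).
#' @return Onset times (ms, relative to segment start), sorted. A crossing
#'   of the difference window `[t, t + dt]` is attributed to the window
#'   end `t + dt`, the first instant at which the rising flank is inside
#'   the window.
#' @export
detect_dpsp_onsets <- function(vm, fs, dt_ms = 4, c_sd = 1.5,
                               refractory_ms = 5, smooth_ms = dt_ms / 2) {
  shift <- max(1L, round(dt_ms * fs / 1000))
  if (length(vm) <= shift)
    stop("segment must be longer than the dV/dt interval")
  k <- max(1L, round(smooth_ms * fs / 1000))
  if (k > 1) {
    if (k %% 2 == 0) k <- k + 1L
    pad <- k %/% 2
    vm <- as.numeric(stats::filter(c(rep(vm[1], pad), vm,
                                     rep(vm[length(vm)], pad)),
                                   rep(1 / k, k), sides = 2))
    vm <- vm[(pad + 1):(length(vm) - pad)]
  }
  n <- length(vm) - shift
  dvdt <- (vm[(1 + shift):length(vm)] - vm[1:n]) / (shift / fs * 1000)
  s <- sd(dvdt)
  if (!is.finite(s) || s == 0) return(numeric(0))
  thr <- c_sd * s
  up <- which(dvdt[-1] > thr & dvdt[-n] <= thr) + 1L
  if (dvdt[1] > thr) up <- c(1L, up)
  if (!length(up)) return(numeric(0))
  times <- (up - 1L + shift) / fs * 1000
  keep <- times[1]
  for (t in times[-1]) if (t - keep[length(keep)] >= refractory_ms)
    keep <- c(keep, t)
  keep
}

#' Cluster stereotyped dPSP onsets across trials
#'
#' Because song and its underlying synaptic drive are stereotyped, dPSP
#' onsets recur at similar latencies across trials and form clusters in
#' the onset raster. Onsets within `range_ms` (relative to the alignment
#' anchor, conventionally 20-200 ms after DAF onset) are clustered by
#' k-means on onset time; cluster centers are reported sorted. When a
#' `condition` vector is given, member onset times are compared between
#' hit and catch with a two-sample t-test per cluster.
#'
#' @param onset_ms dPSP onset times (ms, anchor-relative).
#' @param k Number of clusters (chosen by inspecting the onset histogram;
#'   must not exceed the number of distinct onsets in range).
#' @param range_ms Analysis range (ms).
#' @param seed Integer seed for the k-means initialization.
#' @param condition Optional per-onset condition labels
#'   (`"hit"`/`"catch"`).
#' @param trial Optional per-onset trial ids (carried through).
#' @return Object of class `dpsp_clusters`: `centers` (sorted),
#'   `assignments` (`data.frame` of in-range onsets with `cluster`), and
#'   `comparison` (per-cluster hit/catch test, `NA` rows when a condition
#'   is missing).
#' @export
cluster_dpsp_onsets <- function(onset_ms, k, range_ms = c(20, 200), seed = 1,
                                condition = NULL, trial = NULL) {
  stopifnot(k >= 1)
  keep <- onset_ms >= range_ms[1] & onset_ms <= range_ms[2]
  x <- onset_ms[keep]
  if (k > length(x))
    stop("k exceeds the number of onsets in the analysis range")
  cond <- if (!is.null(condition)) condition[keep] else NULL
  tri <- if (!is.null(trial)) trial[keep] else NULL
  set.seed(seed)
  km <- if (length(unique(x)) <= k) {
    centers <- sort(unique(x))
    list(centers = matrix(centers), cluster = match(x, centers))
  } else {
    kmeans(x, centers = k, nstart = 20, iter.max = 100)
  }
  ord <- order(km$centers[, 1])
  relabel <- match(seq_len(nrow(km$centers)), ord)
  cl <- relabel[km$cluster]
  centers <- km$centers[ord, 1]
  assignments <- data.frame(onset_ms = x, cluster = cl)
  if (!is.null(cond)) assignments$condition <- cond
  if (!is.null(tri)) assignments$trial <- tri
  comparison <- do.call(rbind, lapply(seq_along(centers), function(j) {
    sel <- cl == j
    row <- data.frame(cluster = j, center_ms = centers[j], n = sum(sel),
                      n_hit = NA_integer_, n_catch = NA_integer_,
                      hit_mean_ms = NA_real_, catch_mean_ms = NA_real_,
                      p_value = NA_real_)
    if (!is.null(cond)) {
      h <- x[sel & cond == "hit"]
      c_ <- x[sel & cond == "catch"]
      row$n_hit <- length(h); row$n_catch <- length(c_)
      row$hit_mean_ms <- mean(h); row$catch_mean_ms <- mean(c_)
      if (length(h) > 1 && length(c_) > 1 && (var(h) + var(c_)) > 0)
        row$p_value <- t.test(h, c_)$p.value
      else if (length(h) >= 1 && length(c_) >= 1)
        row$p_value <- if (isTRUE(all.equal(mean(h), mean(c_)))) 1 else NA
    }
    row
  }))
  structure(list(centers = centers, assignments = assignments,
                 comparison = comparison, k = length(centers),
                 range_ms = range_ms),
            class = "dpsp_clusters")
}

#' @export
print.dpsp_clusters <- function(x, ...) {
  cat(sprintf("dPSP onset clusters (k = %d, range %g-%g ms):\n",
              x$k, x$range_ms[1], x$range_ms[2]))
  print(x$comparison, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Event-triggered dPSP onset rate (cross-correlogram)
#'
#' Histogram of dPSP onset times relative to anchor events (syllable
#' onsets or offsets), normalized to a rate: counts divided by the number
#' of anchors times the bin width. A synaptic drive leading the vocal
#' output by `L` ms appears as a correlogram peak at lag `-L`.
#'
#' @param onset_ms dPSP onset times (ms, absolute).
#' @param anchor_ms Anchor times (ms, absolute); an empty vector gives an
#'   empty result.
#' @param lag_range_ms Length-2 lag range (ms).
#' @param bin_ms Bin width (ms).
#' @return `data.frame` with `lag_lo_ms`, `lag_hi_ms`, `lag_mid_ms`,
#'   `count`, `rate_hz` (events/s per anchor).
#' @export
syllable_triggered_dpsp_rate <- function(onset_ms, anchor_ms,
                                         lag_range_ms = c(-100, 100),
                                         bin_ms = 5) {
  breaks <- seq(lag_range_ms[1], lag_range_ms[2], by = bin_ms)
  out <- data.frame(lag_lo_ms = breaks[-length(breaks)],
                    lag_hi_ms = breaks[-1])
  out$lag_mid_ms <- (out$lag_lo_ms + out$lag_hi_ms) / 2
  if (!length(anchor_ms)) return(out[0, ])
  if (length(onset_ms)) {
    lags <- as.vector(outer(onset_ms, anchor_ms, "-"))
    lags <- lags[lags >= lag_range_ms[1] & lags < lag_range_ms[2]]
    out$count <- tabulate(findInterval(lags, breaks), nrow(out))
  } else out$count <- 0L
  out$rate_hz <- out$count / (length(anchor_ms) * bin_ms / 1000)
  out
}
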