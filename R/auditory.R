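#' Response index of a response/baseline measurement pair
#'
#' `|r_response - r_base| / |r_response + r_base|`. For non-negative
#' measures (firing rates, SDs) the index lies in `[0, 1]`, equals 0 when
#' response and baseline agree and 1 when the baseline is 0.
#'
#' @param r_response,r_base Mean or SD of the measured variable during the
#'   response and baseline periods.
#' @return Numeric index.
#' @export
response_index <- function(r_response, r_base) {
  den <- abs(r_response + r_base)
  if (den == 0) return(NA_real_)
  abs(r_response - r_base) / den
}

#' Two-stage significance test of a playback-evoked response
#'
#' Quantifies whether a neuron responds to sound playback in a non-singing
#' state, from per-trial summaries (e.g. mean subthreshold Vm, or firing
#' rate) in a stimulus window and an equal-length pre-stimulus baseline
#' window. The response is first tested for a difference in median
#' (Mann-Whitney U-test); only when that test is not significant is a
#' difference in variance tested (Ansari-Bradley test). A cell is
#' `responsive` when either applicable test falls below `alpha` (0.025 by
#' default). The response index is computed from the statistic that drove
#' significance (means for the median test, SDs for the variance test).
#'
#' @param response,baseline Per-trial measurements (same length; >= 7
#'   trials after exclusions).
#' @param alpha Significance threshold applied to both tests.
#' @param exclude Optional logical vector flagging trials to drop (e.g.
#'   when the bird vocalized during playback).
#' @param measure Label of the measured variable (metadata).
#' @param state `"day"` or `"night"` recording state (metadata).
#' @param min_trials Minimum trial count.
#' @return Object of class `playback_response`: `responsive`, `test_used`
#'   (`"median"`, `"variance"`, or `"none"`), `p_median`, `p_variance`
#'   (`NA` when not evaluated -- the variance test is never run once the
#'   median test is significant), `response_index`, `index_basis`,
#'   `n_trials`, `measure`, `state`.
#' @export
assess_playback_response <- function(response, baseline, alpha = 0.025,
                                     exclude = NULL, measure = "vm",
                                     state = c("day", "night"),
                                     min_trials = 7) {
  state <- match.arg(state)
  stopifnot(length(response) == length(baseline))
  if (!is.null(exclude)) {
    stopifnot(length(exclude) == length(response))
    response <- response[!exclude]
    baseline <- baseline[!exclude]
  }
  n <- length(response)
  if (n < min_trials)
    stop(sprintf("at least %d trials are required (%d supplied)",
                 min_trials, n))
  p_med <- suppressWarnings(wilcox.test(response, baseline)$p.value)
  p_var <- NA_real_
  if (p_med < alpha) {
    test_used <- "median"
    responsive <- TRUE
    idx <- response_index(mean(response), mean(baseline))
    basis <- "mean"
  } else {
    p_var <- suppressWarnings(ansari.test(response, baseline)$p.value)
    if (p_var < alpha) {
      test_used <- "variance"
      responsive <- TRUE
      idx <- response_index(sd(response), sd(baseline))
      basis <- "sd"
    } else {
      test_used <- "none"
      responsive <- FALSE
      idx <- NA_real_
      basis <- NA_character_
    }
  }
  structure(list(responsive = responsive, test_used = test_used,
                 p_median = p_med, p_variance = p_var,
                 response_index = idx, index_basis = basis,
                 n_trials = n, measure = measure, state = state,
                 alpha = alpha),
            class = "playback_response")
}

#' @export
print.playback_response <- function(x, ...) {
  cat(sprintf("Playback response (%s, %s, %d trials): %s\n",
              x$measure, x$state, x$n_trials,
              if (x$responsive) paste0("responsive via ", x$test_used,
                                       " test")
              else "not responsive"))
  cat(sprintf("  p(median) = %.4g", x$p_median))
  if (!is.na(x$p_variance)) cat(sprintf(", p(variance) = %.4g", x$p_variance))
  cat("\n")
  if (!is.na(x$response_index))
    cat(sprintf("  response index (%s-based) = %.3f\n", x$index_basis,
                x$response_index))
  invisible(x)
}

#' Correlation between singing-related and playback-evoked Vm
#'
#' Pearson correlation coefficient of a cell's trial-averaged
#' membrane-potential trace during singing and during playback of the same
#' motif, both on a common motif-aligned time grid (no time warping).
#' Quantifies auditory-vocal "mirroring".
#'
#' @param singing_vm,playback_vm Averaged Vm traces on the same grid.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
singing_hearing_cc <- function(singing_vm, playback_vm) {
  if (length(singing_vm) != length(playback_vm))
    stop("traces must share a common motif-aligned grid")
  cor(singing_vm, playback_vm)
}
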