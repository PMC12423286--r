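#' Label trial outcomes from response time and target duration
#'
#' Applies the task's scoring rule on the wait clock (ms since cue offset):
#' \itemize{
#'   \item `correct` — response in `[0.8 d, 2 d]` (from 20 % before the target
#'     time up to the end of the response window);
#'   \item `early_error` — response at or after the shortest duration's
#'     earliest-correct time (1200 ms by default) but before the cued
#'     duration's own earliest-correct time (defined for the longer
#'     durations);
#'   \item `late_error` — no response within the response window (`NA` or
#'     response > `2 d`);
#'   \item `aborted` — response earlier than the early-error band (ready-period
#'     exits and opt-outs).
#' }
#'
#' @param response_ms Response time(s) on the wait clock (ms since cue
#'   offset); `NA` means no response.
#' @param duration Cued target duration(s), ms; recycled against
#'   `response_ms`.
#' @param task A [task_config()].
#' @return Character vector of outcomes.
#' @export
label_trial <- function(response_ms, duration, task = task_config()) {
  n <- max(length(response_ms), length(duration))
  response_ms <- rep_len(as.numeric(response_ms), n)
  duration <- rep_len(as.numeric(duration), n)
  if (any(!is.na(response_ms) & response_ms < 0)) {
    stop("negative response time")
  }
  if (!all(duration %in% task$durations)) {
    stop("duration not in the task's duration set")
  }
  thr <- task$correct_fraction_threshold
  floor_early <- thr * min(task$durations)   # 1200 ms by default
  out <- rep("aborted", n)
  out[is.na(response_ms) | response_ms > 2 * duration] <- "late_error"
  ok <- !is.na(response_ms)
  out[ok & response_ms >= thr * duration & response_ms <= 2 * duration] <-
    "correct"
  out[ok & duration > min(task$durations) &
        response_ms >= floor_early & response_ms < thr * duration] <-
    "early_error"
  out
}

#' Neuron inclusion filter
#'
#' A neuron is included iff it has at least `min_trials_per_cue` correct
#' trials for every cue (6 cues by default) and an average firing rate of at
#' least `min_rate_hz` over the combined pre-cue, cue, and first 1200 ms of
#' the wait period (a 2100 ms composite window), computed on correct trials.
#' Both boundaries are inclusive.
#'
#' @param session A `session_recording`.
#' @param neuron Neuron id.
#' @param min_trials_per_cue Minimum correct trials per cue (default 8).
#' @param min_rate_hz Minimum mean rate over the composite window (default
#'   0.5 Hz).
#' @return Logical scalar with attribute `reasons` (character vector of failed
#'   criteria, empty when included) and attribute `mean_rate_hz`.
#' @export
neuron_inclusion <- function(session, neuron, min_trials_per_cue = 8,
                             min_rate_hz = 0.5) {
  task <- session$task
  tr <- session$trials
  correct <- tr[tr$outcome == "correct", , drop = FALSE]
  counts <- table(factor(correct$cue,
                         levels = unique(paste(rep(task$protocols,
                                                   each = length(task$durations)),
                                               task$durations, sep = "_"))))
  reasons <- character(0)
  if (any(counts < min_trials_per_cue)) reasons <- c(reasons, "trials")

  # composite window: pre-cue + cue + first earliest-correct(shortest) of wait
  win_lo <- -task$pre_cue_ms
  win_hi <- task$cue_ms + task$correct_fraction_threshold * min(task$durations)
  sp <- session$spikes
  sp <- sp[sp$neuron == neuron & sp$trial %in% correct$trial, , drop = FALSE]
  n_in <- sum(sp$time_ms >= win_lo & sp$time_ms < win_hi)
  rate <- if (nrow(correct) == 0) 0 else
    n_in / (nrow(correct) * (win_hi - win_lo) / 1000)
  if (rate < min_rate_hz) reasons <- c(reasons, "rate")

  structure(length(reasons) == 0, reasons = reasons, mean_rate_hz = rate)
}

#' Extract event-aligned binned firing rates
#'
#' Counts spikes in half-open bins `[a, b)` tiling `window` around the
#' alignment event of each trial and converts to Hz. Response-aligned windows
#' end exactly at response time when `window = c(-L, 0)`.
#'
#' @param session A `session_recording`.
#' @param alignment `"cue_onset"`, `"cue_offset"`, or `"response_onset"`.
#' @param window Length-2 numeric, ms relative to the alignment event.
#' @param bin_width Bin width in ms; must divide the window length.
#' @param trials Trial ids to use (default: all correct trials).
#' @param neurons Neuron ids (default: all).
#' @return An object of class `aligned_rates`: list with `rate` (3-d array,
#'   trials x neurons x bins, Hz), `trials`, `neurons`, `bin_edges` (ms
#'   relative to the event), `alignment`.
#' @export
extract_window_rates <- function(session, alignment = c("cue_offset",
                                                        "response_onset",
                                                        "cue_onset"),
                                 window, bin_width,
                                 trials = NULL, neurons = NULL) {
  alignment <- match.arg(alignment)
  stopifnot(length(window) == 2, window[2] > window[1], bin_width > 0)
  len <- window[2] - window[1]
  if (abs(len / bin_width - round(len / bin_width)) > 1e-9) {
    stop("window length must be divisible by `bin_width`")
  }
  n_bins <- as.integer(round(len / bin_width))
  tr <- session$trials
  if (is.null(trials)) trials <- tr$trial[tr$outcome == "correct"]
  if (is.null(neurons)) neurons <- session$neurons$neuron
  tr <- tr[match(trials, tr$trial), , drop = FALSE]

  event <- switch(alignment,
                  cue_onset = rep(0, nrow(tr)),
                  cue_offset = tr$cue_off,
                  response_onset = tr$response)
  missing_ev <- is.na(event)
  if (any(missing_ev)) {
    warning(sum(missing_ev), " trial(s) lack the alignment event; skipped")
    trials <- trials[!missing_ev]; tr <- tr[!missing_ev, , drop = FALSE]
    event <- event[!missing_ev]
  }

  nt <- length(trials); nn <- length(neurons)
  sp <- session$spikes
  sp <- sp[sp$trial %in% trials & sp$neuron %in% neurons, , drop = FALSE]
  ti <- match(sp$trial, trials)
  rel <- sp$time_ms - event[ti]
  keep <- rel >= window[1] & rel < window[2]
  counts <- array(0L, dim = c(nt, nn, n_bins))
  if (any(keep)) {
    ti <- ti[keep]
    ni <- match(sp$neuron[keep], neurons)
    bi <- floor((rel[keep] - window[1]) / bin_width) + 1L
    lin <- ti + (ni - 1L) * nt + (bi - 1L) * nt * nn
    tab <- tabulate(lin, nbins = nt * nn * n_bins)
    counts[] <- tab
  }
  structure(list(
    rate = counts / (bin_width / 1000),
    trials = trials, neurons = neurons,
    bin_edges = seq(window[1], window[2], by = bin_width),
    alignment = alignment, window = window, bin_width = bin_width,
    meta = tr
  ), class = "aligned_rates")
}

#' Smooth or normalise a rate matrix
#'
#' Three methods used throughout the pipeline:
#' \describe{
#'   \item{`gaussian_kernel`}{convolves each row along time with a Gaussian of
#'     SD `width` ms; the kernel is renormalised to the in-window mass at the
#'     edges, so a constant input stays constant.}
#'   \item{`minmax`}{maps each row's minimum to 0 and maximum to 1; constant
#'     rows map to all zeros.}
#'   \item{`zscore_by_train`}{z-scores each column using the mean and SD of
#'     the `train_idx` rows only (the train-only contract that prevents test
#'     leakage); zero-variance columns map to 0.}
#' }
#'
#' @param x Numeric matrix. For `gaussian_kernel` and `minmax`, rows are units
#'   and columns time bins; for `zscore_by_train`, rows are observations and
#'   columns features.
#' @param method One of `"gaussian_kernel"`, `"minmax"`, `"zscore_by_train"`.
#' @param width Gaussian SD in ms (for `gaussian_kernel`).
#' @param bin_width Time-bin width in ms (for `gaussian_kernel`).
#' @param train_idx Row indices of the training set (for `zscore_by_train`).
#' @return Matrix of the same shape.
#' @export
smooth_and_scale <- function(x, method = c("gaussian_kernel", "minmax",
                                           "zscore_by_train"),
                             width = 200, bin_width = 20, train_idx = NULL) {
  method <- match.arg(method)
  x <- as.matrix(x)
  switch(method,
    gaussian_kernel = gauss_smooth_rows(x, width / bin_width),
    minmax = {
      t(apply(x, 1, function(v) {
        rng <- range(v)
        if (diff(rng) == 0) rep(0, length(v)) else (v - rng[1]) / diff(rng)
      }))
    },
    zscore_by_train = {
      if (is.null(train_idx) || length(train_idx) == 0) {
        stop("`zscore_by_train` requires non-empty `train_idx`")
      }
      mu <- colMeans(x[train_idx, , drop = FALSE])
      sdv <- apply(x[train_idx, , drop = FALSE], 2, stats::sd)
      z <- sweep(x, 2, mu)
      ok <- sdv > 0
      z[, ok] <- sweep(z[, ok, drop = FALSE], 2, sdv[ok], "/")
      z[, !ok] <- 0
      z
    })
}

# Gaussian smoothing along rows with edge renormalisation; sd in bins.
gauss_smooth_rows <- function(x, sd_bins) {
  if (sd_bins <= 0) return(x)
  half <- max(1L, ceiling(4 * sd_bins))
  k <- stats::dnorm(seq(-half, half), sd = sd_bins)
  n <- ncol(x)
  # build the (column x column) smoothing weights once; renormalise per column
  W <- matrix(0, n, n)
  for (j in seq_len(n)) {
    lo <- max(1L, j - half); hi <- min(n, j + half)
    w <- k[(lo - j + half + 1L):(hi - j + half + 1L)]
    W[lo:hi, j] <- w / sum(w)
  }
  x %*% W
}

# Gaussian-smooth a numeric vector (edge-renormalised); sd in bins.
gauss_smooth_vec <- function(v, sd_bins) {
  drop(gauss_smooth_rows(matrix(v, nrow = 1), sd_bins))
}
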