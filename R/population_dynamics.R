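#' Omega-squared percent-explained-variance time course
#'
#' Sliding-window (200 ms, 20 ms steps) two-way ANOVAs (target duration x
#' stimulus protocol) on every neuron's per-trial window rates, with the
#' effect size of each factor expressed as the bias-corrected
#' [omega_squared()] percentage. The population series is the mean omega^2
#' across neurons; the whole computation is repeated `n_resamples` times with
#' fresh balanced trial draws (`n_trials_per_cell` per duration x protocol
#' cell), giving a mean and SEM per window. The baseline repeats the
#' identical ANOVAs with shuffled trial labels, `n_shuffles_per_resample`
#' times per resample (20 x 50 = 1000 reshuffles at the defaults).
#'
#' @param session A `session_recording`.
#' @param neurons Neuron ids (default all); neurons lacking
#'   `n_trials_per_cell` correct trials in any cell are excluded with a
#'   reason.
#' @param span Analysis span, ms relative to cue onset (default pre-cue
#'   onset to 1800 ms after cue offset).
#' @param window_ms,step_ms Sliding-window geometry.
#' @param n_trials_per_cell Balanced trials drawn per cell (default 15).
#' @param n_resamples Trial-draw resamples (default 20).
#' @param n_shuffles_per_resample Label shuffles per resample (default 50).
#' @param seed Integer seed.
#' @return An object of class `pev_timecourse`: list with `time` (window
#'   centers, ms), `omega` (3 x W matrix, rows duration/protocol/
#'   interaction), `sem`, `baseline` (3 x W), `n_resamples`,
#'   `n_shuffles_total`, `excluded`.
#' @export
pev_timecourse <- function(session, neurons = NULL, span = c(-300, 2400),
                           window_ms = 200, step_ms = 20,
                           n_trials_per_cell = 15, n_resamples = 20,
                           n_shuffles_per_resample = 50, seed = 1) {
  set.seed(seed)
  if (is.null(neurons)) neurons <- session$neurons$neuron
  tr <- session$trials
  correct <- tr[tr$outcome == "correct", , drop = FALSE]
  cells <- split(correct$trial,
                 interaction(correct$duration, correct$protocol, drop = FALSE))
  if (any(lengths(cells) < n_trials_per_cell)) {
    stop("fewer than `n_trials_per_cell` correct trials in some cell")
  }
  # in a synthetic session every neuron is recorded on every trial, so the
  # exclusion list is empty; kept for the pooled-data contract
  excluded <- data.frame(neuron = integer(0), reason = character(0))

  sw <- sliding_window_rates(session, correct$trial, neurons, span,
                             window_ms, step_ms)
  W <- length(sw$centers)
  dur_lab <- rep(rep(sort(unique(correct$duration)),
                     each = n_trials_per_cell),
                 times = length(unique(correct$protocol)))
  prot_lab <- rep(sort(unique(correct$protocol)),
                  each = n_trials_per_cell * length(unique(correct$duration)))
  cell_order <- interaction(
    rep(sort(unique(correct$duration)),
        times = length(unique(correct$protocol))),
    rep(sort(unique(correct$protocol)),
        each = length(unique(correct$duration))), drop = FALSE)

  omega_for_rows <- function(rows, durs, prots) {
    # rows: indices into sw trial axis; returns 3 x W mean omega over neurons
    acc <- matrix(0, 3, W)
    for (j in seq_along(neurons)) {
      Y <- sw$rate[rows, j, , drop = FALSE]
      dim(Y) <- c(length(rows), W)
      ss <- balanced_anova_ss(Y, durs, prots)
      acc[1, ] <- acc[1, ] + omega_squared(ss$ss_duration,
                                           ss$df[["duration"]],
                                           ss$ss_total, ss$ms_error)
      acc[2, ] <- acc[2, ] + omega_squared(ss$ss_protocol,
                                           ss$df[["protocol"]],
                                           ss$ss_total, ss$ms_error)
      acc[3, ] <- acc[3, ] + omega_squared(ss$ss_interaction,
                                           ss$df[["interaction"]],
                                           ss$ss_total, ss$ms_error)
    }
    acc / length(neurons)
  }

  res <- array(0, dim = c(n_resamples, 3, W))
  base_sum <- matrix(0, 3, W); n_base <- 0
  for (r in seq_len(n_resamples)) {
    draw <- unlist(lapply(levels(cell_order), function(cl) {
      sample(cells[[cl]], n_trials_per_cell)
    }), use.names = FALSE)
    rows <- match(draw, sw$trials)
    res[r, , ] <- omega_for_rows(rows, dur_lab, prot_lab)
    for (s in seq_len(n_shuffles_per_resample)) {
      perm <- sample(length(rows))
      base_sum <- base_sum + omega_for_rows(rows, dur_lab[perm],
                                            prot_lab[perm])
      n_base <- n_base + 1
    }
  }
  omega <- apply(res, c(2, 3), mean)
  sem <- apply(res, c(2, 3), stats::sd) / sqrt(n_resamples)
  rn <- c("duration", "protocol", "interaction")
  rownames(omega) <- rownames(sem) <- rn
  baseline <- base_sum / max(n_base, 1)
  rownames(baseline) <- rn
  structure(list(time = sw$centers, omega = omega, sem = sem,
                 baseline = baseline, n_resamples = n_resamples,
                 n_shuffles_total = n_base, excluded = excluded),
            class = "pev_timecourse")
}

#' PCA state-space trajectories per target duration
#'
#' Condition-averages each neuron's activity (20 ms bins from 900 ms before
#' cue onset to the end of the guaranteed wait: 1200 / 2400 / 4800 ms into
#' the wait per duration), smooths it (200 ms Gaussian), z-scores neuron-wise
#' over the concatenation of all durations (so a few high-rate neurons do not
#' dominate), fits one PCA on the concatenated matrix (a common basis makes
#' between-condition distances meaningful), and projects each duration's
#' segment onto the first three components. Component signs are fixed by
#' making each component's largest-magnitude loading positive.
#'
#' @param session A `session_recording`.
#' @param neurons Neuron ids (default all).
#' @param bin_ms Time bin (default 20 ms).
#' @param smooth_ms Gaussian SD (default 200 ms).
#' @param min_trials Required correct trials per duration (default 30).
#' @param n_components Components kept (default 3).
#' @return An object of class `trajectory_set`: list with per-duration
#'   `trajectories` (time x 3 matrices), `time` (per-duration ms vectors,
#'   cue-onset clock), `var_explained`, `markers` (cue on/off, 1200 and
#'   2400 ms into the wait), `loadings`.
#' @export
build_trajectories <- function(session, neurons = NULL, bin_ms = 20,
                               smooth_ms = 200, min_trials = 30,
                               n_components = 3) {
  task <- session$task
  if (is.null(neurons)) neurons <- session$neurons$neuron
  if (length(neurons) < 4) stop("need at least 4 neurons")
  tr <- session$trials
  durs <- sort(task$durations)
  thr <- task$correct_fraction_threshold

  mats <- list(); times <- list()
  for (d in durs) {
    dt <- tr$trial[tr$outcome == "correct" & tr$duration == d]
    if (length(dt) < min_trials) {
      stop("fewer than `min_trials` correct trials for duration ", d)
    }
    win <- c(task$ready_ms, task$cue_ms + thr * d)
    ar <- extract_window_rates(session, "cue_onset", win, bin_ms,
                               trials = dt, neurons = neurons)
    avg <- apply(ar$rate, c(2, 3), mean)            # neurons x bins
    sm <- smooth_and_scale(avg, "gaussian_kernel", width = smooth_ms,
                           bin_width = bin_ms)
    mats[[as.character(d)]] <- t(sm)                # time x neurons
    times[[as.character(d)]] <- ar$bin_edges[-length(ar$bin_edges)] +
      bin_ms / 2
  }
  concat <- do.call(rbind, mats)
  mu <- colMeans(concat); sdv <- apply(concat, 2, stats::sd)
  nz <- sdv > 0
  if (sum(nz) < 3) stop("fewer than 3 nonzero-variance neurons")
  z <- sweep(sweep(concat[, nz, drop = FALSE], 2, mu[nz]), 2, sdv[nz], "/")
  pc <- stats::prcomp(z, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  load <- pc$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {                           # reproducible signs
    i_max <- which.max(abs(load[, j]))
    if (load[i_max, j] < 0) { load[, j] <- -load[, j]
                              scores[, j] <- -scores[, j] }
  }
  ve <- pc$sdev^2 / sum(pc$sdev^2)

  lens <- vapply(mats, nrow, 1L)
  idx_end <- cumsum(lens); idx_start <- idx_end - lens + 1
  trajectories <- stats::setNames(lapply(seq_along(durs), function(i) {
    scores[idx_start[i]:idx_end[i], , drop = FALSE]
  }), as.character(durs))

  markers <- c(cue_on = 0, cue_off = task$cue_ms,
               wait_1200 = task$cue_ms + 1200, wait_2400 = task$cue_ms + 2400)
  structure(list(trajectories = trajectories, time = times,
                 var_explained = ve[seq_len(k)], markers = markers,
                 loadings = load, neurons = neurons[nz]),
            class = "trajectory_set")
}

#' Pairwise Euclidean distances between state-space trajectories
#'
#' Distance at each time point between two conditions' 3-D states, over the
#' overlap of their spans (all spans share the same start, 900 ms before cue
#' onset).
#'
#' @param ts A `trajectory_set`.
#' @return List with `time` (ms, overlap grid per pair) and `distance`
#'   (named list of numeric series, e.g. `"1500-3000"`).
#' @export
trajectory_distances <- function(ts) {
  durs <- names(ts$trajectories)
  out <- list(); tout <- list()
  for (i in seq_len(length(durs) - 1)) {
    for (j in (i + 1):length(durs)) {
      a <- ts$trajectories[[i]]; b <- ts$trajectories[[j]]
      n <- min(nrow(a), nrow(b))
      key <- paste(durs[i], durs[j], sep = "-")
      out[[key]] <- sqrt(rowSums((a[seq_len(n), , drop = FALSE] -
                                    b[seq_len(n), , drop = FALSE])^2))
      tout[[key]] <- ts$time[[i]][seq_len(n)]
    }
  }
  list(time = tout, distance = out)
}

#' Amplitude and velocity of a state-space trajectory
#'
#' Amplitude is the Euclidean distance of each trajectory point from the
#' state at cue onset (zero at the reference by construction). Velocity is
#' the distance between consecutive points divided by the time step in
#' seconds, smoothed with a 5-bin boxcar (edges are `NA`).
#'
#' @param trajectory Time x components matrix.
#' @param time_ms Time axis (ms).
#' @param reference_ms Reference time (default 0 = cue onset).
#' @param boxcar Boxcar width in bins (default 5; 1 disables smoothing).
#' @return List with `amplitude` (length T) and `velocity` (length T - 1,
#'   boxcar-smoothed, aligned to interval midpoints).
#' @export
trajectory_kinematics <- function(trajectory, time_ms, reference_ms = 0,
                                  boxcar = 5) {
  stopifnot(nrow(trajectory) >= 6, nrow(trajectory) == length(time_ms))
  ref <- which.min(abs(time_ms - reference_ms))
  refstate <- trajectory[ref, ]
  amplitude <- sqrt(rowSums(sweep(trajectory, 2, refstate)^2))
  step_s <- diff(time_ms) / 1000
  vel <- sqrt(rowSums(diff(trajectory)^2)) / step_s
  if (boxcar > 1) {
    vel <- as.numeric(stats::filter(vel, rep(1 / boxcar, boxcar),
                                    sides = 2))
  }
  list(amplitude = amplitude, velocity = vel)
}
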