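#' Per-neuron trial pools of window-averaged firing rates
#'
#' Builds, for each neuron, one pool of per-trial mean rates (Hz, single
#' window) per class. Classes are target durations by default; restrict to a
#' protocol for within/cross-protocol analyses.
#'
#' @param session A `session_recording`.
#' @param alignment,window Passed to [extract_window_rates()] (single bin).
#' @param outcomes Trial outcomes to include (default `"correct"`).
#' @param protocol Optional protocol filter.
#' @param neurons Neuron ids (default all).
#' @return Named list per neuron: list of numeric vectors per class.
#' @export
unit_feature_pools <- function(session, alignment = "cue_offset",
                               window = c(0, 1200), outcomes = "correct",
                               protocol = NULL, neurons = NULL) {
  tr <- session$trials
  keep <- tr$outcome %in% outcomes
  if (!is.null(protocol)) keep <- keep & tr$protocol %in% protocol
  trials <- tr$trial[keep]
  if (is.null(neurons)) neurons <- session$neurons$neuron
  ar <- extract_window_rates(session, alignment, window,
                             window[2] - window[1],
                             trials = trials, neurons = neurons)
  rates <- ar$rate[, , 1, drop = FALSE][, , 1]       # trials x neurons
  if (is.null(dim(rates))) rates <- matrix(rates, ncol = length(neurons))
  cls <- ar$meta$duration
  pools <- lapply(seq_along(neurons), function(j) {
    split(rates[, j], factor(cls))
  })
  stats::setNames(pools, as.character(neurons))
}

#' Assemble a pseudopopulation from per-neuron trial pools
#'
#' Neurons recorded in different sessions have no true simultaneity, so
#' population feature matrices are assembled by randomly pairing trials
#' within class: per resample, each neuron contributes `min_trials` trials
#' per class drawn without replacement, paired by position into pseudotrials.
#' Neurons lacking `min_trials` in any class are excluded with a reason.
#'
#' @param units Output of [unit_feature_pools()].
#' @param min_trials Required trials per class per neuron.
#' @return An object of class `pseudopopulation`: list with `pools` (included
#'   neurons), `classes`, `min_trials`, `excluded` (data.frame neuron/reason).
#' @export
assemble_pseudopopulation <- function(units, min_trials = 15) {
  classes <- names(units[[1]])
  ok <- vapply(units, function(u) all(vapply(u, length, 1L) >= min_trials),
               logical(1))
  excluded <- data.frame(
    neuron = names(units)[!ok],
    reason = rep("fewer than min_trials in some class", sum(!ok)))
  if (!any(ok)) stop("no neuron meets the min_trials criterion")
  structure(list(pools = units[ok], classes = classes,
                 min_trials = min_trials, excluded = excluded),
            class = "pseudopopulation")
}

#' Draw one pseudotrial feature matrix from a pseudopopulation
#'
#' @param pp A `pseudopopulation`.
#' @param n_per_class Pseudotrials per class (default `pp$min_trials`).
#' @param replace Sample trials with replacement (used only where pools may
#'   be smaller than the draw, e.g. scarce error trials).
#' @return List with `x` (pseudotrials x neurons) and `y` (class labels).
#' @export
draw_pseudotrials <- function(pp, n_per_class = NULL, replace = FALSE) {
  n <- n_per_class %||% pp$min_trials
  blocks <- lapply(pp$classes, function(cl) {
    cols <- lapply(pp$pools, function(u) {
      pool <- u[[cl]]
      pool[sample.int(length(pool), n, replace = replace)]
    })
    matrix(unlist(cols), nrow = n)
  })
  x <- do.call(rbind, blocks)
  list(x = x, y = factor(rep(pp$classes, each = n), levels = pp$classes))
}

#' Pooled target-duration decoding
#'
#' Three-class (target duration) linear SVM decoding of a pseudopopulation
#' assembled from all trials regardless of protocol, with 10-fold
#' cross-validation, train-only z-scoring, fresh pseudotrial draws per
#' resample, and a shuffled-label null.
#'
#' @param session A `session_recording`.
#' @param alignment,window Analysis window (default first 1200 ms after cue
#'   offset).
#' @param min_trials Trials per duration per neuron (default 30, enabling
#'   10-fold CV with 27/3 train/test per class).
#' @param n_folds,n_resamples,n_shuffles,seed Passed to [svm_decode()].
#' @param neurons Neuron ids (default all).
#' @return A `decode_result`.
#' @export
duration_decode <- function(session, alignment = "cue_offset",
                            window = c(0, 1200), min_trials = 30,
                            n_folds = 10, n_resamples = 1000,
                            n_shuffles = 100, seed = 1, neurons = NULL) {
  units <- unit_feature_pools(session, alignment, window, neurons = neurons)
  pp <- assemble_pseudopopulation(units, min_trials)
  svm_decode(n_folds = n_folds, n_resamples = n_resamples,
             n_shuffles = n_shuffles, seed = seed,
             draw = function() draw_pseudotrials(pp))
}

#' Within- and cross-protocol target-duration decoding
#'
#' Within-protocol: stratified CV inside one protocol's trials. Cross-
#' protocol: train on all pseudotrials of one protocol and test on all of
#' the other (train and test are disjoint by construction), z-scoring with
#' training statistics only. High cross-protocol accuracy indicates an
#' abstract, cue-independent duration code.
#'
#' @param session A `session_recording`.
#' @param alignment,window Analysis window.
#' @param min_trials Trials per duration per neuron within each protocol
#'   (default 15; 5-fold CV gives 12/3 train/test per class).
#' @param n_folds,n_resamples,n_shuffles,seed Resampling controls.
#' @param neurons Neuron ids (default all).
#' @return Named list of four `decode_result`s:
#'   `within_<p1>`, `within_<p2>`, `<p1>_to_<p2>`, `<p2>_to_<p1>`.
#' @export
protocol_generalization_decode <- function(session,
                                           alignment = "cue_offset",
                                           window = c(0, 1200),
                                           min_trials = 15, n_folds = 5,
                                           n_resamples = 100,
                                           n_shuffles = 100, seed = 1,
                                           neurons = NULL) {
  protos <- session$task$protocols
  stopifnot(length(protos) == 2)
  pps <- lapply(protos, function(p) {
    assemble_pseudopopulation(
      unit_feature_pools(session, alignment, window, protocol = p,
                         neurons = neurons), min_trials)
  })
  names(pps) <- protos

  out <- list()
  for (i in 1:2) {
    out[[paste0("within_", protos[i])]] <- svm_decode(
      n_folds = n_folds, n_resamples = n_resamples, n_shuffles = n_shuffles,
      seed = seed + i, draw = local({ pp <- pps[[i]]
        function() draw_pseudotrials(pp) }))
  }
  cross <- function(pa, pb, sd0) {
    set.seed(sd0)
    run <- function(n, shuffle) {
      acc <- numeric(n); conf_sum <- NULL
      for (r in seq_len(n)) {
        da <- draw_pseudotrials(pa); db <- draw_pseudotrials(pb)
        ya <- da$y
        if (shuffle) ya <- sample(ya)
        xall <- rbind(da$x, db$x)
        tr_idx <- seq_len(nrow(da$x))
        xs <- smooth_and_scale(xall, "zscore_by_train", train_idx = tr_idx)
        m <- svm_train(xs[tr_idx, , drop = FALSE], ya,
                       seed = sample.int(.Machine$integer.max, 1))
        pred <- svm_predict(m, xs[-tr_idx, , drop = FALSE])
        conf <- table(factor(db$y, levels(db$y)),
                      factor(pred, levels(db$y)))
        acc[r] <- 100 * sum(diag(conf)) / sum(conf)
        conf_sum <- if (is.null(conf_sum)) conf else conf_sum + conf
      }
      list(acc = acc, conf = conf_sum / n)
    }
    true <- run(n_resamples, FALSE)
    null <- run(n_shuffles, TRUE)
    structure(list(accuracy = mean(true$acc), accuracies = true$acc,
                   confusion = true$conf, null_accuracies = null$acc,
                   null_p99 = stats::quantile(null$acc, 0.99, names = FALSE),
                   n_folds = NA, n_resamples = n_resamples),
              class = "decode_result")
  }
  out[[paste0(protos[1], "_to_", protos[2])]] <-
    cross(pps[[1]], pps[[2]], seed + 11)
  out[[paste0(protos[2], "_to_", protos[1])]] <-
    cross(pps[[2]], pps[[1]], seed + 12)
  out
}

# Per-neuron matrix of per-trial rates in n_bins proportional bins over the
# guaranteed wait span [0, 0.8 d) of one duration, cue-offset aligned.
wait_bin_features <- function(session, duration, neurons, n_bins = 20,
                              trials = NULL) {
  thr <- session$task$correct_fraction_threshold
  span <- thr * duration
  tr <- session$trials
  if (is.null(trials)) {
    trials <- tr$trial[tr$outcome == "correct" & tr$duration == duration]
  }
  ar <- extract_window_rates(session, "cue_offset", c(0, span),
                             span / n_bins, trials = trials,
                             neurons = neurons)
  ar    # $rate: trials x neurons x n_bins
}

#' Decode elapsed time within one target duration
#'
#' The guaranteed wait span (first `0.8 d` ms after cue offset) is divided
#' into `n_bins` equal bins; every (trial, bin) pair is an observation
#' (`n_trials * n_bins = 400` per neuron at the defaults), the feature being
#' each neuron's min-max-normalised mean rate in that bin. A 20-class
#' one-vs-one linear SVM is trained on 80 % of observations under 5-fold CV
#' (320 train / 80 test; each bin appears exactly 4 times per test fold) and
#' the predicted-bin distribution per true bin is accumulated over folds and
#' resamples (`n_resamples * 5 folds * 4 = 20,000` predictions per bin at
#' 1000 resamples).
#'
#' @param session A `session_recording`.
#' @param duration Target duration (ms).
#' @param neurons Candidate neuron ids (default all); neurons with fewer than
#'   `n_trials` correct trials are dropped with a warning.
#' @param n_trials,n_bins,n_folds,n_resamples Bookkeeping parameters
#'   (defaults 20/20/5/1000).
#' @param seed Integer seed.
#' @return An object of class `elapsed_decode`: list with `counts`
#'   (true bin x predicted bin), `summary` (data.frame: bin, median_pred,
#'   q25, q75), `accuracy` (%), and the bookkeeping fields
#'   `n_observations`, `n_train`, `n_test`, `predictions_per_bin`.
#' @export
elapsed_time_decode <- function(session, duration, neurons = NULL,
                                n_trials = 20, n_bins = 20, n_folds = 5,
                                n_resamples = 1000, seed = 1) {
  set.seed(seed)
  if (is.null(neurons)) neurons <- session$neurons$neuron
  tr <- session$trials
  pool <- tr$trial[tr$outcome == "correct" & tr$duration == duration]
  # every neuron sees every trial in a synthetic session, but keep the
  # per-neuron contract for real (pooled) data
  if (length(pool) < n_trials) {
    stop("fewer than ", n_trials, " correct trials for duration ", duration)
  }
  feats <- wait_bin_features(session, duration, neurons, n_bins)
  n_avail <- dim(feats$rate)[1]

  counts <- matrix(0, n_bins, n_bins,
                   dimnames = list(true = 1:n_bins, pred = 1:n_bins))
  y <- factor(rep(1:n_bins, times = n_trials), levels = 1:n_bins)
  for (r in seq_len(n_resamples)) {
    # per neuron: draw n_trials trials independently, min-max normalise
    cols <- lapply(seq_along(neurons), function(j) {
      rows <- sample.int(n_avail, n_trials)
      m <- feats$rate[rows, j, ]                   # n_trials x n_bins
      rng <- range(m)
      if (diff(rng) > 0) m <- (m - rng[1]) / diff(rng) else m[] <- 0
      as.numeric(t(m))                             # bin-major within trial
    })
    x <- do.call(cbind, cols)
    conf <- decode_cv_once(x, y, n_folds)
    counts <- counts + conf
  }
  cum_med <- function(v, q) {                      # weighted quantile of bins
    cs <- cumsum(v) / sum(v)
    which(cs >= q)[1]
  }
  summary <- data.frame(
    bin = 1:n_bins,
    median_pred = apply(counts, 1, cum_med, q = 0.5),
    q25 = apply(counts, 1, cum_med, q = 0.25),
    q75 = apply(counts, 1, cum_med, q = 0.75))
  structure(list(
    counts = counts, summary = summary,
    accuracy = 100 * sum(diag(counts)) / sum(counts),
    n_observations = n_trials * n_bins,
    n_train = n_trials * n_bins * (n_folds - 1) / n_folds,
    n_test = n_trials * n_bins / n_folds,
    predictions_per_bin = n_resamples * n_folds * (n_trials / n_folds),
    duration = duration, bin_ms = session$task$correct_fraction_threshold *
      duration / n_bins
  ), class = "elapsed_decode")
}

#' Correct- versus late-error-trial decoding
#'
#' Trains a two-class (shorter two durations) linear SVM on cue-offset-
#' aligned activity from correct trials (10-fold CV) and tests every fold's
#' model both on the held-out correct pseudotrials and on late-error
#' pseudotrials (resampled each iteration), using the training fold's
#' z-scoring throughout. If the late-error population code matches the cued
#' duration, both accuracies agree; a code reflecting a mis-estimated
#' duration drives the late-error accuracy below the shuffled-label
#' threshold.
#'
#' @param session A `session_recording`.
#' @param classes The two durations decoded (default the two shortest).
#' @param neurons Neuron ids (default all); every neuron must have at least
#'   one late-error trial per class in its pools.
#' @param alignment,window Analysis window.
#' @param min_correct Correct pseudotrials per class per neuron.
#' @param n_late Late-error pseudotrials per class per resample (drawn with
#'   replacement; errors are scarce).
#' @param n_folds,n_resamples,n_shuffles,seed Resampling controls.
#' @return List with `correct` and `late_error` (`decode_result`-like:
#'   accuracy, accuracies, confusion), and `null_p99` (%).
#' @export
error_trial_decode <- function(session, classes = NULL, neurons = NULL,
                               alignment = "cue_offset", window = c(0, 1200),
                               min_correct = 15, n_late = 10, n_folds = 10,
                               n_resamples = 100, n_shuffles = 100,
                               seed = 1) {
  set.seed(seed)
  durs <- sort(session$task$durations)
  if (is.null(classes)) classes <- durs[1:2]
  cl <- as.character(classes)

  corr <- assemble_pseudopopulation(
    unit_feature_pools(session, alignment, window, outcomes = "correct",
                       neurons = neurons), min_correct)
  corr$pools <- lapply(corr$pools, function(u) u[cl])
  corr$classes <- cl
  late_units <- unit_feature_pools(session, alignment, window,
                                   outcomes = "late_error",
                                   neurons = as.integer(names(corr$pools)))
  late_n <- vapply(late_units, function(u)
    min(vapply(u[cl], length, 1L)), 1L)
  if (any(late_n < 1)) stop("no late errors in a class for some neuron")
  late <- structure(list(pools = lapply(late_units, function(u) u[cl]),
                         classes = cl, min_trials = 1,
                         excluded = data.frame()),
                    class = "pseudopopulation")

  run <- function(n, shuffle) {
    acc_c <- acc_l <- numeric(n); conf_c <- conf_l <- NULL
    for (r in seq_len(n)) {
      dc <- draw_pseudotrials(corr, min_correct)
      dl <- draw_pseudotrials(late, n_late, replace = TRUE)
      yc <- dc$y
      if (shuffle) yc <- sample(yc)
      folds <- stratified_folds(yc, n_folds)
      cc <- cl_ <- matrix(0, 2, 2, dimnames = list(cl, cl))
      for (f in seq_len(n_folds)) {
        tr_idx <- which(folds != f); te <- which(folds == f)
        xall <- rbind(dc$x, dl$x)
        xs <- smooth_and_scale(xall, "zscore_by_train", train_idx = tr_idx)
        m <- svm_train(xs[tr_idx, , drop = FALSE], yc[tr_idx],
                       seed = sample.int(.Machine$integer.max, 1))
        pc <- svm_predict(m, xs[te, , drop = FALSE])
        pl <- svm_predict(m, xs[nrow(dc$x) + seq_len(nrow(dl$x)), ,
                                drop = FALSE])
        cc <- cc + table(factor(dc$y[te], cl), factor(pc, cl))
        cl_ <- cl_ + table(factor(dl$y, cl), factor(pl, cl))
      }
      acc_c[r] <- 100 * sum(diag(cc)) / sum(cc)
      acc_l[r] <- 100 * sum(diag(cl_)) / sum(cl_)
      conf_c <- if (is.null(conf_c)) cc else conf_c + cc
      conf_l <- if (is.null(conf_l)) cl_ else conf_l + cl_
    }
    list(acc_c = acc_c, acc_l = acc_l, conf_c = conf_c / n,
         conf_l = conf_l / n)
  }
  true <- run(n_resamples, FALSE)
  null <- run(n_shuffles, TRUE)
  list(
    correct = structure(list(accuracy = mean(true$acc_c),
                             accuracies = true$acc_c,
                             confusion = true$conf_c,
                             null_accuracies = null$acc_c,
                             null_p99 = stats::quantile(null$acc_c, 0.99,
                                                        names = FALSE),
                             n_folds = n_folds,
                             n_resamples = n_resamples),
                        class = "decode_result"),
    late_error = structure(list(accuracy = mean(true$acc_l),
                                accuracies = true$acc_l,
                                confusion = true$conf_l,
                                null_accuracies = null$acc_l,
                                null_p99 = stats::quantile(null$acc_l, 0.99,
                                                           names = FALSE),
                                n_folds = n_folds,
                                n_resamples = n_resamples),
                           class = "decode_result"),
    null_p99 = stats::quantile(null$acc_c, 0.99, names = FALSE)
  )
}

# Sliding-window rates on the cue-onset clock. Returns trials x neurons x W
# array plus window centers (ms), with `window_ms` windows stepped every
# `step_ms` across `span`.
sliding_window_rates <- function(session, trials, neurons, span,
                                 window_ms = 200, step_ms = 20) {
  stopifnot(window_ms %% step_ms == 0)
  ar <- extract_window_rates(session, "cue_onset", span, step_ms,
                             trials = trials, neurons = neurons)
  k <- window_ms / step_ms
  nb <- dim(ar$rate)[3]
  W <- nb - k + 1
  cs <- array(0, dim = dim(ar$rate) + c(0, 0, 1))
  cs[, , -1] <- aperm(apply(ar$rate, c(1, 2), cumsum), c(2, 3, 1))
  out <- (cs[, , (k + 1):(nb + 1), drop = FALSE] -
            cs[, , 1:W, drop = FALSE]) / k
  centers <- span[1] + (seq_len(W) - 1) * step_ms + window_ms / 2
  list(rate = out, centers = centers, trials = ar$trials, meta = ar$meta)
}

# Train-at-one-column, test-at-every-column generalization matrix.
# feats: pseudotrials x neurons x W; y: class labels. The training column's
# z-scaler is applied to every tested column. Returns W x W accuracy (0-1).
generalization_matrix <- function(feats, y, n_folds, C = 1) {
  W <- dim(feats)[3]
  y <- factor(y)
  acc <- matrix(0, W, W)
  n_test_total <- 0
  folds <- stratified_folds(y, n_folds)
  for (f in seq_len(n_folds)) {
    tr_idx <- which(folds != f); te <- which(folds == f)
    n_test_total <- n_test_total + length(te)
    for (w in seq_len(W)) {
      xw <- feats[, , w, drop = FALSE][, , 1, drop = FALSE]
      dim(xw) <- dim(feats)[1:2]
      mu <- colMeans(xw[tr_idx, , drop = FALSE])
      sdv <- apply(xw[tr_idx, , drop = FALSE], 2, stats::sd)
      sdv[sdv == 0] <- Inf                 # zero-variance features -> 0
      xtr <- sweep(sweep(xw[tr_idx, , drop = FALSE], 2, mu), 2, sdv, "/")
      m <- svm_train(xtr, y[tr_idx], C = C,
                     seed = sample.int(.Machine$integer.max, 1))
      for (w2 in seq_len(W)) {
        x2 <- feats[, , w2, drop = FALSE][, , 1, drop = FALSE]
        dim(x2) <- dim(feats)[1:2]
        xte <- sweep(sweep(x2[te, , drop = FALSE], 2, mu), 2, sdv, "/")
        pred <- svm_predict(m, xte)
        acc[w, w2] <- acc[w, w2] + sum(pred == y[te])
      }
    }
  }
  acc / n_test_total
}

#' Cross-temporal target-duration decoding
#'
#' Sliding-window (200 ms length, 20 ms steps) three-class decoding in which
#' the classifier trained at one time window is tested at every window of
#' held-out trials (10-fold CV, the training window's z-scaler applied to all
#' test windows). Square regions of high accuracy indicate a static
#' (persistent) code; accuracy confined to the diagonal indicates a dynamic
#' (sequential) code. Shuffled-label repeats provide the null matrices for
#' [cluster_permutation_test()].
#'
#' @param session A `session_recording`.
#' @param neurons Neuron ids (default all).
#' @param span Analysis span, ms relative to cue onset (default pre-cue onset
#'   to 1800 ms after cue offset).
#' @param window_ms,step_ms Sliding-window geometry.
#' @param min_trials Correct trials per duration per neuron (default 20;
#'   10-fold CV trains on 18 and tests on 2 per class).
#' @param n_folds,n_resamples Resampling controls.
#' @param n_shuffles_per_resample Shuffled-label repeats per resample
#'   (default 0 = no null).
#' @param seed Integer seed.
#' @return An object of class `cross_temporal_result`: list with `acc`
#'   (resamples x W x W, proportions), `mean_acc` (W x W), `null`
#'   (n_null x W x W or `NULL`), `centers` (ms).
#' @export
cross_temporal_decode <- function(session, neurons = NULL,
                                  span = c(-300, 2400), window_ms = 200,
                                  step_ms = 20, min_trials = 20,
                                  n_folds = 10, n_resamples = 20,
                                  n_shuffles_per_resample = 0, seed = 1) {
  set.seed(seed)
  if (is.null(neurons)) neurons <- session$neurons$neuron
  tr <- session$trials
  trials <- tr$trial[tr$outcome == "correct"]
  sw <- sliding_window_rates(session, trials, neurons, span, window_ms,
                             step_ms)
  W <- length(sw$centers)
  cls <- factor(sw$meta$duration)
  by_class <- split(seq_along(sw$trials), cls)
  if (any(lengths(by_class) < min_trials)) {
    stop("need at least `min_trials` correct trials per duration")
  }

  y <- factor(rep(levels(cls), each = min_trials), levels = levels(cls))
  acc <- array(0, dim = c(n_resamples, W, W))
  nulls <- if (n_shuffles_per_resample > 0) {
    array(0, dim = c(n_resamples * n_shuffles_per_resample, W, W))
  } else NULL
  ni <- 0
  for (r in seq_len(n_resamples)) {
    rows <- unlist(lapply(by_class, function(ix)
      sample(ix, min_trials)), use.names = FALSE)
    feats <- sw$rate[rows, , , drop = FALSE]
    acc[r, , ] <- generalization_matrix(feats, y, n_folds)
    if (n_shuffles_per_resample > 0) {
      for (s in seq_len(n_shuffles_per_resample)) {
        ni <- ni + 1
        nulls[ni, , ] <- generalization_matrix(feats, sample(y), n_folds)
      }
    }
  }
  structure(list(acc = acc, mean_acc = apply(acc, c(2, 3), mean),
                 null = nulls, centers = sw$centers,
                 window_ms = window_ms, step_ms = step_ms),
            class = "cross_temporal_result")
}

#' Wait-period bin-stability decoding
#'
#' Each duration's guaranteed wait span is split into `n_bins` proportional
#' bins (60/120/240 ms for 1500/3000/6000 ms trials at 20 bins); a
#' three-class (duration) SVM trained on any one bin is tested on every
#' other bin of held-out trials. Uniformly high accuracy across the matrix
#' indicates stable duration tuning throughout the wait.
#'
#' @param session A `session_recording`.
#' @param neurons Neuron ids (default all).
#' @param n_bins Proportional bins per duration (default 20).
#' @param min_trials Correct trials per duration per neuron (default 20).
#' @param n_folds,n_resamples Resampling controls.
#' @param n_shuffles_per_resample Shuffled-label repeats per resample.
#' @param seed Integer seed.
#' @return A `cross_temporal_result` whose axes are proportional bins.
#' @export
bin_stability_decode <- function(session, neurons = NULL, n_bins = 20,
                                 min_trials = 20, n_folds = 5,
                                 n_resamples = 100,
                                 n_shuffles_per_resample = 0, seed = 1) {
  set.seed(seed)
  if (is.null(neurons)) neurons <- session$neurons$neuron
  durs <- sort(session$task$durations)
  per_dur <- lapply(durs, function(d)
    wait_bin_features(session, d, neurons, n_bins))
  n_avail <- vapply(per_dur, function(a) dim(a$rate)[1], 1L)
  if (any(n_avail < min_trials)) {
    stop("need at least `min_trials` correct trials per duration")
  }
  y <- factor(rep(durs, each = min_trials), levels = durs)
  W <- n_bins
  acc <- array(0, dim = c(n_resamples, W, W))
  nulls <- if (n_shuffles_per_resample > 0) {
    array(0, dim = c(n_resamples * n_shuffles_per_resample, W, W))
  } else NULL
  ni <- 0
  for (r in seq_len(n_resamples)) {
    feats <- abind_durations(lapply(seq_along(durs), function(k) {
      rows <- sample.int(n_avail[k], min_trials)
      per_dur[[k]]$rate[rows, , , drop = FALSE]
    }))
    acc[r, , ] <- generalization_matrix(feats, y, n_folds)
    if (n_shuffles_per_resample > 0) {
      for (s in seq_len(n_shuffles_per_resample)) {
        ni <- ni + 1
        nulls[ni, , ] <- generalization_matrix(feats, sample(y), n_folds)
      }
    }
  }
  structure(list(acc = acc, mean_acc = apply(acc, c(2, 3), mean),
                 null = nulls, centers = seq_len(n_bins),
                 window_ms = NA, step_ms = NA),
            class = "cross_temporal_result")
}

# rbind 3-d arrays along the first (trial) dimension
abind_durations <- function(lst) {
  d <- dim(lst[[1]])
  out <- array(0, dim = c(sum(vapply(lst, function(a) dim(a)[1], 1L)),
                          d[2], d[3]))
  at <- 0
  for (a in lst) {
    out[at + seq_len(dim(a)[1]), , ] <- a
    at <- at + dim(a)[1]
  }
  out
}

# 4-connected component labelling of a logical matrix.
connected_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  nxt <- 0L
  for (i in seq_len(nrow(mask))) {
    for (j in seq_len(ncol(mask))) {
      if (mask[i, j] && lab[i, j] == 0L) {
        nxt <- nxt + 1L
        queue <- list(c(i, j)); lab[i, j] <- nxt
        while (length(queue)) {
          p <- queue[[1]]; queue <- queue[-1]
          for (dd in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
            q <- p + dd
            if (q[1] >= 1 && q[1] <= nrow(mask) && q[2] >= 1 &&
                q[2] <= ncol(mask) && mask[q[1], q[2]] &&
                lab[q[1], q[2]] == 0L) {
              lab[q[1], q[2]] <- nxt
              queue[[length(queue) + 1]] <- q
            }
          }
        }
      }
    }
  }
  lab
}

#' Cluster permutation test for cross-temporal accuracy matrices
#'
#' Thresholds the mean true accuracy matrix pixelwise at the
#' `1 - alpha_cluster` quantile of the shuffled-label null, groups
#' supra-threshold pixels into 4-connected candidate clusters, and declares a
#' cluster significant iff its size exceeds the `1 - alpha_rank` quantile of
#' the null maximum-cluster-size distribution (each null matrix thresholded
#' the same way).
#'
#' @param true_acc Resamples x W x W array (or W x W matrix) of true
#'   accuracies.
#' @param null_acc n_null x W x W array of shuffled-label accuracies
#'   (>= 100 recommended).
#' @param alpha_cluster Pixelwise threshold level (default 0.01).
#' @param alpha_rank Cluster-size rank level (default 0.01).
#' @return List with `mask` (significant pixels), `clusters` (data.frame:
#'   id, size, significant), `labels` (component labels),
#'   `null_max_sizes`, `size_threshold`.
#' @export
cluster_permutation_test <- function(true_acc, null_acc,
                                     alpha_cluster = 0.01,
                                     alpha_rank = 0.01) {
  true_mean <- if (length(dim(true_acc)) == 3) {
    apply(true_acc, c(2, 3), mean)
  } else as.matrix(true_acc)
  n_null <- dim(null_acc)[1]
  thr <- apply(null_acc, c(2, 3), stats::quantile, probs = 1 - alpha_cluster,
               names = FALSE)
  mask0 <- true_mean > thr
  lab <- connected_components(mask0)
  sizes <- if (max(lab) > 0) tabulate(lab[lab > 0]) else integer(0)

  null_max <- vapply(seq_len(n_null), function(k) {
    mk <- null_acc[k, , ] > thr
    lk <- connected_components(mk)
    if (max(lk) > 0) max(tabulate(lk[lk > 0])) else 0L
  }, numeric(1))
  size_thr <- stats::quantile(null_max, 1 - alpha_rank, names = FALSE)

  clusters <- data.frame(id = seq_along(sizes), size = sizes,
                         significant = sizes > size_thr)
  sig_ids <- clusters$id[clusters$significant]
  mask <- matrix(lab %in% sig_ids, nrow(lab), ncol(lab)) & mask0
  list(mask = mask, clusters = clusters, labels = lab,
       null_max_sizes = null_max, size_threshold = size_thr)
}
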