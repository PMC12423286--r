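#' Classify a neuron's time selectivity across both alignment windows
#'
#' Combines the ANOVA outcomes of the cue-offset-aligned and response-onset-
#' aligned analysis windows: a neuron is a "time" neuron in an alignment iff
#' the duration main effect is significant with no protocol or interaction
#' effect. Preferred duration per alignment is the duration with the highest
#' mean rate (ties broken to the shorter duration, flagged).
#'
#' @param anova_cue,anova_resp `anova_result` objects for the same neuron
#'   (cue-offset and response-onset windows).
#' @return List with `time_cue`, `time_resp`, `overlap` (significant in both),
#'   `preferred_cue`, `preferred_resp`, `preference_change`, `tie_cue`,
#'   `tie_resp`.
#' @export
classify_time_neuron <- function(anova_cue, anova_resp) {
  pref <- function(a) {
    m <- a$duration_means
    mx <- max(m)
    hits <- which(m == mx)
    list(preferred = as.numeric(names(m))[hits[1]], tie = length(hits) > 1)
  }
  pc <- pref(anova_cue); pr <- pref(anova_resp)
  tc <- anova_cue$classification == "time"
  tr <- anova_resp$classification == "time"
  list(time_cue = tc, time_resp = tr, overlap = tc && tr,
       preferred_cue = pc$preferred, preferred_resp = pr$preferred,
       preference_change = (tc && tr) && pc$preferred != pr$preferred,
       tie_cue = pc$tie, tie_resp = pr$tie)
}

#' Normalised tuning curve and tuning width
#'
#' Min-max normalises the three per-duration mean rates to 0-100 % (most
#' preferred duration = 100, least preferred = 0) and computes the tuning
#' width as the weighted SD of the durations, with the normalised responses
#' as weights: `sqrt(sum(w (x - xbar_w)^2) / sum(w))`.
#'
#' Monotonicity (assessed for the shortest- and longest-preferring neurons):
#' a shortest-preferring neuron is monotonic iff its rates are non-increasing
#' with duration; a longest-preferring neuron iff non-decreasing. For a
#' middle-preferring neuron the flag is `NA`.
#'
#' @param means Named numeric vector of mean rates, names = durations (ms).
#' @return An object of class `tuning_result`: list with `preferred` (ms),
#'   `tie`, `curve` (0-100, named by duration), `weighted_sd` (ms),
#'   `monotonic`.
#' @export
tuning_curve <- function(means) {
  stopifnot(length(means) >= 3, !is.null(names(means)))
  x <- as.numeric(names(means))
  ord <- order(x); x <- x[ord]; m <- as.numeric(means)[ord]
  rng <- range(m)
  if (diff(rng) == 0) stop("all duration means equal: tuning undefined")
  w <- (m - rng[1]) / diff(rng) * 100
  hits <- which(m == rng[2])
  preferred <- x[hits[1]]
  xbar <- sum(w * x) / sum(w)
  wsd <- sqrt(sum(w * (x - xbar)^2) / sum(w))
  monotonic <- if (preferred == x[1]) all(diff(m) <= 0)
    else if (preferred == x[length(x)]) all(diff(m) >= 0)
    else NA
  structure(list(preferred = preferred, tie = length(hits) > 1,
                 curve = stats::setNames(w, x), weighted_sd = wsd,
                 monotonic = monotonic),
            class = "tuning_result")
}

#' Jonckheere-Terpstra trend test for ordered groups
#'
#' Tests for a monotone trend across `k` groups given in increasing order of
#' the ordering covariate (here: target duration). The statistic is the sum
#' of pairwise Mann-Whitney counts over ordered group pairs, ties counting
#' one half. The p-value uses the normal approximation with tie-corrected
#' variance; for pooled `n <= max_exact_n` (or `exact = TRUE`) an exact
#' permutation p-value is computed by full enumeration of the
#' `N! / prod(n_i!)` group assignments.
#'
#' @param groups List of numeric vectors, ordered by the covariate.
#' @param alternative `"increasing"` (one-sided, default) or `"decreasing"`.
#' @param exact Force (`TRUE`) or suppress (`FALSE`) exact enumeration;
#'   default `NULL` enumerates when `N <= max_exact_n`.
#' @param max_exact_n Largest pooled sample size for automatic enumeration.
#' @return List with `statistic` (T_JT), `z`, `p` (normal approximation),
#'   `p_exact` (or `NA`), `n` (group sizes).
#' @export
jonckheere_terpstra <- function(groups, alternative = c("increasing",
                                                        "decreasing"),
                                exact = NULL, max_exact_n = 12) {
  alternative <- match.arg(alternative)
  if (length(groups) < 2) stop("need at least 2 ordered groups")
  if (any(lengths(groups) == 0)) stop("groups must be non-empty")
  if (alternative == "decreasing") groups <- rev(groups)
  ni <- lengths(groups)
  N <- sum(ni)

  jt_stat <- function(gs) {
    s <- 0
    for (i in seq_len(length(gs) - 1)) {
      for (j in (i + 1):length(gs)) {
        cmp <- outer(gs[[i]], gs[[j]], "<")
        tie <- outer(gs[[i]], gs[[j]], "==")
        s <- s + sum(cmp) + 0.5 * sum(tie)
      }
    }
    s
  }
  Tobs <- jt_stat(groups)

  # normal approximation with tie correction
  pooled <- unlist(groups)
  tj <- as.numeric(table(pooled))
  ET <- (N^2 - sum(ni^2)) / 4
  A <- N * (N - 1) * (2 * N + 5) - sum(ni * (ni - 1) * (2 * ni + 5)) -
    sum(tj * (tj - 1) * (2 * tj + 5))
  B <- sum(ni * (ni - 1) * (ni - 2)) * sum(tj * (tj - 1) * (tj - 2))
  C <- sum(ni * (ni - 1)) * sum(tj * (tj - 1))
  varT <- A / 72 + B / (36 * N * (N - 1) * (N - 2)) +
    C / (8 * N * (N - 1))
  if (!is.finite(varT) || varT <= 0) {
    z <- 0; p <- 0.5
  } else {
    z <- (Tobs - ET) / sqrt(varT)
    p <- stats::pnorm(z, lower.tail = FALSE)
  }

  p_exact <- NA_real_
  do_exact <- if (is.null(exact)) N <= max_exact_n else exact
  if (do_exact) {
    stats_all <- jt_enumerate(pooled, ni, jt_stat)
    p_exact <- mean(stats_all >= Tobs - 1e-9)
  }
  list(statistic = Tobs, z = z, p = p, p_exact = p_exact, n = ni)
}

# Enumerate T_JT over all distinct assignments of the pooled values to groups
# of sizes ni (independent brute-force path used for exact p-values).
jt_enumerate <- function(pooled, ni, jt_stat) {
  res <- numeric(0)
  recurse <- function(avail_idx, remaining_ni, chosen) {
    if (length(remaining_ni) == 1) {
      gs <- c(chosen, list(pooled[avail_idx]))
      res[[length(res) + 1]] <<- jt_stat(gs)
      return(invisible(NULL))
    }
    cmb <- utils::combn(seq_along(avail_idx), remaining_ni[1])
    for (c_i in seq_len(ncol(cmb))) {
      pick <- avail_idx[cmb[, c_i]]
      recurse(setdiff(avail_idx, pick), remaining_ni[-1],
              c(chosen, list(pooled[pick])))
    }
  }
  recurse(seq_along(pooled), ni, list())
  res
}

#' Peak-sorted sequence surface of time-neuron activity
#'
#' Trial-averages each neuron's aligned activity, smooths it with a Gaussian
#' kernel, min-max normalises each neuron over its own window (0 = minimum,
#' 1 = maximum; constant neurons map to zero), and sorts rows by the time of
#' the peak. Ensembles of time-field neurons tiling the interval produce a
#' diagonal ridge.
#'
#' @param session A `session_recording`.
#' @param neurons Neuron ids to include (e.g. the time neurons).
#' @param alignment `"cue_offset"` or `"response_onset"`.
#' @param window Analysis window (ms relative to the event).
#' @param bin_width Bin width (ms, default 20).
#' @param smooth_ms Gaussian SD (ms, default 200).
#' @return List with `surface` (neurons x bins, rows sorted), `order`
#'   (neuron ids in plotted order), `peak_time` (ms), `centers` (bin centers).
#' @export
sequence_surface <- function(session, neurons,
                             alignment = c("cue_offset", "response_onset"),
                             window = c(0, 1200), bin_width = 20,
                             smooth_ms = 200) {
  alignment <- match.arg(alignment)
  if (length(neurons) < 1) stop("need at least one neuron")
  ar <- extract_window_rates(session, alignment, window, bin_width,
                             neurons = neurons)
  avg <- apply(ar$rate, c(2, 3), mean)           # neurons x bins
  sm <- smooth_and_scale(avg, "gaussian_kernel", width = smooth_ms,
                         bin_width = bin_width)
  nm <- smooth_and_scale(sm, "minmax")
  centers <- ar$bin_edges[-length(ar$bin_edges)] + bin_width / 2
  pk <- centers[apply(nm, 1, which.max)]
  ord <- order(pk)
  list(surface = nm[ord, , drop = FALSE], order = neurons[ord],
       peak_time = pk[ord], centers = centers)
}

# Least-squares fit of y on a family of one-basis-function models
# y ~ a * b_c(t) + c0, choosing the basis candidate (column of B) with the
# smallest SSE. Closed-form normal equations, vectorised over candidates and,
# when Y has several columns (label shuffles), over responses as well.
# Returns list(sse = matrix candidates x responses minimised over candidates
# -> vector, best = candidate index per response).
basis_family_sse <- function(Y, B) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  sy <- colSums(Y)                      # 1 x resp
  syy <- colSums(Y^2)
  sb <- colSums(B)                      # per candidate
  sbb <- colSums(B^2)
  sby <- crossprod(B, Y)                # candidates x responses
  det <- n * sbb - sb^2
  det[det <= 0] <- NA                   # degenerate (constant) basis
  # coefficients: a = (n*sby - sb*sy)/det ; c0 = (sbb*sy - sb*sby)/det
  a <- (n * sby - outer(sb, sy)) / det
  c0 <- (outer(sbb, sy) - sb * sby) / det
  sse <- syy - (a * sby + c0 * rep(sy, each = nrow(sby)))
  sse[is.na(sse)] <- Inf
  sse <- pmax(sse, 0)
  best <- apply(sse, 2, which.min)
  list(sse_min = sse[cbind(best, seq_along(best))], best = best, a = a,
       c0 = c0)
}

ramp_bases <- function(t, model) {
  span <- diff(range(t)) + mean(diff(t))
  switch(model,
    linear = matrix(t, ncol = 1),
    exponential = {
      ks <- c(-1, 1) %o% (10^seq(log10(0.2 / span), log10(8 / span),
                                 length.out = 12))
      sapply(as.numeric(ks), function(k) exp(k * (t - t[1])))
    },
    sigmoidal = {
      ks <- 10^seq(log10(2 / span), log10(40 / span), length.out = 8)
      t0s <- stats::quantile(t, seq(0.1, 0.9, length.out = 9))
      grid <- expand.grid(k = ks, t0 = t0s)
      mapply(function(k, t0) 1 / (1 + exp(-k * (t - t0))),
             grid$k, grid$t0)
    })
}

#' Ramping ("increasing") classification and model fits
#'
#' A neuron is classified as increasing iff (a) its mean rate in the final
#' 600 ms before response onset is at least the peak of its cue-offset-
#' aligned wait profile assessed in 600 ms windows (the same granularity as
#' the endpoint comparison, so bin noise does not inflate the reference), and
#' (b) a paired t-test across correct trials finds the final 600 ms
#' significantly above the initial 600 ms after cue offset (`alpha = 0.05`).
#'
#' Separately, per target duration, the trial-averaged wait activity
#' (cue-offset aligned, 100 ms bins over the guaranteed wait span
#' `[0, 0.8 d)`) is min-max normalised and fit with linear, exponential
#' (`a exp(b t) + c`), and sigmoidal (`L / (1 + exp(-k (t - t0))) + c`)
#' models (least squares; the nonlinear shapes are profiled over a parameter
#' grid with closed-form amplitude/offset). Each model's r-squared is
#' compared to the 95th percentile of the same fit applied to `n_shuffles`
#' random permutations of the time-bin labels (the neuron's own null).
#'
#' @param session A `session_recording`.
#' @param neuron Neuron id.
#' @param alpha Significance level for the paired t-test.
#' @param n_shuffles Bin-label shuffles for the fit null (default 1000).
#' @param bin_ms Bin width for the fitted profiles (default 100).
#' @param seed Optional seed for the shuffles.
#' @return An object of class `ramp_fit`: list with `increasing`, `t_p`,
#'   `mean_initial`, `mean_final`, and `fits` (data.frame: duration, model,
#'   r2, null95, significant).
#' @export
ramping_analysis <- function(session, neuron, alpha = 0.05,
                             n_shuffles = 1000, bin_ms = 100, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  task <- session$task
  tr <- session$trials
  correct <- tr$trial[tr$outcome == "correct"]
  if (length(correct) < 2) stop("need at least 2 paired trials")

  ini <- extract_window_rates(session, "cue_offset", c(0, 600), 600,
                              trials = correct, neurons = neuron)
  fin <- extract_window_rates(session, "response_onset", c(-600, 0), 600,
                              trials = correct, neurons = neuron)
  ri <- ini$rate[, 1, 1]; rf <- fin$rate[, 1, 1]
  tt <- if (stats::sd(rf - ri) == 0) list(p.value = 1) else
    stats::t.test(rf, ri, paired = TRUE, alternative = "greater")

  thr <- task$correct_fraction_threshold
  fits <- list(); peak_profile <- -Inf
  for (d in sort(task$durations)) {
    dt <- tr$trial[tr$outcome == "correct" & tr$duration == d]
    if (length(dt) == 0) next
    span <- thr * d
    ar600 <- extract_window_rates(session, "cue_offset", c(0, span), 600,
                                  trials = dt, neurons = neuron)
    peak_profile <- max(peak_profile, apply(ar600$rate, 3, mean))
    ar <- extract_window_rates(session, "cue_offset", c(0, span), bin_ms,
                               trials = dt, neurons = neuron)
    prof <- apply(ar$rate, 3, mean)
    rng <- range(prof)
    y <- if (diff(rng) == 0) rep(0, length(prof)) else
      (prof - rng[1]) / diff(rng)
    tmid <- ar$bin_edges[-length(ar$bin_edges)] + bin_ms / 2
    ss_tot <- sum((y - mean(y))^2)
    Yn <- replicate(n_shuffles, sample(y))
    for (model in c("linear", "exponential", "sigmoidal")) {
      B <- ramp_bases(tmid, model)
      r2 <- if (ss_tot == 0) 0 else
        1 - basis_family_sse(matrix(y, ncol = 1), B)$sse_min / ss_tot
      null_r2 <- if (ss_tot == 0) rep(0, n_shuffles) else
        1 - basis_family_sse(Yn, B)$sse_min / ss_tot
      q95 <- stats::quantile(null_r2, 0.95, names = FALSE)
      fits[[length(fits) + 1]] <- data.frame(
        duration = d, model = model, r2 = r2, null95 = q95,
        significant = r2 > q95)
    }
  }
  increasing <- mean(rf) >= peak_profile && tt$p.value < alpha
  structure(list(increasing = increasing, t_p = tt$p.value,
                 mean_initial = mean(ri), mean_final = mean(rf),
                 fits = do.call(rbind, fits)),
            class = "ramp_fit")
}

#' Temporal-scaling grid search between two rate profiles
#'
#' Tests whether the longer condition's activity is a time-stretched copy of
#' the shorter condition's. For each candidate factor `f`, the long profile's
#' time axis is compressed by `f` (value at time `t` becomes the long
#' profile's value at `t / f`, linearly interpolated), resampled onto the
#' short profile's 10 ms bin centers over the overlapping span, and the mean
#' squared error against the short profile is computed. The optimal factor is
#' the MSE argmin; for an exact `1/f`-fold stretch the search recovers `f`
#' (e.g. 0.5 for a two-fold, 0.25 for a four-fold stretch).
#'
#' @param profile_long,profile_short Numeric vectors of binned rates
#'   (`bin_ms` bins starting at 0).
#' @param factors Candidate factor grid (default 0.05 to 3 in steps of 0.05;
#'   the coarser printed grids cannot represent sub-0.3 optima).
#' @param bin_ms Bin width (ms, default 10).
#' @param expected Analytic expectation for the pair (e.g. 0.5 or 0.25),
#'   used for the `within_10pct` flag; `NA` to skip.
#' @return An object of class `scaling_result`: list with `factors`, `mse`,
#'   `optimal`, `min_mse`, `expected`, `within_10pct`.
#' @export
temporal_scaling <- function(profile_long, profile_short,
                             factors = seq(0.05, 3, by = 0.05),
                             bin_ms = 10, expected = NA_real_) {
  yl <- as.numeric(profile_long); ys <- as.numeric(profile_short)
  tl <- (seq_along(yl) - 0.5) * bin_ms
  ts <- (seq_along(ys) - 0.5) * bin_ms
  span_long <- length(yl) * bin_ms
  mse <- rep(NA_real_, length(factors))
  for (i in seq_along(factors)) {
    f <- factors[i]
    keep <- ts <= f * span_long
    if (sum(keep) < 2) next                       # < 2 overlapping bins
    scaled <- stats::approx(tl, yl, xout = ts[keep] / f, rule = 2)$y
    mse[i] <- mean((scaled - ys[keep])^2)
  }
  if (all(is.na(mse))) stop("no factor produced >= 2 overlapping bins")
  opt <- factors[which.min(mse)]
  structure(list(factors = factors, mse = mse, optimal = opt,
                 min_mse = min(mse, na.rm = TRUE), expected = expected,
                 within_10pct = if (is.na(expected)) NA else
                   abs(opt - expected) <= 0.1 * expected),
            class = "scaling_result")
}

#' Per-neuron wait profiles for the temporal-scaling analysis
#'
#' Extracts the trial-averaged, 10 ms-binned, cue-offset-aligned activity of
#' a neuron over the first `0.8 d` of the wait for each duration (the spans
#' the scaling comparison uses: 4800 to 2400/1200 ms and 2400 to 1200 ms).
#'
#' @param session A `session_recording`.
#' @param neuron Neuron id.
#' @param bin_ms Bin width (ms, default 10).
#' @param smooth_ms Gaussian smoothing SD (ms, default 200; 0 for none).
#' @return Named list of numeric profiles, one per duration.
#' @export
scaling_profiles <- function(session, neuron, bin_ms = 10, smooth_ms = 200) {
  task <- session$task
  thr <- task$correct_fraction_threshold
  out <- lapply(sort(task$durations), function(d) {
    tr <- session$trials
    dt <- tr$trial[tr$outcome == "correct" & tr$duration == d]
    ar <- extract_window_rates(session, "cue_offset", c(0, thr * d), bin_ms,
                               trials = dt, neurons = neuron)
    prof <- apply(ar$rate, 3, mean)
    if (smooth_ms > 0) prof <- gauss_smooth_vec(prof, smooth_ms / bin_ms)
    prof
  })
  stats::setNames(out, as.character(sort(task$durations)))
}
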