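#' Generate scalar-expectancy reaction times
#'
#' Draws reaction times (ms on the wait clock, i.e. since cue offset) for `n`
#' trials per target duration. Non-opt-out RTs are Gaussian with mean
#' `duration * (1 + mean_offset_fraction)` and SD `weber_fraction * mean`,
#' truncated at zero by resampling. On the longest duration, each trial is an
#' early opt-out (RT uniform on [0, 400) ms) with probability `optout_prob`.
#' Outcomes are assigned with [label_trial()].
#'
#' @param task A [task_config()].
#' @param model A [behavior_model()].
#' @param n Trials per duration.
#' @param seed Optional integer seed.
#' @return data.frame with columns `duration`, `rt_ms`, `outcome`.
#' @export
generate_behavioral_rts <- function(task, model, n, seed = NULL) {
  stopifnot(inherits(task, "task_config"), inherits(model, "behavior_model"))
  if (n < 1) stop("`n` must be >= 1 per duration")
  if (!is.null(seed)) set.seed(seed)
  longest <- max(task$durations)
  out <- lapply(task$durations, function(d) {
    mu <- d * (1 + model$mean_offset_fraction)
    sigma <- model$weber_fraction * mu
    rt <- rnorm(n, mu, sigma)
    # truncate at zero by resampling (keeps the distribution unimodal)
    bad <- which(rt <= 0)
    while (length(bad) > 0) {
      rt[bad] <- rnorm(length(bad), mu, sigma)
      bad <- bad[rt[bad] <= 0]
    }
    if (d == longest && model$optout_prob > 0) {
      oo <- runif(n) < model$optout_prob
      rt[oo] <- runif(sum(oo), 0, 400)
    }
    data.frame(duration = d, rt_ms = rt)
  })
  out <- do.call(rbind, out)
  out$outcome <- label_trial(out$rt_ms, out$duration, task)
  out
}

#' Sample a ground-truth rate profile on a 1 ms grid
#'
#' Evaluates a [rate_profile_spec()] for one trial condition on a 1 ms grid
#' running from the ready event (`task$ready_ms`, default -900 ms) to the end
#' of the trial (`cue_ms + 2 * duration + 500`, covering the full response
#' window plus the post-response margin), times relative to cue onset. Ramps
#' hold their maximum after the target time; scaled templates clamp at their
#' final value.
#' Condition-dependent gains (duration or protocol) switch on at cue onset,
#' when the cue first reveals the condition, and persist through the wait.
#' Shape parameters are interpreted on the wait clock (ms since cue offset).
#' Rates that would go negative after composition are clipped to 0 with a
#' warning.
#'
#' @param spec A [rate_profile_spec()].
#' @param duration Target duration of the condition (ms).
#' @param protocol Protocol label of the condition (used by
#'   `protocol_modulated`).
#' @param task A [task_config()].
#' @return An object of class `rate_profile`: list with `time` (ms, grid left
#'   edges), `rate` (Hz), `duration`.
#' @export
make_rate_profile <- function(spec, duration, protocol = "color",
                              task = task_config()) {
  stopifnot(inherits(spec, "rate_profile_spec"))
  tt <- seq(task$ready_ms, task$cue_ms + 2 * duration + 500 - 1)
  w <- tt - task$cue_ms                     # wait clock
  in_trial <- tt >= 0                       # cue onset onward
  r <- rep(spec$baseline, length(tt))

  gain_for <- function(g, key) {
    if (!is.null(names(g))) {
      if (!key %in% names(g)) 0 else unname(g[[key]])
    } else g[[1]]
  }

  switch(spec$archetype,
    untuned = NULL,
    duration_tuned = {
      r[in_trial] <- r[in_trial] + gain_for(spec$gain, as.character(duration))
    },
    protocol_modulated = {
      r[in_trial] <- r[in_trial] + gain_for(spec$gain, protocol)
    },
    time_field = {
      # a named gain vector makes the field's amplitude duration-specific
      # (a transient, dynamic duration code); a scalar gain is shared
      g <- gain_for(spec$gain, as.character(duration))
      r <- r + g * exp(-(w - spec$center)^2 / (2 * spec$width^2))
    },
    ramp_linear = {
      ramp <- w >= spec$onset & w <= duration
      frac <- (w[ramp] - spec$onset) / (duration - spec$onset)
      r[ramp] <- r[ramp] + spec$gain[[1]] * frac
      r[w > duration] <- r[w > duration] + spec$gain[[1]]
    },
    ramp_exponential = {
      k <- if (is.null(spec$steepness)) 3 / (duration - spec$onset) else spec$steepness
      ramp <- w >= spec$onset & w <= duration
      u <- w[ramp] - spec$onset
      frac <- expm1(k * u) / expm1(k * (duration - spec$onset))
      r[ramp] <- r[ramp] + spec$gain[[1]] * frac
      r[w > duration] <- r[w > duration] + spec$gain[[1]]
    },
    ramp_sigmoidal = {
      k <- if (is.null(spec$steepness)) 10 / (duration - spec$onset) else spec$steepness
      mid <- spec$onset + spec$midpoint_fraction * (duration - spec$onset)
      s <- function(x) 1 / (1 + exp(-k * (x - mid)))
      ramp <- w >= spec$onset & w <= duration
      frac <- (s(w[ramp]) - s(spec$onset)) / (s(duration) - s(spec$onset))
      r[ramp] <- r[ramp] + spec$gain[[1]] * frac
      r[w > duration] <- r[w > duration] + spec$gain[[1]]
    },
    scaled_template = {
      # profile for duration d is the reference template stretched by d/d_ref
      wait <- w >= 0
      tau <- w[wait] * spec$d_reference / duration
      n_t <- length(spec$template)
      r[wait] <- stats::approx(seq(0, spec$d_reference, length.out = n_t),
                               spec$template, xout = tau, rule = 2)$y
    }
  )
  if (any(r < 0)) {
    warning("negative rates after composition clipped to 0")
    r[r < 0] <- 0
  }
  structure(list(time = tt, rate = r, duration = duration,
                 archetype = spec$archetype),
            class = "rate_profile")
}

#' Sample spike trains from a rate profile (inhomogeneous Poisson)
#'
#' Spikes are drawn per trial by thinning: homogeneous Poisson candidates at
#' the profile's maximum rate are accepted with probability `rate(t) / max`.
#' The expected spike count per trial equals the integral of the rate over the
#' profile span.
#'
#' @param profile A `rate_profile` from [make_rate_profile()].
#' @param n_trials Number of trials.
#' @param seed Optional integer seed.
#' @return data.frame with columns `trial` (1..n_trials) and `time_ms`
#'   (relative to cue onset), sorted by trial then time.
#' @export
sample_spikes <- function(profile, n_trials, seed = NULL) {
  stopifnot(inherits(profile, "rate_profile"), n_trials >= 1)
  if (!is.null(seed)) set.seed(seed)
  rate <- profile$rate
  t0 <- profile$time[1]
  span_ms <- length(rate)
  rmax <- max(rate)
  if (rmax <= 0) {
    return(data.frame(trial = integer(0), time_ms = numeric(0)))
  }
  n_cand <- rpois(n_trials, rmax * span_ms / 1000)
  total <- sum(n_cand)
  if (total == 0) {
    return(data.frame(trial = integer(0), time_ms = numeric(0)))
  }
  trial <- rep.int(seq_len(n_trials), n_cand)
  tcand <- t0 + runif(total, 0, span_ms)
  keep <- runif(total) < rate[floor(tcand - t0) + 1L] / rmax
  out <- data.frame(trial = trial[keep], time_ms = tcand[keep])
  out[order(out$trial, out$time_ms), , drop = FALSE]
}

#' Generate a complete synthetic session
#'
#' Builds one session in which every neuron of `population` is observed on
#' every trial. Per cue (protocol x duration), reaction times are drawn from
#' the behavioral model until `n_correct_trials_per_cue` correct trials have
#' accrued (error trials are retained, emulating the delayed-retry protocol).
#' Spike trains are then emitted per neuron from its archetype's rate profile
#' for the trial's condition; each trial's spikes are truncated at
#' `response + 500` ms.
#'
#' @param task A [task_config()].
#' @param behavior A [behavior_model()].
#' @param population List of [rate_profile_spec()] objects, one per neuron.
#' @param seed Integer seed.
#' @param max_attempts_factor Abort generation if a cue needs more than
#'   `max_attempts_factor * n_correct_trials_per_cue` trials.
#' @return An object of class `session_recording`: list with `trials`,
#'   `spikes`, `neurons` data.frames, the ground-truth `specs` list, and the
#'   `task`.
#' @export
generate_session <- function(task, behavior, population, seed = 1,
                             max_attempts_factor = 60) {
  stopifnot(inherits(task, "task_config"), inherits(behavior, "behavior_model"))
  if (length(population) == 0) stop("`population` must be non-empty")
  set.seed(seed)
  n_goal <- task$n_correct_trials_per_cue
  longest <- max(task$durations)

  rows <- list()
  for (proto in task$protocols) {
    for (d in task$durations) {
      mu <- d * (1 + behavior$mean_offset_fraction)
      sigma <- behavior$weber_fraction * mu
      got <- 0L; attempts <- 0L
      while (got < n_goal) {
        attempts <- attempts + 1L
        if (attempts > max_attempts_factor * n_goal) {
          stop("could not generate ", n_goal, " correct trials for cue ",
               proto, "/", d, " (opt-out/variability too high)")
        }
        if (d == longest && runif(1) < behavior$optout_prob) {
          rt <- runif(1, 0, 400)
        } else {
          rt <- rnorm(1, mu, sigma)
          while (rt <= 0) rt <- rnorm(1, mu, sigma)
        }
        outc <- label_trial(rt, d, task)
        if (outc == "correct") got <- got + 1L
        rows[[length(rows) + 1L]] <- data.frame(
          protocol = proto, duration = d, rt_ms = rt, outcome = outc)
      }
    }
  }
  trials <- do.call(rbind, rows)
  trials <- trials[sample.int(nrow(trials)), , drop = FALSE]  # interleave cues
  trials$trial <- seq_len(nrow(trials))
  trials$cue <- paste(trials$protocol, trials$duration, sep = "_")
  trials$ready <- task$ready_ms
  trials$cue_on <- 0
  trials$cue_off <- task$cue_ms
  # late errors have no in-window response; the trial ends at the window end
  trials$response <- task$cue_ms + pmin(trials$rt_ms, 2 * trials$duration)
  trials <- trials[, c("trial", "cue", "protocol", "duration", "ready",
                       "cue_on", "cue_off", "response", "rt_ms", "outcome")]
  rownames(trials) <- NULL

  spikes <- vector("list", length(population) * length(task$protocols) *
                     length(task$durations))
  k <- 0L
  for (j in seq_along(population)) {
    for (proto in task$protocols) {
      for (d in task$durations) {
        idx <- which(trials$protocol == proto & trials$duration == d)
        if (length(idx) == 0) next
        prof <- make_rate_profile(population[[j]], d, proto, task)
        sp <- sample_spikes(prof, length(idx))
        if (nrow(sp) == 0) next
        sp$trial <- trials$trial[idx][sp$trial]
        cutoff <- (trials$response[match(sp$trial, trials$trial)]) + 500
        sp <- sp[sp$time_ms <= cutoff, , drop = FALSE]
        sp$neuron <- j
        k <- k + 1L
        spikes[[k]] <- sp[, c("neuron", "trial", "time_ms")]
      }
    }
  }
  spikes <- if (k > 0) do.call(rbind, spikes[seq_len(k)]) else
    data.frame(neuron = integer(0), trial = integer(0), time_ms = numeric(0))
  spikes <- spikes[order(spikes$neuron, spikes$trial, spikes$time_ms), ,
                   drop = FALSE]
  rownames(spikes) <- NULL

  neurons <- data.frame(
    neuron = seq_along(population),
    archetype = vapply(population, `[[`, "", "archetype"),
    preferred = vapply(population, function(s)
      as.numeric(s$preferred %||% NA_real_), numeric(1))
  )

  structure(list(trials = trials, spikes = spikes, neurons = neurons,
                 specs = population, task = task),
            class = "session_recording")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.session_recording <- function(x, ...) {
  cat("session_recording:", nrow(x$trials), "trials,",
      nrow(x$neurons), "neurons,", nrow(x$spikes), "spikes\n")
  print(table(outcome = x$trials$outcome, duration = x$trials$duration))
  invisible(x)
}

#' Write a session to plain-text files
#'
#' Writes `trials.csv`, `spikes.csv`, and (when ground-truth specs are
#' present) `neurons.json` under `dir`.
#'
#' @param session A `session_recording`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "session_recording"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(session$trials, file.path(dir, "trials.csv"),
                   row.names = FALSE)
  utils::write.csv(session$spikes, file.path(dir, "spikes.csv"),
                   row.names = FALSE)
  if (!is.null(session$specs) && requireNamespace("jsonlite", quietly = TRUE)) {
    gt <- lapply(session$specs, function(s) s[!vapply(s, is.null, TRUE)])
    jsonlite::write_json(gt, file.path(dir, "neurons.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Read a session from `trials.csv` / `spikes.csv`
#'
#' @param dir Directory containing the two CSV tables.
#' @param task A [task_config()] describing the protocol.
#' @return A `session_recording` (without ground-truth specs unless
#'   `neurons.json` is present and jsonlite is available).
#' @export
read_session <- function(dir, task = task_config()) {
  trials <- utils::read.csv(file.path(dir, "trials.csv"))
  spikes <- utils::read.csv(file.path(dir, "spikes.csv"))
  if (!all(spikes$trial %in% trials$trial)) {
    stop("spike table references trials absent from the trial table")
  }
  neurons <- data.frame(neuron = sort(unique(spikes$neuron)))
  structure(list(trials = trials, spikes = spikes, neurons = neurons,
                 specs = NULL, task = task),
            class = "session_recording")
}
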