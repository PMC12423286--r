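# Builders for small ground-truth populations and sessions used across files.
# Sessions are cached per test file so repeated tests don't regenerate them.

.session_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .session_cache)) {
    assign(key, force(expr), envir = .session_cache)
  }
  get(key, envir = .session_cache)
}

# n_per_pref duration-tuned neurons per preferred duration
tuned_population <- function(n_per_pref = 4, baseline = 4, gain = 10,
                             durations = c(1500, 3000, 6000)) {
  unlist(lapply(durations, function(d) {
    replicate(n_per_pref,
              rate_profile_spec("duration_tuned", baseline = baseline,
                                gain = stats::setNames(gain, d),
                                preferred = d),
              simplify = FALSE)
  }), recursive = FALSE)
}

untuned_population <- function(n = 12, baseline = 5) {
  replicate(n, rate_profile_spec("untuned", baseline = baseline),
            simplify = FALSE)
}

# time-field neurons whose centers tile [0, span]
sequence_population <- function(centers, baseline = 2, gain = 25,
                                width = 120) {
  lapply(centers, function(cc)
    rate_profile_spec("time_field", baseline = baseline, gain = gain,
                      center = cc, width = width))
}

quiet_session <- function(task, bm, pop, seed) {
  suppressWarnings(generate_session(task, bm, pop, seed = seed))
}

# hand-built session from explicit trial/spike tables (exact control over
# counts and rates for boundary tests)
manual_session <- function(trials, spikes, task = task_config()) {
  neurons <- data.frame(neuron = sort(unique(spikes$neuron)))
  structure(list(trials = trials, spikes = spikes, neurons = neurons,
                 specs = NULL, task = task),
            class = "session_recording")
}

# all distinct permutations of 1..n as rows (independent enumeration helper
# for trend-test oracles)
gtools_permutations <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- gtools_permutations(n - 1)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  out
}

manual_trials <- function(n, duration = 1500, protocol = "color",
                          rt = NULL, outcome = "correct",
                          task = task_config()) {
  rt <- if (is.null(rt)) rep(duration * 1.1, n) else rep_len(rt, n)
  data.frame(trial = seq_len(n),
             cue = paste(protocol, duration, sep = "_"),
             protocol = protocol, duration = duration,
             ready = task$ready_ms, cue_on = 0, cue_off = task$cue_ms,
             response = task$cue_ms + rt, rt_ms = rt,
             outcome = rep_len(outcome, n))
}
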