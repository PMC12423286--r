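#' Task configuration for the time-estimation protocol
#'
#' Describes the delayed-response interval-timing task: on each trial one of
#' six visual cues (two stimulus protocols, `color` and `shape`, times three
#' target durations) instructs a minimum wait duration. The subject must hold
#' position for at least the target duration after cue offset and then respond
#' within a response ("go") window equal in length to the target duration.
#' A response is scored correct from 20 % before the target time onward
#' (`correct_fraction_threshold = 0.8`, i.e. earliest-correct times of
#' 1200 / 2400 / 4800 ms for the default durations).
#'
#' All times in the package are milliseconds relative to cue onset. The cue is
#' shown during `[0, cue_ms)`, the pre-cue period during `[-pre_cue_ms, 0)`,
#' and the ready event is placed at `ready_ms` (default -900, i.e. 600 ms of
#' in-position ready time before the pre-cue period). The wait clock used for
#' responses starts at cue offset (`cue_ms`).
#'
#' @param durations Target durations in ms, strictly increasing.
#' @param protocols Stimulus protocol labels.
#' @param pre_cue_ms Pre-cue period length (ms).
#' @param cue_ms Cue presentation length (ms).
#' @param ready_ms Time of the ready event relative to cue onset (ms, negative).
#' @param correct_fraction_threshold Fraction of the target duration from which
#'   a response counts as correct (0.8 per the task's scoring rule).
#' @param n_correct_trials_per_cue Number of correct trials to generate per cue
#'   in synthetic sessions.
#' @return An object of class `task_config`.
#' @export
task_config <- function(durations = c(1500, 3000, 6000),
                        protocols = c("color", "shape"),
                        pre_cue_ms = 300,
                        cue_ms = 600,
                        ready_ms = -900,
                        correct_fraction_threshold = 0.8,
                        n_correct_trials_per_cue = 15) {
  if (length(durations) < 2 || any(diff(durations) <= 0)) {
    stop("`durations` must be strictly increasing")
  }
  if (pre_cue_ms <= 0 || cue_ms <= 0) stop("periods must be positive")
  if (ready_ms >= -pre_cue_ms) stop("`ready_ms` must precede the pre-cue period")
  if (correct_fraction_threshold <= 0 || correct_fraction_threshold > 1) {
    stop("`correct_fraction_threshold` must be in (0, 1]")
  }
  structure(list(
    durations = as.numeric(durations),
    protocols = as.character(protocols),
    pre_cue_ms = pre_cue_ms,
    cue_ms = cue_ms,
    ready_ms = ready_ms,
    correct_fraction_threshold = correct_fraction_threshold,
    n_correct_trials_per_cue = n_correct_trials_per_cue
  ), class = "task_config")
}

#' Earliest response time scored as correct, per duration
#'
#' @param task A [task_config()].
#' @return Named numeric vector (ms on the wait clock), e.g. 1200/2400/4800.
#' @export
earliest_correct <- function(task) {
  stats::setNames(task$correct_fraction_threshold * task$durations,
                  as.character(task$durations))
}

#' Behavioral generative model for reaction times
#'
#' Scalar-expectancy behavior: reaction times (measured from cue offset) are
#' Gaussian around a point just beyond the target duration, with a standard
#' deviation proportional to the mean (constant Weber fraction). On the longest
#' duration the subject sometimes opts out early (response < 400 ms into the
#' wait), trading the timeout penalty against the chance of a shorter next
#' trial.
#'
#' @param weber_fraction SD / mean of the reaction-time distribution.
#' @param mean_offset_fraction Relative overshoot of the target duration
#'   (mean RT = duration * (1 + mean_offset_fraction)).
#' @param optout_prob Probability of an early abort (< 400 ms) on the longest
#'   duration.
#' @return An object of class `behavior_model`.
#' @export
behavior_model <- function(weber_fraction = 0.2,
                           mean_offset_fraction = 0.1,
                           optout_prob = 0.3) {
  if (weber_fraction < 0) stop("`weber_fraction` must be non-negative")
  if (optout_prob < 0 || optout_prob > 1) stop("`optout_prob` must be in [0, 1]")
  structure(list(
    weber_fraction = weber_fraction,
    mean_offset_fraction = mean_offset_fraction,
    optout_prob = optout_prob
  ), class = "behavior_model")
}

#' Ground-truth firing-rate archetype for a synthetic neuron
#'
#' Parameterises a neuron's instantaneous firing rate as a function of time
#' and trial condition. Archetypes mirror the response classes the analyses
#' probe for:
#' \describe{
#'   \item{`duration_tuned`}{baseline plus a per-duration gain, constant over
#'     the wait period (categorical tuning to a preferred duration).}
#'   \item{`time_field`}{baseline plus a Gaussian bump at a characteristic
#'     moment of the wait (sequence / "time cell" coding).}
#'   \item{`ramp_linear`, `ramp_exponential`, `ramp_sigmoidal`}{baseline before
#'     `onset`, then a monotone rise reaching `baseline + gain` at the target
#'     response time (climbing / accumulator-like activity).}
#'   \item{`scaled_template`}{an arbitrary template defined over a reference
#'     duration, time-stretched by `duration / d_reference` for other
#'     durations (temporally scaling activity).}
#'   \item{`protocol_modulated`}{baseline plus a per-protocol gain (sensory,
#'     cue-bound activity).}
#'   \item{`untuned`}{constant baseline.}
#' }
#'
#' Shape parameters (`center`, `width`, `onset`, ...) are on the wait clock,
#' i.e. ms since cue offset.
#'
#' @param archetype One of the archetype names above.
#' @param baseline Baseline rate (Hz), >= 0.
#' @param gain Gain (Hz). For `duration_tuned` a vector named by duration; for
#'   `protocol_modulated` a vector named by protocol; otherwise a scalar.
#' @param center,width Time-field centre and SD (ms since cue offset).
#' @param onset Ramp onset (ms since cue offset).
#' @param steepness Exponential growth constant (1/ms) or sigmoid slope (1/ms).
#' @param midpoint_fraction Sigmoid midpoint as a fraction of the wait.
#' @param template Numeric vector of rate samples (Hz) defining the
#'   `scaled_template` profile over `[0, d_reference)` on a 1 ms grid; recycled
#'   by interpolation.
#' @param d_reference Reference duration (ms) for `scaled_template`.
#' @param preferred Preferred duration (ms), for bookkeeping in recovery tests.
#' @return An object of class `rate_profile_spec`.
#' @export
rate_profile_spec <- function(archetype = c("duration_tuned", "time_field",
                                            "ramp_linear", "ramp_exponential",
                                            "ramp_sigmoidal", "scaled_template",
                                            "protocol_modulated", "untuned"),
                              baseline = 5,
                              gain = 10,
                              center = 600, width = 200,
                              onset = 0,
                              steepness = NULL,
                              midpoint_fraction = 0.5,
                              template = NULL, d_reference = 1500,
                              preferred = NA_real_) {
  archetype <- match.arg(archetype)
  if (baseline < 0) stop("`baseline` must be non-negative")
  if (archetype == "scaled_template" && is.null(template)) {
    stop("`scaled_template` requires a `template`")
  }
  if (!is.null(template) && any(template < 0)) stop("template rates must be >= 0")
  structure(list(
    archetype = archetype, baseline = baseline, gain = gain,
    center = center, width = width, onset = onset,
    steepness = steepness, midpoint_fraction = midpoint_fraction,
    template = template, d_reference = d_reference,
    preferred = preferred
  ), class = "rate_profile_spec")
}
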