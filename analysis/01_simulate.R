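#!/usr/bin/env Rscript
# Simulate one synthetic recording session with a mixed population of neuron
# archetypes (duration-tuned, time-field sequence, ramping, temporally
# scaling, protocol-sensitive, untuned) and scalar-expectancy behavior, and
# write it to results/session/ as plain-text tables.
#
# This session is the shared input of the downstream analysis drivers
# (02-05). All analyses re-derive everything from these tables.

library(crowtime)

seed <- 20260917
out_dir <- "results/session"

task <- task_config(n_correct_trials_per_cue = 35)
behavior <- behavior_model(weber_fraction = 0.2, mean_offset_fraction = 0.1,
                           optout_prob = 0.3)

set.seed(seed)
durs <- c(1500, 3000, 6000)
population <- c(
  # categorical duration tuning, the dominant motif in the data this
  # pipeline targets
  unlist(lapply(durs, function(d) {
    replicate(12, rate_profile_spec("duration_tuned",
                                    baseline = runif(1, 2, 6),
                                    gain = stats::setNames(runif(1, 6, 14), d),
                                    preferred = d), simplify = FALSE)
  }), recursive = FALSE),
  # a sequence of transient time fields tiling the early wait
  lapply(seq(50, 1350, length.out = 16), function(cc)
    rate_profile_spec("time_field", baseline = 2, gain = runif(1, 10, 22),
                      center = cc, width = runif(1, 90, 220))),
  # a minority of climbing neurons
  replicate(6, rate_profile_spec("ramp_linear", baseline = 2,
                                 gain = runif(1, 6, 14), onset = 0),
            simplify = FALSE),
  # one temporally scaling cell (its long-duration profile is a stretched
  # copy of its short-duration profile)
  list(rate_profile_spec("scaled_template", baseline = 3,
                         template = 3 + 12 * exp(-((0:1500) - 600)^2 /
                                                   (2 * 180^2)),
                         d_reference = 1500)),
  # cue-bound (protocol) cells and untuned background
  replicate(6, rate_profile_spec("protocol_modulated", baseline = 3,
                                 gain = c(color = 6, shape = 0)),
            simplify = FALSE),
  replicate(15, rate_profile_spec("untuned", baseline = runif(1, 1, 9)),
            simplify = FALSE))

session <- suppressWarnings(generate_session(task, behavior, population,
                                             seed = seed %% 100000))
write_session(session, out_dir)

cat("Simulated session:\n")
print(session)
cat("\nNeuron archetypes:\n")
print(table(session$neurons$archetype))
cat("\nWritten to", out_dir, "\n")
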