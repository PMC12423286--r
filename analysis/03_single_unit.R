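#!/usr/bin/env Rscript
# Single-unit statistics on the simulated session: inclusion filtering,
# two-way ANOVA selectivity in the cue-offset- and response-onset-aligned
# windows, preferred durations and tuning widths, the tuning-width trend
# test, the peak-sorted sequence surface, ramping classification, and the
# temporal-scaling grid search. Writes results/units.csv and
# results/scaling.csv.

library(crowtime)

session <- read_session("results/session")
neurons <- session$neurons$neuron
task <- session$task

included <- neurons[vapply(neurons, function(j)
  isTRUE(neuron_inclusion(session, j)), logical(1))]
cat(sprintf("%d / %d neurons pass inclusion\n", length(included),
            length(neurons)))

win_cue <- extract_window_rates(session, "cue_offset", c(0, 1200), 1200,
                                neurons = included)
win_resp <- extract_window_rates(session, "response_onset", c(-1200, 0), 1200,
                                 neurons = included)

rows <- lapply(seq_along(included), function(i) {
  a_cue <- two_way_anova(win_cue$rate[, i, 1], win_cue$meta$duration,
                         win_cue$meta$protocol)
  a_resp <- two_way_anova(win_resp$rate[, i, 1], win_resp$meta$duration,
                          win_resp$meta$protocol)
  cl <- classify_time_neuron(a_cue, a_resp)
  tun <- tryCatch(tuning_curve(a_cue$duration_means), error = function(e) NULL)
  data.frame(neuron = included[i],
             class_cue = a_cue$classification,
             class_resp = a_resp$classification,
             p_dur_cue = a_cue$p[["duration"]],
             time_cue = cl$time_cue, time_resp = cl$time_resp,
             overlap = cl$overlap,
             preferred_cue = cl$preferred_cue,
             preferred_resp = cl$preferred_resp,
             width_cue = if (is.null(tun)) NA else tun$weighted_sd,
             monotonic = if (is.null(tun)) NA else tun$monotonic)
})
units <- do.call(rbind, rows)
dir.create("results", showWarnings = FALSE)
write.csv(units, "results/units.csv", row.names = FALSE)

time_cue <- units$neuron[units$time_cue]
cat(sprintf("\nTime neurons: %d cue-offset aligned, %d response aligned, %d both\n",
            sum(units$time_cue), sum(units$time_resp), sum(units$overlap)))
cat("Preferred durations (cue-offset time neurons):\n")
print(table(units$preferred_cue[units$time_cue]))

# tuning width increases with preferred duration (trend test across groups)
grp <- split(units$width_cue[units$time_cue],
             units$preferred_cue[units$time_cue])
grp <- grp[lengths(grp) > 0]
if (length(grp) >= 2) {
  jt <- jonckheere_terpstra(grp)
  cat(sprintf("\nTuning width vs duration trend: T_JT = %.1f, z = %.2f, p = %.4g\n",
              jt$statistic, jt$z, jt$p))
}

# sequence surface of the time neurons
if (length(time_cue) > 1) {
  ss <- sequence_surface(session, time_cue, "cue_offset", c(0, 1200))
  cat(sprintf("\nSequence surface: %d neurons, peaks spanning %d-%d ms\n",
              nrow(ss$surface), min(ss$peak_time), max(ss$peak_time)))
}

# ramping: climbing activity toward the response
ramp <- vapply(included, function(j) {
  rf <- ramping_analysis(session, j, n_shuffles = 200, seed = 1000 + j)
  c(increasing = rf$increasing,
    linear_sig = any(rf$fits$significant[rf$fits$model == "linear"]))
}, logical(2))
cat(sprintf("\nIncreasing neurons: %d; with significant linear fit: %d\n",
            sum(ramp["increasing", ]),
            sum(ramp["increasing", ] & ramp["linear_sig", ])))

# temporal scaling between durations (10 ms bins over the guaranteed waits)
scaling <- do.call(rbind, lapply(included, function(j) {
  prof <- scaling_profiles(session, j)
  rbind(
    data.frame(neuron = j, pair = "3000->1500", expected = 0.5,
               optimal = temporal_scaling(prof[["3000"]], prof[["1500"]],
                                          expected = 0.5)$optimal),
    data.frame(neuron = j, pair = "6000->3000", expected = 0.5,
               optimal = temporal_scaling(prof[["6000"]], prof[["3000"]],
                                          expected = 0.5)$optimal),
    data.frame(neuron = j, pair = "6000->1500", expected = 0.25,
               optimal = temporal_scaling(prof[["6000"]], prof[["1500"]],
                                          expected = 0.25)$optimal))
}))
scaling$within_10pct <- abs(scaling$optimal - scaling$expected) <=
  0.1 * scaling$expected
write.csv(scaling, "results/scaling.csv", row.names = FALSE)
cat("\nTemporal scaling: fraction of neurons within 10% of the expected factor\n")
print(aggregate(within_10pct ~ pair, scaling, mean))
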