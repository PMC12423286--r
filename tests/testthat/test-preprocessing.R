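test_that("trial labeling implements the 20%-early rule", {
  expect_equal(label_trial(1300, 1500), "correct")
  expect_equal(label_trial(1200, 1500), "correct")       # boundary inclusive
  expect_equal(label_trial(2500, 6000), "early_error")
  expect_equal(label_trial(NA, 3000), "late_error")
  expect_equal(label_trial(6500, 3000), "late_error")    # past the window
  expect_equal(label_trial(300, 6000), "aborted")        # opt-out
  expect_equal(label_trial(1199, 1500), "aborted")
  expect_equal(label_trial(c(1300, 2500, 4900), c(1500, 6000, 6000)),
               c("correct", "early_error", "correct"))
  expect_error(label_trial(-5, 1500), "negative")
  expect_error(label_trial(1000, 2000), "duration")

  # partition: every trial receives exactly one outcome
  set.seed(1)
  rt <- c(runif(300, 0, 13000), rep(NA, 10))
  d <- sample(c(1500, 3000, 6000), 310, replace = TRUE)
  out <- label_trial(rt, d)
  expect_true(all(out %in% c("correct", "early_error", "late_error",
                             "aborted")))
  expect_equal(length(out), 310L)
})

test_that("neuron inclusion applies both criteria with inclusive boundaries", {
  task <- task_config()
  # 8 correct trials per each of the 6 cues
  blocks <- list(); id <- 0
  for (p in c("color", "shape")) for (d in c(1500, 3000, 6000)) {
    b <- manual_trials(8, duration = d, protocol = p)
    b$trial <- b$trial + id; id <- id + 8
    blocks[[length(blocks) + 1]] <- b
  }
  trials <- do.call(rbind, blocks)

  # composite window is [-300, 1800): 2.1 s per trial, 48 trials = 100.8 s;
  # 51 spikes -> 0.506 Hz (just above), 50 -> 0.496 Hz (just below)
  mk_spikes <- function(n) {
    data.frame(neuron = 1, trial = rep_len(trials$trial, n),
               time_ms = rep(500, n))
  }
  ses_in <- manual_session(trials, mk_spikes(51), task)
  ses_out <- manual_session(trials, mk_spikes(50), task)
  expect_true(neuron_inclusion(ses_in, 1))
  r <- neuron_inclusion(ses_out, 1)
  expect_false(r)
  expect_equal(attr(r, "reasons"), "rate")

  # one cue short of trials
  trials7 <- trials[-1, ]
  ses7 <- manual_session(trials7, mk_spikes(300), task)
  r7 <- neuron_inclusion(ses7, 1)
  expect_false(r7)
  expect_equal(attr(r7, "reasons"), "trials")

  # silent neuron fails on rate
  ses_sil <- manual_session(trials,
                            data.frame(neuron = 1, trial = 1,
                                       time_ms = 5000), task)
  rs <- neuron_inclusion(ses_sil, 1)
  expect_false(rs)
  expect_true("rate" %in% attr(rs, "reasons"))
})

test_that("window rate extraction counts half-open bins in Hz", {
  task <- task_config()
  trials <- manual_trials(1)
  spikes <- data.frame(neuron = 1, trial = 1,
                       time_ms = task$cue_ms + c(100, 500, 900))
  ses <- manual_session(trials, spikes, task)
  ar <- extract_window_rates(ses, "cue_offset", c(0, 1200), 1200)
  expect_equal(ar$rate[1, 1, 1], 3 / 1.2)         # 2.5 Hz

  # empty window -> 0 Hz everywhere
  ar0 <- extract_window_rates(ses, "cue_offset", c(-1200, 0)+(-300), 300)
  expect_true(all(ar0$rate == 0))

  # spike exactly at the window end is excluded (half-open bins)
  sp_edge <- data.frame(neuron = 1, trial = 1, time_ms = task$cue_ms + 1200)
  ar_e <- extract_window_rates(manual_session(trials, sp_edge, task),
                               "cue_offset", c(0, 1200), 100)
  expect_equal(sum(ar_e$rate), 0)

  # count conservation under binning
  set.seed(2)
  sp <- data.frame(neuron = 1, trial = 1,
                   time_ms = runif(57, task$cue_ms, task$cue_ms + 1200))
  ar_c <- extract_window_rates(manual_session(trials, sp, task),
                               "cue_offset", c(0, 1200), 100)
  expect_equal(sum(ar_c$rate) * 0.1, 57)

  expect_error(extract_window_rates(ses, "cue_offset", c(0, 1000), 300),
               "divisible")
})

test_that("binned rates match the generating rate for a constant Poisson neuron", {
  task <- task_config()
  trials <- manual_trials(1000)
  prof <- structure(list(time = seq(task$ready_ms, 2999),
                         rate = rep(10, 3000 - task$ready_ms),
                         duration = 1500, archetype = "untuned"),
                    class = "rate_profile")
  sp <- sample_spikes(prof, 1000, seed = 3)
  sp$neuron <- 1
  ses <- manual_session(trials, sp[, c("neuron", "trial", "time_ms")], task)
  ar <- extract_window_rates(ses, "cue_offset", c(0, 1200), 100,
                             trials = trials$trial)
  expect_lt(abs(mean(ar$rate) - 10), 0.3)
})

test_that("smoothing and scaling follow their stated conventions", {
  # minmax: constant row maps to zeros
  expect_equal(smooth_and_scale(matrix(5, 1, 10), "minmax"),
               matrix(0, 1, 10))

  # z-score by train: (1 - 1) / sd(0, 2) = 0
  m <- matrix(c(0, 2, 1), ncol = 1)
  z <- smooth_and_scale(m, "zscore_by_train", train_idx = 1:2)
  expect_equal(z[3, 1], 0)
  # zero-variance feature maps to 0
  m2 <- cbind(m, c(7, 7, 7))
  z2 <- smooth_and_scale(m2, "zscore_by_train", train_idx = 1:2)
  expect_equal(z2[, 2], c(0, 0, 0))

  # unit impulse keeps unit mass under the renormalised Gaussian kernel
  v <- matrix(0, 1, 101); v[1, 51] <- 1
  sm <- smooth_and_scale(v, "gaussian_kernel", width = 100, bin_width = 20)
  expect_equal(sum(sm), 1, tolerance = 1e-6)
  # constant input stays constant (edge renormalisation)
  cst <- smooth_and_scale(matrix(3, 1, 40), "gaussian_kernel",
                          width = 200, bin_width = 20)
  expect_equal(as.numeric(cst), rep(3, 40), tolerance = 1e-9)
})

test_that("train-only z-scoring cannot leak test-set information", {
  set.seed(4)
  x <- matrix(rnorm(60), 20, 3)
  tr <- 1:12
  z1 <- smooth_and_scale(x, "zscore_by_train", train_idx = tr)
  x_pert <- x
  x_pert[13:20, ] <- x_pert[13:20, ] + 100     # perturb only the test rows
  z2 <- smooth_and_scale(x_pert, "zscore_by_train", train_idx = tr)
  expect_equal(z1[tr, ], z2[tr, ])             # train statistics unchanged
})
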