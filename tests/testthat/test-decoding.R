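test_that("pseudopopulation assembly keeps its bookkeeping", {
  set.seed(1)
  mk_units <- function(n_neurons, n_trials) {
    u <- lapply(seq_len(n_neurons), function(j) {
      lapply(c("1500" = 1, "3000" = 2, "6000" = 3), function(k)
        rnorm(n_trials, k))
    })
    stats::setNames(u, seq_len(n_neurons))
  }
  pp <- assemble_pseudopopulation(mk_units(3, 15), min_trials = 15)
  set.seed(2); d1 <- draw_pseudotrials(pp)
  expect_equal(dim(d1$x), c(45, 3))
  expect_equal(as.vector(table(d1$y)), c(15, 15, 15))
  set.seed(2); d2 <- draw_pseudotrials(pp)
  expect_identical(d1, d2)                      # same seed, same assembly

  units <- mk_units(3, 35)
  units[["2"]][["3000"]] <- units[["2"]][["3000"]][1:20]  # short neuron
  pp2 <- assemble_pseudopopulation(units, min_trials = 30)
  expect_equal(pp2$excluded$neuron, "2")
  expect_equal(length(pp2$pools), 2L)
  expect_error(assemble_pseudopopulation(mk_units(2, 5), min_trials = 10),
               "no neuron")
})

test_that("the linear SVM separates well-separated clouds and stays at chance on noise", {
  set.seed(3)
  # two classes, margin >> spread
  x <- rbind(matrix(rnorm(200, 0, 0.2), 50), matrix(rnorm(200, 5, 0.2), 50))
  y <- rep(c("a", "b"), each = 50)
  res <- svm_decode(x, y, n_folds = 5, n_resamples = 5, n_shuffles = 0,
                    seed = 4)
  expect_gt(res$accuracy, 99)

  # confusion consistency: accuracy recomputed from the confusion matrix
  expect_equal(res$accuracy,
               100 * sum(diag(res$confusion)) / sum(res$confusion),
               tolerance = 1e-6)

  # shuffled labels, 3 balanced classes: mean accuracy ~ 33.3%
  xr <- matrix(rnorm(60 * 12), 60, 12)
  yr <- rep(1:3, each = 20)
  resr <- svm_decode(xr, yr, n_folds = 5, n_resamples = 2,
                     n_shuffles = 150, seed = 5)
  expect_lt(abs(mean(resr$null_accuracies) - 100 / 3), 2)
})

test_that("SVM decoding agrees with an independent multinomial classifier", {
  skip_if_not_installed("glmnet")
  set.seed(8)
  # moderately separable 3-class problem
  n <- 30; d <- 10
  mu <- rbind(rep(0, d), c(rep(1.2, 3), rep(0, d - 3)),
              c(rep(0, d - 3), rep(1.2, 3)))
  x <- do.call(rbind, lapply(1:3, function(k)
    matrix(rnorm(n * d, mean = rep(mu[k, ], each = n)), n, d)))
  y <- rep(1:3, each = n)

  acc_svm <- svm_decode(x, y, n_folds = 5, n_resamples = 10,
                        n_shuffles = 0, seed = 9)$accuracy

  # oracle: ridge multinomial regression, same fold structure
  folds <- sample(rep_len(1:5, length(y)))
  hits <- 0
  for (f in 1:5) {
    tr <- folds != f
    m <- glmnet::glmnet(x[tr, ], factor(y[tr]), family = "multinomial",
                        lambda = 0.01)
    p <- predict(m, x[!tr, ], type = "class")
    hits <- hits + sum(p == y[!tr])
  }
  acc_glm <- 100 * hits / length(y)
  expect_lt(abs(acc_svm - acc_glm), 10)
})

test_that("zero-variance neurons are neutralised by train-only z-scoring", {
  set.seed(6)
  n <- 30
  informative <- c(rnorm(n, 0, 0.3), rnorm(n, 3, 0.3))
  y <- rep(c("s", "l"), each = n)
  x1 <- matrix(informative, ncol = 1)
  x99 <- cbind(informative, matrix(0, 2 * n, 99))   # 99 silent channels
  a1 <- svm_decode(x1, y, n_folds = 5, n_resamples = 10, n_shuffles = 0,
                   seed = 7)$accuracy
  a99 <- svm_decode(x99, y, n_folds = 5, n_resamples = 10, n_shuffles = 0,
                    seed = 7)$accuracy
  expect_lt(abs(a1 - a99), 2)
})

test_that("cross-protocol generalization tracks the generator's invariance", {
  task <- task_config(n_correct_trials_per_cue = 15)
  bm <- behavior_model(0.15, 0.1, 0)

  # protocol-invariant duration tuning: across ~ within
  ses_inv <- cached("pg_invariant",
                    quiet_session(task, bm, tuned_population(4, gain = 12),
                                  seed = 20))
  pg <- protocol_generalization_decode(ses_inv, n_resamples = 10,
                                       n_shuffles = 5, seed = 21)
  within <- mean(c(pg$within_color$accuracy, pg$within_shape$accuracy))
  across <- mean(c(pg$color_to_shape$accuracy, pg$shape_to_color$accuracy))
  expect_gt(within, 80)
  expect_lt(abs(within - across), 5)

  # no duration signal at all: everything at chance
  ses_null <- cached("pg_null",
                     quiet_session(task, bm, untuned_population(12),
                                   seed = 22))
  pg0 <- protocol_generalization_decode(ses_null, n_resamples = 10,
                                        n_shuffles = 5, seed = 23)
  for (k in names(pg0)) {
    expect_lt(abs(pg0[[k]]$accuracy - 100 / 3), 12)
  }
})

test_that("protocol-bound tuning does not generalize across protocols", {
  # duration gains exist for color cues only
  task <- task_config(n_correct_trials_per_cue = 15)
  pop <- unlist(lapply(c(1500, 3000, 6000), function(d) {
    replicate(4, {
      s <- rate_profile_spec("duration_tuned", baseline = 4,
                             gain = stats::setNames(12, d), preferred = d)
      s$color_only <- TRUE
      s
    }, simplify = FALSE)
  }), recursive = FALSE)
  # emulate protocol-bound tuning by zeroing the gain on shape trials:
  # build two half-sessions and merge the trial/spike tables
  ses_c <- quiet_session(task_config(protocols = "color",
                                     n_correct_trials_per_cue = 15),
                         behavior_model(0.15, 0.1, 0), pop, seed = 24)
  ses_s <- quiet_session(task_config(protocols = "shape",
                                     n_correct_trials_per_cue = 15),
                         behavior_model(0.15, 0.1, 0),
                         untuned_population(length(pop), baseline = 8),
                         seed = 25)
  off <- max(ses_c$trials$trial)
  ses_s$trials$trial <- ses_s$trials$trial + off
  ses_s$spikes$trial <- ses_s$spikes$trial + off
  ses <- ses_c
  ses$trials <- rbind(ses_c$trials, ses_s$trials)
  ses$spikes <- rbind(ses_c$spikes, ses_s$spikes)
  ses$task <- task

  pg <- protocol_generalization_decode(ses, n_resamples = 10,
                                       n_shuffles = 5, seed = 26)
  expect_gt(pg$within_color$accuracy, 80)
  expect_lt(abs(pg$color_to_shape$accuracy - 100 / 3), 12)
})

test_that("elapsed-time decoding reads out a sequence code with exact bookkeeping", {
  task <- task_config(n_correct_trials_per_cue = 14)
  ses <- cached("elapsed_session",
                quiet_session(task, behavior_model(0.15, 0.1, 0),
                              sequence_population(seq(100, 1100,
                                                      length.out = 10)),
                              seed = 30))
  ed <- elapsed_time_decode(ses, 1500, n_trials = 20, n_resamples = 5,
                            seed = 31)
  expect_equal(ed$n_observations, 400)
  expect_equal(ed$n_train, 320)
  expect_equal(ed$n_test, 80)
  expect_equal(ed$predictions_per_bin, 5 * 5 * 4)
  expect_true(all(rowSums(ed$counts) == ed$predictions_per_bin))
  # a tiling sequence population decodes elapsed time: medians on or next to
  # the diagonal for most bins
  hit <- abs(ed$summary$median_pred - ed$summary$bin) <= 1
  expect_gte(mean(hit), 0.8)

  # untuned population: predicted bins near-uniform, accuracy near 5%
  ses0 <- cached("elapsed_null",
                 quiet_session(task, behavior_model(0.15, 0.1, 0),
                               untuned_population(10, baseline = 10),
                               seed = 32))
  ed0 <- elapsed_time_decode(ses0, 1500, n_trials = 20, n_resamples = 5,
                             seed = 33)
  expect_lt(ed0$accuracy, 12)
  expect_gt(min(colSums(ed0$counts)), 0)          # every bin gets predicted
})

test_that("late-error activity carrying the wrong duration is misclassified", {
  task <- task_config(n_correct_trials_per_cue = 20)
  ses <- quiet_session(task, behavior_model(0.12, 0.1, 0),
                       tuned_population(5, gain = 12,
                                        durations = c(1500, 3000)),
                       seed = 40)
  # forge late errors whose spikes carry the OTHER duration's profile:
  # relabel 4 correct trials of each class as late errors of the other class
  tr <- ses$trials
  pick1 <- head(tr$trial[tr$outcome == "correct" & tr$duration == 1500], 4)
  pick2 <- head(tr$trial[tr$outcome == "correct" & tr$duration == 3000], 4)
  tr$outcome[tr$trial %in% c(pick1, pick2)] <- "late_error"
  tr$duration[tr$trial %in% pick1] <- 3000
  tr$duration[tr$trial %in% pick2] <- 1500
  ses$trials <- tr

  et <- error_trial_decode(ses, n_resamples = 15, n_shuffles = 20,
                           min_correct = 12, n_late = 6, seed = 41)
  expect_gt(et$correct$accuracy, 85)
  expect_lt(et$late_error$accuracy, 100 - et$correct$accuracy + 15)
  expect_lt(et$late_error$accuracy, et$null_p99)

  # exchangeable late errors (same distribution as correct) decode equally
  ses2 <- ses
  tr2 <- ses2$trials
  tr2$duration[tr2$trial %in% pick1] <- 1500     # restore the true labels
  tr2$duration[tr2$trial %in% pick2] <- 3000
  ses2$trials <- tr2
  et2 <- error_trial_decode(ses2, n_resamples = 15, n_shuffles = 5,
                            min_correct = 12, n_late = 6, seed = 42)
  expect_lt(abs(et2$late_error$accuracy - et2$correct$accuracy), 15)
})

test_that("cross-temporal decoding distinguishes static from dynamic codes", {
  task <- task_config(n_correct_trials_per_cue = 12)
  bm <- behavior_model(0.15, 0.1, 0)

  ses_static <- cached("ct_static",
                       quiet_session(task, bm, tuned_population(4, gain = 12),
                                     seed = 50))
  ct_s <- cross_temporal_decode(ses_static, span = c(-300, 1500),
                                window_ms = 200, step_ms = 100,
                                min_trials = 20, n_folds = 5,
                                n_resamples = 2, seed = 51)
  on_task <- ct_s$centers > 100
  pre <- ct_s$centers < -50
  # pre-cue windows are at chance; the tuned epoch generalizes everywhere
  expect_lt(mean(ct_s$mean_acc[pre, pre]), 0.45)
  expect_gt(mean(ct_s$mean_acc[on_task, on_task]), 0.8)
  off_diag <- ct_s$mean_acc[on_task, on_task]
  diag_vals <- diag(off_diag)
  off_vals <- off_diag[upper.tri(off_diag)]
  expect_gt(mean(off_vals), 0.75)                # square pattern

  # dynamic code: duration-specific transient fields tiling the wait
  pop_dyn <- unlist(lapply(seq(0, 1400, length.out = 8), function(cc) {
    lapply(c(1500, 3000, 6000), function(d)
      rate_profile_spec("time_field", baseline = 2,
                        gain = stats::setNames(25, d),
                        center = cc, width = 90))
  }), recursive = FALSE)
  ses_dyn <- cached("ct_dynamic", quiet_session(task, bm, pop_dyn, seed = 52))
  ct_d <- cross_temporal_decode(ses_dyn, span = c(-300, 1500),
                                window_ms = 200, step_ms = 100,
                                min_trials = 20, n_folds = 5,
                                n_resamples = 2, seed = 53)
  A <- ct_d$mean_acc[on_task, on_task]
  near <- abs(row(A) - col(A)) <= 1
  far <- abs(row(A) - col(A)) >= 4
  expect_gt(mean(A[near]), mean(A[far]) + 0.15)  # diagonal ridge
})

test_that("cluster permutation test is calibrated and respects 4-connectivity", {
  set.seed(60)
  W <- 20; n_null <- 120
  null_mats <- array(rnorm(n_null * W * W, 0.33, 0.03), c(n_null, W, W))

  # no signal: pixel threshold admits ~1% of pixels, no significant cluster
  true_null <- array(rnorm(5 * W * W, 0.33, 0.03), c(5, W, W))
  cp0 <- cluster_permutation_test(true_null, null_mats)
  thr_frac <- mean(apply(true_null, c(2, 3), mean) >
                     apply(null_mats, c(2, 3), quantile, 0.99))
  expect_lt(thr_frac, 0.05)
  expect_equal(sum(cp0$clusters$significant), 0)
  expect_false(any(cp0$mask))

  # a solid high-accuracy block is recovered as one significant cluster
  true_sig <- true_null
  true_sig[, 5:14, 5:14] <- true_sig[, 5:14, 5:14] + 1
  cp1 <- cluster_permutation_test(true_sig, null_mats)
  expect_equal(sum(cp1$clusters$significant), 1)
  expect_gte(sum(cp1$mask[5:14, 5:14]), 95)
  expect_lte(sum(cp1$mask) - sum(cp1$mask[5:14, 5:14]), 10)

  # diagonal-touching pixels are separate clusters under 4-connectivity
  true_diag <- array(0.33, c(1, W, W))
  true_diag[1, 3, 3] <- 2; true_diag[1, 4, 4] <- 2
  cp2 <- cluster_permutation_test(true_diag, null_mats)
  expect_equal(nrow(cp2$clusters), 2L)
})

test_that("bin-stability decoding reflects stable duration tuning", {
  task <- task_config(n_correct_trials_per_cue = 12)
  ses <- cached("ct_static",
                quiet_session(task, behavior_model(0.15, 0.1, 0),
                              tuned_population(4, gain = 12), seed = 50))
  bs <- bin_stability_decode(ses, n_bins = 5, min_trials = 20, n_folds = 5,
                             n_resamples = 3, seed = 61)
  expect_gt(mean(bs$mean_acc), 0.75)              # whole matrix >> 33%
  expect_true(all(dim(bs$mean_acc) == c(5, 5)))
})
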