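test_that("two-way ANOVA matches the standard decomposition on balanced data", {
  set.seed(1)
  d <- rep(rep(c(1500, 3000, 6000), each = 4), 2)
  p <- rep(c("color", "shape"), each = 12)
  y <- rnorm(24, mean = as.numeric(factor(d)) + (p == "shape") * 0.5)

  res <- two_way_anova(y, d, p)
  # independent oracle: base-R linear-model ANOVA (Type I = Type II when
  # balanced)
  oa <- anova(lm(y ~ factor(d) * factor(p)))
  expect_equal(unname(res$ss[["duration"]]), oa["factor(d)", "Sum Sq"])
  expect_equal(unname(res$ss[["protocol"]]), oa["factor(p)", "Sum Sq"])
  expect_equal(unname(res$ss[["interaction"]]),
               oa["factor(d):factor(p)", "Sum Sq"])
  expect_equal(unname(res$ss[["error"]]), oa["Residuals", "Sum Sq"])
  expect_equal(unname(res$F[["duration"]]), oa["factor(d)", "F value"])
  expect_equal(unname(res$p[["duration"]]), oa["factor(d)", "Pr(>F)"])

  # decomposition identity
  expect_equal(res$ss[["duration"]] + res$ss[["protocol"]] +
                 res$ss[["interaction"]] + res$ss[["error"]],
               res$ss[["total"]], tolerance = 1e-8)

  # identical values everywhere: all effect SS zero, classification none
  res0 <- two_way_anova(rep(2, 24), d, p)
  expect_equal(unname(res0$ss[c("duration", "protocol", "interaction")]),
               c(0, 0, 0))
  expect_equal(res0$classification, "none")

  expect_error(two_way_anova(y[1:20], d[1:20], p[1:20]), "cell")
})

test_that("balanced matrix ANOVA agrees with the per-column route", {
  set.seed(2)
  d <- rep(rep(c(1500, 3000, 6000), each = 5), 2)
  p <- rep(c("color", "shape"), each = 15)
  Y <- matrix(rnorm(30 * 7, as.numeric(factor(d))), 30, 7)
  ss <- balanced_anova_ss(Y, d, p)
  for (j in 1:7) {
    ref <- two_way_anova(Y[, j], d, p)
    expect_equal(ss$ss_duration[j], unname(ref$ss[["duration"]]))
    expect_equal(ss$ss_protocol[j], unname(ref$ss[["protocol"]]))
    expect_equal(ss$ss_interaction[j], unname(ref$ss[["interaction"]]))
    expect_equal(ss$ss_error[j], unname(ref$ss[["error"]]))
    expect_equal(ss$ms_error[j], ref$ms_error)
  }
})

test_that("time-neuron classification and preference follow the stated rules", {
  set.seed(3)
  d <- rep(rep(c(1500, 3000, 6000), each = 10), 2)
  p <- rep(c("color", "shape"), each = 30)
  strong <- rnorm(60, ifelse(d == 1500, 10, 2), 0.5)
  a_cue <- two_way_anova(strong, d, p)
  a_resp <- two_way_anova(strong + rnorm(60, 0, 0.2), d, p)
  cl <- classify_time_neuron(a_cue, a_resp)
  expect_true(cl$time_cue && cl$time_resp && cl$overlap)
  expect_equal(cl$preferred_cue, 1500)
  expect_false(cl$preference_change)

  # significant in one alignment only
  a_none <- two_way_anova(rnorm(60, 5), d, p)
  cl2 <- classify_time_neuron(a_cue, a_none)
  expect_true(cl2$time_cue); expect_false(cl2$time_resp)
  expect_false(cl2$overlap)

  # exact tie in maximal rates: prefer the shorter duration and flag it
  tied <- ifelse(d == 3000, 2, 8) + rep(c(-1, 1), 30)  # means exactly 8, 2, 8
  a_tie <- two_way_anova(tied, d, p)
  cl3 <- classify_time_neuron(a_tie, a_tie)
  expect_equal(cl3$preferred_cue, 1500)
  expect_true(cl3$tie_cue)
})

test_that("tuning curves normalise and measure width as a weighted SD", {
  tc <- tuning_curve(c("1500" = 10, "3000" = 5, "6000" = 0))
  expect_equal(unname(tc$curve), c(100, 50, 0))
  expect_equal(tc$preferred, 1500)
  expect_true(tc$monotonic)

  # w = (100, 0, 100) at x = (1500, 3000, 6000): weighted mean 3750,
  # weighted SD exactly 2250
  tc2 <- tuning_curve(c("1500" = 8, "3000" = 1, "6000" = 8))
  expect_equal(tc2$weighted_sd, 2250)

  # sharper tuning has the smaller width
  narrow <- tuning_curve(c("1500" = 10, "3000" = 0.1, "6000" = 0))
  broad <- tuning_curve(c("1500" = 10, "3000" = 8, "6000" = 0))
  expect_lt(narrow$weighted_sd, broad$weighted_sd)

  # middle-preferring neurons have no monotonicity verdict
  expect_true(is.na(tuning_curve(c("1500" = 0, "3000" = 9,
                                   "6000" = 1))$monotonic))
  expect_error(tuning_curve(c("1500" = 3, "3000" = 3, "6000" = 3)),
               "equal")
})

test_that("broadening duration tuning increases the population's median width", {
  set.seed(4)
  widths <- vapply(c(0.2, 5), function(spread) {
    wsd <- vapply(1:60, function(i) {
      m <- c(10, 0, 0) + abs(rnorm(3, 0, spread))
      names(m) <- c(1500, 3000, 6000)
      tuning_curve(m)$weighted_sd
    }, numeric(1))
    median(wsd)
  }, numeric(1))
  expect_lt(widths[1], widths[2])
})

test_that("Jonckheere-Terpstra statistic and p-values are exact", {
  # maximal separation: T = 12, exact one-sided p = 1/90
  jt <- jonckheere_terpstra(list(c(1, 2), c(3, 4), c(5, 6)))
  expect_equal(jt$statistic, 12)
  expect_equal(jt$p_exact, 1 / 90)

  # no trend at all
  jt0 <- jonckheere_terpstra(list(c(1, 1), c(1, 1), c(1, 1)))
  expect_equal(jt0$z, 0)
  expect_equal(jt0$p, 0.5)

  # statistic equals the pairwise Mann-Whitney count (wilcox.test oracle)
  set.seed(5)
  g <- list(rnorm(4), rnorm(3, 0.5), rnorm(4, 1))
  jt1 <- jonckheere_terpstra(g)
  w_sum <- 0
  for (i in 1:2) for (j in (i + 1):3) {
    w_sum <- w_sum + suppressWarnings(
      wilcox.test(g[[j]], g[[i]])$statistic)
  }
  expect_equal(jt1$statistic, unname(w_sum))

  # exact p equals an independent full-permutation enumeration (n = 7)
  set.seed(6)
  g2 <- list(rnorm(2), rnorm(2), rnorm(3))
  jt2 <- jonckheere_terpstra(g2)
  pooled <- unlist(g2)
  naive_T <- function(v) {
    gs <- list(v[1:2], v[3:4], v[5:7]); s <- 0
    for (i in 1:2) for (j in (i + 1):3) {
      for (a in gs[[i]]) for (b in gs[[j]]) {
        s <- s + (a < b) + 0.5 * (a == b)
      }
    }
    s
  }
  perms <- gtools_permutations(length(pooled))
  stats <- apply(perms, 1, function(ix) naive_T(pooled[ix]))
  expect_equal(jt2$p_exact, mean(stats >= jt2$statistic - 1e-9))

  # normal approximation close to exact for small n
  set.seed(7)
  g3 <- list(rnorm(3), rnorm(3), rnorm(3))
  jt3 <- jonckheere_terpstra(g3)
  expect_lt(abs(jt3$p - jt3$p_exact), 0.03)

  expect_error(jonckheere_terpstra(list(1:3)), "2 ordered groups")
})

test_that("sequence surfaces order neurons by peak time", {
  task <- task_config(n_correct_trials_per_cue = 10)
  pop <- sequence_population(c(600, 200, 1000))   # deliberately out of order
  ses <- cached("seq_session",
                quiet_session(task, behavior_model(0.15, 0.1, 0), pop,
                              seed = 10))
  ss <- sequence_surface(ses, 1:3, "cue_offset", c(0, 1200))
  expect_equal(ss$order, c(2, 1, 3))              # centers 200, 600, 1000
  expect_true(all(diff(ss$peak_time) >= 0))
  expect_true(all(ss$surface >= 0 & ss$surface <= 1))

  # permutation invariance of the sorted surface
  ss2 <- sequence_surface(ses, c(3, 1, 2), "cue_offset", c(0, 1200))
  expect_equal(ss2$order, ss$order)
  expect_equal(ss2$surface, ss$surface)
})

test_that("ramping analysis recovers climbing activity and rejects early fields", {
  task <- task_config(n_correct_trials_per_cue = 14)
  pop <- list(rate_profile_spec("ramp_linear", baseline = 2, gain = 20,
                                onset = 0),
              rate_profile_spec("time_field", baseline = 2, gain = 20,
                                center = 200, width = 150))
  ses <- quiet_session(task, behavior_model(0.15, 0.1, 0), pop, seed = 11)

  rf <- ramping_analysis(ses, 1, n_shuffles = 100, seed = 12)
  expect_true(rf$increasing)
  lin <- rf$fits[rf$fits$model == "linear", ]
  expect_true(all(lin$significant))
  expect_true(all(lin$r2 > 0.7))
  # the shuffle null never certifies a perfect fit
  expect_true(all(rf$fits$null95 < 1))

  rf2 <- ramping_analysis(ses, 2, n_shuffles = 100, seed = 12)
  expect_false(rf2$increasing)
})

test_that("temporal scaling search recovers exact stretches and the identity", {
  t_s <- seq(5, 1195, by = 10)
  short <- 5 + 10 * exp(-(t_s - 500)^2 / (2 * 150^2))
  stretch <- function(fac) {
    tl <- seq(5, 1200 * fac - 5, by = 10)
    5 + 10 * exp(-((tl / fac) - 500)^2 / (2 * 150^2))
  }

  sc2 <- temporal_scaling(stretch(2), short, expected = 0.5)
  expect_equal(sc2$optimal, 0.5)
  expect_true(sc2$within_10pct)
  expect_lt(sc2$min_mse, 1e-4)

  sc4 <- temporal_scaling(stretch(4), short, expected = 0.25)
  expect_equal(sc4$optimal, 0.25)

  # identity: comparing a profile with itself yields factor 1, MSE 0
  sc1 <- temporal_scaling(short, short)
  expect_equal(sc1$optimal, 1)
  expect_equal(sc1$min_mse, 0)

  # unrelated white-noise profiles: the true stretch factor is not
  # preferentially recovered (optima scatter, with noise minima attracted to
  # the small-overlap end of the grid)
  set.seed(13)
  opts <- vapply(1:100, function(i) {
    temporal_scaling(rnorm(240), rnorm(120))$optimal
  }, numeric(1))
  expect_gte(length(unique(opts)), 10)
  within <- mean(abs(opts - 0.5) <= 0.05)
  expect_lt(within, 0.25)                 # ~ the grid-window fraction
})
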