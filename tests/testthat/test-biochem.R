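test_that("ratio error propagation matches the closed form and its limits", {
  r <- propagate_ratio_error(10, 1, 2, 0.2)
  expect_equal(r[["value"]], 5)
  expect_equal(r[["sd"]], 5 * sqrt(0.01 + 0.01), tolerance = 1e-12)
  expect_equal(propagate_ratio_error(10, 1, 2, 0)[["sd"]], 0.5)
  expect_equal(propagate_ratio_error(0, 1, 2, 0.2)[["sd"]], 0.5)
  expect_error(propagate_ratio_error(1, 0.1, 0, 0.1), "zero")
})

test_that("first-order propagation agrees with Monte-Carlo propagation", {
  set.seed(123)
  a <- 100; sa <- 2; b <- 50; sb <- 1
  r <- propagate_ratio_error(a, sa, b, sb)
  mc <- rnorm(1e6, a, sa) / rnorm(1e6, b, sb)
  expect_lt(abs(r[["value"]] - mean(mc)) / mean(mc), 0.005)
  expect_lt(abs(r[["sd"]] - sd(mc)) / sd(mc), 0.05)
})

test_that("synthesis slope subtracts the baseline over the stated windows", {
  flat <- gen_luminescence_trace(baseline_slope = 0, post_slope = 5,
                                 noise_sd = 0)
  expect_equal(synthesis_slope(flat)[["slope"]], 5, tolerance = 1e-9)
  tr <- gen_luminescence_trace(baseline_slope = 1, post_slope = 5,
                               noise_sd = 0)
  expect_equal(synthesis_slope(tr)[["slope"]], 4, tolerance = 1e-9)
  # insufficient pre-NADH span
  short <- tr
  keep <- short$time > 50
  short$time <- short$time[keep]; short$signal <- short$signal[keep]
  expect_error(synthesis_slope(short), "span")
  # noisy recovery within 3 combined standard errors
  noisy <- gen_luminescence_trace(baseline_slope = 1, post_slope = 5,
                                  noise_sd = 3, seed = 7)
  s <- synthesis_slope(noisy)
  expect_lt(abs(s[["slope"]] - 4), 3 * s[["sd"]])
})

test_that("ATP calibration averages the four step heights", {
  tr <- gen_luminescence_trace(baseline_slope = 0, post_slope = 0,
                               step_height = 50, noise_sd = 0)
  cal <- atp_calibration(tr, atp_amount = 2)
  expect_equal(cal[["value"]], 25, tolerance = 1e-9)
  expect_equal(cal[["sd"]], 0, tolerance = 1e-9)
  # hand-built steps {4, 5, 5, 6} on amount 1
  time <- seq(0, 100, by = 0.5)
  h <- c(4, 5, 5, 6); ts <- c(20, 40, 60, 80)
  sig <- rowSums(outer(time, seq_along(ts),
                       function(tt, k) (tt > ts[k]) * h[k]))
  tr2 <- list(time = time, signal = sig,
              annotations = data.frame(time = ts, label = "ATP"))
  cal2 <- atp_calibration(tr2)
  expect_equal(cal2[["value"]], 5)
  expect_equal(cal2[["sd"]], sd(h))
  expect_error(atp_calibration(list(time = time, signal = sig,
                                    annotations = data.frame(
                                      time = ts[1:3], label = "ATP"))),
               "expected 4")
})

test_that("specific activity divides slope by calibration with propagation", {
  expect_equal(specific_activity(c(slope = 10, sd = 0),
                                 c(value = 2, sd = 0))[["value"]], 5)
  sa <- specific_activity(c(slope = 10, sd = 1), c(value = 2, sd = 0.2))
  expect_equal(sa[["sd"]] / sa[["value"]], sqrt(2) * 0.1, tolerance = 1e-12)
  expect_error(specific_activity(c(slope = 1, sd = 0),
                                 c(value = -1, sd = 0)), "positive")
})

test_that("the full luminescence pipeline recovers generator ground truth", {
  truth <- (5 - 1) / (50 / 1)   # (post - baseline) slope over calibration
  est <- sapply(1:20, function(s) {
    tr <- gen_luminescence_trace(baseline_slope = 1, post_slope = 5,
                                 step_height = 50, noise_sd = 2, seed = s)
    sl <- synthesis_slope(tr)
    cal <- atp_calibration(tr)
    specific_activity(sl, cal)
  })
  dev <- est["value", ] - truth
  expect_true(all(abs(dev) < 3 * est["sd", ] + 1e-9))
  expect_lt(abs(mean(dev)), 3 * sd(est["value", ]) / sqrt(20))
})

test_that("expression normalization rescales by the LDAO reference", {
  act <- data.frame(label = c("e", "ef", "eg", "eh"),
                    mean = c(10, 20, 30, 40), sd = c(1, 2, 3, 4))
  ld_eq <- data.frame(label = c("e", "ef", "eg", "eh"),
                      mean = rep(0.1, 4), sd = 0)
  out <- expression_normalize(act, ld_eq)
  expect_equal(out$mean, act$mean)
  expect_equal(out$sd, act$sd)
  # halved expression doubles the corrected activity
  ld <- data.frame(label = c("e", "ef", "eg", "eh"),
                   mean = c(0.05, 0.1, 0.1, 0.15), sd = 0)
  out2 <- expression_normalize(act, ld)
  expect_equal(out2$mean[1], act$mean[1] * mean(ld$mean) / 0.05)
  expect_error(expression_normalize(act, ld[1:2, ]), "missing LDAO")
  ld0 <- ld_eq; ld0$mean[2] <- 0
  expect_error(expression_normalize(act, ld0), "zero LDAO")
})

test_that("normalization errors agree with Monte-Carlo propagation", {
  act <- data.frame(label = c("e", "ef", "eg", "eh"),
                    mean = c(30, 20, 25, 28), sd = c(2, 1.5, 2, 2))
  ld <- data.frame(label = c("e", "ef", "eg", "eh"),
                   mean = c(0.09, 0.08, 0.1, 0.11), sd = rep(0.004, 4))
  out <- expression_normalize(act, ld)
  set.seed(5)
  n <- 2e5
  ref <- (rnorm(n, 0.09, 0.004) + rnorm(n, 0.08, 0.004) +
            rnorm(n, 0.1, 0.004) + rnorm(n, 0.11, 0.004)) / 4
  mc <- rnorm(n, 30, 2) / rnorm(n, 0.09, 0.004) * ref
  # reference reuse induces a small correlation; allow 10% on the SD
  expect_lt(abs(out$sd[1] - sd(mc)) / sd(mc), 0.1)
  expect_lt(abs(out$mean[1] - mean(mc)) / mean(mc), 0.01)
})

test_that("ACMA quench reads 3-minute depth against the FCCP plateau", {
  flat <- gen_acma_trace(depth = 0, noise_sd = 0)
  expect_lt(abs(acma_quench(flat)), 1e-9)
  tr <- gen_acma_trace(depth = 0.4, plateau = 100, noise_sd = 0)
  expect_equal(acma_quench(tr), 40, tolerance = 0.1)
  # scripted levels: F_3min = 60, plateau = 100 -> 40 percent
  time <- seq(0, 600, by = 1)
  sig <- ifelse(time > 60 & time <= 360, 60, 100)
  tr2 <- list(time = time, signal = sig,
              annotations = data.frame(time = c(60, 360),
                                       label = c("ATP", "FCCP")))
  expect_equal(acma_quench(tr2), 40, tolerance = 1e-9)
  expect_error(acma_quench(list(time = time, signal = sig,
                                annotations = data.frame(time = 60,
                                                         label = "ATP"))),
               "FCCP")
})

test_that("DCCD sensitivity is the inhibited activity fraction", {
  expect_equal(dccd_sensitivity(0.2, 0.2), 0)
  expect_equal(dccd_sensitivity(0.087, 0.076), 1 - 0.076 / 0.087)
  expect_equal(dccd_sensitivity(0.1, 0), 1)
  expect_error(dccd_sensitivity(0, 0.1), "positive")
  tab <- atpase_dccd_table()
  frac <- dccd_sensitivity(tab$minus_dccd, tab$plus_dccd)
  # the mutant constructs are mostly DCCD-insensitive
  expect_true(all(frac[tab$label %in% c("e", "ef", "eg", "eh", "ei", "ej")]
                  < 0.3))
})

test_that("pooled t-test reproduces closed-form summary inference", {
  same <- list(mean = 5, sd = 1, n = 6)
  r0 <- pooled_t_test(same, same)
  expect_equal(r0$t, 0); expect_equal(r0$p, 1)
  ef <- list(mean = 22.3, sd = 9.3, n = 10)
  ej <- list(mean = 12.0, sd = 4.7, n = 8)
  r <- pooled_t_test(ef, ej)
  expect_equal(r$df, 16)
  expect_equal(r$p, 0.012, tolerance = 0.03)
  # symmetry and monotonicity in the mean difference
  expect_equal(pooled_t_test(ej, ef)$p, r$p)
  # standard-error interpretation of the spread fields
  ef_se <- list(mean = 22.3, sd = 9.3 / sqrt(10), n = 10)
  ej_se <- list(mean = 12.0, sd = 4.7 / sqrt(8), n = 8)
  expect_equal(pooled_t_test(ef_se, ej_se, dispersion = "se")$p, r$p)
  p_far <- pooled_t_test(list(mean = 30, sd = 9.3, n = 10), ej)$p
  expect_lt(p_far, r$p)
  expect_error(pooled_t_test(list(mean = 1, sd = 1, n = 1), ej), "n >= 2")
  dg <- pooled_t_test(list(mean = 1, sd = 0, n = 3),
                      list(mean = 2, sd = 0, n = 3))
  expect_true(dg$degenerate); expect_equal(dg$p, 0)
})

test_that("pooled t-test agrees with a permutation oracle on replicates", {
  reps <- gen_activity_replicates(seed = 42)
  x <- reps$activity[reps$label == "ef"]
  y <- reps$activity[reps$label == "ej"]
  p_t <- pooled_t_test(list(mean = mean(x), sd = sd(x), n = length(x)),
                       list(mean = mean(y), sd = sd(y), n = length(y)))$p
  pooled <- c(x, y)
  obs <- abs(mean(x) - mean(y))
  set.seed(1)
  nperm <- 2e4
  hits <- 0
  for (k in seq_len(nperm)) {
    idx <- sample.int(length(pooled), length(x))
    d <- abs(mean(pooled[idx]) - mean(pooled[-idx]))
    hits <- hits + (d >= obs - 1e-12)
  }
  p_perm <- hits / nperm
  se <- sqrt(max(p_perm * (1 - p_perm), 1e-6) / nperm)
  expect_lt(abs(p_t - p_perm), 3 * se + 0.02)
})

test_that("distance regression recovers the printed-activity slope", {
  flat <- data.frame(distance = 1:5, activity = rep(3, 5))
  r0 <- distance_regression(flat)
  expect_equal(r0$slope, 0); expect_equal(r0$p, 1)
  s <- activity_summaries()
  s <- s[is.finite(s$distance), ]
  r <- distance_regression(data.frame(distance = s$distance,
                                      activity = s$mean))
  expect_equal(r$slope, -2.5, tolerance = 1e-12)
  expect_lt(r$p, 0.05)
  exact <- data.frame(distance = 1:5, activity = 10 - 2 * (1:5))
  re <- distance_regression(exact)
  expect_true(re$degenerate); expect_equal(re$p, 0)
  expect_error(distance_regression(data.frame(distance = c(1, 1, 2),
                                              activity = 1:3)), "distinct")
})
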