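test_that("log-domain RMS error matches hand evaluation", {
  lp <- function(x) shape_profile(x, domain = "log")
  expect_equal(rms_error(lp(c(1, 2)), lp(c(0, 0))), sqrt(2.5))
  expect_equal(rms_error(lp(c(0.3, -1)), lp(c(0.3, -1))), 0)
  expect_equal(rms_error(lp(2.2), lp(0.7)), 1.5)

  # missing positions are dropped pairwise
  expect_equal(rms_error(lp(c(1, NA, 2)), lp(c(0, 5, NA))), 1)
  expect_error(rms_error(lp(c(NA, 1)), lp(c(2, NA))), "comparable")
  expect_error(rms_error(lp(1:2), lp(1:3)), "equal length")

  # data-domain profiles are log-transformed first
  expect_equal(rms_error(shape_profile(exp(1)), shape_profile(1)), 1 - 0)
})

test_that("confusion counts partition all M(M-1)/2 pairs", {
  ref <- secondary_structure(5, rbind(c(1, 5), c(2, 4)))
  pred <- secondary_structure(5, rbind(c(1, 5), c(2, 3)))
  cc <- confusion_counts(pred, ref)
  expect_equal(unlist(cc[c("TP", "FP", "TN", "FN")]),
               c(TP = 1, FP = 1, TN = 7, FN = 1))

  # identical structures
  cc2 <- confusion_counts(ref, ref)
  expect_equal(cc2$TP, 2); expect_equal(cc2$FP, 0); expect_equal(cc2$FN, 0)
  expect_equal(cc2$TN, 10 - 2)

  # both empty
  e <- secondary_structure(4)
  cc3 <- confusion_counts(e, e)
  expect_equal(unlist(cc3[c("TP", "FP", "TN", "FN")]),
               c(TP = 0, FP = 0, TN = 6, FN = 0))

  expect_error(confusion_counts(e, ref), "equal length")

  # randomized structures: counts always sum to M(M-1)/2
  set.seed(61)
  for (i in 1:25) {
    M <- sample(8:60, 1)
    cc <- confusion_counts(random_structure(M, sample(0:3, 1)),
                           random_structure(M, sample(0:3, 1)))
    expect_equal(cc$TP + cc$FP + cc$TN + cc$FN, M * (M - 1) / 2)
  }
})

test_that("MCC matches hand evaluation and its conventions", {
  cc <- function(tp, fp, tn, fn)
    structure(list(TP = tp, FP = fp, TN = tn, FN = fn, length = NA),
              class = "confusion_counts")
  expect_equal(mcc(cc(3, 1, 10, 2)), 28 / sqrt(2640), tolerance = 1e-12)
  expect_equal(mcc(cc(0, 2, 10, 2)), -4 / 24, tolerance = 1e-12)
  expect_equal(mcc(cc(5, 0, 40, 0)), 1)
  # zero-denominator convention
  expect_equal(mcc(cc(0, 0, 10, 0)), 0)

  # structure interface: perfect prediction, and bounds on random pairs
  s <- read_dotbracket("((((....))))")
  expect_equal(mcc(s, s), 1)
  set.seed(62)
  for (i in 1:20) {
    v <- mcc(random_structure(30, 4), random_structure(30, 4))
    expect_gte(v, -1); expect_lte(v, 1)
  }
})

test_that("mean-SD log-log diagnostic fits the expected line", {
  # two exact points: (mean, sd) = (1, 1) and (10, 10) -> slope 1, icpt 0
  m <- rbind(c(0, 2), c(0, 20))   # means 1 and 10, sds sqrt(2), 10*sqrt(2)
  # construct exactly: rows with mean 1 sd 1: c(1-x, 1+x) has sd sqrt(2)x
  a <- 1 / sqrt(2)
  m <- rbind(c(1 - a, 1 + a), c(10 - 10 * a, 10 + 10 * a))
  fit <- mean_sd_fit(m)
  expect_equal(fit$slope, 1, tolerance = 1e-10)
  expect_equal(fit$intercept, 0, tolerance = 1e-10)
  expect_equal(fit$n_points, 2L)

  # scale equivariance: scaling all measurements leaves slope and (for
  # slope 1) intercept unchanged
  set.seed(63)
  truth <- generate_ground_truth(300, seed = 63)
  reps <- simulate_replicates(truth, 5, noise_regime(0.2, 1.2), seed = 64)
  f1 <- mean_sd_fit(reps)
  f2 <- mean_sd_fit(reps$measurements * 7)
  expect_equal(f1$slope, f2$slope, tolerance = 1e-9)

  # non-positive measurements excluded; degenerate input errors
  m3 <- rbind(c(-1, 2, 3), c(1, 1, 1))
  expect_error(mean_sd_fit(m3), "at least 2 nucleotides")
})

test_that("binned RMS heat map has configured shape and zero-noise zeros", {
  truth <- generate_ground_truth(400, seed = 71)
  reps0 <- simulate_replicates(truth, 3, noise_regime(0, 0))
  # noise_sds all zero: one sigma bin; all cells zero RMS
  g0 <- rms_heatmap(reps0, log_average_profile(reps0),
                    truth_breaks = 4, sigma_breaks = c(-0.1, 0.1))
  expect_equal(dim(g0), c(4L, 1L))
  expect_true(all(g0[!is.na(g0)] < 1e-12))

  reps <- simulate_replicates(truth, 3, noise_regime(0, 1.5), seed = 72)
  g <- rms_heatmap(reps, suppressWarnings(kalman_profile(reps)),
                   truth_breaks = 5, sigma_breaks = 6)
  expect_equal(dim(g), c(5L, 6L))
  expect_true(all(g[!is.na(g)] >= 0))
  expect_error(rms_heatmap(replicate_set(matrix(1:4, 2)), truth),
               "ground_truth")
})
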