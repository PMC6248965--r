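test_that("noise regimes carry the calibrated bounds", {
  expect_equal(unlist(noise_regime("low")[1:2]),
               c(sigma_min = 0, sigma_max = 0.5))
  expect_equal(unlist(noise_regime("medium")[1:2]),
               c(sigma_min = 0.5, sigma_max = 1))
  expect_equal(unlist(noise_regime("high")[1:2]),
               c(sigma_min = 1, sigma_max = 1.5))
  custom <- noise_regime(0.2, 0.9)
  expect_equal(custom$sigma_max, 0.9)
  expect_error(noise_regime(1, 0.5), "sigma_min <= sigma_max")
  expect_error(noise_regime(-1, 0.5), "sigma_min")
})

test_that("per-nucleotide noise SDs are uniform draws from the regime", {
  expect_equal(sample_noise_sd(noise_regime(0, 0), 5), rep(0, 5))
  x <- sample_noise_sd("high", 1000, seed = 2)
  expect_true(all(x >= 1 & x <= 1.5))
  # mean of U(0.5, 1) is 0.75; 3-sigma CLT band with sd 0.5/sqrt(12)
  y <- sample_noise_sd("medium", 1e5, seed = 3)
  expect_lt(abs(mean(y) - 0.75), 3 * (0.5 / sqrt(12)) / sqrt(1e5))
})

test_that("ground-truth generation follows the log-domain prior", {
  expect_equal(as.numeric(generate_ground_truth(3, gaussian_prior(0, 0))),
               rep(1, 3))
  g <- generate_ground_truth(1e5, seed = 4)
  expect_true(all(as.numeric(g) > 0))
  expect_lt(abs(mean(log(as.numeric(g))) - (-1.74)), 3 * 1.52 / sqrt(1e5))
})

test_that("replicate simulation matches the log-normal noise model", {
  truth <- generate_ground_truth(20, seed = 5)
  # zero noise reproduces the truth exactly
  reps0 <- simulate_replicates(truth, N = 4, regime = noise_regime(0, 0))
  expect_equal(reps0$measurements,
               matrix(as.numeric(truth), 20, 4), tolerance = 1e-12)

  # per-nucleotide log mean and SD concentrate on l_m and sigma_wm
  truth1 <- shape_profile(c(0.2, 1.3))
  reps <- simulate_replicates(truth1, N = 1e4,
                              regime = noise_regime(0.4, 1.2), seed = 6)
  lm <- log(reps$measurements)
  for (m in 1:2) {
    expect_lt(abs(mean(lm[m, ]) - log(as.numeric(truth1)[m])),
              3 * reps$noise_sds[m] / sqrt(1e4))
    # chi-square concentration: sd of sample SD ~ sigma / sqrt(2(N-1))
    expect_lt(abs(sd(lm[m, ]) - reps$noise_sds[m]),
              4 * reps$noise_sds[m] / sqrt(2 * (1e4 - 1)))
  }

  # same seed gives identical sets; missing truth propagates
  r1 <- simulate_replicates(truth, 3, "high", seed = 9)
  r2 <- simulate_replicates(truth, 3, "high", seed = 9)
  expect_identical(r1$measurements, r2$measurements)
  tmiss <- shape_profile(c(1, NA, 0.5))
  rm_ <- simulate_replicates(tmiss, 3, "low", seed = 1)
  expect_true(all(is.na(rm_$measurements[2, ])))

  expect_error(simulate_replicates(shape_profile(c(1, -1)), 3, "low"),
               "strictly positive")
})

test_that("data-domain replicate mean is biased up by exp(sigma^2/2)", {
  truth <- shape_profile(0.5)
  reps <- simulate_replicates(truth, N = 2e4, regime = noise_regime(0.8, 0.8),
                              seed = 10)
  ratio <- mean(reps$measurements) / 0.5
  expect_equal(ratio, exp(0.8^2 / 2), tolerance = 0.05)
})
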