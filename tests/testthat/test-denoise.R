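test_that("averaging combiners match hand-computed values", {
  reps <- replicate_set(matrix(c(1, 2, 3), 1))
  expect_equal(as.numeric(average_profile(reps)), 2)
  expect_equal(as.numeric(log_average_profile(replicate_set(
    matrix(c(exp(1), exp(3)), 1)))), exp(2))

  # identical replicates / single replicate are identity for both
  m <- matrix(rep(c(0.4, 1.1), 3), 2)
  expect_equal(as.numeric(average_profile(replicate_set(m))), c(0.4, 1.1))
  expect_equal(as.numeric(log_average_profile(replicate_set(m))),
               c(0.4, 1.1), tolerance = 1e-12)
  expect_equal(as.numeric(average_profile(matrix(c(0.7, 2), 2))), c(0.7, 2))

  # missing measurements are dropped per nucleotide; all-NA rows are NA
  m2 <- rbind(c(1, NA, 3), c(NA, NA, NA))
  expect_equal(as.numeric(average_profile(m2)), c(2, NA))

  expect_error(log_average_profile(matrix(c(1, -2), 1)), "strictly positive")

  # AM >= GM per nucleotide
  set.seed(14)
  m3 <- matrix(rlnorm(300), 50)
  expect_true(all(as.numeric(average_profile(m3)) >=
                  as.numeric(log_average_profile(m3)) - 1e-12))
})

test_that("sample_log_variance is the N-1 sample variance", {
  expect_equal(sample_log_variance(c(2, 2, 2)), 0)
  expect_equal(sample_log_variance(c(1, 2, 3)), 1)
  a <- 0.3; b <- 1.9
  expect_equal(sample_log_variance(c(a, b)), (a - b)^2 / 2)
  expect_error(sample_log_variance(1.5), "at least 2")
  expect_error(sample_log_variance(c(1, NA)), "finite")
})

test_that("scalar filter reproduces hand-worked and degenerate cases", {
  # prior N(0, 1), measurements 0.5, 1.5: sigma_w^2 = 0.5, posterior 4/5
  st <- kalman_filter_nucleotide(c(0.5, 1.5), gaussian_prior(0, 1))
  expect_equal(st$estimate, 0.8, tolerance = 1e-12)
  expect_equal(st$variance, 0.2, tolerance = 1e-12)
  expect_equal(st$meas_var, 0.5)

  # zero-variance prior pins the estimate at mu0
  st0 <- kalman_filter_nucleotide(c(5, -3, 2), gaussian_prior(-1.74, 0))
  expect_equal(st0$estimate, -1.74)
  expect_equal(st0$variance, 0)
  expect_equal(st0$gains, rep(0, 3))

  # identical measurements return the common value with zero variance
  stc <- kalman_filter_nucleotide(rep(0.7, 3), gaussian_prior(0, 1))
  expect_equal(stc$estimate, 0.7)
  expect_equal(stc$variance, 0)

  expect_error(kalman_filter_nucleotide(1.2, gaussian_prior(0, 1)), ">= 2")
  expect_error(kalman_filter_nucleotide(c(1, NA), gaussian_prior(0, 1)),
               "finite")
  # meas_sd override enables N = 1
  st1 <- kalman_filter_nucleotide(1.2, gaussian_prior(0, 1), meas_sd = 1)
  expect_equal(st1$estimate, 0.6, tolerance = 1e-12)
})

test_that("filter equals the conjugate-normal posterior on random instances", {
  set.seed(31)
  for (i in 1:200) {
    n <- sample(2:20, 1)
    l <- rnorm(n, rnorm(1), runif(1, 0.1, 2))
    mu0 <- rnorm(1, 0, 2); s0 <- runif(1, 0.05, 3)
    st <- kalman_filter_nucleotide(l, gaussian_prior(mu0, s0))
    or <- posterior_oracle(l, mu0, s0, st$meas_var)
    expect_equal(st$estimate, or$mean, tolerance = 1e-9)
    expect_equal(st$variance, or$var, tolerance = 1e-9)
    # gains in [0, 1]; variance strictly decreasing; shrinkage between
    # prior mean and log-average
    expect_true(all(st$gains >= 0 & st$gains <= 1))
    expect_lt(st$variance, s0^2)
    lo <- min(mu0, mean(l)); hi <- max(mu0, mean(l))
    expect_gte(st$estimate, lo - 1e-9)
    expect_lte(st$estimate, hi + 1e-9)
  }
})

test_that("posterior variance decreases at every iteration", {
  set.seed(32)
  l <- rnorm(8, 0, 1)
  pr <- gaussian_prior(0, 1.5)
  st <- kalman_filter_nucleotide(l, pr)
  v <- pr$sigma^2
  for (K in st$gains) {
    v_new <- (1 - K) * v
    expect_lt(v_new, v)
    v <- v_new
  }
  expect_equal(v, st$variance, tolerance = 1e-12)
})

test_that("measurement order does not change the final estimate", {
  set.seed(33)
  l <- rnorm(10, -1, 0.8)
  pr <- gaussian_prior(-1.74, 1.52)
  ref <- kalman_filter_nucleotide(l, pr)$estimate
  for (i in 1:25) {
    perm <- sample(l)
    expect_lt(abs(kalman_filter_nucleotide(perm, pr)$estimate - ref), 1e-10)
  }
})

test_that("shape_kalman handles profiles end to end", {
  truth <- generate_ground_truth(80, seed = 41)
  reps <- simulate_replicates(truth, N = 4, regime = "medium", seed = 42)
  fit <- shape_kalman(reps)
  expect_s3_class(fit, "shape_kalman")
  expect_length(coef(fit), 80)
  expect_true(all(is.finite(coef(fit))))
  expect_equal(as.numeric(fitted(fit)), exp(coef(fit)))
  expect_equal(dim(residuals(fit)), c(80, 4))
  expect_equal(residuals(fit)[3, ],
               log(reps$measurements[3, ]) - coef(fit)[3])

  # zero-noise replicates recover the truth exactly
  reps0 <- simulate_replicates(truth, N = 3, regime = noise_regime(0, 0))
  expect_equal(as.numeric(kalman_profile(reps0)), as.numeric(truth),
               tolerance = 1e-9)

  # flat prior converges to the log-average
  flat <- kalman_profile(reps, gaussian_prior(0, 1e6))
  la <- log_average_profile(reps)
  expect_equal(as.numeric(flat), as.numeric(la), tolerance = 1e-6)

  # nucleotides with < 2 measurements are excluded with a warning,
  # filterable via meas_sd
  m <- rbind(c(0.5, 0.9), c(1.2, NA))
  expect_warning(fit1 <- shape_kalman(replicate_set(m)), "excluded")
  expect_true(is.na(coef(fit1)[2]))
  fit2 <- shape_kalman(replicate_set(m), meas_sd = 0.5)
  expect_true(all(is.finite(coef(fit2))))

  # methods run
  expect_output(print(fit), "Kalman-filter")
  s <- summary(fit)
  expect_s3_class(s$table, "data.frame")
  expect_output(print(s), "RMS")
  sim <- simulate(fit, seed = 1)
  expect_s3_class(sim, "replicate_set")
  expect_equal(dim(sim$measurements), c(80, 4))
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("prior fitting and ideal priors behave as specified", {
  expect_equal(unlist(fit_prior(c(-2, 0))[1:2]),
               c(mu = -1, sigma = sqrt(2)))
  pr <- fit_prior(c(3, 3, 3))
  expect_equal(pr$sigma, 0)
  expect_error(fit_prior(2), "at least 2")

  # ideal prior (offset 0, sigma 0): KF returns l_m exactly
  truth <- generate_ground_truth(30, seed = 51)
  lt <- to_log_domain(truth)
  reps <- simulate_replicates(truth, N = 3, regime = "high", seed = 52)
  pr0 <- ideal_prior(lt, mu_offset = 0, sigma = 0)
  kf <- kalman_profile(reps, pr0)
  expect_equal(as.numeric(to_log_domain(kf)), as.numeric(lt),
               tolerance = 1e-12)

  pr3 <- ideal_prior(lt, mu_offset = 3, sigma = 1)
  expect_equal(pr3$mu, as.numeric(lt) + 3)
  expect_equal(pr3$sigma, rep(1, 30))
})
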