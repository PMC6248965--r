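#' Combine replicates by data-domain averaging
#'
#' The per-nucleotide arithmetic mean of the available measurements -- the
#' classical combiner, optimal under additive Gaussian noise in the data
#' domain. Under the multiplicative (log-normal) noise model this estimate
#' is biased upward by the factor exp(sigma_w^2 / 2).
#'
#' @param reps a [replicate_set] or numeric M x N matrix.
#' @return A data-domain [shape_profile]; nucleotides with no measurements
#'   are `NA`.
#' @seealso [log_average_profile()], [kalman_profile()]
#' @export
average_profile <- function(reps) {
  meas <- rep_measurements(reps)
  v <- rowMeans(meas, na.rm = TRUE)
  v[!is.finite(v)] <- NA_real_
  shape_profile(v, rna_id = rep_id(reps), domain = "data")
}

#' Combine replicates by log-averaging (geometric mean)
#'
#' The per-nucleotide mean of the natural-log measurements, exponentiated
#' back to the data domain -- equivalently the geometric mean of the
#' measurements, and the maximum-likelihood combiner under the log-normal
#' noise model (without a prior).
#'
#' @inheritParams average_profile
#' @return A data-domain [shape_profile].
#' @export
log_average_profile <- function(reps) {
  meas <- rep_measurements(reps)
  check_positive_measurements(meas)
  v <- exp(rowMeans(log(meas), na.rm = TRUE))
  v[!is.finite(v)] <- NA_real_
  shape_profile(v, rna_id = rep_id(reps), domain = "data")
}

#' Sample variance of log measurements
#'
#' The filter's estimate of the per-nucleotide measurement variance
#' sigma_w^2: the unbiased sample variance (N - 1 divisor) of the log
#' measurements. Nucleotides with fewer than two measurements carry no
#' variance information and are excluded from filtering.
#'
#' @param log_measurements numeric vector of at least 2 finite values.
#' @return The sample variance.
#' @export
sample_log_variance <- function(log_measurements) {
  x <- as.numeric(log_measurements)
  if (any(!is.finite(x)))
    stop("log measurements must be finite", call. = FALSE)
  if (length(x) < 2L)
    stop("sample_log_variance() needs at least 2 measurements", call. = FALSE)
  stats::var(x)
}

#' Scalar Kalman filter for one nucleotide
#'
#' Sequentially fuses the log measurements of one nucleotide with a Gaussian
#' prior N(mu0, sigma0) on its log reactivity. The state (the true log
#' reactivity) is constant across replicates, so the predict step is the
#' identity and each iteration is a single update: the gain
#' K_i = sigma_\{i-1\}^2 / (sigma_\{i-1\}^2 + sigma_w_hat^2) weighs the new
#' measurement against the running estimate; the estimate moves by
#' K_i (l_i - l_hat_\{i-1\}) and the posterior variance shrinks to
#' (1 - K_i) sigma_\{i-1\}^2. The measurement variance sigma_w_hat^2 is the
#' sample variance of the log measurements unless `meas_sd` overrides it
#' (required when only one measurement is available).
#'
#' Degenerate cases: a zero-variance prior pins the estimate at `mu0` (every
#' gain is 0); identical measurements (sample variance 0) return the common
#' value with zero posterior variance, the sigma_w -> 0 limit of the
#' posterior.
#'
#' @param log_measurements numeric vector of finite log measurements.
#' @param prior a [gaussian_prior] with scalar `mu`, `sigma`.
#' @param meas_sd optional measurement SD override (log domain).
#' @return An object of class `kalman_state`: list with `estimate` (final
#'   log-domain estimate), `variance` (posterior variance), `gains`
#'   (per-iteration Kalman gains, each in \[0, 1\]), `meas_var`
#'   (sigma_w_hat^2) and `n` (measurements used).
#' @examples
#' kalman_filter_nucleotide(c(0.5, 1.5), gaussian_prior(0, 1))$estimate
#' @export
kalman_filter_nucleotide <- function(log_measurements, prior,
                                     meas_sd = NULL) {
  prior <- as_prior(prior)
  if (length(prior$mu) != 1L || length(prior$sigma) != 1L)
    stop("kalman_filter_nucleotide() takes a scalar prior", call. = FALSE)
  l <- as.numeric(log_measurements)
  if (any(!is.finite(l)))
    stop("log measurements must be finite", call. = FALSE)
  n <- length(l)
  if (is.null(meas_sd)) {
    if (n < 2L)
      stop("need >= 2 measurements, or supply 'meas_sd' for a single one",
           call. = FALSE)
    mv <- sample_log_variance(l)
  } else {
    if (!is.numeric(meas_sd) || meas_sd < 0)
      stop("'meas_sd' must be >= 0", call. = FALSE)
    mv <- meas_sd^2
    if (mv == 0 && n > 1L && stats::var(l) > 0)
      stop("zero 'meas_sd' with non-identical measurements", call. = FALSE)
  }
  state <- function(est, v, gains) {
    structure(list(estimate = est, variance = v, gains = gains,
                   meas_var = mv, n = n), class = "kalman_state")
  }
  if (prior$sigma == 0)                  # gain 0 at every step
    return(state(prior$mu, 0, rep(0, n)))
  if (mv == 0)                           # sigma_w -> 0 limit of the posterior
    return(state(l[1L], 0, c(1, rep(0, n - 1L))))
  est <- prior$mu
  v <- prior$sigma^2
  gains <- numeric(n)
  for (i in seq_len(n)) {
    K <- v / (v + mv)
    est <- est + K * (l[i] - est)
    v <- v * mv / (v + mv)   # (1 - K) v, without cancellation for K near 1
    gains[i] <- K
  }
  state(est, v, gains)
}

#' @export
print.kalman_state <- function(x, ...) {
  cat(sprintf(
    "Kalman state: estimate %.4f (posterior var %.4g) after %d measurements\n",
    x$estimate, x$variance, x$n))
  invisible(x)
}

rep_measurements <- function(reps) {
  if (inherits(reps, "replicate_set")) return(reps$measurements)
  m <- as.matrix(reps)
  storage.mode(m) <- "double"
  m
}

rep_id <- function(reps) {
  if (inherits(reps, "replicate_set")) reps$rna_id else "RNA"
}

check_positive_measurements <- function(meas) {
  if (any(!is.na(meas) & meas <= 0))
    stop("measurements must be strictly positive for log-domain ",
         "processing; preprocess with replace_nonpositive() first",
         call. = FALSE)
  invisible(TRUE)
}

#' Fit the Kalman-filter denoising model to a replicate set
#'
#' Runs the per-nucleotide scalar Kalman filter ([kalman_filter_nucleotide()])
#' on the log-transformed measurements of every nucleotide, fusing them with
#' a Gaussian log-domain prior. The fitted object carries the log-domain
#' estimates, posterior variances, gain histories and estimated measurement
#' variances, and has the usual modelling methods: [coef()] (log-domain
#' estimates), [fitted()] (data-domain profile, exp of the estimates),
#' [residuals()] (log measurements minus estimate), `summary()`, `plot()`
#' and `simulate()` (new replicate sets drawn from the fitted model).
#'
#' Nucleotides with fewer than two positive measurements are excluded
#' (estimate `NA`) unless `meas_sd` supplies a fixed measurement SD.
#'
#' @param reps a [replicate_set] or numeric M x N matrix of strictly
#'   positive data-domain measurements (`NA` allowed).
#' @param prior a [gaussian_prior]; scalar (shared) or per-nucleotide
#'   vectors of length M. Default [shape_prior_default()], the reference
#'   database fit N(-1.74, 1.52).
#' @param meas_sd optional fixed measurement SD used for all nucleotides in
#'   place of the per-nucleotide sample SD (enables N = 1 filtering).
#' @return An object of class `shape_kalman`.
#' @examples
#' truth <- generate_ground_truth(100, seed = 1)
#' reps <- simulate_replicates(truth, N = 3, regime = "high", seed = 2)
#' fit <- shape_kalman(reps)
#' fit
#' head(coef(fit))
#' @export
shape_kalman <- function(reps, prior = shape_prior_default(),
                         meas_sd = NULL) {
  cl <- match.call()
  prior <- as_prior(prior)
  meas <- rep_measurements(reps)
  check_positive_measurements(meas)
  M <- nrow(meas)
  if (!(length(prior$mu) %in% c(1L, M)) || !(length(prior$sigma) %in% c(1L, M)))
    stop("prior must be scalar or per-nucleotide of length M", call. = FALSE)
  mu <- rep_len(prior$mu, M)
  sg <- rep_len(prior$sigma, M)
  logmeas <- log(meas)
  est <- rep(NA_real_, M)
  postvar <- rep(NA_real_, M)
  mvar <- rep(NA_real_, M)
  neff <- integer(M)
  gains <- vector("list", M)
  skipped <- 0L
  for (m in seq_len(M)) {
    lm_i <- logmeas[m, ]
    lm_i <- lm_i[!is.na(lm_i)]
    neff[m] <- length(lm_i)
    if (length(lm_i) == 0L || (length(lm_i) < 2L && is.null(meas_sd))) {
      skipped <- skipped + 1L
      next
    }
    st <- kalman_filter_nucleotide(lm_i, gaussian_prior(mu[m], sg[m]),
                                   meas_sd = meas_sd)
    est[m] <- st$estimate
    postvar[m] <- st$variance
    mvar[m] <- st$meas_var
    gains[[m]] <- st$gains
  }
  if (skipped > 0L)
    warning(skipped, " nucleotide(s) with fewer than 2 measurements were ",
            "excluded (estimate NA); supply 'meas_sd' to filter them",
            call. = FALSE)
  structure(list(estimates = est, posterior_var = postvar,
                 meas_var = mvar, gains = gains, n_measurements = neff,
                 prior = prior, log_measurements = logmeas,
                 rna_id = rep_id(reps),
                 ground_truth = if (inherits(reps, "replicate_set"))
                   reps$ground_truth else NULL,
                 call = cl),
            class = "shape_kalman")
}

#' Kalman-filtered reactivity profile
#'
#' Convenience wrapper around [shape_kalman()] returning just the denoised
#' data-domain profile (exp of the per-nucleotide log-domain estimates).
#'
#' @inheritParams shape_kalman
#' @return A data-domain [shape_profile].
#' @export
kalman_profile <- function(reps, prior = shape_prior_default(),
                           meas_sd = NULL) {
  fitted(shape_kalman(reps, prior = prior, meas_sd = meas_sd))
}

#' @export
print.shape_kalman <- function(x, ...) {
  M <- length(x$estimates)
  ok <- sum(!is.na(x$estimates))
  cat(sprintf("Kalman-filter SHAPE denoising fit ('%s')\n", x$rna_id))
  cat(sprintf("  %d nucleotides (%d filtered, %d excluded), N = %s replicates\n",
              M, ok, M - ok,
              paste(range(x$n_measurements), collapse = "-")))
  if (length(x$prior$mu) == 1L)
    cat(sprintf("  prior: N(%g, %g^2) on log reactivity\n",
                x$prior$mu, x$prior$sigma))
  else cat("  prior: per-nucleotide\n")
  invisible(x)
}

#' @export
coef.shape_kalman <- function(object, ...) object$estimates

#' @export
fitted.shape_kalman <- function(object, ...) {
  shape_profile(exp(object$estimates), rna_id = object$rna_id,
                domain = "data")
}

#' @export
residuals.shape_kalman <- function(object, ...) {
  sweep(object$log_measurements, 1L, object$estimates, `-`)
}

#' @export
summary.shape_kalman <- function(object, ...) {
  est <- object$estimates
  out <- list(
    fit = object,
    table = data.frame(position = seq_along(est),
                       estimate_log = est,
                       estimate = exp(est),
                       posterior_var = object$posterior_var,
                       meas_var = object$meas_var,
                       n = object$n_measurements),
    rms_vs_truth = if (!is.null(object$ground_truth))
      rms_error(shape_profile(est, object$rna_id, domain = "log"),
                to_log_domain(object$ground_truth)) else NA_real_)
  class(out) <- "summary.shape_kalman"
  out
}

#' @export
print.summary.shape_kalman <- function(x, ...) {
  print(x$fit)
  cat("Per-nucleotide estimates (first rows):\n")
  print(utils::head(x$table), row.names = FALSE, digits = 4)
  if (!is.na(x$rms_vs_truth))
    cat(sprintf("Log-domain RMS error vs ground truth: %.4f\n",
                x$rms_vs_truth))
  invisible(x)
}

#' @export
plot.shape_kalman <- function(x, ...) {
  prof <- exp(x$estimates)
  pos <- seq_along(prof)
  meas <- exp(x$log_measurements)
  graphics::matplot(pos, meas, pch = 1, col = "grey60",
                    xlab = "nucleotide position", ylab = "reactivity",
                    main = "Kalman-filtered SHAPE profile", ...)
  graphics::lines(pos, prof, col = "firebrick", lwd = 2)
  if (!is.null(x$ground_truth))
    graphics::lines(pos, as_values(x$ground_truth), col = "navy", lty = 2)
  invisible(x)
}

#' @export
simulate.shape_kalman <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  N <- ncol(object$log_measurements)
  sds <- sqrt(object$meas_var)
  sds[is.na(sds)] <- 0
  truth <- fitted(object)
  out <- vector("list", nsim)
  for (k in seq_len(nsim)) {
    meas <- matrix(NA_real_, length(truth), N)
    for (m in seq_along(truth)) {
      if (is.na(object$estimates[m])) next
      meas[m, ] <- exp(object$estimates[m] + stats::rnorm(N, 0, sds[m]))
    }
    out[[k]] <- replicate_set(meas, rna_id = object$rna_id,
                              ground_truth = truth, noise_sds = sds)
  }
  if (nsim == 1L) out[[1L]] else out
}
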