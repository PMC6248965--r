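#' Gaussian log-domain prior on nucleotide reactivities
#'
#' The Kalman filter fuses replicate measurements with a Gaussian prior on
#' the log reactivity of each nucleotide. `gaussian_prior()` builds a prior
#' shared by all nucleotides; `mu` and `sigma` may also be vectors of length
#' M for per-nucleotide priors (see [ideal_prior()]).
#' `shape_prior_default()` is the prior fit to a reference database of
#' 10690 processed, log-transformed SHAPE reactivities: mean -1.74, SD 1.52.
#'
#' @param mu prior mean(s) of the log reactivity.
#' @param sigma prior standard deviation(s), >= 0.
#' @return An object of class `gaussian_prior`.
#' @export
gaussian_prior <- function(mu, sigma) {
  mu <- as.numeric(mu); sigma <- as.numeric(sigma)
  if (any(!is.finite(mu)))
    stop("prior mean must be finite", call. = FALSE)
  if (any(!is.finite(sigma)) || any(sigma < 0))
    stop("prior sigma must be finite and >= 0", call. = FALSE)
  if (length(mu) != length(sigma) && length(mu) != 1L && length(sigma) != 1L)
    stop("'mu' and 'sigma' lengths must match or be scalar", call. = FALSE)
  structure(list(mu = mu, sigma = sigma), class = "gaussian_prior")
}

#' @rdname gaussian_prior
#' @export
shape_prior_default <- function() gaussian_prior(-1.74, 1.52)

#' @export
print.gaussian_prior <- function(x, ...) {
  if (length(x$mu) == 1L && length(x$sigma) == 1L) {
    cat(sprintf("Gaussian log-reactivity prior N(mu = %g, sigma = %g)\n",
                x$mu, x$sigma))
  } else {
    cat(sprintf("Per-nucleotide Gaussian priors (%d nucleotides)\n",
                max(length(x$mu), length(x$sigma))))
  }
  invisible(x)
}

as_prior <- function(x) {
  if (inherits(x, "gaussian_prior")) return(x)
  if (is.numeric(x) && length(x) == 2L) return(gaussian_prior(x[1L], x[2L]))
  stop("expected a gaussian_prior or a (mu, sigma) pair", call. = FALSE)
}

#' Fit a Gaussian prior to log reactivities
#'
#' Moment fit: the prior mean is the sample mean and the prior SD the sample
#' standard deviation (N - 1 divisor) of the supplied log reactivities.
#'
#' @param log_reactivities numeric vector (or log-domain [shape_profile]) of
#'   at least 2 finite values; `NA`s are dropped.
#' @return A [gaussian_prior].
#' @export
fit_prior <- function(log_reactivities) {
  v <- as_values(log_reactivities)
  v <- v[is.finite(v)]
  if (length(v) < 2L)
    stop("fit_prior() needs at least 2 finite log reactivities", call. = FALSE)
  gaussian_prior(mean(v), stats::sd(v))
}

#' Per-nucleotide "ideal" priors from known ground truth
#'
#' In simulation studies where the true log reactivity l_m of every
#' nucleotide is known, the ideal prior for nucleotide m is centred at l_m
#' with SD 0 (perfect information). Deviations from the ideal are modelled
#' by an additive mean offset (loss of accuracy) and an inflated SD (loss of
#' precision): the prior for nucleotide m is N(l_m + mu_offset, sigma).
#'
#' @param truth_log a log-domain [shape_profile] (or numeric vector of log
#'   reactivities).
#' @param mu_offset shift added to every prior mean; the reference study
#'   sweeps offsets in \[-3, 3\].
#' @param sigma common prior SD, >= 0; swept in \[0, 5\].
#' @return A per-nucleotide [gaussian_prior].
#' @export
ideal_prior <- function(truth_log, mu_offset = 0, sigma = 0) {
  if (is_profile(truth_log) && attr(truth_log, "domain") != "log")
    stop("'truth_log' must be in the log domain", call. = FALSE)
  lm <- as_values(truth_log)
  gaussian_prior(lm + mu_offset, rep(sigma, length(lm)))
}
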