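#' Noise regimes for replicate simulation
#'
#' A noise regime is a range of per-nucleotide log-domain noise standard
#' deviations; when simulating, each nucleotide's sigma is drawn uniformly
#' from the range. The named presets were calibrated on log-domain
#' measurement SDs observed across replicated SHAPE experiments:
#' low (0, 0.5), medium (0.5, 1), high (1, 1.5).
#'
#' @param regime a preset name (`"low"`, `"medium"`, `"high"`) or a numeric
#'   lower bound when `sigma_max` is given.
#' @param sigma_max upper bound for a custom regime.
#' @return An object of class `noise_regime` with fields `sigma_min`,
#'   `sigma_max`, `name`.
#' @examples
#' noise_regime("high")
#' noise_regime(0, 1.5)
#' @export
noise_regime <- function(regime = c("low", "medium", "high"),
                         sigma_max = NULL) {
  if (inherits(regime, "noise_regime")) return(regime)
  if (is.numeric(regime)) {
    sigma_min <- regime
    if (is.null(sigma_max))
      stop("custom regimes need both sigma_min and sigma_max", call. = FALSE)
    name <- "custom"
  } else {
    regime <- match.arg(regime)
    bounds <- switch(regime, low = c(0, 0.5), medium = c(0.5, 1),
                     high = c(1, 1.5))
    sigma_min <- bounds[1L]; sigma_max <- bounds[2L]; name <- regime
  }
  if (!is.finite(sigma_min) || !is.finite(sigma_max) || sigma_min < 0 ||
      sigma_max < sigma_min)
    stop("need 0 <= sigma_min <= sigma_max", call. = FALSE)
  structure(list(sigma_min = sigma_min, sigma_max = sigma_max, name = name),
            class = "noise_regime")
}

#' @export
print.noise_regime <- function(x, ...) {
  cat(sprintf("Noise regime '%s': sigma_w ~ U(%g, %g) (log domain)\n",
              x$name, x$sigma_min, x$sigma_max))
  invisible(x)
}

#' Draw per-nucleotide noise standard deviations
#'
#' @param regime a [noise_regime] or preset name.
#' @param M number of nucleotides.
#' @param seed optional integer seed.
#' @return Numeric vector of M log-domain noise SDs.
#' @export
sample_noise_sd <- function(regime, M, seed = NULL) {
  regime <- noise_regime(regime)
  if (!is.null(seed)) set.seed(seed)
  stats::runif(M, regime$sigma_min, regime$sigma_max)
}

#' Generate a synthetic ground-truth reactivity profile
#'
#' Per-nucleotide log reactivities are drawn from the Gaussian prior
#' (default the database fit, mean -1.74 and SD 1.52) and exponentiated,
#' emulating the skewed, log-normal distribution of normalized SHAPE
#' reactivities. All values are strictly positive, so the profile is
#' directly log-transformable.
#'
#' @param M number of nucleotides.
#' @param prior a [gaussian_prior()] for the log reactivities.
#' @param seed optional integer seed.
#' @param rna_id label for the profile.
#' @return A strictly positive data-domain [shape_profile].
#' @export
generate_ground_truth <- function(M, prior = shape_prior_default(),
                                  seed = NULL, rna_id = "synthetic") {
  prior <- as_prior(prior)
  if (!is.numeric(M) || length(M) != 1L || M < 1)
    stop("'M' must be a positive integer", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  l <- stats::rnorm(M, prior$mu, prior$sigma)
  shape_profile(exp(l), rna_id = rna_id, domain = "data")
}

#' Replicate measurements of one RNA
#'
#' A `replicate_set` stores an M x N matrix of data-domain measurements
#' (M nucleotides, N replicates), optionally together with the ground-truth
#' profile and the per-nucleotide noise SDs used in simulation.
#'
#' @param measurements numeric M x N matrix; `NA` marks missing
#'   measurements.
#' @param rna_id label for the RNA.
#' @param ground_truth optional data-domain [shape_profile] of length M.
#' @param noise_sds optional numeric vector of M log-domain noise SDs.
#' @return An object of class `replicate_set`.
#' @export
replicate_set <- function(measurements, rna_id = "RNA", ground_truth = NULL,
                          noise_sds = NULL) {
  measurements <- as.matrix(measurements)
  storage.mode(measurements) <- "double"
  if (ncol(measurements) < 1L || nrow(measurements) < 1L)
    stop("'measurements' must be a non-empty M x N matrix", call. = FALSE)
  M <- nrow(measurements)
  if (!is.null(ground_truth)) {
    if (!is_profile(ground_truth)) ground_truth <- shape_profile(ground_truth)
    if (length(ground_truth) != M)
      stop("ground_truth length must equal nrow(measurements)", call. = FALSE)
  }
  if (!is.null(noise_sds)) {
    noise_sds <- as.numeric(noise_sds)
    if (length(noise_sds) != M || any(noise_sds < 0, na.rm = TRUE))
      stop("noise_sds must be M non-negative values", call. = FALSE)
  }
  structure(list(rna_id = as.character(rna_id)[1L],
                 measurements = measurements,
                 ground_truth = ground_truth, noise_sds = noise_sds),
            class = "replicate_set")
}

#' @export
print.replicate_set <- function(x, ...) {
  cat(sprintf("Replicate set '%s': %d nucleotides x %d replicates%s\n",
              x$rna_id, nrow(x$measurements), ncol(x$measurements),
              if (!is.null(x$ground_truth)) ", with ground truth" else ""))
  invisible(x)
}

#' Simulate replicates under the log-normal noise model
#'
#' For each nucleotide m, one noise SD sigma_wm is drawn uniformly from the
#' regime and shared by all N replicates of that nucleotide; each log
#' measurement is the ground-truth log reactivity plus independent Gaussian
#' noise N(0, sigma_wm), exponentiated back to the data domain (equivalently,
#' the measurement is the truth times a log-normal multiplicative factor).
#' Simulated replicates are not re-normalized: the noise model describes
#' post-normalization variation. Draws are consumed in position order, so
#' the first M draws are stable under extension of the profile.
#'
#' @param truth a strictly positive data-domain [shape_profile].
#' @param N number of replicates (>= 1).
#' @param regime a [noise_regime] or preset name.
#' @param seed optional integer seed.
#' @return A [replicate_set] carrying `ground_truth` and `noise_sds`.
#' @examples
#' truth <- generate_ground_truth(50, seed = 1)
#' reps <- simulate_replicates(truth, N = 3, regime = "high", seed = 2)
#' @export
simulate_replicates <- function(truth, N, regime = "medium", seed = NULL) {
  if (!is_profile(truth)) truth <- shape_profile(truth)
  stopifnot_domain(truth, "data", "simulate_replicates()")
  v <- as_values(truth)
  if (any(!is.na(v) & v <= 0))
    stop("ground truth must be strictly positive; preprocess first",
         call. = FALSE)
  if (!is.numeric(N) || length(N) != 1L || N < 1)
    stop("'N' must be a positive integer", call. = FALSE)
  regime <- noise_regime(regime)
  if (!is.null(seed)) set.seed(seed)
  M <- length(v)
  sds <- stats::runif(M, regime$sigma_min, regime$sigma_max)
  lm <- log(v)
  meas <- matrix(NA_real_, M, N)
  for (m in seq_len(M)) {             # position order: M-prefix stable draws
    if (is.na(lm[m])) next
    meas[m, ] <- exp(lm[m] + stats::rnorm(N, 0, sds[m]))
  }
  replicate_set(meas, rna_id = attr(truth, "rna_id"),
                ground_truth = truth, noise_sds = sds)
}
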