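#' Sweep the replicate count for each combiner
#'
#' Simulates replicate sets at N = `N_values` from a synthetic ground-truth
#' profile and records the log-domain RMS error of the log-average and
#' Kalman-filter combiners at each N, per noise regime. A fresh simulation
#' is drawn for every (regime, N) cell.
#'
#' @param M number of nucleotides in the synthetic profile.
#' @param N_values replicate counts to sweep.
#' @param regimes character vector of regime presets.
#' @param prior [gaussian_prior] used both to generate the ground truth and
#'   as the filter prior.
#' @param seed integer seed.
#' @return A data.frame with columns `regime`, `N`, `method`, `rms`.
#' @export
replicate_count_sweep <- function(M = 10000, N_values = 2:10,
                                  regimes = c("low", "medium", "high"),
                                  prior = shape_prior_default(), seed = 1) {
  set.seed(seed)
  truth <- generate_ground_truth(M, prior)
  lt <- to_log_domain(truth)
  out <- expand.grid(regime = regimes, N = N_values,
                     method = c("logavg", "kalman"),
                     stringsAsFactors = FALSE)
  out$rms <- NA_real_
  for (rg in regimes) {
    for (N in N_values) {
      reps <- simulate_replicates(truth, N = N, regime = rg)
      la <- to_log_domain(log_average_profile(reps))
      kf <- to_log_domain(suppressWarnings(kalman_profile(reps, prior)))
      out$rms[out$regime == rg & out$N == N & out$method == "logavg"] <-
        rms_error(la, lt)
      out$rms[out$regime == rg & out$N == N & out$method == "kalman"] <-
        rms_error(kf, lt)
    }
  }
  out
}

#' Sweep prior accuracy and precision for the Kalman filter
#'
#' Builds per-nucleotide priors N(l_m + mu_offset, sigma0) from the known
#' ground truth ([ideal_prior()]) and records the log-domain RMS error of
#' the Kalman-filter profile for every (mu_offset, sigma0) combination,
#' alongside the log-average RMS as a prior-free baseline.
#'
#' @param M number of nucleotides.
#' @param N replicate count (default 3).
#' @param regime noise regime preset or [noise_regime].
#' @param offsets prior-mean offsets to sweep (default -3..3).
#' @param sigmas prior SDs to sweep (default 0..5).
#' @param truth_prior prior generating the synthetic ground truth.
#' @param seed integer seed.
#' @return A data.frame with columns `mu_offset`, `sigma0`, `rms`, plus
#'   attribute `rms_logavg`.
#' @export
prior_sweep <- function(M = 3000, N = 3, regime = "medium",
                        offsets = -3:3, sigmas = c(0, 0.5, 1, 2, 3, 5),
                        truth_prior = shape_prior_default(), seed = 1) {
  set.seed(seed)
  truth <- generate_ground_truth(M, truth_prior)
  lt <- to_log_domain(truth)
  reps <- simulate_replicates(truth, N = N, regime = regime)
  out <- expand.grid(mu_offset = offsets, sigma0 = sigmas)
  out$rms <- NA_real_
  for (r in seq_len(nrow(out))) {
    pr <- ideal_prior(lt, mu_offset = out$mu_offset[r],
                      sigma = out$sigma0[r])
    kf <- to_log_domain(suppressWarnings(kalman_profile(reps, pr)))
    out$rms[r] <- rms_error(kf, lt)
  }
  attr(out, "rms_logavg") <-
    rms_error(to_log_domain(log_average_profile(reps)), lt)
  out
}

#' Run the full simulation-study grid
#'
#' Reproduces the package's simulation studies at a configurable scale and
#' returns tidy tables: binned RMS heat maps for log-averaging and Kalman
#' filtering at N = 3 and N = 10 replicates, the RMS-versus-replicate-count
#' sweep per noise regime, and the prior accuracy/precision grid.
#'
#' @param M number of nucleotides in the synthetic ground truth.
#' @param seed integer seed governing all simulations.
#' @param heatmap_N replicate counts for the heat maps.
#' @param sweep_N replicate counts for the replicate-count sweep.
#' @param prior the shared Gaussian prior.
#' @return A named list of data.frames: `heatmaps`, `replicate_sweep`,
#'   `prior_grid`.
#' @export
run_experiment_grid <- function(M = 10000, seed = 1, heatmap_N = c(3, 10),
                                sweep_N = 2:10,
                                prior = shape_prior_default()) {
  set.seed(seed)
  truth <- generate_ground_truth(M, prior)
  hm <- do.call(rbind, lapply(heatmap_N, function(N) {
    reps <- simulate_replicates(truth, N = N, regime = noise_regime(0, 1.5))
    res <- lapply(c(logavg = "logavg", kalman = "kalman"), function(meth) {
      est <- if (meth == "logavg") log_average_profile(reps)
             else suppressWarnings(kalman_profile(reps, prior))
      g <- rms_heatmap(reps, est)
      data.frame(N = N, method = meth,
                 truth_bin = rep(seq_len(nrow(g)), ncol(g)),
                 sigma_bin = rep(seq_len(ncol(g)), each = nrow(g)),
                 rms = as.vector(g))
    })
    do.call(rbind, res)
  }))
  rownames(hm) <- NULL
  list(heatmaps = hm,
       replicate_sweep = replicate_count_sweep(M = M, N_values = sweep_N,
                                               prior = prior,
                                               seed = seed + 1L),
       prior_grid = prior_sweep(M = min(M, 3000), seed = seed + 2L,
                                truth_prior = prior))
}
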