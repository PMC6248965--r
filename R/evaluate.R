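#' Log-domain root-mean-square error against ground truth
#'
#' RMS = sqrt( sum_m (l_hat_m - l_m)^2 / M' ) over the M' positions
#' non-missing in both profiles. Denoising accuracy is assessed in the log
#' domain, where the noise model is additive; pass `domain = "data"` to
#' compare raw reactivities instead.
#'
#' @param estimates,truth [shape_profile]s (or numeric vectors) of equal
#'   length. Log-domain profiles are compared as-is; data-domain profiles
#'   are log-transformed first when `domain = "log"`.
#' @param domain domain in which to compute the error.
#' @return The RMS error (a scalar).
#' @examples
#' rms_error(shape_profile(c(1, 2), domain = "log"),
#'           shape_profile(c(0, 0), domain = "log"))   # sqrt(2.5)
#' @export
rms_error <- function(estimates, truth, domain = c("log", "data")) {
  domain <- match.arg(domain)
  to_dom <- function(x) {
    if (!is_profile(x)) x <- shape_profile(x, domain = domain)
    if (attr(x, "domain") == domain) return(as_values(x))
    if (domain == "log") as_values(to_log_domain(x)) else exp(as_values(x))
  }
  e <- to_dom(estimates); t <- to_dom(truth)
  if (length(e) != length(t))
    stop("profiles must have equal length", call. = FALSE)
  ok <- !is.na(e) & !is.na(t)
  if (!any(ok))
    stop("no positions comparable in both profiles", call. = FALSE)
  sqrt(mean((e[ok] - t[ok])^2))
}

#' Base-pair confusion counts between two secondary structures
#'
#' Compares a predicted against a reference structure of the same length M
#' over the universe of all M(M-1)/2 unordered position pairs: TP are pairs
#' present in both structures, FP only in the prediction, FN only in the
#' reference, and TN the remaining possible pairs in neither.
#'
#' @param predicted,reference [secondary_structure]s of equal length.
#' @return A list of class `confusion_counts` with integer fields `TP`,
#'   `FP`, `TN`, `FN` summing to M(M-1)/2.
#' @export
confusion_counts <- function(predicted, reference) {
  if (!inherits(predicted, "secondary_structure") ||
      !inherits(reference, "secondary_structure"))
    stop("inputs must be secondary_structure objects", call. = FALSE)
  if (predicted$length != reference$length)
    stop("structures must have equal length", call. = FALSE)
  M <- predicted$length
  key <- function(s) paste(s$pairs[, 1L], s$pairs[, 2L])
  p <- key(predicted); r <- key(reference)
  TP <- length(intersect(p, r))
  FP <- length(setdiff(p, r))
  FN <- length(setdiff(r, p))
  TN <- M * (M - 1) / 2 - TP - FP - FN
  structure(list(TP = TP, FP = FP, TN = TN, FN = FN, length = M),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("Base-pair confusion (M = %d): TP %d, FP %d, TN %d, FN %d\n",
              x$length, x$TP, x$FP, x$TN, x$FN))
  invisible(x)
}

#' Matthews correlation coefficient of a structure prediction
#'
#' MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)), computed
#' from base-pair confusion counts. If any factor of the denominator is
#' zero, 0 is returned (the standard convention). Values lie in \[-1, 1\],
#' with 1 for a perfect prediction.
#'
#' @param counts a [confusion_counts()] result, or a predicted
#'   [secondary_structure] when `reference` is given.
#' @param reference optional reference structure; if supplied, counts are
#'   computed first.
#' @return The MCC (a scalar).
#' @examples
#' mcc(read_dotbracket("((...))"), read_dotbracket("((...))"))   # 1
#' @export
mcc <- function(counts, reference = NULL) {
  if (!is.null(reference)) counts <- confusion_counts(counts, reference)
  if (!inherits(counts, "confusion_counts"))
    stop("'counts' must be confusion_counts (or supply two structures)",
         call. = FALSE)
  tp <- counts$TP; fp <- counts$FP; tn <- counts$TN; fn <- counts$FN
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

#' Mean-SD log-log heteroskedasticity diagnostic
#'
#' For each nucleotide with at least two strictly positive measurements,
#' computes the data-domain mean and sample SD across replicates, then fits
#' ordinary least squares of log(SD) on log(mean). Under the log-normal
#' (multiplicative) noise model the SD is proportional to the mean, so the
#' slope is close to 1; under additive data-domain noise it is close to 0.
#' Non-positive measurements and nucleotides with zero SD are excluded.
#'
#' @param reps a [replicate_set] or numeric M x N matrix.
#' @return A list of class `mean_sd_fit`: `slope`, `intercept`, `n_points`,
#'   and the per-nucleotide `means` and `sds` used.
#' @export
mean_sd_fit <- function(reps) {
  meas <- rep_measurements(reps)
  meas[!is.na(meas) & meas <= 0] <- NA_real_
  n <- rowSums(!is.na(meas))
  mu <- rowMeans(meas, na.rm = TRUE)
  sd_ <- apply(meas, 1L, stats::sd, na.rm = TRUE)
  keep <- which(n >= 2L & is.finite(sd_) & sd_ > 0 & mu > 0)
  if (length(keep) < 2L)
    stop("need at least 2 nucleotides with >= 2 positive measurements and ",
         "non-zero SD", call. = FALSE)
  fit <- stats::lm(log(sd_[keep]) ~ log(mu[keep]))
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 n_points = length(keep),
                 means = mu[keep], sds = sd_[keep]),
            class = "mean_sd_fit")
}

#' @export
print.mean_sd_fit <- function(x, ...) {
  cat(sprintf(
    "log(SD) ~ log(mean) OLS over %d nucleotides: slope %.3f, intercept %.3f\n",
    x$n_points, x$slope, x$intercept))
  invisible(x)
}

#' @export
plot.mean_sd_fit <- function(x, ...) {
  graphics::plot(log(x$means), log(x$sds), pch = 16, cex = 0.5,
                 xlab = "log mean reactivity", ylab = "log measurement SD",
                 main = "Replicate heteroskedasticity diagnostic", ...)
  graphics::abline(x$intercept, x$slope, col = "red", lwd = 2)
  invisible(x)
}

#' Binned RMS error by ground truth and noise level
#'
#' Bins the nucleotides of a simulated replicate set by ground-truth
#' reactivity s_m and noise SD sigma_wm, and computes the log-domain RMS
#' error of a denoised profile within each bin. Empty bins are `NA`.
#'
#' @param reps a [replicate_set] carrying `ground_truth` and `noise_sds`.
#' @param estimate a data-domain [shape_profile] of denoised reactivities
#'   (e.g. from [log_average_profile()] or [kalman_profile()]).
#' @param truth_breaks,sigma_breaks bin edges for s_m and sigma_wm; a single
#'   integer gives that many equal-width bins over the observed range.
#' @return A matrix of RMS values (rows: truth bins, columns: sigma bins),
#'   with bin edges as attributes `truth_breaks`, `sigma_breaks`.
#' @export
rms_heatmap <- function(reps, estimate, truth_breaks = 5, sigma_breaks = 5) {
  if (!inherits(reps, "replicate_set") || is.null(reps$ground_truth) ||
      is.null(reps$noise_sds))
    stop("rms_heatmap() needs a simulated replicate_set with ground_truth ",
         "and noise_sds", call. = FALSE)
  s <- as_values(reps$ground_truth)
  sg <- reps$noise_sds
  lhat <- as_values(to_log_domain(estimate))
  lm_ <- log(s)
  edges <- function(br, x) {
    if (length(br) == 1L) seq(min(x, na.rm = TRUE), max(x, na.rm = TRUE),
                              length.out = br + 1L) else br
  }
  tb <- edges(truth_breaks, s)
  sb <- edges(sigma_breaks, sg)
  ti <- cut(s, tb, include.lowest = TRUE, labels = FALSE)
  si <- cut(sg, sb, include.lowest = TRUE, labels = FALSE)
  grid <- matrix(NA_real_, length(tb) - 1L, length(sb) - 1L)
  for (a in seq_len(nrow(grid))) {
    for (b in seq_len(ncol(grid))) {
      idx <- which(ti == a & si == b & !is.na(lhat) & !is.na(lm_))
      if (length(idx))
        grid[a, b] <- sqrt(mean((lhat[idx] - lm_[idx])^2))
    }
  }
  attr(grid, "truth_breaks") <- tb
  attr(grid, "sigma_breaks") <- sb
  grid
}
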