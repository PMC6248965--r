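#' Box-plot outlier detection for a reactivity profile
#'
#' Flags the upper-tail outliers of a profile: values greater than
#' Q3 + 1.5 IQR, with quartiles computed by linear interpolation between
#' order statistics (base R's default type-7 quantiles, configurable). The
#' flagged set is capped at 5% of the non-missing values for RNAs shorter
#' than 100 nt and 10% otherwise; when the cap binds, the largest values are
#' kept, ties broken towards lower position.
#'
#' @param profile a data-domain [shape_profile] with at least 4 non-missing
#'   values.
#' @param quantile_type quantile algorithm passed to [stats::quantile()].
#' @return Integer vector of 1-based outlier positions (possibly empty).
#' @export
detect_outliers <- function(profile, quantile_type = 7) {
  if (!is_profile(profile)) profile <- shape_profile(profile)
  stopifnot_domain(profile, "data", "detect_outliers()")
  v <- as_values(profile)
  ok <- which(!is.na(v))
  if (length(ok) < 4L)
    stop("outlier detection needs at least 4 non-missing values",
         call. = FALSE)
  q <- stats::quantile(v[ok], c(0.25, 0.75), type = quantile_type,
                       names = FALSE)
  thr <- q[2L] + 1.5 * (q[2L] - q[1L])
  cand <- ok[v[ok] > thr]
  cap <- floor(ifelse(length(v) < 100L, 0.05, 0.10) * length(ok))
  if (length(cand) > cap) {
    ord <- cand[order(-v[cand], cand)]
    cand <- ord[seq_len(cap)]
  }
  sort(cand)
}

#' Normalization factor from the top reactive band
#'
#' The factor is the mean of the most reactive band of nucleotides (default
#' the top 10%), so that dividing the profile by it brings typical
#' reactivities onto the 0-2 scale. Two variants are provided: `"exclude"`
#' computes the band over non-outlier values (the convention used when
#' assembling reference databases), `"include"` over all non-missing values.
#'
#' @param profile a data-domain [shape_profile].
#' @param outliers integer positions from [detect_outliers()] (ignored by
#'   the `"include"` variant).
#' @param top_fraction fraction of values averaged for the factor, in
#'   (0, 0.2]; default 0.10.
#' @param variant `"exclude"` or `"include"` outliers in the factor
#'   computation.
#' @return A positive scalar.
#' @export
normalization_factor <- function(profile, outliers = integer(0),
                                 top_fraction = 0.10,
                                 variant = c("exclude", "include")) {
  variant <- match.arg(variant)
  if (!is.numeric(top_fraction) || top_fraction <= 0 || top_fraction > 0.2)
    stop("'top_fraction' must be in (0, 0.2]", call. = FALSE)
  if (!is_profile(profile)) profile <- shape_profile(profile)
  stopifnot_domain(profile, "data", "normalization_factor()")
  v <- as_values(profile)
  keep <- which(!is.na(v))
  if (length(keep) < 10L)
    stop("normalization needs at least 10 non-missing values", call. = FALSE)
  if (variant == "exclude") keep <- setdiff(keep, outliers)
  vals <- sort(v[keep], decreasing = TRUE)
  k <- ceiling(top_fraction * length(vals))
  fac <- mean(vals[seq_len(k)])
  if (!is.finite(fac) || fac <= 0)
    stop("normalization factor is non-positive; profile has no reactive ",
         "band to scale by", call. = FALSE)
  fac
}

#' Normalize a reactivity profile by its top reactive band
#'
#' Composes [detect_outliers()] and [normalization_factor()], then divides
#' every non-missing value of the profile -- outliers and negatives
#' included -- by the factor.
#'
#' @inheritParams normalization_factor
#' @return A list of class `normalization_result` with elements `normalized`
#'   (the scaled [shape_profile]), `factor`, `outlier_positions` and
#'   `variant`.
#' @examples
#' p <- shape_profile(1:10)
#' normalize_profile(p)$normalized    # 0.1, 0.2, ..., 1.0
#' @export
normalize_profile <- function(profile, top_fraction = 0.10,
                              variant = c("exclude", "include"),
                              quantile_type = 7) {
  variant <- match.arg(variant)
  if (!is_profile(profile)) profile <- shape_profile(profile)
  out <- detect_outliers(profile, quantile_type = quantile_type)
  fac <- normalization_factor(profile, out, top_fraction, variant)
  v <- as_values(profile) / fac
  structure(list(normalized = shape_profile(v, attr(profile, "rna_id")),
                 factor = fac, outlier_positions = out, variant = variant),
            class = "normalization_result")
}

#' @export
print.normalization_result <- function(x, ...) {
  cat(sprintf("Normalization (%s outliers): factor %.4g, %d outlier(s)\n",
              x$variant, x$factor, length(x$outlier_positions)))
  invisible(x)
}
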