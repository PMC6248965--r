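#' Build an empirical background distribution of negative reactivities
#'
#' Background-subtracted SHAPE profiles routinely contain negative and zero
#' reactivities, which are incompatible with the log transform the noise
#' model requires. Rather than zeroing them, non-positive values are
#' replaced by draws from the empirical distribution of negative values
#' observed across a set of profiles, truncated at a cutoff to remove the
#' long tail (default cutoff -0.25).
#'
#' @param profiles a data-domain [shape_profile] or a list of them.
#' @param cutoff truncation cutoff (must be negative); values below it are
#'   discarded from the background set.
#' @return An object of class `background_distribution` holding the retained
#'   negative values (all in `[cutoff, 0)`) and the cutoff.
#' @seealso [replace_nonpositive()]
#' @export
build_background <- function(profiles, cutoff = -0.25) {
  if (!is.numeric(cutoff) || length(cutoff) != 1L || !is.finite(cutoff) ||
      cutoff >= 0)
    stop("'cutoff' must be a single negative number", call. = FALSE)
  if (is_profile(profiles) || is.numeric(profiles)) profiles <- list(profiles)
  vals <- unlist(lapply(profiles, function(p) {
    stopifnot_domain(p, "data", "build_background()")
    as_values(p)
  }), use.names = FALSE)
  vals <- vals[!is.na(vals)]
  keep <- vals[vals < 0 & vals >= cutoff]
  if (length(keep) == 0L)
    warning("no negative reactivities in [cutoff, 0); background ",
            "distribution is empty and cannot be used for replacement",
            call. = FALSE)
  structure(list(samples = keep, cutoff = cutoff),
            class = "background_distribution")
}

#' @export
print.background_distribution <- function(x, ...) {
  cat(sprintf("Background distribution: %d negative reactivities in [%g, 0)\n",
              length(x$samples), x$cutoff))
  invisible(x)
}

#' Replace non-positive reactivities by background draws
#'
#' Every reactivity <= 0 is replaced by the absolute value of a draw (uniform
#' with replacement) from the truncated background distribution, making the
#' profile strictly positive and therefore log-transformable. Positive and
#' missing entries are untouched. Replacement values lie in `(0, |cutoff|]`
#' by construction.
#'
#' @param profile a data-domain [shape_profile].
#' @param bg a non-empty [build_background()] result.
#' @param seed optional integer seed for reproducible replacement.
#' @return A strictly positive data-domain [shape_profile].
#' @export
replace_nonpositive <- function(profile, bg, seed = NULL) {
  if (!inherits(bg, "background_distribution"))
    stop("'bg' must be a background_distribution", call. = FALSE)
  if (length(bg$samples) == 0L)
    stop("background distribution is empty; cannot replace non-positive ",
         "reactivities", call. = FALSE)
  if (!is_profile(profile)) profile <- shape_profile(profile)
  stopifnot_domain(profile, "data", "replace_nonpositive()")
  if (!is.null(seed)) set.seed(seed)
  v <- as_values(profile)
  tgt <- which(!is.na(v) & v <= 0)
  if (length(tgt))
    v[tgt] <- abs(sample(bg$samples, length(tgt), replace = TRUE))
  shape_profile(v, rna_id = attr(profile, "rna_id"), domain = "data")
}
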