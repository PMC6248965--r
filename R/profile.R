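#' Per-nucleotide reactivity profile
#'
#' A `shape_profile` holds the reactivities of one RNA, one value per
#' nucleotide at positions 1..M. Values may be missing (`NA`); on disk
#' missing values are written as -999 (see [write_shape()]). A profile is
#' tagged with the domain it lives in: `"data"` for raw reactivities,
#' `"log"` for their natural logarithms.
#'
#' @param reactivities numeric vector of per-nucleotide values; `NA` marks a
#'   missing value.
#' @param rna_id character label for the RNA.
#' @param domain `"data"` or `"log"`.
#' @return An object of class `shape_profile`: a numeric vector with
#'   attributes `rna_id` and `domain`.
#' @examples
#' p <- shape_profile(c(0.5, NA, 1.2), rna_id = "hairpin")
#' length(p)
#' @export
shape_profile <- function(reactivities, rna_id = "RNA", domain = c("data", "log")) {
  domain <- match.arg(domain)
  if (!is.numeric(reactivities) || length(reactivities) < 1L)
    stop("'reactivities' must be a non-empty numeric vector", call. = FALSE)
  x <- as.numeric(reactivities)
  if (domain == "log" && any(!is.finite(x[!is.na(x)])))
    stop("log-domain profiles must contain only finite values", call. = FALSE)
  structure(x, rna_id = as.character(rna_id)[1L], domain = domain,
            class = "shape_profile")
}

#' @export
print.shape_profile <- function(x, ...) {
  n <- length(x)
  cat(sprintf("SHAPE reactivity profile '%s' (%s domain): %d nt, %d missing\n",
              attr(x, "rna_id"), attr(x, "domain"), n, sum(is.na(x))))
  show <- utils::head(unclass(x), 10L)
  cat(" ", paste(format(show, digits = 4), collapse = " "),
      if (n > 10L) "...\n" else "\n")
  invisible(x)
}

#' @export
`[.shape_profile` <- function(x, i, ...) {
  structure(NextMethod(), rna_id = attr(x, "rna_id"),
            domain = attr(x, "domain"), class = "shape_profile")
}

is_profile <- function(x) inherits(x, "shape_profile")

profile_domain <- function(x) {
  if (is_profile(x)) attr(x, "domain") else "data"
}

as_values <- function(x) {
  if (is_profile(x)) as.numeric(unclass(x)) else as.numeric(x)
}

stopifnot_domain <- function(x, domain, what) {
  if (is_profile(x) && attr(x, "domain") != domain)
    stop(sprintf("%s requires a %s-domain profile, got %s domain",
                 what, domain, attr(x, "domain")), call. = FALSE)
  invisible(TRUE)
}

#' Transform a profile between the data and log domains
#'
#' The noise model is additive Gaussian in the log domain, so replicate
#' combination is carried out on natural logarithms of the reactivities.
#' `to_log_domain()` requires every non-missing value to be strictly
#' positive (see [replace_nonpositive()] for making profiles positive);
#' `from_log_domain()` is its exact inverse, exponentiating back to the
#' data domain. Missing values propagate through both transforms.
#'
#' @param profile a [shape_profile] in the appropriate domain, or a bare
#'   numeric vector (treated as data-domain for `to_log_domain`).
#' @return A [shape_profile] in the other domain.
#' @examples
#' p <- shape_profile(c(1, exp(1), NA))
#' to_log_domain(p)                      # 0, 1, NA
#' from_log_domain(to_log_domain(p))     # back to 1, e, NA
#' @export
to_log_domain <- function(profile) {
  stopifnot_domain(profile, "data", "to_log_domain()")
  v <- as_values(profile)
  bad <- which(!is.na(v) & v <= 0)
  if (length(bad))
    stop("non-positive reactivities at position(s) ",
         paste(utils::head(bad, 10L), collapse = ", "),
         "; preprocess with replace_nonpositive() first", call. = FALSE)
  shape_profile(log(v), rna_id = attr(profile, "rna_id") %||% "RNA",
                domain = "log")
}

#' @rdname to_log_domain
#' @export
from_log_domain <- function(profile) {
  if (!is_profile(profile) || attr(profile, "domain") != "log")
    stop("from_log_domain() requires a log-domain shape_profile", call. = FALSE)
  shape_profile(exp(as_values(profile)),
                rna_id = attr(profile, "rna_id"), domain = "data")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
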