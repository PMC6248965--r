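#' Read a two-column SHAPE reactivity file
#'
#' Reads the standard two-column text format used by SHAPE-directed folding
#' tools: column 1 is the 1-based nucleotide position (ascending, contiguous
#' from 1), column 2 the reactivity. The value -999 marks a missing
#' reactivity; any value at or below -500 is treated as missing on read, to
#' tolerate -999.0 dialects.
#'
#' @param path path to a whitespace- or tab-delimited two-column file.
#' @param rna_id label for the profile; defaults to the file name.
#' @return A data-domain [shape_profile].
#' @seealso [write_shape()]
#' @export
read_shape <- function(path, rna_id = NULL) {
  tab <- tryCatch(
    utils::read.table(path, header = FALSE, colClasses = "numeric"),
    error = function(e) stop("cannot parse SHAPE file '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (ncol(tab) < 2L)
    stop("SHAPE file '", path, "' must have two columns", call. = FALSE)
  pos <- tab[[1L]]
  if (any(pos != as.integer(pos)))
    stop("non-integer positions in '", path, "'", call. = FALSE)
  if (!identical(as.integer(pos), seq_len(nrow(tab))))
    stop("positions in '", path,
         "' must be contiguous and ascending from 1", call. = FALSE)
  val <- tab[[2L]]
  val[val <= -500] <- NA_real_
  shape_profile(val, rna_id = rna_id %||% basename(path), domain = "data")
}

#' Write a profile to a two-column SHAPE reactivity file
#'
#' Missing values are written as -999. Only data-domain profiles are
#' written; convert log-domain estimates with [from_log_domain()] first.
#'
#' @param profile a data-domain [shape_profile].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_shape <- function(profile, path) {
  if (!is_profile(profile))
    profile <- shape_profile(profile)
  if (attr(profile, "domain") != "data")
    stop("write_shape() writes data-domain profiles only", call. = FALSE)
  v <- as_values(profile)
  v[is.na(v)] <- -999
  lines <- sprintf("%d\t%s", seq_along(v), format(v, digits = 15, trim = TRUE,
                                                  scientific = FALSE))
  writeLines(lines, path)
  invisible(path)
}

#' RNA secondary structure as a set of base pairs
#'
#' Stores a secondary structure of an RNA of length `length` as a set of
#' unordered base pairs (i, j), 1-based with i < j, each index appearing in
#' at most one pair. Used for Matthews-correlation comparison of a predicted
#' against a reference structure ([confusion_counts()], [mcc()]).
#'
#' @param length number of nucleotides M.
#' @param pairs two-column integer matrix (or data.frame) of paired
#'   positions; may be empty.
#' @return An object of class `secondary_structure`.
#' @export
secondary_structure <- function(length, pairs = matrix(integer(), ncol = 2L)) {
  length <- as.integer(length)
  if (is.na(length) || length < 1L)
    stop("'length' must be a positive integer", call. = FALSE)
  pairs <- as.matrix(pairs)
  if (nrow(pairs) == 0L) {
    pairs <- matrix(integer(), ncol = 2L)
  } else {
    storage.mode(pairs) <- "integer"
    if (ncol(pairs) != 2L) stop("'pairs' must have two columns", call. = FALSE)
    pairs <- cbind(pmin(pairs[, 1L], pairs[, 2L]),
                   pmax(pairs[, 1L], pairs[, 2L]))
    if (any(pairs[, 1L] < 1L) || any(pairs[, 2L] > length) ||
        any(pairs[, 1L] == pairs[, 2L]))
      stop("pair indices must satisfy 1 <= i < j <= length", call. = FALSE)
    idx <- as.vector(pairs)
    if (anyDuplicated(idx))
      stop("each position may appear in at most one base pair", call. = FALSE)
    pairs <- pairs[order(pairs[, 1L]), , drop = FALSE]
  }
  dimnames(pairs) <- list(NULL, c("i", "j"))
  structure(list(length = length, pairs = pairs),
            class = "secondary_structure")
}

#' @export
print.secondary_structure <- function(x, ...) {
  cat(sprintf("Secondary structure: %d nt, %d base pairs\n",
              x$length, nrow(x$pairs)))
  invisible(x)
}

#' Read a secondary structure from a CT file
#'
#' Parses the standard six-column connectivity-table format: a header line
#' whose first field is the sequence length, then one row per nucleotide
#' (index, base, previous, next, pairing partner or 0, natural index).
#' Pairing must be symmetric (if i pairs j then j pairs i).
#'
#' @param path path to a CT file.
#' @return A [secondary_structure].
#' @export
read_ct <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 1L) stop("empty CT file '", path, "'", call. = FALSE)
  hdr <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  M <- suppressWarnings(as.integer(hdr[1L]))
  if (is.na(M) || M < 1L)
    stop("CT header of '", path, "' must start with the length", call. = FALSE)
  if (length(lines) < M + 1L)
    stop("CT file '", path, "' has fewer rows than its header length",
         call. = FALSE)
  body <- lines[2L:(M + 1L)]
  fields <- strsplit(trimws(body), "\\s+")
  partner <- integer(M)
  for (r in seq_len(M)) {
    f <- fields[[r]]
    if (length(f) < 6L)
      stop("CT row ", r, " in '", path, "' has fewer than 6 columns",
           call. = FALSE)
    idx <- suppressWarnings(as.integer(f[1L]))
    if (is.na(idx) || idx != r)
      stop("CT row ", r, " in '", path, "' has index ", f[1L], call. = FALSE)
    partner[r] <- suppressWarnings(as.integer(f[5L]))
    if (is.na(partner[r]) || partner[r] < 0L || partner[r] > M)
      stop("invalid pairing index in CT row ", r, call. = FALSE)
  }
  paired <- which(partner > 0L)
  bad <- paired[partner[partner[paired]] != paired]
  if (length(bad))
    stop("asymmetric pairing in '", path, "' at position(s) ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  i <- paired[paired < partner[paired]]
  secondary_structure(M, cbind(i, partner[i]))
}

#' Decode a dot-bracket string into a secondary structure
#'
#' Supports the plain nested alphabet `.`, `(`, `)`. Pseudoknotted
#' structures (extra bracket alphabets) are not supported and must be
#' supplied as CT files.
#'
#' @param text a dot-bracket string.
#' @return A [secondary_structure].
#' @examples
#' read_dotbracket("((...))")   # pairs (1,7) and (2,6)
#' @export
read_dotbracket <- function(text) {
  chars <- strsplit(text, "")[[1L]]
  if (length(chars) < 1L) stop("empty dot-bracket string", call. = FALSE)
  if (!all(chars %in% c(".", "(", ")")))
    stop("unsupported characters in dot-bracket string; only '.', '(' and ",
         "')' are accepted (pseudoknots must come as CT)", call. = FALSE)
  stack <- integer(0)
  pairs <- matrix(integer(), ncol = 2L)
  open <- list()
  for (k in seq_along(chars)) {
    if (chars[k] == "(") {
      stack <- c(stack, k)
    } else if (chars[k] == ")") {
      if (length(stack) == 0L)
        stop("unbalanced dot-bracket string: unmatched ')' at position ", k,
             call. = FALSE)
      i <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pairs <- rbind(pairs, c(i, k))
    }
  }
  if (length(stack))
    stop("unbalanced dot-bracket string: unmatched '(' at position ",
         stack[1L], call. = FALSE)
  secondary_structure(length(chars), pairs)
}
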