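# Fixture builders shared across tests. Everything is generated in code;
# no binary or stored data.

# A 5-nt hairpin CT file pairing 1<->5 and 2<->4.
write_hairpin_ct <- function(path = tempfile(fileext = ".ct")) {
  writeLines(c(
    "5 hairpin",
    "1 G 0 2 5 1",
    "2 C 1 3 4 2",
    "3 A 2 4 0 3",
    "4 G 3 5 2 4",
    "5 C 4 6 1 5"), path)
  path
}

# Random nested dot-bracket string of length n (pair probability p).
random_dotbracket <- function(n, p = 0.4) {
  chars <- character(n)
  stack <- integer(0)
  for (k in seq_len(n)) {
    remaining <- n - k
    if (length(stack) > 0 && (remaining < length(stack) ||
                              stats::runif(1) < p / 2)) {
      chars[k] <- ")"
      stack <- stack[-length(stack)]
    } else if (remaining > length(stack) && stats::runif(1) < p) {
      chars[k] <- "("
      stack <- c(stack, k)
    } else {
      chars[k] <- "."
    }
  }
  while (length(stack) > 0) {  # close leftovers by dotting them out
    chars[stack[length(stack)]] <- "."
    stack <- stack[-length(stack)]
  }
  paste(chars, collapse = "")
}

# Encode a secondary_structure as CT text (for cross-format agreement tests).
structure_to_ct <- function(ss, path = tempfile(fileext = ".ct")) {
  partner <- integer(ss$length)
  if (nrow(ss$pairs) > 0) {
    partner[ss$pairs[, 1]] <- ss$pairs[, 2]
    partner[ss$pairs[, 2]] <- ss$pairs[, 1]
  }
  rows <- sprintf("%d N %d %d %d %d", seq_len(ss$length),
                  seq_len(ss$length) - 1L,
                  seq_len(ss$length) + 1L, partner, seq_len(ss$length))
  writeLines(c(sprintf("%d synthetic", ss$length), rows), path)
  path
}

# Random secondary structure (not necessarily nested) of length M.
random_structure <- function(M, npairs) {
  idx <- sample(M, 2L * npairs)
  secondary_structure(M, cbind(idx[seq_len(npairs)],
                               idx[npairs + seq_len(npairs)]))
}

# Closed-form conjugate-normal posterior: the independent oracle for the
# iterative filter.
posterior_oracle <- function(l, mu0, sigma0, meas_var) {
  n <- length(l)
  prec <- 1 / sigma0^2 + n / meas_var
  list(mean = (mu0 / sigma0^2 + sum(l) / meas_var) / prec,
       var = 1 / prec)
}
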