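## Internal helpers shared across modules.

#' Derive a child seed from a master seed
#'
#' Deterministic fan-out of one master seed into per-stage / per-node seeds,
#' kept inside the 32-bit integer range.
#'
#' @param seed master seed (integer).
#' @param i stream index (integer >= 0).
#' @return an integer seed.
#' @keywords internal
seed_stream <- function(seed, i) {
  ## Lehmer-style mix; modulus 2^31 - 1 keeps the result a valid R integer
  as.integer((as.numeric(seed) * 48271 + as.numeric(i) * 8191 + 1) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_orgsc <- function(...) stop(..., call. = FALSE)

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop_orgsc(msg)
  invisible(TRUE)
}

DNA_ALPHABET <- c("A", "C", "G", "T")

## random DNA string(s)
random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(DNA_ALPHABET, len, replace = TRUE), collapse = "")
  }, character(1))
}

## encode integers in [0, 4^len) as DNA of fixed length
int_to_dna <- function(x, len) {
  out <- character(length(x))
  chars <- matrix("", nrow = length(x), ncol = len)
  v <- x
  for (p in seq_len(len)) {
    chars[, len - p + 1L] <- DNA_ALPHABET[(v %% 4) + 1L]
    v <- v %/% 4
  }
  apply(chars, 1L, paste, collapse = "")
}

## Hamming distance between equal-length strings (substitutions only)
hamming_dist <- function(a, b) {
  mapply(function(x, y) sum(charToRaw(x) != charToRaw(y)), a, b, USE.NAMES = FALSE)
}
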