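## Internal helpers shared across modules.

#' @keywords internal
#' @noRd
phred_decode <- function(qual) {
  if (nchar(qual) == 0L) return(integer(0))
  utf8ToInt(qual) - 33L
}

#' @keywords internal
#' @noRd
phred_encode <- function(scores) {
  if (length(scores) == 0L) return("")
  intToUtf8(as.integer(scores) + 33L)
}

## Hamming distance over the shorter of two sequences, 5'-aligned.
#' @keywords internal
#' @noRd
hamming_prefix <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(0L)
  sum(charToRaw(substr(a, 1L, n)) != charToRaw(substr(b, 1L, n)))
}

## Largest-remainder apportionment of n into parts proportional to `fractions`.
## Guarantees sum(result) == n exactly.
#' @keywords internal
#' @noRd
largest_remainder <- function(fractions, n) {
  raw <- fractions * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    idx <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[idx] <- base[idx] + 1
  }
  as.integer(base)
}

#' @keywords internal
#' @noRd
random_seq <- function(len, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

## Stable per-purpose seed derived from a master seed; stays below 2^31.
#' @keywords internal
#' @noRd
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 1009L + as.integer(offset) %% 1009L
}
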