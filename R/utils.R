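# Internal helpers shared across modules.

#' All 65,536 octamers in lexicographic (C-locale) order
#' @return Character vector of length 4^8.
#' @keywords internal
#' @noRd
all_octamers <- function() {
  bases <- c("A", "C", "G", "T")
  g <- expand.grid(b8 = bases, b7 = bases, b6 = bases, b5 = bases,
                   b4 = bases, b3 = bases, b2 = bases, b1 = bases,
                   stringsAsFactors = FALSE)
  # columns reversed so that the first base varies slowest -> lexicographic
  sort_c(do.call(paste0, g[, 8:1]))
}

# locale-independent sort; all tie-breaking in the package goes through this
sort_c <- function(x) sort(x, method = "radix")

#' Reverse complement of DNA strings
#' @param x Character vector over A/C/G/T/N.
#' @return Character vector of the same length.
#' @export
#' @examples
#' reverse_complement("ACGTN")
reverse_complement <- function(x) {
  stringi::stri_reverse(chartr("ACGTN", "TGCAN", x))
}

# run `expr` under a local RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

# deterministic per-unit seed below 2^31, derived from the master seed
unit_seed <- function(master_seed, sequence_index, read_length, stream = 0L) {
  s <- (as.double(master_seed) * 48271 +
          as.double(sequence_index) * 1000003 +
          as.double(read_length) * 7919 +
          as.double(stream) * 104729) %% 2147483629
  as.integer(s) + 1L
}

# extract all fixed-width windows of `seq` starting at 1-based positions `from`
str_windows <- function(seq, from, width) {
  stringi::stri_sub(seq, from = from, length = width)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
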