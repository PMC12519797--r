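#' Octamer breakage probability tables
#'
#' A breakage probability table assigns every one of the 4^8 = 65,536 DNA
#' octamers a probability of a double-strand break occurring at its centre.
#' Such tables summarise the short-range sequence-context bias of a
#' fragmentation process (ultrasonication, natural decay, ...) and are the
#' prior knowledge the whole ranking approach rests on. The table is a tibble
#' with columns `kmer` (octamer, upper-case A/C/G/T) and `prob` (in `[0, 1]`),
#' ordered lexicographically by `kmer`, carrying a `source_label` attribute.
#'
#' @name break_prob_table
NULL

new_break_prob_table <- function(kmer, prob, source_label) {
  out <- tibble::tibble(kmer = kmer, prob = prob)
  out <- out[order(out$kmer, method = "radix"), ]
  attr(out, "source_label") <- source_label
  class(out) <- c("break_prob_table", class(tibble::tibble()))
  out
}

#' Validate a breakage probability table
#'
#' Checks completeness (all 65,536 octamers exactly once), the octamer
#' alphabet, and that every probability is finite and in `[0, 1]`.
#'
#' @param table A tibble with columns `kmer` and `prob`.
#' @return The validated table (invisibly usable in pipes); errors otherwise.
#' @export
validate_break_table <- function(table) {
  if (!all(c("kmer", "prob") %in% names(table))) {
    stopf("a break probability table needs `kmer` and `prob` columns")
  }
  bad <- !grepl("^[ACGT]{8}$", table$kmer)
  if (any(bad)) {
    stopf("%d malformed octamer(s), e.g. %s", sum(bad),
          paste(utils::head(table$kmer[bad], 3), collapse = ", "))
  }
  dup <- duplicated(table$kmer)
  if (any(dup)) {
    stopf("%d duplicated octamer(s), e.g. %s", sum(dup),
          paste(utils::head(table$kmer[dup], 3), collapse = ", "))
  }
  n_missing <- 65536L - nrow(table)
  if (n_missing != 0L) {
    stopf("%d octamer%s missing (table has %d of 65536 rows)",
          abs(n_missing), if (abs(n_missing) == 1L) "" else "s", nrow(table))
  }
  if (!is.numeric(table$prob) || any(!is.finite(table$prob))) {
    stopf("probabilities must be finite numbers")
  }
  if (any(table$prob < 0 | table$prob > 1)) {
    stopf("%d probabilit(ies) outside [0, 1]", sum(table$prob < 0 | table$prob > 1))
  }
  invisible(table)
}

#' Look up octamer breakage probabilities
#'
#' Octamers containing characters outside A/C/G/T (including `N`) are a hard
#' error rather than a silent default, so callers must implement their own
#' skip policy for ambiguous windows.
#'
#' @param table A validated [break_prob_table].
#' @param kmers Character vector of octamers.
#' @return Numeric vector of probabilities, parallel to `kmers`.
#' @export
prob_lookup <- function(table, kmers) {
  bad <- !grepl("^[ACGT]{8}$", kmers)
  if (any(bad)) {
    stopf("lookup of %d invalid octamer(s), e.g. %s", sum(bad),
          paste(utils::head(kmers[bad], 3), collapse = ", "))
  }
  idx <- match(kmers, table$kmer)
  if (anyNA(idx)) stopf("octamer(s) absent from table; is it complete?")
  table$prob[idx]
}

#' Uniform breakage probability table
#'
#' The context-free control: every octamer gets the same probability, so
#' breakpoint sampling degenerates to uniform over valid positions and the
#' BPS degenerates to `p` times the breakpoint count.
#'
#' @param p Probability assigned to every octamer, in `[0, 1]`.
#' @return A [break_prob_table].
#' @export
#' @examples
#' tab <- uniform_table(0.5)
#' prob_lookup(tab, "ACGTACGT")
uniform_table <- function(p) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1) {
    stopf("`p` must be a single probability in [0, 1]")
  }
  new_break_prob_table(all_octamers(), rep(p, 65536L),
                       sprintf("uniform(%g)", p))
}

#' Random breakage probability table
#'
#' Entries are i.i.d. Uniform(0, 1); identical seeds give bit-identical
#' tables. Used as the "no prior knowledge" control.
#'
#' @param seed Integer seed.
#' @return A [break_prob_table].
#' @export
random_table <- function(seed) {
  probs <- with_seed(seed, stats::runif(65536L))
  new_break_prob_table(all_octamers(), probs, sprintf("random seed=%d", seed))
}

#' Structured synthetic breakage probability table
#'
#' Stands in for an empirically derived library (such as the published
#' ultrasonication octamer probabilities) when that external table is not
#' available. A position weight model over the 8 window positions, with
#' larger weights at the two central positions flanking the break, yields a
#' smooth sequence-context structure; per-octamer scores are mapped linearly
#' in log10 space onto `p_range`, so probabilities span
#' `log10(p_range[2]/p_range[1])` orders of magnitude.
#'
#' @param seed Integer seed for the position weights.
#' @param p_range Length-2 numeric, the (min, max) probability; defaults span
#'   two orders of magnitude.
#' @return A [break_prob_table].
#' @export
structured_table <- function(seed = 101L, p_range = c(0.005, 0.5)) {
  if (length(p_range) != 2L || any(p_range <= 0) || any(p_range > 1) ||
      p_range[1] >= p_range[2]) {
    stopf("`p_range` must be increasing probabilities in (0, 1]")
  }
  octs <- all_octamers()
  # per-position base weights; central positions dominate, mimicking the
  # short-range peak of breakage context effects
  sd_by_pos <- c(0.5, 0.7, 1.0, 1.4, 1.4, 1.0, 0.7, 0.5)
  w <- with_seed(seed, matrix(stats::rnorm(32L, sd = rep(sd_by_pos, each = 4L)),
                              nrow = 4L, ncol = 8L,
                              dimnames = list(c("A", "C", "G", "T"), NULL)))
  score <- numeric(65536L)
  for (j in 1:8) {
    score <- score + w[substr(octs, j, j), j]
  }
  lo <- log10(p_range[1]); hi <- log10(p_range[2])
  lin <- (score - min(score)) / (max(score) - min(score))
  probs <- 10^(lo + lin * (hi - lo))
  new_break_prob_table(octs, probs,
                       sprintf("structured seed=%d range=[%g,%g]",
                               seed, p_range[1], p_range[2]))
}

#' Normalize a k-mer frequency table
#'
#' @param freqs Tibble with columns `kmer` and `freq` (non-negative).
#' @return The same tibble with `freq` summing to 1.
#' @export
normalize_freqs <- function(freqs) {
  if (any(freqs$freq < 0)) stopf("frequencies must be non-negative")
  total <- sum(freqs$freq)
  if (total <= 0) stopf("frequencies sum to zero")
  freqs$freq <- freqs$freq / total
  freqs
}

#' Derive breakage probabilities from breakage and control k-mer frequencies
#'
#' Bayesian update: the probability that a break occurs given the octamer is
#' the marginal break probability times the ratio of the octamer's frequency
#' around observed breakpoints to its background frequency,
#' `P(break | kmer) = p_break * P(kmer | break) / P(kmer)`.
#' Enriched octamers can push the ratio above 1; such entries are clipped to
#' 1 and the clip count is reported, because downstream code uses the entries
#' as relative sampling weights and per-site scores.
#'
#' @param break_freqs Tibble (`kmer`, `freq`): octamer frequencies around
#'   observed breakpoints. Normalized internally.
#' @param control_freqs Tibble (`kmer`, `freq`): background octamer
#'   frequencies. Normalized internally; every entry must be positive.
#' @param p_break Marginal per-position break probability, in `(0, 1]`.
#' @return A [break_prob_table]; the number of clipped entries is available
#'   as `attr(, "n_clipped")`.
#' @export
derive_probabilities <- function(break_freqs, control_freqs, p_break) {
  if (!is.numeric(p_break) || length(p_break) != 1L || p_break <= 0 || p_break > 1) {
    stopf("`p_break` must be in (0, 1]")
  }
  bf <- normalize_freqs(break_freqs)
  cf <- normalize_freqs(control_freqs)
  if (nrow(bf) != 65536L || nrow(cf) != 65536L) {
    stopf("frequency tables must cover all 65536 octamers")
  }
  idx <- match(bf$kmer, cf$kmer)
  if (anyNA(idx)) stopf("frequency tables cover different octamer sets")
  cfreq <- cf$freq[idx]
  zero <- cfreq == 0
  if (any(zero)) {
    stopf("control frequency is zero for %d octamer(s), e.g. %s",
          sum(zero), paste(utils::head(bf$kmer[zero], 3), collapse = ", "))
  }
  p <- p_break * bf$freq / cfreq
  n_clipped <- sum(p > 1)
  if (n_clipped > 0) {
    rlang::inform(sprintf("derive_probabilities: %d entr%s clipped to 1",
                          n_clipped, if (n_clipped == 1L) "y" else "ies"))
  }
  out <- new_break_prob_table(bf$kmer, pmin(p, 1),
                              sprintf("derived p_break=%g", p_break))
  attr(out, "n_clipped") <- n_clipped
  out
}

#' Read a breakage probability table from delimited text
#'
#' Accepts tab- or comma-delimited files with a header row; column names for
#' the octamer and probability are configurable to accommodate external
#' table dialects. K-mers are case-normalized to upper case. If the stored
#' scores are not probabilities, `rescale = TRUE` min-max rescales them to
#' `[0, 1]`; values outside `[0, 1]` without rescaling are an error.
#'
#' @param path Path to a delimited text file.
#' @param kmer_col,prob_col Column names (defaults `"kmer"`, `"prob"`).
#' @param rescale Min-max rescale scores into `[0, 1]` before validation.
#' @return A validated [break_prob_table].
#' @export
load_break_table <- function(path, kmer_col = "kmer", prob_col = "prob",
                             rescale = FALSE) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  header <- readLines(path, n = 1L)
  delim <- if (grepl("\t", header)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(),
                           progress = FALSE)
  for (col in c(kmer_col, prob_col)) {
    if (!col %in% names(raw)) stopf("column `%s` not found in %s", col, path)
  }
  kmer <- toupper(as.character(raw[[kmer_col]]))
  prob <- as.numeric(raw[[prob_col]])
  if (rescale) {
    rng <- range(prob)
    if (diff(rng) == 0) stopf("cannot min-max rescale a constant column")
    prob <- (prob - rng[1]) / (rng[2] - rng[1])
  }
  out <- new_break_prob_table(kmer, prob, sprintf("file:%s", path))
  validate_break_table(out)
  out
}

#' Write a breakage probability table as TSV
#'
#' Header `kmer<TAB>prob`, rows in lexicographic octamer order, full double
#' precision, so write/load round-trips are exact to the printed precision.
#'
#' @param table A [break_prob_table].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_break_table <- function(table, path) {
  validate_break_table(table)
  out <- table[order(table$kmer, method = "radix"), c("kmer", "prob")]
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @export
print.break_prob_table <- function(x, ...) {
  cat(sprintf("<break_prob_table> %d octamers, source: %s\n",
              nrow(x), attr(x, "source_label") %||% "?"))
  cat(sprintf("  prob range [%.4g, %.4g], mean %.4g\n",
              min(x$prob), max(x$prob), mean(x$prob)))
  NextMethod()
}
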