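#' Simulating context-biased DNA fragmentation
#'
#' The simulator emulates mechanical shearing (e.g. ultrasonication) whose
#' breaks carry sequence-context bias: every potential breakpoint is weighted
#' by the breakage probability of the octamer centred on it, breakpoints are
#' sampled in proportion to those weights, and a fixed-length read is taken
#' downstream (3') of each sampled break, as in sequencing by synthesis.
#'
#' Coordinate convention used throughout the package: a breakpoint `pos` is
#' 0-based and sits between `seq[pos - 1]` and `seq[pos]`; its context
#' octamer is the half-open slice `seq[pos - 4, pos + 4)`, i.e. 4 bases on
#' each side of the cut. Valid breakpoints therefore satisfy
#' `4 <= pos <= L - 4`.
#'
#' @name fragmentation
NULL

# accept a reference as a plain string or a one-row tibble with id/seq
as_ref <- function(ref) {
  if (is.character(ref) && length(ref) == 1L) {
    return(list(id = "ref", seq = toupper(ref)))
  }
  if (is.data.frame(ref) && nrow(ref) == 1L && "seq" %in% names(ref)) {
    return(list(id = as.character(ref$id %||% "ref"), seq = toupper(ref$seq)))
  }
  stopf("`ref` must be a single sequence string or a one-row tibble with a `seq` column")
}

#' Per-position breakage weights along a reference
#'
#' Slides an 8-nucleotide window in strides of one nucleotide and assigns
#' each breakpoint position the table probability of its centred octamer.
#' Positions whose window would overrun the sequence ends, or contains `N`
#' (or any non-ACGT character), get weight 0.
#'
#' @param ref Reference sequence: a string or a one-row tibble with `seq`.
#' @param table A [break_prob_table].
#' @return A tibble with columns `pos` (0-based breakpoint position, `0:L`)
#'   and `weight`.
#' @export
#' @examples
#' position_weights(strrep("A", 16), uniform_table(0.5))
position_weights <- function(ref, table) {
  r <- as_ref(ref)
  L <- nchar(r$seq)
  if (L < 16L) stopf("reference must be at least 16 bases (got %d)", L)
  weight <- numeric(L + 1L)
  valid <- 4:(L - 4L)
  octs <- str_windows(r$seq, valid - 3L, 8L) # 1-based start pos-4+1
  idx <- match(octs, table$kmer)             # NA for windows with N etc.
  w <- table$prob[idx]
  w[is.na(w)] <- 0
  weight[valid + 1L] <- w
  tibble::tibble(pos = 0:L, weight = weight)
}

#' Sample breakpoint positions biased by their break weights
#'
#' @param weights Tibble as returned by [position_weights()].
#' @param n Number of breakpoints to draw (with replacement).
#' @param seed Integer seed; identical seed gives an identical draw.
#' @return Integer vector of 0-based breakpoint positions, length `n`.
#' @export
sample_breakpoints <- function(weights, n, seed) {
  if (n < 0) stopf("`n` must be non-negative")
  if (n == 0L) return(integer(0))
  if (all(weights$weight <= 0)) stopf("all breakpoint weights are zero")
  with_seed(seed,
            sample(weights$pos, size = n, replace = TRUE, prob = weights$weight))
}

#' Generate fixed-length reads from context-biased breakpoints
#'
#' Draws `ceiling(target_coverage * L / read_length)` breakpoints in
#' proportion to their octamer breakage weights and emits, for each, the read
#' `seq[pos, pos + read_length)`. Breakpoints too close to the 3' end to
#' yield a full-length read are masked out of the sampling support before
#' drawing, so every read has exactly `read_length` bases.
#'
#' @param ref Reference sequence (string or one-row tibble with `id`, `seq`).
#' @param table A [break_prob_table].
#' @param read_length Read length in bases (>= 8).
#' @param target_coverage Target coverage in x (total read bases / L).
#' @param seed Integer seed.
#' @return A `read_set` tibble with columns `read_id`, `seq`, `origin_pos`
#'   (the generating breakpoint) and attributes `read_length`,
#'   `achieved_coverage`, `ref_id`, `seed`.
#' @export
generate_reads <- function(ref, table, read_length, target_coverage, seed) {
  r <- as_ref(ref)
  L <- nchar(r$seq)
  if (read_length < 8L) stopf("`read_length` must be >= 8")
  if (target_coverage <= 0) stopf("`target_coverage` must be positive")
  w <- position_weights(r$seq, table)
  w$weight[w$pos + read_length > L] <- 0
  if (all(w$weight <= 0)) {
    stopf("no valid breakpoint admits a full %d bp read on a %d bp reference",
          read_length, L)
  }
  n_reads <- as.integer(ceiling(target_coverage * L / read_length))
  pos <- sample_breakpoints(w, n_reads, seed)
  reads <- str_windows(r$seq, pos + 1L, read_length)
  out <- tibble::tibble(
    read_id = sprintf("read_%0*d", nchar(n_reads), seq_len(n_reads)),
    seq = reads,
    origin_pos = as.integer(pos)
  )
  attr(out, "read_length") <- as.integer(read_length)
  attr(out, "achieved_coverage") <- n_reads * read_length / L
  attr(out, "ref_id") <- r$id
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("read_set", class(tibble::tibble()))
  out
}

#' Cut a reference at a set of breakpoints
#'
#' @param ref Reference sequence (string or one-row tibble).
#' @param breaks Sorted, unique, valid 0-based breakpoint positions.
#' @return Character vector of fragments whose concatenation is exactly the
#'   reference sequence.
#' @export
#' @examples
#' fragment_sequence("ACGTACGTACGTACGT", 8L)
fragment_sequence <- function(ref, breaks) {
  r <- as_ref(ref)
  L <- nchar(r$seq)
  breaks <- as.integer(breaks)
  if (length(breaks) == 0L) return(r$seq)
  if (is.unsorted(breaks, strictly = TRUE)) {
    stopf("`breaks` must be sorted and unique")
  }
  if (any(breaks < 4L | breaks > L - 4L)) {
    stopf("breakpoints must satisfy 4 <= pos <= L - 4")
  }
  starts <- c(0L, breaks) + 1L
  ends <- c(breaks, L)
  stringi::stri_sub(r$seq, from = starts, to = ends)
}

#' Write reads as FASTA or FASTQ
#'
#' Record ids encode the originating breakpoint (`read_0001|pos=123`) so
#' downstream validation can recover the ground truth; `blind = TRUE` strips
#' that provenance, emulating the real-world setting where the fragmentation
#' pattern is unknown.
#'
#' @param reads A `read_set` tibble from [generate_reads()].
#' @param path Output path.
#' @param format `"fasta"` or `"fastq"`.
#' @param blind Drop origin positions from record ids.
#' @param qual_char Constant FASTQ quality character (default `"I"`).
#' @return `path`, invisibly.
#' @export
write_reads <- function(reads, path, format = c("fasta", "fastq"),
                        blind = FALSE, qual_char = "I") {
  format <- match.arg(format)
  ids <- if (blind) reads$read_id else
    sprintf("%s|pos=%d", reads$read_id, reads$origin_pos)
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- ids
  if (format == "fasta") {
    Biostrings::writeXStringSet(x, path)
  } else {
    quals <- Biostrings::BStringSet(strrep(qual_char, nchar(reads$seq)))
    Biostrings::writeXStringSet(x, path, format = "fastq", qualities = quals)
  }
  invisible(path)
}

#' Read a FASTA/FASTQ read file back into a read_set tibble
#'
#' Origin positions are recovered from `|pos=` tags when present.
#'
#' @param path Input path.
#' @param format `"fasta"` or `"fastq"`.
#' @return A tibble with columns `read_id`, `seq`, `origin_pos` (NA if blind).
#' @export
read_reads <- function(path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  x <- Biostrings::readDNAStringSet(path, format = format)
  ids <- names(x)
  pos <- suppressWarnings(as.integer(sub("^.*\\|pos=(\\d+)$", "\\1", ids)))
  pos[!grepl("\\|pos=\\d+$", ids)] <- NA_integer_
  tibble::tibble(read_id = sub("\\|pos=\\d+$", "", ids),
                 seq = unname(as.character(x)),
                 origin_pos = pos)
}

#' Export position weights as a BedGraph-like TSV
#'
#' @param weights Tibble from [position_weights()].
#' @param path Output path.
#' @param id Sequence id for the first column.
#' @return `path`, invisibly.
#' @export
write_position_weights <- function(weights, path, id = "ref") {
  readr::write_tsv(tibble::tibble(id = id, pos = weights$pos,
                                  weight = weights$weight),
                   path, progress = FALSE)
  invisible(path)
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("<read_set> %d reads of length %d from `%s` (%.1fx coverage)\n",
              nrow(x), attr(x, "read_length") %||% NA_integer_,
              attr(x, "ref_id") %||% "?",
              attr(x, "achieved_coverage") %||% NA_real_))
  NextMethod()
}
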