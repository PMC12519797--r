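#' Breakage propensity scoring (BPS)
#'
#' Each candidate assembly implies a fragmentation pattern: aligning every
#' read back to the candidate reveals where the DNA must have broken if that
#' candidate were the true sequence. The 5' end of a read marks the break,
#' its context octamer is the candidate slice `[p - 4, p + 4)` around the
#' match position `p`, and the breakage propensity score is the
#' probability-weighted sum over all inferred breakpoint octamers,
#' `BPS = sum_o count(o) * P(break | o)`. Candidates whose implied pattern is
#' consistent with the known context bias of the fragmentation process score
#' higher. Under a uniform table the BPS reduces to `p` times the breakpoint
#' count, which is the context-free control.
#'
#' @name bps_scoring
NULL

as_candidate_seq <- function(candidate) {
  if (is.character(candidate) && length(candidate) == 1L) return(candidate)
  if (is.data.frame(candidate) && nrow(candidate) == 1L && "seq" %in% names(candidate)) {
    return(candidate$seq)
  }
  stopf("`candidate` must be a single sequence string or a one-row tibble with `seq`")
}

#' Locate reads in a candidate by exact substring match
#'
#' Brute-force exact alignment: the leftmost occurrence of each read in the
#' candidate, or `NA` when the read does not occur. Reads are error-free by
#' construction, so no edit tolerance is needed.
#'
#' @param candidate Candidate sequence (string or one-row tibble with `seq`).
#' @param reads Character vector of read sequences, or a `read_set` tibble.
#' @return Integer vector of 0-based leftmost match positions (`NA` where
#'   unmatched), parallel to the reads.
#' @export
#' @examples
#' locate_reads("TTACGTTT", "ACGT")
locate_reads <- function(candidate, reads) {
  cand <- as_candidate_seq(candidate)
  seqs <- as_read_seqs(reads)
  if (length(seqs) == 0L) return(integer(0))
  lens <- unique(nchar(seqs))
  pos <- rep(NA_integer_, length(seqs))
  L <- nchar(cand)
  for (rl in lens) {
    sel <- nchar(seqs) == rl
    if (rl > L) next
    # index every rl-window of the candidate; match() returns the first,
    # i.e. leftmost, occurrence
    windows <- str_windows(cand, seq_len(L - rl + 1L), rl)
    pos[sel] <- match(seqs[sel], windows) - 1L
  }
  pos
}

#' Infer breakpoint octamers implied by a candidate assembly
#'
#' Each matched read contributes one breakpoint instance at its 5' match
#' position `p`; the octamer is `candidate[p - 4, p + 4)`. Matches too close
#' to a candidate end for a full octamer (`p < 4` or `p > len - 4`), or whose
#' octamer contains a non-ACGT character, are tallied as skipped; unmatched
#' reads are tallied separately.
#'
#' @param reads A `read_set` tibble or character vector.
#' @param candidate Candidate sequence (string or one-row tibble with `seq`).
#' @return An `octamer_counts` tibble (`octamer`, `count`, lexicographic
#'   order) with attributes `n_unmatched_reads`, `n_skipped_margin`,
#'   `n_reads`.
#' @export
infer_breakpoint_octamers <- function(reads, candidate) {
  cand <- as_candidate_seq(candidate)
  seqs <- as_read_seqs(reads)
  L <- nchar(cand)
  # scoring is per read instance; collapse duplicates for the search only
  useq <- unique(seqs)
  upos <- locate_reads(cand, useq)
  pos <- upos[match(seqs, useq)]
  unmatched <- is.na(pos)
  in_margin <- !unmatched & (pos < 4L | pos > L - 4L)
  ok <- !unmatched & !in_margin
  octs <- character(0)
  if (any(ok)) {
    octs <- str_windows(cand, pos[ok] - 3L, 8L)
    clean <- grepl("^[ACGT]{8}$", octs)
    in_margin_extra <- sum(!clean)
    octs <- octs[clean]
  } else {
    in_margin_extra <- 0L
  }
  if (length(octs) > 0L) {
    cnt <- table(octs)
    out <- tibble::tibble(octamer = names(cnt), count = as.integer(cnt))
    out <- out[order(out$octamer, method = "radix"), ]
  } else {
    out <- tibble::tibble(octamer = character(0), count = integer(0))
  }
  attr(out, "n_unmatched_reads") <- sum(unmatched)
  attr(out, "n_skipped_margin") <- sum(in_margin) + in_margin_extra
  attr(out, "n_reads") <- length(seqs)
  class(out) <- c("octamer_counts", class(tibble::tibble()))
  out
}

#' Compute the breakage propensity score from octamer counts
#'
#' `bps = sum_o count(o) * P(break | o)`, summed in lexicographic octamer
#' order. Also reports the per-breakpoint and per-length normalizations used
#' to compare candidates of different sizes.
#'
#' @param oc An `octamer_counts` tibble from [infer_breakpoint_octamers()].
#' @param table A [break_prob_table].
#' @param candidate_length Candidate length in bases (> 0).
#' @return One-row tibble: `bps`, `n_breakpoints`, `bps_per_breakpoint`,
#'   `bps_per_length`, `candidate_length`, `n_unmatched`, `n_skipped_margin`,
#'   `degenerate` (TRUE when no breakpoints were identified; both normalized
#'   scores are then 0).
#' @export
compute_bps <- function(oc, table, candidate_length) {
  if (candidate_length <= 0) stopf("`candidate_length` must be positive")
  probs <- if (nrow(oc) > 0L) prob_lookup(table, oc$octamer) else numeric(0)
  n_breakpoints <- sum(oc$count)
  bps <- sum(oc$count * probs)
  degenerate <- n_breakpoints == 0L
  tibble::tibble(
    bps = bps,
    n_breakpoints = as.integer(n_breakpoints),
    bps_per_breakpoint = if (degenerate) 0 else bps / n_breakpoints,
    bps_per_length = if (degenerate) 0 else bps / candidate_length,
    candidate_length = as.integer(candidate_length),
    n_unmatched = as.integer(attr(oc, "n_unmatched_reads") %||% 0L),
    n_skipped_margin = as.integer(attr(oc, "n_skipped_margin") %||% 0L),
    degenerate = degenerate
  )
}

#' Score candidate assemblies by breakage propensity
#'
#' One BPS result per candidate, in candidate order. Candidates are scored
#' independently of each other, so evaluation order cannot change any score.
#'
#' @param reads A `read_set` tibble or character vector of reads.
#' @param candidates A `candidate_set` tibble (needs `candidate_id`, `seq`).
#' @param table A [break_prob_table].
#' @return Tibble parallel to `candidates`: `candidate_id` plus the
#'   [compute_bps()] columns.
#' @export
score_candidates <- function(reads, candidates, table) {
  if (nrow(candidates) == 0L) stopf("no candidates to score")
  res <- lapply(seq_len(nrow(candidates)), function(i) {
    oc <- infer_breakpoint_octamers(reads, candidates$seq[i])
    compute_bps(oc, table, nchar(candidates$seq[i]))
  })
  dplyr::bind_cols(
    tibble::tibble(candidate_id = candidates$candidate_id),
    dplyr::bind_rows(res)
  )
}

#' Ground-truth breakage score of a read set
#'
#' The simulator-side counterpart of the BPS: the probability-weighted sum
#' over the octamers actually sampled as breakpoints (recorded in
#' `origin_pos`), computed directly on the true reference without any
#' alignment. When the true reference is scored with its own generating
#' reads, [score_candidates()] must reproduce this value exactly.
#'
#' @param reads A `read_set` tibble with an `origin_pos` column.
#' @param ref The true reference (string or one-row tibble with `seq`).
#' @param table A [break_prob_table].
#' @return The summed score (numeric scalar).
#' @export
true_breakpoint_score <- function(reads, ref, table) {
  r <- as_ref(ref)
  if (!"origin_pos" %in% names(reads)) stopf("`reads` lacks `origin_pos`")
  octs <- str_windows(r$seq, reads$origin_pos - 3L, 8L)
  cnt <- table(octs)
  octs_u <- sort_c(names(cnt))
  counts <- as.integer(cnt[octs_u])
  sum(counts * prob_lookup(table, octs_u))
}

#' Write BPS scores as TSV
#'
#' @param scores Tibble from [score_candidates()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  readr::write_tsv(scores, path, progress = FALSE)
  invisible(path)
}
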