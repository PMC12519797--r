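#' Toy de Bruijn graph assembler
#'
#' A deliberately simple assembler used to produce a pool of candidate
#' solutions for ranking, not a production tool. A k-mer dictionary is built
#' from the reads ((k-1)-mer nodes, k-mer edges with multiplicities), maximal
#' non-branching paths (unitigs) become contigs, and candidate scaffolds are
#' produced by brute-force enumeration of contig orderings with greedy
#' maximal suffix-prefix merging at each junction. All tie-breaking is
#' lexicographic so the output is fully deterministic given the seed.
#'
#' @name assembler
NULL

as_read_seqs <- function(reads) {
  if (is.character(reads)) return(reads)
  if (is.data.frame(reads) && "seq" %in% names(reads)) return(reads$seq)
  stopf("`reads` must be a character vector or a tibble with a `seq` column")
}

#' Build a de Bruijn graph from reads
#'
#' @param reads A `read_set` tibble or character vector of read sequences.
#' @param k K-mer size for graph edges, `2 <= k <= read length`.
#' @return A `debruijn_graph`: list with `k`, `edges` (named integer vector,
#'   k-mer -> multiplicity, lexicographic order) and `nodes` (sorted
#'   (k-1)-mers).
#' @export
#' @examples
#' build_graph(c("ACGT"), k = 3)
build_graph <- function(reads, k) {
  seqs <- as_read_seqs(reads)
  if (length(seqs) == 0L) stopf("no reads to assemble")
  k <- as.integer(k)
  lens <- nchar(seqs)
  if (k < 2L) stopf("`k` must be >= 2")
  if (k > min(lens)) {
    stopf("`k` (%d) exceeds the shortest read length (%d)", k, min(lens))
  }
  kmers <- unlist(lapply(split(seqs, lens), function(s) {
    nk <- nchar(s[1]) - k + 1L
    str_windows(rep(s, each = nk), rep(seq_len(nk), times = length(s)), k)
  }), use.names = FALSE)
  cnt <- table(kmers)
  edges <- as.integer(cnt)
  names(edges) <- names(cnt)
  o <- order(names(edges), method = "radix")
  edges <- edges[o]
  nodes <- sort_c(unique(c(substr(names(edges), 1L, k - 1L),
                           substr(names(edges), 2L, k))))
  structure(list(k = k, edges = edges, nodes = nodes),
            class = "debruijn_graph")
}

#' @export
print.debruijn_graph <- function(x, ...) {
  cat(sprintf("<debruijn_graph> k=%d, %d distinct k-mer edges (total mult %d), %d nodes\n",
              x$k, length(x$edges), sum(x$edges), length(x$nodes)))
  invisible(x)
}

#' Extract contigs (unitigs) from a de Bruijn graph
#'
#' Edges below `min_multiplicity` are dropped first. Contigs are maximal
#' non-branching paths: extension stops at any node whose in-degree or
#' out-degree (in distinct k-mers) differs from 1. Every surviving edge
#' belongs to exactly one contig; isolated simple cycles are emitted once,
#' opened at their lexicographically smallest edge. Output rows are ordered
#' lexicographically by sequence.
#'
#' @param g A `debruijn_graph`.
#' @param min_multiplicity Minimum edge multiplicity to keep (default 1 = no
#'   filtering; the reads are error-free by construction).
#' @return Tibble with columns `contig_id`, `seq`, `length`, `support`
#'   (minimum edge multiplicity along the path). Empty tibble if no edges
#'   survive.
#' @export
extract_contigs <- function(g, min_multiplicity = 1L) {
  stopifnot(inherits(g, "debruijn_graph"))
  keep <- g$edges[g$edges >= min_multiplicity]
  empty <- tibble::tibble(contig_id = character(0), seq = character(0),
                          length = integer(0), support = integer(0))
  if (length(keep) == 0L) return(empty)
  k <- g$k
  uk <- names(keep) # lexicographic
  pre <- substr(uk, 1L, k - 1L)
  suf <- substr(uk, 2L, k)
  out_idx <- split(seq_along(uk), pre) # per-node outgoing edge indices
  in_deg <- table(suf)
  out_env <- list2env(out_idx, hash = TRUE, size = length(out_idx) * 2L)
  in_list <- as.list(as.integer(in_deg))
  names(in_list) <- names(in_deg)
  in_env <- list2env(in_list, hash = TRUE, size = length(in_list) * 2L)
  is_simple <- function(v) {
    oi <- get0(v, envir = out_env)
    !is.null(oi) && length(oi) == 1L && identical(get0(v, envir = in_env), 1L)
  }
  used <- logical(length(uk))
  walk_from <- function(i) {
    js <- i
    used[i] <<- TRUE
    cur <- suf[i]
    while (is_simple(cur)) {
      j <- get0(cur, envir = out_env)
      if (used[j]) break # closed a cycle
      used[j] <<- TRUE
      js <- c(js, j)
      cur <- suf[j]
    }
    js
  }
  paths <- list()
  starts <- which(!vapply(pre, is_simple, logical(1)))
  for (i in starts) {
    if (!used[i]) paths[[length(paths) + 1L]] <- walk_from(i)
  }
  for (i in seq_along(uk)) { # leftover isolated cycles
    if (!used[i]) paths[[length(paths) + 1L]] <- walk_from(i)
  }
  seqs <- vapply(paths, function(js) {
    paste0(uk[js[1]], stringi::stri_flatten(substr(uk[js[-1]], k, k)))
  }, character(1))
  support <- vapply(paths, function(js) min(keep[js]), integer(1))
  o <- order(seqs, method = "radix")
  tibble::tibble(
    contig_id = sprintf("contig_%0*d", nchar(length(o)), seq_along(o)),
    seq = seqs[o],
    length = nchar(seqs[o]),
    support = unname(support[o])
  )
}

# maximal suffix(a)-prefix(b) overlap >= min_overlap, 0 if none
max_suffix_prefix_overlap <- function(a, b, min_overlap) {
  la <- nchar(a); lb <- nchar(b)
  lo <- max(1L, as.integer(min_overlap))
  hi <- min(la, lb)
  if (hi < lo) return(0L)
  os <- hi:lo
  hit <- which(stringi::stri_sub(a, la - os + 1L, la) ==
                 stringi::stri_sub(b, 1L, os))
  if (length(hit) == 0L) 0L else os[hit[1]]
}

#' Re-merge contigs along a recorded scaffold path
#'
#' Inverse bookkeeping for candidate provenance: merging `contig_seqs` in
#' `contig_order`, dropping `overlaps[i]` bases at junction `i`, must
#' reproduce the candidate sequence exactly.
#'
#' @param contig_seqs Character vector of contig sequences.
#' @param contig_order Integer vector of indices into `contig_seqs`.
#' @param overlaps Integer vector, one per junction (length
#'   `length(contig_order) - 1`).
#' @return The scaffold sequence.
#' @export
reconstruct_scaffold <- function(contig_seqs, contig_order, overlaps) {
  seqs <- contig_seqs[contig_order]
  if (length(seqs) == 1L) return(seqs)
  stopifnot(length(overlaps) == length(seqs) - 1L)
  pieces <- c(seqs[1],
              stringi::stri_sub(seqs[-1], from = overlaps + 1L))
  stringi::stri_flatten(pieces)
}

merge_chain <- function(seqs, min_overlap) {
  s <- seqs[1]
  n <- length(seqs)
  overlaps <- integer(max(0L, n - 1L))
  if (n > 1L) {
    for (i in 2:n) {
      o <- max_suffix_prefix_overlap(s, seqs[i], min_overlap)
      overlaps[i - 1L] <- o
      s <- paste0(s, stringi::stri_sub(seqs[i], from = o + 1L))
    }
  }
  list(seq = s, overlaps = overlaps)
}

# all permutations of 1..n in lexicographic order
all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  idx <- 1L
  for (first in seq_len(n)) {
    rest <- setdiff(seq_len(n), first)
    for (p in sub) {
      out[[idx]] <- c(first, rest[p])
      idx <- idx + 1L
    }
  }
  out
}

#' Enumerate candidate scaffolds from contigs
#'
#' Brute-force scaffolding: contig orderings are enumerated exhaustively when
#' the permutation count does not exceed `max_candidates`, otherwise a seeded
#' uniform subsample of orderings is drawn. Adjacent contigs in an ordering
#' are merged greedily at their maximal suffix-prefix overlap of at least
#' `min_overlap` bases (plain concatenation when none exists). Candidates
#' with identical sequences are collapsed, keeping the first.
#'
#' @param contigs Tibble from [extract_contigs()] (needs a `seq` column).
#' @param min_overlap Minimum junction overlap in bases (default 3).
#' @param max_candidates Upper bound on orderings evaluated (default 1000).
#' @param seed Integer seed for the ordering subsample.
#' @return A `candidate_set` tibble: `candidate_id`, `seq`, `length`, plus
#'   list-columns `contig_order` and `overlaps` recording provenance.
#' @export
enumerate_scaffolds <- function(contigs, min_overlap = 3L,
                                max_candidates = 1000L, seed = 1L) {
  if (nrow(contigs) == 0L) stopf("no contigs to scaffold")
  if (max_candidates < 1L) stopf("`max_candidates` must be >= 1")
  n <- nrow(contigs)
  if (factorial(n) <= max_candidates) {
    orderings <- all_permutations(n)
  } else {
    orderings <- with_seed(seed,
                           replicate(max_candidates, sample.int(n),
                                     simplify = FALSE))
    orderings <- unique(orderings)
  }
  merged <- lapply(orderings, function(o) merge_chain(contigs$seq[o], min_overlap))
  seqs <- vapply(merged, `[[`, character(1), "seq")
  first <- !duplicated(seqs)
  out <- tibble::tibble(
    candidate_id = sprintf("cand_%0*d", nchar(sum(first)), seq_len(sum(first))),
    seq = seqs[first],
    length = nchar(seqs[first]),
    contig_order = orderings[first],
    overlaps = lapply(merged[first], `[[`, "overlaps")
  )
  attr(out, "contig_seqs") <- contigs$seq
  class(out) <- c("candidate_set", class(tibble::tibble()))
  out
}

#' Assemble reads into candidate scaffolds
#'
#' Composition of [build_graph()], [extract_contigs()] and
#' [enumerate_scaffolds()].
#'
#' @param reads A `read_set` tibble or character vector.
#' @param k K-mer size; default `read_length - 1`, the largest usable k,
#'   maximizing context for ultrashort reads.
#' @param min_multiplicity Edge multiplicity filter (default 1 = off).
#' @param min_overlap Minimum scaffold junction overlap (default 3).
#' @param max_candidates Bound on orderings evaluated (default 1000).
#' @param seed Seed for ordering subsampling.
#' @param verbose Log graph/contig/candidate counts.
#' @return A `candidate_set` tibble (see [enumerate_scaffolds()]).
#' @export
assemble <- function(reads, k = NULL, min_multiplicity = 1L, min_overlap = 3L,
                     max_candidates = 1000L, seed = 1L, verbose = FALSE) {
  seqs <- as_read_seqs(reads)
  if (length(seqs) == 0L) stopf("no reads to assemble")
  if (is.null(k)) {
    k <- (attr(reads, "read_length") %||% min(nchar(seqs))) - 1L
  }
  g <- build_graph(seqs, k)
  contigs <- extract_contigs(g, min_multiplicity)
  if (nrow(contigs) == 0L) stopf("no contigs survive the multiplicity filter")
  cands <- enumerate_scaffolds(contigs, min_overlap, max_candidates, seed)
  if (verbose) {
    rlang::inform(sprintf(
      "assemble: %d k-mers (k=%d) -> %d contig(s) -> %d candidate(s)",
      length(g$edges), g$k, nrow(contigs), nrow(cands)))
  }
  attr(cands, "k") <- g$k
  cands
}

#' Write candidate scaffolds as multi-FASTA
#'
#' Provenance (contig order and junction overlaps) goes in the description
#' line.
#'
#' @param candidates A `candidate_set` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_candidates <- function(candidates, path) {
  desc <- vapply(seq_len(nrow(candidates)), function(i) {
    sprintf("order=%s overlaps=%s",
            paste(candidates$contig_order[[i]], collapse = ","),
            paste(candidates$overlaps[[i]], collapse = ","))
  }, character(1))
  x <- Biostrings::DNAStringSet(candidates$seq)
  names(x) <- paste(candidates$candidate_id, desc)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Export a de Bruijn graph as GFA1
#'
#' Segments are the (k-1)-mer nodes; links are the k-mer edges with
#' (k-2)-base overlaps; edge multiplicity goes in a `RC` tag.
#'
#' @param g A `debruijn_graph`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gfa <- function(g, path) {
  stopifnot(inherits(g, "debruijn_graph"))
  k <- g$k
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("H\tVN:Z:1.0", con)
  writeLines(sprintf("S\t%s\t%s", g$nodes, g$nodes), con)
  km <- names(g$edges)
  writeLines(sprintf("L\t%s\t+\t%s\t+\t%dM\tRC:i:%d",
                     substr(km, 1L, k - 1L), substr(km, 2L, k),
                     k - 2L, g$edges), con)
  invisible(path)
}
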