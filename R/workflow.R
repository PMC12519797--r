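#' End-to-end experiment workflow
#'
#' Reproduces the full validation design at configurable scale: sample or
#' synthesize reference sequences, simulate context-biased fragmentation at
#' each read length, assemble candidate scaffolds, score them by BPS,
#' evaluate against the known truth, and summarise with Spearman/ANOVA/top
#' split statistics. Every unit (reference x read length) gets its own seed
#' derived deterministically from the master seed, so units are
#' independently rerunnable and the whole experiment is reproducible.
#'
#' @name workflow
NULL

#' Synthesize random reference sequences
#'
#' I.i.d. bases with `P(G) + P(C) = gc` split evenly within each pair.
#' Stands in for sampling windows from a real genome so that experiments
#' and tests need no external data.
#'
#' @param n Number of sequences.
#' @param length Sequence length in bases.
#' @param gc GC fraction, in the open interval (0, 1).
#' @param seed Integer seed.
#' @return Tibble with columns `id`, `seq`, `length`.
#' @export
#' @examples
#' synthesize_references(2, 100, gc = 0.4, seed = 1)
synthesize_references <- function(n, length, gc = 0.5, seed = 1L) {
  if (n < 1L || length < 16L) stopf("need n >= 1 and length >= 16")
  if (gc <= 0 || gc >= 1) stopf("`gc` must be strictly inside (0, 1)")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqs <- with_seed(seed, vapply(seq_len(n), function(i) {
    paste(sample(names(p), length, replace = TRUE, prob = p), collapse = "")
  }, character(1)))
  tibble::tibble(id = sprintf("synth_%0*d", nchar(n), seq_len(n)),
                 seq = seqs, length = nchar(seqs))
}

#' Sample reference windows from a genome FASTA
#'
#' Draws `n` unique, non-overlapping, N-free windows of the given length,
#' uniformly over eligible positions (chromosomes weighted by their number
#' of eligible starts). Origins are recorded 0-based half-open.
#'
#' @param fasta_path Path to a FASTA file.
#' @param n Number of windows.
#' @param length Window length in bases.
#' @param seed Integer seed.
#' @param max_tries Sampling attempts before giving up (default `200 * n`).
#' @return Tibble with columns `id`, `seq`, `length`, `source_id`, `start`,
#'   `end` (0-based half-open).
#' @export
sample_reference_sequences <- function(fasta_path, n, length, seed,
                                       max_tries = 200L * n) {
  genome <- Biostrings::readDNAStringSet(fasta_path)
  chrom_len <- Biostrings::width(genome)
  eligible <- chrom_len >= length
  if (!any(eligible)) stopf("no sequence in %s is >= %d bp", fasta_path, length)
  genome <- genome[eligible]
  chrom_len <- chrom_len[eligible]
  chrom_ids <- sub("\\s.*$", "", names(genome))
  n_starts <- chrom_len - length + 1L
  taken <- lapply(seq_along(genome), function(i) integer(0)) # window starts
  out <- vector("list", n)
  got <- 0L
  with_seed(seed, {
    for (try in seq_len(max_tries)) {
      if (got >= n) break
      ci <- sample.int(length(genome), 1L, prob = n_starts)
      start <- sample.int(n_starts[ci], 1L) # 1-based
      overlaps <- any(abs(taken[[ci]] - start) < length)
      if (overlaps) next
      win <- as.character(Biostrings::subseq(genome[[ci]], start, start + length - 1L))
      if (grepl("[^ACGT]", win)) next
      got <- got + 1L
      taken[[ci]] <- c(taken[[ci]], start)
      start0 <- start - 1L # 0-based half-open origin
      end0 <- start0 + length
      out[[got]] <- tibble::tibble(
        id = sprintf("%s:%d-%d", chrom_ids[ci], start0, end0),
        seq = win, length = nchar(win),
        source_id = chrom_ids[ci], start = start0, end = end0)
    }
  })
  if (got < n) {
    stopf("could only place %d of %d non-overlapping N-free windows", got, n)
  }
  dplyr::bind_rows(out)
}

#' Experiment configuration
#'
#' The shipped default is the desk-scale design: 20 synthetic 500 bp
#' references, read length 25, ~40x coverage, a structured synthetic table,
#' and a length-scaled k (see the methods vignette for the graph-ambiguity
#' argument behind that choice; k = 9 at 500 bp). [paper_scale_config()]
#' gives the full-scale design: 200 x 1 kb references and the read-length
#' sweep {16, 18, 20, 25, 40}.
#'
#' @param n_sequences Number of reference sequences.
#' @param seq_length Reference length in bases.
#' @param read_lengths Integer vector of read lengths (each >= 8 and <=
#'   `seq_length`).
#' @param target_coverage Target coverage in x.
#' @param k_mode `"length_scaled"` (default), `"read_length_minus_1"`,
#'   `"read_length_minus_2"`, or a fixed integer k.
#' @param table A [break_prob_table] driving the fragmentation bias.
#' @param master_seed Master seed; all unit seeds derive from it.
#' @param reference_fasta Optional genome FASTA to sample windows from
#'   instead of synthesizing references.
#' @param gc GC fraction for synthesized references.
#' @param max_candidates,min_overlap,min_multiplicity Assembler settings.
#' @param bin_width ANOVA bin width; `NULL` picks one populating >= 5 bins.
#' @param top_fraction Top split fraction (default 0.05).
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(n_sequences = 20L, seq_length = 500L,
                              read_lengths = 25L, target_coverage = 40,
                              k_mode = "length_scaled",
                              table = structured_table(),
                              master_seed = 1234L,
                              reference_fasta = NULL, gc = 0.5,
                              max_candidates = 200L, min_overlap = 3L,
                              min_multiplicity = 1L, bin_width = NULL,
                              top_fraction = 0.05) {
  if (n_sequences < 1L || seq_length < 16L || target_coverage <= 0) {
    stopf("counts and coverage must be positive (and seq_length >= 16)")
  }
  if (any(read_lengths < 8L) || any(read_lengths > seq_length)) {
    stopf("read lengths must be >= 8 and <= seq_length")
  }
  cfg <- list(n_sequences = as.integer(n_sequences),
              seq_length = as.integer(seq_length),
              read_lengths = as.integer(read_lengths),
              target_coverage = target_coverage,
              k_mode = k_mode, table = table,
              master_seed = as.integer(master_seed),
              reference_fasta = reference_fasta, gc = gc,
              max_candidates = as.integer(max_candidates),
              min_overlap = as.integer(min_overlap),
              min_multiplicity = as.integer(min_multiplicity),
              bin_width = bin_width, top_fraction = top_fraction)
  class(cfg) <- "experiment_config"
  cfg
}

#' @rdname experiment_config
#' @param ... Overrides passed on to [experiment_config()].
#' @export
paper_scale_config <- function(...) {
  args <- list(n_sequences = 200L, seq_length = 1000L,
               read_lengths = c(16L, 18L, 20L, 25L, 40L),
               max_candidates = 1000L)
  do.call(experiment_config, utils::modifyList(args, list(...)))
}

#' @export
print.experiment_config <- function(x, ...) {
  cat(sprintf(paste0(
    "<experiment_config>\n",
    "  references : %d x %d bp (%s)\n",
    "  reads      : lengths {%s} at %gx coverage\n",
    "  assembler  : k_mode=%s, max_candidates=%d, min_overlap=%d, min_mult=%d\n",
    "  table      : %s\n",
    "  seeds      : master %d\n"),
    x$n_sequences, x$seq_length,
    if (is.null(x$reference_fasta)) sprintf("synthetic, gc=%g", x$gc)
    else x$reference_fasta,
    paste(x$read_lengths, collapse = ","), x$target_coverage,
    as.character(x$k_mode), x$max_candidates, x$min_overlap,
    x$min_multiplicity,
    attr(x$table, "source_label") %||% "?", x$master_seed))
  invisible(x)
}

resolve_k <- function(k_mode, read_length, seq_length) {
  k <- if (is.numeric(k_mode)) {
    as.integer(k_mode)
  } else {
    switch(as.character(k_mode),
           read_length_minus_1 = read_length - 1L,
           read_length_minus_2 = read_length - 2L,
           # smallest k with ~2 or fewer expected repeated (k-1)-mer nodes
           # (L^2/2 window pairs / 4^(k-1) <= 2): enough graph ambiguity that
           # references generically yield several contigs and a real
           # candidate pool, not so much that assemblies are pure fragments
           length_scaled = as.integer(ceiling(log(seq_length^2 / 4, 4))) + 1L,
           stopf("unknown k_mode: %s", k_mode))
  }
  if (k >= read_length) {
    stopf("resolved k (%d) must be below the read length (%d)", k, read_length)
  }
  k
}

#' Run one fragmentation/assembly/scoring/evaluation unit
#'
#' @param ref One-row reference tibble (`id`, `seq`).
#' @param read_length Read length in bases.
#' @param cfg An [experiment_config()].
#' @param seed Unit seed.
#' @return Evaluation records tibble for this unit.
#' @export
run_unit <- function(ref, read_length, cfg, seed) {
  reads <- generate_reads(ref, cfg$table, read_length,
                          cfg$target_coverage, seed)
  cands <- assemble(reads,
                    k = resolve_k(cfg$k_mode, read_length, cfg$seq_length),
                    min_multiplicity = cfg$min_multiplicity,
                    min_overlap = cfg$min_overlap,
                    max_candidates = cfg$max_candidates,
                    seed = seed + 1L)
  scores <- score_candidates(reads, cands, cfg$table)
  evaluate_candidates(ref, cands, scores,
                      meta = list(sequence_id = ref$id,
                                  read_length = as.integer(read_length),
                                  seed = as.integer(seed)))
}

#' Run the full ranking experiment
#'
#' For every reference x read length: simulate reads, assemble candidates,
#' score BPS, evaluate against the truth; then compute pooled and per-length
#' Spearman correlations (BPS vs similarity), binned one-way ANOVA, and the
#' top-fraction split. Unit failures are caught, logged and reported in the
#' summary without aborting the remaining units.
#'
#' @param cfg An [experiment_config()].
#' @param out_dir Optional directory; when given, writes `records.tsv`,
#'   `references.fasta` and `report.json`.
#' @param verbose Log per-unit progress.
#' @return A `bps_experiment` object: list with `records` (tibble),
#'   `stats` (pooled/per-length Spearman, ANOVA, top split), `config`,
#'   `references`, `failures`. Has [tidy()], [glance()] and [autoplot()]
#'   methods.
#' @export
run_experiment <- function(cfg, out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(cfg, "experiment_config"))
  refs <- if (is.null(cfg$reference_fasta)) {
    synthesize_references(cfg$n_sequences, cfg$seq_length, cfg$gc,
                          seed = cfg$master_seed)
  } else {
    sample_reference_sequences(cfg$reference_fasta, cfg$n_sequences,
                               cfg$seq_length, seed = cfg$master_seed)
  }
  units <- expand.grid(i = seq_len(nrow(refs)), rl = cfg$read_lengths)
  records <- vector("list", nrow(units))
  failures <- list()
  for (u in seq_len(nrow(units))) {
    i <- units$i[u]; rl <- units$rl[u]
    seed_u <- unit_seed(cfg$master_seed, i, rl)
    rec <- tryCatch(
      run_unit(refs[i, ], rl, cfg, seed_u),
      error = function(e) {
        rlang::inform(sprintf("unit failed (sequence %s, read length %d): %s",
                              refs$id[i], rl, conditionMessage(e)))
        NULL
      })
    if (is.null(rec)) {
      failures[[length(failures) + 1L]] <-
        tibble::tibble(sequence_id = refs$id[i], read_length = as.integer(rl))
    } else {
      records[[u]] <- rec
      if (verbose) {
        rlang::inform(sprintf("unit %s rl=%d: %d candidates, best distance %d",
                              refs$id[i], rl, nrow(rec), min(rec$levenshtein)))
      }
    }
  }
  records <- dplyr::bind_rows(records)
  if (nrow(records) == 0L) stopf("every unit failed; nothing to report")
  stats <- summarise_experiment(records, cfg)
  report <- structure(
    list(records = records, stats = stats, config = cfg, references = refs,
         failures = dplyr::bind_rows(failures)),
    class = "bps_experiment")
  if (!is.null(out_dir)) write_experiment(report, out_dir)
  report
}

summarise_experiment <- function(records, cfg) {
  bw <- cfg$bin_width %||% auto_bin_width(records$levenshtein)
  per_length <- dplyr::bind_rows(lapply(
    split(records, records$read_length),
    function(r) {
      sp <- tryCatch(spearman_bps_vs_similarity(r), error = function(e) {
        tibble::tibble(rho = NA_real_, p_value = NA_real_, n = nrow(r))
      })
      dplyr::bind_cols(tibble::tibble(read_length = r$read_length[1]), sp)
    }))
  na_spearman <- function(e) tibble::tibble(rho = NA_real_,
                                            p_value = NA_real_,
                                            n = nrow(records))
  pooled <- tryCatch(spearman_bps_vs_similarity(records), error = na_spearman)
  pooled_norm <- tryCatch(
    spearman_bps_vs_similarity(records, bps_field = "bps_per_length"),
    error = na_spearman)
  anova <- tryCatch(anova_by_bin(records, bw),
                    error = function(e) tibble::tibble(
                      F_statistic = NA_real_, p_value = NA_real_,
                      n_bins = NA_integer_, degenerate = NA))
  top <- tryCatch(top_fraction_split(records, fraction = cfg$top_fraction),
                  error = function(e) tibble::tibble())
  list(pooled_spearman = pooled, pooled_spearman_per_length_norm = pooled_norm,
       per_length_spearman = per_length, anova = anova,
       top_split = top, bin_width = bw)
}

write_experiment <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(report$records, file.path(out_dir, "records.tsv"),
                   progress = FALSE)
  refs <- Biostrings::DNAStringSet(report$references$seq)
  names(refs) <- report$references$id
  Biostrings::writeXStringSet(refs, file.path(out_dir, "references.fasta"))
  cfg <- report$config
  json <- list(
    config = list(n_sequences = cfg$n_sequences, seq_length = cfg$seq_length,
                  read_lengths = cfg$read_lengths,
                  target_coverage = cfg$target_coverage,
                  k_mode = as.character(cfg$k_mode),
                  table = attr(cfg$table, "source_label"),
                  master_seed = cfg$master_seed,
                  max_candidates = cfg$max_candidates,
                  min_overlap = cfg$min_overlap,
                  min_multiplicity = cfg$min_multiplicity,
                  top_fraction = cfg$top_fraction),
    stats = report$stats,
    n_records = nrow(report$records),
    n_failures = nrow(report$failures))
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
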