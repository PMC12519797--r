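#' Ground-truth evaluation of candidate assemblies
#'
#' Because the fragmentation is simulated, the true sequence is known, so
#' every candidate can be graded by its Levenshtein distance to the truth
#' (0 = identical). The validation question is whether the BPS — computable
#' without the truth — tracks that distance: Spearman correlation between
#' BPS and similarity, one-way ANOVA of BPS across distance bins, and a
#' top-fraction split comparing the best-scoring candidates to the rest.
#'
#' @name evaluation
NULL

#' Levenshtein edit distance
#'
#' Minimum number of single-character insertions, deletions and
#' substitutions (all unit cost) transforming `a` into `b`. Vectorized with
#' recycling.
#'
#' @param a,b Character vectors.
#' @return Integer vector of distances.
#' @export
#' @examples
#' levenshtein_distance("kitten", "sitting")
levenshtein_distance <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(a, n)
  b <- rep_len(b, n)
  vapply(seq_len(n), function(i) as.integer(utils::adist(a[i], b[i])),
         integer(1))
}

#' Join candidate scores with ground-truth distances
#'
#' @param truth The true reference (string or one-row tibble with `seq`).
#' @param candidates A `candidate_set` tibble.
#' @param scores Tibble from [score_candidates()], parallel to `candidates`.
#' @param meta Named list of per-unit metadata replicated into every record
#'   (typically `sequence_id`, `read_length`, `seed`).
#' @return A tibble of evaluation records: one row per candidate with
#'   `sequence_id`, `candidate_id`, `levenshtein`, `truth_length`, the BPS
#'   columns, and any extra metadata.
#' @export
evaluate_candidates <- function(truth, candidates, scores, meta = list()) {
  if (nrow(candidates) != nrow(scores)) {
    stopf("`candidates` (%d) and `scores` (%d) must be parallel",
          nrow(candidates), nrow(scores))
  }
  r <- as_ref(truth)
  lev <- as.integer(utils::adist(candidates$seq, r$seq))
  base <- tibble::tibble(
    sequence_id = as.character(meta$sequence_id %||% r$id),
    candidate_id = candidates$candidate_id,
    levenshtein = lev,
    truth_length = nchar(r$seq)
  )
  extra <- meta[setdiff(names(meta), "sequence_id")]
  for (nm in names(extra)) base[[nm]] <- extra[[nm]]
  dplyr::bind_cols(base, scores[setdiff(names(scores), "candidate_id")])
}

get_bps_field <- function(records, bps_field) {
  if (!bps_field %in% names(records)) {
    stopf("no column `%s` in records", bps_field)
  }
  records[[bps_field]]
}

#' Spearman correlation between BPS and assembly similarity
#'
#' Similarity is `truth_length - levenshtein`, so a positive rho means
#' better assemblies (smaller distance) score higher — the direction the
#' breakage-ranking idea predicts. Two-sided test, average ranks for ties.
#'
#' @param records Evaluation records from [evaluate_candidates()].
#' @param bps_field Which score variant to correlate: `"bps"` (default),
#'   `"bps_per_breakpoint"` or `"bps_per_length"`.
#' @return One-row tibble: `rho`, `p_value`, `n`.
#' @export
spearman_bps_vs_similarity <- function(records, bps_field = "bps") {
  x <- get_bps_field(records, bps_field)
  similarity <- records$truth_length - records$levenshtein
  if (nrow(records) < 3L) stopf("need at least 3 records")
  if (stats::sd(x) == 0 || stats::sd(similarity) == 0) {
    stopf("Spearman rho is undefined for constant input")
  }
  ct <- suppressWarnings(
    stats::cor.test(x, similarity, method = "spearman",
                    alternative = "two.sided", exact = FALSE))
  tibble::tibble(rho = unname(ct$estimate), p_value = ct$p.value,
                 n = nrow(records))
}

#' One-way ANOVA of BPS across Levenshtein-distance bins
#'
#' Bins are `floor(levenshtein / bin_width)`. Requires at least two
#' non-empty bins. The fully degenerate case (all score values identical)
#' is reported as `F = 0`, `p = 1` with `degenerate = TRUE`.
#'
#' @param records Evaluation records.
#' @param bin_width Bin width in edit operations.
#' @param bps_field Score variant (default `"bps"`).
#' @return One-row tibble: `F_statistic`, `p_value`, `n_bins`, `degenerate`.
#' @export
anova_by_bin <- function(records, bin_width, bps_field = "bps") {
  if (bin_width < 1) stopf("`bin_width` must be >= 1")
  x <- get_bps_field(records, bps_field)
  bin <- floor(records$levenshtein / bin_width)
  n_bins <- length(unique(bin))
  if (n_bins < 2L) stopf("only one populated distance bin; widen the data or shrink `bin_width`")
  if (stats::sd(x) == 0) {
    return(tibble::tibble(F_statistic = 0, p_value = 1,
                          n_bins = n_bins, degenerate = TRUE))
  }
  if (length(x) - n_bins < 1L) {
    stopf("no residual degrees of freedom: need replication within bins")
  }
  fit <- stats::aov(x ~ factor(bin))
  s <- summary(fit)[[1]]
  tibble::tibble(F_statistic = s[["F value"]][1], p_value = s[["Pr(>F)"]][1],
                 n_bins = n_bins, degenerate = FALSE)
}

# smallest width (>=1) whose binning populates >= target_bins bins, falling
# back to width 1 when the distance range is too narrow
auto_bin_width <- function(levenshtein, target_bins = 8L) {
  rng <- diff(range(levenshtein))
  if (rng <= 0) return(1L)
  max(1L, as.integer(floor((rng + 1) / target_bins)))
}

#' Top-fraction BPS split
#'
#' Partitions records at the `1 - fraction` quantile of the chosen score
#' (ties included in the top group) and asks whether the top group sits at
#' smaller distances, via a one-sided Mann-Whitney U test. By default the
#' split is computed within each read-length stratum, since read length sets
#' the BPS scale.
#'
#' @param records Evaluation records.
#' @param fraction Top fraction, in (0, 1) (default 0.05).
#' @param bps_field Score variant (default `"bps"`).
#' @param stratify Column to stratify by (default `"read_length"` when
#'   present); `NULL` pools everything.
#' @return Tibble with one row per stratum: group sizes, mean and median
#'   Levenshtein per group, `p_value` of the one-sided test, `degenerate`
#'   (all scores tied).
#' @export
top_fraction_split <- function(records, fraction = 0.05, bps_field = "bps",
                               stratify = "read_length") {
  if (fraction <= 0 || fraction >= 1) stopf("`fraction` must be in (0, 1)")
  x <- get_bps_field(records, bps_field)
  strata <- if (!is.null(stratify) && stratify %in% names(records)) {
    records[[stratify]]
  } else {
    rep("all", nrow(records))
  }
  one_stratum <- function(idx) {
    xi <- x[idx]
    lev <- records$levenshtein[idx]
    thr <- stats::quantile(xi, 1 - fraction, names = FALSE)
    top <- xi >= thr
    if (!any(top)) stopf("empty top group")
    degenerate <- all(xi == xi[1]) || all(top)
    p <- if (degenerate) NA_real_ else suppressWarnings(
      stats::wilcox.test(lev[top], lev[!top], alternative = "less",
                         exact = FALSE)$p.value)
    tibble::tibble(
      stratum = as.character(strata[idx][1]),
      n_top = sum(top), n_rest = sum(!top),
      mean_lev_top = mean(lev[top]),
      mean_lev_rest = if (any(!top)) mean(lev[!top]) else NA_real_,
      median_lev_top = stats::median(lev[top]),
      median_lev_rest = if (any(!top)) stats::median(lev[!top]) else NA_real_,
      p_value = p,
      degenerate = degenerate
    )
  }
  out <- dplyr::bind_rows(lapply(split(seq_len(nrow(records)), strata),
                                 one_stratum))
  out[order(out$stratum, method = "radix"), ]
}
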