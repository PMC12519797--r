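# Ground-truth evaluation: Levenshtein distance, Spearman, ANOVA, top split.

test_that("levenshtein_distance matches hand cases and the DP oracle", {
  expect_equal(levenshtein_distance("ACGT", "ACGT"), 0L)
  expect_equal(levenshtein_distance("", "ACGT"), 4L)
  expect_equal(levenshtein_distance("kitten", "sitting"), 3L)
  expect_equal(lev_oracle("kitten", "sitting"), 3L)

  withr::with_seed(17, {
    for (i in 1:100) {
      a <- rand_dna(sample(0:12, 1))
      b <- rand_dna(sample(0:12, 1))
      expect_equal(levenshtein_distance(a, b), lev_oracle(a, b))
    }
  })
})

test_that("levenshtein_distance behaves as a metric on random triples", {
  withr::with_seed(18, {
    for (i in 1:30) {
      a <- rand_dna(sample(1:10, 1))
      b <- rand_dna(sample(1:10, 1))
      cc <- rand_dna(sample(1:10, 1))
      dab <- levenshtein_distance(a, b)
      expect_equal(dab, levenshtein_distance(b, a))
      expect_equal(levenshtein_distance(a, a), 0L)
      expect_lte(dab, levenshtein_distance(a, cc) + levenshtein_distance(cc, b))
    }
  })
})

make_records <- function(truth, cands_seq, scores = NULL, tab = uniform_table(0.5)) {
  cands <- tibble::tibble(
    candidate_id = sprintf("c%02d", seq_along(cands_seq)), seq = cands_seq)
  class(cands) <- c("candidate_set", class(tibble::tibble()))
  if (is.null(scores)) {
    scores <- tibble::tibble(candidate_id = cands$candidate_id,
                             bps = seq_along(cands_seq) * 1.0)
  }
  evaluate_candidates(truth, cands, scores,
                      meta = list(sequence_id = "s1", read_length = 25L))
}

test_that("evaluate_candidates joins distances with scores", {
  truth <- strrep("ACGT", 10)
  mutated <- paste0("T", substring(truth, 2))
  recs <- make_records(truth, c(truth, mutated, strrep("G", 40)))
  expect_equal(nrow(recs), 3L)
  expect_equal(recs$levenshtein[1], 0L)
  expect_equal(recs$levenshtein[2], 1L)
  expect_true(all(recs$truth_length == 40L))

  cands <- tibble::tibble(candidate_id = "a", seq = truth)
  expect_error(
    evaluate_candidates(truth, cands,
                        tibble::tibble(candidate_id = c("a", "b"),
                                       bps = c(1, 2))),
    "parallel")
})

test_that("Spearman against similarity has the claimed direction and antisymmetry", {
  truth <- withr::with_seed(20, rand_dna(60))
  # candidates increasingly far from the truth, bps strictly decreasing
  cands_seq <- vapply(0:9, function(m) {
    s <- strsplit(truth, "")[[1]]
    if (m > 0) s[seq_len(m)] <- "N"
    paste(s, collapse = "")
  }, character(1))
  scores <- tibble::tibble(candidate_id = sprintf("c%02d", 1:10),
                           bps = 10:1 * 1.0)
  recs <- make_records(truth, cands_seq, scores)
  sp <- spearman_bps_vs_similarity(recs)
  expect_equal(sp$rho, 1)

  recs_neg <- recs
  recs_neg$bps <- -recs_neg$bps
  expect_equal(spearman_bps_vs_similarity(recs_neg)$rho, -1)

  recs_const <- recs
  recs_const$bps <- 1
  expect_error(spearman_bps_vs_similarity(recs_const), "constant")
})

test_that("Spearman on shuffled scores is near zero, and matches the rank-Pearson oracle", {
  withr::with_seed(21, {
    lev <- sample(0:50, 1000, replace = TRUE)
    bps <- sample(seq(0, 10, length.out = 1000)) # independent of lev
  })
  recs <- tibble::tibble(levenshtein = lev, truth_length = 100L, bps = bps)
  sp <- spearman_bps_vs_similarity(recs)
  expect_lt(abs(sp$rho), 0.1)
  expect_equal(sp$rho, spearman_oracle(bps, 100L - lev), tolerance = 1e-9)
})

test_that("anova_by_bin matches the sum-of-squares oracle", {
  withr::with_seed(22, {
    lev <- sample(0:29, 200, replace = TRUE)
    bps <- 5 - 0.1 * lev + rnorm(200)
  })
  recs <- tibble::tibble(levenshtein = lev, truth_length = 50L, bps = bps)
  res <- anova_by_bin(recs, bin_width = 10)
  expect_equal(res$F_statistic,
               anova_oracle(bps, floor(lev / 10)), tolerance = 1e-9)
  expect_false(res$degenerate)
})

test_that("anova_by_bin handles degenerate and single-bin input", {
  recs <- tibble::tibble(levenshtein = c(0, 0, 15, 15), truth_length = 20L,
                         bps = c(1, 1, 1, 1))
  res <- anova_by_bin(recs, bin_width = 10)
  expect_equal(res$F_statistic, 0)
  expect_true(res$degenerate)

  one_bin <- tibble::tibble(levenshtein = c(1, 2, 3), truth_length = 20L,
                            bps = c(1, 2, 3))
  expect_error(anova_by_bin(one_bin, bin_width = 10), "one populated")
})

test_that("shuffled group labels give approximately uniform ANOVA p-values", {
  withr::with_seed(23, {
    p_vals <- replicate(200, {
      bps <- rnorm(60)
      lev <- sample(rep(c(0, 10, 20), each = 20))
      anova_by_bin(tibble::tibble(levenshtein = lev, truth_length = 30L,
                                  bps = bps), bin_width = 10)$p_value
    })
  })
  expect_gt(mean(p_vals), 0.4)
  expect_lt(mean(p_vals), 0.6)
})

test_that("top_fraction_split separates a constructed good top group", {
  withr::with_seed(24, {
    n <- 100
    bps <- c(runif(5, 0.9, 1), runif(95, 0, 0.5))
    lev <- c(rep(0L, 5), sample(5:40, 95, replace = TRUE))
  })
  recs <- tibble::tibble(levenshtein = lev, truth_length = 50L, bps = bps,
                         read_length = 25L)
  split <- top_fraction_split(recs, fraction = 0.05)
  expect_gte(split$n_top, 5L)
  expect_lt(split$p_value, 0.05)
  expect_lt(split$mean_lev_top, split$mean_lev_rest)
})

test_that("an all-tied score column degenerates the top split", {
  recs <- tibble::tibble(levenshtein = 1:20, truth_length = 30L,
                         bps = rep(2, 20), read_length = 25L)
  split <- top_fraction_split(recs, fraction = 0.05)
  expect_equal(split$n_top, 20L)
  expect_true(split$degenerate)
  expect_true(is.na(split$p_value))
})

test_that("the top split stratifies by read length", {
  recs <- tibble::tibble(
    levenshtein = rep(1:10, 2), truth_length = 30L,
    bps = c(1:10, 101:110), read_length = rep(c(16L, 40L), each = 10))
  split <- top_fraction_split(recs, fraction = 0.2)
  expect_equal(nrow(split), 2L)
  expect_setequal(split$stratum, c("16", "40"))
})
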