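# Context-biased fragmentation: position weights, breakpoint sampling,
# read generation, fragment conservation, read I/O.

test_that("position weights map the centred octamer and zero the margins", {
  w <- position_weights(strrep("A", 16), uniform_table(0.5))
  expect_equal(w$pos, 0:16)
  expect_equal(w$weight[w$pos >= 4 & w$pos <= 12], rep(0.5, 9))
  expect_equal(w$weight[w$pos < 4 | w$pos > 12], rep(0, 8))
})

test_that("windows containing N get zero weight", {
  s <- paste0(strrep("A", 6), "N", strrep("A", 13)) # N at 0-based index 6
  w <- position_weights(s, uniform_table(0.5))
  covers_n <- w$pos >= 4 & w$pos <= 16 & (w$pos - 4) <= 6 & (w$pos + 3) >= 6
  expect_true(all(w$weight[covers_n] == 0))
  expect_true(all(w$weight[w$pos >= 11 & w$pos <= 16] == 0.5))
})

test_that("position weights pick out specific octamer windows", {
  tab <- table_with(0.1, ACGTACGT = 0.9)
  w <- position_weights(strrep("ACGT", 4), tab)
  expect_equal(w$weight[w$pos %in% c(4, 8, 12)], rep(0.9, 3))
  in_range_other <- w$pos >= 4 & w$pos <= 12 & !w$pos %in% c(4, 8, 12)
  expect_equal(w$weight[in_range_other], rep(0.1, 6))
})

test_that("too-short references are rejected", {
  expect_error(position_weights(strrep("A", 15), uniform_table(0.5)),
               "at least 16")
})

test_that("breakpoint sampling respects weights, seeds and degenerate cases", {
  w <- position_weights(strrep("A", 30), uniform_table(0.5))
  expect_identical(sample_breakpoints(w, 0, 1), integer(0))

  w1 <- w; w1$weight[] <- 0; w1$weight[w1$pos == 10] <- 1
  expect_equal(sample_breakpoints(w1, 5, 1), rep(10L, 5))

  w0 <- w; w0$weight[] <- 0
  expect_error(sample_breakpoints(w0, 3, 1), "all breakpoint weights are zero")

  expect_identical(sample_breakpoints(w, 100, 42), sample_breakpoints(w, 100, 42))
})

test_that("sampling proportions converge to the weights", {
  w <- tibble::tibble(pos = 0:1, weight = c(0.9, 0.1))
  draws <- sample_breakpoints(w, 1e5, 7)
  prop0 <- mean(draws == 0)
  expect_gt(prop0, 0.89)
  expect_lt(prop0, 0.91)
})

test_that("under a uniform table realized breakpoints are uniform over valid positions", {
  ref <- withr::with_seed(2, rand_dna(2000))
  w <- position_weights(ref, uniform_table(0.5))
  w$weight[w$pos + 25 > 2000] <- 0
  draws <- sample_breakpoints(w, 1e5, 11)
  valid <- w$pos[w$weight > 0]
  counts <- table(factor(draws, levels = valid))
  p <- stats::chisq.test(as.integer(counts))$p.value
  expect_gt(p, 0.001)
})

test_that("generate_reads hits the coverage-determined read count exactly", {
  ref <- withr::with_seed(3, rand_dna(1000))
  rs <- generate_reads(ref, uniform_table(0.5), 25, 40, seed = 9)
  expect_equal(nrow(rs), 1600L) # ceiling(40 * 1000 / 25)
  expect_true(all(nchar(rs$seq) == 25L))
  expect_equal(attr(rs, "achieved_coverage"), 40)
})

test_that("every read is the reference substring at its origin breakpoint", {
  ref <- withr::with_seed(4, rand_dna(400))
  rs <- generate_reads(ref, uniform_table(0.5), 20, 10, seed = 5)
  expect_identical(rs$seq, substring(ref, rs$origin_pos + 1, rs$origin_pos + 20))
  expect_true(all(rs$origin_pos >= 4 & rs$origin_pos + 20 <= 400))
  # determinism
  rs2 <- generate_reads(ref, uniform_table(0.5), 20, 10, seed = 5)
  expect_identical(rs, rs2)
})

test_that("a table concentrated on one site yields identical reads", {
  ref <- withr::with_seed(6, rand_dna(60))
  oct <- substring(ref, 8, 15) # octamer centred at pos 11
  tab <- uniform_table(0)
  tab$prob[tab$kmer == oct] <- 0.9
  rs <- generate_reads(ref, tab, 16, 5, seed = 1)
  p <- rs$origin_pos[1]
  expect_true(all(rs$origin_pos == p))
  expect_true(all(rs$seq == substring(ref, p + 1, p + 16)))
})

test_that("reads that would overrun the 3' end are never generated", {
  ref <- withr::with_seed(8, rand_dna(40))
  expect_error(generate_reads(ref, uniform_table(0.5), 40, 2, seed = 1),
               "no valid breakpoint")
  rs <- generate_reads(ref, uniform_table(0.5), 30, 5, seed = 1)
  expect_true(all(rs$origin_pos + 30 <= 40))
})

test_that("fragment_sequence cuts are exact and conserve the reference", {
  ref <- "ACGTACGTACGTACGT"
  expect_identical(fragment_sequence(ref, integer(0)), ref)
  expect_identical(fragment_sequence(ref, 8L), c("ACGTACGT", "ACGTACGT"))
  expect_error(fragment_sequence(ref, c(8L, 8L)), "sorted and unique")
  expect_error(fragment_sequence(ref, c(12L, 8L)), "sorted and unique")
  expect_error(fragment_sequence(ref, 2L), "4 <= pos")

  for (i in 1:50) {
    withr::with_seed(i, {
      r <- rand_dna(sample(20:120, 1))
      L <- nchar(r)
      nb <- sample(0:6, 1)
      br <- sort(sample(4:(L - 4), min(nb, L - 7)))
    })
    frags <- fragment_sequence(r, br)
    expect_identical(paste(frags, collapse = ""), r)
  }
})

test_that("read FASTA/FASTQ round-trips preserve sequences and provenance", {
  ref <- withr::with_seed(9, rand_dna(200))
  rs <- generate_reads(ref, uniform_table(0.5), 18, 3, seed = 2)
  fa <- withr::local_tempfile(fileext = ".fasta")
  fq <- withr::local_tempfile(fileext = ".fastq")

  write_reads(rs, fa, format = "fasta")
  back <- read_reads(fa, format = "fasta")
  expect_identical(back$seq, rs$seq)
  expect_identical(back$origin_pos, rs$origin_pos)

  write_reads(rs, fq, format = "fastq")
  backq <- read_reads(fq, format = "fastq")
  expect_identical(backq$seq, rs$seq)
  qline <- readLines(fq)[4]
  expect_identical(qline, strrep("I", 18))

  write_reads(rs, fa, format = "fasta", blind = TRUE)
  blind <- read_reads(fa)
  expect_true(all(is.na(blind$origin_pos)))
  expect_false(any(grepl("pos=", readLines(fa))))
})

test_that("position weights export as a BedGraph-like TSV", {
  w <- position_weights(strrep("A", 20), uniform_table(0.5))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_position_weights(w, f, id = "chr1")
  back <- readr::read_tsv(f, show_col_types = FALSE)
  expect_equal(back$weight, w$weight)
  expect_true(all(back$id == "chr1"))
})
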