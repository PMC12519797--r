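# Independent oracles and small fixture builders used across the suite.

# full dynamic-programming Levenshtein matrix (unit costs)
lev_oracle <- function(a, b) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A)
  m <- length(B)
  d <- matrix(0L, n + 1L, m + 1L)
  d[, 1L] <- 0:n
  d[1L, ] <- 0:m
  if (n > 0L && m > 0L) {
    for (i in seq_len(n)) {
      for (j in seq_len(m)) {
        d[i + 1L, j + 1L] <- min(d[i, j + 1L] + 1L,
                                 d[i + 1L, j] + 1L,
                                 d[i, j] + (A[i] != B[j]))
      }
    }
  }
  d[n + 1L, m + 1L]
}

# textbook between/within sum-of-squares one-way ANOVA F
anova_oracle <- function(values, groups) {
  groups <- as.character(groups)
  gm <- mean(values)
  k <- length(unique(groups))
  n <- length(values)
  ssb <- sum(tapply(values, groups, function(x) length(x) * (mean(x) - gm)^2))
  ssw <- sum(tapply(values, groups, function(x) sum((x - mean(x))^2)))
  (ssb / (k - 1)) / (ssw / (n - k))
}

# Spearman rho as Pearson correlation of average ranks
spearman_oracle <- function(x, y) {
  stats::cor(rank(x), rank(y))
}

rand_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# full tiling reads of fixed length, step 1
tiling_reads <- function(seq, read_length) {
  L <- nchar(seq)
  substring(seq, 1:(L - read_length + 1L), read_length:L)
}

# smallest k <= k_max such that all (k-1)-mers of `seq` are unique
pick_unique_k <- function(seq, k_min = 9L, k_max = 26L) {
  L <- nchar(seq)
  for (k in k_min:k_max) {
    km1 <- substring(seq, 1:(L - k + 2L), (k - 1L):L)
    if (!anyDuplicated(km1)) return(k)
  }
  NA_integer_
}

# a small complete table with one octamer's probability overridden
table_with <- function(base_p, ...) {
  tab <- uniform_table(base_p)
  over <- list(...)
  for (o in names(over)) tab$prob[tab$kmer == o] <- over[[o]]
  tab
}
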