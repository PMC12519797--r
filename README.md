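# breakrank

Ranking *de novo* assembly candidates by DNA breakage propensity.

## The problem

Assembling ultrashort sequencing reads — below the ~25 bp working floor of
standard *de novo* assemblers, the regime typical of ancient, forensic and
cell-free DNA — is ambiguous: the assembly graph bifurcates and many
candidate reconstructions are consistent with the same reads. `breakrank`
is a proof-of-concept toolkit showing that *prior knowledge about how DNA
breaks* can pick the better candidates. Mechanical fragmentation (e.g.
ultrasonication during library preparation) is biased by the sequence
context around each double-strand break, and that bias is summarised by a
table of octamer breakage probabilities P(break | o).

Every candidate assembly implies a fragmentation pattern: aligning the
reads back to the candidate reveals where the molecule must have broken if
that candidate were true. The **breakage propensity score** of a candidate
is

```
BPS = sum over octamers o of  n_o * P(break | o)
```

where `n_o` counts inferred breakpoint instances whose ±4 bp context
octamer is `o`. Candidates whose implied breaks sit at plausible octamers —
and which explain all the reads — score higher. Because the package
simulates the fragmentation itself, the truth is known and the ranking is
validated against the Levenshtein distance of each candidate to it.

The package provides the full pipeline: octamer probability tables (file,
Bayes-derived, uniform, structured synthetic), a context-biased
fragmentation simulator, a small de Bruijn graph assembler with brute-force
scaffold enumeration, BPS scoring, ground-truth evaluation statistics
(Spearman, one-way ANOVA across distance bins, top-5% split), and an
end-to-end experiment runner. See the vignette in `vignettes/` for the
methods and design rationale.

## Worked example

Simulate biased fragmentation of a known 500 bp sequence, assemble, score,
and compare to the truth:

```r
library(breakrank)

tab   <- structured_table()                      # synthetic octamer probabilities
ref   <- synthesize_references(1, 500, gc = 0.5, seed = 42)
reads <- generate_reads(ref, tab, read_length = 25, target_coverage = 40, seed = 7)
reads
#> <read_set> 800 reads of length 25 from `synth_1` (40.0x coverage)

cands   <- assemble(reads, k = 9, max_candidates = 100, seed = 7, verbose = TRUE)
#> assemble: 486 k-mers (k=9) -> 5 contig(s) -> 65 candidate(s)
scores  <- score_candidates(reads, cands, tab)
records <- evaluate_candidates(ref, cands, scores, meta = list(read_length = 25L))
dplyr::arrange(records, levenshtein)[, c("candidate_id", "levenshtein",
                                         "bps", "bps_per_length", "n_unmatched")]
#> # A tibble: 65 × 5
#>   candidate_id levenshtein   bps bps_per_length n_unmatched
#>   <chr>              <int> <dbl>          <dbl>       <int>
#> 1 cand_38                5  84.1          0.169           0
#> 2 cand_48                5  83.9          0.169           4
#> 3 cand_28                6  84.1          0.169           0
#> 4 cand_45                7  83.9          0.166           4
#> 5 cand_19                8  84.2          0.166           0
#> 6 cand_46               15  79.1          0.157          38
```

The mechanism is visible directly: the candidates closest to the truth
(Levenshtein 5–8) explain essentially every read and carry the highest
scores; wrongly ordered scaffolds leave junction-spanning reads unmatched
and lose exactly that score mass. Across the whole candidate pool the score
tracks similarity (`spearman_bps_vs_similarity(records)` gives rho = 0.30,
p = 0.015 here).

The shipped desk-scale experiment repeats this over 20 references:

```r
rep <- run_experiment(experiment_config(master_seed = 1234L))
rep
#> <bps_experiment>
#>   754 evaluation records from 20 reference(s); 0 failed unit(s)
#>   pooled Spearman rho (bps vs similarity): 0.219 (p = 1.2e-09)
#>   ANOVA across distance bins: F = 35.81 (p = 4.4e-48)
#>   median Levenshtein distance: 219
```

A positive pooled rho is the claimed direction: better assemblies score
higher. `tidy(rep)` gives per-read-length statistics, `glance(rep)` a
one-row summary, `autoplot(rep)` the distance-binned BPS boxplot.
`paper_scale_config()` switches to the full design (200 × 1 kb references,
read lengths 16–40).

A thin command-line wrapper with `simulate` / `assemble` / `score` /
`evaluate` / `run` subcommands is installed under
`system.file("cli", "breakrank", package = "breakrank")`.

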