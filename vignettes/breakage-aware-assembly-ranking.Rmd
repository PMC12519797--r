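---
title: "Ranking de novo assemblies by breakage propensity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking de novo assemblies by breakage propensity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the idea

De novo assembly of ultrashort reads (below the ~25 bp working floor of
standard assemblers, the regime of ancient, forensic and cell-free DNA) is
ambiguous: the assembly graph bifurcates and many candidate reconstructions
are consistent with the same read set. `breakrank` implements a
proof-of-concept ranking criterion that uses *prior knowledge about how DNA
breaks*. Mechanical fragmentation such as ultrasonication is not uniform
along the genome: the sequence context immediately around a double-strand
break biases where breaks occur, and this bias is well summarised by a table
of octamer (8-mer) breakage probabilities, $P(\mathrm{break}\mid o)$ for
every octamer $o$.

Each candidate assembly implies a fragmentation pattern: aligning the reads
back to the candidate reveals where the molecule must have broken *if that
candidate were the true sequence*. The breakage propensity score of a
candidate is the probability-weighted sum over the implied breakpoint
octamers,

$$\mathrm{BPS} = \sum_{o} n_o \, P(\mathrm{break}\mid o),$$

where $n_o$ counts breakpoint instances whose context octamer is $o$.
Candidates whose implied pattern is consistent with the known context bias
score higher; candidates whose pattern would require breaks at implausible
octamers — or which fail to explain reads at all — score lower. Because the
package simulates the fragmentation itself, the true sequence is known and
the ranking can be validated against the Levenshtein distance of each
candidate to the truth.

## The probability table

A `break_prob_table` is a complete map from all $4^8 = 65{,}536$ octamers to
a probability in $[0,1]$. Four sources are supported:

* **File** (`load_break_table()`): delimited text with configurable column
  names, for externally published octamer probability libraries. Because
  such files may store odds-like scores rather than probabilities, the
  loader has a `rescale` flag that min-max rescales into $[0,1]$; values
  outside $[0,1]$ without rescaling are an error, so the choice is always
  explicit.
* **Derived** (`derive_probabilities()`): the Bayesian update
  $P(\mathrm{break}\mid o) = p_\mathrm{break}\,
  P(o \mid \mathrm{break}) / P(o)$, with both frequency tables normalized
  internally. The ratio can exceed 1 for strongly enriched octamers; entries
  are clipped to 1 and the clip count reported, rather than renormalizing
  globally — the entries are used as relative sampling weights and per-site
  scores, and a global renormalization would silently rescale every other
  entry.
* **Uniform** (`uniform_table(p)`): the context-free control under which
  breakpoint sampling is uniform and the BPS collapses to $p$ times the
  breakpoint count.
* **Structured synthetic** (`structured_table()`): a stand-in for an
  empirical library when none is at hand. A position weight model over the 8
  window positions (weights drawn once from a seeded normal, with larger
  standard deviation at the two central positions) gives each octamer a
  score; scores are mapped linearly in $\log_{10}$ space onto
  `p_range = c(0.005, 0.5)`, i.e. two orders of magnitude. This emulates two
  qualitative features of real breakage bias — smooth dependence on sequence
  with the strongest effect next to the cut — while remaining fully
  reproducible.

Lookups of octamers containing `N` (or anything outside A/C/G/T) are hard
errors, never silent zeros: callers must make their skip policy explicit.
`position_weights()` does so by assigning weight 0 to any window containing
`N`.

## Simulating context-biased fragmentation

Conventions, fixed once and shared by simulator and scorer so that scoring
the truth is exact by construction:

* A breakpoint `pos` is 0-based and lies *between* `seq[pos-1]` and
  `seq[pos]`; its context octamer is the half-open slice
  `seq[pos-4, pos+4)` — symmetric 4+4 flanks. Valid positions are
  $4 \le pos \le L-4$.
* Reads extend downstream (3') from the break on the given strand, emulating
  sequencing by synthesis from a fragment end. No reverse-complement reads
  are generated; one strand is a deliberate simplification (see
  *Limitations*).
* Coverage accounting is closed-form: `n_reads = ceiling(coverage * L /
  read_length)`, breakpoints drawn with replacement. Positions whose read
  would overrun the 3' end are masked out of the sampling support before
  drawing, so every read has exactly the configured length.

`generate_reads()` records each read's originating breakpoint, which is what
makes ground-truth validation possible; `write_reads(..., blind = TRUE)`
strips that provenance to emulate the real-world setting.

## The toy assembler

The assembler is deliberately minimal — its job is to produce a pool of
candidate solutions whose quality varies, isolating the ranking question
from assembler engineering:

1. **Graph**: k-mer dictionary from the reads; nodes are (k-1)-mers, edges
   k-mers with occurrence multiplicities.
2. **Contigs**: maximal non-branching paths (unitigs); extension stops at
   any node whose in- or out-degree in distinct k-mers differs from 1.
   Isolated simple cycles are emitted once, opened at their smallest edge.
   An optional multiplicity filter (`min_multiplicity`, default 1 = off) is
   the only cleaning step; reads are error-free by construction, so tip and
   bubble removal would only hide the ambiguity being studied.
3. **Scaffolds**: brute-force enumeration of contig orderings — exhaustive
   when the permutation count fits within `max_candidates` (default 1000;
   200 in the desk-scale experiment), otherwise a seeded uniform subsample —
   with greedy maximal suffix–prefix merging (at least `min_overlap = 3`
   bases, plain concatenation otherwise) and exact-duplicate removal.

All tie-breaking is lexicographic in the C locale, so identical inputs and
seeds give byte-identical output everywhere.

### Choosing k for the ranking experiment

`assemble()` defaults to `k = read_length - 1`, the largest usable k and the
natural choice when one simply wants the best single reconstruction from
ultrashort reads. The *experiment* default is different, and the reasoning
is worth recording.

Two failure modes bracket the useful range. With k close to the read length,
a k-mer is only present when two sampled breakpoints fall within
`read_length - k` bases of each other; at 40x coverage of fixed-length
reads the coupon-collector argument shows many start positions are never
sampled, the graph shatters into dozens of unitigs, and — decisively — every
read is wholly contained in some contig. Every scaffold ordering then
contains every contig and matches every read, so all candidates carry
essentially the same BPS and the score cannot rank them. With k very small,
repeated (k-1)-mers are everywhere and contigs collapse into fragments with
no stable ordering signal at all.

The ranking mechanism needs the middle regime: contig boundaries that reads
*span*. When contigs meet at a genuine graph ambiguity, the reads crossing
that junction are explained only by candidates that order and merge the
contigs correctly; wrong orderings leave those reads unmatched, and
candidates lose exactly the score mass of implausible junctions. The
experiment config therefore uses a length-scaled default chosen so that the
expected number of repeated (k-1)-mer nodes, roughly
$\binom{L}{2} / 4^{k-1}$, is about two: the smallest k with
$4^{k-1} \ge L^2/4$. References then generically assemble into several
contigs — giving each unit a real candidate pool, typically between a
handful and a few dozen candidates — without collapsing into pure
fragments. At the desk scale (L = 500) this gives k = 9; at the 1 kb full
scale, k = 10. A fixed k or the read-length rules can be set with
`k_mode`.

## Scoring

`locate_reads()` is brute-force exact substring search returning the
leftmost match (ties resolved leftward so repetitive candidates are not
multi-counted); reads are error-free, so no edit tolerance is needed. The 5'
end of the match marks the break, consistent with the simulator convention.
Each read instance contributes one breakpoint (instance counting, not
distinct-site counting: two reads from the same break are two observations
of that break). Matches whose octamer would overrun a candidate end
(`p < 4` or `p > len - 4`) are tallied as skipped; unmatched reads are
tallied separately, and the ledger always balances:
`sum(counts) + skipped + unmatched = n_reads`.

Besides the raw BPS, two normalizations are reported: per breakpoint
(`bps / n_breakpoints`, comparable across read depths; bounded by the
largest table probability) and per candidate length (`bps / length`, which
penalises inflated scaffolds). When no breakpoints are identified the score
is 0 and a degenerate flag is set rather than producing 0/0.

The BPS sum is accumulated in lexicographic octamer order. Together with the
shared coordinate convention this makes truth-scoring *bitwise* exact: the
BPS of the true reference computed by alignment equals the simulator-side
sum of the sampled breakpoints' probabilities, floating-point addition order
included. The test suite asserts this with `identical()`, not a tolerance.

## Evaluation statistics

* **Levenshtein distance** (unit-cost edits, via `utils::adist`) measures
  candidate quality; 0 means identical to the truth. The suite checks it
  against a full dynamic-programming oracle and for metric axioms.
* **Spearman correlation** is computed between the BPS variant and
  *similarity*, `truth_length - levenshtein`, so the claimed direction of
  the method — better assemblies score higher — is a *positive* rho. This
  resolves the sign ambiguity that arises when correlating against a
  distance. Two-sided test, average ranks for ties.
* **One-way ANOVA** of the score across distance bins
  (`floor(levenshtein / bin_width)`); the default bin width is chosen so
  that roughly eight bins are populated, and the fully constant input is
  reported as F = 0 with a degenerate flag rather than 0/0.
* **Top-fraction split** (default top 5% by score, ties included in the top
  group) compares distances between the top group and the rest with a
  one-sided Mann–Whitney U test. The split is stratified by read length by
  default, because read length sets the BPS scale and pooling would conflate
  scale with quality.

## The experiment runner and problem sizes

`run_experiment()` crosses references with read lengths; each unit gets a
seed that is a fixed arithmetic function of (master seed, sequence index,
read length), so any unit can be rerun in isolation. Unit failures are
caught and reported without aborting the rest.

The shipped desk-scale design — the package's own choice of a size that a
laptop handles in well under a minute while leaving every statistic
estimable — is 20 synthetic 500 bp references, read length 25, ~40x
coverage, the structured table, `max_candidates = 200`. Candidate counts per
reference vary widely with the realized graph ambiguity (from a handful to
~50). `paper_scale_config()` switches to 200 x 1 kb references and the read
length sweep {16, 18, 20, 25, 40}. Reference windows can also be sampled
from a genome FASTA (`sample_reference_sequences()`): uniform over eligible
positions, N-free, and non-overlapping — a strict reading of "unique"
windows that removes any ambiguity about duplicated content.

## What the synthetic generator does and does not show

The generator emulates: context-biased break positioning (via the octamer
table), fixed-length downstream reads, coverage-targeted sampling with
replacement, and N masking. It does *not* emulate: sequencing errors or
quality decay, adapters, paired ends, insert-size distributions, strand
sampling, PCR duplication, or the long-range (tens to hundreds of bp)
context effects known to modulate real breakage on top of the octamer term.
Passing tests therefore demonstrate the *internal consistency and the
in-principle discriminating power* of breakage-aware ranking under its own
generative assumptions — not performance on real libraries, where alignment
would need error tolerance and the octamer table only captures part of the
context signal.

## Numerical choices and degenerate inputs

* Probabilities from the Bayes ratio are clipped to $[0,1]$ with a logged
  count, never silently renormalized.
* All sorting and tie-breaking uses radix (C-locale) order, immune to the
  session locale.
* Seeds are applied through `withr::with_seed`, so library calls never
  disturb the caller's RNG state; derived unit seeds stay below $2^{31}$.
* Zero-breakpoint candidates, all-tied scores, single-bin ANOVA inputs, and
  constant correlation inputs each have an explicit behaviour (degenerate
  flag or informative error), exercised in the test suite.
* `fragment_sequence()` requires sorted, unique, in-range breakpoints and
  guarantees that the fragments concatenate exactly to the input.

## Limitations

**The pooled correlation at desk scale is a noisy estimator.** Within a
reference, candidates share the read set and the score differences are
exactly the junction mechanism above; the within-unit association between
BPS and similarity is consistently positive whenever a unit has enough
candidates to rank. Pooling records across only 20 references additionally
mixes between-unit differences — references differ in ambient breakage
propensity and in realized graph ambiguity — and this between-unit
component carries no ranking information and can partially cancel the
within-unit signal (a Simpson-type effect). At the full design (200
references, five read lengths) the between-unit noise averages out; at 20
references the pooled rho remains positive but its significance varies with
the master seed. The per-read-length and per-unit views in the report, and
the length-normalized score, are the more stable summaries at small scale.

Other limitations: single-strand simulation and scoring; exact-match alignment only; the
brute-force scaffold pool grows factorially and is subsampled, so for
many-contig units the pool is a random sample of orderings rather than an
exhaustive enumeration; the BPS is the plain count-probability dot product —
deliberately the most transparent use of the prior, not necessarily the most
powerful one; and k = 8 context only. These match the proof-of-concept scope:
the package ranks candidate solutions, it does not attempt to be a
production assembler.
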