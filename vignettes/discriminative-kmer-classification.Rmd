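---
title: "Discriminative k-mer classification: model, modes and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discriminative k-mer classification: model, modes and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diskmer)
```

## The classification model

diskmer assigns query sequences ("objects": short reads, contigs, BACs,
transcripts) to user-defined reference groups ("targets") by exact matching
of k-mers — DNA words of fixed length k ≤ 32. A target is whatever grouping
the question calls for: all genomes of one bacterial genus for metagenomic
binning, or a single chromosome arm for assigning unigenes in a large plant
genome. The defining idea is to throw away, before classification starts,
every k-mer that could be ambiguous: the index keeps only *discriminative*
k-mers, those present in exactly one target. With per-target k-mer sets
disjoint by construction, an object that truly originates from one target
can collect hits against that target and no other, so no taxonomy tree or
lowest-common-ancestor arbitration is ever needed — one flat level of
targets suffices.

Classification of an object with $n$ valid k-mer windows counts, for each
target $t$, the number of windows whose canonical k-mer lies in $t$'s
discriminative set. With $h_1$ and $h_2$ the highest and second-highest
counts, the object is assigned to the top target with confidence

$$c = \frac{h_1}{h_1 + h_2} \in [0.5, 1],$$

or left unassigned when $h_1 = 0$. $c = 1$ means no other target received
any hit; $c = 0.5$ means an exact tie (the smaller target ID is then
reported, with a `tie` flag, so output is deterministic). Downstream, an
assignment is called *high confidence* when $c > 0.75$ — strictly, so
$c = 0.75$ is low confidence.

Matching is strand-independent: every window is reduced to its canonical
form, the smaller of the 2-bit encoding (A=0, C=1, G=2, T=3, first base
most significant) of the window and of its reverse complement. Only
canonical codes are stored and queried, which halves the index and costs a
single lookup per window. Windows containing any non-ACGT character are
skipped whole; no IUPAC expansion is attempted, matching k-spectrum
semantics. Codes cross the R boundary as decimal strings because 4^k
overflows exact double precision beyond k = 26; all inner loops run on
64-bit integers in compiled code.

## Index construction

Building the index tabulates every canonical k-mer of every target sequence
with (i) the first target containing it, (ii) the number of distinct
targets containing it and (iii) its total occurrence count. Two filters then
apply, in this order:

1. **Discriminative filtering.** K-mers in more than one target are
   removed — with one exception. If a pair of targets is declared as the
   two arms of one chromosome, k-mers found in exactly those two arms (and
   nowhere else) are re-assigned to the pair's *centromere pseudo-target*
   instead of discarded: arms assembled from flow-sorted material overlap
   across the centromere, and these arm-shared k-mers are precisely the
   signature of that overlap. Objects assigned to the pseudo-target are
   inferred to be of centromeric origin. Re-assignment precedes the
   multi-target drop, and a k-mer shared with any third target is still
   removed.
2. **Minimum occurrence.** K-mers occurring fewer than `min_occurrence`
   times in total are dropped (default 1, i.e. keep everything). This
   matters when targets are themselves reads or draft assemblies, where
   singleton k-mers are mostly sequencing errors; with assembled targets
   the default is appropriate.

## Execution modes

Four modes trade detail for speed and memory. Their contracts, not their
throughput, are what this package fixes; all four produce identical answers
for unambiguous objects.

* **full** — every window queried, all per-target hit counts returned,
  confidence always available. The reference mode; the other three are
  sampled approximations of it.
* **default** — the index keeps roughly half of each target's
  discriminative set, and querying an object stops as soon as one target
  has collected at least half of the object's total possible hits
  ($\lceil n/2 \rceil$ of *all* valid windows, not only the sampled ones —
  the literal reading of the stopping rule). Which half of the index: the
  even ranks of each target's code-sorted set. The original
  implementation samples "by index position" in its hash table, an order
  that is implementation-defined; rank parity in sorted order is the
  deterministic, per-target-balanced equivalent, chosen so that builds are
  reproducible across machines and runs.
* **express** — only non-overlapping object windows (start positions 0, k,
  2k, ...) are queried and the first hit decides. Because discriminative
  sets are disjoint, an object drawn from a target can only ever hit that
  target, so the first hit is as good as any count. $h_2$ is never
  measured and no confidence is reported (the column is left empty rather
  than printed as 1.0, which would be an unearned claim).
* **light** — fixed k = 27, with the index built from a positional sample
  of each target sequence: one 27-mer window kept, the next four
  non-overlapping 27-mers (4 × 27 positions) skipped, i.e. sampled window
  starts are the multiples of 135. The stated sampling rule ("skips four
  consecutive non-overlapping k-mers") is ambiguous between strides in
  window units and in base-pair units; the multiples-of-135 reading keeps
  one window in five non-overlapping windows (~1/5 of target k-mers) and
  is the interpretation implemented. Because position sampling is defined
  on sequences, not on the k-mer table, the index retains its input
  sequences.

Parallelism is a contract, not a primitive: classification accepts a
`chunk_size` and results are verified identical under any chunking, so any
worker scheme that partitions objects preserves output exactly.

## Parameters that matter

* **k** (bases, 1–32; no default — it is the central tuning choice).
  Larger k raises precision and confidence, smaller k raises sensitivity
  and assignment rate. For bacterial-scale references, k around 19–22
  maximizes sensitivity and k ≥ 26 favours precision; k = 31 is the usual
  high-precision choice, k = 19 a good assembly-to-assembly tradeoff.
* **min_occurrence** (count, default 1): raise to 2 only when targets are
  reads/low-quality assemblies.
* **high_conf_threshold** (confidence units, default 0.75, strict): the
  published working definition of a high-confidence assignment.
* **mode** (default `"default"`): use `full` whenever hit vectors or
  confidence post-filtering are the point.

## The synthetic validation design

Real benchmark databases for this method are multi-gigabase; nothing at
that scale fits a test suite, and nothing requires it — every property the
classifier promises is a structural property, testable on synthetic
communities whose ground truth is exact. `make_community()` generates
i.i.d. uniform ACGT genomes with optional *shared blocks*: random segments
copied verbatim into two genomes at non-overlapping positions, the
controlled analogue of inter-target homology. `sample_reads()` draws reads
uniformly with a substitution-only error model (each base independently
replaced with probability `error_rate` by a uniformly chosen different
base). Substitution-only is deliberate: exact k-mer matching responds to
any error by losing the k windows covering it, indels add nothing to what
is being tested, and keeping coordinates exact keeps truth tables exact.
Truth rides both in a sidecar table and inside read IDs
(`readN|label|pos`), so evaluation survives file round trips.

What the generator does *not* emulate — and hence what green tests do not
show — matters as much: real genomes are not i.i.d. (repeats, skewed
composition, mobile elements), real communities have abundance skew, real
homology is diverged rather than verbatim, and real errors are
quality-dependent. Results on synthetic communities validate the
*machinery* (filtering, counting, scoring, modes, formats), not field
accuracy on any real sample.

The validation experiments, and the scales chosen for them:

* **Oracle equivalence.** On 50 random instances (2–5 targets of 0.5–2 kb,
  k ∈ {7, 11, 15, 21, 31}, 100 reads of 50–150 bp), full-mode hit counts
  are compared entry-for-entry against an independent brute-force matcher
  written in string space (no shared code with the compiled path).
* **Perfect recovery.** 10 targets × 100 kb, 10,000 error-free 100-bp
  reads, k = 31: precision, sensitivity and assignment rate are all
  exactly 1.0 and every confidence is 1.0. This is the idealized limit of
  the observation that with disjoint sets the vast majority of assignments
  have confidence exactly 1.
* **Shared-region blindness.** Reads wholly inside a 500-bp block copied
  into two targets must be 100% unassigned (their every k-mer was removed
  as common); reads overhanging the block by at least k bases recover
  their true genome.
* **Confidence behaviour.** Confidence stratification is only observable
  where classification is fallible. With i.i.d. random genomes and any
  k ≥ 15, exact matching is essentially error-proof and every statistic
  collapses to 1.0; so the noisy experiment deliberately uses k = 7 —
  where the 4^7 k-mer space saturates and cross-target hits are common —
  with 5 targets × 5 kb, 2,000 80-bp reads and a 10% substitution rate
  (the five-fold-elevated error design of the hardest published
  benchmark). In that regime overall precision drops well below 1 while
  the high-confidence subset (c > 0.75) remains far more precise than the
  assignment set as a whole, and correct assignments carry systematically
  higher confidence than wrong ones — the relationship that makes
  confidence-based post-filtering worthwhile. One relationship this
  synthetic regime does *not* reproduce: overall mean confidence exceeding
  overall precision. Uniform cross-noise depresses the confidence of
  correct reads faster than it manufactures wrong assignments, so mean
  confidence tracks below precision here — as it also does in the
  published chromosome-arm results (precision 98.49% vs mean confidence
  ≈ 0.96).

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open throughout; read IDs and truth tables
  use 0-based source positions.
* Ties at the top hit count: smallest target ID wins, `tie = TRUE`,
  confidence 0.5. A rule is required for determinism; the score range
  including 0.5 implies tied objects are assigned rather than dropped.
* Objects shorter than k (or emptied by ambiguity skipping) yield
  `n_kmers = 0` and are unassigned, never an error.
* Repeated k-mers in one object count once per window occurrence.
* Evaluation with zero assigned objects reports precision `NaN` with a
  warning rather than inventing a number.
* The index file is a versioned binary format (magic `DKMERIX1`); wrong
  magic, wrong version and truncation each fail with a distinct message.
  Entries are stored code-sorted, so files are byte-stable across builds.
* Paired-end mates are classified independently; no fragment-level pooling.

## Known limitations

Spaced seeds, minimizers, k > 32 and protein alphabets are out of scope, as
are abundance estimation and any taxonomy-tree reasoning. The FASTA/FASTQ
readers load files whole rather than streaming, which is comfortable far
beyond the scales above but would need revisiting for hundred-gigabase
inputs. The express mode's object sampling (stride exactly k) and the light
mode's stride-135 target sampling are each one reasonable reading of a
loosely specified rule; both are documented above so results are
interpretable, and both are fixed by tests.

## A worked example

```{r example, eval = FALSE}
cm <- make_community(n_targets = 3, genome_len = 20000, seed = 42)
reads <- sample_reads(cm, n_reads = 500, read_len = 100,
                      error_rate = 0.01, seed = 43)
idx <- build_index(cm$genomes, cm$table, k = 31)
res <- classify_full(setNames(reads$sequence, reads$id), idx)
evaluate_classification(res, reads_truth(reads))
```
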