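---
title: "Coarse-to-fine batch protein homology search: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-to-fine batch protein homology search: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqsieve)
```

## The problem and the model

Searching a batch of related protein queries against a large database with
a classical one-query-at-a-time local aligner repeats work twice over: the
database is rescanned per query, and common subsequences — shared both
among queries and among database entries — are realigned again and again.
`seqsieve` removes both redundancies before any expensive alignment
happens. The design rests on three ideas:

1. **Local redundancy is removable without loss.** Two sequences sharing an
   exact 5-mer anchor often continue nearly identically downstream. If the
   anchored spans align at more than 80% identity, the later span carries
   at most 20% novel information, which a compact edit script (replace /
   insert / delete operations with positional offsets) captures exactly.
   The retained, non-redundant *pool* plus the scripts is a lossless
   representation: `decompress()` is the exact inverse of
   `compress_collection()`, which the test suite asserts across thresholds
   and inputs.
2. **Seed matching tolerates mutation better in a reduced alphabet.**
   Substitutions that BLOSUM62 scores favourably tend to stay within the
   ten groups (A), (K,R), (E,D,N,Q), (C), (G), (H), (I,L,V,M), (F,Y,W),
   (P), (S,T), so 10-mer seeds compared in the reduced alphabet match
   across conservative substitutions while the original residues remain
   available (through the map locations) for the exact screening step.
3. **Clustering plus a metric bound prunes candidates safely.** Seeds of
   the same key are clustered with radius 1 (Hamming, the 90% cluster
   threshold on 10-mers). A query seed at distance `d_qr` from a cluster
   representative can only be within the member distance limit
   `floor(10 * (1 - T_s)) = 2` of some member if
   `d_qr <= 2 + 1`, by the triangle inequality. Clusters failing that test
   are skipped wholesale, and the bound is exact — no member within reach
   is ever pruned (a property the suite checks on a thousand random
   instances).

The final report is produced by optimal local alignment (Smith-Waterman
with affine gaps) of the *original* queries against the reassembled
execution database, so coarse filtering can only cost sensitivity, never
report a wrong alignment; with exact-copy queries the suite requires every
planted homolog to be recalled and ranked first.

## Parameters that matter

| Parameter | Default | Units | Role |
|---|---|---|---|
| database similarity threshold | 0.80 | identity fraction | span admission during database compression |
| `T_t` | 0.80 | identity fraction | same, for the query set; 1.0 keeps everything but exact duplicates |
| key length | 5 | residues | anchor word for compression |
| minimum removable span | 15 | residues | floor on removed spans (3 keys) |
| key score threshold `T` | 39 | half-bit score sum | admission of 6–9-mer clustering keys |
| seed length | 10 | residues | clustering and query matching unit |
| `T_c` | 0.90 | identity fraction | cluster radius (1 mismatch on 10-mers) |
| `T_s` | 0.80 | identity fraction | fragment screen; member distance limit 2 |
| gap penalty (global) | 11 | score | compression-stage alignments |
| gap open / extend (local) | 11 / 1 | score | hit extension and fine search |
| x-drop | 20 | score | ungapped extension termination |
| ungapped staging score | 15 | score | minimum ungapped score to nominate a segment pair |
| hit score floor | 30 | score | minimum gapped score for a hit |
| E-value cutoff | 10 | expected chance hits | report filter (λ = 0.267, K = 0.041) |

The thresholds `T = 39`, `T_c = 90%`, `T_s = 80%` and the 80% compression
threshold are the method's stated operating point; key lengths adapt in
6–9 because grouped-maximum scores of fixed-length words vary strongly
with composition (`key_score("YKWVN")` is 38, one short of admission,
while `key_score("YKWVNK")` is 43). Gap costs are the BLOSUM62 community
defaults; the x-drop, staging and hit floors are this package's own
choices, recorded in the artifact manifest so a run can be reproduced
from its outputs.

## Numerical and design choices

* **Threshold semantics.** Span admission uses strict inequality
  (`identity > threshold`), so a span at exactly 80% identity is *not*
  redundant. Exact duplicates (`identity == 1`) are always admissible, so
  a threshold of 1.0 removes duplicates and nothing else.
* **Span selection.** When a key matches, the two suffixes from the key
  start to each sequence end are aligned globally; the removed region is
  the longest alignment prefix ending on a consumed query residue that
  spans at least 15 residues, clears the identity threshold, and keeps
  replace+insert operations within 20% of the span. A maximal prefix keeps
  segments long; the 15-residue floor prevents fragmenting the pool into
  confetti.
* **Script offsets** count residues in the representative span, each
  relative to the previous operation (the first relative to the span
  start). Insertions anchor on the following representative residue, so
  consecutive insertions at one point are well defined and decoding is
  single-pass.
* **Traceback determinism.** All dynamic programs break ties in a fixed
  order (diagonal, then gap-in-subject, then gap-in-query; match state
  preferred over gap states), making every alignment bit-reproducible.
  The compression-stage alignment alone prefers gap-in-subject first
  among equal-score paths: when a short redundant sequence aligns against
  a longer representative suffix, this keeps the matched region as a
  clean alignment prefix with the unmatched representative tail as
  trailing deletions, which is what the span-trimming walk expects.
* **Key scanning** registers, at each position, the shortest 6–9-residue
  window beating `T`, then resumes *after* the registered key, so keys
  never start inside one another. Windows containing the unknown residue
  X never become keys or seeds; X maps to its own singleton group with
  score −1 and is rejected in non-degenerate inputs at parse time for the
  other ambiguity codes (B, Z, U, O).
* **Clustering** is greedy, first-fit, in discovery order, and restricted
  to seeds of the same key. Greedy first-fit guarantees the radius
  invariant (every member within distance 1 of its representative) and
  determinism; it does not minimise cluster count, which the method does
  not need.
* **Hit staging.** Candidate (query segment, database segment) pairs are
  deduplicated before the gapped stage, and the gapped extension is a
  full Smith-Waterman of the segment pair rather than a banded x-drop —
  at execution-database scale the exact alignment is affordable and
  removes a family of edge cases.
* **Degenerate inputs.** Empty collections compress to empty pools, an
  empty query set yields an empty report with zero errors, and score-0
  local alignments are reported as "no hit" rather than empty alignments.

## What the synthetic data does and does not emulate

`make_database()` plants a shared, point-mutated (and optionally indel'd)
block of at least 15 residues inside otherwise uniformly random sequences
— exactly the local-redundancy structure the compressor targets, with
known ground truth for family membership and planted homologs.
It does **not** emulate real-protein composition bias (uniform residue
frequencies), domain architectures, repeats, or low-complexity regions.
Passing tests therefore demonstrate the machinery — losslessness, seed
recall, filter safety, ranking — not field sensitivity on real proteomes;
composition-biased databases will produce more spurious key matches
(harmless for correctness, costly for speed) and real homolog pairs
related by distant, gappy similarity will be missed below the seed
thresholds, as they are by any seed-and-extend method at these settings.

Problem sizes in the suite were chosen to exercise every code path while
keeping the default test run brief: lossless round trips on 200 random
collections across thresholds 0.4–1.0, oracle score equality on 500 random
pairs (length ≤ 12) against an independently written brute-force dynamic
program, a 10,000-seed clustering for the radius bound, and an end-to-end
recall run on a 500-sequence database with 30 exact-copy queries.

## Known limitations

* Compression is quadratic in suffix length per anchored comparison;
  pathological inputs (one residue repeated everywhere) anchor often and
  align long suffixes. The X-window and minimum-span rules bound the
  common cases, not the adversarial ones.
* E-values use fixed gapped Karlin-Altschul constants for BLOSUM62 11/1
  without composition-based adjustment, so they are comparable within a
  run, not calibrated against other tools.
* The clustered database must be rebuilt when the database changes; there
  is no incremental update.
* Single-threaded by design; the kernels are C++ but the orchestration is
  plain R.
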