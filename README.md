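# seqsieve

Batch searching for protein homology, the coarse-to-fine way: instead of
scanning a sequence database once per query, `seqsieve` compresses both the
database and the query set, matches clustered reduced-alphabet seeds to
shortlist candidate regions, reassembles only the implicated original
sequences into a small *execution database*, and runs an exact local
alignment search against that. It is aimed at workflows that repeatedly
search many related queries (proteome slices, strain panels, metagenomic
bins) against a large, locally redundant protein collection.

## Method

The pipeline has an offline and an online phase.

**Offline (database side).**

1. *Lossless compression.* A key-entry pair map indexes every 5-mer of the
   retained pool. When a new sequence shares a 5-mer with the pool, the two
   downstream suffixes are globally aligned (Needleman-Wunsch, BLOSUM62,
   linear gap 11). If the aligned span's identity exceeds the threshold
   (80% for the database), the span is removed and a *difference script*
   records how to rebuild it from its representative: a header locating the
   representative span plus ordered edit ops such as `r6L,r8A,r3V,i5D`
   (replace/insert/delete; offsets count residues in the representative,
   each relative to the previous op). Decompression replays the scripts, so
   the pool plus sidecar reproduces every input exactly.
2. *Keys and seeds.* Pool segments are re-expressed in a ten-group reduced
   amino-acid alphabet — (A), (K,R), (E,D,N,Q), (C), (G), (H), (I,L,V,M),
   (F,Y,W), (P), (S,T) — and scanned for *keys*: the shortest window of
   6–9 residues whose grouped-maximum BLOSUM62 diagonal score sum exceeds
   T = 39. (`YKWVN` scores 38 and is rejected; `YKWVNK` scores 43 and is
   accepted.) Each key occurrence at position p yields a 10-residue *seed*
   covering positions p−5…p+4.
3. *Clustering.* Seeds of the same key are greedily clustered: a seed joins
   the first cluster whose representative is within Hamming distance 1
   (the 90% cluster threshold T_c on 10-mers), else founds a new cluster.
   Three maps persist the result: key→entries (Map1), representative
   seed→cluster (Map2), cluster→members (Map3).

**Online (per query batch).**

1. Queries are compressed the same way at a tunable threshold T_t, and
   every 10-mer of the query pool becomes a query seed.
2. Query seeds identical to a cluster representative are screened at the
   original-residue level against the fragment similarity threshold
   T_s = 80%; passing clusters have all members extended. Non-identical
   representatives are kept when the triangle inequality
   d(S_q,S_m) ≥ d(S_q,S_r) − d(S_r,S_m), with d(S_r,S_m) ≤ 1, still
   admits a member within floor(10·(1−T_s)) = 2 mismatches — i.e. when
   d(S_q,S_r) ≤ 3 — and their members are examined individually.
3. Surviving anchors get an ungapped x-drop extension, nominated segment
   pairs get a gapped (Smith-Waterman, affine 11/1) alignment, and scoring
   pairs become hits. Every original sequence whose segment or difference
   script is touched by a hit is reassembled into the execution database.
4. The fine search aligns the *original* queries against the execution
   database (Smith-Waterman, Karlin-Altschul E-values with λ = 0.267,
   K = 0.041) and reports the conventional 12-column tabular layout.

## Worked example

```r
library(seqsieve)

gen <- make_database(family_spec(n_families = 5, members_per_family = 6,
                                 rep_length = 150, block_length = 60,
                                 substitution_rate = 0.03, rng_seed = 1))
db  <- compress_collection(gen$sequences)
#> compressed_db: 30 original sequence(s) -> 30 pool segment(s), 25 script(s)
#>   residues 4500 -> 2681 (threshold 0.80)
cdb <- build_clustered_db(db)
#> clustered_db: 30 segment(s), 388 key occurrence(s), 358 seed(s), 358 cluster(s)

queries <- make_queries(gen$sequences, 3, mutation_rate = 0.05, rng_seed = 2)
res <- run_batch_search(queries$sequences, db, cdb, verbose = TRUE)
#> query seeds: 423
#> hits: 6 on 6 segment(s)
#> execution db: 18 sequence(s), 2700 residues
#> report: 37 alignment(s)

head(as.data.frame(res$report), 3)
#>   qseqid  sseqid pident length mismatch gapopen qstart qend sstart send   evalue score
#> 1   Q001 F004M03   97.3    150        4       0      1  150      1  150 2.58e-90   809
#> 2   Q001 F004M01   96.7     61        2       0     45  105     45  105 2.45e-32   309
#> 3   Q001 F004M02   82.4     74       13       0     44  117     44  117 7.14e-32   305
```

The 30-sequence database compresses to 60% of its residues because family
members share a mutated 60-residue block. Query `Q001` is a 5%-mutated copy
of `F004M03`; only 18 of the 30 originals are reassembled into the
execution database, and the planted homolog tops the query's block with a
full-length 97.3%-identity alignment.

The same pipeline is available from a shell via the bundled launcher
(`system.file("scripts", "seqsieve", package = "seqsieve")`) with the
subcommands `fixture`, `compress`, `decompress`, `makedb` and `search`.

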