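test_that("query compression honours T_t", {
  set.seed(81)
  distinct <- protein_set(paste0("q", 1:5),
                          vapply(1:5, function(i) rnd_protein(40), ""))
  qdb <- compress_queries(distinct, T_t = 1.0)
  expect_identical(qdb$segments$seq, distinct$seq)

  fams <- do.call(rbind, lapply(1:4, function(f) {
    base <- rnd_protein(80)
    data.frame(id = sprintf("f%dq%d", f, 1:5),
               seq = vapply(1:5, function(i) substitute_k(base, 3), ""),
               stringsAsFactors = FALSE)
  }))
  qs <- protein_set(fams$id, fams$seq)
  qdb2 <- compress_queries(qs, T_t = 0.8)
  expect_lt(pool_residues(qdb2), sum(nchar(qs$seq)))
  sizes <- vapply(c(0.4, 0.6, 0.8), function(t)
    pool_residues(compress_queries(qs, t)), 0)
  expect_true(all(diff(sizes) >= 0))
})

test_that("query seeds slide with step one and skip short segments", {
  mk <- function(s) compress_queries(protein_set("q", s), T_t = 1.0)
  set.seed(82)
  expect_equal(nrow(extract_query_seeds(mk(rnd_protein(10)))), 1)
  expect_equal(nrow(extract_query_seeds(mk(rnd_protein(9)))), 0)
  s30 <- extract_query_seeds(mk(rnd_protein(30)))
  expect_equal(nrow(s30), 21)
  expect_equal(s30$pos, 1:21)
  # windows containing X are skipped
  withx <- mk(paste0(rnd_protein(10), "X", rnd_protein(10)))
  expect_equal(nrow(extract_query_seeds(withx)), 2)
})

test_that("the triangle bound examines exactly the reachable clusters", {
  p <- search_params()           # T_s = 0.8 -> max_member_dist = 2
  expect_equal(p$max_member_dist, 2L)
  expect_true(triangle_bound_pass(0, p))
  expect_true(triangle_bound_pass(3, p))    # bound 2 <= 2
  expect_false(triangle_bound_pass(4, p))   # bound 3 > 2
  d <- 0:10
  expect_equal(triangle_bound_pass(d, p), d <= 3)
})

test_that("triangle filtering never prunes a member within reach", {
  set.seed(83)
  p <- search_params()
  for (k in 1:300) {
    rep_seed <- rnd_reduced(10)
    members <- vapply(seq_len(sample(2:6, 1)), function(i) {
      ch <- strsplit(rep_seed, "")[[1]]
      if (stats::runif(1) < 0.7) {
        at <- sample(10, 1)
        ch[at] <- sample(REDUCED_SYMBOLS, 1)
      }
      paste(ch, collapse = "")
    }, "")
    members <- members[vapply(members, function(m)
      hamming_distance(m, rep_seed), 0L) <= 1]
    q <- strsplit(rep_seed, "")[[1]]
    nmut <- sample(0:5, 1)
    if (nmut) q[sample(10, nmut)] <- sample(REDUCED_SYMBOLS, nmut, TRUE)
    q <- paste(q, collapse = "")
    d_qr <- hamming_distance(q, rep_seed)
    dm <- vapply(members, function(m) hamming_distance(q, m), 0L)
    # completeness: a pruned cluster holds no member within reach
    if (!triangle_bound_pass(d_qr, p))
      expect_true(all(dm > p$max_member_dist))
    for (m in members[dm <= p$max_member_dist])
      expect_true(triangle_bound_pass(d_qr, p))
  }
})

local_search_fixture <- function(seed = 84, n_fam = 6, members = 4) {
  gen <- make_database(family_spec(n_families = n_fam,
                                   members_per_family = members,
                                   rep_length = 120, block_length = 50,
                                   substitution_rate = 0.03,
                                   indel_rate = 0.005, rng_seed = seed))
  db <- compress_collection(gen$sequences)
  list(gen = gen, db = db, cdb = build_clustered_db(db))
}

test_that("a query identical to a pool segment recovers itself", {
  fx <- local_search_fixture()
  seg1 <- fx$db$segments[1, ]
  queries <- protein_set("probe", seg1$seq)
  qdb <- compress_queries(queries, 1.0)
  hits <- find_hits(extract_query_seeds(qdb), fx$cdb, fx$db, qdb)
  expect_gt(nrow(hits), 0)
  self <- hits[hits$segment_id == seg1$id, ]
  expect_gt(nrow(self), 0)
  expect_equal(self$qstart[1], self$sstart[1])
  expect_equal(self$qend[1], self$send[1])
})

test_that("an unrelated query finds no hits", {
  fx <- local_search_fixture()
  set.seed(85)
  queries <- protein_set("lone", rnd_protein(100))
  qdb <- compress_queries(queries, 1.0)
  hits <- find_hits(extract_query_seeds(qdb), fx$cdb, fx$db, qdb)
  expect_equal(nrow(hits), 0)
})

test_that("execution assembly recruits scripted dependents exactly once", {
  set.seed(86)
  s <- rnd_protein(60)
  x <- protein_set(c("r", "d1", "d2", "d3"),
                   c(s, s, substitute_k(s, 2), substitute_k(s, 3)))
  db <- compress_collection(x)
  expect_equal(nrow(db$segments), 1)
  expect_length(db$scripts, 3)
  hits <- data.frame(query_id = "q", segment_id = "r", qstart = 1L,
                     qend = 10L, sstart = 1L, send = 10L, score = 50L,
                     stringsAsFactors = FALSE)
  xdb <- assemble_execution_db(hits, db)
  expect_equal(nrow(xdb$sequences), 4)
  expect_identical(xdb$sequences$seq, x$seq)   # bit-identical originals
  expect_equal(sort(names(xdb$origin)), sort(x$id))

  empty <- assemble_execution_db(hits[0, ], db)
  expect_equal(nrow(empty$sequences), 0)
  expect_error(assemble_execution_db(
    transform(hits, segment_id = "ghost"), db), "unknown segment")
})

test_that("the fine search ranks, filters and scores correctly", {
  set.seed(87)
  subjects <- protein_set(paste0("s", 1:5),
                          vapply(1:5, function(i) rnd_protein(40), ""))
  queries <- protein_set(c("self", paste0("q", 2:5)),
                         c(subjects$seq[3],
                           vapply(2:5, function(i) rnd_protein(35), "")))
  rep10 <- fine_search(queries, subjects, search_params(evalue_cutoff = 10))
  top <- rep10[rep10$qseqid == "self", ][1, ]
  expect_equal(top$sseqid, "s3")
  expect_equal(top$pident, 100)

  # tightening the cutoff yields a subset
  rep_tight <- fine_search(queries, subjects,
                           search_params(evalue_cutoff = 1e-5))
  keys10 <- with(rep10, paste(qseqid, sseqid))
  keys_t <- with(rep_tight, paste(qseqid, sseqid))
  expect_true(all(keys_t %in% keys10))

  # scores equal the exhaustive local-alignment oracle
  for (k in seq_len(nrow(rep10))) {
    q <- queries$seq[match(rep10$qseqid[k], queries$id)]
    s <- subjects$seq[match(rep10$sseqid[k], subjects$id)]
    expect_equal(rep10$score[k], oracle_sw_score(q, s))
  }
  # per-query blocks sorted by evalue then score
  for (b in split(rep10, rep10$qseqid))
    expect_true(!is.unsorted(b$evalue))
})

test_that("the full batch search finds planted homologs deterministically", {
  fx <- local_search_fixture(seed = 88)
  qs <- make_queries(fx$gen$sequences, 5, 0, rng_seed = 89)
  res <- run_batch_search(qs$sequences, fx$db, fx$cdb)
  expect_true(all(qs$truth$source_id %in% res$execution_db$sequences$id))
  top <- vapply(split(res$report, res$report$qseqid),
                function(b) b$sseqid[1], "")
  expect_identical(unname(top[qs$truth$query_id]), qs$truth$source_id)
  # execution database never exceeds the original database
  expect_lte(nrow(res$execution_db$sequences), nrow(fx$gen$sequences))

  # byte-identical reports across runs
  res2 <- run_batch_search(qs$sequences, fx$db, fx$cdb)
  expect_identical(res$report, res2$report)

  # per-query blocks independent of query input order
  perm <- rev(seq_len(nrow(qs$sequences)))
  res3 <- run_batch_search(qs$sequences[perm, ], fx$db, fx$cdb)
  for (q in qs$truth$query_id)
    expect_identical(res3$report[res3$report$qseqid == q, ],
                     res$report[res$report$qseqid == q, ],
                     ignore_attr = TRUE)
})

test_that("an empty query set produces an empty report without errors", {
  fx <- local_search_fixture(seed = 90, n_fam = 2, members = 2)
  res <- run_batch_search(protein_set(), fx$db, fx$cdb)
  expect_equal(nrow(res$report), 0)
  expect_equal(res$counts$hits, 0)
})
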