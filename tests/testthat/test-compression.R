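test_that("the key-entry pair map indexes every sliding window", {
  set.seed(3)
  s1 <- rnd_protein(6)
  m <- build_key_entry_map(protein_set("a", s1), key_len = 5)
  expect_equal(nrow(m$entries), 2)            # L - k + 1
  expect_equal(m$entries$pos, c(1L, 2L))

  # a shared word chains two entries (in discovery order)
  x <- protein_set(c("a", "b"),
                   c(paste0("MKT", "SERGK", "AYW"),
                     paste0("AWYC", "SERGK")))
  m2 <- build_key_entry_map(x, 5)
  chain <- m2$index[["SERGK"]]
  expect_equal(nrow(m2$entries[m2$entries$key == "SERGK", ]), 2)
  expect_equal(unname(chain[, 1]), c(1L, 2L))   # sequence index
  expect_equal(unname(chain[, 2]), c(4L, 5L))   # start position

  # too-short sequences contribute nothing
  m3 <- build_key_entry_map(protein_set("a", "MKTA"), 5)
  expect_equal(nrow(m3$entries), 0)
})

test_that("difference scripts encode and decode the worked forms", {
  enc <- encode_diff_script("AAAAAAAAAA", "AAAWAAAAAA")
  expect_equal(nrow(enc$ops), 1)
  expect_equal(enc$ops$kind, "r")
  expect_equal(enc$ops$offset, 4L)            # 4th residue from span start
  expect_equal(enc$ops$residue, "W")

  ident <- encode_diff_script("MKTAYWCDEFGHIKL", "MKTAYWCDEFGHIKL")
  expect_equal(nrow(ident$ops), 0)

  expect_error(encode_diff_script("AAAAAAAAAA", "WWWWWAAAAA"),
               "below the similarity threshold")

  # decoding elementary scripts
  expect_equal(decode_diff_script("MKTAY", parse_ops(".")), "MKTAY")
  expect_equal(decode_diff_script("MKTAY", "d1"), "KTAY")
  expect_error(decode_diff_script("MKTAY", "r9W"), "corrupt")

  # the published op syntax parses into offsets 6, 8, 3, 5
  ops <- parse_ops("r6L,r8A,r3V,i5D")
  expect_equal(ops$kind, c("r", "r", "r", "i"))
  expect_equal(ops$offset, c(6L, 8L, 3L, 5L))
  expect_equal(ops$residue, c("L", "A", "V", "D"))
  expect_equal(format_ops(ops), "r6L,r8A,r3V,i5D")
  expect_error(parse_ops("r6L,q2A"), "malformed")
  expect_error(parse_ops("d3W"), "residue")
})

test_that("offsets agree with an independent column-walk for substitutions", {
  set.seed(21)
  for (k in 1:20) {
    rep_span <- rnd_protein(40)
    nmut <- sample(1:6, 1)
    removed <- substitute_k(rep_span, nmut)
    enc <- encode_diff_script(rep_span, removed)
    # pure substitutions: mismatch positions recomputed directly
    at <- which(strsplit(rep_span, "")[[1]] != strsplit(removed, "")[[1]])
    expect_equal(enc$ops$offset, diff(c(0L, at)))
    expect_equal(enc$ops$residue,
                 strsplit(removed, "")[[1]][at])
    expect_equal(decode_diff_script(rep_span, enc$ops), removed)
  }
})

test_that("encode/decode round-trips 1000 random similar pairs", {
  set.seed(77)
  for (k in 1:1000) {
    len <- sample(20:60, 1)
    a <- rnd_protein(len)
    b <- substitute_k(a, sample(0:floor(len * 0.15), 1))
    enc <- encode_diff_script(a, b)
    expect_identical(decode_diff_script(a, enc$ops), b)
  }
})

test_that("exact duplicates compress to a single whole-span script", {
  set.seed(5)
  s <- rnd_protein(60)
  db <- compress_collection(protein_set(c("a", "b"), c(s, s)))
  expect_equal(nrow(db$segments), 1)
  expect_equal(db$segments$seq, s)
  expect_length(db$scripts, 1)
  expect_equal(nrow(db$scripts[[1]]$ops), 0)
  items <- db$provenance$b
  expect_length(items, 1)
  expect_equal(items[[1]]$type, "script")
  expect_identical(decompress(db)$seq, c(s, s))
})

test_that("block-sharing collections lose the redundant placements", {
  set.seed(31)
  # flanks drawn from disjoint residue sets so only the block can anchor
  fa <- function(n) paste(sample(AMINO_ACIDS[1:10], n, TRUE), collapse = "")
  fb <- function(n) paste(sample(AMINO_ACIDS[11:20], n, TRUE), collapse = "")
  block <- rnd_protein(40)
  q1 <- paste0(fa(30), block, fa(30))                     # donor
  q2 <- paste0(fb(40), block)                             # rear block
  q3 <- paste0(fb(25), block, fb(25))                     # middle block
  q4 <- paste0(block, fb(40))                             # front block
  q5 <- block                                             # block only
  q6 <- fb(60)                                            # unrelated
  x <- protein_set(paste0("q", 1:6), c(q1, q2, q3, q4, q5, q6))
  db <- compress_collection(x)

  expect_identical(as.data.frame(decompress(db)), as.data.frame(x))
  # q5 is completely removed, q6 completely reserved
  expect_false("q5" %in% db$segments$id)
  expect_equal(db$segments$seq[db$segments$id == "q6"], q6)
  # q2 keeps (a prefix of) its front, loses the rear
  s2 <- db$segments$seq[db$segments$id == "q2"]
  expect_lt(nchar(s2), nchar(q2))
  expect_equal(substr(q2, 1, nchar(s2)), s2)
  # q3's retained flanks are concatenated around a middle script
  types3 <- vapply(db$provenance$q3, `[[`, "", "type")
  expect_equal(types3[1], "literal")
  expect_true("script" %in% types3)
  expect_lt(pool_residues(db), sum(nchar(x$seq)))
})

test_that("unrelated random sequences pass through untouched", {
  set.seed(57)
  x <- protein_set(paste0("r", 1:6),
                   vapply(1:6, function(i) rnd_protein(50), ""))
  db <- compress_collection(x)
  expect_identical(db$segments$seq, x$seq)
  expect_length(db$scripts, 0)
  # brute-force all-pairs scan: confirm no anchored pair could qualify
  words <- lapply(x$seq, function(s) substring(s, 1:46, 5:50))
  for (i in 1:5) for (j in (i + 1):6) {
    shared <- intersect(words[[i]], words[[j]])
    for (w in shared) {
      pi <- regexpr(w, x$seq[i], fixed = TRUE)
      pj <- regexpr(w, x$seq[j], fixed = TRUE)
      sim <- nw_similarity(substr(x$seq[i], pi, 50), substr(x$seq[j], pj, 50))
      expect_lte(sim, 0.8)
    }
  }
})

test_that("threshold 1 removes only exact duplicates", {
  set.seed(8)
  a <- rnd_protein(60)
  near <- substitute_k(a, 3)
  x <- protein_set(c("a", "near", "dup"), c(a, near, a))
  db <- compress_collection(x, compression_params(1.0))
  expect_setequal(db$segments$id, c("a", "near"))
  expect_identical(decompress(db)$seq, x$seq)
})

test_that("compression is lossless across thresholds and inputs", {
  set.seed(404)
  for (thr in c(0.4, 0.6, 0.8, 1.0)) {
    for (k in 1:5) {
      x <- shared_block_set(n = 4, flank = sample(10:30, 1),
                            block_len = 40, subs = sample(0:4, 1))
      db <- compress_collection(x, compression_params(thr))
      expect_identical(as.data.frame(decompress(db)), as.data.frame(x))
    }
  }
})

test_that("pool size is monotone in the threshold", {
  set.seed(58)
  x <- shared_block_set(n = 6, flank = 25, block_len = 45, subs = 3)
  sizes <- vapply(c(0.4, 0.6, 0.8, 1.0), function(t)
    pool_residues(compress_collection(x, compression_params(t))), 0)
  expect_true(all(diff(sizes) >= 0))
  expect_lte(sizes[3], sum(nchar(x$seq)))
})

test_that("script op counts respect the 20% mismatch bound", {
  set.seed(59)
  x <- shared_block_set(n = 5, flank = 20, block_len = 50, subs = 4)
  db <- compress_collection(x)
  expect_gt(length(db$scripts), 0)
  for (sc in db$scripts) {
    removed <- decode_diff_script(
      substr(db$segments$seq[sc$rep_seg], sc$start, sc$end), sc$ops)
    n_ri <- sum(sc$ops$kind %in% c("r", "i"))
    expect_lte(n_ri, 0.2 * nchar(removed) + 1e-9)
  }
})

test_that("a hand-built database decompresses by direct assembly", {
  set.seed(60)
  rep_seq <- rnd_protein(30)
  # three members derived from the representative by explicit edits
  m2 <- rep_seq                                        # exact copy
  m3 <- paste0(substr(rep_seq, 1, 4), "W", substr(rep_seq, 6, 30))  # r5W
  m4 <- substr(rep_seq, 2, 30)                         # d1
  db <- structure(list(
    segments = protein_set("r1", rep_seq),
    scripts = list(
      list(owner_id = "m2", rep_seg = 1L, start = 1L, end = 30L,
           ops = parse_ops(".")),
      list(owner_id = "m3", rep_seg = 1L, start = 1L, end = 30L,
           ops = parse_ops("r5W")),
      list(owner_id = "m4", rep_seg = 1L, start = 1L, end = 30L,
           ops = parse_ops("d1"))),
    provenance = list(
      r1 = list(list(type = "literal", seg = 1L, start = 1L, end = 30L)),
      m2 = list(list(type = "script", index = 1L)),
      m3 = list(list(type = "script", index = 2L)),
      m4 = list(list(type = "script", index = 3L))),
    ids = c("r1", "m2", "m3", "m4"),
    desc = setNames(rep("", 4), c("r1", "m2", "m3", "m4")),
    params = compression_params()), class = "compressed_db")
  out <- decompress(db)
  expect_equal(nrow(out), 4)
  expect_identical(out$seq, c(rep_seq, m2, m3, m4))
})

test_that("the on-disk form round-trips pool, scripts and provenance", {
  set.seed(61)
  x <- shared_block_set(n = 5, flank = 25, block_len = 40, subs = 3)
  db <- compress_collection(x)
  dir <- withr::local_tempdir()
  write_compressed_db(db, dir)
  expect_true(file.exists(file.path(dir, "pool.fasta")))
  db2 <- read_compressed_db(dir)
  expect_identical(as.data.frame(db2$segments), as.data.frame(db$segments))
  expect_identical(as.data.frame(decompress(db2)), as.data.frame(x))
  expect_equal(db2$params$similarity_threshold,
               db$params$similarity_threshold)
  expect_error(read_compressed_db(withr::local_tempdir()), "missing")
})
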