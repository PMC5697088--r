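# Online phase: compress the query set, slide reduced-alphabet seeds over
# the query pool, match them against cluster representatives (exact match
# or the triangle-inequality compensation filter), extend matches into
# hits, reassemble the implicated original sequences into an execution
# database, and run the fine local-alignment search against it.

#' Search parameters
#'
#' @param T_t query-set compression threshold (default 0.80).
#' @param T_s fragment similarity threshold for seed-level screening
#'   (default 0.80); on 10-residue seeds this converts to a maximum member
#'   distance of `floor(seed_len * (1 - T_s))` = 2 mismatches.
#' @param T_c cluster threshold the database was built with (default 0.90);
#'   with 10-residue seeds the representative-member distance is at most 1,
#'   which is the compensation term in the triangle bound.
#' @param seed_len seed length (10).
#' @param evalue_cutoff report cutoff (default 10).
#' @param gap_open,gap_extend affine gap parameters of the fine search.
#' @param xdrop ungapped extension drop-off (raw score units).
#' @param ungapped_min_score minimum ungapped-extension score for a seed
#'   match to nominate its segment pair for gapped extension.
#' @param hit_min_score minimum gapped (Smith-Waterman) score for a hit.
#' @return A list of class `search_params`; `max_member_dist` is derived.
#' @export
search_params <- function(T_t = 0.8, T_s = 0.8, T_c = 0.9, seed_len = 10L,
                          evalue_cutoff = 10, gap_open = 11L,
                          gap_extend = 1L, xdrop = 20L,
                          ungapped_min_score = 15L, hit_min_score = 30L) {
  stopifnot(T_t > 0, T_t <= 1, T_s > 0, T_s <= 1, T_c > 0, T_c <= 1,
            seed_len > 0, evalue_cutoff > 0)
  structure(list(T_t = T_t, T_s = T_s, T_c = T_c,
                 seed_len = as.integer(seed_len),
                 max_member_dist = as.integer(
                   floor(seed_len * (1 - T_s) + 1e-9)),
                 evalue_cutoff = evalue_cutoff,
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 xdrop = as.integer(xdrop),
                 ungapped_min_score = as.integer(ungapped_min_score),
                 hit_min_score = as.integer(hit_min_score)),
            class = "search_params")
}

#' Compress the query set
#'
#' [compress_collection()] at the query threshold `T_t`; `T_t = 1` removes
#' only exact duplicates.
#'
#' @param queries a [protein_set].
#' @param T_t query compression threshold.
#' @return A `compressed_db` over the queries.
#' @export
compress_queries <- function(queries, T_t = 0.8) {
  compress_collection(queries, compression_params(similarity_threshold = T_t))
}

#' Extract sliding query seeds from a compressed query set
#'
#' Every ten adjacent residues of every query pool segment, re-expressed in
#' the reduced alphabet (sliding window, step 1). Windows containing X are
#' skipped; segments shorter than the seed length produce no seeds.
#'
#' @param compressed_queries a `compressed_db` over the query set.
#' @param seed_len seed length (default 10).
#' @return A data frame: `residues` (reduced seed), `seg` (query segment
#'   index), `pos` (1-based window start).
#' @export
extract_query_seeds <- function(compressed_queries, seed_len = 10L) {
  stopifnot(inherits(compressed_queries, "compressed_db"))
  segs <- compressed_queries$segments
  out <- vector("list", nrow(segs))
  for (i in seq_len(nrow(segs))) {
    L <- nchar(segs$seq[i])
    if (L < seed_len) next
    rseq <- reduce_sequence(segs$seq[i])
    starts <- 1:(L - seed_len + 1L)
    res <- substring(rseq, starts, starts + seed_len - 1L)
    ok <- !grepl("X", res, fixed = TRUE)
    out[[i]] <- data.frame(residues = res[ok], seg = i, pos = starts[ok],
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(residues = character(0), seg = integer(0),
                      pos = integer(0), stringsAsFactors = FALSE)
  row.names(out) <- NULL
  out
}

#' Triangle-inequality compensation filter
#'
#' For a query seed q with Hamming distance `d_qr` to a cluster
#' representative r, the triangle inequality gives
#' `d(q, m) >= d_qr - d(r, m)` for any member m; with the cluster radius
#' `d(r, m) <= 1` the lower bound is `d_qr - 1`. The cluster's members must
#' be examined individually exactly when that bound does not already exceed
#' the member distance limit, i.e. when `d_qr <= max_member_dist + 1`.
#'
#' @param d_qr Hamming distance between the query seed and a cluster
#'   representative.
#' @param params a [search_params()].
#' @return `TRUE` when the cluster's members must be examined.
#' @export
triangle_bound_pass <- function(d_qr, params = search_params()) {
  stopifnot(all(d_qr >= 0))
  (d_qr - 1L) <= params$max_member_dist
}

#' Find hits between query seeds and the clustered database
#'
#' Each query seed is compared with the cluster representatives (Map2).
#' Identical representatives are screened at the fragment level: the
#' original (non-reduced) ten-residue fragments are recovered via the map
#' locations and must exceed the similarity threshold `T_s`; the cluster's
#' members (Map3) are then anchor-extended. Non-identical representatives
#' passing [triangle_bound_pass()] trigger per-member examination: members
#' within `max_member_dist` of the query seed are anchor-extended. An
#' extension is an ungapped x-drop pass at the seed anchor followed by a
#' gapped (Smith-Waterman) alignment of the nominated segment pair; gapped
#' alignments scoring at least `hit_min_score` become hits, deduplicated
#' per (query segment, database segment) pair.
#'
#' @param query_seeds from [extract_query_seeds()].
#' @param cdb a `clustered_db`.
#' @param db the compressed database (`compressed_db`).
#' @param qdb the compressed query set (`compressed_db`).
#' @param params a [search_params()].
#' @return A data frame of hits: `query_id`, `segment_id`, `qstart`,
#'   `qend`, `sstart`, `send`, `score`.
#' @export
find_hits <- function(query_seeds, cdb, db, qdb, params = search_params()) {
  stopifnot(inherits(cdb, "clustered_db"), inherits(db, "compressed_db"),
            inherits(qdb, "compressed_db"))
  empty <- data.frame(query_id = character(0), segment_id = character(0),
                      qstart = integer(0), qend = integer(0),
                      sstart = integer(0), send = integer(0),
                      score = integer(0), stringsAsFactors = FALSE)
  clusters <- cdb$clustering$clusters
  if (!nrow(query_seeds) || !nrow(clusters)) return(empty)
  S <- blosum62()
  seed_len <- cdb$clustering$seed_len
  members_by_cluster <- split(seq_len(nrow(cdb$clustering$members)),
                              cdb$clustering$members$cluster)
  mem <- cdb$clustering$members

  uq <- unique(query_seeds$residues)
  occ_by_seed <- split(seq_len(nrow(query_seeds)), query_seeds$residues)
  pairs <- .hamming_pairs_cpp(uq, clusters$residues,
                              params$max_member_dist + 1L)

  seen <- new.env(hash = TRUE, parent = emptyenv())     # (qseg, dseg) pairs
  cand_q <- integer(0); cand_s <- integer(0)
  extend_anchor <- function(qrow, mseg, mpos) {
    qseg <- query_seeds$seg[qrow]
    pk <- paste0(qseg, ":", mseg)
    if (!is.null(seen[[pk]])) return(invisible())
    ext <- .xdrop_extend_cpp(qdb$segments$seq[qseg], db$segments$seq[mseg],
                             query_seeds$pos[qrow], mpos, seed_len, S,
                             params$xdrop)
    if (ext$score >= params$ungapped_min_score) {
      seen[[pk]] <- TRUE
      cand_q <<- c(cand_q, qseg)
      cand_s <<- c(cand_s, mseg)
    }
    invisible()
  }

  for (r in seq_len(nrow(pairs))) {
    qi <- pairs$qi[r]; ci <- pairs$ri[r]; d <- pairs$d[r]
    occs <- occ_by_seed[[uq[qi]]]
    mrows <- members_by_cluster[[as.character(clusters$cluster[ci])]]
    if (d == 0L) {
      rep_frag <- substr(db$segments$seq[clusters$seg[ci]], clusters$pos[ci],
                         clusters$pos[ci] + seed_len - 1L)
      for (o in occs) {
        qfrag <- substr(qdb$segments$seq[query_seeds$seg[o]],
                        query_seeds$pos[o],
                        query_seeds$pos[o] + seed_len - 1L)
        ident <- 1 - hamming_distance(qfrag, rep_frag) / seed_len
        if (!.sim_pass(ident, params$T_s)) next
        for (m in mrows) extend_anchor(o, mem$seg[m], mem$pos[m])
      }
    } else {
      # compensation path (triangle bound passed by construction)
      for (m in mrows) {
        dm <- hamming_distance(uq[qi], mem$residues[m])
        if (dm > params$max_member_dist) next
        for (o in occs) extend_anchor(o, mem$seg[m], mem$pos[m])
      }
    }
  }

  if (!length(cand_q)) return(empty)
  ord <- order(cand_q, cand_s)
  cand_q <- cand_q[ord]; cand_s <- cand_s[ord]
  rows <- vector("list", length(cand_q))
  for (k in seq_along(cand_q)) {
    al <- .sw_align_cpp(qdb$segments$seq[cand_q[k]],
                        db$segments$seq[cand_s[k]], S,
                        params$gap_open, params$gap_extend)
    if (al$score < params$hit_min_score) next
    rows[[k]] <- data.frame(query_id = qdb$segments$id[cand_q[k]],
                            segment_id = db$segments$id[cand_s[k]],
                            qstart = al$a_start, qend = al$a_end,
                            sstart = al$b_start, send = al$b_end,
                            score = al$score, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty)
  row.names(out) <- NULL
  out
}

#' Assemble the execution database from hits
#'
#' Every database segment named by a hit recruits its own original sequence
#' plus every original sequence whose difference scripts reference that
#' segment; the recruited originals are reconstructed in full (via the
#' scripts) and added once.
#'
#' @param hits a hit data frame from [find_hits()].
#' @param db the compressed database.
#' @return An object of class `execution_db`: `sequences` (a
#'   [protein_set] of exact original sequences) and `origin` (per sequence,
#'   the recruiting segment ids).
#' @export
assemble_execution_db <- function(hits, db) {
  stopifnot(inherits(db, "compressed_db"))
  seg_ids <- unique(hits$segment_id)
  origin <- list()
  for (sid in seg_ids) {
    if (!sid %in% db$segments$id)
      stop("hit references unknown segment '", sid, "'", call. = FALSE)
    seg_idx <- match(sid, db$segments$id)
    dependents <- vapply(db$scripts, function(sc) {
      if (sc$rep_seg == seg_idx) sc$owner_id else NA_character_
    }, "")
    recruited <- unique(c(sid, dependents[!is.na(dependents)]))
    for (rid in recruited) origin[[rid]] <- unique(c(origin[[rid]], sid))
  }
  ids <- db$ids[db$ids %in% names(origin)]
  structure(list(sequences = decompress(db, ids),
                 origin = origin[ids]),
            class = "execution_db")
}

#' @export
print.execution_db <- function(x, ...) {
  cat(sprintf("execution_db: %d sequence(s), %d residues\n",
              nrow(x$sequences), sum(nchar(x$sequences$seq))))
  invisible(x)
}

.gap_opens <- function(chars) {
  g <- chars == "-"
  sum(g & !c(FALSE, g[-length(g)]))
}

#' Fine search: local alignment of the original queries
#'
#' Smith-Waterman with affine gaps between every original query and every
#' execution-database sequence, with Karlin-Altschul E-values over the
#' execution database's total residue count. Alignments with E-value above
#' the cutoff (or score zero) are dropped; each query's block is sorted by
#' ascending E-value, then descending score, then subject id.
#'
#' @param original_queries a [protein_set] (the uncompressed queries).
#' @param xdb an `execution_db` (or a [protein_set] of subjects).
#' @param params a [search_params()].
#' @return A `homology_report` data frame in conventional 12-column tabular
#'   layout: `qseqid`, `sseqid`, `pident`, `length`, `mismatch`, `gapopen`,
#'   `qstart`, `qend`, `sstart`, `send`, `evalue`, `score`.
#' @export
fine_search <- function(original_queries, xdb, params = search_params()) {
  queries <- as_protein_set(original_queries)
  subjects <- if (inherits(xdb, "execution_db")) xdb$sequences else
    as_protein_set(xdb)
  cols <- data.frame(qseqid = character(0), sseqid = character(0),
                     pident = numeric(0), length = integer(0),
                     mismatch = integer(0), gapopen = integer(0),
                     qstart = integer(0), qend = integer(0),
                     sstart = integer(0), send = integer(0),
                     evalue = numeric(0), score = integer(0),
                     stringsAsFactors = FALSE)
  if (!nrow(queries) || !nrow(subjects))
    return(structure(cols, class = c("homology_report", "data.frame")))
  S <- blosum62()
  n_db <- sum(nchar(subjects$seq))
  blocks <- vector("list", nrow(queries))
  for (qi in seq_len(nrow(queries))) {
    m <- nchar(queries$seq[qi])
    rows <- vector("list", nrow(subjects))
    for (si in seq_len(nrow(subjects))) {
      al <- .sw_align_cpp(queries$seq[qi], subjects$seq[si], S,
                          params$gap_open, params$gap_extend)
      if (al$score <= 0) next
      ev <- evalue(al$score, m, n_db)
      if (ev > params$evalue_cutoff) next
      ca <- strsplit(al$aligned_a, "", fixed = TRUE)[[1]]
      cb <- strsplit(al$aligned_b, "", fixed = TRUE)[[1]]
      len <- length(ca)
      ident <- sum(ca == cb & ca != "-")
      rows[[si]] <- data.frame(
        qseqid = queries$id[qi], sseqid = subjects$id[si],
        pident = round(100 * ident / len, 2), length = len,
        mismatch = sum(ca != "-" & cb != "-" & ca != cb),
        gapopen = .gap_opens(ca) + .gap_opens(cb),
        qstart = al$a_start, qend = al$a_end,
        sstart = al$b_start, send = al$b_end,
        evalue = ev, score = al$score, stringsAsFactors = FALSE)
    }
    block <- do.call(rbind, rows)
    if (!is.null(block))
      blocks[[qi]] <- block[order(block$evalue, -block$score,
                                  block$sseqid), , drop = FALSE]
  }
  out <- do.call(rbind, blocks)
  if (is.null(out)) out <- cols
  row.names(out) <- NULL
  structure(out, class = c("homology_report", "data.frame"))
}

#' @export
print.homology_report <- function(x, ...) {
  cat(sprintf("homology report: %d alignment(s), %d query(ies)\n",
              nrow(x), length(unique(x$qseqid))))
  if (nrow(x)) print.data.frame(head(as.data.frame(x), 10), digits = 3)
  invisible(x)
}

#' Run the complete batch search
#'
#' The full online phase: [compress_queries()], [extract_query_seeds()],
#' [find_hits()], [assemble_execution_db()] and [fine_search()], with
#' per-stage counters. The fine search always runs against the original
#' (uncompressed) queries.
#'
#' @param queries a [protein_set] of query sequences.
#' @param db the compressed database.
#' @param cdb the clustered database built from `db`.
#' @param params a [search_params()].
#' @param verbose emit per-stage progress via [message()].
#' @return A list of class `batch_search_result` with `report`
#'   (the `homology_report`), `hits`, `execution_db` and `counts`.
#' @export
run_batch_search <- function(queries, db, cdb, params = search_params(),
                             verbose = FALSE) {
  queries <- as_protein_set(queries)
  say <- function(...) if (verbose) message(sprintf(...))
  say("queries: %d sequence(s), %d residues", nrow(queries),
      sum(nchar(queries$seq)))
  qdb <- compress_queries(queries, params$T_t)
  say("query pool: %d segment(s), %d residues", nrow(qdb$segments),
      pool_residues(qdb))
  qseeds <- extract_query_seeds(qdb, params$seed_len)
  say("query seeds: %d", nrow(qseeds))
  hits <- find_hits(qseeds, cdb, db, qdb, params)
  say("hits: %d on %d segment(s)", nrow(hits),
      length(unique(hits$segment_id)))
  xdb <- assemble_execution_db(hits, db)
  say("execution db: %d sequence(s), %d residues", nrow(xdb$sequences),
      sum(nchar(xdb$sequences$seq)))
  report <- fine_search(queries, xdb, params)
  say("report: %d alignment(s)", nrow(report))
  structure(list(report = report, hits = hits, execution_db = xdb,
                 counts = list(queries = nrow(queries),
                               query_pool_residues = pool_residues(qdb),
                               query_seeds = nrow(qseeds),
                               hits = nrow(hits),
                               execution_sequences = nrow(xdb$sequences))),
            class = "batch_search_result")
}

#' @export
print.batch_search_result <- function(x, ...) {
  cat("batch search result\n")
  cat(sprintf("  %s: %s\n", names(x$counts), unlist(x$counts)), sep = "")
  print(x$report)
  invisible(x)
}
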