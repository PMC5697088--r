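# Lossless redundancy removal. A key-entry pair map anchors candidate
# redundant regions on shared 5-mers; anchored suffixes are compared by
# global alignment, spans clearing the similarity threshold are removed
# from the later sequence, and a difference script (replace / insert /
# delete operations with residue offsets) records how to reconstruct the
# removed span from its representative.

#' Compression parameters
#'
#' @param similarity_threshold admission threshold for redundant spans. A
#'   span is removed when its alignment identity exceeds the threshold
#'   (strictly), or equals 1 (exact duplicates are always removable). The
#'   database default is 0.80; the query-side threshold `T_t` is tunable.
#' @param key_len anchor word length (5).
#' @param min_span minimum removable span length in residues (3 * key_len);
#'   prevents pathological fragmentation.
#' @return A list of class `compression_params`.
#' @export
compression_params <- function(similarity_threshold = 0.8, key_len = 5L,
                               min_span = 15L) {
  stopifnot(similarity_threshold > 0, similarity_threshold <= 1,
            key_len >= 1, min_span >= key_len)
  structure(list(similarity_threshold = similarity_threshold,
                 key_len = as.integer(key_len),
                 min_span = as.integer(min_span)),
            class = "compression_params")
}

.sim_pass <- function(sim, threshold) {
  sim > threshold + 1e-12 | sim >= 1 - 1e-12
}

.window_keys <- function(s, key_len) {
  L <- nchar(s)
  if (L < key_len) return(character(0))
  substring(s, 1:(L - key_len + 1), key_len:L)
}

#' Build a key-entry pair map
#'
#' Indexes every overlapping `key_len`-residue window of every sequence
#' (sliding step 1). Each key maps to the chain of its occurrences
#' `(seq_index, start_pos)` in discovery order. Windows containing the
#' unknown residue X are not indexed, and sequences shorter than `key_len`
#' contribute no entries.
#'
#' @param sequences a [protein_set].
#' @param key_len word length (default 5).
#' @return An object of class `key_entry_map` with the occurrence table
#'   (`$entries`) and a hashed index (`$index`).
#' @export
build_key_entry_map <- function(sequences, key_len = 5L) {
  sequences <- as_protein_set(sequences)
  key_len <- as.integer(key_len)
  stopifnot(key_len >= 1)
  keys <- character(0); seq_index <- integer(0); pos <- integer(0)
  for (i in seq_len(nrow(sequences))) {
    w <- .window_keys(sequences$seq[i], key_len)
    if (!length(w)) next
    ok <- !grepl("X", w, fixed = TRUE)
    keys <- c(keys, w[ok])
    seq_index <- c(seq_index, rep.int(i, sum(ok)))
    pos <- c(pos, which(ok))
  }
  entries <- data.frame(key = keys, seq_index = seq_index, pos = pos,
                        stringsAsFactors = FALSE)
  index <- new.env(hash = TRUE, parent = emptyenv())
  if (nrow(entries)) {
    sp <- split(seq_len(nrow(entries)), entries$key)
    for (k in names(sp))
      assign(k, cbind(seq_index[sp[[k]]], pos[sp[[k]]]), envir = index)
  }
  structure(list(key_len = key_len, entries = entries, index = index),
            class = "key_entry_map")
}

#' @export
print.key_entry_map <- function(x, ...) {
  cat(sprintf("key_entry_map: %d occurrence(s) of %d distinct %d-mer key(s)\n",
              nrow(x$entries), length(unique(x$entries$key)), x$key_len))
  invisible(x)
}

# ---- difference scripts -----------------------------------------------------

# Edit operations from an aligned span pair. Offsets are counted in
# representative coordinates: each op's offset is the distance from the
# previous op's position (or from the span start for the first op).
.ops_from_alignment <- function(rep_chars, rem_chars) {
  kind <- character(0); offset <- integer(0); residue <- character(0)
  rep_pos <- 0L; last <- 0L
  for (k in seq_along(rep_chars)) {
    a <- rep_chars[k]; b <- rem_chars[k]
    if (a != "-" && b != "-") {
      rep_pos <- rep_pos + 1L
      if (a != b) {
        kind <- c(kind, "r"); offset <- c(offset, rep_pos - last)
        residue <- c(residue, b); last <- rep_pos
      }
    } else if (b == "-") {           # gap in removed: delete a rep residue
      rep_pos <- rep_pos + 1L
      kind <- c(kind, "d"); offset <- c(offset, rep_pos - last)
      residue <- c(residue, ""); last <- rep_pos
    } else {                          # gap in rep: insert a removed residue
      target <- rep_pos + 1L
      kind <- c(kind, "i"); offset <- c(offset, target - last)
      residue <- c(residue, b); last <- target - 1L
    }
  }
  data.frame(kind = kind, offset = offset, residue = residue,
             stringsAsFactors = FALSE)
}

#' Encode a difference script between two similar spans
#'
#' Globally aligns the representative span against the removed span and
#' derives the edit operations: mismatch columns become `r` (replace), gaps
#' in the representative become `i` (insert), gaps in the removed span
#' become `d` (delete). Offsets count residues in the representative span,
#' each relative to the previous operation (the first relative to the span
#' start). Encoding refuses span pairs whose similarity does not clear the
#' threshold; [decode_diff_script()] inverts the encoding exactly.
#'
#' @param rep_span representative (retained) span.
#' @param removed_span redundant (removed) span.
#' @param similarity_threshold admission threshold (default 0.8).
#' @return A list with `ops` (data frame `kind`/`offset`/`residue`) and the
#'   alignment `similarity`.
#' @export
encode_diff_script <- function(rep_span, removed_span,
                               similarity_threshold = 0.8) {
  al <- needleman_wunsch(rep_span, removed_span)
  if (!.sim_pass(al$identity_fraction, similarity_threshold))
    stop(sprintf(paste0("spans are below the similarity threshold ",
                        "(%.3f <= %.2f); refusing to encode"),
                 al$identity_fraction, similarity_threshold), call. = FALSE)
  ca <- strsplit(al$aligned_query, "", fixed = TRUE)[[1]]
  cb <- strsplit(al$aligned_subject, "", fixed = TRUE)[[1]]
  list(ops = .ops_from_alignment(ca, cb), similarity = al$identity_fraction)
}

#' Decode a difference script
#'
#' Replays the edit operations against the representative span and returns
#' the removed span exactly.
#'
#' @param rep_span representative span the script was encoded against.
#' @param ops an ops data frame as produced by [encode_diff_script()], or an
#'   op string such as `"r6L,r8A,r3V,i5D"` (see [parse_ops()]).
#' @return The reconstructed removed span.
#' @export
decode_diff_script <- function(rep_span, ops) {
  if (is.character(ops)) ops <- parse_ops(ops)
  n <- nchar(rep_span)
  out <- character(0)
  rp <- 1L; last <- 0L
  for (k in seq_len(nrow(ops))) {
    target <- last + ops$offset[k]
    kind <- ops$kind[k]
    limit <- if (kind == "i") n + 1L else n
    if (target > limit)
      stop("corrupt difference script: offset past span end", call. = FALSE)
    if (target - 1L >= rp) out <- c(out, substr(rep_span, rp, target - 1L))
    if (kind == "r") {
      out <- c(out, ops$residue[k]); rp <- target + 1L; last <- target
    } else if (kind == "d") {
      rp <- target + 1L; last <- target
    } else {
      out <- c(out, ops$residue[k]); rp <- target; last <- target - 1L
    }
  }
  if (rp <= n) out <- c(out, substr(rep_span, rp, n))
  paste(out, collapse = "")
}

#' Parse and format difference-script op strings
#'
#' The textual form is a comma-separated list like `"r6L,r8A,r3V,i5D"`:
#' a lower-case op letter (`r`eplace / `i`nsert / `d`elete), a positive
#' offset, and for `r` and `i` the residue in the removed span. The empty
#' op list is written `"."`.
#'
#' @param text a single op string.
#' @return `parse_ops()`: a data frame with columns `kind`, `offset`,
#'   `residue`; `format_ops()`: the op string.
#' @export
parse_ops <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  text <- trimws(text)
  empty <- data.frame(kind = character(0), offset = integer(0),
                      residue = character(0), stringsAsFactors = FALSE)
  if (text == "." || text == "") return(empty)
  parts <- trimws(strsplit(text, ",", fixed = TRUE)[[1]])
  m <- regmatches(parts, regexec("^([rid])([0-9]+)([A-Z]?)$", parts))
  bad <- which(vapply(m, length, integer(1)) == 0)
  if (length(bad))
    stop("malformed difference-script op: '", parts[bad[1]], "'",
         call. = FALSE)
  kind <- vapply(m, `[`, "", 2)
  offset <- as.integer(vapply(m, `[`, "", 3))
  residue <- vapply(m, `[`, "", 4)
  if (any(offset < 1))
    stop("difference-script offsets must be >= 1", call. = FALSE)
  if (any((kind %in% c("r", "i")) != nzchar(residue)))
    stop("residue must be present exactly for r and i ops", call. = FALSE)
  data.frame(kind = kind, offset = offset, residue = residue,
             stringsAsFactors = FALSE)
}

#' @rdname parse_ops
#' @param ops an ops data frame.
#' @export
format_ops <- function(ops) {
  if (!nrow(ops)) return(".")
  paste0(ops$kind, ops$offset, ops$residue, collapse = ",")
}

# ---- span trimming ----------------------------------------------------------

# Given the global alignment of (representative suffix, new suffix), find
# the longest alignment-prefix ending on a consumed new-sequence residue
# that (a) spans at least min_span new residues, (b) clears the similarity
# threshold, and (c) keeps r+i ops within 20% of the span length.
.trim_redundant <- function(aligned_rep, aligned_new, threshold, min_span) {
  ca <- strsplit(aligned_rep, "", fixed = TRUE)[[1]]
  cb <- strsplit(aligned_new, "", fixed = TRUE)[[1]]
  consume_rep <- ca != "-"
  consume_new <- cb != "-"
  ident <- cumsum(consume_rep & consume_new & ca == cb)
  n_new <- cumsum(consume_new)
  n_rep <- cumsum(consume_rep)
  n_ri <- cumsum((consume_rep & consume_new & ca != cb) | !consume_rep)
  cols <- seq_along(ca)
  ok <- consume_new & n_new >= min_span & n_rep >= 1 &
    .sim_pass(ident / cols, threshold) &
    n_ri <= 0.2 * n_new + 1e-9
  if (!any(ok)) return(NULL)
  j <- max(which(ok))
  list(rep_len = n_rep[j], new_len = n_new[j],
       ops = .ops_from_alignment(ca[seq_len(j)], cb[seq_len(j)]))
}

# ---- collection compression -------------------------------------------------

#' Compress a protein collection by redundancy removal
#'
#' Sequences are processed in input order; earlier sequences become
#' representatives. For each sequence, 5-mer windows are looked up in the
#' key-entry map over the already-retained pool. On a key match, the
#' downstream suffixes are globally aligned; when the aligned span clears
#' the similarity threshold (and is at least `min_span` residues), the span
#' is removed from the current sequence and a difference script referencing
#' the representative segment is recorded. The retained pieces of each
#' sequence are concatenated into a single pool segment (carrying the
#' sequence's own id), and its windows join the map for later sequences.
#' The pool plus the scripts reconstructs every input exactly
#' ([decompress()]).
#'
#' @param sequences a [protein_set].
#' @param params a [compression_params()].
#' @return An object of class `compressed_db` with fields `segments`
#'   (the non-redundant pool as a [protein_set]), `scripts`, `provenance`
#'   (per-original assembly plan), `ids` and `params`.
#' @export
compress_collection <- function(sequences, params = compression_params()) {
  sequences <- as_protein_set(sequences)
  stopifnot(inherits(params, "compression_params"))
  key_len <- params$key_len
  min_span <- params$min_span
  threshold <- params$similarity_threshold
  S <- blosum62()

  pool_seq <- character(0); pool_id <- character(0); pool_desc <- character(0)
  map <- new.env(hash = TRUE, parent = emptyenv())
  scripts <- list()
  provenance <- setNames(vector("list", nrow(sequences)), sequences$id)

  add_windows <- function(seg_index, s) {
    w <- .window_keys(s, key_len)
    if (!length(w)) return(invisible())
    ok <- which(!grepl("X", w, fixed = TRUE))
    for (p in ok) {
      key <- w[p]
      cur <- map[[key]]
      map[[key]] <- if (is.null(cur)) matrix(c(seg_index, p), nrow = 1)
                    else rbind(cur, c(seg_index, p))
    }
    invisible()
  }

  for (i in seq_len(nrow(sequences))) {
    s <- sequences$seq[i]
    id <- sequences$id[i]
    L <- nchar(s)
    items <- list()
    kept <- list()
    kept_start <- 1L
    p <- 1L
    kmax <- L - key_len + 1L
    while (p <= kmax) {
      key <- substr(s, p, p + key_len - 1L)
      matched <- FALSE
      if (!grepl("X", key, fixed = TRUE) && L - p + 1L >= min_span) {
        entries <- map[[key]]
        if (!is.null(entries)) {
          new_suffix <- substr(s, p, L)
          for (e in seq_len(nrow(entries))) {
            seg <- entries[e, 1]; pos <- entries[e, 2]
            rep_seq <- pool_seq[seg]
            if (nchar(rep_seq) - pos + 1L < min_span) next
            rep_suffix <- substr(rep_seq, pos, nchar(rep_seq))
            al <- .nw_align_cpp(rep_suffix, new_suffix, S, 11L,
                                prefer_up = TRUE)
            trim <- .trim_redundant(al$aligned_a, al$aligned_b,
                                    threshold, min_span)
            if (is.null(trim)) next
            if (kept_start <= p - 1L) {
              kept[[length(kept) + 1L]] <- c(kept_start, p - 1L)
              items[[length(items) + 1L]] <-
                list(type = "literal", piece = length(kept))
            }
            scripts[[length(scripts) + 1L]] <-
              list(owner_id = id, rep_seg = seg, start = pos,
                   end = pos + trim$rep_len - 1L, ops = trim$ops)
            items[[length(items) + 1L]] <-
              list(type = "script", index = length(scripts))
            p <- p + trim$new_len
            kept_start <- p
            matched <- TRUE
            break
          }
        }
      }
      if (!matched) p <- p + 1L
    }
    if (kept_start <= L) {
      kept[[length(kept) + 1L]] <- c(kept_start, L)
      items[[length(items) + 1L]] <- list(type = "literal", piece = length(kept))
    }
    if (length(kept)) {
      seg_seq <- paste(vapply(kept, function(k) substr(s, k[1], k[2]), ""),
                       collapse = "")
      pool_seq <- c(pool_seq, seg_seq)
      pool_id <- c(pool_id, id)
      pool_desc <- c(pool_desc, sequences$desc[i])
      seg_index <- length(pool_seq)
      cum <- 0L
      for (k in seq_along(items)) {
        if (items[[k]]$type == "literal") {
          piece <- kept[[items[[k]]$piece]]
          len <- piece[2] - piece[1] + 1L
          items[[k]] <- list(type = "literal", seg = seg_index,
                             start = cum + 1L, end = cum + len)
          cum <- cum + len
        }
      }
      add_windows(seg_index, seg_seq)
    }
    provenance[[id]] <- items
  }

  structure(list(segments = protein_set(pool_id, pool_seq, pool_desc),
                 scripts = scripts,
                 provenance = provenance,
                 ids = sequences$id,
                 desc = setNames(sequences$desc, sequences$id),
                 params = params),
            class = "compressed_db")
}

#' @export
print.compressed_db <- function(x, ...) {
  cat(sprintf(paste0("compressed_db: %d original sequence(s) -> %d pool ",
                     "segment(s), %d script(s)\n  residues %d -> %d ",
                     "(threshold %.2f)\n"),
              length(x$ids), nrow(x$segments), length(x$scripts),
              sum(nchar(decompress(x)$seq)), sum(nchar(x$segments$seq)),
              x$params$similarity_threshold))
  invisible(x)
}

#' Total residues retained in the compressed pool
#' @param db a `compressed_db`.
#' @return Integer residue count.
#' @export
pool_residues <- function(db) {
  stopifnot(inherits(db, "compressed_db"))
  sum(nchar(db$segments$seq))
}

.assemble_one <- function(db, id) {
  items <- db$provenance[[id]]
  if (is.null(items))
    stop("unknown sequence id in provenance: ", id, call. = FALSE)
  parts <- vapply(items, function(it) {
    if (it$type == "literal") {
      substr(db$segments$seq[it$seg], it$start, it$end)
    } else {
      sc <- db$scripts[[it$index]]
      if (is.null(sc) || sc$rep_seg > nrow(db$segments))
        stop("dangling script reference for ", id, call. = FALSE)
      rep_span <- substr(db$segments$seq[sc$rep_seg], sc$start, sc$end)
      decode_diff_script(rep_span, sc$ops)
    }
  }, "")
  paste(parts, collapse = "")
}

#' Reconstruct the original collection from a compressed database
#'
#' The defining round trip: `decompress(compress_collection(x, p))`
#' reproduces `x` exactly (ids, order and residues).
#'
#' @param db a `compressed_db`.
#' @param ids optionally, a subset of original ids to reconstruct (in the
#'   stored original order).
#' @return A [protein_set].
#' @export
decompress <- function(db, ids = NULL) {
  stopifnot(inherits(db, "compressed_db"))
  take <- if (is.null(ids)) db$ids else db$ids[db$ids %in% ids]
  seqs <- vapply(take, function(id) .assemble_one(db, id), "")
  protein_set(take, unname(seqs), unname(db$desc[take]))
}

# ---- on-disk form -----------------------------------------------------------

.slot_labels <- function(n) {
  if (n == 1) return("whole")
  c("prefix", rep("middle", max(0L, n - 2L)), "suffix")
}

#' Write / read a compressed database
#'
#' The pool is written as FASTA (`pool.fasta`); scripts and provenance go to
#' a tab-separated sidecar (`scripts.tsv`), one record per provenance item:
#' `owner_id TAB slot TAB rep_id,start,end TAB op[,op...]`. A literal item
#' (a retained piece of the owner's own pool segment) is marked by a leading
#' `=` in the reference field and has op field `.`; `#D` lines carry record
#' descriptions and a `#params` line the compression parameters.
#'
#' @param db a `compressed_db`.
#' @param dir artifact directory.
#' @return `write_compressed_db()` the directory, invisibly;
#'   `read_compressed_db()` the reconstructed `compressed_db`.
#' @export
write_compressed_db <- function(db, dir) {
  stopifnot(inherits(db, "compressed_db"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(db$segments, file.path(dir, "pool.fasta"))
  con <- file(file.path(dir, "scripts.tsv"), "w")
  on.exit(close(con))
  writeLines(sprintf("#params\tsimilarity_threshold=%s;key_len=%d;min_span=%d",
                     format(db$params$similarity_threshold),
                     db$params$key_len, db$params$min_span), con)
  for (id in db$ids)
    writeLines(sprintf("#D\t%s\t%s", id, db$desc[[id]]), con)
  for (id in db$ids) {
    items <- db$provenance[[id]]
    slots <- .slot_labels(length(items))
    for (k in seq_along(items)) {
      it <- items[[k]]
      if (it$type == "literal") {
        line <- sprintf("%s\t%s\t=%s,%d,%d\t.", id, slots[k],
                        db$segments$id[it$seg], it$start, it$end)
      } else {
        sc <- db$scripts[[it$index]]
        line <- sprintf("%s\t%s\t%s,%d,%d\t%s", id, slots[k],
                        db$segments$id[sc$rep_seg], sc$start, sc$end,
                        format_ops(sc$ops))
      }
      writeLines(line, con)
    }
  }
  invisible(dir)
}

#' @rdname write_compressed_db
#' @export
read_compressed_db <- function(dir) {
  pool_path <- file.path(dir, "pool.fasta")
  side_path <- file.path(dir, "scripts.tsv")
  for (p in c(pool_path, side_path))
    if (!file.exists(p))
      stop("missing compressed-database artifact: ", p, call. = FALSE)
  segments <- read_fasta(pool_path)
  seg_of <- setNames(seq_len(nrow(segments)), segments$id)
  lines <- readLines(side_path)

  pline <- grep("^#params\t", lines, value = TRUE)
  if (!length(pline)) stop("sidecar lacks a #params line", call. = FALSE)
  kv <- strsplit(strsplit(sub("^#params\t", "", pline[1]), ";")[[1]], "=")
  pv <- setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  params <- compression_params(as.numeric(pv[["similarity_threshold"]]),
                               as.integer(pv[["key_len"]]),
                               as.integer(pv[["min_span"]]))

  dlines <- strsplit(grep("^#D\t", lines, value = TRUE), "\t", fixed = TRUE)
  ids <- vapply(dlines, `[`, "", 2)
  desc <- setNames(vapply(dlines, function(x) {
    if (length(x) >= 3) x[3] else ""
  }, ""), ids)

  scripts <- list()
  provenance <- setNames(vector("list", length(ids)), ids)
  for (ln in lines[!startsWith(lines, "#")]) {
    if (!nzchar(trimws(ln))) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) != 4)
      stop("malformed sidecar record: ", ln, call. = FALSE)
    owner <- f[1]
    ref <- f[3]
    literal <- startsWith(ref, "=")
    if (literal) ref <- substring(ref, 2)
    rparts <- strsplit(ref, ",", fixed = TRUE)[[1]]
    if (length(rparts) != 3)
      stop("malformed reference field: ", f[3], call. = FALSE)
    seg <- seg_of[[rparts[1]]]
    if (is.null(seg))
      stop("sidecar references unknown segment '", rparts[1], "'",
           call. = FALSE)
    start <- as.integer(rparts[2]); end <- as.integer(rparts[3])
    if (literal) {
      item <- list(type = "literal", seg = seg, start = start, end = end)
    } else {
      scripts[[length(scripts) + 1L]] <-
        list(owner_id = owner, rep_seg = seg, start = start, end = end,
             ops = parse_ops(f[4]))
      item <- list(type = "script", index = length(scripts))
    }
    provenance[[owner]] <- c(provenance[[owner]], list(item))
  }
  structure(list(segments = segments, scripts = scripts,
                 provenance = provenance, ids = ids, desc = desc,
                 params = params),
            class = "compressed_db")
}
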