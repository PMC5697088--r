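# Clustered-database construction: score-thresholded variable-length keys
# in the reduced alphabet, ten-residue seeds extended leftward from each
# key, and greedy Hamming-distance clustering around representative seeds.
# The result is the three-map structure used by the online search:
#   Map1  key -> occurrence entries
#   Map2  representative seed -> (cluster id, representative location)
#   Map3  cluster id -> member locations

#' Key finder parameters
#'
#' @param min_key_len,max_key_len key length range (6-9 residues).
#' @param score_threshold admission threshold `T` for the grouped-maximum
#'   BLOSUM62 score sum (default 39, chosen empirically): a window is a key
#'   only when its [key_score()] exceeds `T`.
#' @return A list of class `key_finder_params`.
#' @export
key_finder_params <- function(min_key_len = 6L, max_key_len = 9L,
                              score_threshold = 39L) {
  stopifnot(min_key_len >= 1, min_key_len <= max_key_len,
            score_threshold > 0)
  structure(list(min_key_len = as.integer(min_key_len),
                 max_key_len = as.integer(max_key_len),
                 score_threshold = as.integer(score_threshold)),
            class = "key_finder_params")
}

#' Grouped-maximum BLOSUM62 score of a subsequence
#'
#' Each residue contributes the maximum BLOSUM62 diagonal score among the
#' members of its reduced-alphabet group; the key score is the sum over the
#' subsequence. For example `YKWVN` scores 11+5+11+5+6 = 38 (below the
#' default threshold 39) while `YKWVNK` scores 43 (above it).
#'
#' @param subseq a non-empty string over the 20 standard residues.
#' @return Integer score.
#' @export
key_score <- function(subseq) {
  if (!is.character(subseq) || length(subseq) != 1 || !nzchar(subseq))
    stop("key_score needs one non-empty string", call. = FALSE)
  chars <- strsplit(subseq, "", fixed = TRUE)[[1]]
  if (any(!chars %in% AMINO_ACIDS))
    stop("non-standard residue in key: '",
         chars[!chars %in% AMINO_ACIDS][1], "'", call. = FALSE)
  alpha <- reduced_alphabet()
  sum(alpha$group_max_diag[alpha$symbol[chars]])
}

.residue_scores <- function() {
  alpha <- reduced_alphabet()
  setNames(as.integer(alpha$group_max_diag[alpha$symbol]),
           names(alpha$symbol))
}

#' Find score-thresholded keys in a compressed pool (Map1)
#'
#' Scans each segment left to right. At each position the shortest window
#' of length `min_key_len..max_key_len` whose [key_score()] exceeds the
#' threshold is registered as a key (stored in reduced-alphabet form with
#' original coordinates); the scan then steps past the registered key so
#' keys do not start inside one another. Positions where even the longest
#' window fails, or whose windows contain X, register nothing.
#'
#' @param segments a [protein_set] (typically the compressed pool).
#' @param params a [key_finder_params()].
#' @return An object of class `key_map` with the occurrence table
#'   (`$entries`: columns `key`, `seg`, `pos`, `len`) and a hashed index.
#' @export
find_keys <- function(segments, params = key_finder_params()) {
  segments <- as_protein_set(segments)
  stopifnot(inherits(params, "key_finder_params"))
  score_of <- .residue_scores()
  lens <- params$min_key_len:params$max_key_len
  keys <- character(0); seg_i <- integer(0); pos_i <- integer(0)
  len_i <- integer(0)
  for (i in seq_len(nrow(segments))) {
    s <- segments$seq[i]
    L <- nchar(s)
    if (L < params$min_key_len) next
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    v <- score_of[chars]
    isx <- chars == "X"
    cs <- cumsum(c(0L, ifelse(isx, 0L, v)))
    cx <- cumsum(c(0L, isx))
    rseq <- reduce_sequence(s)
    p <- 1L
    while (p <= L - params$min_key_len + 1L) {
      hit <- 0L
      for (l in lens) {
        q <- p + l - 1L
        if (q > L) break
        if (cx[q + 1L] - cx[p] > 0L) break      # window contains X
        if (cs[q + 1L] - cs[p] > params$score_threshold) { hit <- l; break }
      }
      if (hit > 0L) {
        keys <- c(keys, substr(rseq, p, p + hit - 1L))
        seg_i <- c(seg_i, i); pos_i <- c(pos_i, p); len_i <- c(len_i, hit)
        p <- p + hit
      } else {
        p <- p + 1L
      }
    }
  }
  entries <- data.frame(key = keys, seg = seg_i, pos = pos_i, len = len_i,
                        stringsAsFactors = FALSE)
  index <- new.env(hash = TRUE, parent = emptyenv())
  if (nrow(entries)) {
    sp <- split(seq_len(nrow(entries)), entries$key)
    for (k in names(sp)) assign(k, sp[[k]], envir = index)
  }
  structure(list(entries = entries, index = index, params = params),
            class = "key_map")
}

#' @export
print.key_map <- function(x, ...) {
  cat(sprintf("key_map: %d key occurrence(s), %d distinct key(s), T = %d\n",
              nrow(x$entries), length(unique(x$entries$key)),
              x$params$score_threshold))
  invisible(x)
}

#' Generate ten-residue seeds from key occurrences
#'
#' For a key occurring at position p, the seed covers residues
#' `[p - 5, p + 4]` in the reduced alphabet: five residues extended forward
#' (leftward) from the key start plus the first five residues of the key.
#' Occurrences with `p <= 5` have insufficient left context and produce no
#' seed.
#'
#' @param map1 a `key_map` from [find_keys()].
#' @param segments the [protein_set] the keys were found in.
#' @return A data frame of seeds: `key`, `residues` (reduced 10-mer), `seg`,
#'   `pos` (1-based seed start).
#' @export
generate_seeds <- function(map1, segments) {
  stopifnot(inherits(map1, "key_map"))
  segments <- as_protein_set(segments)
  e <- map1$entries
  keep <- e$pos >= 6L
  e <- e[keep, , drop = FALSE]
  rmap <- reduce_sequence(segments$seq)
  res <- substr(rmap[e$seg], e$pos - 5L, e$pos + 4L)
  out <- data.frame(key = e$key, residues = res, seg = e$seg,
                    pos = e$pos - 5L, stringsAsFactors = FALSE)
  out[!grepl("X", out$residues, fixed = TRUE), , drop = FALSE]
}

#' Cluster seeds by Hamming distance around representatives (Map2/Map3)
#'
#' Greedy single-pass clustering in discovery order, restricted to seeds
#' produced from the same key: a seed joins the first existing cluster of
#' its key whose representative is within the cluster radius
#' (`floor(seed_len * (1 - T_c))`, i.e. 1 mismatch at the default 90%
#' threshold on 10-residue seeds), otherwise it founds a new cluster with
#' itself as representative. Every member is therefore within Hamming
#' distance 1 of its representative.
#'
#' @param seeds a seed data frame from [generate_seeds()].
#' @param T_c cluster similarity threshold (default 0.90).
#' @return A list of class `seed_clustering`: `clusters` (a data frame with
#'   the representative of each cluster), `members` (Map3: data frame
#'   `cluster`, `seg`, `pos`, `residues`, `is_rep`) and `map2` (hashed index
#'   representative residues -> cluster ids).
#' @export
cluster_seeds <- function(seeds, T_c = 0.9) {
  stopifnot(is.data.frame(seeds), T_c > 0, T_c <= 1)
  seed_len <- if (nrow(seeds)) nchar(seeds$residues[1]) else 10L
  if (nrow(seeds) && !all(nchar(seeds$residues) == seed_len))
    stop("all seeds must have the same length", call. = FALSE)
  max_d <- floor(seed_len * (1 - T_c) + 1e-9)

  by_key <- new.env(hash = TRUE, parent = emptyenv())
  rep_chars <- list()
  rep_res <- character(0); rep_key <- character(0)
  rep_seg <- integer(0); rep_pos <- integer(0)
  assign_cluster <- integer(nrow(seeds))
  for (k in seq_len(nrow(seeds))) {
    key <- seeds$key[k]
    sc <- strsplit(seeds$residues[k], "", fixed = TRUE)[[1]]
    cids <- by_key[[key]]
    placed <- 0L
    for (cid in cids) {
      if (sum(sc != rep_chars[[cid]]) <= max_d) { placed <- cid; break }
    }
    if (!placed) {
      placed <- length(rep_res) + 1L
      rep_chars[[placed]] <- sc
      rep_res <- c(rep_res, seeds$residues[k])
      rep_key <- c(rep_key, key)
      rep_seg <- c(rep_seg, seeds$seg[k])
      rep_pos <- c(rep_pos, seeds$pos[k])
      by_key[[key]] <- c(cids, placed)
    }
    assign_cluster[k] <- placed
  }

  clusters <- data.frame(cluster = seq_along(rep_res), key = rep_key,
                         residues = rep_res, seg = rep_seg, pos = rep_pos,
                         stringsAsFactors = FALSE)
  members <- data.frame(cluster = assign_cluster,
                        seg = seeds$seg, pos = seeds$pos,
                        residues = seeds$residues,
                        is_rep = assign_cluster %in% integer(0),
                        stringsAsFactors = FALSE)
  if (nrow(members)) {
    first_of <- match(seq_along(rep_res), assign_cluster)
    members$is_rep <- seq_len(nrow(members)) %in% first_of
    members <- members[order(members$cluster, -members$is_rep,
                             members$seg, members$pos), , drop = FALSE]
    row.names(members) <- NULL
  }
  map2 <- new.env(hash = TRUE, parent = emptyenv())
  for (cid in seq_along(rep_res))
    assign(rep_res[cid], c(map2[[rep_res[cid]]], cid), envir = map2)
  structure(list(clusters = clusters, members = members, map2 = map2,
                 T_c = T_c, seed_len = seed_len),
            class = "seed_clustering")
}

#' Build the clustered database from a compressed database
#'
#' Composition of [find_keys()], [generate_seeds()] and [cluster_seeds()]
#' over the compressed pool.
#'
#' @param db a `compressed_db`.
#' @param params a [key_finder_params()].
#' @param T_c cluster similarity threshold (default 0.90).
#' @return An object of class `clustered_db` holding Map1 (`$map1`), the
#'   seeds, and the clustering (Map2/Map3).
#' @export
build_clustered_db <- function(db, params = key_finder_params(), T_c = 0.9) {
  stopifnot(inherits(db, "compressed_db"))
  map1 <- find_keys(db$segments, params)
  seeds <- generate_seeds(map1, db$segments)
  clustering <- cluster_seeds(seeds, T_c = T_c)
  structure(list(map1 = map1, seeds = seeds, clustering = clustering,
                 params = params, T_c = T_c,
                 n_segments = nrow(db$segments)),
            class = "clustered_db")
}

#' @export
print.clustered_db <- function(x, ...) {
  cat(sprintf(paste0("clustered_db: %d segment(s), %d key occurrence(s), ",
                     "%d seed(s), %d cluster(s)\n"),
              x$n_segments, nrow(x$map1$entries), nrow(x$seeds),
              nrow(x$clustering$clusters)))
  invisible(x)
}

#' Persist / restore a clustered database
#'
#' The three maps are written as inspectable TSV files (`map1.tsv`,
#' `map2.tsv`, `map3.tsv`) plus a YAML parameter manifest; the round trip
#' `load_clustered_db(save_clustered_db(x, dir))` is exact.
#'
#' @param cdb a `clustered_db`.
#' @param dir artifact directory.
#' @param extra named list merged into the manifest (used by the command
#'   line interface to record search-stage thresholds and input checksums).
#' @return `save_clustered_db()` the directory, invisibly;
#'   `load_clustered_db()` the restored `clustered_db`.
#' @export
save_clustered_db <- function(cdb, dir, extra = list()) {
  stopifnot(inherits(cdb, "clustered_db"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(cdb$map1$entries, file.path(dir, "map1.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(cdb$clustering$clusters, file.path(dir, "map2.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(cdb$clustering$members, file.path(dir, "map3.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- c(list(
    key_score_threshold = cdb$params$score_threshold,
    min_key_len = cdb$params$min_key_len,
    max_key_len = cdb$params$max_key_len,
    cluster_threshold = cdb$T_c,
    seed_len = cdb$clustering$seed_len,
    n_segments = cdb$n_segments,
    alphabet = "blosum62-10group"
  ), extra)
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' @rdname save_clustered_db
#' @export
load_clustered_db <- function(dir) {
  paths <- file.path(dir, c("map1.tsv", "map2.tsv", "map3.tsv",
                            "manifest.yaml"))
  for (p in paths)
    if (!file.exists(p))
      stop("missing clustered-database artifact: ", p, call. = FALSE)
  man <- yaml::read_yaml(paths[4])
  params <- key_finder_params(man$min_key_len, man$max_key_len,
                              man$key_score_threshold)
  entries <- read.table(paths[1], sep = "\t", header = TRUE,
                        colClasses = c("character", "integer", "integer",
                                       "integer"))
  index <- new.env(hash = TRUE, parent = emptyenv())
  if (nrow(entries)) {
    sp <- split(seq_len(nrow(entries)), entries$key)
    for (k in names(sp)) assign(k, sp[[k]], envir = index)
  }
  map1 <- structure(list(entries = entries, index = index, params = params),
                    class = "key_map")
  clusters <- read.table(paths[2], sep = "\t", header = TRUE,
                         colClasses = c("integer", "character", "character",
                                        "integer", "integer"))
  members <- read.table(paths[3], sep = "\t", header = TRUE,
                        colClasses = c("integer", "integer", "integer",
                                       "character", "logical"))
  map2 <- new.env(hash = TRUE, parent = emptyenv())
  for (k in seq_len(nrow(clusters)))
    assign(clusters$residues[k],
           c(map2[[clusters$residues[k]]], clusters$cluster[k]),
           envir = map2)
  # seeds (in discovery order) are the members sorted back by segment/pos
  seeds <- members[order(members$seg, members$pos), c("seg", "pos",
                                                      "residues")]
  seeds$key <- clusters$key[match(
    members$cluster[order(members$seg, members$pos)], clusters$cluster)]
  seeds <- seeds[, c("key", "residues", "seg", "pos")]
  row.names(seeds) <- NULL
  clustering <- structure(list(clusters = clusters, members = members,
                               map2 = map2, T_c = man$cluster_threshold,
                               seed_len = man$seed_len),
                          class = "seed_clustering")
  structure(list(map1 = map1, seeds = seeds, clustering = clustering,
                 params = params, T_c = man$cluster_threshold,
                 n_segments = man$n_segments, manifest = man),
            class = "clustered_db")
}
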