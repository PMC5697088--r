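# Synthetic protein collections with controlled local redundancy: families
# of sequences sharing a mutated block, plus ground truth, so every
# pipeline stage is testable without external downloads.

.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

.random_residues <- function(n) {
  paste(sample(AMINO_ACIDS, n, replace = TRUE), collapse = "")
}

.mutate_residues <- function(s, substitution_rate, indel_rate) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  out <- character(0)
  for (ch in chars) {
    u <- stats::runif(1)
    if (u < indel_rate / 2) next                       # deletion
    if (substitution_rate > 0 && stats::runif(1) < substitution_rate)
      ch <- sample(setdiff(AMINO_ACIDS, ch), 1)
    out <- c(out, ch)
    if (u >= indel_rate / 2 && u < indel_rate)          # insertion after
      out <- c(out, sample(AMINO_ACIDS, 1))
  }
  paste(out, collapse = "")
}

#' Specification for a synthetic protein-family database
#'
#' Families share a representative block; members carry a mutated copy of
#' the block (point substitutions and indels at the stated per-residue
#' rates) embedded in otherwise-random background residues drawn uniformly
#' from the 20 standard amino acids.
#'
#' @param n_families number of families.
#' @param members_per_family sequences per family (the first member carries
#'   the unmutated block).
#' @param rep_length nominal member length in residues.
#' @param block_length shared-block length (at least 15 residues so blocks
#'   clear the minimum removable span).
#' @param substitution_rate,indel_rate per-residue mutation rates applied to
#'   the block copies; keep both at or below 0.2 for fixtures that must
#'   clear the 80% redundancy threshold.
#' @param placement where the block sits in each member: `"prefix"`,
#'   `"middle"`, `"suffix"` or `"whole"`.
#' @param rng_seed integer seed; generation is deterministic given the spec.
#' @return A list of class `family_spec`.
#' @export
family_spec <- function(n_families = 10L, members_per_family = 5L,
                        rep_length = 200L, block_length = 60L,
                        substitution_rate = 0.02, indel_rate = 0.005,
                        placement = c("middle", "prefix", "suffix", "whole"),
                        rng_seed = 42L) {
  placement <- match.arg(placement)
  stopifnot(n_families >= 1, members_per_family >= 1, block_length >= 15,
            substitution_rate >= 0, substitution_rate <= 1,
            indel_rate >= 0, indel_rate <= 1)
  if (placement != "whole" && block_length > rep_length)
    stop("block_length must not exceed rep_length", call. = FALSE)
  structure(list(n_families = as.integer(n_families),
                 members_per_family = as.integer(members_per_family),
                 rep_length = as.integer(rep_length),
                 block_length = as.integer(block_length),
                 substitution_rate = substitution_rate,
                 indel_rate = indel_rate,
                 placement = placement,
                 rng_seed = as.integer(rng_seed)),
            class = "family_spec")
}

#' Generate a synthetic protein database with ground truth
#'
#' @param spec a [family_spec()].
#' @return A list with `sequences` (a [protein_set]) and `truth` (a data
#'   frame: `id`, `family`, `is_rep`, `block_start`, `block_end` giving the
#'   planted block coordinates within each member).
#' @export
make_database <- function(spec = family_spec()) {
  stopifnot(inherits(spec, "family_spec"))
  .with_seed(spec$rng_seed, {
    ids <- character(0); seqs <- character(0)
    fam <- integer(0); is_rep <- logical(0)
    bstart <- integer(0); bend <- integer(0)
    for (f in seq_len(spec$n_families)) {
      block <- .random_residues(spec$block_length)
      for (m in seq_len(spec$members_per_family)) {
        b <- if (m == 1) block else
          .mutate_residues(block, spec$substitution_rate, spec$indel_rate)
        flank_total <- max(0L, spec$rep_length - nchar(b))
        if (spec$placement == "whole") flank_total <- 0L
        left_len <- switch(spec$placement,
                           prefix = 0L,
                           suffix = flank_total,
                           middle = flank_total %/% 2L,
                           whole = 0L)
        right_len <- flank_total - left_len
        s <- paste0(if (left_len) .random_residues(left_len) else "",
                    b,
                    if (right_len) .random_residues(right_len) else "")
        ids <- c(ids, sprintf("F%03dM%02d", f, m))
        seqs <- c(seqs, s)
        fam <- c(fam, f)
        is_rep <- c(is_rep, m == 1L)
        bstart <- c(bstart, left_len + 1L)
        bend <- c(bend, left_len + nchar(b))
      }
    }
    list(sequences = protein_set(ids, seqs,
                                 desc = sprintf("family %d", fam)),
         truth = data.frame(id = ids, family = fam, is_rep = is_rep,
                            block_start = bstart, block_end = bend,
                            stringsAsFactors = FALSE))
  })
}

#' Generate queries as (mutated) copies of database sequences
#'
#' Each query is a copy of a distinct database sequence with point
#' substitutions applied at `mutation_rate`; at rate 0 the queries are
#' verbatim copies. The planted homolog of every query is recorded.
#'
#' @param db_sequences the database [protein_set].
#' @param n_queries number of queries (at most the database size; sampling
#'   is without replacement).
#' @param mutation_rate per-residue substitution rate.
#' @param rng_seed integer seed.
#' @return A list with `sequences` (a [protein_set] of queries) and `truth`
#'   (data frame `query_id`, `source_id`).
#' @export
make_queries <- function(db_sequences, n_queries, mutation_rate = 0,
                         rng_seed = 43L) {
  db_sequences <- as_protein_set(db_sequences)
  stopifnot(mutation_rate >= 0, mutation_rate <= 1)
  if (n_queries > nrow(db_sequences))
    stop("n_queries exceeds the database size (sampling is without ",
         "replacement)", call. = FALSE)
  .with_seed(rng_seed, {
    src <- sample(db_sequences$id, n_queries)
    seqs <- vapply(src, function(id) {
      s <- db_sequences$seq[match(id, db_sequences$id)]
      if (mutation_rate > 0) .mutate_residues(s, mutation_rate, 0) else s
    }, "")
    qid <- sprintf("Q%03d", seq_len(n_queries))
    list(sequences = protein_set(qid, unname(seqs),
                                 desc = paste("copy of", src)),
         truth = data.frame(query_id = qid, source_id = src,
                            stringsAsFactors = FALSE, row.names = NULL))
  })
}
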