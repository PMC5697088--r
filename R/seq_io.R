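# FASTA input/output, the substitution matrix, and the reduced
# amino-acid alphabet used for keys and seeds.

#' The 20 standard amino-acid one-letter codes
#' @export
AMINO_ACIDS <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

.residue_regex <- "[^ACDEFGHIKLMNPQRSTVWXY]"

.check_residues <- function(x, what = "sequence") {
  bad <- regexpr(.residue_regex, x)
  hit <- which(bad > 0)
  if (length(hit)) {
    stop(sprintf("invalid residue '%s' at position %d of %s %d",
                 substr(x[hit[1]], bad[hit[1]], bad[hit[1]]), bad[hit[1]],
                 what, hit[1]), call. = FALSE)
  }
  invisible(TRUE)
}

#' Construct a protein sequence collection
#'
#' A `protein_set` is a plain data frame with columns `id`, `desc` and `seq`
#' (upper-case amino-acid strings; `X` is allowed as the unknown residue).
#' Ids must be unique and sequences non-empty.
#'
#' @param id character vector of unique accession tokens.
#' @param seq character vector of amino-acid strings.
#' @param desc optional character vector of free-text descriptions.
#' @return A data frame of class `protein_set`.
#' @export
protein_set <- function(id = character(), seq = character(),
                        desc = rep("", length(id))) {
  id <- as.character(id)
  seq <- toupper(as.character(seq))
  desc <- as.character(desc)
  stopifnot(length(id) == length(seq), length(id) == length(desc))
  if (anyDuplicated(id))
    stop("duplicate sequence id: ", id[duplicated(id)][1], call. = FALSE)
  if (length(seq)) {
    empty <- which(!nzchar(seq))
    if (length(empty))
      stop("empty sequence for id '", id[empty[1]], "'", call. = FALSE)
    .check_residues(seq)
  }
  structure(data.frame(id = id, desc = desc, seq = seq,
                       stringsAsFactors = FALSE, row.names = NULL),
            class = c("protein_set", "data.frame"))
}

#' @export
print.protein_set <- function(x, ...) {
  cat(sprintf("protein_set with %d sequence(s), %d residues total\n",
              nrow(x), sum(nchar(x$seq))))
  if (nrow(x)) {
    shown <- head(x, 6)
    cat(sprintf("  %s  (%d aa)\n", shown$id, nchar(shown$seq)), sep = "")
    if (nrow(x) > 6) cat("  ...\n")
  }
  invisible(x)
}

#' Read a protein FASTA file
#'
#' Wraps [Biostrings::readAAStringSet()] with the validation this pipeline
#' requires: records are upper-cased, the first whitespace-delimited header
#' token becomes the id, ids must be unique and every record must have at
#' least one residue.
#'
#' @param path path to a FASTA file.
#' @return A [protein_set].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  meaningful <- which(nzchar(trimws(lines)))
  if (!length(meaningful)) {
    warning("empty FASTA file: ", path, call. = FALSE)
    return(protein_set())
  }
  first <- meaningful[1]
  if (!startsWith(trimws(lines[first]), ">"))
    stop(sprintf("malformed FASTA: sequence line before any header at line %d of %s",
                 first, path), call. = FALSE)
  x <- withCallingHandlers(
    Biostrings::readAAStringSet(path),
    warning = function(w) {
      # stray whitespace inside sequence lines is silently stripped;
      # genuinely invalid residues are caught by protein_set() below
      if (grepl("invalid one-letter sequence codes", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  headers <- names(x)
  id <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seqs <- toupper(as.character(x))
  width0 <- which(!nzchar(seqs))
  if (length(width0))
    stop("empty sequence for record '", id[width0[1]], "' in ", path,
         call. = FALSE)
  protein_set(id = unname(id), seq = unname(seqs), desc = unname(desc))
}

#' Write a protein FASTA file
#'
#' Sequence lines are wrapped at 60 residues. The round trip
#' `read_fasta(write_fasta(x))` reproduces `x` exactly.
#'
#' @param records a [protein_set].
#' @param path output file path.
#' @export
write_fasta <- function(records, path) {
  records <- as_protein_set(records)
  headers <- ifelse(nzchar(records$desc),
                    paste(records$id, records$desc), records$id)
  aa <- Biostrings::AAStringSet(setNames(records$seq, headers))
  Biostrings::writeXStringSet(aa, filepath = path, width = 60L)
  invisible(path)
}

#' @rdname protein_set
#' @param x object to coerce (a `protein_set` or a data frame with the same
#'   columns).
#' @export
as_protein_set <- function(x) {
  if (inherits(x, "protein_set")) return(x)
  if (is.data.frame(x) && all(c("id", "seq") %in% names(x)))
    return(protein_set(x$id, x$seq, if ("desc" %in% names(x)) x$desc else
      rep("", nrow(x))))
  stop("cannot coerce to protein_set", call. = FALSE)
}

# ---- scoring matrix ---------------------------------------------------------

.pkg_env <- new.env(parent = emptyenv())

#' The BLOSUM62 substitution matrix
#'
#' Parsed from the plain-text matrix bundled with the package (standard NCBI
#' layout, half-bit units). Includes the ambiguity codes B, Z, X and the stop
#' symbol `*`; the 20x20 standard-residue core is symmetric with the
#' published diagonal (for example `score(W, W) == 11`).
#'
#' @return Integer matrix with residue dimnames.
#' @export
blosum62 <- function() {
  if (is.null(.pkg_env$blosum62)) {
    path <- system.file("extdata", "BLOSUM62.txt", package = "seqsieve",
                        mustWork = TRUE)
    m <- as.matrix(read.table(path, comment.char = "#", check.names = FALSE))
    storage.mode(m) <- "integer"
    .pkg_env$blosum62 <- m
  }
  .pkg_env$blosum62
}

# ---- reduced alphabet -------------------------------------------------------

#' The ten-group reduced amino-acid alphabet
#'
#' The 20 standard residues are partitioned into ten groups derived from
#' BLOSUM62 similarity: (A), (K,R), (E,D,N,Q), (C), (G), (H), (I,L,V,M),
#' (F,Y,W), (P), (S,T). Each group is written with its alphabetically first
#' member as symbol, and carries the maximum BLOSUM62 diagonal score among
#' its members (used by [key_score()]). The unknown residue X forms its own
#' singleton group with score -1 and never participates in keys or seeds.
#'
#' @return A list with elements `groups` (named list of member residues),
#'   `symbol` (named map residue -> group symbol) and `group_max_diag`
#'   (named integer per group symbol).
#' @export
reduced_alphabet <- function() {
  if (!is.null(.pkg_env$reduced)) return(.pkg_env$reduced)
  groups <- list(
    A = "A",
    K = c("K", "R"),
    D = c("D", "E", "N", "Q"),
    C = "C",
    G = "G",
    H = "H",
    I = c("I", "L", "M", "V"),
    F = c("F", "W", "Y"),
    P = "P",
    S = c("S", "T")
  )
  S <- blosum62()
  diag20 <- diag(S[AMINO_ACIDS, AMINO_ACIDS])
  group_max_diag <- vapply(groups, function(g) max(diag20[g]), integer(1))
  symbol <- character(0)
  for (s in names(groups)) symbol[groups[[s]]] <- s
  symbol["X"] <- "X"
  group_max_diag <- c(group_max_diag, X = -1L)
  .pkg_env$reduced <- list(groups = groups, symbol = symbol,
                           group_max_diag = group_max_diag)
  .pkg_env$reduced
}

#' Re-express amino-acid strings in the reduced alphabet
#'
#' Each residue is replaced by its group symbol; length is preserved and the
#' mapping is idempotent on already-reduced strings. X maps to itself.
#'
#' @param residues character vector of amino-acid strings.
#' @return Character vector of reduced-alphabet strings of equal lengths.
#' @export
reduce_sequence <- function(residues) {
  if (!length(residues)) return(character(0))
  .check_residues(residues)
  map <- reduced_alphabet()$symbol
  from <- paste(names(map), collapse = "")
  to <- paste(unname(map), collapse = "")
  chartr(from, to, residues)
}
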