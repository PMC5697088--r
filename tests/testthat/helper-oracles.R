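# Independent scoring oracles and fixture builders. The oracles are
# deliberately separate, score-only dynamic programs written against the
# textbook recurrences; they share no code with the package kernels.

oracle_nw_score <- function(a, b, S = blosum62(), gap = 11) {
  A <- strsplit(a, "", fixed = TRUE)[[1]]
  B <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(A); m <- length(B)
  H <- matrix(0L, n + 1, m + 1)
  H[, 1] <- -gap * (0:n)
  H[1, ] <- -gap * (0:m)
  for (i in seq_len(n))
    for (j in seq_len(m))
      H[i + 1, j + 1] <- max(H[i, j] + S[A[i], B[j]],
                             H[i, j + 1] - gap,
                             H[i + 1, j] - gap)
  H[n + 1, m + 1]
}

# Affine-gap local alignment, gap of length k costs open + k * ext.
oracle_sw_score <- function(a, b, S = blosum62(), open = 11, ext = 1) {
  A <- strsplit(a, "", fixed = TRUE)[[1]]
  B <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  M <- matrix(0, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      X[i + 1, j + 1] <- max(M[i, j + 1] - open - ext, X[i, j + 1] - ext)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - open - ext, Y[i + 1, j] - ext)
      M[i + 1, j + 1] <- max(0, S[A[i], B[j]] +
                                  max(M[i, j], X[i, j], Y[i, j]))
      best <- max(best, M[i + 1, j + 1])
    }
  }
  best
}

rnd_protein <- function(n) paste(sample(AMINO_ACIDS, n, TRUE), collapse = "")

# Point-substitute k positions of a string (never to the same residue).
substitute_k <- function(s, k) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  at <- sample(length(ch), k)
  for (i in at) ch[i] <- sample(setdiff(AMINO_ACIDS, ch[i]), 1)
  paste(ch, collapse = "")
}

# A small collection of sequences sharing a mutated block, built directly
# (independent of the synthetic_data module) for compression tests.
shared_block_set <- function(n = 4, flank = 30, block_len = 40, subs = 2) {
  block <- rnd_protein(block_len)
  seqs <- vapply(seq_len(n), function(i) {
    b <- if (i == 1) block else substitute_k(block, subs)
    paste0(rnd_protein(flank), b, rnd_protein(flank))
  }, "")
  protein_set(paste0("s", seq_len(n)), seqs)
}

REDUCED_SYMBOLS <- c("A", "K", "D", "C", "G", "H", "I", "F", "P", "S")

rnd_reduced <- function(n) paste(sample(REDUCED_SYMBOLS, n, TRUE),
                                 collapse = "")

write_tmp_fasta <- function(lines) {
  path <- withr::local_tempfile(fileext = ".fasta",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
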