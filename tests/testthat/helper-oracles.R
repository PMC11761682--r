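# Independent oracles used to cross-check the implementation. These are
# deliberately naive re-derivations (explicit loops, enumeration) and share
# no code with the package internals.

# Brute-force overlap merge: enumerate every candidate overlap, score by
# match count (ties -> smallest overlap), and assemble the merged sequence.
# `rev_rc` is the reverse-complemented reverse mate.
oracle_merge <- function(fwd, rev_rc, min_overlap, max_mm_frac) {
  nf <- nchar(fwd); nr <- nchar(rev_rc)
  f <- strsplit(fwd, "")[[1]]; r <- strsplit(rev_rc, "")[[1]]
  best <- NULL
  for (o in seq_len(min(nf, nr))) {
    if (o < min_overlap) next
    m <- sum(f[(nf - o + 1):nf] == r[1:o])
    if ((o - m) / o > max_mm_frac) next
    if (is.null(best) || m > best$m) best <- list(o = o, m = m)
  }
  if (is.null(best)) return(NULL)
  o <- best$o
  # disagreeing bases resolve to the forward read (equal constant qualities)
  cons <- f[(nf - o + 1):nf]
  tail_part <- if (o < nr) r[(o + 1):nr] else character(0)
  list(seq = paste(c(f[seq_len(nf - o)], cons, tail_part), collapse = ""),
       overlap = o, mismatches = o - best$m)
}

# Union-find single-linkage clustering over equal-length strings with
# Hamming identity strictly greater than `threshold`.
oracle_components <- function(seqs, threshold) {
  n <- length(seqs)
  chars <- strsplit(seqs, "")
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  len <- nchar(seqs[1])
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ident <- 100 * sum(chars[[i]] == chars[[j]]) / len
      if (ident > threshold) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  vapply(seq_len(n), find, integer(1))
}

# Normalize a cluster labelling to a canonical partition signature so two
# labellings can be compared as set partitions.
partition_signature <- function(labels) {
  groups <- split(seq_along(labels), labels)
  sig <- vapply(groups, function(g) paste(g, collapse = ","), character(1))
  sort(unname(sig))
}

# Brute-force unequal-length identity: max matches over all alignments with
# match = 1, mismatch = 0, gap = 0 equals the longest common subsequence;
# enumerated over all subsequences of the shorter string.
oracle_align_identity <- function(a, b) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  if (length(ca) > length(cb)) { tmp <- ca; ca <- cb; cb <- tmp }
  is_subseq <- function(x, y) {
    j <- 1
    for (ch in y) {
      if (j <= length(x) && x[j] == ch) j <- j + 1
    }
    j > length(x)
  }
  best <- 0
  for (mask in 0:(2^length(ca) - 1)) {
    sub <- ca[bitwAnd(mask, 2^(seq_along(ca) - 1)) > 0]
    if (length(sub) > best && is_subseq(sub, cb)) best <- length(sub)
  }
  100 * best / max(nchar(a), nchar(b))
}

# Naive UPGMA returning the cophenetic matrix (merge heights); average
# distances are recomputed from the original matrix at every step.
oracle_upgma_cophenetic <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  while (length(clusters) > 1) {
    best <- NULL
    for (i in seq_len(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        avg <- mean(d[clusters[[i]], clusters[[j]]])
        if (is.null(best) || avg < best$avg) best <- list(i = i, j = j, avg = avg)
      }
    }
    for (a in clusters[[best$i]]) for (b in clusters[[best$j]])
      coph[a, b] <- coph[b, a] <- best$avg
    clusters[[best$i]] <- c(clusters[[best$i]], clusters[[best$j]])
    clusters[[best$j]] <- NULL
  }
  coph
}

# Minimal FASTQ writer (no package code) for fixture construction.
write_tiny_fastq <- function(path, ids, seqs, quals = NULL) {
  if (is.null(quals)) quals <- strrep("I", nchar(seqs))
  lines <- as.vector(rbind(paste0("@", ids), seqs, "+", quals))
  writeLines(lines, path)
  path
}

# Fixed-codon reverse translation (independent of the generator's).
aa_to_nt <- local({
  codon1 <- c(A = "GCT", R = "CGT", N = "AAT", D = "GAT", C = "TGT",
              Q = "CAA", E = "GAA", G = "GGT", H = "CAT", I = "ATT",
              L = "CTT", K = "AAA", M = "ATG", F = "TTT", P = "CCT",
              S = "TCT", T = "ACT", W = "TGG", Y = "TAT", V = "GTT")
  function(protein) {
    paste(codon1[strsplit(protein, "")[[1]]], collapse = "")
  }
})

# Random protein strings over a reduced alphabet.
random_proteins <- function(n, len, alphabet = c("A", "D", "G", "K", "S")) {
  vapply(seq_len(n), function(i)
    paste(sample(alphabet, len, replace = TRUE), collapse = ""), character(1))
}
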