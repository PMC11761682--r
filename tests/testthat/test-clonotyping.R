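# CDR3 identity, clonotype clustering, member search, tree construction.

test_that("percent identity handles equal and unequal lengths and is symmetric", {
  a <- strrep("A", 14)
  expect_equal(cdr3_identity(a, a), 100)
  b <- paste0(strrep("A", 13), "K")
  expect_equal(cdr3_identity(a, b), 100 * 13 / 14)
  expect_error(cdr3_identity("", a), "non-empty")
  set.seed(8)
  for (i in 1:25) {
    x <- paste(sample(LETTERS[1:6], sample(3:8, 1), TRUE), collapse = "")
    y <- paste(sample(LETTERS[1:6], sample(3:8, 1), TRUE), collapse = "")
    expect_equal(cdr3_identity(x, y), cdr3_identity(y, x))
    if (nchar(x) != nchar(y))
      expect_equal(cdr3_identity(x, y), oracle_align_identity(x, y))
  }
})

test_that("clonotype clustering follows strict greater-than threshold semantics", {
  cdr3s <- c(strrep("A", 14), paste0(strrep("A", 13), "K"), strrep("D", 14))
  cs <- cluster_clonotypes(c("x", "y", "z"), cdr3s, threshold = 85)
  expect_identical(length(cs$clusters), 2L)
  part <- split(cs$assignments$id, cs$assignments$cluster_id)
  expect_true(any(vapply(part, function(g) setequal(g, c("x", "y")), logical(1))))
  # at threshold 100 identity can never strictly exceed it
  cs100 <- cluster_clonotypes(c("x", "y"), c(strrep("A", 8), strrep("A", 8)),
                              threshold = 100)
  expect_identical(length(cs100$clusters), 2L)
})

test_that("representatives are the highest-count members with lexicographic ties", {
  cdr3s <- c("AAAA", "AAAK", "AAKK")
  cs <- cluster_clonotypes(c("a", "b", "c"), cdr3s, threshold = 70,
                           counts = c(2L, 9L, 2L))
  expect_identical(length(cs$clusters), 1L)  # single-linkage chain
  expect_identical(cs$clusters[[1]]$representative_id, "b")
  tie <- cluster_clonotypes(c("a", "b"), c("AAAK", "AAAA"), threshold = 70,
                            counts = c(3L, 3L))
  expect_identical(tie$clusters[[1]]$representative_id, "b")  # smallest seq
})

test_that("clustering matches a brute-force union-find oracle at 85/90/95", {
  set.seed(13)
  # mutated families plus background to create non-trivial components
  seeds <- random_proteins(12, 14, alphabet = LETTERS[1:8])
  cdr3s <- unlist(lapply(seeds, function(s) {
    vapply(1:12, function(i) {
      v <- strsplit(s, "")[[1]]
      k <- sample(0:3, 1)
      if (k > 0) v[sample(14, k)] <- sample(LETTERS[1:8], k, TRUE)
      paste(v, collapse = "")
    }, character(1))
  }))
  cdr3s <- c(cdr3s, random_proteins(56, 14, alphabet = LETTERS[1:8]))
  ids <- sprintf("q%03d", seq_along(cdr3s))
  for (t in c(85, 90, 95)) {
    cs <- cluster_clonotypes(ids, cdr3s, threshold = t)
    mine <- cs$assignments$cluster_id
    oracle <- oracle_components(cdr3s, t)
    expect_identical(partition_signature(mine), partition_signature(oracle))
  }
})

test_that("clustering output is a partition and refines as the threshold rises", {
  set.seed(17)
  for (i in 1:20) {
    cdr3s <- unique(unlist(lapply(random_proteins(6, 10, LETTERS[1:5]),
      function(s) vapply(1:7, function(j) {
        v <- strsplit(s, "")[[1]]
        k <- sample(0:2, 1)
        if (k > 0) v[sample(10, k)] <- sample(LETTERS[1:5], k, TRUE)
        paste(v, collapse = "")
      }, character(1)))))
    ids <- sprintf("s%03d", seq_along(cdr3s))
    lo <- cluster_clonotypes(ids, cdr3s, threshold = 85)$assignments
    hi <- cluster_clonotypes(ids, cdr3s, threshold = 92)$assignments
    expect_setequal(unlist(split(lo$id, lo$cluster_id)), ids)
    # each high-threshold cluster is inside exactly one low-threshold cluster
    agree <- tapply(lo$cluster_id, hi$cluster_id,
                    function(x) length(unique(x)))
    expect_true(all(agree == 1L))
  }
})

test_that("member search returns exactly the constructed clonotype", {
  set.seed(23)
  sc <- build_scaffold("II", 12)
  seed_chars <- strsplit(sc$protein, "")[[1]]
  cdr3_span <- (sc$regions$CDR3[1] + 1):(sc$regions$CDR3[2])
  fw_span <- setdiff(which(seed_chars %in% LETTERS), c(cdr3_span, 18, 72))
  # 77 distinct variants, each with at most one CDR3 substitution (identity
  # >= 11/12 > 85%) plus framework substitutions for uniqueness
  variants <- vapply(1:76, function(i) {
    v <- seed_chars
    pos <- sample(fw_span, 2)
    v[pos] <- vapply(v[pos], function(ch) sample(setdiff(c("A", "G", "S", "T"),
                                                         ch), 1), character(1))
    if (i %% 2 == 0) {
      p <- sample(cdr3_span[v[cdr3_span] != "C"], 1)
      v[p] <- sample(setdiff(c("A", "G", "S", "T"), v[p]), 1)
    }
    paste(v, collapse = "")
  }, character(1))
  lineage <- unique(c(sc$protein, variants))
  background <- vapply(1:50, function(i)
    build_scaffold("II", 12)$protein, character(1))
  tab <- annotate_repertoire(dereplicate(c(lineage, background), "lib"))
  hits <- find_clonotype_members(sc$cdr3, tab, threshold = 85)
  expect_setequal(hits$sequence, lineage)
  expect_identical(length(lineage), 77L)
  expect_true(all(diff(hits$count) <= 0))
  # a query with no neighborhood comes back empty
  none <- find_clonotype_members(strrep("W", 12), tab, threshold = 85)
  expect_identical(nrow(none), 0L)
  # consistency with clustering at the same threshold: members found from
  # the seed equal the seed's single-linkage component restricted to direct
  # neighbors of the query
  direct <- tab$records$sequence[
    vapply(tab$records$cdr3, function(x) cdr3_identity(sc$cdr3, x) > 85,
           logical(1))]
  expect_setequal(hits$sequence, direct)
})

test_that("UPGMA trees join closest pairs first and serialize canonically", {
  cherry <- build_tree(c("a", "b"), c("AAAA", "AAAA"))
  expect_identical(write_newick(cherry), "(a:0,b:0);")
  # d(A,B)=0.1 < d(A,C)=d(B,C): A,B join first
  A <- strrep("G", 10)
  B <- paste0(strrep("G", 9), "K")
  C <- paste0(strrep("S", 5), strrep("G", 5))
  tr <- write_newick(build_tree(c("A", "B", "C"), c(A, B, C)))
  expect_match(tr, "\\(A:[^,]+,B:[^)]+\\)")
  expect_error(build_tree("a", "AAAA"), "at least 2")
  expect_error(build_tree(c("a", "a"), c("AAAA", "AAAK")), "duplicate")
})

test_that("tree cophenetic distances match a naive UPGMA oracle", {
  set.seed(29)
  # prefixes of one mother string with prime lengths: the alignment score of
  # a pair is the shorter length, so identities are ratios of distinct
  # primes and every pairwise distance is distinct (tie-free by design)
  lens <- c(17L, 19L, 23L, 29L, 31L, 37L, 41L)
  n <- length(lens)
  mother <- paste(sample(LETTERS[1:20], max(lens), TRUE), collapse = "")
  seqs <- substr(rep(mother, n), 1, lens)
  d <- matrix(0, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    d[i, j] <- d[j, i] <- 1 - cdr3_identity(seqs[i], seqs[j]) / 100
  expect_identical(anyDuplicated(round(d[upper.tri(d)], 12)), 0L)
  ids <- sprintf("t%02d", 1:n)
  tree <- build_tree(ids, seqs)
  phylo <- ape::read.tree(text = write_newick(tree))
  coph_mine <- ape::cophenetic.phylo(phylo)[ids, ids]
  coph_oracle <- oracle_upgma_cophenetic(d)
  dimnames(coph_oracle) <- list(ids, ids)
  expect_equal(unname(coph_mine), unname(coph_oracle), tolerance = 1e-10)
})
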