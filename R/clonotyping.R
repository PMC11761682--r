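# CDR3 identity, single-linkage clonotype clustering, member search and
# UPGMA tree construction. "Homology" is implemented as percent identity;
# thresholds are strict (identity must exceed the threshold).

#' Percent identity between two CDR3 sequences
#'
#' Equal lengths: Hamming identity, 100 * matches / length. Unequal
#' lengths: global alignment with match = 1, mismatch = 0, gap = 0 (the
#' optimum equals the longest-common-subsequence length), normalized by the
#' longer sequence. Symmetric; empty strings are an error.
#'
#' @param a,b amino-acid strings.
#' @return percent identity in [0, 100].
#' @export
cdr3_identity <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) stop("cdr3_identity requires non-empty strings")
  na <- nchar(a); nb <- nchar(b)
  if (na == nb) return(100 * (na - cpp_hamming(a, b)) / na)
  100 * cpp_lcs(a, b) / max(na, nb)
}

# Identity of one query against many sequences (vectorized over the
# equal-length case).
.identity_to_many <- function(query, seqs) {
  out <- numeric(length(seqs))
  nq <- nchar(query)
  lens <- nchar(seqs)
  same <- lens == nq
  if (any(same))
    out[same] <- 100 * (nq - cpp_hamming(rep(query, sum(same)), seqs[same])) / nq
  for (i in which(!same)) out[i] <- 100 * cpp_lcs(query, seqs[i]) / max(nq, lens[i])
  out
}

# Edge list (i, j) over seqs where identity strictly exceeds threshold.
.identity_edges <- function(seqs, threshold) {
  n <- length(seqs)
  lens <- nchar(seqs)
  edges <- matrix(integer(0), ncol = 2L)
  for (len in unique(lens)) {
    idx <- which(lens == len)
    if (length(idx) < 2L) next
    e <- cpp_identity_edges(seqs[idx], threshold)
    if (nrow(e)) edges <- rbind(edges, cbind(idx[e[, 1L]], idx[e[, 2L]]))
  }
  # cross-length pairs (alignment identity); only when lengths are mixed
  if (length(unique(lens)) > 1L) {
    groups <- split(seq_len(n), lens)
    glens <- as.integer(names(groups))
    for (gi in seq_along(groups)) {
      for (gj in seq_along(groups)) {
        if (gj <= gi) next
        for (i in groups[[gi]]) {
          denom <- max(glens[gi], glens[gj])
          for (j in groups[[gj]]) {
            if (100 * cpp_lcs(seqs[i], seqs[j]) / denom > threshold)
              edges <- rbind(edges, cbind(min(i, j), max(i, j)))
          }
        }
      }
    }
  }
  edges
}

#' Cluster CDR3s into clonotypes
#'
#' Single linkage (default): clonotypes are the connected components of the
#' graph whose edges join pairs with identity strictly greater than
#' `threshold`. Complete linkage cuts an agglomerative complete-linkage
#' dendrogram at the equivalent height instead. Cluster ids are
#' deterministic, ordered by representative (count descending, then
#' sequence ascending); the representative of a cluster is its
#' highest-count member, ties broken by lexicographically smallest
#' sequence.
#'
#' @param ids record identifiers.
#' @param cdr3s CDR3 strings parallel to `ids`.
#' @param threshold percent identity threshold in (0, 100]; strictly
#'   greater-than semantics (at 100 every unique string is its own cluster).
#' @param counts read counts (default 1 each).
#' @param linkage "single" (default) or "complete".
#' @return object of class `clonotype_set`: list with `assignments`
#'   (data.frame id, cdr3, count, cluster_id, is_representative) and
#'   `clusters` (list of per-cluster lists: cluster_id, member_ids,
#'   representative_id, cdr3_consensus_len).
#' @export
cluster_clonotypes <- function(ids, cdr3s, threshold,
                               counts = rep(1L, length(ids)),
                               linkage = c("single", "complete")) {
  linkage <- match.arg(linkage)
  stopifnot(length(ids) == length(cdr3s), length(counts) == length(ids),
            threshold > 0, threshold <= 100)
  n <- length(ids)
  if (n == 0L)
    return(structure(list(assignments = data.frame(), clusters = list()),
                     class = "clonotype_set"))
  if (any(!nzchar(cdr3s))) stop("empty CDR3 strings cannot be clustered")
  if (linkage == "single") {
    edges <- .identity_edges(cdr3s, threshold)
    g <- igraph::make_empty_graph(n = n, directed = FALSE)
    if (nrow(edges)) g <- igraph::add_edges(g, t(edges))
    comp <- igraph::components(g)$membership
  } else {
    d <- .identity_dist_matrix(cdr3s)
    hc <- stats::hclust(stats::as.dist(d), method = "complete")
    comp <- stats::cutree(hc, h = (1 - threshold / 100) - 1e-9)
  }
  # representative per component: max count, ties lexicographic sequence
  reps <- vapply(split(seq_len(n), comp), function(members) {
    members[order(-counts[members], cdr3s[members], method = "radix")][1L]
  }, integer(1))
  # deterministic cluster ids ordered by representative
  rep_order <- order(-counts[reps], cdr3s[reps], ids[reps], method = "radix")
  new_id <- integer(max(comp))
  new_id[as.integer(names(reps))[rep_order]] <- seq_along(reps)
  cluster_id <- new_id[comp]
  rep_idx <- reps[rep_order]
  clusters <- lapply(seq_along(rep_idx), function(k) {
    members <- which(cluster_id == k)
    lens <- nchar(cdr3s[members])
    tl <- sort(table(lens), decreasing = TRUE)
    list(cluster_id = k, member_ids = ids[members],
         representative_id = ids[rep_idx[k]],
         cdr3_consensus_len = as.integer(names(tl)[1L]))
  })
  assignments <- data.frame(id = ids, cdr3 = cdr3s, count = counts,
                            cluster_id = cluster_id,
                            is_representative = seq_len(n) %in% rep_idx,
                            stringsAsFactors = FALSE)
  structure(list(assignments = assignments, clusters = clusters),
            class = "clonotype_set")
}

# Full pairwise distance matrix 1 - identity/100 (for trees and complete
# linkage; quadratic, intended for reporting-sized inputs).
.identity_dist_matrix <- function(seqs) {
  n <- length(seqs)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    ident <- .identity_to_many(seqs[i], seqs[(i + 1L):n])
    d[i, (i + 1L):n] <- d[(i + 1L):n, i] <- 1 - ident / 100
  }
  d
}

#' Find all clonotype members of a query CDR3 in a repertoire
#'
#' Returns the records whose CDR3 identity with the query strictly exceeds
#' `threshold`, sorted by count descending (ties by ascending sequence).
#'
#' @param query_cdr3 query CDR3 string.
#' @param tab an annotated `repertoire_table`.
#' @param threshold percent identity threshold.
#' @return data.frame of matching records with an `identity` column.
#' @export
find_clonotype_members <- function(query_cdr3, tab, threshold) {
  validate_repertoire_table(tab)
  stopifnot(nzchar(query_cdr3))
  rec <- tab$records
  ok <- !is.na(rec$cdr3)
  ident <- rep(NA_real_, nrow(rec))
  ident[ok] <- .identity_to_many(query_cdr3, rec$cdr3[ok])
  hit <- which(!is.na(ident) & ident > threshold)
  res <- rec[hit, , drop = FALSE]
  res$id <- record_ids(tab)[hit]
  res$identity <- ident[hit]
  res <- res[order(-res$count, res$sequence, method = "radix"), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Build a UPGMA tree over CDR3 sequences
#'
#' Agglomerative average-linkage (UPGMA) tree on the distance
#' 1 - identity/100; branch lengths are in distance units (node height =
#' half the merge distance, so leaf-to-leaf path length equals the
#' cophenetic distance). Serialization via [write_newick()] is canonical.
#'
#' @param ids leaf labels (unique).
#' @param seqs CDR3 strings parallel to `ids` (at least 2).
#' @return a `vnar_tree`.
#' @export
build_tree <- function(ids, seqs) {
  stopifnot(length(ids) == length(seqs))
  if (length(ids) < 2L) stop("build_tree requires at least 2 sequences")
  if (anyDuplicated(ids)) stop("duplicate leaf labels")
  d <- .identity_dist_matrix(seqs)
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  heights <- hc$height / 2
  nodes <- vector("list", nrow(hc$merge))
  node_h <- numeric(nrow(hc$merge))
  get_child <- function(v, parent_h) {
    if (v < 0L) tree_leaf(ids[-v], length = parent_h)
    else {
      child <- nodes[[v]]
      child$length <- parent_h - node_h[v]
      child
    }
  }
  for (k in seq_len(nrow(hc$merge))) {
    h <- heights[k]
    nodes[[k]] <- tree_node(list(get_child(hc$merge[k, 1L], h),
                                 get_child(hc$merge[k, 2L], h)))
    node_h[k] <- h
  }
  nodes[[length(nodes)]]
}
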