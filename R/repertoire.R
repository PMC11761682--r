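# Dereplication and library-level summary statistics.

#' Dereplicate translated proteins into a ranked repertoire table
#'
#' Identical protein sequences are collated into one record with a read
#' count; records are ranked by count (ties broken by ascending sequence so
#' ranks, and hence any downstream "top N" selection, are deterministic).
#'
#' @param proteins character vector of protein sequences (one per read), or
#'   the `vnars` data.frame returned by [process_library()].
#' @param library_id library label.
#' @return a [repertoire_table()] with `total_reads == length(proteins)`.
#' @export
dereplicate <- function(proteins, library_id) {
  if (is.data.frame(proteins)) proteins <- proteins$protein
  if (length(proteins) == 0L) {
    rec <- data.frame(sequence = character(0), count = integer(0),
                      rank = integer(0))
    return(repertoire_table(rec, library_id, total_reads = 0L))
  }
  tab <- table(proteins)
  rec <- data.frame(sequence = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  rec <- rec[order(-rec$count, rec$sequence, method = "radix"), , drop = FALSE]
  rec$rank <- seq_len(nrow(rec))
  repertoire_table(rec, library_id, total_reads = length(proteins))
}

#' Rank-abundance summary of a repertoire
#'
#' Reports the fraction of unique sequences seen fewer than `k` times and
#' the singleton fraction, the two quantities summarizing the skew of the
#' clone-abundance distribution.
#'
#' @param tab a `repertoire_table` (non-empty).
#' @param k count threshold for the "rare" fraction (default 10).
#' @return list with `n_unique`, `frac_lt_k_reads`, `frac_singletons`.
#' @export
abundance_summary <- function(tab, k = 10L) {
  validate_repertoire_table(tab)
  stopifnot(k >= 1L)
  n <- nrow(tab$records)
  if (n == 0L) stop("abundance summary is undefined for an empty table")
  counts <- tab$records$count
  list(n_unique = n,
       frac_lt_k_reads = sum(counts < k) / n,
       frac_singletons = sum(counts == 1L) / n)
}

#' Sequence sharing between two libraries
#'
#' Counts unique amino-acid sequences present in both tables. Sharing is
#' reported per library (the convention headline sharing percentages use)
#' and additionally as a Jaccard fraction of the union, so either
#' denominator convention can be compared directly.
#'
#' @param a,b dereplicated `repertoire_table`s.
#' @return list with `n_unique_a`, `n_unique_b`, `n_shared`,
#'   `frac_shared_of_a`, `frac_shared_of_b`, `frac_shared_of_union`.
#' @export
library_overlap <- function(a, b) {
  validate_repertoire_table(a)
  validate_repertoire_table(b)
  sa <- a$records$sequence
  sb <- b$records$sequence
  n_shared <- sum(sa %in% sb)
  n_union <- length(sa) + length(sb) - n_shared
  list(n_unique_a = length(sa), n_unique_b = length(sb),
       n_shared = n_shared,
       frac_shared_of_a = if (length(sa)) n_shared / length(sa) else NA_real_,
       frac_shared_of_b = if (length(sb)) n_shared / length(sb) else NA_real_,
       frac_shared_of_union = if (n_union) n_shared / n_union else NA_real_)
}
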