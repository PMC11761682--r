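# Differential clade mining: pool the top-prevalence equal-length CDR3s
# from a target-immunized and a control-immunized library, cluster them at
# the clonotype threshold, and report target-unique clades above the size
# floor with prevalence-ranked representatives.

#' Select the top prevalent records of a given CDR3 length
#'
#' Records with the requested CDR3 length, ordered by count descending
#' (ties by ascending sequence), truncated to `n`. If fewer than `n`
#' qualify, all are returned with a warning.
#'
#' @param tab an annotated `repertoire_table`.
#' @param cdr3_len required CDR3 length (aa).
#' @param n number of records to keep.
#' @return data.frame of selected records with an `id` column.
#' @export
select_top_prevalent <- function(tab, cdr3_len, n) {
  validate_repertoire_table(tab)
  stopifnot(n >= 1L)
  rec <- tab$records
  rec$id <- record_ids(tab)
  keep <- which(!is.na(rec$cdr3_len) & rec$cdr3_len == cdr3_len)
  rec <- rec[keep, , drop = FALSE]
  # table order is already count desc, sequence asc
  if (nrow(rec) < n) {
    warning(sprintf(
      "library '%s': only %d records with CDR3 length %d (requested top %d)",
      tab$library_id, nrow(rec), cdr3_len, n), call. = FALSE)
  } else {
    rec <- rec[seq_len(n), , drop = FALSE]
  }
  rownames(rec) <- NULL
  rec
}

#' Mine target-unique clades from a target/control library pair
#'
#' Pools the top-`top_n_prevalent` records of CDR3 length `cdr3_len` from
#' each library, single-linkage clusters the pooled CDR3s at the clonotype
#' identity threshold (Hamming, equal lengths), marks clades with zero
#' control-library members as target-unique, and nominates as candidates
#' the target-unique clades with at least `min_clade_unique_sequences`
#' distinct member sequences. Each candidate's representative is its
#' highest-count target-library member's full-length sequence.
#'
#' @param target,control annotated `repertoire_table`s.
#' @param config a [pipeline_config()].
#' @param cdr3_len CDR3 length to mine; must be in
#'   `config$cdr3_lengths_to_mine`.
#' @return object of class `mining_report`: list with `params`, `pooled`
#'   (the pooled selection), `clades` (data.frame), `candidates`
#'   (data.frame subset of clades), `members` (data.frame record-level
#'   clade assignments) and `representatives` (data.frame id, sequence,
#'   cdr3, count).
#' @export
mine_differential_clades <- function(target, control, config, cdr3_len) {
  validate_pipeline_config(config)
  if (!cdr3_len %in% config$cdr3_lengths_to_mine)
    stop("cdr3_len ", cdr3_len, " is not in config$cdr3_lengths_to_mine")
  sel_t <- select_top_prevalent(target, cdr3_len, config$top_n_prevalent)
  sel_c <- select_top_prevalent(control, cdr3_len, config$top_n_prevalent)
  if (nrow(sel_t) == 0L)
    stop("no records of CDR3 length ", cdr3_len, " in target library '",
         target$library_id, "'")
  if (nrow(sel_c) == 0L)
    stop("no records of CDR3 length ", cdr3_len, " in control library '",
         control$library_id, "'")
  sel_t$library <- "target"
  sel_c$library <- "control"
  cols <- c("id", "sequence", "count", "cdr3", "library")
  pooled <- rbind(sel_t[, cols], sel_c[, cols])
  pooled$pool_id <- paste(pooled$library, pooled$id, sep = ":")
  cs <- cluster_clonotypes(pooled$pool_id, pooled$cdr3,
                           threshold = config$clonotype_identity_threshold,
                           counts = pooled$count)
  pooled$clade_id <- cs$assignments$cluster_id
  agg <- split(seq_len(nrow(pooled)), pooled$clade_id)
  clades <- do.call(rbind, lapply(names(agg), function(cid) {
    idx <- agg[[cid]]
    n_target <- sum(pooled$library[idx] == "target")
    n_control <- sum(pooled$library[idx] == "control")
    data.frame(clade_id = as.integer(cid), cdr3_len = cdr3_len,
               n_members = length(idx),
               n_unique_sequences = length(unique(pooled$sequence[idx])),
               n_target = n_target, n_control = n_control,
               is_target_unique = n_control == 0L,
               stringsAsFactors = FALSE)
  }))
  clades <- clades[order(clades$clade_id), , drop = FALSE]
  # representative: highest-count target member; ties -> smallest sequence
  clades$representative_id <- vapply(clades$clade_id, function(cid) {
    idx <- agg[[as.character(cid)]]
    idx <- idx[pooled$library[idx] == "target"]
    if (!length(idx)) return(NA_character_)
    pooled$id[idx[order(-pooled$count[idx], pooled$sequence[idx],
                        method = "radix")][1L]]
  }, character(1))
  candidates <- clades[clades$is_target_unique &
                       clades$n_unique_sequences >=
                         config$min_clade_unique_sequences, , drop = FALSE]
  rownames(clades) <- rownames(candidates) <- NULL
  representatives <- do.call(rbind, lapply(candidates$clade_id, function(cid) {
    idx <- agg[[as.character(cid)]]
    idx <- idx[pooled$library[idx] == "target"]
    best <- idx[order(-pooled$count[idx], pooled$sequence[idx],
                      method = "radix")][1L]
    data.frame(clade_id = cid, id = pooled$id[best],
               sequence = pooled$sequence[best], cdr3 = pooled$cdr3[best],
               count = pooled$count[best], stringsAsFactors = FALSE)
  }))
  if (is.null(representatives))
    representatives <- data.frame(clade_id = integer(0), id = character(0),
                                  sequence = character(0), cdr3 = character(0),
                                  count = integer(0))
  structure(list(
    params = list(top_n = config$top_n_prevalent, cdr3_len = cdr3_len,
                  min_clade = config$min_clade_unique_sequences,
                  threshold = config$clonotype_identity_threshold),
    pooled = pooled, clades = clades, candidates = candidates,
    representatives = representatives
  ), class = "mining_report")
}

#' @export
print.mining_report <- function(x, ...) {
  cat(sprintf(
    "mining_report: CDR3 length %d, top %d/library, threshold >%g%%\n",
    x$params$cdr3_len, x$params$top_n, x$params$threshold))
  cat(sprintf("  %d clades, %d target-unique candidates (>= %d unique seqs)\n",
              nrow(x$clades), nrow(x$candidates), x$params$min_clade))
  invisible(x)
}

#' Rank candidate clades by representative prevalence
#'
#' @param report a `mining_report`.
#' @return the `candidates` data.frame joined with representative id,
#'   sequence and count, ordered by representative count descending (ties
#'   by ascending sequence); stable and deterministic.
#' @export
rank_candidates <- function(report) {
  stopifnot(inherits(report, "mining_report"))
  cand <- report$candidates
  reps <- report$representatives
  if (nrow(cand) == 0L) {
    cand$representative_count <- integer(0)
    cand$representative_sequence <- character(0)
    return(cand)
  }
  m <- match(cand$clade_id, reps$clade_id)
  cand$representative_count <- reps$count[m]
  cand$representative_sequence <- reps$sequence[m]
  cand <- cand[order(-cand$representative_count, cand$representative_sequence,
                     method = "radix"), , drop = FALSE]
  rownames(cand) <- NULL
  cand
}
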