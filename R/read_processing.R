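# Raw paired reads -> translated full-length VNAR proteins:
# trim -> merge -> flank filter -> in-frame translation -> stop filter.
# Per-record work runs in compiled kernels (src/core.cpp) or vectorized
# Biostrings calls; R code only orchestrates.

#' 3' quality trimming with optional adapter removal
#'
#' Sliding-window rule: the last base is dropped while its own quality, or
#' the mean Phred quality of the terminal window (width `window`, default
#' 4), falls below `min_phred`. Before quality trimming, an adapter
#' read-through -- the leftmost read suffix matching a prefix of `adapter`
#' with at most one mismatch -- is removed. Reads are never lengthened.
#'
#' @param pairs a `read_pairs` object (see [read_fastq_pair()]).
#' @param min_phred minimum window mean quality (default 20).
#' @param adapter adapter sequence or NULL.
#' @param window sliding window width (default 4).
#' @return a `read_pairs` object with trimmed sequences and qualities.
#' @export
quality_trim <- function(pairs, min_phred = 20L, adapter = NULL,
                         window = 4L) {
  stopifnot(inherits(pairs, "read_pairs"), min_phred >= 0L)
  ad <- if (is.null(adapter)) NA_character_ else toupper(adapter)
  f <- cpp_trim_reads(pairs$fwd_seq, pairs$fwd_qual, min_phred, window, ad)
  r <- cpp_trim_reads(pairs$rev_seq, pairs$rev_qual, min_phred, window, ad)
  structure(list(id = pairs$id,
                 fwd_seq = f$seq, rev_seq = r$seq,
                 fwd_qual = f$qual, rev_qual = r$qual),
            class = "read_pairs")
}

.revcomp <- function(seqs) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs)))
}

.rev_string <- function(x) {
  vapply(strsplit(x, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

#' Merge read pairs by overlap consensus
#'
#' The reverse mate is reverse-complemented and the overlap (length at least
#' `min_overlap_nt`, mismatch fraction at most `max_overlap_mismatch_frac`)
#' maximizing the number of matching bases is chosen; among equally good
#' overlaps the shortest wins. Disagreeing overlap bases resolve to the
#' higher-quality base (forward read wins ties). Pairs without a qualifying
#' overlap fail with `NA` in the merged sequence.
#'
#' @param pairs a `read_pairs` object; both mates must be non-empty.
#' @param min_overlap_nt minimum overlap length in nt.
#' @param max_overlap_mismatch_frac maximum mismatch fraction in the overlap.
#' @return data.frame with columns `id`, `seq` (NA on merge failure),
#'   `overlap_len`, `overlap_mismatches`.
#' @export
merge_pairs <- function(pairs, min_overlap_nt = 10L,
                        max_overlap_mismatch_frac = 0.25) {
  stopifnot(inherits(pairs, "read_pairs"))
  n <- length(pairs$id)
  if (n == 0L)
    return(data.frame(id = character(0), seq = character(0),
                      overlap_len = integer(0),
                      overlap_mismatches = integer(0)))
  if (any(!nzchar(pairs$fwd_seq)) || any(!nzchar(pairs$rev_seq)))
    stop("merge requires non-empty mates")
  rev_rc <- .revcomp(pairs$rev_seq)
  rq_rev <- .rev_string(pairs$rev_qual)
  m <- cpp_merge_pairs(pairs$fwd_seq, pairs$fwd_qual, rev_rc, rq_rev,
                       as.integer(min_overlap_nt), max_overlap_mismatch_frac)
  data.frame(id = pairs$id, seq = m$seq, overlap_len = m$overlap_len,
             overlap_mismatches = m$mismatches, stringsAsFactors = FALSE)
}

#' Merge a single read pair
#'
#' Scalar wrapper around [merge_pairs()]; returns an `amplicon` on success
#' and a `vnar_merge_failure` (with a `reason`) otherwise.
#'
#' @param id read identifier
#' @param fwd_seq,rev_seq mate sequences
#' @param fwd_qual,rev_qual mate qualities (Phred+33); default constant.
#' @inheritParams merge_pairs
#' @export
merge_pair <- function(id, fwd_seq, rev_seq,
                       fwd_qual = strrep("I", nchar(fwd_seq)),
                       rev_qual = strrep("I", nchar(rev_seq)),
                       min_overlap_nt = 10L,
                       max_overlap_mismatch_frac = 0.25) {
  pairs <- structure(list(id = id, fwd_seq = fwd_seq, rev_seq = rev_seq,
                          fwd_qual = fwd_qual, rev_qual = rev_qual),
                     class = "read_pairs")
  m <- merge_pairs(pairs, min_overlap_nt, max_overlap_mismatch_frac)
  if (is.na(m$seq[1L]))
    return(structure(list(id = id, reason = "no qualifying overlap"),
                     class = "vnar_merge_failure"))
  structure(list(id = id, seq = m$seq[1L], overlap_len = m$overlap_len[1L],
                 overlap_mismatches = m$overlap_mismatches[1L]),
            class = "amplicon")
}

#' Locate the conserved flanks and return the insert interval
#'
#' Finds the leftmost occurrence of `flank5` with at most `max_mismatches`
#' Hamming mismatches, then (when `flank3` is non-empty) the first
#' subsequent occurrence of `flank3`. The insert is the interval strictly
#' between them, 0-based half-open; with an empty `flank3` the insert runs
#' to the end of the sequence. Both orientations are searched and the
#' result is reported in the orientation that puts `flank5` upstream.
#'
#' @param seq nucleotide string.
#' @param flank5 5' anchor (non-empty).
#' @param flank3 3' anchor or "" (empty).
#' @param max_mismatches Hamming mismatch allowance for both anchors.
#' @return list with `start`, `end` (0-based half-open, in the normalized
#'   orientation), `revcomp` (TRUE if the sequence was flipped) and
#'   `oriented_seq`; or a `vnar_flank_notfound` with `reason` "flank5" or
#'   "flank3".
#' @export
locate_flanks <- function(seq, flank5, flank3 = "", max_mismatches = 0L) {
  stopifnot(nzchar(flank5))
  hit <- .locate_flanks_all(seq, flank5, flank3, max_mismatches)
  if (is.na(hit$start[1L]))
    return(structure(list(reason = hit$fail[1L]), class = "vnar_flank_notfound"))
  list(start = hit$start[1L], end = hit$end[1L],
       revcomp = hit$revcomp[1L], oriented_seq = hit$oriented_seq[1L])
}

# Vectorized flank location over a character vector of merged amplicons.
# Returns a data.frame(start, end, revcomp, oriented_seq, fail) with NA
# start on failure; intervals are 0-based half-open.
.locate_flanks_all <- function(seqs, flank5, flank3, max_mismatches) {
  n <- length(seqs)
  out <- data.frame(start = rep(NA_integer_, n), end = rep(NA_integer_, n),
                    revcomp = rep(FALSE, n),
                    oriented_seq = toupper(seqs),
                    fail = rep(NA_character_, n),
                    stringsAsFactors = FALSE)
  find5 <- function(subjects) {
    m <- Biostrings::vmatchPattern(flank5, Biostrings::DNAStringSet(subjects),
                                   max.mismatch = max_mismatches,
                                   with.indels = FALSE)
    starts <- IRanges::start(m)
    vapply(starts, function(s) if (length(s)) min(s) else NA_integer_,
           integer(1))
  }
  s5 <- find5(out$oriented_seq)
  flip <- which(is.na(s5))
  if (length(flip)) {
    rc <- .revcomp(out$oriented_seq[flip])
    s5rc <- find5(rc)
    ok <- !is.na(s5rc)
    out$oriented_seq[flip[ok]] <- rc[ok]
    out$revcomp[flip[ok]] <- TRUE
    s5[flip[ok]] <- s5rc[ok]
  }
  miss5 <- is.na(s5)
  out$fail[miss5] <- "flank5"
  insert_start <- s5 + nchar(flank5) - 1L  # 0-based position after flank5
  if (!nzchar(flank3)) {
    keep <- !miss5
    out$start[keep] <- insert_start[keep]
    out$end[keep] <- nchar(out$oriented_seq)[keep]
    bad <- keep & out$start > out$end
    out$start[bad] <- NA_integer_
    out$fail[bad] <- "flank5"
    return(out)
  }
  idx <- which(!miss5)
  if (length(idx)) {
    m3 <- Biostrings::vmatchPattern(flank3,
                                    Biostrings::DNAStringSet(out$oriented_seq[idx]),
                                    max.mismatch = max_mismatches,
                                    with.indels = FALSE)
    starts3 <- IRanges::start(m3)
    for (k in seq_along(idx)) {
      i <- idx[k]
      cand <- starts3[[k]]
      cand <- cand[cand - 1L >= insert_start[i]]  # flank3 at/after insert start
      if (!length(cand)) {
        out$fail[i] <- "flank3"
      } else {
        out$start[i] <- insert_start[i]
        out$end[i] <- min(cand) - 1L
      }
    }
  }
  out
}

#' Extract the insert delimited by the flanks
#' @param loc result of [locate_flanks()]
#' @return nucleotide string between the flanks
#' @export
extract_insert <- function(loc) {
  stopifnot(!inherits(loc, "vnar_flank_notfound"))
  substr(loc$oriented_seq, loc$start + 1L, loc$end)
}

#' Translate an insert into a VNAR protein
#'
#' Rejects inserts whose length is not a multiple of 3 (`frame`), that
#' contain a codon with N (`ambiguous`), whose translation contains a stop
#' before the final codon (`internal_stop`) or at the final codon
#' (`terminal_stop`), or whose protein length falls outside the configured
#' bounds (`length`). Accepted translations use the standard genetic code
#' and never contain `*` or `X`.
#'
#' @param nt_insert nucleotide string located by [locate_flanks()].
#' @param min_len,max_len accepted protein length bounds (aa).
#' @return list with `protein` and `nt_insert`, or a `vnar_reject` with a
#'   `reason`.
#' @export
translate_insert <- function(nt_insert, min_len = 80L, max_len = 220L) {
  reject <- function(reason)
    structure(list(reason = reason), class = "vnar_reject")
  nt_insert <- toupper(nt_insert)
  if (nchar(nt_insert) %% 3L != 0L || nchar(nt_insert) == 0L)
    return(reject("frame"))
  if (grepl("[^ACGT]", nt_insert)) return(reject("ambiguous"))
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(nt_insert),
                                           no.init.codon = TRUE))
  stop_pos <- regexpr("*", aa, fixed = TRUE)
  if (stop_pos > 0L) {
    return(reject(if (stop_pos < nchar(aa)) "internal_stop" else "terminal_stop"))
  }
  if (nchar(aa) < min_len || nchar(aa) > max_len) return(reject("length"))
  list(protein = aa, nt_insert = nt_insert)
}

#' Per-stage survivor counts of the read-processing pipeline
#' @param n_pairs_in,n_merged,n_flank_pass,n_in_frame,n_no_stop,n_len_pass
#'   integer counters; monotone non-increasing in that order.
#' @export
qc_report <- function(n_pairs_in, n_merged, n_flank_pass, n_in_frame,
                      n_no_stop, n_len_pass) {
  counts <- c(n_pairs_in = n_pairs_in, n_merged = n_merged,
              n_flank_pass = n_flank_pass, n_in_frame = n_in_frame,
              n_no_stop = n_no_stop, n_len_pass = n_len_pass)
  counts <- vapply(counts, as.integer, integer(1))
  if (any(diff(counts) > 0L))
    stop("QC counters must be monotone non-increasing")
  structure(as.list(counts), class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("read-processing QC:\n")
  for (k in names(x)) cat(sprintf("  %-12s %d\n", k, x[[k]]))
  invisible(x)
}

#' Process a paired-end library into translated VNAR proteins
#'
#' Runs trim -> merge -> flank filter -> translate -> stop/length filter
#' over a FASTQ pair in chunks, logging per-stage counts. Output order is
#' deterministic (input order).
#'
#' @param path_fwd,path_rev FASTQ file pair.
#' @param config a [pipeline_config()].
#' @param min_phred quality-trim threshold (default 20).
#' @param adapter adapter for read-through removal, or NULL.
#' @param chunk_size records per chunk (default 20000).
#' @return list with `vnars` (data.frame id, protein, nt_insert) and `qc`
#'   (a `qc_report`).
#' @export
process_library <- function(path_fwd, path_rev, config = pipeline_config(),
                            min_phred = 20L, adapter = NULL,
                            chunk_size = 20000L) {
  validate_pipeline_config(config)
  counters <- c(n_pairs_in = 0L, n_merged = 0L, n_flank_pass = 0L,
                n_in_frame = 0L, n_no_stop = 0L, n_len_pass = 0L)
  out <- list()
  skip <- 0L
  repeat {
    pairs <- read_fastq_pair(path_fwd, path_rev, nrec = chunk_size,
                             skip = skip)
    n <- length(pairs$id)
    if (n == 0L) break
    skip <- skip + n
    counters["n_pairs_in"] <- counters["n_pairs_in"] + n
    pairs <- quality_trim(pairs, min_phred = min_phred, adapter = adapter)
    nonempty <- nzchar(pairs$fwd_seq) & nzchar(pairs$rev_seq)
    merged <- data.frame(id = character(0), seq = character(0))
    if (any(nonempty)) {
      sub <- structure(lapply(pairs, `[`, which(nonempty)),
                       class = "read_pairs")
      merged <- merge_pairs(sub, config$min_overlap_nt,
                            config$max_overlap_mismatch_frac)
      merged <- merged[!is.na(merged$seq), , drop = FALSE]
    }
    counters["n_merged"] <- counters["n_merged"] + nrow(merged)
    if (nrow(merged)) {
      loc <- .locate_flanks_all(merged$seq, config$flank5, config$flank3,
                                config$max_flank_mismatches)
      pass <- !is.na(loc$start)
      counters["n_flank_pass"] <- counters["n_flank_pass"] + sum(pass)
      if (any(pass)) {
        ins <- substr(loc$oriented_seq[pass], loc$start[pass] + 1L,
                      loc$end[pass])
        ids <- merged$id[pass]
        frame_ok <- nchar(ins) %% 3L == 0L & nchar(ins) > 0L &
          !grepl("[^ACGT]", ins)
        counters["n_in_frame"] <- counters["n_in_frame"] + sum(frame_ok)
        if (any(frame_ok)) {
          ins2 <- ins[frame_ok]
          aa <- as.character(
            Biostrings::translate(Biostrings::DNAStringSet(ins2),
                                  no.init.codon = TRUE))
          no_stop <- !grepl("*", aa, fixed = TRUE)
          counters["n_no_stop"] <- counters["n_no_stop"] + sum(no_stop)
          len_ok <- no_stop & nchar(aa) >= config$min_protein_len_aa &
            nchar(aa) <= config$max_protein_len_aa
          counters["n_len_pass"] <- counters["n_len_pass"] + sum(len_ok)
          if (any(len_ok))
            out[[length(out) + 1L]] <- data.frame(
              id = ids[frame_ok][len_ok], protein = aa[len_ok],
              nt_insert = ins2[len_ok], stringsAsFactors = FALSE)
        }
      }
    }
    if (n < chunk_size) break
  }
  vnars <- if (length(out)) do.call(rbind, out)
           else data.frame(id = character(0), protein = character(0),
                           nt_insert = character(0))
  rownames(vnars) <- NULL
  qc <- do.call(qc_report, as.list(counters))
  vnar_log("process", "%d pairs in, %d merged, %d flank-pass, %d full-length",
           qc$n_pairs_in, qc$n_merged, qc$n_flank_pass, qc$n_len_pass)
  list(vnars = vnars, qc = qc)
}
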