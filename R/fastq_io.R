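# FASTQ input for positionally paired mates. Parsing is delegated to
# Biostrings; this layer enforces pairing and exposes plain character
# vectors, which is what the merge kernel consumes.

.normalize_read_id <- function(id) {
  id <- sub("[ \t].*$", "", id)
  sub("/[12]$", "", id)
}

#' Read a positionally paired FASTQ file pair
#'
#' Records are paired by file position; identifiers must agree after
#' stripping the standard `/1`,`/2` mate suffix or a whitespace-delimited
#' mate field. `nrec`/`skip` allow chunked reading so the caller's working
#' state stays constant-size per record regardless of file size.
#'
#' @param path_fwd,path_rev FASTQ files (4-line records, Phred+33; gzip
#'   accepted).
#' @param nrec maximum number of records to read (-1 = all).
#' @param skip number of records to skip from the start of each file.
#' @param check_ids verify that mate identifiers match (default TRUE).
#' @return object of class `read_pairs`: list with character vectors `id`,
#'   `fwd_seq`, `rev_seq`, `fwd_qual`, `rev_qual`.
#' @export
read_fastq_pair <- function(path_fwd, path_rev, nrec = -1L, skip = 0L,
                            check_ids = TRUE) {
  for (p in c(path_fwd, path_rev))
    if (!file.exists(p)) stop("FASTQ file not found: ", p)
  read_one <- function(path) {
    tryCatch(
      Biostrings::readDNAStringSet(path, format = "fastq",
                                   nrec = nrec, skip = skip,
                                   with.qualities = TRUE),
      error = function(e) stop("FASTQ parse error in '", path, "': ",
                               conditionMessage(e), call. = FALSE)
    )
  }
  fwd <- read_one(path_fwd)
  rev <- read_one(path_rev)
  if (length(fwd) != length(rev))
    stop("pairing error: '", path_fwd, "' and '", path_rev,
         "' yield ", length(fwd), " vs ", length(rev), " records")
  ids_f <- .normalize_read_id(names(fwd))
  ids_r <- .normalize_read_id(names(rev))
  if (check_ids && !identical(ids_f, ids_r)) {
    bad <- which(ids_f != ids_r)[1L]
    stop("pairing error: mate identifiers differ at record ", skip + bad,
         " ('", ids_f[bad], "' vs '", ids_r[bad], "')")
  }
  structure(list(
    id = unname(ids_f),
    fwd_seq = unname(as.character(fwd)),
    rev_seq = unname(as.character(rev)),
    fwd_qual = unname(as.character(S4Vectors::mcols(fwd)$qualities)),
    rev_qual = unname(as.character(S4Vectors::mcols(rev)$qualities))
  ), class = "read_pairs")
}

#' Number of read pairs
#' @param x a `read_pairs` object
#' @export
length.read_pairs <- function(x) length(x$id)

#' Write a FASTQ file
#' @param id,seq,qual parallel character vectors
#' @param path output path (gzip if it ends in .gz)
#' @keywords internal
#' @export
write_fastq <- function(id, seq, qual, path) {
  x <- Biostrings::DNAStringSet(seq)
  names(x) <- id
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(qual),
                              compress = grepl("\\.gz$", path))
  invisible(path)
}
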