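# On-disk form of a repertoire table: UTF-8 TSV with a fixed leading column
# order (sequence, count, rank, cdr3, cdr3_len, subtype, library) so golden
# files are reproducible; annotation may append further columns after these.

.REPERTOIRE_COLUMNS <- c("sequence", "count", "rank", "cdr3", "cdr3_len",
                         "subtype", "library")

#' Construct a repertoire table object
#'
#' @param records data.frame with at least columns `sequence`, `count`,
#'   `rank`; annotation columns (`cdr3`, `cdr3_len`, `subtype`, ...) may be
#'   present.
#' @param library_id library label.
#' @param total_reads total reads behind the table; defaults to sum(count).
#' @return object of class `repertoire_table`.
#' @export
repertoire_table <- function(records, library_id,
                             total_reads = sum(records$count)) {
  for (col in c("cdr3", "cdr3_len", "subtype"))
    if (is.null(records[[col]]))
      records[[col]] <- rep(NA, nrow(records))
  records$cdr3 <- as.character(records$cdr3)
  records$cdr3_len <- as.integer(records$cdr3_len)
  records$subtype <- as.character(records$subtype)
  rownames(records) <- NULL
  tab <- structure(list(library_id = library_id,
                        records = records,
                        total_reads = as.integer(total_reads)),
                   class = "repertoire_table")
  validate_repertoire_table(tab)
  tab
}

#' @rdname repertoire_table
#' @param tab a `repertoire_table`
#' @export
validate_repertoire_table <- function(tab) {
  stopifnot(inherits(tab, "repertoire_table"))
  rec <- tab$records
  if (anyDuplicated(rec$sequence))
    stop("integrity error: duplicate sequences in repertoire table")
  n <- nrow(rec)
  if (n > 0L) {
    ord <- order(-rec$count, rec$sequence)
    if (!identical(ord, seq_len(n)))
      stop("records must be sorted by count descending, sequence ascending")
    if (!identical(as.integer(rec$rank), seq_len(n)))
      stop("rank must equal 1-based row position")
  }
  if (sum(rec$count) != tab$total_reads)
    stop("sum of counts (", sum(rec$count), ") != total_reads (",
         tab$total_reads, ")")
  invisible(tab)
}

#' @export
print.repertoire_table <- function(x, ...) {
  cat(sprintf("repertoire_table '%s': %d unique sequences, %d reads\n",
              x$library_id, nrow(x$records), x$total_reads))
  invisible(x)
}

#' Record identifiers (NGS<rank>) of a repertoire table
#' @param tab a `repertoire_table`
#' @return character vector, one id per record, in table order.
#' @export
record_ids <- function(tab) {
  if (nrow(tab$records) == 0L) return(character(0))
  sprintf("NGS%d", tab$records$rank)
}

#' Write / read a repertoire table as TSV
#'
#' One row per unique sequence; `read_repertoire_table(write_repertoire_table(t))`
#' restores `t` exactly. Duplicate sequence rows on read raise an integrity
#' error.
#'
#' @param tab a `repertoire_table`
#' @param path TSV path
#' @export
write_repertoire_table <- function(tab, path) {
  validate_repertoire_table(tab)
  rec <- tab$records
  rec$library <- rep(tab$library_id, nrow(rec))
  cols <- c(.REPERTOIRE_COLUMNS, setdiff(names(rec), .REPERTOIRE_COLUMNS))
  write.table(rec[, cols, drop = FALSE], path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_repertoire_table
#' @param library_id library label override; defaults to the `library` column.
#' @export
read_repertoire_table <- function(path, library_id = NULL) {
  rec <- read.delim(path, sep = "\t", header = TRUE,
                    colClasses = NA, stringsAsFactors = FALSE)
  missing <- setdiff(.REPERTOIRE_COLUMNS, names(rec))
  if (length(missing))
    stop("repertoire TSV is missing columns: ", paste(missing, collapse = ", "))
  if (anyDuplicated(rec$sequence))
    stop("integrity error: duplicate sequence rows in '", path, "'")
  if (is.null(library_id))
    library_id <- if (nrow(rec)) rec$library[1L] else NA_character_
  rec$library <- NULL
  rec$sequence <- as.character(rec$sequence)
  rec$count <- as.integer(rec$count)
  rec$rank <- as.integer(rec$rank)
  repertoire_table(rec, library_id = library_id)
}
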