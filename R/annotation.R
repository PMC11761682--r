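# Region delineation, cysteine profiling, subtype classification and CDR3
# statistics. VNARs carry two CDRs (no CDR2) plus two hypervariable loops
# (HV2, HV4); non-canonical cysteines outside the conserved immunoglobulin-
# fold pair define subtypes I-IV. All intervals are 0-based half-open in
# protein coordinates.

.REGION_NAMES <- c("FR1", "CDR1", "FR2", "HV2", "FR3a", "HV4", "FR3b",
                   "CDR3", "FR4")

# Last occurrence (0-based start) of `motif` in `protein` with at most
# `max_mm` mismatches, starting at 0-based position >= min_start; NA if none.
.find_fr4_motif <- function(protein, motif, max_mm, min_start = 0L) {
  n <- nchar(protein)
  m <- nchar(motif)
  if (n < m) return(NA_integer_)
  hits <- gregexpr(motif, protein, fixed = TRUE)[[1L]]
  if (hits[1L] > 0L) {
    hits0 <- hits - 1L
    hits0 <- hits0[hits0 >= min_start]
    if (length(hits0)) return(max(hits0))
  }
  if (max_mm > 0L) {
    mot <- strsplit(motif, "", fixed = TRUE)[[1L]]
    chars <- strsplit(protein, "", fixed = TRUE)[[1L]]
    for (s in (n - m):max(min_start, 0L)) {    # scan from the 3' end
      if (s < min_start) break
      if (sum(chars[(s + 1L):(s + m)] != mot) <= max_mm) return(s)
    }
  }
  NA_integer_
}

#' Delineate VNAR regions from cysteine and FR4 anchors
#'
#' Anchor-based rules (robust to CDR length variation): the first canonical
#' cysteine is the first C inside the FR1 window; the second is the last C
#' inside a framework window at a fixed offset from the first (the FR3b
#' tail); FR4 starts at the last occurrence of the FR4 motif (default
#' "DGAGT", at most one mismatch) after that cysteine. CDR3 is the interval
#' strictly between the second canonical cysteine and FR4. Remaining
#' framework/loop boundaries sit at fixed offsets from the first anchor.
#' `mode = "absolute"` instead uses fixed template coordinates for strict
#' reproduction on indel-free scaffolds.
#'
#' @param protein amino-acid string.
#' @param fr4_motif FR4 start motif (default "DGAGT").
#' @param fr4_max_mismatch mismatch allowance for the motif (default 1).
#' @param cys1_window 0-based half-open window for the first canonical C
#'   (default c(15, 30)).
#' @param cys2_offset_window offsets from cys1 delimiting the window whose
#'   last C is the second canonical cysteine (default c(45, 55)).
#' @param mode "anchor" (default) or "absolute".
#' @return list with `regions` (named list of c(start, end) 0-based
#'   half-open intervals), `canonical_cys1`, `canonical_cys2`, `cdr3`
#'   (string) -- or a `vnar_unannotatable` with `reason` in
#'   {"no_canonical_cys", "no_fr4"}.
#' @export
annotate_regions <- function(protein, fr4_motif = "DGAGT",
                             fr4_max_mismatch = 1L,
                             cys1_window = c(15L, 30L),
                             cys2_offset_window = c(45L, 55L),
                             mode = c("anchor", "absolute")) {
  mode <- match.arg(mode)
  fail <- function(reason)
    structure(list(reason = reason), class = "vnar_unannotatable")
  n <- nchar(protein)
  cpos <- as.integer(gregexpr("C", protein, fixed = TRUE)[[1L]]) - 1L
  cpos <- cpos[cpos >= 0L]
  if (mode == "absolute") {
    cys1 <- 17L
    cys2 <- 71L
    fr4 <- n - 10L
    if (!(cys1 %in% cpos) || !(cys2 %in% cpos)) return(fail("no_canonical_cys"))
    if (fr4 < cys2 + 2L) return(fail("no_fr4"))
  } else {
    in1 <- cpos[cpos >= cys1_window[1L] & cpos < cys1_window[2L]]
    if (!length(in1)) return(fail("no_canonical_cys"))
    cys1 <- in1[1L]
    in2 <- cpos[cpos >= cys1 + cys2_offset_window[1L] &
                cpos < cys1 + cys2_offset_window[2L]]
    if (!length(in2)) return(fail("no_canonical_cys"))
    cys2 <- in2[length(in2)]
    fr4 <- .find_fr4_motif(protein, fr4_motif, fr4_max_mismatch,
                           min_start = cys2 + 2L)
    if (is.na(fr4)) return(fail("no_fr4"))
  }
  bounds <- c(0L, cys1 + 3L, cys1 + 11L, cys1 + 22L, cys1 + 30L,
              cys1 + 38L, cys1 + 43L, cys2 + 1L, fr4, n)
  if (any(diff(bounds) < 0L) || bounds[8L] <= bounds[7L])
    return(fail("no_canonical_cys"))
  regions <- lapply(seq_len(9L), function(i) c(bounds[i], bounds[i + 1L]))
  names(regions) <- .REGION_NAMES
  list(regions = regions, canonical_cys1 = cys1, canonical_cys2 = cys2,
       cdr3 = substr(protein, cys2 + 2L, fr4))
}

#' Cysteine profile of an annotated VNAR
#'
#' Assigns every cysteine to exactly one region bucket (FR1, CDR1, FR2, the
#' FR3 block HV2+FR3a+HV4+FR3b, CDR3, FR4); bucket counts sum to the total.
#' Non-canonical counts subtract the canonical pair from the FR1 and FR3
#' buckets. Also records whether CDR1 carries the conservation marker motif
#' that distinguishes Type III from Type II.
#'
#' @param protein amino-acid string.
#' @param ann result of [annotate_regions()].
#' @param cdr1_motif CDR1 conservation motif (default "W").
#' @return list of class `cysteine_profile` with `positions`, `counts`
#'   (named: FR1, CDR1, FR2, FR3, CDR3, FR4), `noncanonical` (named: FR1,
#'   CDR1, FR2, FR3, CDR3, FR4), `n_total`, `has_canonical_pair`,
#'   `cdr1_motif_present`.
#' @export
cysteine_profile <- function(protein, ann, cdr1_motif = "W") {
  stopifnot(!inherits(ann, "vnar_unannotatable"))
  cpos <- as.integer(gregexpr("C", protein, fixed = TRUE)[[1L]]) - 1L
  cpos <- cpos[cpos >= 0L]
  r <- ann$regions
  bucket_of <- function(p) {
    if (p < r$CDR1[1L]) "FR1"
    else if (p < r$FR2[1L]) "CDR1"
    else if (p < r$HV2[1L]) "FR2"
    else if (p < r$CDR3[1L]) "FR3"
    else if (p < r$FR4[1L]) "CDR3"
    else "FR4"
  }
  buckets <- c("FR1", "CDR1", "FR2", "FR3", "CDR3", "FR4")
  counts <- setNames(integer(6L), buckets)
  for (p in cpos) {
    b <- bucket_of(p)
    counts[b] <- counts[b] + 1L
  }
  noncan <- counts
  has_pair <- !is.na(ann$canonical_cys1) && !is.na(ann$canonical_cys2)
  if (!is.na(ann$canonical_cys1) && ann$canonical_cys1 %in% cpos)
    noncan["FR1"] <- noncan["FR1"] - 1L
  if (!is.na(ann$canonical_cys2) && ann$canonical_cys2 %in% cpos)
    noncan["FR3"] <- noncan["FR3"] - 1L
  cdr1_seq <- substr(protein, r$CDR1[1L] + 1L, r$CDR1[2L])
  structure(list(positions = cpos, counts = counts, noncanonical = noncan,
                 n_total = length(cpos), has_canonical_pair = has_pair,
                 cdr1_motif_present = grepl(cdr1_motif, cdr1_seq, fixed = TRUE)),
            class = "cysteine_profile")
}

#' Subtype call from architecture flags
#'
#' Pure rule table over the evidence flags, exhaustive and mutually
#' exclusive: Type I has FR2 and FR4 non-canonical cysteines with an even
#' CDR3 cysteine count of at least two; Types II/III have a CDR1-CDR3
#' cysteine pair without framework cysteines, split by the CDR1
#' conservation motif (absent = II, present = III); Type IV has only the
#' canonical pair. Everything else is "unclassified".
#'
#' @param cdr1_cys,fr2_cys,fr4_cys,cdr3_cys non-canonical cysteine counts.
#' @param cdr1_motif logical, CDR1 conservation motif present.
#' @param other_noncanonical non-canonical cysteines outside those buckets
#'   (FR1/FR3 block); any such cysteine excludes Type IV.
#' @return subtype string: "I", "II", "III", "IV" or "unclassified".
#' @export
subtype_from_flags <- function(cdr1_cys, fr2_cys, fr4_cys, cdr3_cys,
                               cdr1_motif, other_noncanonical = 0L) {
  if (fr2_cys >= 1L && fr4_cys >= 1L && cdr3_cys >= 2L &&
      cdr3_cys %% 2L == 0L) return("I")
  if (cdr1_cys >= 1L && cdr3_cys >= 1L && fr2_cys == 0L && fr4_cys == 0L)
    return(if (cdr1_motif) "III" else "II")
  if (cdr1_cys == 0L && fr2_cys == 0L && fr4_cys == 0L && cdr3_cys == 0L &&
      other_noncanonical == 0L) return("IV")
  "unclassified"
}

#' Classify the VNAR subtype from a cysteine profile
#'
#' @param profile a [cysteine_profile()]. Sequences without the canonical
#'   cysteine pair are "unclassified".
#' @return list with `subtype` and `rationale_flags`.
#' @export
classify_subtype <- function(profile) {
  stopifnot(inherits(profile, "cysteine_profile"))
  nc <- profile$noncanonical
  flags <- list(cdr1_cys = nc[["CDR1"]], fr2_cys = nc[["FR2"]],
                fr4_cys = nc[["FR4"]], cdr3_cys_count = nc[["CDR3"]],
                cdr1_conserved_motif = profile$cdr1_motif_present,
                other_noncanonical = nc[["FR1"]] + nc[["FR3"]])
  subtype <- if (!profile$has_canonical_pair) "unclassified"
             else subtype_from_flags(flags$cdr1_cys, flags$fr2_cys,
                                     flags$fr4_cys, flags$cdr3_cys_count,
                                     flags$cdr1_conserved_motif,
                                     flags$other_noncanonical)
  list(subtype = subtype, rationale_flags = flags)
}

#' CDR3 length distribution statistics
#'
#' Quartiles use linear interpolation between order statistics (the
#' midpoint-exclusive convention, `quantile type 6`); box-plot whiskers are
#' Q1 - 1.5 IQR and Q3 + 1.5 IQR clamped to observed values, and outliers
#' are exactly the lengths outside the fences.
#'
#' @param lengths integer CDR3 lengths.
#' @param ids optional ids parallel to `lengths` (outlier reporting).
#' @param subtypes optional subtype labels parallel to `lengths`.
#' @return list with `n`, `median`, `q1`, `q3`, `iqr`, `whisker_low`,
#'   `whisker_high`, `outliers` (data.frame id, length) and `by_subtype`
#'   (list of length vectors).
#' @export
cdr3_length_stats <- function(lengths, ids = NULL, subtypes = NULL) {
  lengths <- as.numeric(lengths)
  lengths_ok <- !is.na(lengths)
  if (!any(lengths_ok)) stop("no annotated CDR3 lengths")
  if (is.null(ids)) ids <- as.character(seq_along(lengths))
  x <- lengths[lengths_ok]
  xi <- ids[lengths_ok]
  q <- unname(quantile(x, c(0.25, 0.5, 0.75), type = 6))
  iqr <- q[3L] - q[1L]
  lo_fence <- q[1L] - 1.5 * iqr
  hi_fence <- q[3L] + 1.5 * iqr
  inside <- x >= lo_fence & x <= hi_fence
  outliers <- data.frame(id = xi[!inside], length = x[!inside],
                         stringsAsFactors = FALSE)
  by_subtype <- NULL
  if (!is.null(subtypes))
    by_subtype <- split(x, subtypes[lengths_ok])
  list(n = length(x), median = q[2L], q1 = q[1L], q3 = q[3L], iqr = iqr,
       whisker_low = min(x[inside]), whisker_high = max(x[inside]),
       outliers = outliers, by_subtype = by_subtype)
}

#' Annotate every record of a repertoire table
#'
#' Adds `cdr3`, `cdr3_len`, `subtype`, `n_cys_total` and `n_cys_cdr3`
#' columns; records that cannot be annotated keep NA in those columns and
#' are excluded from downstream CDR3 analyses.
#'
#' @param tab a `repertoire_table`.
#' @inheritParams annotate_regions
#' @inheritParams cysteine_profile
#' @return the annotated `repertoire_table`.
#' @export
annotate_repertoire <- function(tab, fr4_motif = "DGAGT",
                                fr4_max_mismatch = 1L, cdr1_motif = "W",
                                mode = "anchor") {
  validate_repertoire_table(tab)
  rec <- tab$records
  n <- nrow(rec)
  cdr3 <- rep(NA_character_, n)
  subtype <- rep(NA_character_, n)
  n_cys <- rep(NA_integer_, n)
  n_cys_cdr3 <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    ann <- annotate_regions(rec$sequence[i], fr4_motif = fr4_motif,
                            fr4_max_mismatch = fr4_max_mismatch, mode = mode)
    if (inherits(ann, "vnar_unannotatable")) next
    prof <- cysteine_profile(rec$sequence[i], ann, cdr1_motif = cdr1_motif)
    cdr3[i] <- ann$cdr3
    subtype[i] <- classify_subtype(prof)$subtype
    n_cys[i] <- prof$n_total
    n_cys_cdr3[i] <- prof$counts[["CDR3"]]
  }
  rec$cdr3 <- cdr3
  rec$cdr3_len <- ifelse(is.na(cdr3), NA_integer_, nchar(cdr3))
  rec$subtype <- subtype
  rec$n_cys_total <- n_cys
  rec$n_cys_cdr3 <- n_cys_cdr3
  repertoire_table(rec, tab$library_id, tab$total_reads)
}
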