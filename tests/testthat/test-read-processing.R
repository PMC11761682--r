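# Trim -> merge -> flank filter -> translate, against constructed reads and
# brute-force oracles.

.pairs1 <- function(fwd, rev, fq = strrep("I", nchar(fwd)),
                    rq = strrep("I", nchar(rev))) {
  structure(list(id = "r", fwd_seq = fwd, rev_seq = rev,
                 fwd_qual = fq, rev_qual = rq), class = "read_pairs")
}

test_that("quality trimming leaves clean reads unchanged and removes bad tails", {
  clean <- .pairs1("ACGTACGTACGT", "TGCATGCATGCA")
  out <- quality_trim(clean, min_phred = 20)
  expect_identical(out$fwd_seq, clean$fwd_seq)
  expect_identical(out$rev_qual, clean$rev_qual)
  # trailing run of quality-2 ('#') bases is removed by the sliding window
  tail_bad <- .pairs1("ACGTACGTACGT", "TGCATGCATGCA",
                      fq = paste0(strrep("I", 8), strrep("#", 4)))
  out <- quality_trim(tail_bad, min_phred = 20)
  expect_identical(out$fwd_seq, "ACGTACGT")
  expect_identical(nchar(out$fwd_qual), 8L)
})

test_that("a read ending in the adapter loses the adapter suffix", {
  p <- .pairs1(paste0("ACGTACGTAC", "AGATCGGAAG"), "TGCATGCATGCA")
  out <- quality_trim(p, min_phred = 0, adapter = "AGATCGGAAGAGC")
  expect_identical(out$fwd_seq, "ACGTACGTAC")
  # one mismatch in the adapter still triggers removal
  p2 <- .pairs1(paste0("ACGTACGTAC", "AGATCGGTAG"), "TGCATGCATGCA")
  out2 <- quality_trim(p2, min_phred = 0, adapter = "AGATCGGAAGAGC")
  expect_identical(out2$fwd_seq, "ACGTACGTAC")
})

test_that("merge_pair reproduces the constructed exact-overlap case", {
  # fwd AAACCCGG, rev AAACCCGG (revcomp CCGGGTTT): overlap 4, template
  # AAACCCGGGTTT
  amp <- merge_pair("r", "AAACCCGG", "AAACCCGG", min_overlap_nt = 4)
  expect_s3_class(amp, "amplicon")
  expect_identical(amp$seq, "AAACCCGGGTTT")
  expect_identical(amp$overlap_len, 4L)
  expect_identical(amp$overlap_mismatches, 0L)
})

test_that("pairs without a qualifying overlap fail to merge", {
  out <- merge_pair("r", "AAAAAAAA", "CCCCCCCC", min_overlap_nt = 4)
  expect_s3_class(out, "vnar_merge_failure")
})

test_that("error-free reads from random templates reconstruct the template and match the oracle", {
  set.seed(7)
  for (i in 1:60) {
    tpl_len <- sample(16:30, 1)
    read_len <- sample(12:15, 1)
    if (2 * read_len - 4 < tpl_len) read_len <- ceiling((tpl_len + 4) / 2)
    tpl <- paste(sample(c("A", "C", "G", "T"), tpl_len, TRUE), collapse = "")
    fwd <- substr(tpl, 1, read_len)
    rev_rc <- substr(tpl, tpl_len - read_len + 1, tpl_len)
    rev <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(rev_rc)))
    amp <- merge_pair("r", fwd, rev, min_overlap_nt = 4)
    orc <- oracle_merge(fwd, rev_rc, 4, 0.25)
    expect_identical(amp$seq, orc$seq)
    expect_identical(amp$overlap_len, orc$overlap)
    if (orc$overlap == 2 * read_len - tpl_len)  # unique true overlap chosen
      expect_identical(amp$seq, tpl)
  }
})

test_that("flank location returns the insert between the conserved anchors", {
  flank5 <- pipeline_config()$flank5
  flank3 <- pipeline_config()$flank3
  seq <- paste0("NNN", flank5, "ATGGCC", flank3)
  loc <- locate_flanks(seq, flank5, flank3)
  expect_identical(loc$start, 3L + nchar(flank5))
  expect_identical(loc$end, loc$start + 6L)
  expect_identical(extract_insert(loc), "ATGGCC")
  expect_false(loc$revcomp)
})

test_that("flank location is orientation-invariant and reports the failing flank", {
  flank5 <- pipeline_config()$flank5
  flank3 <- pipeline_config()$flank3
  seq <- paste0("ACGT", flank5, "ATGGCCAAATTT", flank3, "GG")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  loc <- locate_flanks(seq, flank5, flank3)
  loc_rc <- locate_flanks(rc, flank5, flank3)
  expect_true(loc_rc$revcomp)
  expect_identical(extract_insert(loc_rc), extract_insert(loc))
  miss5 <- locate_flanks("ACGTACGTACGT", flank5, flank3)
  expect_s3_class(miss5, "vnar_flank_notfound")
  expect_identical(miss5$reason, "flank5")
  miss3 <- locate_flanks(paste0(flank5, "ATGGCC"), flank5, flank3)
  expect_identical(miss3$reason, "flank3")
})

test_that("an empty 3' flank extends the insert to the end of the sequence", {
  flank5 <- pipeline_config()$flank5
  loc <- locate_flanks(paste0(flank5, "ATGGCC"), flank5, flank3 = "")
  expect_identical(extract_insert(loc), "ATGGCC")
})

test_that("insert translation enforces frame, stops, ambiguity and length", {
  ok <- translate_insert("ATGGCC", min_len = 1L, max_len = 10L)
  expect_identical(ok$protein, "MA")
  # TTG at position 1 is not special-cased as an initiator codon
  expect_identical(translate_insert("TTGGCC", min_len = 1L, max_len = 10L)$protein,
                   "LA")
  expect_identical(translate_insert("ATGTAAGCC", min_len = 1L, max_len = 10L)$reason,
                   "internal_stop")
  expect_identical(translate_insert("ATGGC", min_len = 1L, max_len = 10L)$reason,
                   "frame")
  expect_identical(translate_insert("ATGNCC", min_len = 1L, max_len = 10L)$reason,
                   "ambiguous")
  expect_identical(translate_insert("ATGGCC", min_len = 5L, max_len = 10L)$reason,
                   "length")
  expect_identical(translate_insert("ATGTAA", min_len = 1L, max_len = 10L)$reason,
                   "terminal_stop")
})

test_that("process_library counts survivors per stage and drops stop-codon inserts", {
  cfg <- pipeline_config(min_protein_len_aa = 2L, max_protein_len_aa = 50L)
  proteins <- random_proteins(15, 12, alphabet = c("A", "D", "G", "K", "S", "T"))
  inserts <- vapply(proteins, aa_to_nt, character(1), USE.NAMES = FALSE)
  # 5 additional inserts with an internal stop codon
  stopped <- vapply(random_proteins(5, 12), aa_to_nt, character(1),
                    USE.NAMES = FALSE)
  substr(stopped, 13, 15) <- "TAA"
  amps <- paste0(cfg$flank5, c(inserts, stopped), cfg$flank3)
  read_len <- 80L
  fwd <- substr(amps, 1, read_len)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(amps)))
  rev <- substr(rc, 1, read_len)
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  ids <- sprintf("m%02d", seq_along(amps))
  write_tiny_fastq(f1, paste0(ids, "/1"), fwd)
  write_tiny_fastq(f2, paste0(ids, "/2"), rev)
  res <- process_library(f1, f2, cfg)
  qc <- res$qc
  expect_identical(qc$n_pairs_in, 20L)
  expect_identical(qc$n_merged, 20L)
  expect_identical(qc$n_flank_pass, 20L)
  expect_identical(qc$n_no_stop, qc$n_in_frame - 5L)
  expect_identical(qc$n_len_pass, 15L)
  expect_setequal(res$vnars$protein, proteins)
})

test_that("QC counters are monotone non-increasing on arbitrary random input", {
  set.seed(11)
  cfg <- pipeline_config(min_protein_len_aa = 2L, max_protein_len_aa = 50L)
  for (i in 1:5) {
    n <- 30L
    fwd <- vapply(seq_len(n), function(j)
      paste(sample(c("A", "C", "G", "T"), sample(40:120, 1), TRUE),
            collapse = ""), character(1))
    rev <- vapply(seq_len(n), function(j)
      paste(sample(c("A", "C", "G", "T"), sample(40:120, 1), TRUE),
            collapse = ""), character(1))
    f1 <- withr::local_tempfile(fileext = ".fastq")
    f2 <- withr::local_tempfile(fileext = ".fastq")
    write_tiny_fastq(f1, paste0("r", 1:n, "/1"), fwd)
    write_tiny_fastq(f2, paste0("r", 1:n, "/2"), rev)
    qc <- process_library(f1, f2, cfg)$qc
    counts <- unlist(unclass(qc))
    expect_true(all(diff(counts) <= 0))
  }
})
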