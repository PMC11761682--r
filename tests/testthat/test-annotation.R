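# Region delineation, cysteine profiling, subtype calling, CDR3 statistics.

test_that("region annotation agrees with the generator's ground truth", {
  set.seed(21)
  for (i in 1:200) {
    subtype <- sample(c("I", "II", "III", "IV"), 1)
    len <- sample(5:30, 1)
    sc <- build_scaffold(subtype, len)
    ann <- annotate_regions(sc$protein)
    expect_false(inherits(ann, "vnar_unannotatable"))
    expect_identical(ann$regions, sc$regions)
    expect_identical(ann$canonical_cys1, sc$canonical_cys1)
    expect_identical(ann$canonical_cys2, sc$canonical_cys2)
    expect_identical(ann$cdr3, sc$cdr3)
  }
})

test_that("region intervals tile the protein in order", {
  set.seed(4)
  sc <- build_scaffold("II", 14)
  ann <- annotate_regions(sc$protein)
  b <- unlist(ann$regions)
  starts <- b[seq(1, 17, 2)]
  ends <- b[seq(2, 18, 2)]
  expect_true(all(ends[-9] == starts[-1]))  # contiguous tiling
  expect_identical(unname(ends[9]), nchar(sc$protein))
  expect_lt(ann$canonical_cys1, ann$canonical_cys2)
  expect_gt(ann$regions$CDR3[1], ann$canonical_cys2)
})

test_that("unannotatable sequences report the failing anchor", {
  no_cys <- annotate_regions(strrep("A", 100))
  expect_s3_class(no_cys, "vnar_unannotatable")
  expect_identical(no_cys$reason, "no_canonical_cys")
  set.seed(9)
  sc <- build_scaffold("IV", 12)
  broken <- sub("DGAGT", "QQQQQ", sc$protein, fixed = TRUE)
  no_fr4 <- annotate_regions(broken)
  expect_identical(no_fr4$reason, "no_fr4")
  # one motif mismatch is tolerated
  one_mm <- sub("DGAGT", "DGTGT", sc$protein, fixed = TRUE)
  expect_false(inherits(annotate_regions(one_mm), "vnar_unannotatable"))
})

test_that("cysteine buckets cover every cysteine exactly once", {
  set.seed(2)
  sc <- build_scaffold("IV", 10)
  ann <- annotate_regions(sc$protein)
  prof <- cysteine_profile(sc$protein, ann)
  expect_identical(prof$n_total, 2L)                # only the canonical pair
  expect_true(prof$has_canonical_pair)
  expect_identical(sum(prof$noncanonical), 0L)
  # one extra C inside CDR3
  p2 <- sc$protein
  substr(p2, ann$regions$CDR3[1] + 3, ann$regions$CDR3[1] + 3) <- "C"
  prof2 <- cysteine_profile(p2, annotate_regions(p2))
  expect_identical(unname(prof2$counts["CDR3"]), 1L)
  # property: buckets sum to the total over random lineage mutants
  for (i in 1:40) {
    st <- sample(c("I", "II", "III", "IV"), 1)
    sc <- build_scaffold(st, sample(5:25, 1))
    variants <- expand_lineage(sc, 25, 0.02)
    for (v in variants[sample.int(25, 5)]) {
      pr <- cysteine_profile(v, annotate_regions(v))
      expect_identical(sum(pr$counts), pr$n_total)
      expect_identical(pr$n_total,
                       lengths(regmatches(v, gregexpr("C", v, fixed = TRUE))))
    }
  }
})

test_that("subtype calls follow the cysteine architecture definitions", {
  expect_identical(subtype_from_flags(0L, 1L, 1L, 2L, FALSE), "I")
  expect_identical(subtype_from_flags(1L, 0L, 0L, 1L, FALSE), "II")
  expect_identical(subtype_from_flags(1L, 0L, 0L, 1L, TRUE), "III")
  expect_identical(subtype_from_flags(0L, 0L, 0L, 0L, FALSE), "IV")
  # odd CDR3 cysteine count with framework cysteines is not forced to Type I
  expect_identical(subtype_from_flags(0L, 1L, 1L, 3L, FALSE), "unclassified")
  expect_identical(subtype_from_flags(0L, 0L, 0L, 0L, FALSE, 1L), "unclassified")
})

test_that("the subtype rule table is exhaustive and mutually exclusive", {
  grid <- expand.grid(cdr1 = 0:2, fr2 = 0:2, fr4 = 0:2, cdr3 = 0:4,
                      motif = c(TRUE, FALSE), other = 0:1)
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    call <- subtype_from_flags(g$cdr1, g$fr2, g$fr4, g$cdr3, g$motif, g$other)
    expect_true(call %in% c("I", "II", "III", "IV", "unclassified"))
    # re-derive each rule independently and check at most one fires
    is_I <- g$fr2 >= 1 && g$fr4 >= 1 && g$cdr3 >= 2 && g$cdr3 %% 2 == 0
    is_II <- g$cdr1 >= 1 && g$cdr3 >= 1 && g$fr2 == 0 && g$fr4 == 0 && !g$motif
    is_III <- g$cdr1 >= 1 && g$cdr3 >= 1 && g$fr2 == 0 && g$fr4 == 0 && g$motif
    is_IV <- g$cdr1 == 0 && g$fr2 == 0 && g$fr4 == 0 && g$cdr3 == 0 &&
      g$other == 0
    expect_lte(sum(is_I, is_II, is_III, is_IV), 1L)
    expected <- if (is_I) "I" else if (is_II) "II" else if (is_III) "III"
                else if (is_IV) "IV" else "unclassified"
    expect_identical(call, expected)
  }
})

test_that("a sequence without the canonical pair is unclassified", {
  set.seed(6)
  sc <- build_scaffold("II", 10)
  ann <- annotate_regions(sc$protein)
  prof <- cysteine_profile(sc$protein, ann)
  prof$has_canonical_pair <- FALSE
  expect_identical(classify_subtype(prof)$subtype, "unclassified")
})

test_that("CDR3 length statistics use midpoint-exclusive quartiles and IQR fences", {
  s <- cdr3_length_stats(c(10, 12, 14, 16, 18))
  expect_equal(s$median, 14)
  expect_equal(s$q1, 11)
  expect_equal(s$q3, 17)
  expect_identical(nrow(s$outliers), 0L)

  eq <- cdr3_length_stats(rep(15, 10))
  expect_equal(eq$iqr, 0)
  expect_identical(nrow(eq$outliers), 0L)
  expect_equal(eq$whisker_low, 15)
  expect_equal(eq$whisker_high, 15)

  lens <- c(rep(10:20, each = 4), 90)
  ids <- c(sprintf("n%02d", 1:44), "ultra")
  out <- cdr3_length_stats(lens, ids = ids)
  expect_identical(out$outliers$id, "ultra")
  expect_equal(out$outliers$length, 90)
  expect_error(cdr3_length_stats(NA_integer_), "no annotated")
})

test_that("repertoire annotation adds CDR3 and subtype columns", {
  set.seed(31)
  scaffolds <- lapply(1:20, function(i)
    build_scaffold(sample(c("I", "II", "III", "IV"), 1), sample(8:20, 1)))
  tab <- dereplicate(vapply(scaffolds, `[[`, character(1), "protein"), "lib")
  ann <- annotate_repertoire(tab)
  expect_true(all(!is.na(ann$records$cdr3)))
  expect_identical(ann$records$cdr3_len, nchar(ann$records$cdr3))
  truth <- setNames(vapply(scaffolds, `[[`, character(1), "subtype"),
                    vapply(scaffolds, `[[`, character(1), "protein"))
  expect_identical(ann$records$subtype,
                   unname(truth[ann$records$sequence]))
})
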