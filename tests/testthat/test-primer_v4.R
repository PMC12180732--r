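test_that("planted primer sites are found with the expected mismatches", {
  set.seed(11)
  # concrete realisation of the forward primer: S->C, Y->T
  site <- "CCAGCACCTGCGGTAATTCC"
  pad1 <- paste(sample(c("A", "C", "G", "T"), 100, TRUE), collapse = "")
  pad2 <- paste(sample(c("A", "C", "G", "T"), 100, TRUE), collapse = "")
  seq <- paste0(pad1, site, pad2)
  hits <- find_primer_sites(seq, tar_euk_primers()$fwd, 0)
  hit0 <- hits[hits$mismatches == 0, ]
  expect_equal(hit0$start, 100L)          # 0-based
  expect_equal(hit0$end, 120L)            # exclusive

  sub <- seq
  substr(sub, 105, 105) <- "T"            # C -> T inside the site
  h1 <- find_primer_sites(sub, tar_euk_primers()$fwd, 1)
  expect_true(any(h1$start == 100L & h1$mismatches == 1L))
  h0 <- find_primer_sites(sub, tar_euk_primers()$fwd, 0)
  expect_false(any(h0$start == 100L))
})

test_that("primer longer than the sequence yields an empty hit list", {
  h <- find_primer_sites("ACGT", tar_euk_primers()$fwd, 2)
  expect_equal(nrow(h), 0L)
})

test_that("hit finding agrees with a brute-force sliding-window oracle", {
  set.seed(23)
  fwd <- primer("f", "ACGRNT", "forward")
  for (rep in 1:20) {
    seq <- paste(sample(c("A", "C", "G", "T"),
                        sample(20:60, 1), TRUE), collapse = "")
    for (mm in 0:2) {
      got <- find_primer_sites(seq, fwd, mm)
      want <- oracle_scan(seq, "ACGRNT", mm)
      expect_setequal(got$start, want$start)
      expect_equal(got$mismatches[order(got$start)],
                   want$mismatches[order(want$start)])
    }
  }
})

test_that("reverse primers are also scanned as their reverse complement", {
  rev <- tar_euk_primers()$rev
  plus_site <- radvar:::concretize(rev$sequence)  # as-given orientation
  rc_site <- revcomp(plus_site)
  seq <- paste0(strrep("A", 30), rc_site, strrep("G", 30))
  h <- find_primer_sites(seq, rev, 0)
  expect_true(any(h$strand_matched == "reverse-complement" & h$start == 30))
})

test_that("V4 extraction recovers a planted insert and handles geometry", {
  tm <- radvar:::make_template(1450L, 440L)
  v4 <- extract_v4(tm$seq)
  expect_equal(nchar(v4), 440L)
  expect_equal(v4, substr(tm$seq, tm$v4_window["start"],
                          tm$v4_window["start"] + 439L))
  # case and flanking padding invariance
  expect_equal(extract_v4(paste0("acgt", tolower(tm$seq), "ttag")), v4)
  # missing reverse site -> absent
  truncated <- substr(tm$seq, 1, 700)
  expect_true(is.na(extract_v4(truncated)))
  # reverse site upstream of forward site -> absent
  prm <- tar_euk_primers()
  fsite <- radvar:::concretize(prm$fwd$sequence)
  rsite <- revcomp(radvar:::concretize(prm$rev$sequence))
  bad <- paste0(strrep("A", 20), rsite, strrep("C", 50), fsite,
                strrep("G", 20))
  expect_true(is.na(extract_v4(bad)))
  # include_primers widens the region by both primer lengths
  withp <- extract_v4(tm$seq, include_primers = TRUE)
  expect_equal(nchar(withp), 440L + 20L + 18L)
})

test_that("identical-V4 merging sums counts and conserves read mass", {
  tm <- radvar:::make_template(1450L, 440L)
  s1 <- tm$seq
  s2 <- tm$seq; substr(s2, 10, 10) <- chartr("ACGT", "GTAC",
                                             substr(s2, 10, 10))
  s3 <- tm$seq
  mid <- tm$v4_window["start"] + 100L
  substr(s3, mid, mid) <- chartr("ACGT", "GTAC", substr(s3, mid, mid))
  counts <- matrix(c(10L, 5L, 7L), 3, 1,
                   dimnames = list(c("a1", "a2", "a3"), "s1"))
  ch <- occurrence_chart(counts,
                         sequence = c(a1 = s1, a2 = s2, a3 = s3))
  tab <- merge_by_v4(ch)
  expect_equal(nrow(tab$counts), 2L)        # a1+a2 merged, a3 distinct
  expect_equal(sum(tab$counts), sum(ch$counts))
  prov <- attr(tab, "provenance")
  merged_row <- names(prov)[vapply(prov, length, integer(1)) == 2]
  expect_setequal(prov[[merged_row]], c("a1", "a2"))
  expect_equal(unname(tab$counts[merged_row, "s1"]), 15L)
  expect_true(tab$merged[[merged_row]])
  # ASVs without an extractable V4 are excluded and reported
  ch2 <- occurrence_chart(
    rbind(counts, matrix(4L, 1, 1, dimnames = list("a4", "s1"))),
    sequence = c(a1 = s1, a2 = s2, a3 = s3, a4 = strrep("ACGT", 100)))
  tab2 <- merge_by_v4(ch2)
  expect_equal(attr(tab2, "no_v4"), "a4")
  expect_equal(sum(tab2$counts), sum(ch$counts))
})

test_that("three distinct V4s stay three rows", {
  tm <- radvar:::make_template(1450L, 440L)
  seqs <- vapply(1:3, function(i) {
    s <- tm$seq
    pos <- tm$v4_window["start"] + 50L * i
    substr(s, pos, pos) <- chartr("ACGT", "GTAC", substr(s, pos, pos))
    s
  }, character(1))
  names(seqs) <- c("x1", "x2", "x3")
  counts <- matrix(c(5L, 6L, 7L), 3, 1,
                   dimnames = list(names(seqs), "s1"))
  tab <- merge_by_v4(occurrence_chart(counts, sequence = seqs))
  expect_equal(nrow(tab$counts), 3L)
  expect_false(any(tab$merged))
})

test_that("shipped primer sets are valid IUPAC and well-formed", {
  for (set in c("nassellaria", "spumellaria", "collodaria")) {
    p <- polycystine_primers(set)
    expect_s3_class(p$fwd, "primer")
    expect_equal(p$rev$orientation, "reverse")
  }
  expect_error(primer("bad", "ACGTX"), "IUPAC")
})
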