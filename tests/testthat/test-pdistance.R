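test_that("alignment matches the exhaustive recursive oracle on short pairs", {
  set.seed(31)
  expect_equal(align_pair("ACGT", "ACGT")$score, 4)
  expect_equal(align_pair("ACGT", "AGT")$score, 1)   # 3 matches, 1 gap
  expect_error(align_pair("", "ACGT"), "non-empty")
  for (rep in 1:30) {
    a <- paste(sample(c("A", "C", "G", "T"), sample(1:8, 1), TRUE),
               collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), sample(1:8, 1), TRUE),
               collapse = "")
    al <- align_pair(a, b)
    expect_equal(al$score, oracle_align_score(a, b),
                 info = paste(a, b))
    # returned strings really realise the returned score
    xa <- strsplit(al$a, "")[[1]]; xb <- strsplit(al$b, "")[[1]]
    expect_equal(length(xa), length(xb))
    expect_equal(gsub("-", "", al$a), a)
    expect_equal(gsub("-", "", al$b), b)
    sc <- sum(ifelse(xa == "-" | xb == "-", -2, ifelse(xa == xb, 1, -1)))
    expect_equal(sc, al$score)
  }
})

test_that("p-distance handles gaps, identity and degenerate input", {
  expect_equal(p_distance("ACGA", "ACGT"), 0.25)
  expect_equal(p_distance("AC-T", "ACGT"), 0)        # 3 retained sites
  expect_equal(p_distance("ACGT", "ACGT"), 0)
  expect_error(p_distance("ACG", "ACGT"), "equal length")
  expect_error(p_distance("--", "AA"), "zero retained")
  expect_error(p_distance("A-GT", "AC-T", deletion = "complete"), "gap")
})

test_that("p-distance properties hold on random aligned sets", {
  set.seed(7)
  for (rep in 1:10) {
    n <- sample(3:6, 1)
    len <- sample(20:40, 1)
    seqs <- vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "T", "-"), len, TRUE,
                   prob = c(.24, .24, .24, .24, .04)), collapse = ""),
      character(1))
    names(seqs) <- paste0("q", seq_len(n))
    d <- p_distance_matrix(seqs)
    expect_true(all(d[is.finite(d)] >= 0 & d[is.finite(d)] <= 1))
    expect_equal(d, t(d))
    # agreement with the scalar implementation
    expect_equal(d["q1", "q2"], p_distance(seqs["q1"], seqs["q2"]))
    expect_equal(d["q2", "q3"], p_distance(seqs["q2"], seqs["q3"]))
  }
})

test_that("group means follow the hand-computed examples", {
  # two sequences at p 0.10: ten sites, one difference
  a <- "ACGTACGTAC"; b <- "ACGTACGTAG"
  expect_equal(group_mean_within(c(x = a, y = b))$mean_p, 0.1)
  # pairwise {0, 0.1, 0.1} -> 0.0667
  g <- c(x = a, y = a, z = b)
  expect_equal(round(group_mean_within(g)$mean_p, 4), 0.0667)
  expect_equal(group_mean_within(g)$n_pairs, 3L)
  # singleton -> absent, not an error
  expect_true(is.na(group_mean_within(c(x = a))$mean_p))
  # identical sequences -> 0 for any group size
  expect_equal(group_mean_within(c(a, a, a, a) |>
                                   stats::setNames(paste0("i", 1:4)))$mean_p,
               0)
})

test_that("between-group means are symmetric and reduce to pair distance", {
  a <- "ACGTACGTAC"; b <- "ACGTACGTAG"; c <- "TTGTACGTAG"
  expect_equal(group_mean_between(a, b)$mean_p, p_distance(a, b))
  ab_c <- group_mean_between(c(a, b), c)
  c_ab <- group_mean_between(c, c(a, b))
  expect_equal(ab_c$mean_p, c_ab$mean_p)
  expect_equal(ab_c$n_pairs, 2L)
})

test_that("the hierarchy driver groups specimens and species correctly", {
  # two morphospecies, two specimens each, one order; sequences built so
  # intragenomic < intraspecies < interspecies by construction
  base <- strrep("ACGT", 25)                 # 100 nt
  mut <- function(s, pos) {
    for (p in pos) substr(s, p, p) <- chartr("ACGT", "GTAC",
                                             substr(s, p, p))
    s
  }
  seqs <- c(h1 = base, h2 = mut(base, 1),                 # specimen 1
            h3 = mut(base, 11), h4 = mut(base, c(11, 2)), # specimen 2
            h5 = mut(base, 51:60), h6 = mut(base, c(51:60, 3)))
  counts <- matrix(0L, 6, 3,
                   dimnames = list(names(seqs), c("s1", "s2", "s3")))
  counts[c("h1", "h2"), "s1"] <- c(50L, 10L)
  counts[c("h3", "h4"), "s2"] <- c(40L, 10L)
  counts[c("h5", "h6"), "s3"] <- c(60L, 10L)
  ch <- occurrence_chart(counts, sequence = seqs)
  meta <- data.frame(
    specimen_id = c("s1", "s2", "s3"),
    morphotaxon = c("Pterocorys zancleus", "Pterocorys zancleus",
                    "Pterocanium praetextum"),
    morph_rank = "species", order = "Nassellaria",
    family = "Pterocorythidae", relaxed_filter = FALSE)
  h <- pdistance_hierarchy(ch, meta)
  intra_g <- h[h$level == "intragenomic", ]
  expect_equal(intra_g$mean_p[intra_g$group_a == "s1"], 0.01)
  intra_s <- h[h$level == "intraspecies", ]
  # pooled zancleus ASVs h1..h4: pairs (.01,.01,.02,.02,.03,.01) -> mean
  expect_equal(intra_s$mean_p[intra_s$group_a == "Pterocorys zancleus"],
               mean(c(.01, .01, .02, .02, .03, .01)))
  inter <- h[h$level == "interspecies", ]
  expect_equal(nrow(inter), 1L)
  expect_gt(inter$mean_p, max(intra_s$mean_p, na.rm = TRUE))
})
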