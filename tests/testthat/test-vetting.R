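lin <- function(order, family)
  sprintf("Eukaryota;Rhizaria;Radiolaria;Polycystinea;%s;%s;G;G_sp.",
          order, family)

# 3 ASVs x 2 specimens: A1 on-family, A2 off-family, A3 on-family low count
vet_fixture <- function() {
  counts <- matrix(c(10L, 8L,
                     6L, 0L,
                     2L, 2L), nrow = 3, byrow = TRUE,
                   dimnames = list(c("A1", "A2", "A3"), c("s1", "s2")))
  ch <- occurrence_chart(
    counts,
    sequence = c(A1 = "ACGTACGT", A2 = "ACGTACGA", A3 = "ACGTACCC"),
    taxon = c(A1 = lin("Nassellaria", "Pterocorythidae"),
              A2 = lin("Collodaria", "Sphaerozoidae"),
              A3 = lin("Nassellaria", "Pterocorythidae")),
    confidence = c(A1 = 0.99, A2 = 0.95, A3 = 0.8))
  list(chart = ch, meta = tiny_meta(c("s1", "s2")))
}

test_that("family mismatches are zeroed and logged with both families", {
  fx <- vet_fixture()
  res <- filter_taxonomy_consistency(fx$chart, fx$meta)
  expect_equal(res$chart$counts["A2", "s1"], 0L)
  expect_equal(res$chart$counts["A1", "s1"], 10L)   # exact match retained
  tax <- res$report$removed_by_taxonomy
  expect_equal(nrow(tax), 1L)
  expect_equal(tax$assigned_family, "sphaerozoidae")
  expect_equal(tax$expected_family, "pterocorythidae")
})

test_that("relaxed specimens accept any polycystine assignment", {
  fx <- vet_fixture()
  fx$meta$relaxed_filter <- TRUE
  fx$meta$family <- "unknown"
  fx$meta$morph_rank <- "indeterminate"
  res <- filter_taxonomy_consistency(fx$chart, fx$meta)
  expect_equal(res$chart$counts["A2", "s1"], 6L)    # Collodaria: permitted
  # a non-polycystine ASV is still removed
  ch2 <- fx$chart
  ch2$taxon["A2"] <- "Eukaryota;Alveolata;Dinoflagellata;Dinophyceae;Gymnodiniales;Gymnodiniaceae;Gyrodinium;Gyrodinium_sp."
  res2 <- filter_taxonomy_consistency(ch2, fx$meta)
  expect_equal(res2$chart$counts["A2", "s1"], 0L)
})

test_that("specimens without metadata are an error naming them", {
  fx <- vet_fixture()
  expect_error(
    filter_taxonomy_consistency(fx$chart, fx$meta[1, , drop = FALSE]),
    "s2")
})

test_that("low-confidence ASVs are removed everywhere", {
  fx <- vet_fixture()
  fx$chart$confidence["A1"] <- 0.1
  res <- filter_taxonomy_consistency(fx$chart, fx$meta)
  expect_false("A1" %in% asv_ids(res$chart))
  expect_equal(res$report$removed_low_confidence$asv_id, "A1")
})

test_that("count thresholds: presence, global ASV rule, specimen rule", {
  # cell of 2 zeroed, cell of 3 kept (A2 keeps both specimens above the
  # 5-read specimen rule so the presence rule is observable in isolation)
  counts <- matrix(c(3L, 2L,
                     9L, 9L), 2, 2, byrow = TRUE,
                   dimnames = list(c("A1", "A2"), c("s1", "s2")))
  ch <- occurrence_chart(counts, sequence = c(A1 = "ACGT", A2 = "GGTT"))
  res <- apply_count_thresholds(ch)
  expect_equal(unname(res$chart$counts["A1", ]), c(3L, 0L))

  # ASV with {2,2,2} removed globally (both rules, applied brute-force)
  counts <- matrix(c(2L, 2L, 2L,
                     9L, 9L, 9L), 2, 3, byrow = TRUE,
                   dimnames = list(c("B1", "B2"), c("s1", "s2", "s3")))
  ch <- occurrence_chart(counts, sequence = c(B1 = "AA", B2 = "CC"))
  res <- apply_count_thresholds(ch)
  expect_equal(asv_ids(res$chart), "B2")
  expect_equal(res$report$removed_asvs_global, "B1")

  # specimen with surviving total 4 dropped and logged
  counts <- matrix(c(4L, 9L), 1, 2, dimnames = list("C1", c("s1", "s2")))
  ch <- occurrence_chart(counts, sequence = c(C1 = "AA"))
  res <- apply_count_thresholds(ch)
  expect_equal(specimen_ids(res$chart), "s2")
  expect_equal(res$report$removed_specimens$specimen_id, "s1")
  expect_equal(res$report$removed_specimens$surviving_reads, 4L)
})

test_that("vet_dataset is idempotent and reconciles its mass balance", {
  fx <- vet_fixture()
  v1 <- vet_dataset(fx$chart, fx$meta)
  v2 <- vet_dataset(v1$chart, fx$meta)
  expect_true(charts_equal(v1$chart, v2$chart))

  m <- v1$report$mass_balance
  expect_equal(m$input,
               m$retained + m$low_confidence + m$taxonomy + m$presence +
                 m$global_asvs + m$specimens + m$strict_extra)
})

test_that("strict mode reports/removes ASVs orphaned by specimen removal", {
  # B's only qualifying reads sit in s1, which fails the specimen rule
  counts <- matrix(c(2L, 9L,
                     3L, 0L), 2, 2, byrow = TRUE,
                   dimnames = list(c("A", "B"), c("s1", "s2")))
  ch <- occurrence_chart(counts, sequence = c(A = "AA", B = "CC"),
                         taxon = stats::setNames(
                           rep(lin("Nassellaria", "Pterocorythidae"), 2),
                           c("A", "B")),
                         confidence = c(A = 1, B = 1))
  meta <- tiny_meta(c("s1", "s2"))
  v <- vet_dataset(ch, meta)                       # default mode
  expect_false("B" %in% asv_ids(v$chart))          # all-zero row dropped
  expect_true("B" %in% v$report$removed_with_specimens)
  v2 <- vet_dataset(v$chart, meta)
  expect_true(charts_equal(v$chart, v2$chart))     # still idempotent
})

test_that("raising thresholds never increases what is retained", {
  ch <- random_chart(n_asv = 10, n_spec = 6, seed = 42)
  ch$taxon[] <- lin("Spumellaria", "Spongodiscidae")
  meta <- data.frame(specimen_id = specimen_ids(ch),
                     morphotaxon = "Dictyocoryne profunda",
                     morph_rank = "species", order = "Spumellaria",
                     family = "Spongodiscidae", relaxed_filter = FALSE)
  base <- vet_dataset(ch, meta)$chart
  for (cfg in list(vetting_config(min_reads_presence = 5L),
                   vetting_config(min_specimen_reads = 12L),
                   vetting_config(min_asv_reads_somewhere = 6L),
                   vetting_config(min_confidence = 0.8))) {
    v <- vet_dataset(ch, meta, cfg)$chart
    expect_lte(nrow(v$counts), nrow(base$counts))
    expect_lte(ncol(v$counts), ncol(base$counts))
  }
})
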