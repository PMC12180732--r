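test_that("configs validate their feasibility invariants", {
  op <- radiolarian_order_params()
  op$p_intraspecies[1] <- 0.5               # > interspecies: infeasible
  expect_error(synthetic_config(order_params = op), "infeasible")
  sp <- radiolarian_species_table()
  sp$n_subgroups[sp$category == "NO_UNIVERSAL_ASV"][1] <- 1
  expect_error(synthetic_config(species = sp), "mismatch")
})

test_that("truth construction is deterministic and category-consistent", {
  cfg <- small_config(seed = 42)
  t1 <- build_truth(cfg)
  t2 <- build_truth(cfg)
  expect_identical(t1$specimens, t2$specimens)

  # one subgroup + no flips => shared dominant haplotype by construction
  sp <- data.frame(morphospecies = "Pterocanium praetextum",
                   order = "Nassellaria", family = "Pterocorythidae",
                   n_specimens = 3, n_subgroups = 1,
                   category = "SHARED_DOMINANT", haplotypes = 3)
  tr <- build_truth(synthetic_config(seed = 1, species = sp))
  doms <- vapply(tr$specimens, function(s) s$haplotypes[1], character(1))
  expect_equal(length(unique(doms)), 1L)

  # two disjoint subgroups => no haplotype shared across subgroups
  sp$n_subgroups <- 2; sp$category <- "NO_UNIVERSAL_ASV"
  sp$n_specimens <- 4
  tr2 <- build_truth(synthetic_config(seed = 1, species = sp))
  by_sub <- split(lapply(tr2$specimens, `[[`, "haplotypes"),
                  vapply(tr2$specimens, `[[`, integer(1), "subgroup"))
  h1 <- unique(unlist(by_sub[[1]])); h2 <- unique(unlist(by_sub[[2]]))
  expect_equal(length(intersect(h1, h2)), 0L)
})

test_that("sampled charts are reproducible bit-for-bit under one seed", {
  cfg <- small_config(seed = 9)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$chart$counts, d2$chart$counts)
  expect_identical(d1$chart$sequence, d2$chart$sequence)
  d3 <- generate_dataset(small_config(seed = 10))
  expect_false(identical(d1$chart$counts, d3$chart$counts))
})

test_that("read allocation tracks the haplotype frequencies", {
  # 100 independent genomes with two haplotypes at (0.9, 0.1), depth 10000:
  # mean rank-1 share within 3 binomial standard errors of 0.9
  sp <- data.frame(morphospecies = "Collosphaera huxleyi",
                   order = "Collodaria", family = "Collosphaeridae",
                   n_specimens = 100, n_subgroups = 1,
                   category = "SHARED_DOMINANT", haplotypes = 0)
  op <- radiolarian_order_params()
  op$dominance_decay[op$order == "Collodaria"] <- 2 - 1 / 0.9  # w1 = 0.9
  cfg <- synthetic_config(seed = 12, species = sp, order_params = op,
                          depth_mean = 10000, depth_sdlog = 0,
                          noise_rate = 0, contamination_rate = 0)
  ds <- generate_dataset(cfg)
  shares <- vapply(specimen_ids(ds$chart), function(s)
    dominant_set(ds$chart, s)$dominant_share, numeric(1))
  se <- sqrt(0.9 * 0.1 / 10000) / sqrt(100)
  expect_lt(abs(mean(shares) - 0.9), 3 * se + 1e-4)
})

test_that("injections are bookkept and empty configs degrade gracefully", {
  cfg <- small_config(seed = 4)
  ds <- generate_dataset(cfg)
  inj <- attr(ds$chart, "injections")
  expect_true(all(c("noise", "contaminant") %in% inj$kind))
  expect_true(all(inj$count[inj$kind == "noise"] <= 2))
  expect_true(all(inj$asv_id %in% asv_ids(ds$chart)))

  empty <- synthetic_config(
    seed = 1, species = radiolarian_species_table()[0, ])
  de <- generate_dataset(empty)
  expect_equal(dim(de$chart$counts), c(0L, 0L))
  expect_equal(nrow(de$meta), 0L)
})

test_that("zero noise and contamination vet clean at high depth", {
  cfg <- small_config(seed = 8, noise_rate = 0, contamination_rate = 0)
  cfg$depth_mean <- 50000
  # two haplotypes per genome: every rank is far above the presence
  # threshold at this depth, so nothing genuine can be lost
  cfg$species$haplotypes <- 0
  ds <- generate_dataset(cfg)
  v <- vet_dataset(ds$chart, ds$meta)
  expect_equal(nrow(v$report$removed_by_taxonomy), 0L)
  expect_equal(length(v$report$removed_asvs_global), 0L)
  expect_equal(nrow(v$report$removed_specimens), 0L)
})

test_that("relaxed specimens survive vetting via the polycystine rule", {
  cfg <- small_config(seed = 15, n_relaxed = 2)
  ds <- generate_dataset(cfg)
  expect_true(any(ds$meta$relaxed_filter))
  v <- vet_dataset(ds$chart, ds$meta)
  expect_true(all(ds$meta$specimen_id[ds$meta$relaxed_filter] %in%
                    specimen_ids(v$chart)))
})

test_that("the generated V4 window is recoverable by primer extraction", {
  cfg <- small_config(seed = 21)
  ds <- generate_dataset(cfg)
  tr <- ds$truth
  # every genuine haplotype yields a 440-nt V4 (primer sites are conserved)
  inj <- attr(ds$chart, "injections")
  genuine <- setdiff(asv_ids(ds$chart), inj$asv_id)
  v4 <- vapply(ds$chart$sequence[genuine][1:10], extract_v4, character(1))
  expect_true(all(nchar(v4) == cfg$v4_insert))
})
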