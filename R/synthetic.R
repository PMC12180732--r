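#' Configuration for the synthetic occurrence-chart generator
#'
#' The generator emulates the statistical structure of single-specimen
#' long-read 18S amplicon data from polycystine Radiolaria: per-specimen
#' read depth log-normal around a mean of 22,617 reads; one dominant
#' haplotype per genome plus subdominants under a geometric rank-abundance
#' decay whose per-order parameter matches the observed median rank-1 read
#' shares (Collodaria 0.77, Nassellaria 0.92, Spumellaria 0.60); mutation
#' targets per order for intragenomic, intraspecies and interspecies mean
#' p-distances taken from the observed per-order medians; cryptic subgroups
#' with disjoint ASV sets; low-count noise variants (removed by the >= 3
#' read rule); and off-target contaminant ASVs (removed by the
#' family-consistency rule).
#'
#' @param seed integer seed (< 2^31) controlling all randomness
#' @param species data.frame describing the morphospecies to simulate, with
#'   columns `morphospecies`, `order`, `family`, `n_specimens`,
#'   `n_subgroups`, `category` (the intended three-way classification; must
#'   be consistent with `n_subgroups`: `NO_UNIVERSAL_ASV` requires >= 2
#'   subgroups, the other categories exactly 1), `haplotypes` (mean
#'   haplotypes per genome). Defaults to [radiolarian_species_table()].
#' @param order_params data.frame per order: `order`, `dominance_decay`
#'   (geometric rank-1 share), `p_intragenomic`, `p_intraspecies`,
#'   `p_interspecies` (target mean p-distances; must be non-decreasing in
#'   that order). Defaults to [radiolarian_order_params()].
#' @param depth_mean,depth_sdlog log-normal read-depth model; `depth_mean`
#'   is the arithmetic mean (default 22,617 reads), `depth_sdlog` the
#'   log-scale standard deviation (default 0.6, a typical amplicon
#'   depth spread)
#' @param noise_rate expected number of injected 1-2-read noise variants per
#'   specimen (default 2)
#' @param contamination_rate expected number of injected off-target
#'   contaminant ASVs per specimen (default 0.5)
#' @param template_length length of the ancestral 18S-like template
#'   (default 1450 nt)
#' @param v4_insert length of the V4 region planted between the general
#'   eukaryotic primer sites (default 440 nt)
#' @param n_relaxed number of naked/juvenile specimens with relaxed
#'   taxonomic filtering to append (default 0)
#' @param flip_fraction fraction of specimens of a
#'   `SHARED_ASV_DIFFERENT_DOMINANTS` morphospecies whose dominant is a
#'   private haplotype instead of the shared one (default 0.4, at least one
#'   specimen)
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 1L,
                             species = radiolarian_species_table(),
                             order_params = radiolarian_order_params(),
                             depth_mean = 22617,
                             depth_sdlog = 0.6,
                             noise_rate = 2,
                             contamination_rate = 0.5,
                             template_length = 1450L,
                             v4_insert = 440L,
                             n_relaxed = 0L,
                             flip_fraction = 0.4) {
  stopifnot(seed == round(seed), abs(seed) < 2^31,
            all(c("morphospecies", "order", "family", "n_specimens",
                  "n_subgroups", "category", "haplotypes") %in%
              names(species)),
            all(c("order", "dominance_decay", "p_intragenomic",
                  "p_intraspecies", "p_interspecies") %in%
              names(order_params)),
            depth_mean > 0, noise_rate >= 0, contamination_rate >= 0)
  bad <- with(order_params,
              p_intragenomic > p_intraspecies |
                p_intraspecies > p_interspecies)
  if (any(bad))
    stop("infeasible targets: need p_intragenomic <= p_intraspecies <= ",
         "p_interspecies for order(s) ",
         paste(order_params$order[bad], collapse = ", "))
  if (any(!species$order %in% order_params$order))
    stop("species table references orders missing from order_params")
  mism <- (species$category == "NO_UNIVERSAL_ASV" & species$n_subgroups < 2) |
    (species$category != "NO_UNIVERSAL_ASV" & species$n_subgroups != 1)
  if (any(mism))
    stop("category/n_subgroups mismatch for: ",
         paste(species$morphospecies[mism], collapse = ", "))
  structure(list(seed = as.integer(seed), species = species,
                 order_params = order_params, depth_mean = depth_mean,
                 depth_sdlog = depth_sdlog, noise_rate = noise_rate,
                 contamination_rate = contamination_rate,
                 template_length = as.integer(template_length),
                 v4_insert = as.integer(v4_insert),
                 n_relaxed = as.integer(n_relaxed),
                 flip_fraction = flip_fraction),
            class = "synthetic_config")
}

#' Built-in morphospecies table mirroring the study design
#'
#' The 14 multi-specimen, species-rank morphospecies with their specimen
#' counts and observed variation categories (1 shared-dominant, 4
#' shared-ASV-different-dominants, 9 no-universal-ASV), which the generator
#' reproduces by construction.
#'
#' @return data.frame consumed by [synthetic_config()].
#' @export
radiolarian_species_table <- function() {
  d <- function(m, o, f, n, g, c, h)
    data.frame(morphospecies = m, order = o, family = f, n_specimens = n,
               n_subgroups = g, category = c, haplotypes = h,
               stringsAsFactors = FALSE)
  rbind(
    d("Acrosphaera murrayanna", "Collodaria", "Collosphaeridae", 6, 2,
      "NO_UNIVERSAL_ASV", 32),
    d("Collosphaera huxleyi", "Collodaria", "Collosphaeridae", 51, 1,
      "SHARED_ASV_DIFFERENT_DOMINANTS", 32),
    d("Disolenia zanguebarica", "Collodaria", "Collosphaeridae", 2, 1,
      "SHARED_ASV_DIFFERENT_DOMINANTS", 32),
    d("Procyttarium primordialis", "Collodaria", "Thalassicollidae", 3, 1,
      "SHARED_ASV_DIFFERENT_DOMINANTS", 32),
    d("Siphonosphera socialis", "Collodaria", "Collosphaeridae", 6, 2,
      "NO_UNIVERSAL_ASV", 12),
    d("Thalassicolla nucleata", "Collodaria", "Thalassicollidae", 10, 3,
      "NO_UNIVERSAL_ASV", 32),
    d("Acanthodesmia vinculata", "Nassellaria", "Acanthodesmidae", 2, 2,
      "NO_UNIVERSAL_ASV", 3),
    d("Eucyrtidium hexagonatum", "Nassellaria", "Eucyrtidiidae", 2, 2,
      "NO_UNIVERSAL_ASV", 3),
    d("Pterocanium praetextum", "Nassellaria", "Pterocorythidae", 3, 1,
      "SHARED_DOMINANT", 3),
    d("Pterocorys zancleus", "Nassellaria", "Pterocorythidae", 19, 3,
      "NO_UNIVERSAL_ASV", 3),
    d("Dictyocoryne profunda", "Spumellaria", "Spongodiscidae", 6, 2,
      "NO_UNIVERSAL_ASV", 6),
    d("Dictyocoryne truncatum", "Spumellaria", "Spongodiscidae", 3, 2,
      "NO_UNIVERSAL_ASV", 6),
    d("Didymocyrtis tetrathalamus", "Spumellaria", "Coccodiscidae", 10, 2,
      "NO_UNIVERSAL_ASV", 6),
    d("Euchitonia elegans-furcata", "Spumellaria", "Spongodiscidae", 5, 1,
      "SHARED_ASV_DIFFERENT_DOMINANTS", 6))
}

#' Built-in per-order generator parameters
#'
#' Dominance decay set to the observed median rank-1 read shares and
#' p-distance targets set to the observed per-order medians at each
#' hierarchical level.
#'
#' @return data.frame consumed by [synthetic_config()].
#' @export
radiolarian_order_params <- function() {
  data.frame(
    order = c("Collodaria", "Nassellaria", "Spumellaria"),
    dominance_decay = c(0.77, 0.92, 0.60),
    p_intragenomic = c(0.009, 0.001, 0.009),
    p_intraspecies = c(0.037, 0.004, 0.013),
    p_interspecies = c(0.203, 0.113, 0.027),
    stringsAsFactors = FALSE)
}

#' A small, fast configuration for tests and examples
#'
#' Two morphospecies per order (one single-subgroup, one split), 3-4
#' specimens each, shallow depth. Same statistical shape as the full
#' configuration, a fraction of the cost.
#'
#' @inheritParams synthetic_config
#' @param ... passed to [synthetic_config()]
#' @return a `synthetic_config`.
#' @export
small_config <- function(seed = 1L, ...) {
  d <- function(m, o, f, n, g, c, h)
    data.frame(morphospecies = m, order = o, family = f, n_specimens = n,
               n_subgroups = g, category = c, haplotypes = h,
               stringsAsFactors = FALSE)
  species <- rbind(
    d("Collosphaera huxleyi", "Collodaria", "Collosphaeridae", 4, 1,
      "SHARED_ASV_DIFFERENT_DOMINANTS", 8),
    d("Siphonosphera socialis", "Collodaria", "Collosphaeridae", 4, 2,
      "NO_UNIVERSAL_ASV", 6),
    d("Pterocanium praetextum", "Nassellaria", "Pterocorythidae", 3, 1,
      "SHARED_DOMINANT", 3),
    d("Pterocorys zancleus", "Nassellaria", "Pterocorythidae", 4, 2,
      "NO_UNIVERSAL_ASV", 3),
    d("Euchitonia elegans-furcata", "Spumellaria", "Spongodiscidae", 3, 1,
      "SHARED_ASV_DIFFERENT_DOMINANTS", 5),
    d("Didymocyrtis tetrathalamus", "Spumellaria", "Coccodiscidae", 4, 2,
      "NO_UNIVERSAL_ASV", 5))
  synthetic_config(seed = seed, species = species, depth_mean = 3000,
                   ...)
}

# ---- internal sequence machinery -------------------------------------------

BASES <- c("A", "C", "G", "T")

random_dna <- function(n) paste(sample(BASES, n, replace = TRUE),
                                collapse = "")

# concrete (non-degenerate) realisation of an IUPAC string
concretize <- function(iupac) {
  sets <- list(A = "A", C = "C", G = "G", T = "T", R = c("A", "G"),
               Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
               K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
               D = c("A", "G", "T"), H = c("A", "C", "T"),
               V = c("A", "C", "G"), N = BASES)
  paste(vapply(strsplit(iupac, "")[[1]],
               function(ch) sets[[ch]][1], character(1)), collapse = "")
}

# substitute each unprotected site independently with probability `rate`,
# uniformly over the three alternative bases
mutate_seq <- function(seq, rate, protect = integer(0)) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  eligible <- setdiff(seq_along(chars), protect)
  hit <- eligible[stats::runif(length(eligible)) < rate]
  if (length(hit)) {
    chars[hit] <- vapply(chars[hit], function(b)
      sample(setdiff(BASES, b), 1), character(1))
  }
  paste(chars, collapse = "")
}

# per-branch substitution rate so two lineages independently mutated from a
# common ancestor have expected pairwise difference `p`:
# P(diff) = 2r(1-r) + (2/3)r^2
rate_for_pairwise_p <- function(p) {
  stopifnot(p >= 0, p < 0.7)
  (2 - sqrt(4 - 16 * p / 3)) * 3 / 8
}

# mutants are drawn conditioned on carrying at least one substitution
# (a silent mutant would be the same ASV and collapse at deduplication);
# under that conditioning the effective per-site divergence of one branch
# over L mutable sites is r / (1 - (1-r)^L)
conditional_site_rate <- function(r, L) {
  if (r <= 0) return(0)
  r / (1 - (1 - r)^L)
}

# single-branch rate so the mean p-distance over all haplotype pairs of one
# genome (1 ancestor + (k-1) conditioned mutants) equals `p`:
# mean = [ (k-1) m1 + C(k-1,2) m2 ] / C(k,2),
# m1 = conditional anc-mutant divergence, m2 ~ 2 m1 (1-m1) + (2/3) m1^2.
# The smallest representable mean (one substitution per mutant) bounds p
# from below; infeasible targets error rather than silently saturate.
rate_for_intragenomic_p <- function(p, k, L) {
  if (p <= 0 || k < 2) return(0)
  mean_for <- function(r) {
    m1 <- conditional_site_rate(r, L)
    m2 <- 2 * m1 * (1 - m1) + (2 / 3) * m1^2
    ((k - 1) * m1 + choose(k - 1, 2) * m2) / choose(k, 2)
  }
  lo <- mean_for(1e-12)
  # k distinct sequences cannot sit closer than one substitution apart;
  # genomes whose floor exceeds the target saturate at the floor (rate 0
  # makes every mutant a single-substitution variant), which keeps the
  # order-level average within a few percent of the target
  if (p <= lo) return(0)
  stats::uniroot(function(r) mean_for(r) - p, c(1e-12, 0.6),
                 tol = 1e-12)$root
}

# rejection-sample a mutant that differs from its ancestor: exactly the
# conditioned distribution assumed by rate_for_intragenomic_p; in the
# low-rate limit the conditioned draw is a single uniform substitution
mutate_seq_distinct <- function(seq, rate, protect = integer(0)) {
  L <- nchar(seq) - length(protect)
  if (rate <= 0 || 1 - (1 - rate)^L < 0.05) {
    chars <- strsplit(seq, "")[[1]]
    site <- sample(setdiff(seq_along(chars), protect), 1)
    chars[site] <- sample(setdiff(BASES, chars[site]), 1)
    return(paste(chars, collapse = ""))
  }
  repeat {
    out <- mutate_seq(seq, rate, protect)
    if (out != seq) return(out)
  }
}

# 18S-like template with concrete V4 primer sites flanking a v4_insert
# region; returns list(seq, protect = primer site positions, v4_window)
make_template <- function(template_length, v4_insert) {
  prm <- tar_euk_primers()
  fwd <- concretize(prm$fwd$sequence)
  rev_plus <- revcomp(concretize(prm$rev$sequence))  # plus-strand site
  lead <- 380L
  need <- lead + nchar(fwd) + v4_insert + nchar(rev_plus)
  if (template_length < need + 50L)
    stop("template_length too short for the V4 geometry")
  seq <- random_dna(template_length)
  f_start <- lead + 1L
  f_end <- lead + nchar(fwd)
  r_start <- f_end + v4_insert + 1L
  r_end <- r_start + nchar(rev_plus) - 1L
  substr(seq, f_start, f_end) <- fwd
  substr(seq, r_start, r_end) <- rev_plus
  list(seq = seq, protect = c(f_start:f_end, r_start:r_end),
       v4_window = c(start = f_end + 1L, length = v4_insert))
}

synth_lineage <- function(order, family, genus, species) {
  paste("Eukaryota", "Rhizaria", "Radiolaria", "Polycystinea",
        order, family, genus, species, sep = ";")
}

# off-target lineages for contaminants (never polycystine)
contaminant_lineages <- function() {
  c("Eukaryota;Rhizaria;Radiolaria;Acantharea;Chaunacanthida;Stauracanthidae;Stauracon;Stauracon_pallidus",
    "Eukaryota;Stramenopiles;Ochrophyta;Bacillariophyta;Bacillariophyta_X;Polar-centric-Mediophyceae;Chaetoceros;Chaetoceros_sp.",
    "Eukaryota;Alveolata;Dinoflagellata;Dinophyceae;Gymnodiniales;Gymnodiniaceae;Gyrodinium;Gyrodinium_sp.")
}

# ---- truth construction -----------------------------------------------------

#' Build the generative ground truth
#'
#' Deterministic under `cfg$seed`. Per order, an ancestral template with
#' planted V4 primer sites is mutated into morphospecies ancestors (to the
#' interspecies p target), then into subgroup ancestors (intraspecies
#' target), then into per-genome haplotypes (intragenomic target, with the
#' per-branch rate calibrated so the expected within-genome mean equals the
#' target). Haplotype frequencies follow a geometric law with the order's
#' dominance decay. The intended variation category is forced by
#' construction: the subgroup ancestor is shared by (and usually dominant
#' in) every specimen of its subgroup; flip specimens of a
#' shared-ASV-different-dominants morphospecies promote a private haplotype
#' to rank 1; multi-subgroup morphospecies have disjoint haplotype sets.
#'
#' @param cfg a [synthetic_config()]
#' @return a `synthetic_truth` list: `templates` (per order), `specimens`
#'   (per specimen: morphospecies, order, family, subgroup, relaxed,
#'   haplotype sequences and frequencies), `categories` (expected
#'   classification per morphospecies), `meta` (specimen metadata
#'   data.frame), `v4_window`, and the `config`.
#' @export
build_truth <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)
  op <- cfg$order_params
  templates <- list()
  for (o in unique(cfg$species$order))
    templates[[o]] <- make_template(cfg$template_length, cfg$v4_insert)

  specimens <- list()
  meta_rows <- list()
  categories <- cfg$species[, c("morphospecies", "order", "category",
                                "n_specimens")]
  genus_counter <- 0L

  for (i in seq_len(nrow(cfg$species))) {
    sp <- cfg$species[i, ]
    o <- sp$order
    pars <- op[op$order == o, ]
    tmpl <- templates[[o]]
    genus_counter <- genus_counter + 1L
    genus <- gsub("[^A-Za-z].*", "", sp$morphospecies)
    lineage <- synth_lineage(o, sp$family, genus,
                             gsub("\\s+", "_", sp$morphospecies))

    sp_anc <- mutate_seq(tmpl$seq, rate_for_pairwise_p(pars$p_interspecies),
                         tmpl$protect)
    # subgroup ancestors must be pairwise distinct or the intended
    # NO_UNIVERSAL_ASV structure collapses; at low mutation targets the
    # no-mutation draw is non-negligible, so re-draw on collision
    sub_anc <- character(sp$n_subgroups)
    for (g in seq_len(sp$n_subgroups)) {
      if (sp$n_subgroups == 1) { sub_anc[g] <- sp_anc; next }
      repeat {
        cand <- mutate_seq(sp_anc,
                           rate_for_pairwise_p(pars$p_intraspecies),
                           tmpl$protect)
        if (cand != sp_anc && !cand %in% sub_anc[seq_len(g - 1)]) break
      }
      sub_anc[g] <- cand
    }

    # assign specimens round-robin to subgroups so each subgroup is used
    sub_of <- rep(seq_len(sp$n_subgroups),
                  length.out = sp$n_specimens)
    flips <- rep(FALSE, sp$n_specimens)
    if (sp$category == "SHARED_ASV_DIFFERENT_DOMINANTS") {
      n_flip <- max(1L, round(cfg$flip_fraction * sp$n_specimens))
      n_flip <- min(n_flip, sp$n_specimens - 1L)  # keep >= 1 unflipped
      flips[sample(sp$n_specimens, n_flip)] <- TRUE
    }

    L_mut <- cfg$template_length - length(tmpl$protect)
    for (j in seq_len(sp$n_specimens)) {
      k <- max(2L, stats::rpois(1, sp$haplotypes))
      r <- rate_for_intragenomic_p(pars$p_intragenomic, k, L_mut)
      anc <- sub_anc[sub_of[j]]
      haps <- c(anc, vapply(seq_len(k - 1L), function(z)
        mutate_seq_distinct(anc, r, tmpl$protect), character(1)))
      # geometric frequencies; rank 1 is the shared ancestor unless flipped
      w <- pars$dominance_decay *
        (1 - pars$dominance_decay)^(seq_len(k) - 1L)
      w <- w / sum(w)
      ord <- seq_len(k)
      if (flips[j] && k >= 2) ord <- c(2L, 1L, seq_len(k)[-(1:2)])
      sid <- sprintf("%s-%02d", gsub("[^A-Za-z]+", "-",
                                     sp$morphospecies), j)
      specimens[[sid]] <- list(
        specimen_id = sid, morphospecies = sp$morphospecies, order = o,
        family = sp$family, subgroup = sub_of[j], relaxed = FALSE,
        haplotypes = haps[ord], frequencies = w, lineage = lineage,
        flipped = flips[j])
      meta_rows[[sid]] <- data.frame(
        specimen_id = sid, morphotaxon = sp$morphospecies,
        morph_rank = "species", order = o, family = sp$family,
        relaxed_filter = FALSE, stringsAsFactors = FALSE)
    }
  }

  # naked / juvenile specimens: genuinely polycystine, but with no
  # morphological family, so vetting must use the relaxed rule
  if (cfg$n_relaxed > 0) {
    orders <- unique(cfg$species$order)
    for (j in seq_len(cfg$n_relaxed)) {
      o <- orders[1 + (j - 1) %% length(orders)]
      pars <- op[op$order == o, ]
      tmpl <- templates[[o]]
      anc <- mutate_seq(tmpl$seq,
                        rate_for_pairwise_p(pars$p_interspecies),
                        tmpl$protect)
      k <- max(2L, stats::rpois(1, 3))
      r <- rate_for_intragenomic_p(pars$p_intragenomic, k,
                                   cfg$template_length - length(tmpl$protect))
      haps <- c(anc, vapply(seq_len(k - 1L), function(z)
        mutate_seq_distinct(anc, r, tmpl$protect), character(1)))
      w <- pars$dominance_decay *
        (1 - pars$dominance_decay)^(seq_len(k) - 1L)
      w <- w / sum(w)
      sid <- sprintf("juvenile-%02d", j)
      fam <- cfg$species$family[cfg$species$order == o][1]
      specimens[[sid]] <- list(
        specimen_id = sid, morphospecies = "juvenile sp.", order = o,
        family = fam, subgroup = 1L, relaxed = TRUE,
        haplotypes = haps, frequencies = w,
        lineage = synth_lineage(o, fam, "Juvenilis", "Juvenilis_sp."),
        flipped = FALSE)
      meta_rows[[sid]] <- data.frame(
        specimen_id = sid, morphotaxon = "juvenile sp.",
        morph_rank = "indeterminate", order = o, family = "unknown",
        relaxed_filter = TRUE, stringsAsFactors = FALSE)
    }
  }

  meta <- if (length(meta_rows))
    do.call(rbind, c(meta_rows, list(make.row.names = FALSE)))
  else data.frame(specimen_id = character(0), morphotaxon = character(0),
                  morph_rank = character(0), order = character(0),
                  family = character(0), relaxed_filter = logical(0))
  structure(list(templates = templates, specimens = specimens,
                 categories = categories, meta = meta,
                 v4_window = if (length(templates))
                   templates[[1]]$v4_window else NULL,
                 config = cfg),
            class = "synthetic_truth")
}

# ---- read sampling ----------------------------------------------------------

#' Sample an occurrence chart from a synthetic truth
#'
#' Per specimen: a read depth is drawn from the log-normal depth model and
#' reads are allocated multinomially over the genome's haplotype
#' frequencies. Noise variants (1-2 reads, same-family lineage, fresh
#' 1-2-site mutants — below the presence rule by construction) and
#' contaminant ASVs (off-target lineage, 3-30 reads — removed by the
#' taxonomy rule by construction) are then injected. ASV identity is by
#' sequence: the same haplotype sampled in two specimens is one ASV.
#'
#' @param truth a `synthetic_truth` from [build_truth()]
#' @param cfg the same [synthetic_config()] (defaults to the one recorded
#'   in the truth)
#' @return an [occurrence_chart()] with attribute `injections`: a data.frame
#'   of injected noise/contaminant ASVs (`asv_id`, `specimen_id`, `kind`,
#'   `count`).
#' @export
sample_reads_table <- function(truth, cfg = truth$config) {
  stopifnot(inherits(truth, "synthetic_truth"))
  set.seed(cfg$seed + 1L)
  meanlog <- log(cfg$depth_mean) - cfg$depth_sdlog^2 / 2

  seq_pool <- character(0)   # sequence -> asv_id
  taxon_pool <- character(0)
  conf_pool <- numeric(0)
  next_id <- 0L
  id_for <- function(seq, taxon, conf) {
    hit <- match(seq, names(seq_pool))
    if (!is.na(hit)) return(unname(seq_pool[hit]))
    next_id <<- next_id + 1L
    id <- sprintf("asv-%04d", next_id)
    seq_pool[seq] <<- id
    taxon_pool[id] <<- taxon
    conf_pool[id] <<- conf
    id
  }

  cells <- list()
  injections <- list()
  for (sp in truth$specimens) {
    depth <- max(50L, round(stats::rlnorm(1, meanlog, cfg$depth_sdlog)))
    reads <- stats::rmultinom(1, depth, sp$frequencies)[, 1]
    conf <- round(stats::runif(length(reads), 0.7, 1), 3)
    for (h in which(reads > 0)) {
      id <- id_for(sp$haplotypes[h], sp$lineage, conf[h])
      cells[[length(cells) + 1]] <- data.frame(
        asv_id = id, specimen_id = sp$specimen_id, count = reads[h],
        stringsAsFactors = FALSE)
    }
    n_noise <- stats::rpois(1, cfg$noise_rate)
    for (z in seq_len(n_noise)) {
      base <- sp$haplotypes[sample(length(sp$haplotypes), 1)]
      nv <- mutate_seq(base, 2 / nchar(base))
      if (nv %in% names(seq_pool)) next  # keep noise variants novel
      id <- id_for(nv, sp$lineage, round(stats::runif(1, 0.7, 1), 3))
      cnt <- sample(1:2, 1)
      cells[[length(cells) + 1]] <- data.frame(
        asv_id = id, specimen_id = sp$specimen_id, count = cnt,
        stringsAsFactors = FALSE)
      injections[[length(injections) + 1]] <- data.frame(
        asv_id = id, specimen_id = sp$specimen_id, kind = "noise",
        count = cnt, stringsAsFactors = FALSE)
    }
    n_cont <- stats::rpois(1, cfg$contamination_rate)
    for (z in seq_len(n_cont)) {
      cseq <- random_dna(cfg$template_length)
      lin <- sample(contaminant_lineages(), 1)
      id <- id_for(cseq, lin, round(stats::runif(1, 0.4, 0.95), 3))
      cnt <- sample(3:30, 1)
      cells[[length(cells) + 1]] <- data.frame(
        asv_id = id, specimen_id = sp$specimen_id, count = cnt,
        stringsAsFactors = FALSE)
      injections[[length(injections) + 1]] <- data.frame(
        asv_id = id, specimen_id = sp$specimen_id, kind = "contaminant",
        count = cnt, stringsAsFactors = FALSE)
    }
  }

  spec_ids <- names(truth$specimens)
  if (is.null(spec_ids)) spec_ids <- character(0)
  all_ids <- unname(seq_pool)
  counts <- matrix(0L, length(all_ids), length(spec_ids),
                   dimnames = list(all_ids, spec_ids))
  if (length(cells)) {
    long <- do.call(rbind, cells)
    for (r in seq_len(nrow(long)))
      counts[long$asv_id[r], long$specimen_id[r]] <-
        counts[long$asv_id[r], long$specimen_id[r]] + long$count[r]
  }
  chart <- occurrence_chart(
    counts,
    sequence = stats::setNames(as.character(names(seq_pool)),
                               unname(seq_pool)),
    taxon = taxon_pool[all_ids],
    confidence = conf_pool[all_ids])
  attr(chart, "injections") <- if (length(injections))
    do.call(rbind, injections)
  else data.frame(asv_id = character(0), specimen_id = character(0),
                  kind = character(0), count = integer(0))
  chart
}

#' Generate a fully seeded synthetic dataset bundle
#'
#' Composes [build_truth()] and [sample_reads_table()]; deterministic and
#' bit-identical under a fixed seed.
#'
#' @param cfg a [synthetic_config()] (default: the study-scale
#'   configuration with 3 relaxed specimens)
#' @return list with `chart` (an [occurrence_chart()]), `meta` (specimen
#'   metadata), `truth` (a `synthetic_truth`).
#' @export
generate_dataset <- function(cfg = synthetic_config(n_relaxed = 3L)) {
  truth <- build_truth(cfg)
  chart <- sample_reads_table(truth, cfg)
  list(chart = chart, meta = truth$meta, truth = truth)
}
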