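# shared fixtures and independent oracles (kept brute-force on purpose:
# they must not share code paths with the implementation they check)

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
  D = c("A", "G", "T"), H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T"))

# set-intersection IUPAC compatibility, one position
iupac_compatible <- function(a, b) {
  length(intersect(IUPAC_SETS[[a]], IUPAC_SETS[[b]])) > 0
}

# brute-force sliding-window primer scan (one strand)
oracle_scan <- function(seq, pattern, max_mismatch) {
  s <- strsplit(toupper(seq), "")[[1]]
  p <- strsplit(toupper(pattern), "")[[1]]
  hits <- data.frame(start = integer(0), mismatches = integer(0))
  if (length(p) > length(s)) return(hits)
  for (off in 0:(length(s) - length(p))) {
    mm <- sum(!mapply(iupac_compatible, p, s[off + seq_along(p)]))
    if (mm <= max_mismatch)
      hits <- rbind(hits, data.frame(start = off, mismatches = mm))
  }
  hits
}

# exhaustive recursive global-alignment score (no dynamic programming)
oracle_align_score <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  rec <- function(i, j) {
    if (i == 0 && j == 0) return(0)
    best <- -Inf
    if (i > 0 && j > 0)
      best <- max(best, rec(i - 1, j - 1) +
                    if (substr(a, i, i) == substr(b, j, j)) match
                    else mismatch)
    if (j > 0) best <- max(best, rec(i, j - 1) + gap)
    if (i > 0) best <- max(best, rec(i - 1, j) + gap)
    best
  }
  rec(nchar(a), nchar(b))
}

# direct set-logic classifier over a plain count matrix
oracle_classify <- function(counts, min_presence = 3) {
  dom <- lapply(seq_len(ncol(counts)), function(j) {
    v <- counts[, j]
    v <- v[v > 0]
    names(v)[v == max(v)]
  })
  if (length(Reduce(intersect, dom)) > 0) return("SHARED_DOMINANT")
  present <- counts >= min_presence
  if (any(rowSums(present) == ncol(counts)))
    return("SHARED_ASV_DIFFERENT_DOMINANTS")
  "NO_UNIVERSAL_ASV"
}

# small hand-rolled chart: 3 specimens of one morphospecies plus annotations
tiny_chart <- function(counts = NULL) {
  if (is.null(counts)) {
    counts <- matrix(c(70L, 20L, 10L,
                       60L, 30L, 10L,
                       80L, 10L, 10L), nrow = 3,
                     dimnames = list(c("A1", "A2", "A3"),
                                     c("s1", "s2", "s3")))
  }
  lin <- "Eukaryota;Rhizaria;Radiolaria;Polycystinea;Nassellaria;Pterocorythidae;Pterocorys;Pterocorys_zancleus"
  ids <- rownames(counts)
  occurrence_chart(
    counts,
    sequence = stats::setNames(
      vapply(seq_along(ids), function(i)
        paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
              collapse = ""), character(1)), ids),
    taxon = stats::setNames(rep(lin, length(ids)), ids),
    confidence = stats::setNames(rep(0.99, length(ids)), ids))
}

tiny_meta <- function(specimens = c("s1", "s2", "s3"),
                      family = "Pterocorythidae") {
  data.frame(specimen_id = specimens,
             morphotaxon = "Pterocorys zancleus",
             morph_rank = "species",
             order = "Nassellaria",
             family = family,
             relaxed_filter = FALSE,
             stringsAsFactors = FALSE)
}

# random valid chart for round-trip / property tests
random_chart <- function(n_asv = 6, n_spec = 4, seed = 1) {
  set.seed(seed)
  ids <- sprintf("asv-%02d", seq_len(n_asv))
  specs <- sprintf("sp-%02d", seq_len(n_spec))
  counts <- matrix(rpois(n_asv * n_spec, 4), n_asv, n_spec,
                   dimnames = list(ids, specs))
  storage.mode(counts) <- "integer"
  occurrence_chart(
    counts,
    sequence = stats::setNames(vapply(ids, function(i)
      paste(sample(c("A", "C", "G", "T", "R", "N"), 40, replace = TRUE),
            collapse = ""), character(1)), ids),
    taxon = stats::setNames(rep(
      "Eukaryota;Rhizaria;Radiolaria;Polycystinea;Spumellaria;Spongodiscidae;Dictyocoryne;Dictyocoryne_profunda",
      n_asv), ids),
    confidence = stats::setNames(round(runif(n_asv, 0.3, 1), 3), ids))
}

charts_equal <- radvar:::charts_equal
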