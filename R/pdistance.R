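#' Global pairwise alignment (Needleman-Wunsch)
#'
#' Deterministic optimal global alignment under additive scoring. Traceback
#' ties are broken by preferring a match/mismatch column over a gap in `a`,
#' and a gap in `a` over a gap in `b`.
#'
#' @param a,b non-empty nucleotide strings
#' @param match,mismatch,gap scoring parameters (defaults +1 / -1 / -2)
#' @return list with aligned strings `a`, `b` (equal length, `-` for gaps)
#'   and the optimal `score`.
#' @export
align_pair <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  x <- strsplit(toupper(a), "")[[1]]
  y <- strsplit(toupper(b), "")[[1]]
  n <- length(x); m <- length(y)
  S <- matrix(0, n + 1, m + 1)
  S[, 1] <- gap * (0:n)
  S[1, ] <- gap * (0:m)
  for (i in seq_len(n)) {
    sub <- ifelse(x[i] == y, match, mismatch)
    for (j in seq_len(m))
      S[i + 1, j + 1] <- max(S[i, j] + sub[j],      # diagonal
                             S[i + 1, j] + gap,     # gap in a
                             S[i, j + 1] + gap)     # gap in b
  }
  # traceback, diag > gap-in-a > gap-in-b
  ra <- character(0); rb <- character(0)
  i <- n; j <- m
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
        S[i + 1, j + 1] == S[i, j] +
        (if (x[i] == y[j]) match else mismatch)) {
      ra <- c(x[i], ra); rb <- c(y[j], rb); i <- i - 1; j <- j - 1
    } else if (j > 0 && S[i + 1, j + 1] == S[i + 1, j] + gap) {
      ra <- c("-", ra); rb <- c(y[j], rb); j <- j - 1
    } else {
      ra <- c(x[i], ra); rb <- c("-", rb); i <- i - 1
    }
  }
  list(a = paste(ra, collapse = ""), b = paste(rb, collapse = ""),
       score = S[n + 1, m + 1])
}

#' Proportion of differing sites between two aligned sequences
#'
#' p-distance: differing sites divided by retained sites. Under pairwise
#' deletion, retained sites are those where neither sequence has a gap;
#' under complete deletion, the caller is expected to have already removed
#' columns gapped in any sequence of the set (see [group_mean_within()]),
#' and remaining gap columns are an error.
#'
#' @param a,b equal-length aligned strings over `A,C,G,T,-` (IUPAC
#'   ambiguities allowed; any character mismatch counts as a difference)
#' @param deletion `"pairwise"` (default) or `"complete"`
#' @return a fraction in \[0, 1\].
#' @export
p_distance <- function(a, b, deletion = c("pairwise", "complete")) {
  deletion <- match.arg(deletion)
  x <- strsplit(toupper(a), "")[[1]]
  y <- strsplit(toupper(b), "")[[1]]
  if (length(x) != length(y))
    stop("sequences must be aligned to equal length")
  gapped <- x == "-" | y == "-"
  if (deletion == "complete" && any(gapped))
    stop("gap columns present under complete deletion; ",
         "remove them set-wide first")
  keep <- !gapped
  if (!any(keep)) stop("zero retained sites")
  sum(x[keep] != y[keep]) / sum(keep)
}

#' All pairwise p-distances within a set of aligned sequences
#'
#' Vectorised via base-indicator cross-products: with X_b the sequences x
#' sites indicator of base b, the match-count matrix is the sum of X_b X_b'
#' over A, C, G, T, and the retained-site matrix counts positions where both
#' members are ungapped. Sequences must share one length (a supplied MSA, or
#' indel-free data); unequal lengths are an error rather than silently
#' aligned.
#'
#' @param seqs named character vector of aligned sequences (length >= 2)
#' @param deletion `"pairwise"` or `"complete"`
#' @return symmetric numeric matrix of p-distances (`NaN` where a pair
#'   retains zero sites).
#' @export
p_distance_matrix <- function(seqs, deletion = c("pairwise", "complete")) {
  deletion <- match.arg(deletion)
  if (length(seqs) < 2) stop("need at least two sequences")
  len <- unique(nchar(seqs))
  if (length(len) != 1)
    stop("sequences differ in length; supply an alignment ",
         "(or use align_pair() for pairs)")
  M <- do.call(rbind, strsplit(toupper(seqs), ""))
  rownames(M) <- names(seqs)
  if (deletion == "complete")
    M <- M[, colSums(M == "-") == 0, drop = FALSE]
  ungapped <- M != "-"
  match_m <- matrix(0, nrow(M), nrow(M))
  for (b in c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
              "B", "D", "H", "V", "N")) {
    X <- (M == b) * 1
    if (any(X > 0)) match_m <- match_m + tcrossprod(X)
  }
  retained <- tcrossprod(ungapped * 1)
  d <- 1 - match_m / retained
  diag(d) <- 0
  dimnames(d) <- list(names(seqs), names(seqs))
  d
}

#' Mean p-distance within a group of sequences
#'
#' Arithmetic mean of the p-distance over all unordered pairs, the
#' "within-group mean distance" of distance-based phylogenetics software.
#' A singleton group has no pairs and yields `NA` (reported, not an error,
#' matching the N/A convention of per-specimen distance tables).
#'
#' @param seqs named character vector of aligned sequences
#' @param deletion gap-handling mode, see [p_distance()]
#' @param label optional group label carried into the result
#' @return list with `label`, `mean_p`, `n_pairs`, `n_seqs`.
#' @export
group_mean_within <- function(seqs, deletion = "pairwise", label = NA) {
  if (length(seqs) < 2)
    return(list(label = label, mean_p = NA_real_, n_pairs = 0L,
                n_seqs = length(seqs)))
  d <- p_distance_matrix(seqs, deletion)
  vals <- d[lower.tri(d)]
  list(label = label, mean_p = mean(vals, na.rm = TRUE),
       n_pairs = length(vals), n_seqs = length(seqs))
}

#' Mean p-distance between two groups of sequences
#'
#' Mean over all cross pairs (n_a x n_b); symmetric in its arguments.
#'
#' @param seqs_a,seqs_b named character vectors of aligned sequences
#' @inheritParams group_mean_within
#' @return list with `label`, `mean_p`, `n_pairs`.
#' @export
group_mean_between <- function(seqs_a, seqs_b, deletion = "pairwise",
                               label = NA) {
  stopifnot(length(seqs_a) > 0, length(seqs_b) > 0)
  names(seqs_a) <- paste0("a_", seq_along(seqs_a))
  names(seqs_b) <- paste0("b_", seq_along(seqs_b))
  d <- p_distance_matrix(c(seqs_a, seqs_b), deletion)
  cross <- d[seq_along(seqs_a), length(seqs_a) + seq_along(seqs_b),
             drop = FALSE]
  list(label = label, mean_p = mean(cross, na.rm = TRUE),
       n_pairs = length(cross))
}

#' Hierarchical p-distance summaries of a vetted chart
#'
#' Computes, per taxonomic order (orders are summarised separately):
#' \describe{
#'   \item{intragenomic}{within-group mean over the ASVs present in each
#'     specimen;}
#'   \item{intraspecies}{within-group mean over the unique ASVs pooled
#'     across all specimens of each morphospecies;}
#'   \item{interspecies}{between-group mean for every pair of morphospecies
#'     of the same order.}
#' }
#' Only specimens morphologically identified to species rank enter the
#' intraspecies and interspecies levels. Sequences default to the chart's
#' own (appropriate for indel-free or pre-aligned data); supply an MSA via
#' `sequences` to reproduce externally aligned results.
#'
#' @param chart a vetted [occurrence_chart()]
#' @param meta specimen metadata
#' @param sequences named character vector of (aligned) sequences for the
#'   chart's ASVs (default `chart$sequence`)
#' @param deletion gap-handling mode
#' @return data.frame with `level`, `order`, `group_a`, `group_b` (`NA`
#'   within groups), `mean_p`, `n_pairs`, `n_seqs`.
#' @export
pdistance_hierarchy <- function(chart, meta, sequences = chart$sequence,
                                deletion = "pairwise") {
  stopifnot(inherits(chart, "occurrence_chart"))
  meta <- validate_specimen_meta(meta)
  meta <- meta[meta$specimen_id %in% specimen_ids(chart), ]
  rows <- list()
  add <- function(level, order, a, b, r)
    rows[[length(rows) + 1]] <<- data.frame(
      level = level, order = order, group_a = a, group_b = b,
      mean_p = r$mean_p, n_pairs = r$n_pairs,
      n_seqs = if (!is.null(r$n_seqs)) r$n_seqs else NA_integer_,
      stringsAsFactors = FALSE)

  for (s in meta$specimen_id) {
    present <- asv_ids(chart)[chart$counts[, s] > 0L]
    add("intragenomic", meta$order[meta$specimen_id == s], s, NA,
        group_mean_within(sequences[present], deletion))
  }

  sp_meta <- meta[meta$morph_rank == "species", ]
  pooled <- list()
  for (m in unique(sp_meta$morphotaxon)) {
    specs <- sp_meta$specimen_id[sp_meta$morphotaxon == m]
    present <- asv_ids(chart)[
      rowSums(chart$counts[, specs, drop = FALSE] > 0L) > 0L]
    pooled[[m]] <- list(order = sp_meta$order[match(m, sp_meta$morphotaxon)],
                        seqs = sequences[present])
    add("intraspecies", pooled[[m]]$order, m, NA,
        group_mean_within(pooled[[m]]$seqs, deletion))
  }

  for (o in unique(vapply(pooled, `[[`, character(1), "order"))) {
    members <- names(pooled)[vapply(pooled, `[[`, character(1),
                                    "order") == o]
    if (length(members) < 2) next
    prs <- utils::combn(sort(members), 2)
    for (k in seq_len(ncol(prs))) {
      a <- prs[1, k]; b <- prs[2, k]
      add("interspecies", o, a, b,
          group_mean_between(pooled[[a]]$seqs, pooled[[b]]$seqs, deletion))
    }
  }
  do.call(rbind, rows)
}
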