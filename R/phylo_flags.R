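#' Export each specimen's dominant ASV as FASTA records
#'
#' One sequence per specimen (the most abundant ASV, ties resolved
#' deterministically by lexicographic asv_id and noted in the result),
#' labelled `specimen_id|morphotaxon|asv_id` — the input for external
#' maximum-likelihood tree building.
#'
#' @param chart a vetted [occurrence_chart()]
#' @param meta specimen metadata
#' @param path optional FASTA output path
#' @return named character vector of sequences (invisibly written to `path`
#'   when given), with attribute `ties` listing specimens whose dominant ASV
#'   was tie-broken.
#' @export
export_dominant_fasta <- function(chart, meta, path = NULL) {
  meta <- validate_specimen_meta(meta)
  ties <- character(0)
  recs <- vapply(specimen_ids(chart), function(s) {
    d <- dominant_set(chart, s)
    if (d$tie) ties <<- c(ties, s)
    d$dominant_asvs[1]
  }, character(1))
  labels <- sprintf("%s|%s|%s", specimen_ids(chart),
                    meta$morphotaxon[match(specimen_ids(chart),
                                           meta$specimen_id)], recs)
  out <- stats::setNames(unname(chart$sequence[recs]), labels)
  attr(out, "ties") <- ties
  if (!is.null(path)) write_fasta(out, path)
  invisible(out)
}

#' Flag chimera candidates on a supplied phylogeny
#'
#' Implements the screening heuristic for hidden chimeras in a
#' reference-anchored maximum-likelihood tree: ASV tips (or maximal
#' monophyletic ASV-only clades) are flagged when their stem branch is
#' longer than `long_branch_factor` times the median tip branch length, the
#' clade contains no reference tips, and the member ASVs sum to fewer than
#' `read_threshold` reads. Flags are advisory candidates for external
#' verification (e.g. split-query database searches); nothing is removed.
#'
#' @param tree an [ape::phylo] object or newick file path. Tip labels that
#'   resolve to chart asv_ids (directly, or as the third `|`-separated field
#'   of a `specimen|taxon|asv` label) are ASV tips; all others are reference
#'   tips.
#' @param chart an [occurrence_chart()] supplying read counts
#' @param long_branch_factor stem-length multiplier over the median tip
#'   branch length (default 3)
#' @param read_threshold flag only candidates with fewer summed reads
#'   (default 50)
#' @return data.frame with `asv_id`, `clade_tips`, `reason`,
#'   `branch_length`, `total_reads`; zero rows when nothing is flagged.
#' @export
flag_chimera_candidates <- function(tree, chart, long_branch_factor = 3,
                                    read_threshold = 50L) {
  if (is.character(tree)) tree <- ape::read.tree(tree)
  stopifnot(inherits(tree, "phylo"), inherits(chart, "occurrence_chart"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")

  tip_asv <- tip_to_asv(tree$tip.label, asv_ids(chart))
  is_asv_tip <- !is.na(tip_asv)
  ntip <- length(tree$tip.label)
  tip_edge <- match(seq_len(ntip), tree$edge[, 2])
  med_tip_len <- stats::median(tree$edge.length[tip_edge])

  # maximal ASV-only clades: internal nodes whose descendants are all ASV
  # tips and whose parent's clade is not; plus ASV tips not inside any such
  # clade
  clades <- list()
  internal <- (ntip + 1L):(ntip + tree$Nnode)
  all_asv_node <- logical(ntip + tree$Nnode)
  all_asv_node[seq_len(ntip)] <- is_asv_tip
  all_asv_node[internal] <- TRUE
  # postorder: a child's subtree is fully resolved before its stem edge
  po <- ape::reorder.phylo(tree, "postorder")$edge
  for (k in seq_len(nrow(po)))
    all_asv_node[po[k, 1]] <- all_asv_node[po[k, 1]] &&
      all_asv_node[po[k, 2]]
  parent_of <- function(node) {
    p <- tree$edge[tree$edge[, 2] == node, 1]
    if (length(p)) p else NA_integer_
  }
  is_maximal <- function(node) {
    p <- parent_of(node)
    is.na(p) || !all_asv_node[p]
  }
  roots <- c(seq_len(ntip), internal)[all_asv_node &
                                        vapply(c(seq_len(ntip), internal),
                                               is_maximal, logical(1))]
  rows <- lapply(roots, function(node) {
    tips <- if (node <= ntip) node else
      unlist(phangorn_free_descendants(tree, node, ntip))
    stem_i <- match(node, tree$edge[, 2])
    if (is.na(stem_i)) return(NULL)  # root clade has no stem
    stem <- tree$edge.length[stem_i]
    members <- tip_asv[tips]
    reads <- sum(chart$counts[members, , drop = FALSE])
    if (stem > long_branch_factor * med_tip_len && reads < read_threshold)
      data.frame(asv_id = members,
                 clade_tips = paste(tree$tip.label[tips], collapse = ","),
                 reason = "long_branch_no_reference_low_reads",
                 branch_length = stem,
                 total_reads = reads,
                 stringsAsFactors = FALSE)
    else NULL
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(asv_id = character(0), clade_tips = character(0),
                      reason = character(0), branch_length = numeric(0),
                      total_reads = integer(0))
  out[order(out$asv_id), , drop = FALSE]
}

# tip label -> asv_id (NA for reference tips)
tip_to_asv <- function(labels, ids) {
  direct <- ifelse(labels %in% ids, labels, NA_character_)
  third <- vapply(strsplit(labels, "|", fixed = TRUE), function(p)
    if (length(p) >= 3 && p[3] %in% ids) p[3] else NA_character_,
    character(1))
  ifelse(!is.na(direct), direct, third)
}

# descendant tips of an internal node without extra deps
phangorn_free_descendants <- function(tree, node, ntip) {
  if (node <= ntip) return(node)
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, phangorn_free_descendants, tree = tree, ntip = ntip))
}

#' Split-query fragments for flagged chimera candidates
#'
#' Emits the first and last ~300 bases of each flagged ASV as FASTA records
#' (`<asv>__head` / `<asv>__tail`) for external database verification of the
#' two putative parent fragments.
#'
#' @param flags data.frame from [flag_chimera_candidates()]
#' @param chart the [occurrence_chart()] holding the sequences
#' @param fragment_length bases per fragment (default 300)
#' @param path optional FASTA output path
#' @return named character vector of fragments.
#' @export
chimera_fragments <- function(flags, chart, fragment_length = 300L,
                              path = NULL) {
  frags <- character(0)
  for (a in unique(flags$asv_id)) {
    s <- chart$sequence[[a]]
    n <- nchar(s)
    frags[paste0(a, "__head")] <- substr(s, 1, min(fragment_length, n))
    frags[paste0(a, "__tail")] <- substr(s, max(1, n - fragment_length + 1), n)
  }
  if (!is.null(path) && length(frags)) write_fasta(frags, path)
  frags
}
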