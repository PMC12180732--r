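#' Primer definitions
#'
#' A primer is an IUPAC nucleotide string with an orientation. Degenerate
#' codes match any base whose IUPAC set intersects theirs (the usual
#' in-silico PCR convention).
#'
#' @param name primer name
#' @param sequence IUPAC nucleotide string (5'-3')
#' @param orientation `"forward"` or `"reverse"`
#' @return a `primer` list.
#' @export
primer <- function(name, sequence, orientation = c("forward", "reverse")) {
  orientation <- match.arg(orientation)
  sequence <- toupper(sequence)
  if (grepl("[^ACGTRYSWKMBDHVN]", sequence))
    stop("primer '", name, "' contains non-IUPAC characters")
  structure(list(name = name, sequence = sequence,
                 orientation = orientation), class = "primer")
}

#' General eukaryotic V4 primers (TAR-EukF1 / TAR-EukR3)
#'
#' The primer pair delimiting the ~440-nt V4 hypervariable region of the 18S
#' rRNA gene, used to excise V4 sub-sequences from full-length ASVs.
#'
#' @return list with elements `fwd` and `rev` (each a [primer()]).
#' @export
tar_euk_primers <- function() {
  list(fwd = primer("TAR-EukF1", "CCAGCASCYGCGGTAATTCC", "forward"),
       rev = primer("TAR-EukR3", "ACTTTCGTTCTTGATYRA", "reverse"))
}

#' Order-targeted polycystine primer sets
#'
#' The custom ~1450-bp 18S primer pairs designed for each polycystine
#' radiolarian order, shipped as a named configuration for in-silico
#' matching.
#'
#' @param set `"nassellaria"`, `"spumellaria"` or `"collodaria"`
#' @return list with elements `fwd` and `rev`.
#' @export
polycystine_primers <- function(set = c("nassellaria", "spumellaria",
                                        "collodaria")) {
  set <- match.arg(set)
  switch(set,
    nassellaria = list(
      fwd = primer("Nas-F", "GTCGGTAGTGTATTGGRCTAC", "forward"),
      rev = primer("Nas-R", "CYGCAGGTTCACCTACGG", "reverse")),
    spumellaria = list(
      fwd = primer("Spu-F", "GACGTKTCATTCAAATTTCTGCC", "forward"),
      rev = primer("Spu-R", "GTTACGACTTCTCCTTCCTC", "reverse")),
    collodaria = list(
      fwd = primer("Col-F", "GGTTGABCCTGCCAGTAG", "forward"),
      rev = primer("Col-R", "CYTATTGTAGCCCGTGCGC", "reverse")))
}

#' Reverse complement of an IUPAC nucleotide string
#' @param seq nucleotide string
#' @return reverse-complemented string.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Find ungapped primer matches in a sequence
#'
#' Scans for all ungapped alignments of the primer with at most
#' `max_mismatch` IUPAC-compatible mismatches, using Biostrings with
#' ambiguity codes active on both pattern and subject. Reverse primers are
#' additionally scanned as their reverse complement (the orientation in
#' which they appear on the sequenced strand). Matching is case-insensitive.
#'
#' @param seq nucleotide string to scan (non-empty)
#' @param prm a [primer()]
#' @param max_mismatch maximum number of mismatching positions
#' @return data.frame with columns `start` (0-based inclusive), `end`
#'   (0-based exclusive), `mismatches`, `strand_matched` (`"as-given"` or
#'   `"reverse-complement"`), sorted by (mismatches, start). A primer longer
#'   than the sequence yields zero rows.
#' @export
find_primer_sites <- function(seq, prm, max_mismatch = 0L) {
  stopifnot(inherits(prm, "primer"), nzchar(seq))
  seq <- toupper(seq)
  pats <- list(`as-given` = prm$sequence)
  if (prm$orientation == "reverse")
    pats[["reverse-complement"]] <- revcomp(prm$sequence)
  subject <- Biostrings::DNAString(seq)
  hits <- lapply(names(pats), function(strand) {
    pat <- Biostrings::DNAString(pats[[strand]])
    if (length(pat) > length(subject))
      return(NULL)
    m <- Biostrings::matchPattern(pat, subject,
                                  max.mismatch = max_mismatch,
                                  fixed = FALSE)
    # drop matches overhanging the subject (ungapped, fully inside only)
    inb <- BiocGenerics::start(m) >= 1L &
      BiocGenerics::end(m) <= length(subject)
    m <- m[inb]
    if (length(m) == 0) return(NULL)
    mm <- vapply(seq_along(m), function(i)
      Biostrings::neditAt(pat, subject,
                          at = BiocGenerics::start(m)[i],
                          fixed = FALSE), integer(1))
    data.frame(start = BiocGenerics::start(m) - 1L,
               end = BiocGenerics::end(m),
               mismatches = mm,
               strand_matched = strand,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, hits)
  if (is.null(out))
    out <- data.frame(start = integer(0), end = integer(0),
                      mismatches = integer(0),
                      strand_matched = character(0),
                      stringsAsFactors = FALSE)
  out[order(out$mismatches, out$start), , drop = FALSE]
}

#' Extract the V4 sub-region delimited by a primer pair
#'
#' Takes the sub-sequence strictly between the best forward hit and the best
#' reverse hit (primers excluded by default). "Best" is fewest mismatches,
#' ties broken by the leftmost forward / rightmost reverse position, which
#' maximises the enclosed region. Returns `NA` when either primer is absent
#' or the enclosed region is empty or negative (e.g. reverse site upstream of
#' the forward site). Case- and padding-invariant. For genuine 18S inputs the
#' region is ~440 nt.
#'
#' @param seq full-length nucleotide string
#' @param fwd,rev forward and reverse [primer()]s (defaults:
#'   [tar_euk_primers()])
#' @param max_mismatch mismatch tolerance (default 0; up to 2 is useful for
#'   divergent taxa)
#' @param include_primers if `TRUE`, the primer-matched segments are included
#'   in the returned region
#' @return the V4 nucleotide string, or `NA_character_` when absent.
#' @export
extract_v4 <- function(seq, fwd = tar_euk_primers()$fwd,
                       rev = tar_euk_primers()$rev, max_mismatch = 0L,
                       include_primers = FALSE) {
  fh <- find_primer_sites(seq, fwd, max_mismatch)
  rh <- find_primer_sites(seq, rev, max_mismatch)
  if (nrow(fh) == 0 || nrow(rh) == 0) return(NA_character_)
  f <- fh[1L, ]                                  # fewest mismatches, leftmost
  rh <- rh[order(rh$mismatches, -rh$start), , drop = FALSE]
  r <- rh[1L, ]                                  # fewest mismatches, rightmost
  from <- if (include_primers) f$start + 1L else f$end + 1L
  to <- if (include_primers) r$end else r$start
  if (to < from) return(NA_character_)
  substr(toupper(seq), from, to)
}

#' Merge ASVs with identical V4 regions into a V4 occurrence chart
#'
#' Extracts the V4 region of every ASV in a vetted chart and sums read
#' counts over ASVs sharing an identical extracted V4 string. ASVs without
#' an extractable V4 are excluded and reported. Per-specimen read totals are
#' conserved over the merged subset. Rows backed by more than one source ASV
#' carry the `merged` flag, mirroring the supplementary-layout convention.
#'
#' @inheritParams extract_v4
#' @param chart a vetted [occurrence_chart()]
#' @return an `occurrence_chart` (subclass `v4_table`) keyed by V4 sequence,
#'   with attributes `provenance` (named list: v4 id -> source asv_ids) and
#'   `no_v4` (asv_ids lacking an extractable V4).
#' @export
merge_by_v4 <- function(chart, fwd = tar_euk_primers()$fwd,
                        rev = tar_euk_primers()$rev, max_mismatch = 0L,
                        include_primers = FALSE) {
  stopifnot(inherits(chart, "occurrence_chart"))
  v4 <- vapply(chart$sequence, extract_v4, character(1),
               fwd = fwd, rev = rev, max_mismatch = max_mismatch,
               include_primers = include_primers)
  has <- !is.na(v4)
  no_v4 <- asv_ids(chart)[!has]
  src <- asv_ids(chart)[has]
  v4 <- v4[has]

  groups <- split(src, v4[src])
  # stable ids: keep the source asv_id for singleton groups, mark merged rows
  ord <- order(vapply(groups, function(g) min(match(g, src)), integer(1)))
  groups <- groups[ord]
  n_merged <- 0L
  ids <- vapply(groups, function(g) {
    if (length(g) == 1L) g else {
      n_merged <<- n_merged + 1L
      sprintf("merged-%03d", n_merged)
    }
  }, character(1))
  counts <- matrix(0L, nrow = length(groups), ncol = ncol(chart$counts),
                   dimnames = list(ids, specimen_ids(chart)))
  for (i in seq_along(groups))
    counts[i, ] <- as.integer(colSums(
      chart$counts[groups[[i]], , drop = FALSE]))

  out <- occurrence_chart(
    counts,
    sequence = stats::setNames(names(groups), ids),
    taxon = stats::setNames(chart$taxon[vapply(groups, `[`, character(1), 1)],
                            ids),
    confidence = stats::setNames(
      chart$confidence[vapply(groups, `[`, character(1), 1)], ids),
    merged = vapply(groups, length, integer(1)) > 1L)
  class(out) <- c("v4_table", class(out))
  attr(out, "provenance") <- stats::setNames(groups, ids)
  attr(out, "no_v4") <- no_v4
  out
}
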