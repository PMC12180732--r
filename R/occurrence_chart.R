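#' Construct an ASV-by-specimen occurrence chart
#'
#' The occurrence chart is the central container of the package: an ASV x
#' specimen matrix of absolute read counts, with one nucleotide sequence, one
#' PR2-style lineage string and one taxonomic-assignment confidence per ASV.
#' Counts are always absolute integers; relative abundances are derived on
#' demand and never stored.
#'
#' @param counts integer matrix, rows = ASVs, columns = specimens. Dimnames
#'   are required and must be unique.
#' @param sequence named character vector of uppercase IUPAC nucleotide
#'   sequences, one per ASV (names matching `rownames(counts)`).
#' @param taxon named character vector of semicolon-delimited lineage strings
#'   per ASV. Defaults to empty strings.
#' @param confidence named numeric vector in \[0, 1\] per ASV. Values outside
#'   the range are clipped with a warning. Defaults to `NA`.
#' @param merged logical vector flagging rows that represent merged V4
#'   sequences (as in the supplementary occurrence-chart layout where such
#'   rows are labelled "merged"). Defaults to `FALSE`.
#' @return An object of class `occurrence_chart`: a list with elements
#'   `counts`, `sequence`, `taxon`, `confidence`, `merged`.
#' @export
occurrence_chart <- function(counts, sequence, taxon = NULL,
                             confidence = NULL, merged = NULL) {
  counts <- as.matrix(counts)
  # R normalises zero-length dimnames to NULL, so empty margins are exempt
  if ((nrow(counts) > 0 && is.null(rownames(counts))) ||
      (ncol(counts) > 0 && is.null(colnames(counts))))
    stop("counts must have ASV row names and specimen column names")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate asv_ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate specimen_ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]),
               collapse = ", "))
  if (any(is.na(counts)) || any(counts < 0))
    stop("counts must be non-negative and non-missing")
  if (any(counts != round(counts)))
    stop("counts must be integers (absolute read counts)")
  storage.mode(counts) <- "integer"
  ids <- rownames(counts)
  if (is.null(ids)) ids <- character(0)

  sequence <- toupper(as.character(sequence))
  if (is.null(names(sequence))) names(sequence) <- ids
  if (!setequal(names(sequence), ids) || length(sequence) != length(ids))
    stop("sequence must be named by asv_id, one entry per ASV")
  sequence <- sequence[ids]
  if (any(!nzchar(sequence)))
    stop("every ASV needs a sequence of length >= 1")
  bad <- grepl("[^ACGTRYSWKMBDHVN-]", sequence)
  if (any(bad))
    stop("non-IUPAC characters in sequences of: ",
         paste(utils::head(ids[bad], 5), collapse = ", "))

  if (is.null(taxon)) taxon <- stats::setNames(rep("", length(ids)), ids)
  if (is.null(names(taxon))) names(taxon) <- ids
  taxon <- as.character(taxon)[match(ids, names(taxon))]
  names(taxon) <- ids
  taxon[is.na(taxon)] <- ""

  if (is.null(confidence))
    confidence <- stats::setNames(rep(NA_real_, length(ids)), ids)
  if (is.null(names(confidence))) names(confidence) <- ids
  confidence <- as.numeric(confidence)[match(ids, names(confidence))]
  names(confidence) <- ids
  out_of_range <- !is.na(confidence) & (confidence < 0 | confidence > 1)
  if (any(out_of_range)) {
    warning(sum(out_of_range),
            " confidence value(s) outside [0,1]; clipped")
    confidence <- pmin(pmax(confidence, 0), 1)
  }

  if (is.null(merged)) merged <- rep(FALSE, length(ids))
  merged <- as.logical(merged)
  if (length(merged) == 1L) merged <- rep(merged, length(ids))
  names(merged) <- ids

  structure(
    list(counts = counts, sequence = sequence, taxon = taxon,
         confidence = confidence, merged = merged),
    class = "occurrence_chart"
  )
}

#' @export
print.occurrence_chart <- function(x, ...) {
  cat("occurrence_chart:", nrow(x$counts), "ASVs x",
      ncol(x$counts), "specimens;",
      format(sum(x$counts), big.mark = ","), "reads total\n")
  invisible(x)
}

#' ASV and specimen identifiers of a chart
#' @param chart an `occurrence_chart`
#' @return character vector of identifiers.
#' @export
asv_ids <- function(chart) rownames(chart$counts) %||% character(0)

#' @rdname asv_ids
#' @export
specimen_ids <- function(chart) colnames(chart$counts) %||% character(0)

#' Subset an occurrence chart by ASVs and/or specimens
#'
#' Keeps the per-ASV annotations in step with the count matrix. Dropping all
#' rows or columns is allowed and yields a degenerate but valid chart.
#'
#' @param chart an `occurrence_chart`
#' @param asvs,specimens character vectors of identifiers to keep (default:
#'   keep all)
#' @return an `occurrence_chart`
#' @export
subset_chart <- function(chart, asvs = asv_ids(chart),
                         specimens = specimen_ids(chart)) {
  stopifnot(inherits(chart, "occurrence_chart"))
  missing_a <- setdiff(asvs, asv_ids(chart))
  missing_s <- setdiff(specimens, specimen_ids(chart))
  if (length(missing_a) || length(missing_s))
    stop("unknown identifiers: ",
         paste(c(missing_a, missing_s), collapse = ", "))
  structure(
    list(counts = chart$counts[asvs, specimens, drop = FALSE],
         sequence = chart$sequence[asvs],
         taxon = chart$taxon[asvs],
         confidence = chart$confidence[asvs],
         merged = chart$merged[asvs]),
    class = class(chart)
  )
}

#' Relative read abundances per specimen
#'
#' Divides each column of the count matrix by its total. Specimens with zero
#' total reads yield `NaN` columns; vetting removes such specimens upstream.
#'
#' @param chart an `occurrence_chart`
#' @return numeric matrix with the dimensions of `chart$counts`.
#' @export
relative_abundance <- function(chart) {
  tot <- colSums(chart$counts)
  sweep(chart$counts, 2, tot, "/")
}

# identical structure and content, ignoring attribute order
charts_equal <- function(a, b) {
  isTRUE(all.equal(a$counts, b$counts)) &&
    identical(a$sequence, b$sequence) &&
    identical(a$taxon, b$taxon) &&
    isTRUE(all.equal(a$confidence, b$confidence)) &&
    identical(a$merged, b$merged)
}
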