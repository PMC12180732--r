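#' Default PR2-style rank scheme
#'
#' Eight-rank ordering used to parse semicolon-delimited lineage strings
#' positionally. The `order` and `family` ranks are the ones consumed by the
#' taxonomic-consistency filter.
#'
#' @return character vector of rank names, outermost first.
#' @export
pr2_ranks <- function() {
  c("domain", "supergroup", "division", "class",
    "order", "family", "genus", "species")
}

#' Parse a semicolon-delimited lineage string
#'
#' Fields are assigned to ranks positionally against an ordered rank scheme.
#' The function is total: ragged, short or empty strings never error; ranks
#' without a field (or with an empty field) become `"unassigned"`.
#'
#' @param taxon_string semicolon-delimited lineage, e.g.
#'   `"Eukaryota;Rhizaria;Radiolaria;Polycystinea;Nassellaria;Pterocorythidae;Pterocorys;Pterocorys_zancleus"`
#' @param scheme ordered character vector of rank names
#'   (default [pr2_ranks()])
#' @return named character vector, one taxon name per rank.
#' @export
parse_lineage <- function(taxon_string, scheme = pr2_ranks()) {
  if (length(taxon_string) != 1L) stop("one lineage string at a time")
  fields <- if (is.na(taxon_string) || !nzchar(trimws(taxon_string)))
    character(0)
  else trimws(strsplit(taxon_string, ";", fixed = TRUE)[[1]])
  out <- rep("unassigned", length(scheme))
  names(out) <- scheme
  n <- min(length(fields), length(scheme))
  if (n > 0) {
    filled <- fields[seq_len(n)]
    filled[!nzchar(filled)] <- "unassigned"
    out[seq_len(n)] <- filled
  }
  out
}

#' Look up one rank of a lineage string
#'
#' @inheritParams parse_lineage
#' @param rank a rank name from `scheme`
#' @return taxon name at that rank, or `"unassigned"`.
#' @export
lineage_rank <- function(taxon_string, rank, scheme = pr2_ranks()) {
  rank <- match.arg(rank, scheme)
  unname(parse_lineage(taxon_string, scheme)[rank])
}

# vectorised family/order lookup used by the vetting filter
lineage_rank_all <- function(taxa, rank, scheme = pr2_ranks()) {
  vapply(taxa, function(t) lineage_rank(t, rank, scheme), character(1),
         USE.NAMES = FALSE)
}

#' Read an occurrence chart
#'
#' Two dialects are supported. `"tsv"` is the canonical on-disk format:
#' columns `asv_id`, `sequence`, `taxon`, `confidence`, then one column of
#' absolute read counts per specimen. `"s1data_xlsx"` imports the multi-sheet
#' supplementary-workbook layout (one sheet per order, header `ASV_ID`,
#' sequence, `Taxon`, `Confidence`, then specimen columns); rows labelled
#' `"merged"` in `ASV_ID` are retained and flagged as merged-V4 rows. All
#' rows are imported, including ASVs with fewer than 3 reads everywhere;
#' empty cells become count 0.
#'
#' @param path file path (TSV) or workbook path (xlsx dialect)
#' @param dialect `"tsv"` or `"s1data_xlsx"`
#' @param sheets for the xlsx dialect, sheet names to import (default: all)
#' @return an [occurrence_chart()]
#' @export
read_occurrence_chart <- function(path, dialect = c("tsv", "s1data_xlsx"),
                                  sheets = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (dialect == "tsv") {
    df <- utils::read.delim(path, sep = "\t", header = TRUE,
                            check.names = FALSE, stringsAsFactors = FALSE,
                            colClasses = "character")
    return(chart_from_table(df, path,
                            id_col = "asv_id", seq_col = "sequence",
                            taxon_col = "taxon", conf_col = "confidence"))
  }
  if (!requireNamespace("readxl", quietly = TRUE))
    stop("the s1data_xlsx dialect requires the readxl package")
  if (is.null(sheets)) sheets <- readxl::excel_sheets(path)
  parts <- lapply(sheets, function(sh) {
    df <- as.data.frame(readxl::read_excel(path, sheet = sh,
                                           col_types = "text"),
                        check.names = FALSE)
    chart_from_table(df, paste0(path, "#", sh),
                     id_col = "ASV_ID", seq_col = 2L,
                     taxon_col = "Taxon", conf_col = "Confidence",
                     allow_merged = TRUE)
  })
  if (length(parts) == 1L) return(parts[[1]])
  bind_charts(parts)
}

# shared table -> chart conversion for both dialects
chart_from_table <- function(df, origin, id_col, seq_col, taxon_col,
                             conf_col, allow_merged = FALSE) {
  cols <- names(df)
  named_needed <- c(if (is.character(id_col)) id_col,
                    if (is.character(seq_col)) seq_col,
                    taxon_col, conf_col)
  missing_cols <- setdiff(named_needed, cols)
  if (length(missing_cols))
    stop("malformed header in ", origin, ": missing column(s) ",
         paste(missing_cols, collapse = ", "))
  seq_col_i <- if (is.character(seq_col)) match(seq_col, cols) else seq_col
  meta_idx <- c(match(id_col, cols), seq_col_i,
                match(taxon_col, cols), match(conf_col, cols))
  spec_cols <- cols[-meta_idx]
  if (anyDuplicated(spec_cols))
    stop("malformed header in ", origin, ": duplicate specimen column(s) ",
         paste(unique(spec_cols[duplicated(spec_cols)]), collapse = ", "))

  ids_raw <- trimws(df[[meta_idx[1]]])
  merged <- tolower(ids_raw) == "merged"
  if (any(merged) && !allow_merged)
    stop("rows labelled 'merged' are only valid in the s1data layout")
  ids <- ids_raw
  if (any(merged))
    ids[merged] <- sprintf("merged-%03d", seq_len(sum(merged)))
  if (anyDuplicated(ids))
    stop("duplicate asv_id values in ", origin, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))

  if (nrow(df) == 0) {
    counts <- matrix(integer(0), nrow = 0, ncol = length(spec_cols),
                     dimnames = list(character(0), spec_cols))
    return(occurrence_chart(counts, sequence = stats::setNames(
      character(0), character(0))))
  }

  counts <- matrix(0L, nrow = nrow(df), ncol = length(spec_cols),
                   dimnames = list(ids, spec_cols))
  for (sc in spec_cols) {
    raw <- trimws(df[[sc]])
    raw[is.na(raw) | raw == ""] <- "0"
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(val) | val != round(val) | val < 0)
    if (length(bad))
      stop("parse error in ", origin, ": non-integer or negative count '",
           df[[sc]][bad[1]], "' at row ", bad[1], ", column '", sc, "'")
    counts[, sc] <- as.integer(val)
  }
  conf <- suppressWarnings(as.numeric(df[[meta_idx[4]]]))
  occurrence_chart(counts,
                   sequence = stats::setNames(toupper(trimws(df[[meta_idx[2]]])), ids),
                   taxon = stats::setNames(trimws(df[[meta_idx[3]]]), ids),
                   confidence = stats::setNames(conf, ids),
                   merged = merged)
}

# row-bind charts from multiple sheets; specimen columns are unioned
bind_charts <- function(parts) {
  all_specs <- unique(unlist(lapply(parts, specimen_ids)))
  all_ids <- unlist(lapply(parts, asv_ids))
  if (anyDuplicated(all_ids))
    stop("duplicate asv_id values across sheets: ",
         paste(unique(all_ids[duplicated(all_ids)]), collapse = ", "))
  counts <- matrix(0L, nrow = length(all_ids), ncol = length(all_specs),
                   dimnames = list(all_ids, all_specs))
  for (p in parts) counts[asv_ids(p), specimen_ids(p)] <- p$counts
  occurrence_chart(counts,
                   sequence = unlist(lapply(parts, `[[`, "sequence")),
                   taxon = unlist(lapply(parts, `[[`, "taxon")),
                   confidence = unlist(lapply(parts, `[[`, "confidence")),
                   merged = unlist(lapply(parts, `[[`, "merged")))
}

#' Write an occurrence chart as canonical TSV
#'
#' Round-trip identity holds: `read_occurrence_chart(write_occurrence_chart(x))`
#' equals `x`. Sequences (including IUPAC-degenerate bases) are written
#' verbatim.
#'
#' @param chart an [occurrence_chart()]
#' @param path output file path
#' @return `path`, invisibly.
#' @export
write_occurrence_chart <- function(chart, path) {
  stopifnot(inherits(chart, "occurrence_chart"))
  df <- data.frame(asv_id = asv_ids(chart),
                   sequence = unname(chart$sequence),
                   taxon = unname(chart$taxon),
                   confidence = unname(chart$confidence),
                   check.names = FALSE, stringsAsFactors = FALSE)
  cnt <- as.data.frame(chart$counts, check.names = FALSE)
  df <- if (nrow(df)) cbind(df, cnt) else
    stats::setNames(
      as.data.frame(matrix(nrow = 0, ncol = 4 + ncol(chart$counts))),
      c("asv_id", "sequence", "taxon", "confidence", specimen_ids(chart)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read and write FASTA files
#'
#' `read_fasta()` returns an insertion-order-preserving named character
#' vector with sequences normalised to uppercase; duplicate identifiers are
#' an error. `write_fasta()` writes a named character vector. The pair is
#' round-trip stable after normalisation. Backed by Biostrings.
#'
#' @param path file path
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path, format = "fasta")
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  stats::setNames(toupper(as.character(set)), ids)
}

#' @rdname read_fasta
#' @param sequences named character vector of nucleotide sequences
#' @export
write_fasta <- function(sequences, path) {
  if (is.null(names(sequences)) || any(!nzchar(names(sequences))))
    stop("sequences must be named")
  set <- Biostrings::BStringSet(sequences)
  Biostrings::writeXStringSet(set, path, format = "fasta")
  invisible(path)
}

#' Read and write specimen metadata
#'
#' TSV with columns `specimen_id`, `morphotaxon`, `morph_rank`, `order`,
#' `family`, `relaxed_filter`. `morph_rank` is one of species, genus, family,
#' order, indeterminate. `relaxed_filter` marks naked or putative-juvenile
#' specimens that lack a confident family-level morphological identification;
#' for those, the taxonomic-consistency filter accepts any polycystine
#' assignment. The invariant that `relaxed_filter` is only set when the
#' family is unknown or the rank indeterminate is enforced on read.
#'
#' @param path file path
#' @return data.frame of specimen metadata.
#' @export
read_specimen_meta <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  validate_specimen_meta(df)
}

#' @rdname read_specimen_meta
#' @param meta specimen metadata data.frame
#' @export
write_specimen_meta <- function(meta, path) {
  meta <- validate_specimen_meta(meta)
  utils::write.table(meta, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

validate_specimen_meta <- function(df) {
  need <- c("specimen_id", "morphotaxon", "morph_rank", "order", "family",
            "relaxed_filter")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("specimen metadata missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (anyDuplicated(df$specimen_id))
    stop("duplicate specimen_id in metadata")
  ok_rank <- c("species", "genus", "family", "order", "indeterminate")
  bad <- setdiff(unique(df$morph_rank), ok_rank)
  if (length(bad))
    stop("invalid morph_rank value(s): ", paste(bad, collapse = ", "))
  df$relaxed_filter <- as.logical(df$relaxed_filter)
  viol <- df$relaxed_filter &
    !(tolower(df$family) == "unknown" | df$morph_rank == "indeterminate")
  if (any(viol))
    stop("relaxed_filter=TRUE requires family 'unknown' or indeterminate ",
         "rank; offending specimen(s): ",
         paste(df$specimen_id[viol], collapse = ", "))
  df
}
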