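#' Per-specimen ASV richness at relative-abundance thresholds
#'
#' Relative abundance of ASV a in specimen s is c(a,s) divided by the
#' specimen's post-vetting total. An ASV counts towards threshold t when its
#' relative abundance is at least t (inclusive, "at least"); threshold 0
#' means simple presence (count > 0).
#'
#' @param chart a vetted [occurrence_chart()]
#' @param thresholds numeric vector of relative-abundance thresholds
#' @param meta optional specimen metadata; when supplied, an `order` column
#'   is attached
#' @return data.frame with `specimen_id`, optional `order`, `n_asvs_total`,
#'   and one `n_at_<t>` column per threshold. Richness is non-increasing in
#'   the threshold.
#' @export
richness_per_specimen <- function(chart, thresholds = c(0.001, 0.01, 0.10),
                                  meta = NULL) {
  stopifnot(inherits(chart, "occurrence_chart"))
  tot <- colSums(chart$counts)
  if (any(tot == 0))
    stop("specimen(s) with zero total reads (vet the chart first): ",
         paste(names(tot)[tot == 0], collapse = ", "))
  rel <- relative_abundance(chart)
  out <- data.frame(specimen_id = specimen_ids(chart),
                    n_asvs_total = unname(colSums(chart$counts > 0L)),
                    stringsAsFactors = FALSE, row.names = NULL)
  for (t in thresholds)
    out[[sprintf("n_at_%g", t)]] <-
      if (t <= 0) unname(colSums(chart$counts > 0L))
      else unname(colSums(rel >= t))
  if (!is.null(meta)) {
    meta <- validate_specimen_meta(meta)
    out$order <- meta$order[match(out$specimen_id, meta$specimen_id)]
    out <- out[, c("specimen_id", "order",
                   setdiff(names(out), c("specimen_id", "order")))]
  }
  out
}

#' Rank-abundance profiles of the top ASVs per specimen
#'
#' ASVs are ranked by decreasing read count within each specimen; exact ties
#' are broken lexicographically by asv_id so the profile is deterministic.
#' Absent ranks (specimens with fewer ASVs than `top_n`) are omitted.
#'
#' @param chart a vetted [occurrence_chart()]
#' @param top_n number of ranks to report (default 10)
#' @return long data.frame with `specimen_id`, `rank`, `asv_id`,
#'   `rel_abundance`.
#' @export
rank_abundance_profiles <- function(chart, top_n = 10L) {
  stopifnot(inherits(chart, "occurrence_chart"))
  tot <- colSums(chart$counts)
  rows <- lapply(specimen_ids(chart), function(s) {
    cnt <- chart$counts[, s]
    cnt <- cnt[cnt > 0L]
    if (!length(cnt)) return(NULL)
    ord <- order(-cnt, names(cnt))
    keep <- utils::head(ord, top_n)
    data.frame(specimen_id = s,
               rank = seq_along(keep),
               asv_id = names(cnt)[keep],
               rel_abundance = unname(cnt[keep] / tot[s]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(specimen_id = character(0), rank = integer(0),
                      asv_id = character(0), rel_abundance = numeric(0))
  out
}

#' Per-order summaries of richness records or rank profiles
#'
#' Summarises a numeric column by taxonomic order. The median of an
#' even-sized group is the mean of the two central values, so half-integer
#' medians (e.g. 5.5 ASVs) are representable. Empty orders are omitted with
#' a warning.
#'
#' @param records data.frame containing an `order` column (e.g. from
#'   [richness_per_specimen()] with `meta`, or a rank profile joined to
#'   metadata)
#' @param column name of the numeric column to summarise
#' @param statistics subset of `c("median", "min", "max")`
#' @return data.frame with one row per order.
#' @export
order_summary <- function(records, column,
                          statistics = c("median", "min", "max")) {
  statistics <- match.arg(statistics, several.ok = TRUE)
  if (!all(c("order", column) %in% names(records)))
    stop("records must contain columns 'order' and '", column, "'")
  orders <- unique(records$order)
  rows <- lapply(orders, function(o) {
    v <- records[[column]][records$order == o]
    v <- v[!is.na(v)]
    if (!length(v)) {
      warning("order '", o, "' has no data; omitted")
      return(NULL)
    }
    row <- data.frame(order = o, n = length(v), stringsAsFactors = FALSE)
    for (s in statistics)
      row[[s]] <- switch(s, median = stats::median(v), min = min(v),
                         max = max(v))
    row
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no non-empty order groups")
  out
}
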