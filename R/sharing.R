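#' Dominant ASV(s) of a specimen
#'
#' The dominant set is the set of ASVs attaining the specimen's maximum read
#' count: a singleton except under exact ties, which are preserved and
#' flagged rather than broken arbitrarily.
#'
#' @param chart a vetted [occurrence_chart()]
#' @param specimen_id one specimen identifier present in the chart
#' @return list with `specimen_id`, `dominant_asvs` (character), `dominant_share`
#'   (fraction of the specimen's reads held by one dominant ASV) and `tie`
#'   (logical).
#' @export
dominant_set <- function(chart, specimen_id) {
  stopifnot(inherits(chart, "occurrence_chart"))
  if (!specimen_id %in% specimen_ids(chart))
    stop("unknown specimen: ", specimen_id)
  cnt <- chart$counts[, specimen_id]
  cnt <- cnt[cnt > 0L]
  if (!length(cnt)) stop("specimen ", specimen_id, " has no ASVs")
  mx <- max(cnt)
  dom <- sort(names(cnt)[cnt == mx])
  list(specimen_id = specimen_id,
       dominant_asvs = dom,
       dominant_share = mx / sum(cnt),
       tie = length(dom) > 1L)
}

#' Shared-ASV prevalence across a specimen subset
#'
#' For each ASV, the number and fraction of specimens in the subset that
#' contain it with at least `min_presence` reads (the same presence rule as
#' vetting), and its summed read abundance over the subset. Any log
#' transform for display is left to the caller.
#'
#' @param chart a vetted [occurrence_chart()]
#' @param specimens character vector of specimen ids (default: all)
#' @param min_presence presence threshold in reads (default 3)
#' @return data.frame with `asv_id`, `n_specimens_present`, `pct_specimens`,
#'   `total_reads`, restricted to ASVs with at least one read in the subset.
#' @export
asv_prevalence <- function(chart, specimens = specimen_ids(chart),
                           min_presence = 3L) {
  stopifnot(inherits(chart, "occurrence_chart"), length(specimens) > 0)
  sub <- chart$counts[, specimens, drop = FALSE]
  keep <- rowSums(sub) > 0L
  sub <- sub[keep, , drop = FALSE]
  data.frame(asv_id = rownames(sub),
             n_specimens_present = rowSums(sub >= min_presence),
             pct_specimens = rowSums(sub >= min_presence) / length(specimens),
             total_reads = rowSums(sub),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Three-way classification of intraspecies ASV variation
#'
#' Classifies a morphospecies (>= 2 specimens morphologically identified to
#' species rank) into one of three mutually exclusive, exhaustive
#' categories:
#' \describe{
#'   \item{SHARED_DOMINANT}{a single ASV belongs to every specimen's
#'     dominant set;}
#'   \item{SHARED_ASV_DIFFERENT_DOMINANTS}{no universally dominant ASV, but
#'     at least one ASV is present (>= `min_presence` reads) in every
#'     specimen;}
#'   \item{NO_UNIVERSAL_ASV}{no ASV is present in all specimens — the
#'     pattern suggestive of separate genetic subgroups (possible cryptic
#'     species).}
#' }
#'
#' @param chart a vetted [occurrence_chart()]
#' @param meta specimen metadata
#' @param morphospecies morphotaxon name to classify
#' @param min_presence presence threshold in reads (default 3)
#' @return list with `morphospecies`, `n_specimens`, `category`, and
#'   `universal_asvs` (ASVs present in all specimens, possibly empty).
#' @export
classify_morphospecies <- function(chart, meta, morphospecies,
                                   min_presence = 3L) {
  meta <- validate_specimen_meta(meta)
  specs <- meta$specimen_id[meta$morphotaxon == morphospecies &
                              meta$morph_rank == "species"]
  specs <- intersect(specs, specimen_ids(chart))
  if (length(specs) < 2)
    stop("unclassifiable: fewer than 2 species-rank specimens of '",
         morphospecies, "' in the chart")
  dom_sets <- lapply(specs, function(s) dominant_set(chart, s)$dominant_asvs)
  shared_dominant <- Reduce(intersect, dom_sets)
  present <- chart$counts[, specs, drop = FALSE] >= min_presence
  universal <- rownames(present)[rowSums(present) == length(specs)]
  category <- if (length(shared_dominant) > 0) "SHARED_DOMINANT"
  else if (length(universal) > 0) "SHARED_ASV_DIFFERENT_DOMINANTS"
  else "NO_UNIVERSAL_ASV"
  list(morphospecies = morphospecies,
       n_specimens = length(specs),
       category = category,
       universal_asvs = universal)
}

#' Classify every eligible morphospecies in a dataset
#'
#' Applies [classify_morphospecies()] to each morphotaxon with at least two
#' species-rank specimens present in the chart. Genus-level and
#' open-nomenclature groups are excluded.
#'
#' @inheritParams classify_morphospecies
#' @return data.frame with `morphospecies`, `order`, `n_specimens`,
#'   `category`.
#' @export
classify_all_morphospecies <- function(chart, meta, min_presence = 3L) {
  meta <- validate_specimen_meta(meta)
  sp <- meta[meta$morph_rank == "species" &
               meta$specimen_id %in% specimen_ids(chart), ]
  tab <- table(sp$morphotaxon)
  eligible <- names(tab)[tab >= 2]
  rows <- lapply(eligible, function(m) {
    cl <- classify_morphospecies(chart, meta, m, min_presence)
    data.frame(morphospecies = m,
               order = sp$order[match(m, sp$morphotaxon)],
               n_specimens = cl$n_specimens,
               category = cl$category,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(morphospecies = character(0), order = character(0),
                      n_specimens = integer(0), category = character(0))
  out[order(out$order, out$morphospecies), , drop = FALSE]
}
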