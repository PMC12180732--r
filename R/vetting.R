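#' Vetting thresholds
#'
#' Defaults encode the study's inclusion rules for single-specimen long-read
#' ASV tables: an ASV is present in a specimen only with >= 3 reads there;
#' an ASV is kept at all only with >= 3 reads in at least one specimen; a
#' specimen is kept only with >= 5 taxonomically-consistent reads surviving;
#' taxonomic assignments below confidence 0.3 are dropped.
#'
#' @param min_reads_presence per-cell presence threshold (reads)
#' @param min_specimen_reads minimum surviving reads for a specimen
#' @param min_asv_reads_somewhere minimum reads in at least one specimen for
#'   an ASV to be retained globally
#' @param min_confidence minimum taxonomic assignment confidence
#' @param scope_for_relaxed orders accepted for relaxed-filter specimens
#'   (naked/juvenile): any assignment within these orders passes
#' @param strict_reevaluate if `TRUE`, the global ASV rule is re-applied
#'   after specimen removal (the narrative order of the filters leaves this
#'   ambiguous; the default evaluates it before, and [vet_dataset()] reports
#'   how many ASVs the strict mode would additionally drop)
#' @return a `vetting_config` list.
#' @export
vetting_config <- function(min_reads_presence = 3L,
                           min_specimen_reads = 5L,
                           min_asv_reads_somewhere = 3L,
                           min_confidence = 0.3,
                           scope_for_relaxed = c("Collodaria", "Nassellaria",
                                                 "Spumellaria"),
                           strict_reevaluate = FALSE) {
  stopifnot(min_reads_presence >= 0, min_specimen_reads >= 0,
            min_asv_reads_somewhere >= 0, min_confidence >= 0)
  structure(list(min_reads_presence = as.integer(min_reads_presence),
                 min_specimen_reads = as.integer(min_specimen_reads),
                 min_asv_reads_somewhere = as.integer(min_asv_reads_somewhere),
                 min_confidence = min_confidence,
                 scope_for_relaxed = scope_for_relaxed,
                 strict_reevaluate = isTRUE(strict_reevaluate)),
            class = "vetting_config")
}

#' Taxonomic-consistency filter
#'
#' Removes, per specimen, read counts of ASVs whose assigned family does not
#' match the specimen's morphological family (string equality on the parsed
#' family rank after trimming and case-folding). Specimens flagged
#' `relaxed_filter` (naked or putative juvenile, no confident family) retain
#' any ASV assigned within a polycystine order. ASVs whose assignment
#' confidence is below `cfg$min_confidence` are removed everywhere first.
#'
#' @param chart an [occurrence_chart()]
#' @param meta specimen metadata (see [read_specimen_meta()]) covering every
#'   specimen column of `chart`
#' @param cfg a [vetting_config()]
#' @return list with elements `chart` (filtered) and `report` (a fragment
#'   with `removed_low_confidence` and `removed_by_taxonomy`).
#' @export
filter_taxonomy_consistency <- function(chart, meta, cfg = vetting_config()) {
  stopifnot(inherits(chart, "occurrence_chart"))
  meta <- validate_specimen_meta(meta)
  missing_meta <- setdiff(specimen_ids(chart), meta$specimen_id)
  if (length(missing_meta))
    stop("specimen(s) without metadata: ",
         paste(missing_meta, collapse = ", "))

  low_conf <- !is.na(chart$confidence) &
    chart$confidence < cfg$min_confidence
  removed_low_confidence <- data.frame(
    asv_id = asv_ids(chart)[low_conf],
    confidence = unname(chart$confidence[low_conf]),
    stringsAsFactors = FALSE)
  chart2 <- subset_chart(chart, asvs = asv_ids(chart)[!low_conf])

  fam_asv <- norm_name(lineage_rank_all(chart2$taxon, "family"))
  ord_asv <- norm_name(lineage_rank_all(chart2$taxon, "order"))
  meta_i <- meta[match(specimen_ids(chart2), meta$specimen_id), ]
  scope <- norm_name(cfg$scope_for_relaxed)

  counts <- chart2$counts
  removed <- vector("list", ncol(counts))
  for (j in seq_len(ncol(counts))) {
    keep <- if (isTRUE(meta_i$relaxed_filter[j]))
      ord_asv %in% scope
    else
      fam_asv == norm_name(meta_i$family[j])
    drop <- which(!keep & counts[, j] > 0L)
    if (length(drop)) {
      removed[[j]] <- data.frame(
        asv_id = rownames(counts)[drop],
        specimen_id = colnames(counts)[j],
        count = counts[drop, j],
        assigned_family = fam_asv[drop],
        expected_family = if (isTRUE(meta_i$relaxed_filter[j]))
          "<any polycystine order>" else norm_name(meta_i$family[j]),
        stringsAsFactors = FALSE)
      counts[drop, j] <- 0L
    }
  }
  chart2$counts <- counts
  list(chart = chart2,
       report = list(
         removed_low_confidence = removed_low_confidence,
         removed_by_taxonomy = do.call(rbind, c(
           removed[!vapply(removed, is.null, logical(1))],
           list(empty_taxonomy_frame())))))
}

norm_name <- function(x) tolower(trimws(x))

empty_taxonomy_frame <- function() {
  data.frame(asv_id = character(0), specimen_id = character(0),
             count = integer(0), assigned_family = character(0),
             expected_family = character(0), stringsAsFactors = FALSE)
}

#' Abundance thresholds
#'
#' Applies, in order: (1) the per-cell presence rule (counts below
#' `min_reads_presence` are zeroed); (2) the global ASV rule (ASVs with no
#' specimen reaching `min_asv_reads_somewhere` are removed entirely); (3) the
#' specimen rule (specimens whose surviving total is below
#' `min_specimen_reads` are removed). With `cfg$strict_reevaluate`, rule (2)
#' is applied again after (3).
#'
#' @inheritParams filter_taxonomy_consistency
#' @return list with `chart` and `report` fragment (`removed_by_presence`,
#'   `removed_asvs_global`, `removed_specimens`,
#'   `strict_additional_asvs_removed`).
#' @export
apply_count_thresholds <- function(chart, cfg = vetting_config()) {
  stopifnot(inherits(chart, "occurrence_chart"))
  counts <- chart$counts

  below <- which(counts > 0L & counts < cfg$min_reads_presence,
                 arr.ind = TRUE)
  removed_by_presence <- data.frame(
    asv_id = rownames(counts)[below[, 1]],
    specimen_id = colnames(counts)[below[, 2]],
    count = counts[below],
    stringsAsFactors = FALSE)
  counts[below] <- 0L

  global_gone <- rownames(counts)[apply_max(counts) < cfg$min_asv_reads_somewhere]
  chart2 <- chart
  chart2$counts <- counts
  chart2 <- subset_chart(chart2, asvs = setdiff(rownames(counts), global_gone))

  surv <- colSums(chart2$counts)
  spec_gone <- names(surv)[surv < cfg$min_specimen_reads]
  removed_specimens <- data.frame(
    specimen_id = spec_gone,
    surviving_reads = unname(surv[spec_gone]),
    stringsAsFactors = FALSE)
  chart2 <- subset_chart(chart2,
                         specimens = setdiff(specimen_ids(chart2), spec_gone))

  # ASVs whose only surviving reads sat in removed specimens are now
  # all-zero; dropping them keeps vetting idempotent and costs no reads
  # (attributed to the specimen stage, not the global ASV rule)
  zero_rows <- asv_ids(chart2)[apply_max(chart2$counts) == 0L]
  chart2 <- subset_chart(chart2, asvs = setdiff(asv_ids(chart2), zero_rows))

  # strict mode: re-evaluate the global ASV rule after specimen removal
  # (differs from the default only when min_asv_reads_somewhere exceeds
  # min_reads_presence)
  would_go <- asv_ids(chart2)[
    apply_max(chart2$counts) < cfg$min_asv_reads_somewhere]
  strict_mass <- 0L
  if (isTRUE(cfg$strict_reevaluate) && length(would_go)) {
    strict_mass <- sum(chart2$counts[would_go, , drop = FALSE])
    chart2 <- subset_chart(chart2, asvs = setdiff(asv_ids(chart2), would_go))
  }
  # in default mode would_go is reported, not removed

  list(chart = chart2,
       report = list(removed_by_presence = removed_by_presence,
                     removed_asvs_global = global_gone,
                     removed_specimens = removed_specimens,
                     removed_with_specimens = zero_rows,
                     strict_additional_asvs_removed = would_go,
                     strict_mass = strict_mass))
}

apply_max <- function(m) {
  if (ncol(m) == 0) rep(0L, nrow(m)) else apply(m, 1, max)
}

#' Vet a dataset: taxonomy filter, then abundance thresholds
#'
#' Deterministic and idempotent composition of
#' [filter_taxonomy_consistency()] and [apply_count_thresholds()], with an
#' auditable report. Every read of the input is attributed to exactly one
#' fate: retained, removed as low-confidence, removed by the taxonomy rule,
#' zeroed by the presence rule, removed with a globally-failing ASV, or
#' removed with a failing specimen (partition property; see
#' `report$mass_balance`).
#'
#' @inheritParams filter_taxonomy_consistency
#' @return list with `chart` (vetted) and `report` (class `vetting_report`).
#' @export
vet_dataset <- function(chart, meta, cfg = vetting_config()) {
  input_mass <- sum(chart$counts)
  s1 <- filter_taxonomy_consistency(chart, meta, cfg)
  s2 <- apply_count_thresholds(s1$chart, cfg)
  out <- s2$chart

  meta <- validate_specimen_meta(meta)
  meta_kept <- meta[match(specimen_ids(out), meta$specimen_id), ]
  retained_summary <- if (nrow(meta_kept)) {
    present <- out$counts > 0L
    orders <- sort(unique(meta_kept$order))
    do.call(rbind, lapply(orders, function(o) {
      sel <- meta_kept$order == o
      data.frame(order = o,
                 n_specimens = sum(sel),
                 n_asvs = sum(apply_max(out$counts[, sel, drop = FALSE]) > 0L),
                 stringsAsFactors = FALSE)
    }))
  } else data.frame(order = character(0), n_specimens = integer(0),
                    n_asvs = integer(0))

  frag <- c(s1$report, s2$report)
  mass <- list(
    input = input_mass,
    retained = sum(out$counts),
    low_confidence = sum_mass(chart, frag$removed_low_confidence$asv_id),
    taxonomy = sum(frag$removed_by_taxonomy$count),
    presence = sum(frag$removed_by_presence$count),
    global_asvs = sum_mass(s1_after_presence(s1$chart, cfg),
                           frag$removed_asvs_global),
    specimens = sum(frag$removed_specimens$surviving_reads),
    strict_extra = frag$strict_mass)
  report <- structure(c(frag, list(retained_summary = retained_summary,
                                   mass_balance = mass,
                                   config = cfg)),
                      class = "vetting_report")
  list(chart = out, report = report)
}

# helper: the chart state at which the global-ASV rule fires
s1_after_presence <- function(chart, cfg) {
  chart$counts[chart$counts < cfg$min_reads_presence] <- 0L
  chart
}

sum_mass <- function(chart, ids) {
  if (!length(ids)) return(0L)
  sum(chart$counts[ids, , drop = FALSE])
}

#' @export
print.vetting_report <- function(x, ...) {
  m <- x$mass_balance
  cat("vetting_report\n")
  cat("  reads in:", m$input, " retained:", m$retained, "\n")
  cat("  removed: low-confidence", m$low_confidence,
      "| taxonomy", m$taxonomy, "| presence", m$presence,
      "| global-ASV", m$global_asvs, "| specimens", m$specimens, "\n")
  cat("  ASVs removed globally:", length(x$removed_asvs_global),
      " specimens removed:", nrow(x$removed_specimens), "\n")
  if (nrow(x$retained_summary)) {
    cat("  retained per order:\n")
    print(x$retained_summary, row.names = FALSE)
  }
  invisible(x)
}

#' Serialise a vetting report to JSON
#'
#' @param report a `vetting_report`
#' @param path output path
#' @return `path`, invisibly.
#' @export
write_vetting_report <- function(report, path) {
  stopifnot(inherits(report, "vetting_report"))
  x <- unclass(report)
  x$config <- unclass(x$config)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
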