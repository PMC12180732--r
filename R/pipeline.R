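#' Run the full analysis pipeline from one configuration
#'
#' Orchestrates vetting, V4 extraction/merging, richness and rank-abundance
#' profiling, shared-ASV classification, hierarchical p-distances and
#' (optionally) chimera flagging, writing every stage's table to the output
#' directory and returning a machine-readable run report. Deterministic
#' given its inputs; a stage failure is recorded in the report without
#' destroying the outputs of earlier stages.
#'
#' @param config a named list, or a path to a YAML/JSON file, with entries:
#'   \describe{
#'     \item{chart, meta}{paths to the occurrence chart and specimen
#'       metadata TSVs (required)}
#'     \item{tree}{optional newick path; without it the chimera stage is
#'       skipped and recorded as `"skipped: no tree"`}
#'     \item{alignment}{optional aligned FASTA used for p-distances in
#'       place of the chart's raw sequences}
#'     \item{out_dir}{output directory (required)}
#'     \item{vetting}{optional list of [vetting_config()] overrides}
#'     \item{thresholds}{richness thresholds (default 0.001, 0.01, 0.10)}
#'     \item{max_mismatch}{V4 primer mismatch tolerance (default 0)}
#'     \item{long_branch_factor, read_threshold}{chimera heuristic knobs}
#'   }
#' @return a `run_report` list (stage records, parameters, output paths,
#'   headline numbers).
#' @export
run_pipeline <- function(config) {
  cfg <- load_pipeline_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(parameters = cfg[setdiff(names(cfg), "vetting_config")],
                 stages = list())
  note <- function(stage, status, outputs = character(0), summary = list())
    report$stages[[stage]] <<- list(status = status, outputs = outputs,
                                    summary = summary)
  out_path <- function(f) file.path(cfg$out_dir, f)

  chart <- read_occurrence_chart(cfg$chart)
  meta <- read_specimen_meta(cfg$meta)
  note("input", "ok", summary = list(
    n_asvs = nrow(chart$counts), n_specimens = ncol(chart$counts),
    total_reads = sum(chart$counts)))

  res <- try({
    v <- vet_dataset(chart, meta, cfg$vetting_config)
    write_occurrence_chart(v$chart, out_path("vetted_chart.tsv"))
    write_vetting_report(v$report, out_path("vetting_report.json"))
    v
  }, silent = TRUE)
  if (inherits(res, "try-error")) {
    note("vetting", paste("error:", attr(res, "condition")$message))
    return(finish_report(report, cfg))
  }
  vetted <- res$chart
  note("vetting", "ok",
       c(out_path("vetted_chart.tsv"), out_path("vetting_report.json")),
       summary = list(
         n_asvs = nrow(vetted$counts), n_specimens = ncol(vetted$counts),
         retained_per_order = res$report$retained_summary))

  v4 <- try({
    tab <- merge_by_v4(vetted, max_mismatch = cfg$max_mismatch)
    write_occurrence_chart(tab, out_path("v4_chart.tsv"))
    tab
  }, silent = TRUE)
  if (inherits(v4, "try-error")) {
    note("v4", paste("error:", attr(v4, "condition")$message))
    v4 <- NULL
  } else
    note("v4", "ok", out_path("v4_chart.tsv"), summary = list(
      n_v4 = nrow(v4$counts), n_without_v4 = length(attr(v4, "no_v4"))))

  rich <- richness_per_specimen(vetted, cfg$thresholds, meta)
  utils::write.table(rich, out_path("richness.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  prof <- rank_abundance_profiles(vetted)
  prof$order <- meta$order[match(prof$specimen_id, meta$specimen_id)]
  utils::write.table(prof, out_path("rank_profiles.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  note("richness", "ok",
       c(out_path("richness.tsv"), out_path("rank_profiles.tsv")),
       summary = list(
         median_asvs_per_specimen = stats::median(rich$n_asvs_total),
         per_order = order_summary(rich, "n_asvs_total")))

  cls <- classify_all_morphospecies(vetted, meta)
  utils::write.table(cls, out_path("categories.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  prev <- asv_prevalence(vetted)
  utils::write.table(prev, out_path("prevalence.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  note("classification", "ok",
       c(out_path("categories.tsv"), out_path("prevalence.tsv")),
       summary = list(category_counts = as.list(table(cls$category))))

  pd <- try({
    seqs <- if (!is.null(cfg$alignment)) read_fasta(cfg$alignment)
    else vetted$sequence
    h <- pdistance_hierarchy(vetted, meta, sequences = seqs)
    utils::write.table(h, out_path("pdistances.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    h
  }, silent = TRUE)
  if (inherits(pd, "try-error"))
    note("pdistance", paste("error:", attr(pd, "condition")$message))
  else {
    med <- stats::aggregate(mean_p ~ level + order, pd, stats::median,
                            na.action = stats::na.omit)
    note("pdistance", "ok", out_path("pdistances.tsv"),
         summary = list(median_mean_p = med))
  }

  if (is.null(cfg$tree)) {
    note("chimera_flags", "skipped: no tree")
  } else {
    fl <- try({
      flags <- flag_chimera_candidates(cfg$tree, vetted,
                                       cfg$long_branch_factor,
                                       cfg$read_threshold)
      utils::write.table(flags, out_path("chimera_flags.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      if (nrow(flags))
        chimera_fragments(flags, vetted,
                          path = out_path("chimera_fragments.fasta"))
      flags
    }, silent = TRUE)
    if (inherits(fl, "try-error"))
      note("chimera_flags", paste("error:", attr(fl, "condition")$message))
    else
      note("chimera_flags", "ok", out_path("chimera_flags.tsv"),
           summary = list(n_flagged = length(unique(fl$asv_id))))
  }
  finish_report(report, cfg)
}

load_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    ext <- tolower(tools::file_ext(config))
    config <- if (ext %in% c("yml", "yaml")) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("YAML configs require the yaml package")
      yaml::read_yaml(config)
    } else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  for (k in c("chart", "meta", "out_dir"))
    if (is.null(config[[k]])) stop("config is missing '", k, "'")
  for (k in c("chart", "meta", "tree", "alignment"))
    if (!is.null(config[[k]]) && !file.exists(config[[k]]))
      stop("config input does not exist: ", config[[k]])
  defaults <- list(thresholds = c(0.001, 0.01, 0.10), max_mismatch = 0L,
                   long_branch_factor = 3, read_threshold = 50L)
  for (k in names(defaults))
    if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
  config$thresholds <- sort(as.numeric(config$thresholds))
  config$vetting_config <- do.call(vetting_config,
                                   as.list(config$vetting %||% list()))
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

finish_report <- function(report, cfg) {
  report$ok <- all(vapply(report$stages, function(s)
    !startsWith(s$status, "error"), logical(1)))
  report$out_dir <- cfg$out_dir
  class(report) <- "run_report"
  report
}

#' Serialise a run report
#'
#' @param report a `run_report` from [run_pipeline()]
#' @param path output path (default `report.json` in the run's output
#'   directory)
#' @return `path`, invisibly.
#' @export
make_report <- function(report, path = file.path(report$out_dir,
                                                 "report.json")) {
  stopifnot(inherits(report, "run_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, dataframe = "rows", force = TRUE)
  invisible(path)
}

#' @export
print.run_report <- function(x, ...) {
  cat("run_report (", if (isTRUE(x$ok)) "ok" else "with errors", ")\n",
      sep = "")
  for (s in names(x$stages))
    cat(sprintf("  %-15s %s\n", s, x$stages[[s]]$status))
  invisible(x)
}
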