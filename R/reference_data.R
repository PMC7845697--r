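#' Bundled reference evaluation tables
#'
#' Per-disease AUROC values previously reported for this screening approach
#' at full data scale (partially connected and fully connected variants,
#' single-block ablations, classical machine-learning baselines, and the
#' natural-compound test sets with verified or verified-plus-inferred
#' effects). Bundled as the worked example for the report-summary utilities:
#' [summarize_values()] reproduces each table's average row from the
#' per-disease values.
#'
#' @return `data.frame` with a `disease` column and one AUROC column per
#'   model variant.
#' @export
reference_auroc_tables <- function() {
  utils::read.delim(
    system.file("extdata", "reference_auroc_tables.tsv",
                package = "phytoscreen"),
    stringsAsFactors = FALSE, check.names = FALSE
  )
}

#' Bundled reference literature-statistics summary
#'
#' Reported mean and SD of the literature co-occurrence count, mean Jaccard
#' index and Fisher-significant pair counts for the high-scored,
#' low-scored and random prediction sets at full corpus scale; the worked
#' example for ratio computations on [literature_report()]-style summaries
#' (e.g. the high-scored/random mean co-occurrence ratio of 3.8).
#'
#' @return `data.frame`, one row per prediction set.
#' @export
reference_literature_summary <- function() {
  utils::read.delim(
    system.file("extdata", "reference_literature_summary.tsv",
                package = "phytoscreen"),
    stringsAsFactors = FALSE
  )
}
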