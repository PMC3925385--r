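## Thin orchestration over the modules: clones -> OTUs -> assignments
## (identify) and clone table -> diet summary (dietstats). The numbered
## scripts under analysis/ and scripts/acceptance.R drive these.

#' Identify prey taxa from clone sequences
#'
#' Dereplicates clone sequences into OTUs and runs the two-criterion
#' assignment engine against a reference library.
#'
#' @param clones data frame (`sample_id`, `clone_id`, `sequence`), e.g.
#'   from [read_clone_fastas()] or [make_gut_samples()].
#' @param db a [reference_db()].
#' @param cfg an [assignment_config()].
#' @param seed RNG seed (bootstraps).
#' @param params an [alignment_params()].
#' @return list with `otus`, `assignments`, and `report` (one row per OTU:
#'   assignment plus total clone count).
#' @export
run_identify <- function(clones, db, cfg = assignment_config(), seed = 1,
                         params = alignment_params()) {
  otus <- dereplicate_clones(clones, threshold = cfg$species_identity_threshold,
                             params = params)
  assignments <- assign_all(otus, db, cfg, seed = seed, params = params)
  report <- assignment_report(assignments)
  report$total_clones <- vapply(otus, function(o) sum(o$per_sample_counts), 0L)
  list(otus = otus, assignments = assignments, report = report)
}

#' Diet statistics from the packaged (or a compatible) clone table
#'
#' Loads the OTU x sample clone table plus sample metadata, computes the
#' full [diet_summary()], and optionally writes the report tables.
#'
#' @param table2_tsv,table1_tsv fixture paths (defaults: the packaged
#'   largemouth bass study tables).
#' @param exclude_self drop the predator's own (self-DNA) OTU before
#'   computing compositions.
#' @param out_dir optional directory for [render_report()] TSVs.
#' @return the [diet_summary()] (invisibly returns it after printing if
#'   `out_dir` given).
#' @export
run_dietstats <- function(table2_tsv = barcodediet_example("table2.tsv"),
                          table1_tsv = barcodediet_example("table1.tsv"),
                          exclude_self = FALSE, out_dir = NULL) {
  t <- load_clone_table(table2_tsv, table1_tsv)
  s <- diet_summary(t, exclude_self = exclude_self)
  if (!is.null(out_dir)) render_report(s, out_dir)
  s
}
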