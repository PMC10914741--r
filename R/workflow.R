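#' Run the full parsing workflow
#'
#' Chains the whole pipeline on an in-memory occurrence table: backbone
#' name check, collector-surname standardization, collection-event keys,
#' digital-voucher selection with consensus taxon, duplicate merging, and
#' partitioning into useable / unusable / duplicate records.
#'
#' @param occ occurrence tibble in the standard field profile (from
#'   [read_occurrence_table()] or [generate_occurrences()]).
#' @param wcvp a WCVP-style names table.
#' @param dictionary optional collector dictionary.
#' @param score_table issue-score table (default: the shipped 33-category
#'   table).
#' @param mergeable_fields fields eligible for duplicate-to-voucher
#'   filling.
#' @param merge fill empty voucher fields from duplicates (default TRUE).
#' @return List with `data` (annotated, partitioned table), `merge_log`,
#'   and `summary` (a [parse_summary()] object).
#' @export
#' @examples
#' sim <- generate_occurrences(synthetic_scenario(n_events = 5, seed = 7))
#' res <- run_workflow(sim$occ, sim$wcvp)
#' res$summary
run_workflow <- function(occ, wcvp, dictionary = NULL,
                         score_table = default_issue_scores(),
                         mergeable_fields = default_mergeable_fields,
                         merge = TRUE) {
  occ <- wcvp_check_name_batch(occ, wcvp)
  occ <- apply_collector_dictionary(occ, dictionary)
  occ <- assign_event_keys(occ)
  occ <- select_digital_voucher(occ, score_table)
  merge_log <- NULL
  if (merge) {
    merged <- merge_duplicates(occ, mergeable_fields, score_table)
    occ <- merged$data
    merge_log <- merged$merge_log
  }
  occ <- partition_dataset(occ)
  list(data = occ, merge_log = merge_log,
       summary = parse_summary(occ, merge_log))
}
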