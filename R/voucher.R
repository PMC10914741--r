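# Digital-voucher selection: per collection event, score every duplicate by
# spatial quality + record completeness, keep the best record, agree on a
# consensus taxon, and fill the voucher's gaps from its duplicates.

# The ten unit completeness flags, in scoring order. The country flag is
# special-cased: it is satisfied by the *absence* of the COUNTRY_INVALID
# issue, not by a populated column.
completeness_fields <- c(
  collector = "recordedBy",
  collection_number = "recordNumber",
  year = "year",
  institution_code = "institutionCode",
  catalog_number = "catalogNumber",
  locality = "locality",
  municipality = "municipality",
  state_province = "stateProvince",
  field_notes = "fieldNotes"
)

#' Record-completeness score
#'
#' Sum of ten unit flags per record: collector, collection number, year,
#' institution code, catalogue number, locality, municipality,
#' state/province and field notes are satisfied when the corresponding
#' field is non-empty; the country flag is satisfied when the GBIF issue
#' `COUNTRY_INVALID` is absent. Range 0..10.
#'
#' @param tbl occurrence tibble carrying the nine source fields plus
#'   `issue`.
#' @return Integer vector of scores in `[0, 10]`.
#' @export
completeness_score <- function(tbl) {
  assert_columns(tbl, c(unname(completeness_fields), "issue"),
                 "completeness_score")
  flags <- vapply(unname(completeness_fields),
                  function(f) !is_blank(tbl[[f]]),
                  logical(nrow(tbl)))
  flags <- matrix(flags, nrow = nrow(tbl))
  country_ok <- !vapply(issue_tokens(tbl$issue),
                        function(tok) "COUNTRY_INVALID" %in% tok,
                        logical(1))
  as.integer(rowSums(flags) + country_ok)
}

#' Consensus taxon of a duplicate group
#'
#' Given the accepted names applied to the duplicates of one collection
#' event (empty string where a record carries no determination at or below
#' species rank), the most frequently applied name wins; an exact frequency
#' tie resolves to the alphabetically first name so the choice is
#' automatic; when no record is determined to species or below the event is
#' `"UNIDENTIFIED"`.
#'
#' @param accepted_names character vector of accepted, species-or-below
#'   names for the group's members (`""` = no species-level determination).
#' @return One name string, or `"UNIDENTIFIED"`.
#' @export
#' @examples
#' consensus_taxon(c("Eugenia uniflora", "Eugenia uniflora", "Myrcia spl."))
consensus_taxon <- function(accepted_names) {
  nm <- canon_missing(accepted_names)
  nm <- nm[nzchar(nm)]
  if (length(nm) == 0) return("UNIDENTIFIED")
  tab <- table(nm)
  winners <- names(tab)[tab == max(tab)]
  sort(winners)[1]
}

# Deterministic voucher choice inside one group: argmax of total score,
# ties by higher completeness, then smallest record id. Returns the index.
select_voucher_idx <- function(total, completeness, record_id) {
  stopifnot(length(total) > 0)
  ord <- order(-total, -completeness, record_id)
  ord[1]
}

#' Select the digital voucher for every collection event
#'
#' Scores each record (effective spatial score from GBIF issues, -9 when
#' coordinates are missing, plus the ten-flag completeness score), then per
#' `gp_event_key` group marks the highest-total record as the digital
#' voucher and records the group's consensus taxon. Ties on total score are
#' broken by higher completeness, then by smallest record id, so the result
#' is invariant under row permutation.
#'
#' @param tbl occurrence tibble that has been through
#'   [wcvp_check_name_batch()] and [assign_event_keys()].
#' @param score_table issue-score table, default the shipped 33-category
#'   table.
#' @return `tbl` plus `gp_spatial_score`, `gp_completeness`,
#'   `gp_total_score`, `gp_is_voucher`, `gp_consensus_taxon` (broadcast to
#'   all group members).
#' @export
select_digital_voucher <- function(tbl, score_table = default_issue_scores()) {
  assert_columns(tbl, c("gbifID", "gp_event_key", "wcvp_match_status"),
                 "select_digital_voucher")
  tbl <- tibble::as_tibble(tbl)
  if (nrow(tbl) == 0) {
    tbl$gp_spatial_score <- integer()
    tbl$gp_completeness <- integer()
    tbl$gp_total_score <- integer()
    tbl$gp_is_voucher <- logical()
    tbl$gp_consensus_taxon <- character()
    return(tbl)
  }
  tbl$gp_spatial_score <- effective_spatial_score(tbl, score_table)
  tbl$gp_completeness <- completeness_score(tbl)
  tbl$gp_total_score <- tbl$gp_spatial_score + tbl$gp_completeness
  tbl$.species_name <- accepted_species_name(tbl)

  tbl <- dplyr::group_by(tbl, .data$gp_event_key) |>
    dplyr::mutate(
      gp_is_voucher = seq_along(.data$gp_total_score) ==
        select_voucher_idx(.data$gp_total_score, .data$gp_completeness,
                           as.character(.data$gbifID)),
      gp_consensus_taxon = consensus_taxon(.data$.species_name)
    ) |>
    dplyr::ungroup()
  tbl$.species_name <- NULL
  tbl
}

# Fields whose content describes the gathering itself and may be pooled
# across duplicates. Coordinates move only as an atomic lat+lon pair so a
# merged voucher never carries a fabricated mixed locality.
default_mergeable_fields <- c(
  "habitat", "fieldNotes", "locality", "municipality", "stateProvince",
  "countryCode", "year", "month", "day", "eventDate", "elevation"
)

#' Fill empty voucher fields from duplicates
#'
#' For each multi-record collection event, fields that are empty in the
#' digital voucher are populated from the duplicate with the highest total
#' score that has the field non-empty (ties by smallest record id).
#' Non-empty voucher cells are never overwritten, so the fill is monotone
#' and re-running the merge is a no-op. `decimalLatitude`/
#' `decimalLongitude` move together: both must be empty in the voucher and
#' both non-empty in the donor.
#'
#' @param tbl output of [select_digital_voucher()].
#' @param mergeable_fields character vector of field names eligible for
#'   filling; defaults to the gathering-description set.
#' @param score_table issue-score table used to re-score a voucher whose
#'   coordinates were filled in.
#' @return List with `data` (the table, voucher rows merged) and
#'   `merge_log` (tibble `gp_event_key`, `field`, `donor_gbifID`,
#'   `voucher_gbifID`).
#' @export
merge_duplicates <- function(tbl, mergeable_fields = default_mergeable_fields,
                             score_table = default_issue_scores()) {
  assert_columns(tbl, c("gbifID", "gp_event_key", "gp_is_voucher",
                        "gp_total_score"), "merge_duplicates")
  tbl <- tibble::as_tibble(tbl)
  fields <- intersect(mergeable_fields, names(tbl))
  has_coords <- all(c("decimalLatitude", "decimalLongitude") %in% names(tbl))
  log <- list()

  multi <- tbl$gp_event_key[duplicated(tbl$gp_event_key)]
  for (key in unique(multi)) {
    rows <- which(tbl$gp_event_key == key)
    v <- rows[tbl$gp_is_voucher[rows]][1]
    donors <- setdiff(rows, v)
    donors <- donors[order(-tbl$gp_total_score[donors],
                           as.character(tbl$gbifID[donors]))]
    for (f in fields) {
      if (!is_blank(tbl[[f]][v])) next
      have <- donors[!is_blank(tbl[[f]][donors])]
      if (length(have) == 0) next
      d <- have[1]
      tbl[[f]][v] <- tbl[[f]][d]
      log[[length(log) + 1]] <- tibble::tibble(
        gp_event_key = key, field = f,
        donor_gbifID = as.character(tbl$gbifID[d]),
        voucher_gbifID = as.character(tbl$gbifID[v])
      )
    }
    if (has_coords &&
        is_blank(tbl$decimalLatitude[v]) &&
        is_blank(tbl$decimalLongitude[v])) {
      have <- donors[!is_blank(tbl$decimalLatitude[donors]) &
                       !is_blank(tbl$decimalLongitude[donors])]
      if (length(have) > 0) {
        d <- have[1]
        tbl$decimalLatitude[v] <- tbl$decimalLatitude[d]
        tbl$decimalLongitude[v] <- tbl$decimalLongitude[d]
        # the donor's issue-based quality travels with its coordinates
        if (all(c("issue", "gp_spatial_score") %in% names(tbl))) {
          tbl$issue[v] <- tbl$issue[d]
          tbl$gp_spatial_score[v] <- effective_spatial_score(
            tbl[d, , drop = FALSE], score_table)
          tbl$gp_total_score[v] <- tbl$gp_spatial_score[v] +
            tbl$gp_completeness[v]
        }
        for (f in c("decimalLatitude", "decimalLongitude")) {
          log[[length(log) + 1]] <- tibble::tibble(
            gp_event_key = key, field = f,
            donor_gbifID = as.character(tbl$gbifID[d]),
            voucher_gbifID = as.character(tbl$gbifID[v])
          )
        }
      }
    }
  }
  merge_log <- if (length(log) == 0) {
    tibble::tibble(gp_event_key = character(), field = character(),
                   donor_gbifID = character(), voucher_gbifID = character())
  } else {
    dplyr::bind_rows(log)
  }
  list(data = tbl, merge_log = merge_log)
}
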