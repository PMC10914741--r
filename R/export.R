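# Output partitioning, dataset summaries and 1x1-degree richness grids.

#' Partition parsed records into useable / unusable / duplicates
#'
#' Appends `gp_dataset_result`: a digital voucher whose consensus taxon is
#' resolved (not `UNIDENTIFIED`) and whose spatial score is above -9 (which
#' requires an interpretable coordinate pair) is `"useable"`; a voucher
#' failing either test is `"unusable"`; every non-voucher group member is a
#' `"duplicate"`. The three labels are disjoint and exhaustive, and each
#' event key contributes exactly one non-duplicate record.
#'
#' @param tbl output of [select_digital_voucher()] (optionally merged with
#'   [merge_duplicates()]).
#' @return `tbl` with the `gp_dataset_result` column appended.
#' @export
partition_dataset <- function(tbl) {
  assert_columns(tbl, c("gp_is_voucher", "gp_consensus_taxon",
                        "gp_spatial_score"), "partition_dataset")
  tbl <- tibble::as_tibble(tbl)
  tbl$gp_dataset_result <- dplyr::case_when(
    !tbl$gp_is_voucher ~ "duplicate",
    tbl$gp_consensus_taxon != "UNIDENTIFIED" &
      tbl$gp_spatial_score > -9L ~ "useable",
    TRUE ~ "unusable"
  )
  tbl
}

#' Summarize a parsed dataset
#'
#' Headline totals plus merge-action frequencies and records-per-taxon
#' means, the before/after currency of the workflow.
#'
#' @param tbl a partitioned table from [partition_dataset()].
#' @param merge_log the merge log from [merge_duplicates()] (optional).
#' @return A list of class `gp_summary`: `totals` (n_records, n_events,
#'   n_duplicates, n_useable, n_unusable), `merge_actions` (per-field
#'   frequencies, overall and split by the voucher's partition),
#'   `records_per_taxon` (mean records per taxon for all identified data
#'   and for the spatially useable subset, before and after parsing).
#' @export
parse_summary <- function(tbl, merge_log = NULL) {
  assert_columns(tbl, c("gp_event_key", "gp_dataset_result",
                        "gp_consensus_taxon", "gp_spatial_score"),
                 "parse_summary")
  n_records <- nrow(tbl)
  n_events <- dplyr::n_distinct(tbl$gp_event_key)
  n_dup <- sum(tbl$gp_dataset_result == "duplicate")
  n_use <- sum(tbl$gp_dataset_result == "useable")
  n_unuse <- sum(tbl$gp_dataset_result == "unusable")

  merge_actions <- NULL
  if (!is.null(merge_log) && nrow(merge_log) > 0) {
    voucher_part <- tbl$gp_dataset_result[tbl$gp_is_voucher]
    names(voucher_part) <- tbl$gp_event_key[tbl$gp_is_voucher]
    merge_actions <- merge_log |>
      dplyr::mutate(partition = unname(voucher_part[.data$gp_event_key])) |>
      dplyr::count(.data$field, .data$partition, name = "n_actions") |>
      dplyr::arrange(dplyr::desc(.data$n_actions), .data$field)
  }

  mean_rpt <- function(ids, taxa) {
    keep <- nzchar(taxa) & taxa != "UNIDENTIFIED"
    if (!any(keep)) return(NA_real_)
    length(ids[keep]) / dplyr::n_distinct(taxa[keep])
  }
  voucher <- tbl[tbl$gp_dataset_result != "duplicate", , drop = FALSE]
  useable <- tbl[tbl$gp_dataset_result == "useable", , drop = FALSE]
  spatial_all <- tbl[tbl$gp_spatial_score > -9L, , drop = FALSE]
  records_per_taxon <- c(
    all_records = mean_rpt(seq_len(nrow(tbl)), tbl$gp_consensus_taxon),
    all_events = mean_rpt(seq_len(nrow(voucher)), voucher$gp_consensus_taxon),
    spatial_records = mean_rpt(seq_len(nrow(spatial_all)),
                               spatial_all$gp_consensus_taxon),
    spatial_events = mean_rpt(seq_len(nrow(useable)),
                              useable$gp_consensus_taxon)
  )

  structure(
    list(
      totals = c(n_records = n_records, n_events = n_events,
                 n_duplicates = n_dup, n_useable = n_use,
                 n_unusable = n_unuse),
      merge_actions = merge_actions,
      records_per_taxon = records_per_taxon
    ),
    class = "gp_summary"
  )
}

#' @export
print.gp_summary <- function(x, ...) {
  t <- x$totals
  cat("Parsed GBIF dataset summary\n")
  cat(sprintf("  records:                 %d\n", t[["n_records"]]))
  cat(sprintf("  unique collection events:%d\n", t[["n_events"]]))
  cat(sprintf("  duplicate records:       %d\n", t[["n_duplicates"]]))
  cat(sprintf("  useable records:         %d\n", t[["n_useable"]]))
  cat(sprintf("  unusable records:        %d\n", t[["n_unusable"]]))
  rpt <- x$records_per_taxon
  cat(sprintf("  records/taxon (all):     %.1f -> %.1f\n",
              rpt[["all_records"]], rpt[["all_events"]]))
  cat(sprintf("  records/taxon (spatial): %.1f -> %.1f\n",
              rpt[["spatial_records"]], rpt[["spatial_events"]]))
  if (!is.null(x$merge_actions)) {
    cat("  top merged fields:\n")
    print(utils::head(x$merge_actions, 5))
  }
  invisible(x)
}

#' Export the three dataset partitions as TSV files
#'
#' Writes `useable.tsv`, `unusable.tsv` and `duplicates.tsv` in the GBIF
#' dialect, plus `merge_log.csv` when a merge log is supplied (duplicates
#' plus the log support downstream quality control).
#'
#' @param tbl a partitioned table from [partition_dataset()].
#' @param outdir output directory (created if needed).
#' @param merge_log optional merge log.
#' @return Named character vector of the files written, invisibly.
#' @export
export_partitions <- function(tbl, outdir, merge_log = NULL) {
  assert_columns(tbl, "gp_dataset_result", "export_partitions")
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  paths <- c(
    useable = file.path(outdir, "useable.tsv"),
    unusable = file.path(outdir, "unusable.tsv"),
    duplicates = file.path(outdir, "duplicates.tsv")
  )
  lab <- c(useable = "useable", unusable = "unusable",
           duplicates = "duplicate")
  for (p in names(paths)) {
    write_occurrence_table(
      tbl[tbl$gp_dataset_result == lab[[p]], , drop = FALSE], paths[[p]])
  }
  if (!is.null(merge_log)) {
    ml <- file.path(outdir, "merge_log.csv")
    readr::write_csv(merge_log, ml, progress = FALSE)
    paths <- c(paths, merge_log = ml)
  }
  invisible(paths)
}

#' Taxon richness on a degree grid
#'
#' Assigns each record to the grid cell whose west/south corner is
#' `(floor(lon / cell) * cell, floor(lat / cell) * cell)` (half-open cells,
#' west and south edges inclusive — unambiguous at negative coordinates)
#' and counts distinct taxa per cell. Records with missing coordinates or
#' coordinates outside `[-180, 180] x [-90, 90]` are skipped with a
#' warning.
#'
#' @param tbl a tibble of records with coordinates.
#' @param taxon_col name of the column holding the taxon per record.
#' @param cell_degrees cell edge in degrees (default 1).
#' @param lon_col,lat_col coordinate column names.
#' @return Tibble `cell_lon`, `cell_lat`, `taxon_count`, one row per
#'   occupied cell.
#' @export
grid_richness <- function(tbl, taxon_col = "gp_consensus_taxon",
                          cell_degrees = 1,
                          lon_col = "decimalLongitude",
                          lat_col = "decimalLatitude") {
  assert_columns(tbl, c(taxon_col, lon_col, lat_col), "grid_richness")
  lon <- suppressWarnings(as.numeric(canon_missing(tbl[[lon_col]])))
  lat <- suppressWarnings(as.numeric(canon_missing(tbl[[lat_col]])))
  taxon <- canon_missing(tbl[[taxon_col]])
  ok <- !is.na(lon) & !is.na(lat) & nzchar(taxon) &
    lon >= -180 & lon <= 180 & lat >= -90 & lat <= 90
  n_bad <- sum(!is.na(lon) & !is.na(lat) &
                 (lon < -180 | lon > 180 | lat < -90 | lat > 90))
  if (n_bad > 0) {
    warning(sprintf("%d record(s) with out-of-range coordinates skipped",
                    n_bad), call. = FALSE)
  }
  if (!any(ok)) {
    return(tibble::tibble(cell_lon = numeric(), cell_lat = numeric(),
                          taxon_count = integer()))
  }
  tibble::tibble(
    cell_lon = floor(lon[ok] / cell_degrees) * cell_degrees,
    cell_lat = floor(lat[ok] / cell_degrees) * cell_degrees,
    taxon = taxon[ok]
  ) |>
    dplyr::distinct() |>
    dplyr::count(.data$cell_lon, .data$cell_lat, name = "taxon_count") |>
    dplyr::arrange(.data$cell_lon, .data$cell_lat)
}

#' Per-cell percent difference between two richness grids
#'
#' `100 * (a - b) / a` per cell, relative to the first (reference, e.g.
#' pre-parse) grid. Cells absent from one grid count 0 taxa there; a cell
#' with `a == 0` has an undefined relative difference and reports `NA`.
#'
#' @param grid_a,grid_b richness grids from [grid_richness()] on the same
#'   cell convention; `grid_a` is the reference.
#' @return Tibble `cell_lon`, `cell_lat`, `richness_a`, `richness_b`,
#'   `pct_diff`.
#' @export
richness_percent_diff <- function(grid_a, grid_b) {
  out <- dplyr::full_join(
    dplyr::rename(grid_a, richness_a = "taxon_count"),
    dplyr::rename(grid_b, richness_b = "taxon_count"),
    by = c("cell_lon", "cell_lat")
  )
  out$richness_a[is.na(out$richness_a)] <- 0L
  out$richness_b[is.na(out$richness_b)] <- 0L
  out$pct_diff <- ifelse(out$richness_a > 0,
                         100 * (out$richness_a - out$richness_b) /
                           out$richness_a,
                         NA_real_)
  dplyr::arrange(out, .data$cell_lon, .data$cell_lat)
}
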