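#' Darwin Core field profiles for GBIF occurrence downloads
#'
#' GBIF "simple" occurrence downloads carry a wide set of Darwin Core and
#' GBIF-interpreted columns. Two working profiles are shipped as plain-text
#' config files: `"standard"` (54 columns, the fields the parsing workflow
#' actually consumes plus common context) and `"all"` (257 columns, the full
#' vocabulary). The standard profile is a strict subset of the all profile.
#'
#' @param name `"standard"` or `"all"`.
#' @param path optional path to a custom profile file (one column name per
#'   line); overrides the shipped file.
#' @return Character vector of column names, in output order.
#' @export
#' @examples
#' length(gbif_field_profile("standard"))
gbif_field_profile <- function(name = c("standard", "all"), path = NULL) {
  name <- match.arg(name)
  if (is.null(path)) {
    path <- system.file("extdata",
                        paste0("gbif_fields_", name, ".txt"),
                        package = "gatherparse", mustWork = TRUE)
  }
  cols <- readLines(path, encoding = "UTF-8")
  cols <- cols[nzchar(trimws(cols))]
  if (anyDuplicated(cols)) {
    stop("field profile contains duplicate column names", call. = FALSE)
  }
  cols
}

#' Read a GBIF occurrence table
#'
#' Reads a tab-delimited, UTF-8 GBIF occurrence download (the "simple"
#' dialect: no quoting, header row, one record per line), canonicalizes
#' missing values to the empty string, and restricts the columns to a field
#' profile. Columns named by the profile but absent from the file are created
#' empty, with a warning.
#'
#' @param path path to the tab-delimited occurrence file.
#' @param profile `"standard"`, `"all"`, or a character vector of column
#'   names.
#' @return A tibble with exactly the profile columns, all character, missing
#'   values as `""`.
#' @export
read_occurrence_table <- function(path, profile = "standard") {
  if (!file.exists(path)) {
    stop("cannot read occurrence file: ", path, call. = FALSE)
  }
  cols <- if (is.character(profile) && length(profile) > 1) profile
          else gbif_field_profile(profile)
  tbl <- readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    quote = "", na = character(), progress = FALSE,
    show_col_types = FALSE
  )
  if (!"gbifID" %in% names(tbl)) {
    stop("occurrence file header lacks the 'gbifID' record-id column",
         call. = FALSE)
  }
  select_fields(tbl, cols)
}

#' Project an occurrence table onto a field profile
#'
#' Pure column projection: the result has exactly the profile's columns in
#' profile order; rows and shared cell values are unchanged. Profile columns
#' absent from the input are created empty (warning). Missing values are
#' canonicalized to `""`.
#'
#' @param tbl a data frame of occurrence records.
#' @param profile `"standard"`, `"all"`, or a character vector of column
#'   names.
#' @return A tibble with the profile columns.
#' @export
select_fields <- function(tbl, profile = "standard") {
  cols <- if (is.character(profile) && length(profile) > 1) profile
          else gbif_field_profile(profile)
  tbl <- tibble::as_tibble(tbl)
  miss <- setdiff(cols, names(tbl))
  if (length(miss) > 0) {
    warning(sprintf("%d profile column(s) absent from input, created empty: %s",
                    length(miss), paste(utils::head(miss, 8), collapse = ", ")),
            call. = FALSE)
    for (m in miss) tbl[[m]] <- ""
  }
  out <- tbl[, cols, drop = FALSE]
  out[] <- lapply(out, canon_missing)
  out
}

#' Write an occurrence table in the GBIF TSV dialect
#'
#' Tab-delimited, UTF-8, no quoting, empty string for missing. A table
#' written with this function and re-read with [read_occurrence_table()]
#' round-trips cell-identically.
#'
#' @param tbl occurrence tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_occurrence_table <- function(tbl, path) {
  readr::write_tsv(tbl, path, na = "", quote = "none", escape = "none",
                   progress = FALSE)
  invisible(path)
}

#' Download and unpack a GBIF occurrence archive
#'
#' Fetches the zip archive behind a GBIF download URL (the DOI landing
#' address generated by a portal download request) and extracts it, returning
#' the path to the occurrence core file. Requires network access; all other
#' workflow steps are offline.
#'
#' @param url archive URL.
#' @param dest_dir writable destination directory.
#' @param quiet suppress download progress.
#' @return Path to the extracted tab-delimited occurrence file.
#' @export
fetch_gbif_archive <- function(url, dest_dir, quiet = TRUE) {
  if (!dir.exists(dest_dir)) dir.create(dest_dir, recursive = TRUE)
  zip_path <- file.path(dest_dir, "gbif_download.zip")
  status <- tryCatch(
    utils::download.file(url, zip_path, mode = "wb", quiet = quiet),
    error = function(e) {
      stop("network error while fetching GBIF archive (retriable): ",
           conditionMessage(e), call. = FALSE)
    }
  )
  if (!identical(status, 0L)) {
    stop("network error while fetching GBIF archive (retriable), status ",
         status, call. = FALSE)
  }
  extract_occurrence_from_zip(zip_path, dest_dir)
}

# Locate the occurrence core inside an unzipped GBIF archive. Shared by
# fetch_gbif_archive() and directly testable offline.
extract_occurrence_from_zip <- function(zip_path, dest_dir) {
  listing <- utils::unzip(zip_path, list = TRUE)$Name
  cand <- grep("(^|/)occurrence\\.(txt|tsv)$", listing, value = TRUE)
  if (length(cand) == 0) {
    # simple downloads: a single .csv/.txt named after the download key
    cand <- grep("\\.(csv|txt|tsv)$", listing, value = TRUE)
    cand <- setdiff(cand, grep("(citation|rights|meta)", cand, value = TRUE))
  }
  if (length(cand) == 0) {
    stop("archive contains no occurrence table", call. = FALSE)
  }
  utils::unzip(zip_path, files = cand[1], exdir = dest_dir)
  file.path(dest_dir, cand[1])
}
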