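# Collector-name standardization and the collector dictionary.
#
# The dictionary is keyed on the *raw* recordedBy string (never fuzzy), so
# distinct team spellings from different sources index separately and can be
# curated independently.

# Separators that end the primary collector's token inside a recordedBy
# string. " and " is matched case-insensitively as a word.
collector_separators <- "\\s*(;|\\||&|\\b[Aa][Nn][Dd]\\b)\\s*"

# Team-suffix markers that never carry the primary surname.
team_suffix_re <- "(?i)\\b(et\\.?\\s*al\\.?|e\\s+outros|and\\s+others|with\\b.*)\\s*$"

#' Extract the primary collector's surname
#'
#' Isolates the first collector from a free-text `recordedBy` string (split
#' on `;`, `|`, `&`, `" and "`, after stripping numbered-list prefixes and
#' team suffixes such as "et al."), then takes the text before the first
#' comma when one exists ("Surname, I." dialect) or else the last
#' whitespace-delimited word ("I. Surname" dialect). The result is
#' diacritic-folded to ASCII and uppercased. Unparseable input yields `""`.
#'
#' Particles survive only in the comma dialect ("de Melo, P." -> "DE MELO");
#' in "P. de Melo" the last-word rule keeps "MELO" alone.
#'
#' @param recordedBy character vector of raw collector strings.
#' @return Character vector of uppercase ASCII surnames (possibly `""`).
#' @export
#' @examples
#' extract_primary_surname("Gardner, G.")
#' extract_primary_surname("Müller, K.; Silva, J.")
extract_primary_surname <- function(recordedBy) {
  x <- canon_missing(recordedBy)
  vapply(x, function(s) {
    if (!nzchar(s)) return("")
    s <- sub(team_suffix_re, "", s, perl = TRUE)
    s <- sub("^\\s*\\d+\\s*[.)-]\\s*", "", s)      # "1. Smith, J.; 2. ..."
    first <- strsplit(s, collector_separators, perl = TRUE)[[1]][1]
    first <- squish(first %||% "")
    if (!nzchar(first)) return("")
    if (grepl(",", first, fixed = TRUE)) {
      surname <- sub(",.*$", "", first)
    } else {
      parts <- strsplit(first, " ", fixed = TRUE)[[1]]
      # drop trailing initials ("Gardner G.") so the surname survives both
      # "I. Surname" and "Surname I." orders
      is_initial <- grepl("^([A-Za-z]\\.-?)+$|^[A-Z]$", parts)
      if (any(!is_initial)) parts <- parts[seq_len(max(which(!is_initial)))]
      surname <- parts[length(parts)]
    }
    surname <- fold_ascii_upper(surname)
    surname <- gsub("[^A-Z' -]", "", surname)
    surname <- squish(gsub("^[-' ]+|[-' ]+$", "", surname))
    if (!grepl("[A-Z]", surname)) return("")
    surname
  }, character(1), USE.NAMES = FALSE)
}

#' Build a collector dictionary from an occurrence table
#'
#' One entry per distinct raw `recordedBy` string, with the primary surname
#' extracted automatically and `checked = FALSE` (entries become checked
#' only through human review). Sorted by the raw key for stable output.
#'
#' @param tbl occurrence tibble with a `recordedBy` column.
#' @return Tibble `recordedBy_raw`, `surname_standard`, `checked`.
#' @export
prepare_collector_dictionary <- function(tbl) {
  assert_columns(tbl, "recordedBy", "prepare_collector_dictionary")
  raw <- sort(unique(canon_missing(tbl$recordedBy)))
  raw <- raw[nzchar(raw)]
  tibble::tibble(
    recordedBy_raw = raw,
    surname_standard = extract_primary_surname(raw),
    checked = FALSE
  )
}

#' Apply a collector dictionary to an occurrence table
#'
#' Appends `nameRecordedBy_Standard` and `CollectorDictionary`. Lookup is
#' exact on the raw `recordedBy` string: a hit takes the dictionary surname,
#' marked `"checked"` when the entry was human-reviewed; a miss falls back
#' to automatic surname extraction and stays `"unchecked"` for later
#' review. Idempotent for a fixed dictionary.
#'
#' @param tbl occurrence tibble with a `recordedBy` column.
#' @param dictionary a dictionary tibble (as from
#'   [prepare_collector_dictionary()] or [read_collector_dictionary()]), or
#'   `NULL` for extraction-only.
#' @return `tbl` with the two appended columns.
#' @export
apply_collector_dictionary <- function(tbl, dictionary = NULL) {
  assert_columns(tbl, "recordedBy", "apply_collector_dictionary")
  tbl <- tibble::as_tibble(tbl)
  raw <- canon_missing(tbl$recordedBy)
  surname <- extract_primary_surname(raw)
  status <- rep("unchecked", length(raw))
  if (!is.null(dictionary) && nrow(dictionary) > 0) {
    assert_columns(dictionary,
                   c("recordedBy_raw", "surname_standard", "checked"),
                   "collector dictionary")
    if (anyDuplicated(dictionary$recordedBy_raw)) {
      stop("collector dictionary has duplicate raw keys", call. = FALSE)
    }
    idx <- match(raw, dictionary$recordedBy_raw)
    hit <- !is.na(idx)
    surname[hit] <- fold_ascii_upper(dictionary$surname_standard[idx[hit]])
    reviewed <- rep(FALSE, length(raw))
    reviewed[hit] <- as.logical(dictionary$checked[idx[hit]])
    status[reviewed] <- "checked"
  }
  tbl$nameRecordedBy_Standard <- surname
  tbl$CollectorDictionary <- status
  tbl
}

#' Read / write a collector-dictionary CSV
#'
#' Plain CSV with columns `recordedBy_raw,surname_standard,checked`.
#'
#' @param path file path.
#' @return `read_collector_dictionary()`: the dictionary tibble.
#' @export
read_collector_dictionary <- function(path) {
  tbl <- readr::read_csv(path, col_types = "ccl", progress = FALSE)
  assert_columns(tbl, c("recordedBy_raw", "surname_standard", "checked"),
                 "collector dictionary")
  tbl
}

#' @rdname read_collector_dictionary
#' @param dictionary dictionary tibble to write.
#' @export
write_collector_dictionary <- function(dictionary, path) {
  readr::write_csv(dictionary, path, progress = FALSE)
  invisible(path)
}
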