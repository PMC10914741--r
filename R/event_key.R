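# Collection-event key: FAMILY_SURNAME_COLLECTIONNUMBER.
#
# Collection date is deliberately not part of the key: it is too often
# absent from aggregated records to be effective. The family name guards
# against merging distinct gatherings that share a common surname and a low
# collection number.

# "s.n." (sine numero) spellings: a specimen collected without a number.
# Mapping these to "" keeps distinct unnumbered gatherings from merging
# under a shared literal "S.N.".
sine_numero_re <- "^[sS][\\s./-]*[nN]\\.?$"

#' Normalize a collection-number string
#'
#' Trims whitespace, strips a leading "no."/"n."/"nº"/"#" marker, removes
#' internal spaces and uppercases. "s.n." (sine numero) and strings with no
#' alphanumeric content normalize to `""`, which makes the event key
#' incomplete.
#'
#' @param recordNumber character vector.
#' @return Character vector of normalized numbers (possibly `""`).
#' @export
#' @examples
#' normalize_collection_number("  no. 417 ")
#' normalize_collection_number("s.n.")
normalize_collection_number <- function(recordNumber) {
  x <- canon_missing(recordNumber)
  vapply(x, function(n) {
    n <- trimws(n)
    if (!nzchar(n)) return("")
    if (grepl(sine_numero_re, n)) return("")
    n <- sub("(?i)^(no\\.?|n\\.|n[º°]|#)\\s*", "", n, perl = TRUE)
    n <- toupper(gsub("\\s+", "", n))
    if (!grepl("[A-Z0-9]", n)) return("")
    n
  }, character(1), USE.NAMES = FALSE)
}

#' Construct collection-event keys
#'
#' Joins uppercase family, standardized primary-collector surname and
#' normalized collection number as `FAMILY_SURNAME_NUMBER`. The key is
#' complete only when all three parts are non-empty; an empty surname
#' additionally tags the record `UNKNOWN-COLLECTOR`. Incomplete keys must
#' never be used to group records.
#'
#' @param family character vector of family names.
#' @param surname character vector of standardized surnames (as from
#'   [apply_collector_dictionary()]).
#' @param recordNumber character vector of raw collection numbers.
#' @return Tibble `family`, `surname`, `number`, `key_string`, `complete`,
#'   `unknown_collector`.
#' @export
#' @examples
#' make_event_key("Myrtaceae", "GARDNER", "417")
make_event_key <- function(family, surname, recordNumber) {
  n <- max(length(family), length(surname), length(recordNumber))
  fam <- squish(fold_ascii_upper(canon_missing(rep_len(family, n))))
  sur <- squish(fold_ascii_upper(canon_missing(rep_len(surname, n))))
  num <- normalize_collection_number(rep_len(recordNumber, n))
  complete <- nzchar(fam) & nzchar(sur) & nzchar(num)
  key <- ifelse(complete, paste(fam, sur, num, sep = "_"), "")
  tibble::tibble(
    family = fam, surname = sur, number = num,
    key_string = key, complete = complete,
    unknown_collector = !nzchar(sur)
  )
}

#' Assign collection-event keys to an occurrence table
#'
#' Appends `gp_event_key`, `gp_key_complete` and `gp_unknown_collector`.
#' Records whose key is incomplete receive their own record id as a
#' singleton key, so each is treated as a unique collection event lacking
#' duplicates and can never share a group with another record.
#'
#' @param tbl occurrence tibble carrying `gbifID`, `family`,
#'   `nameRecordedBy_Standard` and `recordNumber`.
#' @return `tbl` with the three appended columns.
#' @export
assign_event_keys <- function(tbl) {
  assert_columns(tbl, c("gbifID", "family", "nameRecordedBy_Standard",
                        "recordNumber"), "assign_event_keys")
  tbl <- tibble::as_tibble(tbl)
  keys <- make_event_key(tbl$family, tbl$nameRecordedBy_Standard,
                         tbl$recordNumber)
  tbl$gp_event_key <- ifelse(keys$complete, keys$key_string,
                             as.character(tbl$gbifID))
  tbl$gp_key_complete <- keys$complete
  tbl$gp_unknown_collector <- keys$unknown_collector
  tbl
}
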