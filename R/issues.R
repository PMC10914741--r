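#' The geospatial issue-score table
#'
#' GBIF appends `issue` tokens to records altered during interpretation or
#' flagged as suspicious. The subset that can affect the geospatial reading
#' of a record (33 categories in the shipped table) is scored by impact on
#' coordinate precision: `none` -> 0, `low` -> -1 (does not affect
#' coordinate accuracy), `medium` -> -3 (potentially affects accuracy),
#' `exclude` -> -9 (unsuitable for spatial analysis). The table is a config
#' file and can be replaced wholesale via [read_issue_scores()].
#'
#' @return A tibble with columns `issue_token`, `impact`, `score`.
#' @export
#' @examples
#' nrow(default_issue_scores())
default_issue_scores <- function() {
  path <- system.file("extdata", "issue_scores.csv",
                      package = "gatherparse", mustWork = TRUE)
  read_issue_scores(path)
}

#' Read and validate an issue-score table
#'
#' @param path CSV with columns `issue_token,impact,score`.
#' @return A validated tibble.
#' @export
read_issue_scores <- function(path) {
  tbl <- readr::read_csv(path, col_types = "cci", progress = FALSE)
  assert_columns(tbl, c("issue_token", "impact", "score"), "issue-score table")
  if (anyDuplicated(tbl$issue_token)) {
    stop("issue-score table has duplicate issue tokens", call. = FALSE)
  }
  expected <- c(none = 0L, low = -1L, medium = -3L, exclude = -9L)
  bad <- tbl$score != unname(expected[tbl$impact])
  if (anyNA(bad) || any(bad)) {
    stop("issue-score table scores must map none/low/medium/exclude to 0/-1/-3/-9",
         call. = FALSE)
  }
  tbl
}

# Split one raw issue string into uppercase tokens.
issue_tokens <- function(x) {
  x <- canon_missing(x)
  lapply(strsplit(x, ";", fixed = TRUE), function(tok) {
    tok <- toupper(trimws(tok))
    tok[nzchar(tok)]
  })
}

#' Extract GBIF issue flags from an occurrence table
#'
#' Splits each record's semicolon-delimited `issue` field into uppercase
#' tokens and tallies records per issue category. Tokens outside the score
#' table are retained (they tally, and score 0 downstream).
#'
#' @param tbl occurrence tibble with `gbifID` and `issue` columns.
#' @return A list of class `gp_issue_matrix` with elements `record_id`
#'   (character), `tokens` (list of character vectors, parallel to
#'   `record_id`) and `summary` (tibble `issue_token`, `n_records`, sorted by
#'   descending count).
#' @export
extract_issues <- function(tbl) {
  assert_columns(tbl, c("gbifID", "issue"), "extract_issues")
  toks <- issue_tokens(tbl$issue)
  flat <- unlist(toks, use.names = FALSE)
  summary <- if (length(flat) == 0) {
    tibble::tibble(issue_token = character(), n_records = integer())
  } else {
    tab <- table(flat)
    tibble::tibble(issue_token = names(tab),
                   n_records = as.integer(tab)) |>
      dplyr::arrange(dplyr::desc(.data$n_records), .data$issue_token)
  }
  structure(
    list(record_id = as.character(tbl$gbifID), tokens = toks,
         summary = summary),
    class = "gp_issue_matrix"
  )
}

#' @export
print.gp_issue_matrix <- function(x, ...) {
  cat("GBIF issue matrix:", length(x$record_id), "records,",
      nrow(x$summary), "issue categories\n")
  if (nrow(x$summary) > 0) print(utils::head(x$summary, 10))
  invisible(x)
}

#' Spatial-quality selection score of an issue-token set
#'
#' The score of a record is the worst (minimum) score over its issue tokens
#' that appear in the score table; a record with no scored geospatial issue
#' scores 0. Values are always in \{0, -1, -3, -9\}.
#'
#' @param tokens a character vector of issue tokens for one record, or a
#'   list of such vectors for many records.
#' @param score_table an issue-score table, by default
#'   [default_issue_scores()].
#' @return Integer score(s).
#' @export
#' @examples
#' spatial_score(c("COORDINATE_ROUNDED", "ZERO_COORDINATE"))
spatial_score <- function(tokens, score_table = default_issue_scores()) {
  if (!is.list(tokens)) tokens <- list(tokens)
  lookup <- setNames(as.integer(score_table$score), score_table$issue_token)
  vapply(tokens, function(tok) {
    s <- lookup[tok]
    s <- s[!is.na(s)]
    if (length(s) == 0) 0L else min(s)
  }, integer(1))
}

#' Is a spatial score useable for spatial analysis?
#'
#' Records scored -9 are excluded from spatial analysis; all other scores
#' (0, -1, -3) remain useable.
#'
#' @param score integer score(s) in \{0, -1, -3, -9\}.
#' @return Logical vector.
#' @export
is_spatially_useable <- function(score) {
  if (!all(score %in% c(0L, -1L, -3L, -9L))) {
    stop("spatial score must be one of 0, -1, -3, -9", call. = FALSE)
  }
  score > -9L
}

# Effective per-record spatial score used by voucher selection and the
# useable/unusable partition: the issue-based score, overridden to -9 when a
# record has no interpretable coordinate pair (coordinates are a
# precondition for spatial use).
effective_spatial_score <- function(tbl, score_table = default_issue_scores()) {
  assert_columns(tbl, c("issue", "decimalLatitude", "decimalLongitude"),
                 "effective_spatial_score")
  sc <- spatial_score(issue_tokens(tbl$issue), score_table)
  lat <- suppressWarnings(as.numeric(canon_missing(tbl$decimalLatitude)))
  lon <- suppressWarnings(as.numeric(canon_missing(tbl$decimalLongitude)))
  no_coord <- is.na(lat) | is.na(lon)
  sc[no_coord] <- -9L
  sc
}
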