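#' Load a WCVP-style names table
#'
#' Reads a World Checklist of Vascular Plants names export (pipe- or
#' tab-delimited text with a header; the delimiter is auto-detected from the
#' header line). A full export has 33 columns; any table carrying the key
#' columns `plant_name_id`, `taxon_name`, `taxon_status`,
#' `accepted_plant_name_id`, `taxon_rank` is accepted, so down-sampled
#' backbones work.
#'
#' @param path path to the delimited names file.
#' @return A tibble of backbone names, all columns character.
#' @export
load_wcvp <- function(path) {
  if (!file.exists(path)) stop("cannot read WCVP file: ", path, call. = FALSE)
  header <- readLines(path, n = 1L, encoding = "UTF-8")
  delim <- if (stringr::str_count(header, stringr::fixed("|")) >
               stringr::str_count(header, "\t")) "|" else "\t"
  tbl <- readr::read_delim(
    path, delim = delim,
    col_types = readr::cols(.default = readr::col_character()),
    quote = "", na = character(), progress = FALSE, show_col_types = FALSE
  )
  need <- c("plant_name_id", "taxon_name", "taxon_status",
            "accepted_plant_name_id", "taxon_rank")
  miss <- setdiff(need, names(tbl))
  if (length(miss) > 0) {
    stop("WCVP table lacks required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(tbl$plant_name_id)) {
    stop("WCVP table has duplicate plant_name_id values", call. = FALSE)
  }
  message(sprintf("WCVP table: %d names, %d columns", nrow(tbl), ncol(tbl)))
  tbl[] <- lapply(tbl, canon_missing)
  tbl
}

# Infraspecific-marker spellings accepted on input, mapped to the
# nomenclaturally standard abbreviation.
infra_marker_map <- c(
  "var" = "var.", "var." = "var.", "variety" = "var.",
  "subsp" = "subsp.", "subsp." = "subsp.", "ssp" = "subsp.",
  "ssp." = "subsp.", "subspecies" = "subsp.",
  "f" = "f.", "f." = "f.", "fo" = "f.", "fo." = "f.",
  "form" = "f.", "forma" = "f."
)

#' Standardize a scientific-name string
#'
#' Brings verbatim name strings in line with the backbone format: collapses
#' repeated whitespace, separates a hybrid marker fused to the specific
#' epithet (`Salix xfragilis` -> `Salix x fragilis`, and the multiplication
#' sign is mapped to `x`), and normalizes infraspecific-rank markers to the
#' standard abbreviations `var.`, `subsp.`, `f.`. All other tokens are
#' preserved byte-identically. Idempotent.
#'
#' @param x character vector of raw names (empty allowed).
#' @return Character vector of standardized names.
#' @export
#' @examples
#' standardize_scientific_name("Salix xfragilis")
#' standardize_scientific_name("Eugenia punicifolia variety minor")
standardize_scientific_name <- function(x) {
  x <- canon_missing(x)
  vapply(x, function(nm) {
    if (!nzchar(nm)) return("")
    nm <- gsub("×", "x ", nm)   # multiplication sign -> hybrid 'x'
    nm <- squish(nm)
    tok <- strsplit(nm, " ", fixed = TRUE)[[1]]
    # fused hybrid epithet after a capitalized genus token: "xfragilis"
    out <- character(0)
    for (i in seq_along(tok)) {
      t <- tok[i]
      prev_cap <- i > 1 && grepl("^[A-ZÀ-Ý]", tok[i - 1])
      if (prev_cap && grepl("^x[a-z]", t)) {
        out <- c(out, "x", substring(t, 2))
      } else {
        out <- c(out, t)
      }
    }
    # infraspecific markers: interior tokens followed by an epithet
    if (length(out) >= 3) {
      for (i in 2:(length(out) - 1)) {
        key <- tolower(out[i])
        if (key %in% names(infra_marker_map)) {
          out[i] <- unname(infra_marker_map[key])
        }
      }
    }
    paste(out, collapse = " ")
  }, character(1), USE.NAMES = FALSE)
}

# Empty single-name check result (row template).
empty_name_check <- function(input_name = "") {
  tibble::tibble(
    input_name = input_name,
    standardized_name = "",
    match_status = "unmatched",
    plant_name_id = "",
    accepted_plant_name_id = "",
    accepted_taxon_name = "",
    taxon_rank = "",
    binomial_fallback = FALSE
  )
}

#' Check one scientific name against a WCVP table
#'
#' The standardized name is matched exactly against `taxon_name`. An
#' `Accepted` match reports itself; a `Synonym` match is resolved one hop
#' through `accepted_plant_name_id` to its accepted name. Homonyms prefer
#' the single Accepted row; several (or zero) viable resolutions yield
#' `ambiguous`. A synonym pointing at a missing or non-Accepted row is not
#' chased further and is reported `ambiguous`. When the full standardized
#' string finds nothing, the binomial (first two tokens) is tried and the
#' fallback recorded.
#'
#' @param name one raw scientific-name string.
#' @param wcvp a table from [load_wcvp()] (or [generate_mini_wcvp()]).
#' @return A one-row tibble: `input_name`, `standardized_name`,
#'   `match_status` (`matched_accepted`, `matched_synonym_resolved`,
#'   `ambiguous`, `unmatched`), `plant_name_id`, `accepted_plant_name_id`,
#'   `accepted_taxon_name`, `taxon_rank` (of the accepted name),
#'   `binomial_fallback`.
#' @export
wcvp_check_name <- function(name, wcvp) {
  stopifnot(length(name) == 1)
  res <- empty_name_check(canon_missing(name))
  std <- standardize_scientific_name(name)
  res$standardized_name <- std
  if (!nzchar(std)) return(res)

  hit <- wcvp[wcvp$taxon_name == std, , drop = FALSE]
  if (nrow(hit) == 0) {
    tok <- strsplit(std, " ", fixed = TRUE)[[1]]
    if (length(tok) > 2) {
      binom <- paste(tok[1:2], collapse = " ")
      hit <- wcvp[wcvp$taxon_name == binom, , drop = FALSE]
      if (nrow(hit) > 0) res$binomial_fallback <- TRUE
    }
  }
  if (nrow(hit) == 0) return(res)

  acc <- hit[hit$taxon_status == "Accepted", , drop = FALSE]
  if (nrow(acc) > 1) {
    res$match_status <- "ambiguous"
    return(res)
  }
  if (nrow(acc) == 1) {
    res$match_status <- "matched_accepted"
    res$plant_name_id <- acc$plant_name_id
    res$accepted_plant_name_id <- acc$plant_name_id
    res$accepted_taxon_name <- acc$taxon_name
    res$taxon_rank <- acc$taxon_rank
    return(res)
  }
  # synonym rows only: every viable row must resolve to one Accepted target
  syn <- hit[hit$taxon_status == "Synonym", , drop = FALSE]
  if (nrow(syn) == 0) {
    res$match_status <- "ambiguous"
    return(res)
  }
  targets <- unique(syn$accepted_plant_name_id)
  targets <- targets[nzchar(targets)]
  if (length(targets) != 1) {
    res$match_status <- "ambiguous"
    return(res)
  }
  tgt <- wcvp[wcvp$plant_name_id == targets, , drop = FALSE]
  if (nrow(tgt) != 1 || tgt$taxon_status != "Accepted") {
    res$match_status <- "ambiguous"   # dangling or synonym-of-synonym
    return(res)
  }
  res$match_status <- "matched_synonym_resolved"
  res$plant_name_id <- syn$plant_name_id[1]
  res$accepted_plant_name_id <- tgt$plant_name_id
  res$accepted_taxon_name <- tgt$taxon_name
  res$taxon_rank <- tgt$taxon_rank
  res
}

#' Check scientific names in batch
#'
#' Annotates an occurrence table with backbone-reconciliation columns. Each
#' distinct `scientificName` is checked once with [wcvp_check_name()] and
#' the result broadcast to all rows carrying that name. Appended columns are
#' prefixed `wcvp_`; row count and order are unchanged.
#'
#' @param occ occurrence tibble with a `scientificName` column.
#' @param wcvp a WCVP-style names table.
#' @return `occ` plus `wcvp_standardized_name`, `wcvp_match_status`,
#'   `wcvp_plant_name_id`, `wcvp_accepted_plant_name_id`,
#'   `wcvp_accepted_name`, `wcvp_taxon_rank`, `wcvp_binomial_fallback`.
#' @export
wcvp_check_name_batch <- function(occ, wcvp) {
  assert_columns(occ, "scientificName", "wcvp_check_name_batch")
  occ <- tibble::as_tibble(occ)
  nm <- canon_missing(occ$scientificName)
  uniq <- unique(nm)
  res <- if (length(uniq) == 0) empty_name_check(character(0))
         else purrr::map_dfr(uniq, wcvp_check_name, wcvp = wcvp)
  res <- dplyr::rename_with(res, ~ paste0("wcvp_", .x))
  res <- dplyr::rename(res, wcvp_accepted_name = "wcvp_accepted_taxon_name")
  idx <- match(nm, uniq)
  out <- dplyr::bind_cols(
    occ,
    res[idx, setdiff(names(res), "wcvp_input_name"), drop = FALSE]
  )
  tibble::as_tibble(out)
}

# Ranks counted as a determination at or below species rank.
species_or_below_ranks <- c("Species", "Subspecies", "Variety", "Form")

# Species-or-below accepted name per record ("" when none): the currency of
# consensus counting.
accepted_species_name <- function(checked) {
  ok <- checked$wcvp_match_status %in%
    c("matched_accepted", "matched_synonym_resolved") &
    checked$wcvp_taxon_rank %in% species_or_below_ranks
  ifelse(ok, checked$wcvp_accepted_name, "")
}
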