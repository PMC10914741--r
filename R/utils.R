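# shared helpers: blank handling and ASCII folding

# Missing values arrive in several dialects ("", "NA", "\\N", literal NULL
# strings from some publishers); canonical form is the empty string.
blank_tokens <- c("", "NA", "\\N", "NULL", "null")

is_blank <- function(x) {
  x <- as.character(x)
  is.na(x) | trimws(x) %in% blank_tokens
}

canon_missing <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  x[trimws(x) %in% blank_tokens] <- ""
  x
}

# Diacritic-fold to ASCII and uppercase; the canonical form for surnames,
# family names and key parts.
fold_ascii_upper <- function(x) {
  x <- stringi::stri_trans_general(as.character(x), "Latin-ASCII")
  toupper(x)
}

squish <- function(x) stringr::str_squish(x)

assert_columns <- function(tbl, cols, where) {
  miss <- setdiff(cols, names(tbl))
  if (length(miss) > 0) {
    stop(sprintf("%s: required column(s) missing: %s",
                 where, paste(miss, collapse = ", ")), call. = FALSE)
  }
  invisible(tbl)
}
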