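# In-code fixtures shared across test files.

# A minimal occurrence tibble in the standard profile; `...` overrides or
# appends columns, recycled to the longest length.
make_occ <- function(...) {
  over <- tibble::tibble(...)
  n <- max(1L, nrow(over))
  base <- tibble::tibble(
    gbifID = sprintf("%03d", seq_len(n)),
    family = "Myrtaceae",
    scientificName = "Eugenia uniflora",
    recordedBy = "Gardner, G.",
    recordNumber = "417",
    year = "1841",
    institutionCode = "K",
    catalogNumber = paste0("CAT-", seq_len(n)),
    locality = "Serra dos Orgaos",
    municipality = "Teresopolis",
    stateProvince = "Rio de Janeiro",
    countryCode = "BR",
    fieldNotes = "Shrub, white flowers",
    habitat = "Montane forest",
    decimalLatitude = "-22.45",
    decimalLongitude = "-42.98",
    issue = ""
  )
  for (nm in names(over)) base[[nm]] <- over[[nm]]
  suppressWarnings(gatherparse::select_fields(base, "standard"))
}

# Two-species mini backbone traced by hand in the name-check tests:
#   wcvp-0001 Eugenia uniflora  (Accepted)
#   wcvp-0002 Myrcia splendens  (Accepted)
#   wcvp-0003 Stenocalyx unifl. (Synonym -> wcvp-0001)
mini_wcvp <- function() {
  w <- gatherparse::generate_mini_wcvp(
    c("Eugenia uniflora", "Myrcia splendens"), synonyms_per_species = 0)
  syn <- w[1, ]
  syn$plant_name_id <- "wcvp-9001"
  syn$taxon_status <- "Synonym"
  syn$taxon_name <- "Stenocalyx unifloras"
  syn$accepted_plant_name_id <- "wcvp-0001"
  dplyr::bind_rows(w, syn)
}

# Full pipeline over a table, with the default synthetic backbone.
run_pipeline <- function(occ, wcvp = gatherparse::generate_mini_wcvp()) {
  gatherparse::run_workflow(occ, wcvp)
}
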