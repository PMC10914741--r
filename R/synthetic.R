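# Synthetic occurrence data with known gathering structure.
#
# The generator emulates the duplicate structure of aggregated herbarium
# data: each simulated gathering is copied to several institutions, and
# individual copies are corrupted with the error modes observed in real
# aggregated data (swapped or zeroed coordinates with their matching GBIF
# issue flags, centroid substitution, conflicting or synonymous
# determinations, dropped fields, lost collector or collection number).

synthetic_species_pool <- c(
  "Eugenia uniflora", "Campomanesia hirsuta", "Psidium guajava",
  "Myrcia splendens", "Eucalyptus globulus", "Syzygium cumini",
  "Plinia cauliflora", "Myrciaria dubia"
)

synthetic_collectors <- c(
  "Gardner", "Silva", "Hopkins", "Müller", "Souza", "Fernández",
  "Oliveira", "Krause"
)

synthetic_institutions <- c("K", "NY", "US", "E", "F", "S", "MO", "INPA",
                            "NHMUK", "CAS", "GH", "W", "MNHN")

#' Define a synthetic-data scenario
#'
#' Bundles the generator's conditions: number of gatherings, duplicates per
#' gathering, per-duplicate corruption probabilities and the seed. All
#' probabilities default to 0 (clean data); each models one error mode seen
#' in aggregated occurrence data.
#'
#' @param n_events number of true collection events (gatherings).
#' @param dups_per_event duplicates per event: a single integer for fixed
#'   k, or an integer vector sampled from uniformly (e.g. `1:32`).
#' @param p_conflict_id probability a duplicate carries a conflicting
#'   (wrong-species) determination.
#' @param p_synonym probability a duplicate's determination uses a synonym
#'   of the true species.
#' @param p_missing_number probability `recordNumber` is lost ("s.n.").
#' @param p_missing_collector probability `recordedBy` is lost.
#' @param p_swap_coord probability latitude and longitude are swapped (the
#'   record gains `PRESUMED_SWAPPED_COORDINATE`).
#' @param p_zero_coord probability coordinates are zeroed (gains
#'   `ZERO_COORDINATE`).
#' @param p_centroid probability coordinates are replaced by a coarse
#'   centroid (gains `COORDINATE_ROUNDED`).
#' @param p_drop_field per-field probability that a completeness field
#'   (year, locality, municipality, stateProvince, fieldNotes, habitat,
#'   catalogNumber) is blanked.
#' @param seed integer seed; all draws flow from it.
#' @return A list of class `gp_scenario`.
#' @export
synthetic_scenario <- function(n_events = 100, dups_per_event = 3,
                               p_conflict_id = 0, p_synonym = 0,
                               p_missing_number = 0, p_missing_collector = 0,
                               p_swap_coord = 0, p_zero_coord = 0,
                               p_centroid = 0, p_drop_field = 0,
                               seed = 1L) {
  probs <- c(p_conflict_id, p_synonym, p_missing_number, p_missing_collector,
             p_swap_coord, p_zero_coord, p_centroid, p_drop_field)
  stopifnot(n_events >= 1, all(dups_per_event >= 1),
            all(probs >= 0 & probs <= 1))
  structure(
    list(n_events = as.integer(n_events),
         dups_per_event = as.integer(dups_per_event),
         p_conflict_id = p_conflict_id, p_synonym = p_synonym,
         p_missing_number = p_missing_number,
         p_missing_collector = p_missing_collector,
         p_swap_coord = p_swap_coord, p_zero_coord = p_zero_coord,
         p_centroid = p_centroid, p_drop_field = p_drop_field,
         seed = as.integer(seed)),
    class = "gp_scenario"
  )
}

# Render a collector name in one of the recordedBy dialects found in
# aggregated data. The primary surname survives every dialect.
render_recorded_by <- function(surname, dialect) {
  initial <- paste0(substr(surname, 1, 1), ".")
  switch(dialect,
    comma = paste0(surname, ", ", initial),
    initial_first = paste(initial, surname),
    team = paste0(surname, ", ", initial, "; Colleague, A."),
    et_al = paste0(surname, " et al."),
    paste0(surname, ", ", initial)
  )
}

#' Generate a synthetic GBIF occurrence table with known structure
#'
#' Deterministic given the scenario seed. Every duplicate of an event
#' shares the event's true family, collector and collection number
#' (possibly corrupted per the scenario's error rates); injected coordinate
#' errors carry the matching GBIF issue token. Output columns are the
#' standard field profile.
#'
#' @param scenario a [synthetic_scenario()].
#' @param wcvp optional backbone from [generate_mini_wcvp()]; generated
#'   from the default species pool when `NULL`. Determinations are drawn
#'   from its accepted names (and synonyms, under `p_synonym`).
#' @return List with `occ` (occurrence tibble, standard profile), `truth`
#'   (tibble `gbifID`, `event_id`, `true_taxon`, `true_key`) and `wcvp`
#'   (the backbone used).
#' @export
generate_occurrences <- function(scenario = synthetic_scenario(),
                                 wcvp = NULL) {
  stopifnot(inherits(scenario, "gp_scenario"))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(scenario$seed)

  if (is.null(wcvp)) {
    wcvp <- generate_mini_wcvp(synthetic_species_pool,
                               synonyms_per_species = 1)
  }
  accepted <- wcvp$taxon_name[wcvp$taxon_status == "Accepted" &
                                wcvp$taxon_rank == "Species"]
  synonym_of <- split(
    wcvp$taxon_name[wcvp$taxon_status == "Synonym"],
    wcvp$accepted_plant_name_id[wcvp$taxon_status == "Synonym"]
  )
  acc_id <- setNames(
    wcvp$plant_name_id[wcvp$taxon_status == "Accepted" &
                         wcvp$taxon_rank == "Species"],
    accepted)

  ne <- scenario$n_events
  ev_species <- sample(accepted, ne, replace = TRUE)
  ev_collector <- sample(synthetic_collectors, ne, replace = TRUE)
  ev_number <- as.character(1000L + seq_len(ne))
  ev_lon <- stats::runif(ne, -60, -40)
  ev_lat <- stats::runif(ne, -30, 0)
  ev_year <- as.character(sample(1950:2020, ne, replace = TRUE))
  ev_locality <- paste("Locality of event", seq_len(ne))
  ev_municipality <- paste("Municipality", sample(1:40, ne, replace = TRUE))
  ev_state <- paste("State", sample(1:8, ne, replace = TRUE))
  ev_habitat <- paste("Forest remnant, plot", seq_len(ne))
  ev_notes <- paste("Shrub 2-4 m, flowers white; note", seq_len(ne))
  k <- if (length(scenario$dups_per_event) == 1) {
    rep(scenario$dups_per_event, ne)
  } else {
    sample(scenario$dups_per_event, ne, replace = TRUE)
  }

  rows <- vector("list", sum(k))
  r <- 0L
  for (e in seq_len(ne)) {
    for (d in seq_len(k[e])) {
      r <- r + 1L
      surname <- ev_collector[e]
      dialect <- sample(c("comma", "initial_first", "team", "et_al"), 1)
      recorded_by <- render_recorded_by(surname, dialect)
      number <- ev_number[e]
      name <- ev_species[e]
      issues <- character(0)
      lon <- ev_lon[e]; lat <- ev_lat[e]

      if (stats::runif(1) < scenario$p_conflict_id) {
        name <- sample(setdiff(accepted, ev_species[e]), 1)
      } else if (stats::runif(1) < scenario$p_synonym) {
        syns <- synonym_of[[acc_id[[ev_species[e]]]]]
        if (length(syns) > 0) name <- sample(syns, 1)
      }
      if (stats::runif(1) < scenario$p_missing_number) number <- "s.n."
      if (stats::runif(1) < scenario$p_missing_collector) recorded_by <- ""
      if (stats::runif(1) < scenario$p_zero_coord) {
        lon <- 0; lat <- 0; issues <- c(issues, "ZERO_COORDINATE")
      } else if (stats::runif(1) < scenario$p_swap_coord) {
        tmp <- lon; lon <- lat; lat <- tmp
        issues <- c(issues, "PRESUMED_SWAPPED_COORDINATE")
      } else if (stats::runif(1) < scenario$p_centroid) {
        lon <- round(lon); lat <- round(lat)
        issues <- c(issues, "COORDINATE_ROUNDED")
      }
      drop <- function(x) {
        if (stats::runif(1) < scenario$p_drop_field) "" else x
      }
      rows[[r]] <- tibble::tibble(
        gbifID = sprintf("%07d", r),
        family = "Myrtaceae",
        scientificName = name,
        recordedBy = recorded_by,
        recordNumber = number,
        year = drop(ev_year[e]),
        institutionCode = sample(synthetic_institutions, 1),
        catalogNumber = drop(sprintf("BC-%05d", r)),
        locality = drop(ev_locality[e]),
        municipality = drop(ev_municipality[e]),
        stateProvince = drop(ev_state[e]),
        countryCode = "BR",
        fieldNotes = drop(ev_notes[e]),
        habitat = drop(ev_habitat[e]),
        decimalLatitude = format(lat, digits = 8),
        decimalLongitude = format(lon, digits = 8),
        issue = paste(issues, collapse = ";"),
        .event = e
      )
    }
  }
  occ <- dplyr::bind_rows(rows)
  truth <- tibble::tibble(
    gbifID = occ$gbifID,
    event_id = occ$.event,
    true_taxon = ev_species[occ$.event],
    true_key = paste("MYRTACEAE", fold_ascii_upper(ev_collector[occ$.event]),
                     ev_number[occ$.event], sep = "_")
  )
  occ$.event <- NULL
  occ <- suppressWarnings(select_fields(occ, "standard"))
  list(occ = occ, truth = truth, wcvp = wcvp)
}

# Standard WCVP names-export column set, padded to the full 33.
wcvp_columns <- c(
  "plant_name_id", "ipni_id", "taxon_rank", "taxon_status", "family",
  "genus_hybrid", "genus", "species_hybrid", "species",
  "infraspecific_rank", "infraspecies", "parenthetical_author",
  "primary_author", "publication_author", "place_of_publication",
  "volume_and_page", "first_published", "nomenclatural_remarks",
  "geographic_area", "lifeform_description", "climate_description",
  "taxon_name", "taxon_authors", "accepted_plant_name_id",
  "basionym_plant_name_id", "replaced_synonym_author", "homotypic_synonym",
  "parent_plant_name_id", "powo_id", "hybrid_formula", "reviewed",
  "publication_year", "taxon_name_id"
)

#' Generate a miniature WCVP-style names table
#'
#' A 33-column backbone with one Accepted row per species and
#' `synonyms_per_species` Synonym rows resolving to it, for offline testing
#' of the name-reconciliation path.
#'
#' @param species character vector of accepted binomials.
#' @param synonyms_per_species synonyms generated per species.
#' @return A 33-column tibble in the WCVP column layout.
#' @export
generate_mini_wcvp <- function(species = synthetic_species_pool,
                               synonyms_per_species = 1) {
  stopifnot(length(species) > 0, synonyms_per_species >= 0)
  n <- length(species)
  blank_row <- function(k) {
    out <- as.data.frame(matrix("", nrow = k, ncol = length(wcvp_columns)),
                         stringsAsFactors = FALSE)
    names(out) <- wcvp_columns
    tibble::as_tibble(out)
  }
  acc <- blank_row(n)
  acc$plant_name_id <- sprintf("wcvp-%04d", seq_len(n))
  acc$taxon_rank <- "Species"
  acc$taxon_status <- "Accepted"
  acc$family <- "Myrtaceae"
  acc$genus <- vapply(strsplit(species, " "), `[`, "", 1)
  acc$species <- vapply(strsplit(species, " "), `[`, "", 2)
  acc$taxon_name <- species
  acc$taxon_authors <- "Auth."
  acc$accepted_plant_name_id <- acc$plant_name_id

  out <- acc
  if (synonyms_per_species > 0) {
    for (s in seq_len(synonyms_per_species)) {
      syn <- blank_row(n)
      syn$plant_name_id <- sprintf("wcvp-%04d", n * s + seq_len(n))
      syn$taxon_rank <- "Species"
      syn$taxon_status <- "Synonym"
      syn$family <- "Myrtaceae"
      syn$genus <- paste0("Oldgenus", s)
      syn$species <- paste0(acc$species, "oides")
      syn$taxon_name <- paste(syn$genus, syn$species)
      syn$taxon_authors <- "Auth."
      syn$accepted_plant_name_id <- acc$plant_name_id
      out <- dplyr::bind_rows(out, syn)
    }
  }
  stopifnot(ncol(out) == 33)
  out
}
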