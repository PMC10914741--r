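# Brute-force oracles: an independent scan over all group members.
oracle_voucher <- function(total, completeness, id) {
  best <- which(total == max(total))
  if (length(best) > 1) best <- best[completeness[best] ==
                                       max(completeness[best])]
  if (length(best) > 1) best <- best[order(id[best])]
  best[1]
}

oracle_consensus <- function(names) {
  names <- names[nzchar(names)]
  if (length(names) == 0) return("UNIDENTIFIED")
  freq <- sapply(unique(names), function(n) sum(names == n))
  cand <- names(freq)[freq == max(freq)]
  sort(cand)[1]
}

test_that("completeness_score counts the ten unit flags", {
  full <- make_occ(gbifID = "1")
  expect_identical(completeness_score(full), 10L)

  empty <- make_occ(
    gbifID = "1", recordedBy = "", recordNumber = "", year = "",
    institutionCode = "", catalogNumber = "", locality = "",
    municipality = "", stateProvince = "", fieldNotes = "",
    issue = "COUNTRY_INVALID"
  )
  expect_identical(completeness_score(empty), 0L)

  # hand count: collector + number + year + valid country = 4
  partial <- make_occ(
    gbifID = "1", institutionCode = "", catalogNumber = "", locality = "",
    municipality = "", stateProvince = "", fieldNotes = ""
  )
  expect_identical(completeness_score(partial), 4L)

  # COUNTRY_INVALID switches exactly the country flag off
  flagged <- make_occ(gbifID = "1", issue = "COUNTRY_INVALID")
  expect_identical(completeness_score(flagged), 9L)
})

test_that("consensus_taxon follows plurality, alphabetical ties, UNIDENTIFIED", {
  expect_identical(consensus_taxon(c("A sp", "A sp", "B sp")), "A sp")
  expect_identical(consensus_taxon(c("B sp", "A sp")), "A sp")
  expect_identical(consensus_taxon(c("", "")), "UNIDENTIFIED")
  expect_identical(consensus_taxon(character(0)), "UNIDENTIFIED")
  expect_identical(consensus_taxon(c("", "B sp")), "B sp")
})

test_that("voucher choice matches the brute-force argmax on random groups", {
  set.seed(42)
  for (i in 1:300) {
    n <- sample(1:32, 1)
    total <- sample(-9:10, n, replace = TRUE)
    completeness <- sample(0:10, n, replace = TRUE)
    id <- sample(sprintf("%04d", sample(9999, n)))
    got <- gatherparse:::select_voucher_idx(total, completeness, id)
    expect_identical(got, oracle_voucher(total, completeness, id))
  }
})

test_that("select_digital_voucher picks the highest-total member per group", {
  occ <- make_occ(
    gbifID = c("001", "002", "003"),
    recordedBy = "Gardner, G.", recordNumber = "417",
    locality = c("x", "", ""), municipality = c("x", "", ""),
    fieldNotes = c("x", "", ""), habitat = c("x", "", "")
  )
  res <- run_pipeline(occ)$data
  expect_identical(res$gp_is_voucher, c(TRUE, FALSE, FALSE))
  expect_equal(sum(res$gp_is_voucher), 1L)
  expect_true(all(res$gp_total_score[res$gp_is_voucher] >=
                    res$gp_total_score))
})

test_that("total scores stay within [-9, 10]", {
  sim <- generate_occurrences(synthetic_scenario(
    n_events = 40, dups_per_event = 1:4, p_zero_coord = 0.3,
    p_drop_field = 0.5, p_missing_collector = 0.2, seed = 5))
  res <- run_pipeline(sim$occ, sim$wcvp)$data
  expect_true(all(res$gp_total_score >= -9 & res$gp_total_score <= 10))
  expect_true(all(res$gp_spatial_score %in% c(0L, -1L, -3L, -9L)))
})

test_that("merge fills only empty voucher fields from the best donor", {
  occ <- make_occ(
    gbifID = c("001", "002", "003"),
    recordedBy = "Gardner, G.", recordNumber = "417",
    habitat = c("", "Riverine forest", "Cerrado"),
    locality = c("Keep me", "Donor locality", "Other"),
    municipality = c("", "", ""),
    fieldNotes = c("x", "x", "x")
  )
  # make record 001 the clear voucher and 002 the better donor
  occ$year <- c("1841", "1841", "")
  res <- run_pipeline(occ)
  v <- res$data[res$data$gp_is_voucher, ]
  expect_identical(v$habitat, "Riverine forest")   # filled from 002
  expect_identical(v$locality, "Keep me")          # never overwritten
  expect_true(all(res$merge_log$field %in% c("habitat")))
  expect_identical(res$merge_log$donor_gbifID, "002")
})

test_that("a fully populated voucher triggers zero merge actions", {
  occ <- make_occ(gbifID = c("001", "002"),
                  recordedBy = "Gardner, G.", recordNumber = "417")
  res <- run_pipeline(occ)
  expect_equal(nrow(res$merge_log), 0L)
})

test_that("coordinates move as an atomic pair with their issue context", {
  # all members tie on total score (all -9 spatial: no coords or a zeroed
  # coordinate), so the smallest id (001) is the voucher; donor 002 holds
  # the only full coordinate pair
  occ <- make_occ(
    gbifID = c("001", "002", "003"),
    recordedBy = "Gardner, G.", recordNumber = "417",
    decimalLatitude = c("", "-22.4", ""),
    decimalLongitude = c("", "-42.9", ""),
    issue = c("", "ZERO_COORDINATE", "")
  )
  res <- run_pipeline(occ)
  v <- res$data[res$data$gp_is_voucher, ]
  expect_identical(v$gbifID, "001")
  expect_identical(v$decimalLatitude, "-22.4")
  expect_identical(v$decimalLongitude, "-42.9")
  # the donor's issue-based quality travels with its coordinates
  expect_identical(v$issue, "ZERO_COORDINATE")
  expect_identical(v$gp_spatial_score, -9L)
  expect_setequal(
    res$merge_log$field[res$merge_log$donor_gbifID == "002"],
    c("decimalLatitude", "decimalLongitude"))
})

test_that("re-running select+merge on a merged single-voucher set is a no-op", {
  sim <- generate_occurrences(synthetic_scenario(
    n_events = 15, dups_per_event = 3, p_drop_field = 0.4, seed = 9))
  res <- run_pipeline(sim$occ, sim$wcvp)
  vouchers <- res$data[res$data$gp_is_voucher,
                       gbif_field_profile("standard")]
  res2 <- run_pipeline(vouchers, sim$wcvp)
  expect_equal(nrow(res2$merge_log), 0L)
  expect_true(all(res2$data$gp_is_voucher))
  expect_identical(
    res2$data[, gbif_field_profile("standard")],
    vouchers)
})
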