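test_that("partition labels are disjoint, exhaustive and voucher-consistent", {
  sim <- generate_occurrences(synthetic_scenario(
    n_events = 30, dups_per_event = 1:4, p_zero_coord = 0.2,
    p_conflict_id = 0.2, p_missing_collector = 0.1, seed = 3))
  res <- run_pipeline(sim$occ, sim$wcvp)$data
  expect_true(all(res$gp_dataset_result %in%
                    c("useable", "unusable", "duplicate")))
  expect_equal(sum(table(res$gp_dataset_result)), nrow(res))
  # one non-duplicate per event key
  per_key <- tapply(res$gp_dataset_result != "duplicate", res$gp_event_key,
                    sum)
  expect_true(all(per_key == 1))
})

test_that("unidentified or spatially excluded vouchers are unusable", {
  occ <- make_occ(
    gbifID = c("001", "002"),
    recordedBy = c("Gardner, G.", "Silva, J."),
    recordNumber = c("417", "88"),
    scientificName = c("Ignotus ignotus", "Eugenia uniflora"),
    issue = c("", "ZERO_COORDINATE")
  )
  res <- run_pipeline(occ, mini_wcvp())$data
  expect_identical(res$gp_dataset_result, c("unusable", "unusable"))
})

test_that("summary totals add up on a hand-tallied fixture", {
  # 10 records in 4 gatherings: sizes 4, 3, 2, 1; the size-2 group is
  # unidentified, the singleton has zeroed coordinates
  occ <- make_occ(
    gbifID = sprintf("%03d", 1:10),
    recordedBy = "Gardner, G.",
    recordNumber = c(rep("1", 4), rep("2", 3), rep("3", 2), "4"),
    scientificName = c(rep("Eugenia uniflora", 7),
                       rep("Ignotus ignotus", 2), "Eugenia uniflora"),
    issue = c(rep("", 9), "ZERO_COORDINATE")
  )
  res <- run_pipeline(occ, mini_wcvp())
  t <- res$summary$totals
  expect_equal(t[["n_records"]], 10)
  expect_equal(t[["n_events"]], 4)
  expect_equal(t[["n_duplicates"]], 6)
  expect_equal(t[["n_useable"]], 2)
  expect_equal(t[["n_unusable"]], 2)
})

test_that("zero-record input summarizes to zero totals", {
  sim <- generate_occurrences(synthetic_scenario(n_events = 2, seed = 1))
  res <- run_pipeline(sim$occ[0, ], sim$wcvp)
  expect_true(all(res$summary$totals == 0))
})

test_that("merge-frequency table sums to total merge actions", {
  sim <- generate_occurrences(synthetic_scenario(
    n_events = 25, dups_per_event = 3, p_drop_field = 0.5, seed = 21))
  res <- run_pipeline(sim$occ, sim$wcvp)
  ma <- res$summary$merge_actions
  expect_equal(sum(ma$n_actions), nrow(res$merge_log))
})

test_that("export writes the three partitions plus the merge log", {
  sim <- generate_occurrences(synthetic_scenario(
    n_events = 8, dups_per_event = 2, p_drop_field = 0.3, seed = 2))
  res <- run_pipeline(sim$occ, sim$wcvp)
  outdir <- withr::local_tempdir()
  paths <- export_partitions(res$data, outdir, res$merge_log)
  expect_true(all(file.exists(paths)))
  reread <- readr::read_tsv(paths[["duplicates"]],
                            col_types = readr::cols(.default = "c"),
                            quote = "", na = character())
  expect_equal(nrow(reread), sum(res$data$gp_dataset_result == "duplicate"))
})

test_that("grid_richness floors signed coordinates and counts distinct taxa", {
  tbl <- tibble::tibble(
    gp_consensus_taxon = c("A", "B", "A", "C"),
    decimalLongitude = c("-43.2", "-43.9", "-43.5", "10.1"),
    decimalLatitude = c("-22.9", "-22.1", "-22.9", "5.5")
  )
  g <- grid_richness(tbl)
  cell <- g[g$cell_lon == -44 & g$cell_lat == -23, ]
  expect_equal(cell$taxon_count, 2L)   # A (deduplicated) and B
  expect_equal(g$taxon_count[g$cell_lon == 10], 1L)
})

test_that("grid_richness skips out-of-range coordinates with a warning", {
  tbl <- tibble::tibble(
    gp_consensus_taxon = c("A", "B"),
    decimalLongitude = c("-43.2", "999"),
    decimalLatitude = c("-22.9", "0")
  )
  expect_warning(g <- grid_richness(tbl), "out-of-range")
  expect_equal(sum(g$taxon_count), 1L)
})

test_that("empty input yields an empty grid", {
  tbl <- tibble::tibble(gp_consensus_taxon = character(),
                        decimalLongitude = character(),
                        decimalLatitude = character())
  expect_equal(nrow(grid_richness(tbl)), 0L)
})

test_that("percent difference follows 100*(a-b)/a with absent cells as 0", {
  a <- tibble::tibble(cell_lon = c(0, 1, 2), cell_lat = 0,
                      taxon_count = c(100L, 4L, 7L))
  b <- tibble::tibble(cell_lon = c(0, 1), cell_lat = 0,
                      taxon_count = c(50L, 4L))
  d <- richness_percent_diff(a, b)
  expect_equal(d$pct_diff[d$cell_lon == 0], 50)
  expect_equal(d$pct_diff[d$cell_lon == 1], 0)
  expect_equal(d$pct_diff[d$cell_lon == 2], 100)  # cell absent from b
})

test_that("parsing never creates taxa in a cell (richness monotonicity)", {
  sim <- generate_occurrences(synthetic_scenario(
    n_events = 60, dups_per_event = 1:3, p_conflict_id = 0.2, seed = 13))
  checked <- wcvp_check_name_batch(sim$occ, sim$wcvp)
  checked$taxon <- ifelse(nzchar(checked$wcvp_accepted_name),
                          checked$wcvp_accepted_name,
                          checked$scientificName)
  pre <- grid_richness(checked, taxon_col = "taxon")
  res <- run_pipeline(sim$occ, sim$wcvp)$data
  post <- grid_richness(res[res$gp_dataset_result == "useable", ])
  joined <- dplyr::left_join(post, pre, by = c("cell_lon", "cell_lat"),
                             suffix = c("_post", "_pre"))
  expect_true(all(joined$taxon_count_post <= joined$taxon_count_pre))
})
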