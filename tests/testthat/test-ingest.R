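test_that("DAP unit dialects convert correctly and round-trip", {
  expect_equal(convert_dap(0.0001952, "gym2", "cgycm2"), 195.2)
  expect_equal(convert_dap(1, "ugym2", "cgycm2"), 1)
  expect_equal(convert_dap(1, "gycm2", "cgycm2"), 100)
  # round-trip identity across all dialect pairs
  units <- c("cgycm2", "gycm2", "gym2", "ugym2", "mgycm2")
  x <- c(0.001, 1, 195.2, 1e4)
  for (u in units) for (v in units) {
    expect_equal(convert_dap(convert_dap(x, u, v), v, u), x,
                 tolerance = 1e-9)
  }
  expect_error(convert_dap(1, "sievert"), "Unknown DAP unit")
})

test_that("event tables read with unit conversion and column mapping", {
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(
    tibble::tibble(
      proc = c("A", "A"), plane = c("frontal", "lateral"),
      irradiation_type = c("fluoroscopy", "cinegraphy"),
      KAP = c(0.0001952, 0.0000100), weight_kg = 19
    ), path)
  ev <- read_event_table(
    path, dap_unit = "gym2",
    col_map = c(procedure_id = "proc", dap_cgycm2 = "KAP"))
  expect_equal(nrow(ev), 2)
  expect_equal(ev$dap_cgycm2, c(195.2, 10))
  expect_identical(names(ev)[seq_along(cathdose:::.event_columns)],
                   cathdose:::.event_columns)
  # row order preserved
  expect_equal(ev$plane, c("frontal", "lateral"))
})

test_that("empty file with header yields an empty event table", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("procedure_id,plane,irradiation_type,dap_cgycm2", path)
  ev <- read_event_table(path)
  expect_equal(nrow(ev), 0)
})

test_that("format and validity errors are raised by name", {
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(plane = "frontal", dap_cgycm2 = 1), path)
  expect_error(read_event_table(path), "procedure_id")
  expect_error(canonicalize_events(make_event(dap_cgycm2 = -1)),
               "Negative dose")
  expect_error(canonicalize_events(make_event(plane = "oblique")),
               "plane")
  expect_warning(canonicalize_events(make_event(procedure_type = "Biopsy")),
                 "other")
})

test_that("validation excludes rotational events and flags missing geometry", {
  ev <- dplyr::bind_rows(
    make_events(8),
    make_event(irradiation_type = "rotational"),
    make_event(primary_angle = NA_real_)
  )
  v <- validate_events(ev)
  expect_equal(v$report$n_events_in, 10)
  expect_equal(v$report$n_events_kept, 9)
  expect_equal(v$report$exclusions$reason, "rotational")
  expect_equal(v$report$flags$reason, "incomplete_geometry")
  # flagged event kept for DRL, unusable for jobs
  expect_equal(sum(!v$events$job_ok), 1)
  # all-valid stream has no exclusions
  v2 <- validate_events(make_events(5))
  expect_equal(nrow(v2$report$exclusions), 0)
  expect_equal(v2$report$n_events_kept, 5)
})

test_that("procedure aggregation sums events per modality and plane", {
  ev <- dplyr::bind_rows(
    make_event(dap_cgycm2 = 100, duration_s = 60),
    make_event(dap_cgycm2 = 50, duration_s = 30),
    make_event(dap_cgycm2 = 20, duration_s = 0, frame_count = 40,
               irradiation_type = "cinegraphy", plane = "lateral")
  )
  s <- aggregate_procedure(ev)
  expect_equal(s$total_dap, 170)
  expect_equal(s$dap_fluoro, 150)
  expect_equal(s$dap_cine, 20)
  expect_equal(s$dap_frontal, 150)
  expect_equal(s$dap_lateral, 20)
  expect_equal(s$fluoro_time_s, 90)
  expect_equal(s$cine_frames, 40)
  expect_true(s$is_biplane)
  # per-procedure fluoroscopy share of DAP, the cohort-level statistic
  expect_equal(s$dap_fluoro / s$total_dap, 150 / 170)
  # aggregation invariants
  expect_equal(s$total_dap, s$dap_frontal + s$dap_lateral)
  expect_equal(s$total_dap, s$dap_fluoro + s$dap_cine)
})

test_that("aggregation is permutation-invariant and rejects mixed procedures", {
  ev <- dplyr::bind_rows(lapply(1:6, function(i) {
    make_event(dap_cgycm2 = i * 10, duration_s = i,
               plane = ifelse(i %% 2 == 0, "lateral", "frontal"))
  }))
  perm <- withr::with_seed(7, ev[sample.int(6), ])
  expect_equal(aggregate_procedure(ev), aggregate_procedure(perm))
  expect_error(
    aggregate_procedure(dplyr::bind_rows(make_event(),
                                         make_event(procedure_id = "P2"))),
    "multiple procedures")
})

test_that("zero-event procedure yields an all-zero summary", {
  s <- aggregate_procedure(make_event()[0, ])
  expect_equal(s$total_dap, 0)
  expect_equal(s$cine_frames, 0)
  expect_false(s$is_biplane)
})

test_that("cohort DAP is conserved from events to summaries", {
  co <- generate_cohort(cohort_config(n_procedures = 12, seed = 5,
                                      mean_events = 8))
  kept <- validate_events(co$events)$events
  s <- aggregate_procedures(kept)
  expect_equal(sum(s$total_dap), sum(kept$dap_cgycm2))
})
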