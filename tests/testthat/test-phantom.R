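test_that("phantom selection picks the nearest age class, ties older", {
  expect_equal(select_phantom(0.9)$age_class, "1y")
  expect_equal(select_phantom(0)$age_class, "newborn")
  expect_equal(select_phantom(69.6)$age_class, "adult")
  # age 3 is equidistant from 1y and 5y: older class wins
  expect_equal(select_phantom(3)$age_class, "5y")
  expect_equal(select_phantom(12.4)$age_class, "10y")
})

test_that("phantom scaling conserves mass under uniform density", {
  ref <- select_phantom(10) # 139.8 cm / 32.4 kg reference
  id <- scale_phantom(ref, ref$height_cm, ref$weight_kg)
  expect_equal(id$scale_height, 1)
  expect_equal(id$scale_transverse, 1)

  quad <- scale_phantom(ref, ref$height_cm, 4 * ref$weight_kg)
  expect_equal(quad$scale_transverse, 2)

  # closed form at off-reference size, checked against a hand evaluation
  toy <- ref
  toy$height_cm <- 140; toy$weight_kg <- 32
  sc <- scale_phantom(toy, 150, 35)
  expect_equal(sc$scale_height, 150 / 140)
  expect_equal(sc$scale_transverse, sqrt((35 / 32) / (150 / 140)))
  # mass conservation to 1e-9
  expect_equal(toy$weight_kg * sc$scale_height * sc$scale_transverse^2, 35,
               tolerance = 1e-9)
  expect_error(scale_phantom(ref, -1, 10), "positive")
})

test_that("FSD matches the straight-line cases and stays inside the SAD", {
  ph <- phantom_stub(lat_cm = 11, ap_cm = 8) # 110 x 80 mm semi-axes
  expect_equal(compute_fsd(ph, 0, 0, 765), 765 - 80)
  expect_equal(compute_fsd(ph, 90, 0, 765), 765 - 110)
  expect_equal(compute_fsd(ph, -90, 0, 765), 765 - 110)
  expect_equal(compute_fsd(ph, 180, 0, 765), 765 - 80)
  # cranio-caudal angulation lengthens the in-tissue path
  expect_equal(compute_fsd(ph, 0, 30, 765), 765 - 80 / cos(30 * pi / 180))
  for (p in seq(-180, 180, by = 30)) {
    f <- compute_fsd(ph, p, 0, 765)
    expect_true(f > 0 && f < 765)
  }
})

test_that("FSD is symmetric in primary angle and constant on a circular trunk", {
  ph <- phantom_stub(11, 8)
  for (p in c(15, 37.5, 60, 120)) {
    expect_equal(compute_fsd(ph, p, 0, 765), compute_fsd(ph, -p, 0, 765))
  }
  circ <- phantom_stub(9, 9)
  fsd <- vapply(seq(-180, 180, 15), function(p) compute_fsd(circ, p, 5, 800),
                numeric(1))
  expect_equal(fsd, rep(fsd[1], length(fsd)))
})

test_that("FSD is monotonically non-increasing in each trunk semi-axis", {
  for (p in c(0, 30, 60, 90)) {
    f_lat <- vapply(c(8, 10, 12, 14),
                    function(a) compute_fsd(phantom_stub(a, 8), p, 0, 765),
                    numeric(1))
    expect_true(all(diff(f_lat) <= 1e-12))
    f_ap <- vapply(c(6, 8, 10, 12),
                   function(b) compute_fsd(phantom_stub(11, b), p, 0, 765),
                   numeric(1))
    expect_true(all(diff(f_ap) <= 1e-12))
  }
})

test_that("simulation jobs compose selection, scaling and FSD", {
  job <- build_simulation_job(make_event())
  expect_equal(job$phantom_class, "5y")
  expect_true(job$fsd_mm > 0 && job$fsd_mm < job$source_isocenter_mm)
  # field size at the reference point from DAP / kerma
  expect_equal(job$field_size_cm2, 100 / (14 * 0.1))
  expect_error(build_simulation_job(make_event(primary_angle = NA_real_)),
               "primary_angle")
})

test_that("one job per usable event, flagged events refused unless skipped", {
  co <- generate_cohort(cohort_config(n_procedures = 1, seed = 3,
                                      mean_events = 63))
  ev <- validate_events(co$events)$events
  jobs <- build_simulation_jobs(ev)
  expect_equal(nrow(jobs), nrow(ev))

  ev2 <- dplyr::bind_rows(make_events(3), make_event(primary_angle = NA_real_))
  v <- validate_events(ev2)
  expect_error(build_simulation_jobs(v$events), "incomplete_geometry")
  expect_equal(nrow(build_simulation_jobs(v$events, skip_flagged = TRUE)), 3)
})

test_that("job files serialize deterministically with a manifest", {
  dir <- withr::local_tempdir()
  jobs <- build_simulation_jobs(dplyr::bind_rows(
    make_event(dap_cgycm2 = 10), make_event(dap_cgycm2 = 20)))
  manifest <- write_job_files(jobs, dir)
  files <- list.files(dir, pattern = "\\.def$")
  expect_equal(length(files), 2)
  lines <- readLines(file.path(dir, files[1]))
  expect_true(any(grepl("^fsd_mm=", lines)))
  expect_equal(nrow(readr::read_csv(manifest, show_col_types = FALSE)), 2)
})
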