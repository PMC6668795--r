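test_that("conversion-factor lookup maps weight to group and validates keys", {
  tb <- default_cf_table()
  expect_equal(lookup_cf(tb, "ED", 40, "total"), 20.63)
  expect_equal(lookup_cf(tb, "ED", 40, "frontal"), 16.71)
  expect_equal(lookup_cf(tb, "lungs", 35, "biplane"), 77.12)
  expect_equal(lookup_cf(tb, "ED", group = "All", plane = "total"), 19.84)
  # patients above the table's range use the >=80 kg group
  expect_equal(lookup_cf(tb, "ED", 105, "total"),
               lookup_cf(tb, "ED", 85, "total"))
  expect_error(lookup_cf(tb, "spleen", 35, "biplane"), "Available targets")
  expect_error(lookup_cf(tb, "ED", 35, "oblique"), "plane")
})

test_that("the table is complete: every target/plane has all groups, slopes > 0", {
  tb <- default_cf_table()
  groups <- c("<5", "5-<15", "15-<30", "30-<50", "50-<80", ">=80", "All")
  cells <- dplyr::count(tb, .data$target, .data$plane)
  expect_true(all(cells$n == length(groups)))
  expect_true(all(tb$slope > 0))
  expect_true(all(is.na(tb$ci_low) | tb$ci_low <= tb$slope))
  expect_true(all(is.na(tb$ci_high) | tb$ci_high >= tb$slope))
})

test_that("organ and effective dose estimates follow dose = CF x DAP_BW / 100", {
  s <- worked_example_summary()
  od <- estimate_organ_doses(s, organs = "lungs")
  expect_equal(round(od$dose_mgy, 2), 15.05)

  ed <- estimate_effective_dose(s)
  expect_equal(ed$ed_msv, 20.63 * (683.13 / 35) / 100)

  # zero DAP gives zero everywhere
  s0 <- s
  s0$total_dap <- 0; s0$dap_frontal <- 0; s0$dap_fluoro <- 0
  expect_true(all(estimate_organ_doses(s0)$dose_mgy == 0))

  # linearity: doubling DAP doubles every estimate
  s2 <- s
  for (c in c("total_dap", "dap_frontal", "dap_fluoro")) s2[[c]] <- 2 * s[[c]]
  expect_equal(estimate_organ_doses(s2)$dose_mgy,
               2 * estimate_organ_doses(s)$dose_mgy)

  # frontal-only procedure: per-plane mode equals the frontal-CF route
  pp <- estimate_organ_doses(s, mode = "per_plane", organs = "lungs")
  cf_f <- lookup_cf(default_cf_table(), "lungs", 35, "frontal")
  expect_equal(pp$dose_mgy, cf_f * (683.13 / 35) / 100)
})

test_that("tissue-weighted effective dose normalizes and warns on gaps", {
  for (w in c("ICRP103", "ICRP60")) {
    expect_equal(sum(tissue_weights(w)), 1, tolerance = 1e-9)
  }
  # complete tissue set all at dose d: ED = d
  tissues <- names(tissue_weights("ICRP103"))
  doses <- setNames(rep(2.5, length(tissues)), tissues)
  doses <- doses[!names(doses) %in% c("gonads", "remainder")]
  doses <- c(doses, ovaries = 2.5, remainder_male = 2.5,
             remainder_female = 2.5)
  expect_equal(effective_dose_from_organ_doses(doses), 2.5)

  # single nonzero tissue contributes w_t * d
  expect_warning(
    ed <- effective_dose_from_organ_doses(c(lungs = 10)),
    "treated as 0")
  expect_equal(ed, 0.12 * 10)

  # hand-computed toy set
  ed2 <- effective_dose_from_organ_doses(
    c(lungs = 10, liver = 5, thyroid = 2), quiet = TRUE)
  expect_equal(ed2, 0.12 * 10 + 0.04 * 5 + 0.04 * 2)
  expect_error(effective_dose_from_organ_doses(c(lungs = -1)), ">= 0")
})

test_that("noiseless cohorts give back the generating slopes exactly", {
  cf <- default_cf_table()
  cf <- cf[cf$target %in% c("lungs", "ED"), ]
  co <- generate_cohort(cohort_config(n_procedures = 150, seed = 17,
                                      cf_table = cf), events = FALSE)
  derived <- derive_cf_table(co$summaries, co$truth)
  per_group <- derived[derived$weight_group != "All", ]
  truth <- cf[cf$weight_group != "All", ]
  j <- dplyr::inner_join(per_group, truth,
                         by = c("target", "plane", "weight_group"),
                         suffix = c("_fit", "_true"))
  expect_true(nrow(j) > 10)
  expect_equal(j$slope_fit, j$slope_true, tolerance = 1e-8)
  expect_true(all(abs(j$r_squared - 1) < 1e-9))
})

test_that("a monoplane cohort yields no lateral conversion factors", {
  cf <- default_cf_table()
  cf <- cf[cf$target == "lungs", ]
  co <- generate_cohort(cohort_config(n_procedures = 60, seed = 19,
                                      cf_table = cf,
                                      biplane_prob = c(diagnostic = 0,
                                                       interventional = 0)),
                        events = FALSE)
  derived <- derive_cf_table(co$summaries, co$truth)
  expect_false("lateral" %in% derived$plane)
  expect_true(all(c("biplane", "frontal") %in% derived$plane))
})
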