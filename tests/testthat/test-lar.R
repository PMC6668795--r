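test_that("risk coefficients: grid lookup, interpolation, clamping", {
  tb <- beir_coefficients()
  # the tabulated lung/male/age-10 incidence cell
  expect_equal(risk_coefficient(tb, "lung", "male", 10, "incidence"), 216)
  # midpoint between grid ages is the mean of the bracketing values
  v10 <- risk_coefficient(tb, "lung", "male", 10)
  v15 <- risk_coefficient(tb, "lung", "male", 15)
  expect_equal(risk_coefficient(tb, "lung", "male", 12.5), (v10 + v15) / 2)
  # interpolated values bounded by their bracketing grid values
  for (a in c(2.5, 7, 33, 61)) {
    lo <- max(tb$age[tb$age <= a]); hi <- min(tb$age[tb$age >= a])
    v <- risk_coefficient(tb, "all_cancers", "female", a)
    bounds <- range(risk_coefficient(tb, "all_cancers", "female", lo),
                    risk_coefficient(tb, "all_cancers", "female", hi))
    expect_true(v >= bounds[1] - 1e-12 && v <= bounds[2] + 1e-12)
  }
  # beyond the grid: nearest endpoint
  expect_equal(risk_coefficient(tb, "lung", "male", 200),
               risk_coefficient(tb, "lung", "male", 80))
  expect_error(risk_coefficient(tb, "pancreas", "male", 10), "Available sites")
})

test_that("the coefficient fixture is internally consistent", {
  tb <- beir_coefficients()
  expect_true(all(tb$coefficient >= 0))
  # site rows sum to the all-solid row (to the report's unit rounding),
  # and all_solid + leukemia = all_cancers
  for (k in c("incidence", "mortality")) {
    for (sx in c("male", "female")) {
      sub <- tb[tb$kind == k & tb$sex == sx, ]
      solid_sites <- setdiff(unique(sub$site),
                             c("all_solid", "leukemia", "all_cancers"))
      for (a in c(0, 10, 30)) {
        at <- function(s) sub$coefficient[sub$site == s & sub$age == a]
        expect_equal(sum(vapply(solid_sites, at, numeric(1))),
                     at("all_solid"), tolerance = 5e-3)
        expect_equal(at("all_solid") + at("leukemia"), at("all_cancers"),
                     tolerance = 1e-9)
      }
    }
  }
})

test_that("LAR scales linearly with dose and the DDREF ratio is exactly 0.75", {
  tb <- beir_coefficients()
  expect_equal(lar_for_site(0, "lung", "male", 10, table = tb), 0)
  # linearity
  l1 <- lar_for_site(10, "stomach", "female", 4.3, table = tb)
  l2 <- lar_for_site(20, "stomach", "female", 4.3, table = tb)
  expect_equal(l2, 2 * l1)
  # DDREF 2 vs 1.5, property-style over random inputs
  cases <- withr::with_seed(31, tibble::tibble(
    dose = runif(20, 0.1, 200),
    site = sample(c("lung", "colon", "leukemia", "all_cancers"), 20, TRUE),
    sex = sample(c("male", "female"), 20, TRUE),
    age = runif(20, 0, 80),
    kind = sample(c("incidence", "mortality"), 20, TRUE)
  ))
  for (i in seq_len(nrow(cases))) {
    a <- lar_for_site(cases$dose[i], cases$site[i], cases$sex[i],
                      cases$age[i], cases$kind[i], ddref = 1.5, table = tb)
    b <- lar_for_site(cases$dose[i], cases$site[i], cases$sex[i],
                      cases$age[i], cases$kind[i], ddref = 2, table = tb)
    expect_equal(b / a, 0.75, tolerance = 1e-12)
  }
  expect_error(lar_for_site(-1, "lung", "male", 10, table = tb), ">= 0")
  expect_error(lar_for_site(1, "lung", "male", 10, ddref = 3, table = tb),
               "ddref")
})

test_that("the reporting chain rounds at each reported step", {
  ch <- lar_report_chain(15.05, "lung", "male", 10, "incidence")
  expect_equal(ch$lar_ddref15, 33)
  expect_equal(ch$lar_ddref2, 25)
  expect_equal(ch$unrounded, 0.01505 / 0.1 * 216, tolerance = 1e-9)
})

test_that("total LAR is additive over sites and respects sex validity", {
  tb <- beir_coefficients()
  organs <- setNames(rep(0, length(cathdose:::.organ_targets)),
                     cathdose:::.organ_targets)
  z <- lar_total(organs, "male", 10, "incidence", table = tb)
  expect_equal(z$all_cancers, 0)

  # a single exposed organ contributes exactly its site LAR
  organs_l <- organs
  organs_l[["lungs"]] <- 15.05
  r <- lar_total(organs_l, "male", 10, "incidence", table = tb)
  expect_equal(r$all_cancers,
               lar_for_site(15.05, "lung", "male", 10, table = tb))

  # breast and ovary sites absent for male patients, present for female
  expect_false(any(c("breast", "ovary") %in% r$per_site$site))
  rf <- lar_total(organs_l, "female", 10, "incidence", table = tb)
  expect_true(all(c("breast", "ovary") %in% rf$per_site$site))

  # doubling every organ dose doubles every LAR (seeded random dose sets)
  for (seed in 1:3) {
    doses <- withr::with_seed(seed, setNames(
      runif(length(cathdose:::.organ_targets), 0, 30),
      cathdose:::.organ_targets))
    r1 <- lar_total(doses, "female", 6, "mortality", table = tb)
    r2 <- lar_total(doses * 2, "female", 6, "mortality", table = tb)
    expect_equal(r2$per_site$lar, 2 * r1$per_site$lar)
  }

  expect_error(lar_total(c(lungs = 1), "male", 10, table = tb), "missing")
})
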