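#' BEIR VII lifetime-attributable-risk coefficients
#'
#' Site-, sex- and age-at-exposure-specific lifetime attributable risk
#' (LAR) coefficients for cancer incidence and mortality, expressed as
#' cases (or deaths) per 100,000 persons exposed to 0.1 Gy, at the models'
#' native dose and dose-rate effectiveness factor (DDREF) of 1.5. The
#' shipped fixture is a transcription of the per-0.1-Gy LAR tables of the
#' BEIR VII Phase 2 report (tables 12D-1 for incidence and 12D-2 for
#' mortality, Euro-American population), on the report's age grid
#' 0, 5, 10, 15, 20, 30, 40, ..., 80 years; users can verify or replace it
#' against the public report via `path`. Mortality coefficients carry no
#' thyroid row (the report folds thyroid deaths into "other").
#'
#' @param path Optional path to an alternative CSV with columns `kind`,
#'   `sex`, `site`, `age0` ... `age80`.
#' @return A long tibble: `kind`, `sex`, `site`, `age`, `coefficient`.
#' @export
beir_coefficients <- function(path = NULL) {
  path <- path %||% system.file("extdata", "beir_lar_coefficients.csv",
                                package = "cathdose", mustWork = TRUE)
  wide <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  long <- tidyr::pivot_longer(wide, dplyr::starts_with("age"),
                              names_to = "age", names_prefix = "age",
                              values_to = "coefficient")
  long$age <- as.numeric(long$age)
  long
}

#' Risk coefficient for a site, sex and age at exposure
#'
#' Exact grid ages return the tabulated value; between grid ages the
#' coefficient is linearly interpolated; ages beyond either end of the grid
#' are clamped to the nearest endpoint. The grid is coarse (5-year steps in
#' childhood, 10-year above 30), so interpolation is the pragmatic choice
#' for the fractional ages of a paediatric cohort.
#'
#' @param table Coefficient table from [beir_coefficients()].
#' @param site Cancer site, e.g. `"lung"`, `"leukemia"`, `"all_cancers"`.
#' @param sex `"male"` or `"female"`.
#' @param age Age at exposure in years, `>= 0`.
#' @param kind `"incidence"` or `"mortality"`.
#' @return Coefficient per 100,000 per 0.1 Gy (DDREF 1.5) as a number.
#' @export
risk_coefficient <- function(table, site, sex, age,
                             kind = c("incidence", "mortality")) {
  kind <- match.arg(kind)
  sex <- match.arg(tolower(sex), c("male", "female"))
  stopifnot(is.finite(age), age >= 0)
  rows <- table[table$kind == kind & table$sex == sex & table$site == site, ]
  if (!nrow(rows)) {
    avail <- sort(unique(table$site[table$kind == kind & table$sex == sex]))
    abort(paste0("No ", kind, " coefficient for site '", site, "' (", sex,
                 "). Available sites: ", paste(avail, collapse = ", ")))
  }
  rows <- rows[order(rows$age), ]
  approx(rows$age, rows$coefficient, xout = age, rule = 2)$y
}

#' Lifetime attributable risk for one site from one organ dose
#'
#' Linear scaling of the BEIR VII coefficient to the delivered dose,
#' `LAR = (dose_Gy / 0.1) x coefficient`, followed by the DDREF
#' adjustment `x (1.5 / ddref)`: the tables are built at DDREF 1.5, and
#' `ddref = 2` (the ICRP-recommended value) multiplies the risk by 0.75.
#' The returned value is unrounded; rounding to whole cases per 100,000 is
#' a reporting concern, see [lar_report_chain()].
#'
#' @param dose_mgy Organ dose in mGy, `>= 0`.
#' @inheritParams risk_coefficient
#' @param ddref Dose and dose-rate effectiveness factor, 1.5 or 2.
#' @return LAR per 100,000 persons as a bare number.
#' @export
lar_for_site <- function(dose_mgy, site, sex, age,
                         kind = c("incidence", "mortality"), ddref = 1.5,
                         table = beir_coefficients()) {
  kind <- match.arg(kind)
  if (!is.finite(dose_mgy) || dose_mgy < 0) abort("dose_mgy must be >= 0")
  if (!ddref %in% c(1.5, 2)) abort("ddref must be 1.5 or 2")
  coefficient <- risk_coefficient(table, site, sex, age, kind)
  (dose_mgy / 1000) / 0.1 * coefficient * (1.5 / ddref)
}

#' Default mapping from BEIR VII sites to dosimetric organs
#'
#' Which organ dose drives which cancer site, and for which sex the site
#' exists. This mapping is the single authority on which organ doses are
#' risk-relevant: edit it to include or exclude sites. `other` (solid)
#' cancers are driven by the remainder-tissue dose of the matching sex;
#' leukemia by the active bone marrow dose. Thyroid has incidence
#' coefficients only.
#'
#' @return A tibble: `site`, `organ`, `sexes` (`"both"`, `"male"`,
#'   `"female"`).
#' @export
default_site_map <- function() {
  tibble::tribble(
    ~site,      ~organ,               ~sexes,
    "stomach",  "stomach",            "both",
    "colon",    "colon",              "both",
    "liver",    "liver",              "both",
    "lung",     "lungs",              "both",
    "bladder",  "urinary_bladder",    "both",
    "thyroid",  "thyroid",            "both",
    "breast",   "breasts",            "female",
    "ovary",    "ovaries",            "female",
    "leukemia", "active_bone_marrow", "both",
    "other",    "remainder",          "both"
  )
}

#' Total lifetime attributable risk from a set of organ doses
#'
#' Computes the per-site LAR for every site of the site map that is valid
#' for the patient's sex and present in the coefficient table for the
#' requested kind, and sums them into the all-cancer estimate. Sites whose
#' mapped organ dose is absent raise an error (set the dose to 0 to assert
#' a genuinely unexposed organ).
#'
#' @param organ_doses Named numeric vector of organ doses in mGy; names as
#'   in [estimate_organ_doses()] output (`lungs`, `active_bone_marrow`,
#'   `remainder_male`/`remainder_female`, ...).
#' @inheritParams lar_for_site
#' @param site_map See [default_site_map()].
#' @return A list: `per_site` (tibble `site`, `organ`, `dose_mgy`, `lar`),
#'   `all_cancers` (sum over sites), `kind`, `ddref`, `sex`, `age`.
#' @export
lar_total <- function(organ_doses, sex, age,
                      kind = c("incidence", "mortality"), ddref = 1.5,
                      site_map = default_site_map(),
                      table = beir_coefficients()) {
  kind <- match.arg(kind)
  sex <- match.arg(tolower(sex), c("male", "female"))
  map <- site_map[site_map$sexes %in% c("both", sex), , drop = FALSE]
  # sites the coefficient table does not carry for this kind (e.g. thyroid
  # mortality) are skipped: they have no model, not a zero risk
  map <- map[map$site %in% table$site[table$kind == kind], , drop = FALSE]
  per_site <- dplyr::bind_rows(lapply(seq_len(nrow(map)), function(i) {
    organ <- map$organ[i]
    if (organ == "remainder") {
      organ <- if (sex == "male") "remainder_male" else "remainder_female"
    }
    if (!organ %in% names(organ_doses)) {
      abort(paste0("Site '", map$site[i], "' needs organ dose '", organ,
                   "', which is missing"))
    }
    d <- organ_doses[[organ]]
    tibble::tibble(site = map$site[i], organ = organ, dose_mgy = d,
                   lar = lar_for_site(d, map$site[i], sex, age, kind, ddref,
                                      table))
  }))
  list(per_site = per_site, all_cancers = sum(per_site$lar),
       kind = kind, ddref = ddref, sex = sex, age = age)
}

#' Stepwise-rounded LAR reporting chain
#'
#' Risk communicated in whole cases per 100,000 is conventionally rounded
#' at each reported step: first the DDREF-1.5 value is rounded, then the
#' DDREF-2 adjustment (x 0.75) is applied to the rounded figure and rounded
#' again. This helper reproduces that chain; the analysis functions
#' themselves never round.
#'
#' @inheritParams lar_for_site
#' @return A list: `lar_ddref15` and `lar_ddref2` (integers per 100,000),
#'   plus the `unrounded` DDREF-1.5 value.
#' @export
lar_report_chain <- function(dose_mgy, site, sex, age,
                             kind = c("incidence", "mortality"),
                             table = beir_coefficients()) {
  raw <- lar_for_site(dose_mgy, site, sex, age, kind, ddref = 1.5,
                      table = table)
  step1 <- round(raw)
  list(lar_ddref15 = step1, lar_ddref2 = round(step1 * 1.5 / 2),
       unrounded = raw)
}
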