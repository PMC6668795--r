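#' Configuration for the synthetic cohort generator
#'
#' The generator emulates the event stream of a paediatric cardiac
#' catheterization service: a procedure-type mix matching a single-centre
#' caseload, a strongly right-skewed age distribution (median 4.3 y, from
#' days-old newborns to adults with congenital heart disease), parametric
#' growth curves for weight and height, and the multiplicative dose model
#' `DAP = k_type x BW x FT x exp(eps)`, `eps ~ N(0, sigma_dap^2)` — the
#' structure under which DAP normalized by body weight times fluoroscopy
#' time is a size- and complexity-independent quantity. The per-type scale
#' constants `k_type` are back-solved from the target 75th percentiles of
#' DAP/(BWxFT) so that a default cohort lands at clinically plausible
#' magnitudes (pooled P75 near 2 cGy.cm2/kg/min).
#'
#' @param n_procedures Number of procedures, default 222.
#' @param seed Integer seed; every downstream draw is determined by it.
#' @param sigma_dap Log-scale SD of the multiplicative DAP noise, default
#'   0.8 (order-of-magnitude spread, as dose distributions in this setting
#'   show).
#' @param mean_events Mean irradiation events per procedure, default 63.
#' @param cf_table Conversion factors used as ground truth when generating
#'   reference doses; default the shipped table.
#' @param ... Overrides for any other element of the returned list.
#' @return A config list, see the field comments in the source.
#' @export
cohort_config <- function(n_procedures = 222, seed = 1, sigma_dap = 0.8,
                          mean_events = 63, cf_table = default_cf_table(),
                          ...) {
  cfg <- list(
    n_procedures = n_procedures,
    seed = seed,
    sigma_dap = sigma_dap,
    mean_events = mean_events,
    cf_table = cf_table,
    # single-centre caseload mix (counts, normalized internally)
    type_counts = c("Diagnostic" = 33, "ASD closure" = 33,
                    "PFO closure" = 17, "PDA closure" = 18,
                    "Single Balloon Valvuloplasty" = 43,
                    "Single Balloon Angioplasty" = 34,
                    "Multi Balloon Dilatation" = 13,
                    "Pulmonary Valve Replacement" = 7, "Stenting" = 14),
    # target P75 of DAP/(BWxFT) per type, cGy.cm2/kg/min; k_type is
    # back-solved from these and sigma_dap
    p75_dap_bwxft = c("Diagnostic" = 3.59, "ASD closure" = 1.48,
                      "PFO closure" = 1.45, "PDA closure" = 1.33,
                      "Single Balloon Valvuloplasty" = 1.53,
                      "Single Balloon Angioplasty" = 2.01,
                      "Multi Balloon Dilatation" = 1.91,
                      "Pulmonary Valve Replacement" = 3.50,
                      "Stenting" = 3.21),
    # median fluoroscopy time per type, seconds
    ft_median_s = c("Diagnostic" = 481, "ASD closure" = 254,
                    "PFO closure" = 243, "PDA closure" = 358,
                    "Single Balloon Valvuloplasty" = 490,
                    "Single Balloon Angioplasty" = 486,
                    "Multi Balloon Dilatation" = 1142,
                    "Pulmonary Valve Replacement" = 2055, "Stenting" = 1642),
    sdlog_ft = 0.7,
    ft_range_s = c(30, 6024),
    # age: log-normal, median 4.3 y, heavy right tail, truncated to the
    # 2-days-to-70-years span of a congenital heart disease service
    age_meanlog = log(4.3), age_sdlog = 1.9, age_range = c(0.005, 70),
    weight_noise_sdlog = 0.13, height_noise_sdlog = 0.04,
    # median fluoroscopy share of total DAP and biplane probability,
    # per stratum
    fluoro_fraction = c(diagnostic = 0.77, interventional = 0.91),
    fluoro_fraction_sdlogit = 0.5,
    biplane_prob = c(diagnostic = 0.85, interventional = 0.73),
    lateral_share_mean = 0.35, lateral_share_conc = 10,
    # air kerma at the reference point per unit DAP, mGy per cGy.cm2
    kerma_per_dap = 0.14, kerma_noise_sdlog = 0.3,
    # cine frame count medians per type (0 allowed: device-closure
    # procedures are often fluoroscopy-only)
    frames_median = c("Diagnostic" = 456, "ASD closure" = 0,
                      "PFO closure" = 0, "PDA closure" = 172,
                      "Single Balloon Valvuloplasty" = 216,
                      "Single Balloon Angioplasty" = 324,
                      "Multi Balloon Dilatation" = 452,
                      "Pulmonary Valve Replacement" = 1274,
                      "Stenting" = 1052),
    source_isocenter_mm = 765,
    source_detector_range_mm = c(950, 1200)
  )
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  .validate_config(cfg)
  cfg
}

.validate_config <- function(cfg) {
  if (cfg$n_procedures < 1) abort("n_procedures must be >= 1")
  if (cfg$sigma_dap < 0) abort("sigma_dap must be >= 0")
  if (any(cfg$type_counts < 0) || sum(cfg$type_counts) <= 0) {
    abort("type_counts must be non-negative and sum > 0")
  }
  for (f in c("p75_dap_bwxft", "ft_median_s", "frames_median")) {
    missing <- setdiff(names(cfg$type_counts), names(cfg[[f]]))
    if (length(missing)) {
      abort(paste0("Config field ", f, " lacks type(s): ",
                   paste(missing, collapse = ", ")))
    }
  }
  if (any(cfg$fluoro_fraction <= 0 | cfg$fluoro_fraction > 1)) {
    abort("fluoro_fraction must be in (0, 1]")
  }
  invisible(cfg)
}

# parametric growth curves: coarse piecewise-linear medians, enough to put
# a realistic weight and height on an age — not population reference charts
.growth_weight <- function(age) {
  w <- ifelse(age < 1, 3.4 + 5.5 * age,
       ifelse(age < 10, 9 + 2.3 * (age - 1),
       ifelse(age < 15, 30 + 5 * (age - 10),
              55 + 1.5 * pmin(age - 15, 10))))
  pmin(w, 72)
}

.growth_height <- function(age) {
  h <- ifelse(age < 1, 50 + 25 * age,
       ifelse(age < 10, 75 + 7 * (age - 1),
       ifelse(age < 15, 138 + 6 * (age - 10),
              168 + 0.8 * pmin(age - 15, 10))))
  pmin(h, 178)
}

#' Generate a seeded synthetic cohort
#'
#' Draws patients, procedures and (optionally) their per-event exposure
#' streams under the configured model, together with the ground-truth
#' reference doses implied by the configured conversion-factor table. The
#' emitted event table is in the canonical schema of
#' [read_event_table()] and passes [validate_events()] with zero
#' exclusions. The ground truth carries, per procedure and target, the
#' noiseless dose of each estimation route: `biplane` (single factor on
#' cumulative DAP) and `frontal`/`lateral` (per-plane factors on the
#' plane's DAP share); it is never read by the analysis pipeline.
#'
#' @param config From [cohort_config()].
#' @param events Also generate the per-event stream (set `FALSE` for
#'   summary-level studies such as parameter-recovery simulations, where
#'   only per-procedure totals matter).
#' @return A list: `events` (tibble or `NULL`), `summaries` (normalized
#'   per-procedure tibble), `truth` (long tibble `procedure_id`, `target`,
#'   `plane`, `dose`), and `config`.
#' @export
generate_cohort <- function(config = cohort_config(), events = TRUE) {
  .validate_config(config)
  withr::with_seed(config$seed, .generate_cohort_impl(config, events))
}

.generate_cohort_impl <- function(cfg, gen_events) {
  n <- cfg$n_procedures
  types <- names(cfg$type_counts)
  type <- sample(types, n, replace = TRUE,
                 prob = cfg$type_counts / sum(cfg$type_counts))
  k_type <- cfg$p75_dap_bwxft / exp(qnorm(0.75) * cfg$sigma_dap)

  age <- pmin(pmax(rlnorm(n, cfg$age_meanlog, cfg$age_sdlog),
                   cfg$age_range[1]), cfg$age_range[2])
  weight <- .growth_weight(age) * rlnorm(n, 0, cfg$weight_noise_sdlog)
  height <- .growth_height(age) * rlnorm(n, 0, cfg$height_noise_sdlog)
  sex <- sample(c("male", "female"), n, replace = TRUE)

  ft_s <- pmin(pmax(rlnorm(n, log(unname(cfg$ft_median_s[type])),
                           cfg$sdlog_ft),
                    cfg$ft_range_s[1]), cfg$ft_range_s[2])
  dap <- unname(k_type[type]) * weight * (ft_s / 60) *
    rlnorm(n, 0, cfg$sigma_dap)

  stratum <- ifelse(type == "Diagnostic", "diagnostic", "interventional")
  frac_fluoro <- stats::plogis(
    unname(stats::qlogis(cfg$fluoro_fraction[stratum])) +
      rnorm(n, 0, cfg$fluoro_fraction_sdlogit))
  fm <- unname(cfg$frames_median[type])
  frames <- ifelse(fm > 0, round(rlnorm(n, log(pmax(fm, 1)), 0.6)), 0)
  # a procedure with cine DAP needs at least one frame, and vice versa
  frac_fluoro[frames == 0] <- 1
  frames[frac_fluoro >= 1] <- 0

  biplane <- rbinom(n, 1, unname(cfg$biplane_prob[stratum])) == 1
  lat_share <- ifelse(
    biplane,
    stats::rbeta(n, cfg$lateral_share_mean * cfg$lateral_share_conc,
                 (1 - cfg$lateral_share_mean) * cfg$lateral_share_conc),
    0)
  kerma <- dap * cfg$kerma_per_dap * rlnorm(n, 0, cfg$kerma_noise_sdlog)

  ids <- sprintf("P%04d", seq_len(n))
  summaries <- tibble::tibble(
    procedure_id = ids,
    patient_id = sprintf("PAT%04d", seq_len(n)),
    age = age, sex = sex, height_cm = height, weight_kg = weight,
    procedure_type = type,
    n_events = NA_integer_,
    total_dap = dap,
    dap_frontal = dap * (1 - lat_share),
    dap_lateral = dap * lat_share,
    dap_fluoro = dap * frac_fluoro,
    dap_cine = dap * (1 - frac_fluoro),
    total_kerma_mgy = kerma,
    fluoro_time_s = ft_s,
    cine_frames = as.integer(frames),
    is_biplane = biplane
  )
  summaries <- normalize_doses(summaries)

  truth <- .ground_truth(summaries, cfg$cf_table)

  ev <- NULL
  if (gen_events) {
    ev <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
      .events_for_procedure(summaries[i, , drop = FALSE], cfg)
    }))
    summaries$n_events <- as.integer(table(ev$procedure_id)[ids])
  }
  list(events = ev, summaries = summaries, truth = truth, config = cfg)
}

# noiseless reference doses per estimation route (vectorized join: the
# recovery simulations call this hundreds of times)
.ground_truth <- function(summaries, cf_table) {
  cf <- cf_table[cf_table$weight_group != "All",
                 c("target", "plane", "weight_group", "slope")]
  s <- summaries[, c("procedure_id", "weight_kg", "weight_group",
                     "total_dap", "dap_frontal", "dap_lateral")]
  s$weight_group <- as.character(s$weight_group)
  j <- dplyr::inner_join(cf, s, by = "weight_group",
                         relationship = "many-to-many")
  share <- dplyr::case_when(
    j$plane == "biplane" ~ j$total_dap,
    j$plane == "frontal" ~ j$dap_frontal,
    .default = j$dap_lateral
  )
  tibble::tibble(procedure_id = j$procedure_id, target = j$target,
                 plane = j$plane,
                 dose = j$slope * (share / j$weight_kg) / 100)
}

.events_for_procedure <- function(s, cfg) {
  n_ev <- max(2L, rpois(1, cfg$mean_events))
  # bucket DAP totals: modality x plane
  bucket_dap <- c(
    fl_f = s$dap_fluoro * (1 - s$dap_lateral / s$total_dap),
    fl_l = s$dap_fluoro * (s$dap_lateral / s$total_dap),
    ci_f = s$dap_cine * (1 - s$dap_lateral / s$total_dap),
    ci_l = s$dap_cine * (s$dap_lateral / s$total_dap)
  )
  if (s$total_dap <= 0) bucket_dap[] <- c(1, 0, 0, 0)
  n_bucket <- pmax(as.integer(bucket_dap > 0),
                   as.integer(round(n_ev * bucket_dap / sum(bucket_dap))))
  modality <- rep(c("fluoroscopy", "fluoroscopy", "cinegraphy", "cinegraphy"),
                  n_bucket)
  plane <- rep(c("frontal", "lateral", "frontal", "lateral"), n_bucket)
  m <- length(modality)
  # split each bucket's DAP across its events with gamma weights
  dap_ev <- numeric(m)
  pos <- cumsum(n_bucket)
  start <- c(1, head(pos, -1) + 1)
  for (b in seq_along(n_bucket)) {
    if (n_bucket[b] == 0) next
    wts <- rgamma(n_bucket[b], shape = 1.2)
    dap_ev[start[b]:pos[b]] <- bucket_dap[b] * wts / sum(wts)
  }
  fl <- modality == "fluoroscopy"
  dur <- numeric(m)
  wts <- rgamma(sum(fl), shape = 1.2)
  dur[fl] <- s$fluoro_time_s * wts / sum(wts)
  fr <- integer(m)
  if (s$cine_frames > 0 && any(!fl)) {
    fr[!fl] <- as.integer(stats::rmultinom(1, s$cine_frames,
                                           rep(1, sum(!fl))))
  }
  lat <- plane == "lateral"
  prim <- ifelse(lat, rnorm(m, 87, 4), rnorm(m, 0, 20))
  sec <- ifelse(lat, rnorm(m, 1, 3), rnorm(m, 0, 12))
  tibble::tibble(
    procedure_id = s$procedure_id, patient_id = s$patient_id,
    age = s$age, sex = s$sex, height_cm = s$height_cm,
    weight_kg = s$weight_kg, procedure_type = s$procedure_type,
    plane = plane, irradiation_type = modality,
    dap_cgycm2 = dap_ev,
    kerma_mgy = s$total_kerma_mgy * dap_ev / sum(dap_ev),
    duration_s = dur, frame_count = fr,
    primary_angle = pmax(-180, pmin(180, prim)),
    secondary_angle = pmax(-90, pmin(90, sec)),
    source_isocenter_mm = cfg$source_isocenter_mm,
    source_detector_mm = runif(m, cfg$source_detector_range_mm[1],
                               cfg$source_detector_range_mm[2]),
    kvp = runif(m, 60, 110),
    filtration_cu_mm = 0.4
  )
}

#' Attach noisy reference doses to a synthetic cohort
#'
#' Multiplies the ground-truth doses by seeded log-normal noise,
#' `dose_ref = dose_true x exp(eta)`, `eta ~ N(0, noise_sd^2)` — the
#' stand-in for per-procedure Monte Carlo dose results that
#' [derive_cf_table()] recovery studies regress on.
#'
#' @param cohort List from [generate_cohort()].
#' @param noise_sd Log-scale SD of the dose noise; 0 returns the truth.
#' @param seed Integer seed for the noise draws.
#' @return The `truth` tibble with `dose` replaced by its noisy version.
#' @export
attach_reference_doses <- function(cohort, noise_sd = 0.1, seed = 1) {
  truth <- cohort$truth
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  truth$dose <- withr::with_seed(seed, {
    truth$dose * rlnorm(nrow(truth), 0, noise_sd)
  })
  truth
}
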