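#' Reference mathematical-phantom dimensions
#'
#' Returns the table of reference hermaphrodite mathematical phantoms, one
#' row per age class (newborn, 1, 5, 10, 15 years, adult): nominal age,
#' reference height and weight, and the trunk semi-axes at heart level
#' (the trunk is modelled as an elliptical cylinder whose cross-section has
#' a lateral semi-axis — half the trunk width, arms included — and an
#' anterior-posterior semi-axis — half the trunk thickness). Heart-center
#' offsets from the trunk axis default to zero and are configuration, not
#' anatomy: the geometry model only assumes the heart sits at the C-arm
#' isocenter.
#'
#' The shipped defaults follow the published age-scaled hermaphrodite
#' phantom series used throughout paediatric Monte Carlo dosimetry. Pass a
#' modified copy of this table to the geometry functions to use different
#' phantom dimensions.
#'
#' @param path Optional path to an alternative reference CSV with the same
#'   columns.
#' @return A tibble with columns `age_class`, `nominal_age_y`, `height_cm`,
#'   `weight_kg`, `trunk_semi_axis_lat_cm`, `trunk_semi_axis_ap_cm`,
#'   `heart_offset_lat_cm`, `heart_offset_ap_cm`, `heart_offset_cc_cm`.
#' @export
phantom_reference <- function(path = NULL) {
  path <- path %||% system.file("extdata", "phantom_reference.csv",
                                package = "cathdose", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Select the reference phantom for a patient age
#'
#' Picks the age class whose nominal age is nearest to the patient's age;
#' exact ties go to the older class. Ages beyond the grid map to the adult
#' phantom.
#'
#' @param age Patient age in years (fractional allowed), `age >= 0`.
#' @param reference Phantom reference table, see [phantom_reference()].
#' @return One row of `reference`.
#' @export
select_phantom <- function(age, reference = phantom_reference()) {
  stopifnot(length(age) == 1, is.finite(age), age >= 0)
  ref <- reference[order(reference$nominal_age_y), , drop = FALSE]
  d <- abs(ref$nominal_age_y - age)
  # which.max on the reversed vector finds the LAST minimum: older class wins ties
  idx <- length(d) + 1 - which.min(rev(d))
  ref[idx, , drop = FALSE]
}

#' Scale a reference phantom to a patient's height and weight
#'
#' Uniform-density scaling: the longitudinal factor is `height /
#' reference_height` and the transverse factor is chosen so that mass is
#' conserved, `scale_transverse = sqrt((weight / reference_weight) /
#' scale_height)`. Both trunk semi-axes scale by the transverse factor.
#'
#' @param spec One-row phantom reference (from [select_phantom()]).
#' @param height_cm,weight_kg Patient height and weight, both positive.
#' @return A list with the base `spec`, `scale_height`, `scale_transverse`,
#'   and the scaled trunk semi-axes / heart offsets in cm.
#' @export
scale_phantom <- function(spec, height_cm, weight_kg) {
  if (!is.finite(height_cm) || height_cm <= 0 ||
      !is.finite(weight_kg) || weight_kg <= 0) {
    abort("height_cm and weight_kg must be positive")
  }
  sh <- height_cm / spec$height_cm
  st <- sqrt((weight_kg / spec$weight_kg) / sh)
  list(
    base = spec,
    scale_height = sh,
    scale_transverse = st,
    trunk_semi_axis_lat_cm = spec$trunk_semi_axis_lat_cm * st,
    trunk_semi_axis_ap_cm = spec$trunk_semi_axis_ap_cm * st,
    heart_offset_lat_cm = spec$heart_offset_lat_cm * st,
    heart_offset_ap_cm = spec$heart_offset_ap_cm * st,
    patient = list(height_cm = height_cm, weight_kg = weight_kg)
  )
}

#' Focal-spot-to-entrance-skin distance for a C-arm pose
#'
#' With the patient's heart assumed at the C-arm isocenter, the entrance
#' skin point is where the central ray, travelling from the heart center
#' towards the focal spot, crosses the trunk surface. The trunk is an
#' elliptical cylinder with the scaled semi-axes; the primary (RAO-/LAO+)
#' angle rotates the ray in the transverse plane and the secondary
#' (CAU-/CRA+) angulation lengthens the in-tissue path by `1/cos(secondary)`
#' (cylinder approximation, the trunk surface is treated as invariant along
#' the cranio-caudal axis). The result is
#' `FSD = source_isocenter_dist - d`, `d` being the heart-to-skin distance
#' along the ray.
#'
#' @param phantom Scaled phantom from [scale_phantom()].
#' @param primary_angle,secondary_angle Gantry angles in degrees.
#' @param source_isocenter_mm Source (focal spot) to isocenter distance, mm.
#' @return FSD in mm, strictly between 0 and `source_isocenter_mm`.
#' @export
compute_fsd <- function(phantom, primary_angle, secondary_angle,
                        source_isocenter_mm) {
  stopifnot(is.finite(primary_angle), is.finite(secondary_angle),
            is.finite(source_isocenter_mm), source_isocenter_mm > 0)
  a <- phantom$trunk_semi_axis_lat_cm * 10 # mm
  b <- phantom$trunk_semi_axis_ap_cm * 10
  ox <- phantom$heart_offset_lat_cm * 10
  oy <- phantom$heart_offset_ap_cm * 10
  if (a <= 0 || b <= 0) abort("Trunk semi-axes must be positive")
  cs <- cos(secondary_angle * pi / 180)
  if (cs <= 1e-9) abort("Secondary angulation too steep for cylinder model")

  p <- primary_angle * pi / 180
  ux <- sin(p)
  uy <- cos(p)
  # ray (ox,oy) + t*(ux,uy) on ellipse (x/a)^2 + (y/b)^2 = 1
  A <- (ux / a)^2 + (uy / b)^2
  B <- 2 * (ox * ux / a^2 + oy * uy / b^2)
  C <- (ox / a)^2 + (oy / b)^2 - 1
  disc <- B^2 - 4 * A * C
  if (C >= 0 || disc <= 0) abort("no skin entry: heart center outside trunk")
  t_hit <- (-B + sqrt(disc)) / (2 * A)
  d <- t_hit / cs
  fsd <- source_isocenter_mm - d
  if (fsd <= 0) abort("no skin entry: skin point beyond focal spot")
  fsd
}

#' Build a dose-simulation job descriptor for one irradiation event
#'
#' Composes phantom selection, mass-conserving scaling and FSD computation
#' into the flat per-event record a Monte Carlo dose engine consumes: one
#' job per irradiation event, carrying the scaled phantom, the C-arm pose,
#' the FSD and the beam quality. When both DAP and air kerma at the
#' reference point are present, the field size at the reference point is
#' derived as their ratio.
#'
#' @param event One-row canonical event tibble (must have passed geometry
#'   validation, see [validate_events()]).
#' @param reference Phantom reference table.
#' @return A one-row tibble with phantom scale factors, pose, `fsd_mm` and
#'   `field_size_cm2` (NA when kerma is absent or zero).
#' @export
build_simulation_job <- function(event, reference = phantom_reference()) {
  stopifnot(nrow(event) == 1)
  need <- c("age", "height_cm", "weight_kg", "primary_angle",
            "secondary_angle", "source_isocenter_mm", "source_detector_mm")
  miss <- need[!vapply(need, function(c) is.finite(event[[c]]), logical(1))]
  if (length(miss)) {
    abort(paste0("Event lacks fields required for a simulation job: ",
                 paste(miss, collapse = ", ")))
  }
  spec <- select_phantom(event$age, reference)
  ph <- scale_phantom(spec, event$height_cm, event$weight_kg)
  fsd <- compute_fsd(ph, event$primary_angle, event$secondary_angle,
                     event$source_isocenter_mm)
  field <- if (is.finite(event$kerma_mgy) && event$kerma_mgy > 0) {
    # DAP [cGy.cm2] / kerma [cGy] = field area [cm2] at the reference point
    event$dap_cgycm2 / (event$kerma_mgy * 0.1)
  } else NA_real_
  tibble::tibble(
    procedure_id = event$procedure_id,
    phantom_class = spec$age_class,
    scale_height = ph$scale_height,
    scale_transverse = ph$scale_transverse,
    trunk_semi_axis_lat_cm = ph$trunk_semi_axis_lat_cm,
    trunk_semi_axis_ap_cm = ph$trunk_semi_axis_ap_cm,
    plane = event$plane,
    primary_angle = event$primary_angle,
    secondary_angle = event$secondary_angle,
    source_isocenter_mm = event$source_isocenter_mm,
    source_detector_mm = event$source_detector_mm,
    fsd_mm = fsd,
    field_size_cm2 = field,
    dap_cgycm2 = event$dap_cgycm2,
    kvp = event$kvp,
    filtration_cu_mm = event$filtration_cu_mm
  )
}

#' Build simulation jobs for a validated event stream
#'
#' @param events Canonical event tibble with the `job_ok` column from
#'   [validate_events()]; rows with `job_ok = FALSE` raise an error unless
#'   `skip_flagged = TRUE`.
#' @param reference Phantom reference table.
#' @param skip_flagged Drop geometry-incomplete events instead of erroring.
#' @return Tibble of job rows, one per usable event.
#' @export
build_simulation_jobs <- function(events, reference = phantom_reference(),
                                  skip_flagged = FALSE) {
  if (!"job_ok" %in% names(events)) {
    events$job_ok <- TRUE
  }
  if (any(!events$job_ok)) {
    if (!skip_flagged) {
      abort(paste0(sum(!events$job_ok),
                   " event(s) flagged incomplete_geometry; run validate_events",
                   " and drop them or set skip_flagged = TRUE"))
    }
    events <- events[events$job_ok, , drop = FALSE]
  }
  dplyr::bind_rows(lapply(seq_len(nrow(events)), function(i) {
    build_simulation_job(events[i, , drop = FALSE], reference)
  }))
}

#' Write simulation job files
#'
#' One flat `key=value` text file per irradiation event, with a
#' deterministic field order, plus a CSV manifest listing every file. This
#' is the hand-off format for an external Monte Carlo dose engine.
#'
#' @param jobs Tibble from [build_simulation_jobs()].
#' @param dir Output directory (created if needed).
#' @return Path of the manifest CSV, invisibly.
#' @export
write_job_files <- function(jobs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(nrow(jobs))
  for (i in seq_len(nrow(jobs))) {
    row <- jobs[i, , drop = FALSE]
    lines <- vapply(names(row), function(k) {
      v <- row[[k]]
      paste0(k, "=", if (is.numeric(v)) format(v, digits = 12) else as.character(v))
    }, character(1))
    files[i] <- file.path(dir, sprintf("job_%05d.def", i))
    writeLines(lines, files[i])
  }
  manifest <- file.path(dir, "manifest.csv")
  readr::write_csv(tibble::tibble(job = seq_len(nrow(jobs)), file = files,
                                  procedure_id = jobs$procedure_id),
                   manifest)
  invisible(manifest)
}
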