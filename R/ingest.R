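#' Read a per-irradiation-event exposure table
#'
#' Reads the flat-file analogue of a DICOM Radiation Dose Structured Report
#' export (one row per irradiation event) and canonicalizes units and column
#' names. CSV/TSV are read with readr; `.xlsx` files are read through readxl
#' when that package is installed.
#'
#' The canonical schema has one row per irradiation event with patient
#' context repeated on each row:
#' `procedure_id`, `patient_id`, `age` (years), `sex` (`"male"`/`"female"`),
#' `height_cm`, `weight_kg`, `procedure_type`, `plane`
#' (`"frontal"`/`"lateral"`), `irradiation_type` (`"fluoroscopy"`,
#' `"cinegraphy"`, `"rotational"`, `"other"`), `dap_cgycm2`, `kerma_mgy`,
#' `duration_s`, `frame_count`, `primary_angle` (degrees, RAO-/LAO+),
#' `secondary_angle` (degrees, CAU-/CRA+), `source_isocenter_mm`,
#' `source_detector_mm`, `kvp`, `filtration_cu_mm`.
#'
#' @param path Path to a CSV, TSV or XLSX file.
#' @param dap_unit Unit of the DAP column in the source file; see
#'   [convert_dap()] for the supported dialects. Default `"cgycm2"`.
#' @param kerma_unit Unit of the air-kerma column; default `"mgy"`.
#' @param col_map Optional named character vector mapping canonical column
#'   names to the source file's headers, e.g.
#'   `c(dap_cgycm2 = "Dose Area Product", weight_kg = "Patient Weight")`.
#'   Export headers vary between dose-management-system versions, so the
#'   mapping is configuration rather than convention.
#' @return A tibble of irradiation events in canonical columns and units.
#'   Row order of the source is preserved. Optional fields missing from the
#'   source are `NA`; required fields (`procedure_id`, `plane`,
#'   `irradiation_type`, `dap_cgycm2`) must be present and parseable.
#' @export
read_event_table <- function(path, dap_unit = "cgycm2", kerma_unit = "mgy",
                             col_map = NULL) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    xlsx = {
      if (!requireNamespace("readxl", quietly = TRUE)) {
        abort("Reading .xlsx requires the readxl package")
      }
      tibble::as_tibble(readxl::read_excel(path))
    },
    tsv = readr::read_tsv(path, show_col_types = FALSE, progress = FALSE),
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  )
  canonicalize_events(raw, dap_unit = dap_unit, kerma_unit = kerma_unit,
                      col_map = col_map)
}

#' Canonicalize a raw event data frame
#'
#' Lower-level companion of [read_event_table()] for tables already in
#' memory: renames columns per `col_map`, converts units, coerces types and
#' checks basic validity (non-negative doses and durations).
#'
#' @inheritParams read_event_table
#' @param raw A data frame of events.
#' @return A tibble in canonical schema.
#' @export
canonicalize_events <- function(raw, dap_unit = "cgycm2", kerma_unit = "mgy",
                                col_map = NULL) {
  raw <- tibble::as_tibble(raw)
  if (!is.null(col_map)) {
    bad <- setdiff(unname(col_map), names(raw))
    if (length(bad)) {
      abort(paste0("col_map refers to missing source column(s): ",
                   paste(bad, collapse = ", ")))
    }
    for (canon in names(col_map)) {
      names(raw)[names(raw) == col_map[[canon]]] <- canon
    }
  }
  required <- c("procedure_id", "plane", "irradiation_type", "dap_cgycm2")
  missing_req <- setdiff(required, names(raw))
  if (length(missing_req)) {
    abort(paste0("Missing required column(s): ",
                 paste(missing_req, collapse = ", ")))
  }
  n <- nrow(raw)
  out <- tibble::tibble(.rows = n)
  chr_cols <- c("procedure_id", "patient_id", "procedure_type", "sex",
                "plane", "irradiation_type")
  for (col in .event_columns) {
    if (col %in% names(raw)) {
      v <- raw[[col]]
      out[[col]] <- if (col %in% chr_cols) as.character(v) else as.numeric(v)
    } else {
      out[[col]] <- if (col %in% chr_cols) NA_character_ else NA_real_
    }
  }
  out$plane <- tolower(out$plane)
  out$irradiation_type <- tolower(out$irradiation_type)
  out$sex <- tolower(out$sex)
  out$dap_cgycm2 <- convert_dap(out$dap_cgycm2, from = dap_unit, to = "cgycm2")
  out$kerma_mgy <- convert_kerma(out$kerma_mgy, from = kerma_unit, to = "mgy")
  # events with no frame count are zero-frame for aggregation purposes
  out$frame_count[is.na(out$frame_count) &
                    out$irradiation_type == "fluoroscopy"] <- 0

  if (n > 0) {
    if (anyNA(out$dap_cgycm2)) abort("Unparseable or missing DAP value(s)")
    neg <- which(out$dap_cgycm2 < 0 |
                   (!is.na(out$kerma_mgy) & out$kerma_mgy < 0) |
                   (!is.na(out$duration_s) & out$duration_s < 0))
    if (length(neg)) {
      abort(paste0("Negative dose or duration in row(s): ",
                   paste(head(neg, 5), collapse = ", ")))
    }
    bad_plane <- setdiff(unique(out$plane), c("frontal", "lateral"))
    if (length(bad_plane)) {
      abort(paste0("Unknown plane value(s): ", paste(bad_plane, collapse = ", ")))
    }
    unknown_type <- !is.na(out$procedure_type) &
      !out$procedure_type %in% .procedure_types
    if (any(unknown_type)) {
      warn(paste0("Unknown procedure type label(s) mapped to 'other': ",
                  paste(unique(out$procedure_type[unknown_type]), collapse = ", ")))
      out$procedure_type[unknown_type] <- "other"
    }
  }
  out
}

#' Validate irradiation events for downstream use
#'
#' Applies the cohort inclusion rules: rotational-angiography events are
#' excluded outright (their exposure records carry too little geometry to
#' reconstruct), and events missing the geometry needed for a dose-simulation
#' job (gantry angles or source distances) are kept for DRL statistics but
#' flagged as unusable for dose estimation.
#'
#' @param events Canonical event tibble from [read_event_table()].
#' @return A list with
#'   \describe{
#'     \item{events}{kept events, with a logical `job_ok` column;}
#'     \item{report}{a list: `n_events_in`, `n_events_kept`,
#'       `exclusions` (tibble `index`, `reason`) and `flags` (tibble
#'       `index`, `reason`) — indices refer to the input row order.}
#'   }
#' @export
validate_events <- function(events) {
  n_in <- nrow(events)
  reason_excl <- rep(NA_character_, n_in)
  reason_flag <- rep(NA_character_, n_in)

  rot <- !is.na(events$irradiation_type) & events$irradiation_type == "rotational"
  reason_excl[rot] <- "rotational"

  bad_geom <- !is.na(events$source_isocenter_mm) &
    !is.na(events$source_detector_mm) &
    (events$source_isocenter_mm <= 0 |
       events$source_detector_mm <= events$source_isocenter_mm)
  reason_excl[bad_geom & is.na(reason_excl)] <- "invalid_geometry"

  incomplete <- is.na(events$primary_angle) | is.na(events$secondary_angle) |
    is.na(events$source_isocenter_mm) | is.na(events$source_detector_mm)
  reason_flag[incomplete & is.na(reason_excl)] <- "incomplete_geometry"

  keep <- is.na(reason_excl)
  kept <- events[keep, , drop = FALSE]
  kept$job_ok <- is.na(reason_flag[keep])

  report <- list(
    n_events_in = n_in,
    n_events_kept = sum(keep),
    exclusions = tibble::tibble(
      index = which(!keep), reason = reason_excl[!keep]
    ),
    flags = tibble::tibble(
      index = which(keep & !is.na(reason_flag)),
      reason = reason_flag[keep & !is.na(reason_flag)]
    )
  )
  stopifnot(report$n_events_kept + nrow(report$exclusions) == n_in)
  list(events = kept, report = report)
}

#' Aggregate the events of one procedure into a cumulative summary
#'
#' Sums the per-event exposure quantities of a single catheterization into
#' the cumulative values the DRL statistics work with: total DAP and its
#' splits by C-arm plane (frontal/lateral) and by modality
#' (fluoroscopy/cinegraphy), cumulative air kerma at the interventional
#' reference point, fluoroscopy time and number of cinegraphic frames.
#'
#' @param events Event tibble, all rows sharing one `procedure_id`.
#' @return A one-row tibble (see [aggregate_procedures()] for columns).
#' @export
aggregate_procedure <- function(events) {
  ids <- unique(events$procedure_id)
  if (length(ids) > 1) {
    abort(paste0("Events from multiple procedures: ",
                 paste(ids, collapse = ", ")))
  }
  .aggregate_one(events, if (length(ids)) ids else NA_character_)
}

#' Aggregate a cohort event stream into per-procedure summaries
#'
#' @param events Canonical event tibble, any number of procedures.
#' @return A tibble with one row per procedure: patient context
#'   (`patient_id`, `age`, `sex`, `height_cm`, `weight_kg`,
#'   `procedure_type`), `n_events`, `total_dap`, `dap_frontal`,
#'   `dap_lateral`, `dap_fluoro`, `dap_cine` (all cGy.cm2), `total_kerma_mgy`,
#'   `fluoro_time_s`, `cine_frames`, and `is_biplane` (any lateral-plane
#'   event present).
#' @export
aggregate_procedures <- function(events) {
  ids <- unique(events$procedure_id)
  dplyr::bind_rows(lapply(ids, function(id) {
    .aggregate_one(events[events$procedure_id == id, , drop = FALSE], id)
  }))
}

.aggregate_one <- function(ev, id) {
  first_of <- function(col) {
    v <- ev[[col]][!is.na(ev[[col]])]
    if (length(v)) v[[1]] else if (is.character(ev[[col]])) NA_character_ else NA_real_
  }
  fl <- !is.na(ev$irradiation_type) & ev$irradiation_type == "fluoroscopy"
  ci <- !is.na(ev$irradiation_type) & ev$irradiation_type == "cinegraphy"
  lat <- !is.na(ev$plane) & ev$plane == "lateral"
  s <- function(x) sum(x, na.rm = TRUE)
  tibble::tibble(
    procedure_id = id,
    patient_id = first_of("patient_id"),
    age = first_of("age"),
    sex = first_of("sex"),
    height_cm = first_of("height_cm"),
    weight_kg = first_of("weight_kg"),
    procedure_type = first_of("procedure_type"),
    n_events = nrow(ev),
    total_dap = s(ev$dap_cgycm2),
    dap_frontal = s(ev$dap_cgycm2[!lat]),
    dap_lateral = s(ev$dap_cgycm2[lat]),
    dap_fluoro = s(ev$dap_cgycm2[fl]),
    dap_cine = s(ev$dap_cgycm2[ci]),
    total_kerma_mgy = s(ev$kerma_mgy),
    fluoro_time_s = s(ev$duration_s[fl]),
    cine_frames = s(ev$frame_count[ci]),
    is_biplane = any(lat)
  )
}

#' Write per-procedure summaries to CSV
#'
#' Column names carry their units, so the exported file is self-describing.
#'
#' @param summaries Tibble from [aggregate_procedures()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_procedure_summaries <- function(summaries, path) {
  out <- summaries
  ren <- c(total_dap = "total_dap_cgycm2", dap_frontal = "dap_frontal_cgycm2",
           dap_lateral = "dap_lateral_cgycm2", dap_fluoro = "dap_fluoro_cgycm2",
           dap_cine = "dap_cine_cgycm2")
  for (old in names(ren)) {
    if (old %in% names(out)) names(out)[names(out) == old] <- ren[[old]]
  }
  readr::write_csv(out, path)
  invisible(path)
}
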