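#' Default conversion-factor table
#'
#' Regression-slope conversion factors from weight-normalized DAP
#' (Gy.cm2/kg) to organ dose (mGy) and effective dose (mSv, ICRP 103
#' weighting), per RP 185 weight group and per C-arm plane. The `biplane`
#' plane is the single-factor route applied to the cumulative DAP of the
#' whole procedure; `frontal` and `lateral` factors are applied to each
#' C-arm's own DAP share and summed, which is the more accurate route on a
#' biplane system. The `All` weight group pools the whole cohort and is
#' used only on explicit request.
#'
#' @param path Optional path to an alternative CSV with columns `target`,
#'   `weighting`, `plane`, `weight_group`, `slope`, `ci_low`, `ci_high`, `n`.
#' @return A tibble of conversion factors.
#' @export
default_cf_table <- function(path = NULL) {
  path <- path %||% system.file("extdata", "conversion_factors.csv",
                                package = "cathdose", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                  na = c("", "NA"))
}

.cf_plane <- function(plane) {
  plane <- tolower(plane)
  if (plane == "total") plane <- "biplane"
  if (!plane %in% c("biplane", "frontal", "lateral")) {
    abort(paste0("Unknown plane '", plane,
                 "'; use biplane/total, frontal or lateral"))
  }
  plane
}

#' Look up a conversion factor
#'
#' Maps the patient weight to its RP 185 group and returns the slope for
#' the requested target and plane. Weights above the table's range use the
#' `>=80` kg group. The pooled `All` entry is returned only when requested
#' explicitly via `group = "All"`.
#'
#' @param table Conversion-factor table, see [default_cf_table()].
#' @param target `"ED"` or an organ name (`"lungs"`, `"heart"`, ...).
#' @param weight_kg Patient body weight in kg (ignored when `group` given).
#' @param plane `"biplane"` (alias `"total"`), `"frontal"` or `"lateral"`.
#' @param weighting Tissue weighting for `target = "ED"`, default
#'   `"ICRP103"`.
#' @param group Optional explicit weight-group label, e.g. `"All"`.
#' @return The slope (mGy or mSv per Gy.cm-2.kg) as a bare number.
#' @export
lookup_cf <- function(table, target, weight_kg = NULL, plane = "biplane",
                      weighting = "ICRP103", group = NULL) {
  plane <- .cf_plane(plane)
  rows <- table[table$target == target & table$plane == plane, , drop = FALSE]
  if (target == "ED") rows <- rows[!is.na(rows$weighting) &
                                     rows$weighting == weighting, , drop = FALSE]
  if (!nrow(rows)) {
    abort(paste0("No conversion factor for target '", target, "', plane '",
                 plane, "'. Available targets: ",
                 paste(sort(unique(table$target)), collapse = ", ")))
  }
  grp <- group %||% as.character(weight_group(weight_kg))
  hit <- rows[rows$weight_group == grp, , drop = FALSE]
  if (!nrow(hit)) {
    abort(paste0("No '", grp, "' entry for target '", target, "', plane '",
                 plane, "'"))
  }
  hit$slope[[1]]
}

#' Estimate organ doses for procedures from their DAP
#'
#' For each procedure and organ, `dose_mGy = CF x DAP_BW` with DAP_BW in
#' Gy.cm2/kg — DAP is carried internally in cGy.cm2, so the division by
#' 100 happens here, at this single conversion point. In `"total"` mode one
#' biplane factor is applied to the cumulative DAP; in `"per_plane"` mode
#' the frontal and lateral factors are applied to their respective DAP
#' shares and summed, the more accurate route when per-plane DAP is
#' recorded.
#'
#' @param summaries One or more rows of per-procedure summaries (with
#'   `weight_kg` positive).
#' @param table Conversion-factor table.
#' @param mode `"total"` or `"per_plane"`.
#' @param organs Organ targets to estimate; defaults to every organ in the
#'   table.
#' @return A long tibble: `procedure_id`, `organ`, `dose_mgy`.
#' @export
estimate_organ_doses <- function(summaries, table = default_cf_table(),
                                 mode = c("total", "per_plane"),
                                 organs = NULL) {
  mode <- match.arg(mode)
  organs <- organs %||% setdiff(unique(table$target), "ED")
  if (any(!is.finite(summaries$weight_kg) | summaries$weight_kg <= 0)) {
    abort("All procedures need a positive weight_kg")
  }
  dplyr::bind_rows(lapply(seq_len(nrow(summaries)), function(i) {
    s <- summaries[i, , drop = FALSE]
    dose <- vapply(organs, function(org) {
      .cf_dose(s, table, org, mode)
    }, numeric(1))
    tibble::tibble(procedure_id = s$procedure_id, organ = organs,
                   dose_mgy = unname(dose))
  }))
}

# single procedure, single target; dap quantities in cGy.cm2
.cf_dose <- function(s, table, target, mode, weighting = "ICRP103") {
  w <- s$weight_kg
  if (mode == "total") {
    cf <- lookup_cf(table, target, w, "biplane", weighting)
    cf * (s$total_dap / w) / 100
  } else {
    cf_f <- lookup_cf(table, target, w, "frontal", weighting)
    cf_l <- lookup_cf(table, target, w, "lateral", weighting)
    (cf_f * (s$dap_frontal / w) + cf_l * (s$dap_lateral / w)) / 100
  }
}

#' Estimate effective dose for procedures from their DAP
#'
#' `ED = CF_ED x DAP_BW` (DAP_BW in Gy.cm2/kg). See
#' [estimate_organ_doses()] for the `total` vs `per_plane` modes.
#'
#' @inheritParams estimate_organ_doses
#' @param weighting `"ICRP103"` (shipped default table) or another
#'   weighting present in `table`.
#' @return A tibble: `procedure_id`, `ed_msv`, `weighting`, `mode`.
#' @export
estimate_effective_dose <- function(summaries, table = default_cf_table(),
                                    mode = c("total", "per_plane"),
                                    weighting = "ICRP103") {
  mode <- match.arg(mode)
  ed <- vapply(seq_len(nrow(summaries)), function(i) {
    .cf_dose(summaries[i, , drop = FALSE], table, "ED", mode, weighting)
  }, numeric(1))
  tibble::tibble(procedure_id = summaries$procedure_id, ed_msv = ed,
                 weighting = weighting, mode = mode)
}

#' ICRP tissue weighting factors
#'
#' The tissue weights of ICRP publication 103 (default) or 60. Weights sum
#' to one exactly.
#'
#' @param weighting `"ICRP103"` or `"ICRP60"`.
#' @return Named numeric vector of tissue weights.
#' @export
tissue_weights <- function(weighting = c("ICRP103", "ICRP60")) {
  weighting <- match.arg(weighting)
  w <- if (weighting == "ICRP103") {
    c(active_bone_marrow = 0.12, colon = 0.12, lungs = 0.12, stomach = 0.12,
      breasts = 0.12, remainder = 0.12, gonads = 0.08,
      urinary_bladder = 0.04, oesophagus = 0.04, liver = 0.04,
      thyroid = 0.04, bone_surface = 0.01, brain = 0.01,
      salivary_glands = 0.01, skin = 0.01)
  } else {
    c(gonads = 0.20, active_bone_marrow = 0.12, colon = 0.12, lungs = 0.12,
      stomach = 0.12, urinary_bladder = 0.05, breasts = 0.05, liver = 0.05,
      oesophagus = 0.05, thyroid = 0.05, skin = 0.01, bone_surface = 0.01,
      remainder = 0.05)
  }
  stopifnot(abs(sum(w) - 1) < 1e-9)
  w
}

#' Effective dose as the tissue-weighted sum of organ doses
#'
#' `ED = sum(w_T x H_T)` over the tissue set of the chosen ICRP weighting.
#' Tissues without a supplied dose contribute zero, with a warning naming
#' them. The `gonads` weight is applied to the `ovaries` dose when present
#' (the mathematical-phantom organ set used here carries no testes dose);
#' `remainder` is taken from `remainder_male` / `remainder_female`
#' averaged over whichever are present.
#'
#' @param organ_doses Named numeric vector of organ doses in mGy (names as
#'   in the conversion-factor table, e.g. `lungs`, `active_bone_marrow`).
#' @param weighting `"ICRP103"` or `"ICRP60"`.
#' @param quiet Suppress the missing-tissue warning.
#' @return Effective dose in mSv as a bare number.
#' @export
effective_dose_from_organ_doses <- function(organ_doses,
                                            weighting = "ICRP103",
                                            quiet = FALSE) {
  w <- tissue_weights(weighting)
  if (any(organ_doses < 0, na.rm = TRUE)) abort("Organ doses must be >= 0")
  get <- function(nm) {
    if (nm %in% names(organ_doses)) organ_doses[[nm]] else NA_real_
  }
  dose_for <- function(tissue) {
    if (tissue == "gonads") return(get("ovaries"))
    if (tissue == "remainder") {
      rem <- c(get("remainder_male"), get("remainder_female"))
      rem <- rem[!is.na(rem)]
      return(if (length(rem)) mean(rem) else NA_real_)
    }
    get(tissue)
  }
  doses <- vapply(names(w), dose_for, numeric(1))
  missing <- names(w)[is.na(doses)]
  if (length(missing) && !quiet) {
    warn(paste0("No dose supplied for tissue(s), treated as 0: ",
                paste(missing, collapse = ", ")))
  }
  doses[is.na(doses)] <- 0
  sum(w * doses)
}

#' Derive a conversion-factor table from a dose-labelled cohort
#'
#' Fits, for every (target, plane, weight group) cell with at least
#' `min_n` procedures, an ordinary least-squares regression of reference
#' dose on weight-normalized DAP (Gy.cm2/kg) and stores the slope with its
#' 95% CI — the construction of the shipped table, applicable to any
#' cohort that carries per-procedure reference doses (e.g. Monte Carlo
#' results, or the synthetic generator's ground truth). Frontal and lateral
#' fits use the per-plane DAP share as the regressor; lateral fits include
#' only procedures with nonzero lateral DAP, so their n is smaller on a
#' partly monoplane cohort.
#'
#' @param summaries Per-procedure summaries (normalized or not).
#' @param ref_doses Long tibble `procedure_id`, `target`, `plane`
#'   (`biplane`/`frontal`/`lateral`), `dose` (mGy, or mSv for `ED`).
#' @param min_n Minimum procedures per cell, default 3; smaller cells are
#'   omitted.
#' @param through_origin,robust Passed to [fit_linear()]. Robust (HC4)
#'   slope CIs are the default: dose spread grows with DAP, and the
#'   classical homoscedastic interval is anti-conservative on such data.
#' @return A conversion-factor tibble in the [default_cf_table()] schema
#'   (plus `r_squared`), including per-weight-group rows and the pooled
#'   `All` row.
#' @export
derive_cf_table <- function(summaries, ref_doses, min_n = 3,
                            through_origin = FALSE, robust = TRUE) {
  if (!"weight_group" %in% names(summaries)) {
    summaries <- normalize_doses(summaries)
  }
  joined <- dplyr::inner_join(ref_doses, summaries, by = "procedure_id")
  joined$x <- dplyr::case_when(
    joined$plane == "biplane" ~ joined$total_dap,
    joined$plane == "frontal" ~ joined$dap_frontal,
    joined$plane == "lateral" ~ joined$dap_lateral
  ) / joined$weight_kg / 100
  joined <- joined[!(joined$plane == "lateral" & joined$x <= 0), , drop = FALSE]

  cells <- unique(joined[, c("target", "plane")])
  out <- dplyr::bind_rows(lapply(seq_len(nrow(cells)), function(i) {
    sub <- joined[joined$target == cells$target[i] &
                    joined$plane == cells$plane[i], , drop = FALSE]
    grps <- c(split(sub, as.character(sub$weight_group)), list(All = sub))
    dplyr::bind_rows(lapply(names(grps), function(g) {
      d <- grps[[g]]
      if (nrow(d) < min_n) return(NULL)
      f <- tryCatch(fit_linear(d$x, d$dose, through_origin = through_origin,
                               robust = robust),
                    error = function(e) NULL)
      if (is.null(f)) return(NULL)
      tibble::tibble(
        target = cells$target[i],
        weighting = if (cells$target[i] == "ED") "ICRP103" else NA_character_,
        plane = cells$plane[i], weight_group = g,
        slope = f$slope, ci_low = f$slope_ci_low, ci_high = f$slope_ci_high,
        n = f$n, r_squared = f$r_squared
      )
    }))
  }))
  out
}
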