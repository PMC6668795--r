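#' Weight-normalized DRL quantities
#'
#' Adds the two candidate size-independent DRL parameters to a
#' per-procedure summary table: `dap_bw = total_dap / weight`
#' (cGy.cm2/kg) and `dap_bwxft = total_dap / (weight x fluoroscopy time)`
#' (cGy.cm2/kg/min). Fluoroscopy time is stored in seconds and converted to
#' minutes here, at the reporting boundary. Procedures without any
#' fluoroscopy (`fluoro_time_s = 0`) get `NA` for `dap_bwxft`: the quantity
#' is undefined for them, and they are excluded from its distributions but
#' kept in all others.
#'
#' @param summaries Tibble from [aggregate_procedures()].
#' @return The input with `dap_bw`, `dap_bwxft` and `weight_group` columns
#'   appended.
#' @export
normalize_doses <- function(summaries) {
  if (any(!is.na(summaries$weight_kg) & summaries$weight_kg <= 0)) {
    abort("weight_kg must be positive")
  }
  summaries$dap_bw <- summaries$total_dap / summaries$weight_kg
  ft_min <- summaries$fluoro_time_s / 60
  summaries$dap_bwxft <- ifelse(
    is.na(ft_min) | ft_min <= 0, NA_real_,
    summaries$total_dap / (summaries$weight_kg * ft_min)
  )
  summaries$weight_group <- weight_group(summaries$weight_kg)
  summaries
}

#' RP 185 weight group of a patient
#'
#' Half-open weight bins `[lo, hi)`: `<5`, `5-<15`, `15-<30`, `30-<50`,
#' `50-<80` kg, plus `>=80` for heavier (including adult) patients. A
#' weight exactly on a boundary belongs to the upper bin (15.0 kg is
#' `15-<30`).
#'
#' @param weight_kg Numeric vector of body weights, all positive.
#' @return Factor with the six group labels.
#' @export
weight_group <- function(weight_kg) {
  if (any(!is.na(weight_kg) & weight_kg <= 0)) abort("weight_kg must be positive")
  cut(weight_kg, breaks = c(0, 5, 15, 30, 50, 80, Inf),
      labels = c("<5", "5-<15", "15-<30", "30-<50", "50-<80", ">=80"),
      right = FALSE)
}

#' Percentile with linear interpolation between order statistics
#'
#' The percentile convention used for every DRL in this package: linear
#' interpolation at rank `h = (n - 1) p + 1` (the default of most
#' statistics packages, type 7 in R). The choice matters at the small
#' per-procedure-type sample sizes typical of a single centre, so the
#' method is a visible parameter and is echoed in the DRL tables.
#'
#' @param x Non-empty numeric vector; `NA`s are dropped.
#' @param p Probability in `[0, 1]`.
#' @param type Quantile type passed to [stats::quantile()], default 7.
#' @return The percentile as a bare number.
#' @export
drl_percentile <- function(x, p, type = 7) {
  x <- x[!is.na(x)]
  if (!length(x)) abort("Cannot take a percentile of an empty set")
  unname(quantile(x, probs = p, type = type, names = FALSE))
}

# quantities summarized in every DRL table
.drl_quantities <- c("total_dap", "total_kerma_mgy", "fluoro_time_s",
                     "cine_frames", "dap_bw", "dap_bwxft")

#' Build a DRL table
#'
#' Computes n, median, P25 and P75 for each DRL quantity (DAP, air kerma,
#' fluoroscopy time, cine frames, DAP/BW, DAP/(BWxFT)), grouped by
#' procedure type, by RP 185 weight group, or pooled over the whole cohort.
#' The 75th percentile column is the local DRL. Groups with fewer than 20
#' procedures carry a `small_sample` flag, following the RP 185
#' recommendation of at least 20 cases per procedure type.
#'
#' @param summaries Normalized summaries from [normalize_doses()].
#' @param grouping `"pooled"`, `"procedure_type"` or `"weight_group"`.
#' @param type Percentile method, see [drl_percentile()].
#' @return Tibble with columns `group`, `quantity`, `n`, `p25`, `median`,
#'   `p75`, `small_sample`; attribute `percentile_type` records the method.
#' @export
build_drl_table <- function(summaries,
                            grouping = c("pooled", "procedure_type",
                                         "weight_group"),
                            type = 7) {
  grouping <- match.arg(grouping)
  if (!nrow(summaries)) abort("Empty cohort")
  if (!"dap_bw" %in% names(summaries)) summaries <- normalize_doses(summaries)
  key <- switch(grouping,
    pooled = rep("All", nrow(summaries)),
    procedure_type = as.character(summaries$procedure_type),
    weight_group = as.character(summaries$weight_group)
  )
  out <- dplyr::bind_rows(lapply(split(seq_len(nrow(summaries)), key), function(ix) {
    grp <- summaries[ix, , drop = FALSE]
    dplyr::bind_rows(lapply(.drl_quantities, function(q) {
      v <- grp[[q]][!is.na(grp[[q]])]
      tibble::tibble(
        group = key[ix[1]], quantity = q, n = length(v),
        p25 = if (length(v)) drl_percentile(v, 0.25, type) else NA_real_,
        median = if (length(v)) drl_percentile(v, 0.5, type) else NA_real_,
        p75 = if (length(v)) drl_percentile(v, 0.75, type) else NA_real_,
        small_sample = length(v) < 20
      )
    }))
  }))
  attr(out, "percentile_type") <- type
  out
}

#' Cohort-level descriptive statistics
#'
#' Per stratum (diagnostic vs interventional procedures, plus the pooled
#' cohort): the median per-procedure fraction of total DAP delivered by
#' fluoroscopy, the fraction of procedures done in the biplane
#' configuration, and the range of each DRL quantity.
#'
#' @param summaries Normalized summaries from [normalize_doses()].
#' @return A tibble with one row per stratum: `stratum`, `n`,
#'   `median_fluoro_dap_fraction`, `biplane_fraction`, and `min_` / `max_`
#'   columns for each quantity.
#' @export
summarize_cohort <- function(summaries) {
  if (!"dap_bw" %in% names(summaries)) summaries <- normalize_doses(summaries)
  strata <- list(
    all = rep(TRUE, nrow(summaries)),
    diagnostic = !is.na(summaries$procedure_type) &
      summaries$procedure_type == "Diagnostic",
    interventional = !is.na(summaries$procedure_type) &
      summaries$procedure_type != "Diagnostic"
  )
  dplyr::bind_rows(lapply(names(strata), function(s) {
    grp <- summaries[strata[[s]], , drop = FALSE]
    if (!nrow(grp)) return(NULL)
    frac <- ifelse(grp$total_dap > 0, grp$dap_fluoro / grp$total_dap, NA_real_)
    row <- tibble::tibble(
      stratum = s, n = nrow(grp),
      median_fluoro_dap_fraction = median(frac, na.rm = TRUE),
      biplane_fraction = mean(grp$is_biplane)
    )
    for (q in .drl_quantities) {
      v <- grp[[q]][!is.na(grp[[q]])]
      row[[paste0("min_", q)]] <- if (length(v)) min(v) else NA_real_
      row[[paste0("max_", q)]] <- if (length(v)) max(v) else NA_real_
    }
    row
  }))
}

#' Compare one procedure against a DRL table
#'
#' A DRL is a threshold, not a limit: the alert triggers on strict
#' exceedance of the group's P75 for the configured primary parameter
#' (equality does not trigger). Secondary parameters (fluoroscopy time,
#' cine frames, air kerma) are flagged against the same table to assist
#' root-cause analysis of a high exposure. When the primary parameter is
#' `dap_bwxft` but the procedure had no fluoroscopy, the comparison falls
#' back to `dap_bw`.
#'
#' @param summary One-row normalized procedure summary.
#' @param drl_table Table from [build_drl_table()].
#' @param parameter Primary DRL parameter, `"dap_bwxft"` (default) or
#'   `"dap_bw"`.
#' @param group Group label to compare against; defaults to the procedure's
#'   type when present in the table, else the pooled `"All"` row.
#' @return A one-row tibble: `procedure_id`, `parameter`, `group`, `value`,
#'   `threshold`, `exceeded`, and logical flag columns
#'   `ft_above_p75`, `frames_above_p75`, `kerma_above_p75`.
#' @export
check_alert <- function(summary, drl_table,
                        parameter = c("dap_bwxft", "dap_bw"),
                        group = NULL) {
  parameter <- match.arg(parameter)
  stopifnot(nrow(summary) == 1)
  if (is.null(group)) {
    pt <- as.character(summary$procedure_type)
    group <- if (!is.na(pt) && pt %in% drl_table$group) pt else "All"
  }
  if (!group %in% drl_table$group) {
    abort(paste0("Group '", group, "' not in DRL table and no pooled row"))
  }
  row_for <- function(q) {
    r <- drl_table[drl_table$group == group & drl_table$quantity == q, ]
    if (!nrow(r)) NA_real_ else r$p75[[1]]
  }
  value <- summary[[parameter]]
  used <- parameter
  if (is.na(value) && parameter == "dap_bwxft") {
    used <- "dap_bw"
    value <- summary$dap_bw
  }
  threshold <- row_for(used)
  tibble::tibble(
    procedure_id = summary$procedure_id,
    parameter = used,
    group = group,
    value = value,
    threshold = threshold,
    exceeded = isTRUE(value > threshold),
    ft_above_p75 = isTRUE(summary$fluoro_time_s > row_for("fluoro_time_s")),
    frames_above_p75 = isTRUE(summary$cine_frames > row_for("cine_frames")),
    kerma_above_p75 = isTRUE(summary$total_kerma_mgy > row_for("total_kerma_mgy"))
  )
}
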