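#' Convert dose-area product between reporting units
#'
#' Fluoroscopy systems and dose-management exports report the kerma-area
#' product (DAP) in a variety of units. The package stores DAP internally in
#' cGy.cm2 (the unit used by most paediatric DRL literature); this helper
#' converts between the supported dialects.
#'
#' @param x Numeric vector of DAP values.
#' @param from,to Unit names, one of `"cgycm2"`, `"gycm2"`, `"gym2"`,
#'   `"ugym2"` (micro-Gray times square metre), `"mgycm2"`.
#' @return Numeric vector in the `to` unit.
#' @examples
#' convert_dap(0.0001952, from = "gym2", to = "cgycm2") # 195.2
#' convert_dap(1, from = "ugym2", to = "cgycm2")        # 1
#' @export
convert_dap <- function(x, from = "cgycm2", to = "cgycm2") {
  f <- .dap_unit_factor(from)
  t <- .dap_unit_factor(to)
  x * f / t
}

# factor to Gy.cm2
.dap_unit_factors <- c(
  gycm2  = 1,
  cgycm2 = 1e-2,
  mgycm2 = 1e-3,
  gym2   = 1e4,   # 1 m2 = 1e4 cm2
  ugym2  = 1e-2   # 1e-6 Gy * 1e4 cm2
)

.dap_unit_factor <- function(unit) {
  unit <- tolower(unit)
  if (!unit %in% names(.dap_unit_factors)) {
    abort(paste0(
      "Unknown DAP unit '", unit, "'. Supported: ",
      paste(names(.dap_unit_factors), collapse = ", ")
    ))
  }
  .dap_unit_factors[[unit]]
}

#' Convert air kerma between reporting units
#'
#' @param x Numeric vector of air-kerma values.
#' @param from,to One of `"mgy"`, `"gy"`, `"cgy"`.
#' @return Numeric vector in the `to` unit.
#' @export
convert_kerma <- function(x, from = "mgy", to = "mgy") {
  fac <- c(gy = 1, cgy = 1e-2, mgy = 1e-3)
  from <- tolower(from); to <- tolower(to)
  for (u in c(from, to)) {
    if (!u %in% names(fac)) abort(paste0("Unknown kerma unit '", u, "'"))
  }
  x * fac[[from]] / fac[[to]]
}
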