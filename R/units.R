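#' Unit conversion for in vitro rates and concentrations
#'
#' All internal computation uses canonical units: hours, litres, milligrams,
#' concentrations in ug/ml (= mg/L) and flows/clearances in L/h. Molar
#' quantities are converted at the boundary using the molecular weight.
#'
#' Recognised conversions:
#' * `"ul/min" -> "L/h"` (factor 60/1e6) and back
#' * `"uM" -> "ug/ml"` (factor mw/1000) and back
#' * `"pmol/min" -> "mg/h"` (factor 60e-9 * mw) and back
#'
#' @param value numeric value(s) to convert.
#' @param from,to unit tags (see above).
#' @param mw molecular weight in g/mol; required for molar conversions.
#' @return converted numeric value.
#' @examples
#' convert_rate_units(1935.2, "ul/min", "L/h")        # 0.116112
#' convert_rate_units(6.97, "uM", "ug/ml", mw = 345.42)
#' @export
convert_rate_units <- function(value, from, to, mw = NULL) {
  stopifnot(is.numeric(value), length(from) == 1L, length(to) == 1L)
  key <- paste(from, to, sep = "->")
  needs_mw <- grepl("uM|pmol", key)
  if (needs_mw && (is.null(mw) || !is.finite(mw) || mw <= 0)) {
    stop("molar unit conversion '", key, "' requires a positive molecular weight")
  }
  factor <- switch(key,
    "ul/min->L/h"   = 60 / 1e6,
    "L/h->ul/min"   = 1e6 / 60,
    "uM->ug/ml"     = mw / 1000,
    "ug/ml->uM"     = 1000 / mw,
    "pmol/min->mg/h" = 60 * 1e-9 * mw,
    "mg/h->pmol/min" = 1 / (60 * 1e-9 * mw),
    stop("unknown unit conversion: '", from, "' -> '", to, "'")
  )
  value * factor
}
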