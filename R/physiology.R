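#' Rat physiology configuration
#'
#' Loads the system parameters of the minimal PBPK model: body and liver
#' size, hepatic and villous blood flows, IVIVE scaling factors (MPPGL, HPGL,
#' total gut microsomal protein), intestinal geometry and transit, plasma
#' volume, blood pH values, and the permeability regression coefficients.
#' The tissue composition table used for partition-coefficient prediction is
#' attached as `tissue_composition`.
#'
#' @param path YAML file of physiology values; defaults to the packaged
#'   configuration.
#' @param tissue_path CSV of tissue composition; defaults to the packaged
#'   rat table.
#' @return an object of class `rat_physiology` (a named list).
#' @export
rat_physiology <- function(path = NULL, tissue_path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "physiology.yaml", package = "rpbpk")
  }
  if (is.null(tissue_path)) {
    tissue_path <- system.file("extdata", "tissue_composition_rat.csv",
                               package = "rpbpk")
  }
  phys <- yaml::read_yaml(path)
  phys$tissue_composition <- load_tissue_composition(tissue_path)
  class(phys) <- "rat_physiology"
  validate_physiology(phys)
}

#' @rdname rat_physiology
#' @param phys a `rat_physiology` object to validate.
#' @export
validate_physiology <- function(phys) {
  stopifnot(inherits(phys, "rat_physiology"))
  scalar_fields <- c("body_weight", "liver_weight", "hepatic_blood_flow",
                     "villous_blood_flow", "mppgl", "hpgl",
                     "gut_microsomal_protein_total", "intestine_radius",
                     "small_intestine_transit_time", "enterocyte_volume",
                     "plasma_volume", "hematocrit", "plasma_ph",
                     "intracellular_ph", "blood_cell_ph", "dispersion_number")
  for (f in scalar_fields) {
    v <- phys[[f]]
    if (is.null(v) || !is.finite(v) || v <= 0) {
      stop("physiology field '", f, "' must be a positive number", call. = FALSE)
    }
  }
  if (phys$villous_blood_flow >= phys$hepatic_blood_flow) {
    stop("villous_blood_flow must be smaller than hepatic_blood_flow",
         call. = FALSE)
  }
  tc <- phys$tissue_composition
  if (!is.data.frame(tc) || !all(c("tissue", "frac_volume") %in% names(tc))) {
    stop("tissue_composition table missing or malformed", call. = FALSE)
  }
  if (sum(tc$frac_volume) > 1) {
    stop("tissue fractional volumes exceed body volume", call. = FALSE)
  }
  invisible(phys)
}

#' Load a tissue composition table
#'
#' @param path CSV with columns `tissue`, `frac_volume`, `f_ew`, `f_iw`,
#'   `f_nl`, `f_np`, `ap_mg_g`, `albumin_ratio`, `ph_iw`. Lines starting with
#'   `#` are treated as the provenance header and skipped.
#' @return a data.frame, one row per tissue plus `plasma` and `erythrocyte`.
#' @export
load_tissue_composition <- function(path) {
  tc <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  frac_cols <- c("frac_volume", "f_ew", "f_iw", "f_nl", "f_np")
  for (cl in frac_cols) {
    if (any(!is.finite(tc[[cl]]) | tc[[cl]] < 0 | tc[[cl]] > 1)) {
      stop("tissue composition column '", cl, "' must lie in [0, 1]")
    }
  }
  if (any(tc$ap_mg_g < 0) || any(tc$albumin_ratio < 0)) {
    stop("acidic phospholipid and albumin ratio must be non-negative")
  }
  tc
}

#' @export
print.rat_physiology <- function(x, ...) {
  cat("<rat_physiology>\n")
  cat(sprintf("  body %.3g kg | liver %.3g g | Qh %.3g L/h | Qvilli %.3g L/h\n",
              x$body_weight, x$liver_weight, x$hepatic_blood_flow,
              x$villous_blood_flow))
  cat(sprintf("  MPPGL %.3g mg/g | HPGL %.3g x10^6/g | gut protein %.3g mg\n",
              x$mppgl, x$hpgl, x$gut_microsomal_protein_total))
  cat(sprintf("  %d tissue rows\n", nrow(x$tissue_composition)))
  invisible(x)
}

#' Single oral dose regimen
#'
#' @param dose_per_kg dose in mg/kg.
#' @param body_weight body weight in kg.
#' @return an object of class `dose_regimen` with the derived absolute
#'   `dose_amount` (mg).
#' @export
dose_regimen <- function(dose_per_kg, body_weight = 0.25) {
  stopifnot(is.finite(dose_per_kg), dose_per_kg > 0,
            is.finite(body_weight), body_weight > 0)
  structure(list(route = "oral", dose_per_kg = dose_per_kg,
                 body_weight = body_weight,
                 dose_amount = dose_per_kg * body_weight),
            class = "dose_regimen")
}
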