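#' Scale hepatic intrinsic clearance to the whole liver
#'
#' IVIVE scaling: microsomal rates (ul/min/mg protein) scale by
#' MPPGL x liver weight, hepatocyte rates (ul/min/1e6 cells) by
#' HPGL x liver weight. The result is divided by the incubation unbound
#' fraction and canonicalised to L/h. A Michaelis-Menten liver specification
#' is collapsed to its low-concentration limit `Vmax / (Km * fu_inc)` before
#' scaling (hepatic concentrations of the supported compound classes stay
#' well below Km).
#'
#' @param spec a [clearance_spec()] with `organ = "liver"`.
#' @param phys a [rat_physiology()].
#' @return whole-liver unbound intrinsic clearance, L/h.
#' @export
scale_liver_clint <- function(spec, phys = rat_physiology()) {
  stopifnot(inherits(spec, "clearance_spec"), spec$organ == "liver")
  per_unit <- if (spec$kind == "linear") spec$clint / spec$fu_inc
              else spec$vmax / (spec$km * spec$fu_inc)
  unit <- if (spec$kind == "linear") spec$unit else "ul/min/mg"
  scale <- switch(unit,
    "ul/min/mg" = phys$mppgl * phys$liver_weight,
    "ul/min/1e6 cells" = phys$hpgl * phys$liver_weight,
    stop("unknown liver CLint unit tag: '", unit, "'"))
  convert_rate_units(per_unit * scale, "ul/min", "L/h")
}

#' Scale intestinal clearance to the whole gut
#'
#' Linear intrinsic clearances (ul/min/mg microsomal protein) scale by the
#' total gut microsomal protein; Michaelis-Menten pairs scale Vmax the same
#' way and convert it to mg/h via the molecular weight, while Km converts
#' from uM to ug/ml and is multiplied by `fu_inc` (the unbound affinity
#' correction). Per-gram-intestine units require an `intestine_mass` entry in
#' the physiology and are rejected otherwise.
#'
#' @param spec a [clearance_spec()] with `organ = "intestine"`, or `NULL` for
#'   a compound without gut metabolism.
#' @param mw molecular weight (g/mol), needed for Michaelis-Menten scaling.
#' @param phys a [rat_physiology()].
#' @return `NULL` if `spec` is `NULL`; otherwise a list with `kind` and
#'   either `clint_whole` (L/h) or `vmax_whole` (mg/h) + `km_ugml` (ug/ml).
#' @export
scale_gut_clint <- function(spec, mw, phys = rat_physiology()) {
  if (is.null(spec)) return(NULL)
  stopifnot(inherits(spec, "clearance_spec"), spec$organ == "intestine")
  g_protein <- phys$gut_microsomal_protein_total
  if (spec$kind == "linear") {
    scale <- switch(spec$unit,
      "ul/min/mg" = g_protein,
      "ul/min/g intestine" = {
        if (is.null(phys$intestine_mass)) {
          stop("per-gram-intestine CLint requires 'intestine_mass' in the physiology")
        }
        phys$intestine_mass
      },
      stop("unknown gut CLint unit tag: '", spec$unit, "'"))
    list(kind = "linear",
         clint_whole = convert_rate_units(spec$clint / spec$fu_inc * scale,
                                          "ul/min", "L/h"))
  } else {
    list(kind = "michaelis_menten",
         vmax_whole = convert_rate_units(spec$vmax * g_protein,
                                         "pmol/min", "mg/h", mw = mw),
         km_ugml = convert_rate_units(spec$km, "uM", "ug/ml", mw = mw) *
           spec$fu_inc)
  }
}

#' Hepatic extraction by the well-stirred, parallel-tube or dispersion model
#'
#' With `x = (fu / B:P) * CLint_u` (unbound blood intrinsic clearance):
#' * well-stirred:  `CLb = Qh x / (Qh + x)`
#' * parallel tube: `CLb = Qh (1 - exp(-x / Qh))`
#' * dispersion:    two-parameter closed form with dispersion number `DN`
#'   (default 0.17): availability
#'   `F = 4a / ((1+a)^2 exp((a-1)/(2 DN)) - (1-a)^2 exp(-(a+1)/(2 DN)))`
#'   with `a = sqrt(1 + 4 RN DN)`, `RN = x / Qh`, and `CLb = Qh (1 - F)`.
#'
#' For any `x > 0` the models order as well-stirred <= dispersion <=
#' parallel-tube; all agree to first order as `x/Qh -> 0`.
#'
#' @param clint_whole whole-organ unbound intrinsic clearance, L/h.
#' @param fu fraction unbound in plasma.
#' @param bp blood:plasma ratio.
#' @param q_h hepatic blood flow, L/h.
#' @param model liver model name.
#' @param dispersion_number axial dispersion number for the dispersion model.
#' @return an object of class `organ_clearance`: list with `cl_blood`,
#'   `cl_plasma` (L/h), `extraction_ratio`, `bioavailability_fraction` (Fh)
#'   and the inputs.
#' @export
hepatic_model <- function(clint_whole, fu, bp, q_h,
                          model = c("well_stirred", "parallel_tube", "dispersion"),
                          dispersion_number = 0.17) {
  model <- match.arg(model)
  stopifnot(q_h > 0, fu > 0, fu <= 1, clint_whole >= 0, bp > 0)
  x <- (fu / bp) * clint_whole
  cl_b <- switch(model,
    well_stirred = q_h * x / (q_h + x),
    parallel_tube = q_h * (1 - exp(-x / q_h)),
    dispersion = {
      rn <- x / q_h
      dn <- dispersion_number
      a <- sqrt(1 + 4 * rn * dn)
      f_avail <- 4 * a / ((1 + a)^2 * exp((a - 1) / (2 * dn)) -
                          (1 - a)^2 * exp(-(a + 1) / (2 * dn)))
      q_h * (1 - f_avail)
    })
  e <- cl_b / q_h
  structure(list(organ = "liver", model = model, clint_whole = clint_whole,
                 cl_blood = cl_b, cl_plasma = cl_b * bp,
                 extraction_ratio = e, bioavailability_fraction = 1 - e,
                 q_organ = q_h), class = "organ_clearance")
}

#' @export
print.organ_clearance <- function(x, ...) {
  cat(sprintf("<organ_clearance> %s (%s)\n", x$organ, x$model))
  cat(sprintf("  CLint,u %.4g L/h | CLb %.4g L/h | CLp %.4g L/h | E %.3f | F %.3f\n",
              x$clint_whole, x$cl_blood, x$cl_plasma, x$extraction_ratio,
              x$bioavailability_fraction))
  invisible(x)
}
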