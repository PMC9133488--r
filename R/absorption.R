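#' Human effective jejunal permeability from PSA and HBD
#'
#' Evaluates the log-linear regression
#' `log10 Peff(human, cm/s) = c0 + c1 * PSA + c2 * HBD`, the descriptor-based
#' permeability model lineage used for bottom-up absorption prediction.
#' With the packaged default coefficients (c0 = -2.546, c1 = -0.011 per A^2,
#' c2 = -0.278 per donor) permeability is strictly decreasing in both
#' descriptors.
#'
#' @param psa polar surface area, A^2 (>= 0).
#' @param hbd hydrogen bond donor count (>= 0).
#' @param phys a [rat_physiology()] carrying the coefficient block.
#' @return human Peff in 1e-4 cm/s.
#' @export
peff_human_from_psa_hbd <- function(psa, hbd, phys = rat_physiology()) {
  stopifnot(all(psa >= 0), all(hbd >= 0))
  cf <- phys$permeability$psa_hbd
  peff_cm_s <- 10^(cf$c0 + cf$c1 * psa + cf$c2 * hbd)
  peff_cm_s * 1e4  # report in 1e-4 cm/s
}

#' Human effective permeability from in vitro apparent permeability
#'
#' Log-linear Caco-2 (or MDCK/PAMPA) correlation:
#' `log10 Peff(1e-4 cm/s) = slope * log10 Papp(1e-6 cm/s) + intercept`,
#' strictly increasing in Papp.
#'
#' @param papp apparent permeability, 1e-6 cm/s (> 0).
#' @param assay assay tag, recorded in the result for provenance.
#' @param phys a [rat_physiology()].
#' @return human Peff in 1e-4 cm/s, with attribute `assay`.
#' @export
peff_human_from_papp <- function(papp, assay = "Caco-2",
                                 phys = rat_physiology()) {
  if (any(!is.finite(papp) | papp <= 0)) {
    stop("papp must be > 0 (1e-6 cm/s)")
  }
  cf <- phys$permeability$papp
  out <- 10^(cf$slope * log10(papp) + cf$intercept)
  attr(out, "assay") <- assay
  out
}

#' Rat effective permeability from the human value
#'
#' Inverts the linear inter-species relation
#' `Peff,human = a * Peff,rat + b` (default a = 3.6, b = 0.03, both axes in
#' 1e-4 cm/s).
#'
#' @param peff_human human Peff, 1e-4 cm/s; must be at least the intercept
#'   `b`, otherwise the implied rat permeability would be negative.
#' @param phys a [rat_physiology()].
#' @return rat Peff in 1e-4 cm/s.
#' @export
peff_rat_from_human <- function(peff_human, phys = rat_physiology()) {
  cf <- phys$permeability$interspecies
  if (any(peff_human < cf$b)) {
    stop("peff_human below the inter-species intercept (", cf$b,
         " x 1e-4 cm/s): would give negative rat permeability")
  }
  (peff_human - cf$b) / cf$a
}

#' Absorption rate constant and fraction absorbed from rat permeability
#'
#' The gut lumen is a single well-mixed cylinder of radius `r`: the
#' first-order absorption rate constant is `ka = 2 Peff / r` and absorption
#' competes with lumenal transit loss at `kt = 1 / transit time`, giving a
#' fraction absorbed `fa = ka / (ka + kt)`.
#'
#' @param peff_rat rat effective permeability, 1e-4 cm/s (>= 0).
#' @param phys a [rat_physiology()] providing `intestine_radius` (cm) and
#'   `small_intestine_transit_time` (h).
#' @return list with `ka` (1/h), `fa` (0..1) and `kt` (1/h).
#' @export
ka_fa_from_peff <- function(peff_rat, phys = rat_physiology()) {
  stopifnot(all(peff_rat >= 0))
  ka <- 2 * (peff_rat * 1e-4) / phys$intestine_radius * 3600  # 1/s -> 1/h
  kt <- 1 / phys$small_intestine_transit_time
  list(ka = ka, fa = ka / (ka + kt), kt = kt)
}

#' Full absorption chain for a compound
#'
#' Composes the permeability route (PSA/HBD descriptors or measured Papp),
#' the human-to-rat inter-species scaling and the lumen absorption model into
#' a single estimate.
#'
#' @param compound a [compound_record()].
#' @param phys a [rat_physiology()].
#' @param route `"psa_hbd"` (default) or `"papp"`; the latter requires a
#'   `papp` value on the record.
#' @return an object of class `permeability_estimate` with fields
#'   `peff_human`, `peff_rat` (1e-4 cm/s), `ka` (1/h), `fa`, `kt` (1/h) and
#'   `source`.
#' @export
predict_absorption <- function(compound, phys = rat_physiology(),
                               route = c("psa_hbd", "papp")) {
  route <- match.arg(route)
  peff_h <- if (route == "psa_hbd") {
    peff_human_from_psa_hbd(compound$psa, compound$hbd, phys)
  } else {
    if (!is.finite(compound$papp)) {
      stop("compound '", compound$name, "' has no papp value for the papp route")
    }
    as.numeric(peff_human_from_papp(compound$papp, compound$papp_assay, phys))
  }
  peff_r <- peff_rat_from_human(peff_h, phys)
  kafa <- ka_fa_from_peff(peff_r, phys)
  if (kafa$ka <= 0) {
    stop("compound '", compound$name, "' is predicted non-absorbable (ka = 0)")
  }
  structure(list(peff_human = peff_h, peff_rat = peff_r,
                 ka = kafa$ka, fa = kafa$fa, kt = kafa$kt, source = route),
            class = "permeability_estimate")
}
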