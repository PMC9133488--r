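#' Ionisation of a compound at a given pH
#'
#' Henderson-Hasselbalch speciation. For partition prediction the useful
#' quantity is `Z = (total)/(neutral) = 1 + sum of ionised-species ratios`;
#' `ionized_fractions()` reports the neutral and ionised fractions, while the
#' internal `.ion_Z()` returns `Z` itself.
#'
#' @param compound_type one of the supported compound classes (see
#'   [compound_record()]).
#' @param pka1,pka2 ionisation constants as stored on the record (for an
#'   ampholyte `pka1` is the acidic and `pka2` the basic pKa).
#' @param ph pH in `[1, 14]`.
#' @return list with `neutral` and `ionized` fractions (summing to 1).
#' @examples
#' ionized_fractions("monoprotic acid", pka1 = 5.16, ph = 7.4)  # 99.4% ionised
#' @export
ionized_fractions <- function(compound_type, pka1 = NA_real_, pka2 = NA_real_,
                              ph) {
  stopifnot(ph >= 1, ph <= 14)
  z <- .ion_Z(compound_type, pka1, pka2, ph)
  list(neutral = 1 / z, ionized = 1 - 1 / z)
}

.ion_Z <- function(compound_type, pka1, pka2, ph) {
  need_pka <- function(p, lab) {
    if (!is.finite(p)) stop("missing ", lab, " for compound_type '",
                            compound_type, "'", call. = FALSE)
    p
  }
  switch(compound_type,
    "neutral" = 1,
    "monoprotic acid" = 1 + 10^(ph - need_pka(pka1, "pka1")),
    "monoprotic base" = 1 + 10^(need_pka(pka1, "pka1") - ph),
    "diprotic acid" = 1 + 10^(ph - need_pka(pka1, "pka1")) +
      10^(2 * ph - pka1 - need_pka(pka2, "pka2")),
    "diprotic base" = 1 + 10^(need_pka(pka1, "pka1") - ph) +
      10^(pka1 + need_pka(pka2, "pka2") - 2 * ph),
    "ampholyte" = 1 + 10^(ph - need_pka(pka1, "acidic pka1")) +
      10^(need_pka(pka2, "basic pka2") - ph),
    stop("unknown compound_type '", compound_type, "'")
  )
}

# TRUE when the compound carries a basic centre strong enough (pKa >= 7) to
# partition onto acidic phospholipids (the moderate-to-strong base class).
.is_strong_base <- function(compound) {
  base_pka <- switch(compound$compound_type,
                     "monoprotic base" = compound$pka1,
                     "diprotic base" = max(compound$pka1, compound$pka2),
                     "ampholyte" = compound$pka2,
                     NA_real_)
  is.finite(base_pka) && base_pka >= 7
}

# Neutral lipid / neutral phospholipid affinity from logP.
.lipid_term <- function(p_ow, f_nl, f_np) {
  p_ow * f_nl + (0.3 * p_ow + 0.7) * f_np
}

#' Predict a tissue:plasma partition coefficient from tissue composition
#'
#' Mechanistic partitioning in the tissue-composition lineage (the published
#' framework behind preset "mechanistic model 2" partition prediction):
#' tissue water weighted by Henderson-Hasselbalch ionisation, neutral-lipid
#' and neutral-phospholipid terms driven by the logP-derived membrane
#' affinity, plus, for moderate-to-strong bases, electrostatic binding to
#' acidic phospholipids scaled by the blood-cell association inferred from
#' B/P and hematocrit, or, for acids/neutrals/weak bases, binding to tissue
#' albumin scaled by `(1/fu - 1)` after removal of the plasma lipid
#' contribution.
#'
#' @param compound a [compound_record()].
#' @param tissue tissue name present in the composition table.
#' @param phys a [rat_physiology()].
#' @return plasma-referenced partition coefficient `Kp` (unbound-referenced
#'   `Kpu` available as attribute `"kpu"`).
#' @export
predict_kp <- function(compound, tissue, phys = rat_physiology()) {
  tc <- phys$tissue_composition
  row <- tc[tc$tissue == tissue, ]
  if (nrow(row) != 1) stop("unknown tissue '", tissue, "'")
  # adipose neutral lipid is storage fat: use the vegetable oil:water
  # partition coefficient (log Pvo:w = 1.115 logPo:w - 1.35) instead of
  # octanol:water, which overstates partitioning into triglyceride
  p_ow <- if (tissue == "adipose") 10^(1.115 * compound$logp - 1.35)
          else 10^compound$logp
  z_p <- .ion_Z(compound$compound_type, compound$pka1, compound$pka2,
                phys$plasma_ph)
  z_iw <- .ion_Z(compound$compound_type, compound$pka1, compound$pka2,
                 row$ph_iw)
  kpu <- row$f_ew + (z_iw / z_p) * row$f_iw +
    .lipid_term(p_ow, row$f_nl, row$f_np) / z_p

  if (.is_strong_base(compound)) {
    kpu <- kpu + .ka_ap(compound, phys) * row$ap_mg_g * (z_iw - 1) / z_p
  } else {
    kpu <- kpu + .ka_pr(compound, phys) * row$albumin_ratio
  }
  out <- kpu * compound$fu
  attr(out, "kpu") <- kpu
  out
}

# Acidic-phospholipid association constant inferred from blood-cell
# partitioning (B/P and hematocrit). Floored at 0 with a warning when the
# lipid and water terms alone already exceed the observed blood-cell uptake.
.ka_ap <- function(compound, phys) {
  hct <- phys$hematocrit
  tc <- phys$tissue_composition
  bc <- tc[tc$tissue == "erythrocyte", ]
  kpu_bc <- (compound$bp - (1 - hct)) / (hct * compound$fu)
  z_p <- .ion_Z(compound$compound_type, compound$pka1, compound$pka2,
                phys$plasma_ph)
  z_bc <- .ion_Z(compound$compound_type, compound$pka1, compound$pka2,
                 bc$ph_iw)
  p_ow <- 10^compound$logp
  resid <- kpu_bc - (z_bc / z_p) * bc$f_iw -
    .lipid_term(p_ow, bc$f_nl, bc$f_np) / z_p
  if (resid < 0) {
    warning("compound '", compound$name, "': inferred blood-cell association ",
            "below the water/lipid baseline; acidic-phospholipid term floored at 0")
    return(0)
  }
  resid * z_p / (bc$ap_mg_g * (z_bc - 1))
}

# Albumin association term for acids, neutrals and weak bases: the plasma
# protein-bound fraction not explained by plasma lipid, per unit plasma
# albumin. Floored at 0 with a warning when plasma lipid alone would
# over-explain (1/fu - 1).
.ka_pr <- function(compound, phys) {
  tc <- phys$tissue_composition
  pl <- tc[tc$tissue == "plasma", ]
  z_p <- .ion_Z(compound$compound_type, compound$pka1, compound$pka2,
                phys$plasma_ph)
  p_ow <- 10^compound$logp
  resid <- 1 / compound$fu - 1 - .lipid_term(p_ow, pl$f_nl, pl$f_np) / z_p
  if (resid < 0) {
    warning("compound '", compound$name, "': plasma lipid term exceeds ",
            "(1/fu - 1); albumin binding term floored at 0")
    return(0)
  }
  resid
}

#' Predict the steady-state volume of distribution
#'
#' Sums the predicted tissue partition coefficients over the composition
#' table, closes the volume balance with a rest-of-body compartment at the
#' volume-weighted mean of the predicted tissue Kp values (so the closure is
#' neutral with respect to the compound's own partitioning), adds the plasma
#' volume and an erythrocyte term derived from B/P and hematocrit. The
#' global `kp_scalar` multiplies every tissue partition coefficient
#' (default 1).
#'
#' @param compound a [compound_record()].
#' @param phys a [rat_physiology()].
#' @param kp_scalar global multiplier on all tissue Kp values.
#' @return an object of class `distribution_result`: list with `kp` (named
#'   vector), `kp_scalar`, `vss_l`, `vss_l_kg`, `liver_kp` and the volume
#'   bookkeeping needed by the simulator.
#' @export
predict_vss <- function(compound, phys = rat_physiology(), kp_scalar = 1) {
  stopifnot(is.finite(kp_scalar), kp_scalar > 0)
  tc <- phys$tissue_composition
  tissues <- setdiff(tc$tissue, c("plasma", "erythrocyte"))
  kp <- vapply(tissues, function(t) as.numeric(predict_kp(compound, t, phys)),
               0)
  bw <- phys$body_weight
  v_t <- tc$frac_volume[match(tissues, tc$tissue)] * bw  # L, density ~1
  v_plasma <- phys$plasma_volume
  v_ery <- tc$frac_volume[tc$tissue == "erythrocyte"] * bw
  v_rest <- bw - sum(v_t) - v_plasma - v_ery
  if (v_rest < 0) stop("tissue volumes exceed body volume")
  ep_ratio <- (compound$bp - (1 - phys$hematocrit)) / phys$hematocrit
  ep_ratio <- max(ep_ratio, 0)
  kp_rest <- sum(kp * v_t) / sum(v_t)  # volume-weighted mean tissue Kp
  vss_l <- v_plasma + kp_scalar * (sum(kp * v_t) + kp_rest * v_rest) +
    v_ery * ep_ratio
  structure(list(
    kp = kp, kp_scalar = kp_scalar,
    vss_l = vss_l, vss_l_kg = vss_l / bw,
    liver_kp = kp_scalar * kp[["liver"]],
    volumes = c(stats::setNames(v_t, tissues), plasma = v_plasma,
                erythrocyte = v_ery, rest = v_rest),
    kp_rest = kp_rest, ep_ratio = ep_ratio), class = "distribution_result")
}

#' @export
print.distribution_result <- function(x, ...) {
  cat("<distribution_result>\n")
  cat(sprintf("  Vss %.3g L (%.3g L/kg) | Kp scalar %.3g | liver Kp %.3g\n",
              x$vss_l, x$vss_l_kg, x$kp_scalar, x$liver_kp))
  invisible(x)
}
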