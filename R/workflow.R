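#' Run the prediction workflow for one compound and write its outputs
#'
#' For each dose: simulates the oral profile, writes `profile_<dose>.csv`
#' (`time_h, conc_ug_ml`), writes the derived PK parameters to
#' `pk_parameters.json`, and writes a coefficient log (`run_log.json`) with
#' every derived intermediate (Peff, ka, fa, Vss, liver Kp, scaled
#' clearances, Fg, Fh, CL) so any downstream discrepancy is diagnosable from
#' the log alone.
#'
#' @param compound a [compound_record()] or the name of a packaged fixture.
#' @param doses numeric vector of doses, mg/kg.
#' @param out_dir output directory (created if needed).
#' @param phys a [rat_physiology()].
#' @param perm_route,liver_model,kp_scalar,duration,grid_step model settings
#'   (see [build_model()] and [simulate_oral()]).
#' @return invisibly, a data.frame of PK parameters per dose.
#' @export
run_simulation <- function(compound, doses, out_dir = ".",
                           phys = rat_physiology(),
                           perm_route = "psa_hbd",
                           liver_model = "well_stirred", kp_scalar = 1,
                           duration = 24, grid_step = 0.01) {
  if (is.character(compound)) compound <- pbpk_compound(compound)
  stopifnot(length(doses) >= 1, all(doses > 0))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  model <- build_model(compound, phys, perm_route, liver_model, kp_scalar)
  rows <- list()
  for (d in doses) {
    prof <- simulate_oral(model, d, duration, grid_step)
    utils::write.csv(prof, file.path(out_dir,
                                     sprintf("profile_%s_%g.csv",
                                             compound$name, d)),
                     row.names = FALSE)
    pk <- pk_parameters(prof)
    rows[[length(rows) + 1]] <- data.frame(
      compound = compound$name, dose_mg_per_kg = d, tmax_h = pk$tmax,
      cmax_ug_ml = pk$cmax, auc_ug_h_ml = pk$auc0t)
  }
  pk_df <- do.call(rbind, rows)
  jsonlite::write_json(pk_df, file.path(out_dir, "pk_parameters.json"),
                       digits = NA, pretty = TRUE)
  log <- list(compound = compound$name, perm_route = perm_route,
              liver_model = liver_model, kp_scalar = kp_scalar,
              peff_human_1e4cm_s = model$peff_human,
              peff_rat_1e4cm_s = model$peff_rat,
              ka_per_h = model$ka, fa = model$fa, kt_per_h = model$kt,
              vss_l = model$vss_l, vss_l_kg = model$vss_l / phys$body_weight,
              kp_liver = model$liver_kp, v_sys_l = model$v_sys,
              clint_liver_l_h = model$clint_liver,
              cl_blood_l_h = model$hepatic$cl_blood,
              cl_plasma_l_h = model$hepatic$cl_plasma,
              fh = model$hepatic$bioavailability_fraction,
              fg_linear = model$fg_linear,
              gut = model$gut)
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       digits = NA, pretty = TRUE, auto_unbox = TRUE)
  invisible(pk_df)
}

#' Run the validation workflow
#'
#' Simulates every (compound, dose) present in the observed data, scores the
#' predictions with [validate_predictions()], and writes
#' `validation_report.csv` plus a JSON summary with the fraction of fold
#' errors within two-fold.
#'
#' @param observed an `observed_pk` data.frame ([load_observed()]) or a path
#'   to one; defaults to the packaged fixture.
#' @param compounds named list of [compound_record()]s; defaults to the
#'   packaged fixtures.
#' @param out_dir output directory, or `NULL` to skip writing.
#' @param phys,perm_route,liver_model,kp_scalar,duration model settings.
#' @return the `validation_report`, invisibly when writing.
#' @export
run_validation <- function(observed = NULL, compounds = NULL, out_dir = NULL,
                           phys = rat_physiology(), perm_route = "psa_hbd",
                           liver_model = "well_stirred", kp_scalar = 1,
                           duration = 24) {
  if (is.null(observed)) observed <- load_observed()
  if (is.character(observed)) observed <- load_observed(observed)
  if (is.null(compounds)) compounds <- pbpk_compound()
  keys <- unique(observed[, c("compound", "dose_mg_per_kg")])
  preds <- list()
  for (i in seq_len(nrow(keys))) {
    nm <- keys$compound[i]
    if (!nm %in% names(compounds)) next
    pk <- predict_pk(compounds[[nm]], keys$dose_mg_per_kg[i], phys,
                     duration = duration, perm_route = perm_route,
                     liver_model = liver_model, kp_scalar = kp_scalar)
    preds[[i]] <- data.frame(compound = nm,
                             dose_mg_per_kg = keys$dose_mg_per_kg[i],
                             tmax_h = pk$tmax, cmax_ug_ml = pk$cmax,
                             auc_ug_h_ml = pk$auc0t)
  }
  report <- validate_predictions(do.call(rbind, preds), observed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(report, file.path(out_dir, "validation_report.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(n_rows = nrow(report),
           fraction_within_2 = attr(report, "fraction_within_2")),
      file.path(out_dir, "validation_summary.json"),
      digits = NA, auto_unbox = TRUE, pretty = TRUE)
    return(invisible(report))
  }
  report
}

#' Run the sensitivity workflow
#'
#' Runs [sensitivity_grid()] for a compound over given (or packaged) fu and
#' CLint ranges and writes the long-format grid CSV and the range summary.
#'
#' @param compound a [compound_record()] or packaged fixture name.
#' @param dose dose in mg/kg; defaults to the packaged range table's dose.
#' @param fu_range,clint_range,clint_unit axis ranges; default to the
#'   packaged literature spans for the compound.
#' @param n_steps grid resolution per axis.
#' @param out_dir output directory, or `NULL` to skip writing.
#' @param phys a [rat_physiology()].
#' @return the `sensitivity_grid`, invisibly when writing.
#' @export
run_sensitivity <- function(compound, dose = NULL, fu_range = NULL,
                            clint_range = NULL, clint_unit = NULL,
                            n_steps = 21, out_dir = NULL,
                            phys = rat_physiology()) {
  if (is.character(compound)) compound <- pbpk_compound(compound)
  if (is.null(fu_range) || is.null(clint_range) || is.null(dose)) {
    rng <- pbpk_sensitivity_ranges()
    rng <- rng[rng$compound == compound$name, ]
    if (nrow(rng) != 1) {
      stop("no packaged sensitivity ranges for '", compound$name,
           "'; supply fu_range/clint_range/dose")
    }
    if (is.null(dose)) dose <- rng$dose_mg_per_kg
    if (is.null(fu_range)) fu_range <- c(rng$fu_lo, rng$fu_hi)
    if (is.null(clint_range)) clint_range <- c(rng$clint_lo, rng$clint_hi)
    if (is.null(clint_unit)) clint_unit <- rng$clint_unit
  }
  grid <- sensitivity_grid(compound, dose, fu_range, clint_range,
                           clint_unit = clint_unit, n_steps = n_steps,
                           phys = phys)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(grid$grid,
                     file.path(out_dir, sprintf("sensitivity_grid_%s.csv",
                                                compound$name)),
                     row.names = FALSE)
    utils::write.csv(grid$summary,
                     file.path(out_dir, sprintf("sensitivity_summary_%s.csv",
                                                compound$name)),
                     row.names = FALSE)
    return(invisible(grid))
  }
  grid
}
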