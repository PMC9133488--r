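#' Fold error between a predicted and an observed PK parameter
#'
#' The symmetric accuracy ratio used for PBPK model verification:
#' `max(predicted, observed) / min(predicted, observed)`, always >= 1. The
#' conventional acceptance threshold is a fold error of less than 2.
#'
#' @param predicted,observed positive values (vectorised).
#' @return fold error(s) >= 1.
#' @examples
#' fold_error(3.34, 1.73)       # 1.93
#' fold_error(1965.99, 1309.00) # 1.50
#' @export
fold_error <- function(predicted, observed) {
  if (any(!is.finite(predicted) | predicted <= 0) ||
      any(!is.finite(observed) | observed <= 0)) {
    stop("fold_error requires strictly positive predicted and observed values")
  }
  pmax(predicted, observed) / pmin(predicted, observed)
}

#' Overall model performance metrics
#'
#' Coefficient of determination, mean absolute error and root mean squared
#' error of predictions `y` against observations `x`:
#' `R2 = 1 - sum((x - y)^2) / sum((x - mean(x))^2)`,
#' `MAE = sum(|x - y|) / N`, `RMSE = sqrt(sum((x - y)^2) / N)`.
#'
#' @param observed numeric vector of observations (`x`).
#' @param predicted numeric vector of predictions (`y`), same length.
#' @return an object of class `performance_metrics`: list with `r2`, `mae`,
#'   `rmse`, `n_points`. `r2` is `NA` (with a warning) when the observations
#'   have zero variance.
#' @export
performance_metrics <- function(observed, predicted) {
  if (length(observed) != length(predicted)) {
    stop("observed and predicted series must have equal length")
  }
  if (length(observed) < 2) stop("need at least 2 points")
  resid <- observed - predicted
  ss_tot <- sum((observed - mean(observed))^2)
  r2 <- if (ss_tot == 0) {
    warning("zero variance in observed values: R2 undefined")
    NA_real_
  } else 1 - sum(resid^2) / ss_tot
  structure(list(r2 = r2, mae = mean(abs(resid)),
                 rmse = sqrt(mean(resid^2)), n_points = length(observed)),
            class = "performance_metrics")
}

#' @export
print.performance_metrics <- function(x, ...) {
  cat(sprintf("<performance_metrics> R2 %.4f | MAE %.4g | RMSE %.4g | n %d\n",
              x$r2, x$mae, x$rmse, x$n_points))
  invisible(x)
}

#' Validate predictions against observed PK studies
#'
#' Builds the fold-error report: one row per (study, parameter) pair with the
#' fold error and the two-fold acceptance flag. Observed Tmax ranges are
#' scored against the nearer bound, with the fold errors against both bounds
#' retained (`fold_lo`/`fold_hi`).
#'
#' @param predictions data.frame with columns `compound`, `dose_mg_per_kg`,
#'   `tmax_h`, `cmax_ug_ml`, `auc_ug_h_ml` (e.g. built from [predict_pk()]
#'   results, or [pbpk_reference_predictions()]).
#' @param observed an `observed_pk` data.frame from [load_observed()].
#' @return an object of class `validation_report`: data.frame with columns
#'   `compound`, `dose`, `obs_id`, `parameter`, `predicted`, `observed`,
#'   `fold_lo`, `fold_hi`, `fold_error`, `within_2`, `reference`; summary
#'   fraction within two-fold as attribute `"fraction_within_2"`.
#' @export
validate_predictions <- function(predictions, observed) {
  rows <- list()
  for (i in seq_len(nrow(observed))) {
    ob <- observed[i, ]
    pr <- predictions[predictions$compound == ob$compound &
                      abs(predictions$dose_mg_per_kg - ob$dose_mg_per_kg) < 1e-9, ]
    if (nrow(pr) == 0) {
      warning("no prediction for ", ob$compound, " at ", ob$dose_mg_per_kg,
              " mg/kg; skipped")
      next
    }
    pr <- pr[1, ]
    add <- function(par, pred, obs_lo, obs_hi) {
      if (!is.finite(pred) || !is.finite(obs_lo)) return()
      fl <- fold_error(pred, obs_lo); fh <- fold_error(pred, obs_hi)
      if (obs_lo <= pred && pred <= obs_hi) { fl <- 1; fh <- max(fl, fh) }
      fe <- min(fl, fh)
      rows[[length(rows) + 1]] <<- data.frame(
        compound = ob$compound, dose = ob$dose_mg_per_kg, obs_id = ob$obs_id,
        parameter = par, predicted = pred, observed = (obs_lo + obs_hi) / 2,
        fold_lo = min(fl, fh), fold_hi = max(fl, fh),
        fold_error = fe, within_2 = fe <= 2,
        reference = ob$reference, stringsAsFactors = FALSE)
    }
    add("tmax", pr$tmax_h, ob$tmax_lo, ob$tmax_hi)
    add("cmax", pr$cmax_ug_ml, ob$cmax, ob$cmax)
    add("auc0t", pr$auc_ug_h_ml, ob$auc0t, ob$auc0t)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(compound = character(), dose = numeric(), obs_id = integer(),
               parameter = character(), predicted = numeric(),
               observed = numeric(), fold_lo = numeric(), fold_hi = numeric(),
               fold_error = numeric(), within_2 = logical(),
               reference = character(), stringsAsFactors = FALSE)
  structure(out, class = c("validation_report", "data.frame"),
            fraction_within_2 = if (nrow(out)) mean(out$within_2) else NA_real_)
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> %d rows | %.1f%% within 2-fold\n",
              nrow(x), 100 * attr(x, "fraction_within_2")))
  NextMethod()
}

#' fu x CLint sensitivity grid
#'
#' Full-factorial re-simulation over a grid of plasma fraction unbound and
#' hepatic intrinsic clearance values with every other input fixed,
#' summarising the prediction uncertainty induced by the literature spread of
#' the two most variable in vitro parameters. For each PK parameter the
#' (min, max) range over the grid and the fold range `max/min` are reported.
#'
#' @param compound a [compound_record()].
#' @param dose dose in mg/kg.
#' @param fu_range length-2 numeric, span of fu (0 < fu <= 1).
#' @param clint_range length-2 numeric, span of hepatic CLint in the unit of
#'   `clint_unit`.
#' @param clint_unit `"ul/min/mg"` (microsomes) or `"ul/min/1e6 cells"`
#'   (hepatocytes); defaults to the unit of the compound's own record.
#' @param n_steps grid resolution per axis (>= 2 unless the range is
#'   degenerate).
#' @param phys a [rat_physiology()].
#' @param duration,grid_step simulation settings (see [simulate_oral()]).
#' @return an object of class `sensitivity_grid`: list with `fu`, `clint`
#'   axis vectors, matrices `tmax`, `cmax`, `auc0t` (fu rows x clint
#'   columns), a long-format data.frame `grid`, and a `summary` data.frame
#'   with min/max/fold_range per parameter.
#' @export
sensitivity_grid <- function(compound, dose, fu_range, clint_range,
                             clint_unit = NULL, n_steps = 21,
                             phys = rat_physiology(),
                             duration = 24, grid_step = 0.01) {
  stopifnot(length(fu_range) == 2, length(clint_range) == 2,
            all(fu_range > 0), all(clint_range > 0), n_steps >= 1)
  if (fu_range[1] > fu_range[2] || clint_range[1] > clint_range[2]) {
    stop("inverted sensitivity range")
  }
  if (is.null(clint_unit)) {
    clint_unit <- if (compound$liver_clint$kind == "linear")
      compound$liver_clint$unit else "ul/min/mg"
  }
  fu_axis <- if (fu_range[1] == fu_range[2]) fu_range[1] else
    seq(fu_range[1], fu_range[2], length.out = n_steps)
  cl_axis <- if (clint_range[1] == clint_range[2]) clint_range[1] else
    seq(clint_range[1], clint_range[2], length.out = n_steps)
  tmax <- cmax <- auc <- matrix(NA_real_, length(fu_axis), length(cl_axis),
                                dimnames = list(NULL, NULL))
  for (i in seq_along(fu_axis)) {
    for (j in seq_along(cl_axis)) {
      cmp <- compound
      cmp$fu <- fu_axis[i]
      cmp$liver_clint <- clearance_spec("liver", clint = cl_axis[j],
                                        unit = clint_unit,
                                        fu_inc = compound$liver_clint$fu_inc)
      pk <- tryCatch(
        predict_pk(cmp, dose, phys, duration = duration, grid_step = grid_step),
        error = function(e) stop("sensitivity simulation failed at fu = ",
                                 fu_axis[i], ", clint = ", cl_axis[j], ": ",
                                 conditionMessage(e), call. = FALSE))
      tmax[i, j] <- pk$tmax; cmax[i, j] <- pk$cmax; auc[i, j] <- pk$auc0t
    }
  }
  summarise <- function(m, par) data.frame(
    parameter = par, min = min(m), max = max(m), fold_range = max(m) / min(m))
  grid_long <- expand.grid(fu = fu_axis, clint = cl_axis,
                           KEEP.OUT.ATTRS = FALSE)
  grid_long$tmax <- as.vector(tmax)
  grid_long$cmax <- as.vector(cmax)
  grid_long$auc0t <- as.vector(auc)
  structure(list(compound = compound$name, dose = dose,
                 fu = fu_axis, clint = cl_axis, clint_unit = clint_unit,
                 tmax = tmax, cmax = cmax, auc0t = auc, grid = grid_long,
                 summary = rbind(summarise(tmax, "tmax"),
                                 summarise(cmax, "cmax"),
                                 summarise(auc, "auc0t"))),
            class = "sensitivity_grid")
}

#' @export
print.sensitivity_grid <- function(x, ...) {
  cat(sprintf("<sensitivity_grid> %s at %g mg/kg | fu %g-%g x CLint %g-%g %s (%d x %d)\n",
              x$compound, x$dose, min(x$fu), max(x$fu), min(x$clint),
              max(x$clint), x$clint_unit, length(x$fu), length(x$clint)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
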