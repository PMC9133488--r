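#' Observed pharmacokinetic study records
#'
#' Reads literature-style (or synthetic) observed PK parameter records from a
#' CSV with columns `compound`, `dose_mg_per_kg`, `obs_id`, `tmax_h`,
#' `tmax_sd`, `cmax_ug_ml`, `cmax_sd`, `auc_ug_h_ml`, `auc_sd`, `reference`.
#' `tmax_h` may be a point value or a range written `"lo-hi"` (hyphen or
#' en-dash); ranges are parsed into `tmax_lo`/`tmax_hi` with `tmax` set to
#' the midpoint.
#'
#' @param path CSV file path; defaults to the packaged observation fixture
#'   transcribed from published rat PK studies of the seven probe substrates.
#' @return a data.frame of class `observed_pk` with numeric columns `tmax`,
#'   `tmax_lo`, `tmax_hi`, `cmax`, `auc0t` (plus sd columns and `reference`).
#' @export
load_observed <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "observed_pk.csv", package = "rpbpk")
  }
  if (!file.exists(path)) stop("observed PK file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = list(tmax_h = "character"))
  if (nrow(df) == 0) {
    return(structure(df, class = c("observed_pk", "data.frame")))
  }
  required <- c("compound", "dose_mg_per_kg", "tmax_h", "cmax_ug_ml", "auc_ug_h_ml")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("observed PK file missing column(s): ", paste(missing, collapse = ", "))
  }
  rng <- lapply(seq_len(nrow(df)), function(i) {
    out <- tryCatch(parse_range(df$tmax_h[i]),
                    error = function(e) stop("observed_pk row ", i, ": ",
                                             conditionMessage(e), call. = FALSE))
    out
  })
  df$tmax_lo <- vapply(rng, `[[`, 0, "lo")
  df$tmax_hi <- vapply(rng, `[[`, 0, "hi")
  df$tmax <- vapply(rng, `[[`, 0, "mid")
  df$cmax <- as.numeric(df$cmax_ug_ml)
  df$auc0t <- as.numeric(df$auc_ug_h_ml)
  for (i in seq_len(nrow(df))) {
    vals <- c(df$tmax[i], df$cmax[i], df$auc0t[i])
    if (all(is.na(vals))) {
      stop("observed_pk row ", i, ": needs at least one of tmax/cmax/auc")
    }
    if (any(vals < 0, na.rm = TRUE)) {
      stop("observed_pk row ", i, ": negative PK parameter")
    }
  }
  structure(df, class = c("observed_pk", "data.frame"))
}

#' Parse a point value or "lo-hi" range
#'
#' Accepts plain numbers, hyphen-separated and en-dash-separated ranges.
#'
#' @param x a character scalar (or `NA`).
#' @return list with `lo`, `hi` and midpoint `mid` (all `NA` for empty input).
#' @export
parse_range <- function(x) {
  if (is.null(x) || is.na(x) || !nzchar(trimws(as.character(x)))) {
    return(list(lo = NA_real_, hi = NA_real_, mid = NA_real_))
  }
  x <- trimws(as.character(x))
  # split on hyphen or en-dash between two numbers (not a leading minus sign)
  parts <- strsplit(x, "(?<=[0-9.])\\s*[-–]\\s*(?=[0-9.])", perl = TRUE)[[1]]
  vals <- suppressWarnings(as.numeric(parts))
  if (any(is.na(vals)) || !length(vals) %in% 1:2) {
    stop("unparsable value or range: '", x, "'")
  }
  if (any(vals < 0)) stop("negative value in range: '", x, "'")
  if (length(vals) == 1) {
    list(lo = vals, hi = vals, mid = vals)
  } else {
    if (vals[1] > vals[2]) stop("inverted range: '", x, "'")
    list(lo = vals[1], hi = vals[2], mid = mean(vals))
  }
}

#' Packaged model predictions transcribed from the source tables
#'
#' The reference predictions of the original Simcyp implementation for each
#' compound and dose, used for fold-error arithmetic checks and as the
#' comparison surface for this package's own simulations.
#'
#' @return data.frame with columns `compound`, `dose_mg_per_kg`, `tmax_h`,
#'   `cmax_ug_ml`, `auc_ug_h_ml`.
#' @export
pbpk_reference_predictions <- function() {
  utils::read.csv(system.file("extdata", "predicted_pk.csv", package = "rpbpk"),
                  stringsAsFactors = FALSE)
}

#' Packaged literature variation ranges of fu and CLint
#'
#' The spans of fraction unbound and intrinsic clearance reported across
#' literature sources for each compound, with the dose at which the
#' sensitivity analysis is run.
#'
#' @return data.frame with columns `compound`, `dose_mg_per_kg`, `fu_lo`,
#'   `fu_hi`, `clint_lo`, `clint_hi`, `clint_unit`.
#' @export
pbpk_sensitivity_ranges <- function() {
  utils::read.csv(system.file("extdata", "sensitivity_ranges.csv",
                              package = "rpbpk"),
                  stringsAsFactors = FALSE)
}
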