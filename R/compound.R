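#' Compound records: the in vitro input set for one drug
#'
#' A `compound_record` bundles every in vitro parameter the bottom-up model
#' consumes: physicochemistry and blood binding (MW, logP, compound type,
#' pKa, B/P, fu), absorption inputs (PSA, HBD, optional Papp) and intrinsic
#' clearance specifications for liver and, optionally, intestine.
#'
#' @param name compound name.
#' @param mw molecular weight, g/mol.
#' @param logp octanol:water log partition coefficient of the neutral species.
#' @param compound_type one of `"neutral"`, `"monoprotic acid"`,
#'   `"monoprotic base"`, `"diprotic acid"`, `"diprotic base"`, `"ampholyte"`.
#' @param pka1 first ionisation constant (acidic pKa for acids and ampholytes,
#'   basic pKa for bases); `NA` for neutral compounds.
#' @param pka2 second ionisation constant (diprotic compounds) or the basic
#'   pKa of an ampholyte.
#' @param bp blood:plasma concentration ratio.
#' @param fu fraction unbound in plasma, in (0, 1].
#' @param psa polar surface area, A^2.
#' @param hbd hydrogen bond donor count (non-negative integer).
#' @param papp optional apparent permeability, 1e-6 cm/s.
#' @param papp_assay assay tag for `papp` (`"Caco-2"`, `"MDCK"`, `"PAMPA"`).
#' @param liver_clint a [clearance_spec()] with `organ = "liver"`.
#' @param gut_clint optional [clearance_spec()] with `organ = "intestine"`.
#' @return an object of class `compound_record`.
#' @seealso [load_compound()], [pbpk_compound()]
#' @export
compound_record <- function(name, mw, logp, compound_type, pka1 = NA_real_,
                            pka2 = NA_real_, bp, fu, psa, hbd,
                            papp = NA_real_, papp_assay = NA_character_,
                            liver_clint, gut_clint = NULL) {
  rec <- structure(
    list(name = as.character(name), mw = as.numeric(mw), logp = as.numeric(logp),
         compound_type = as.character(compound_type),
         pka1 = as.numeric(pka1), pka2 = as.numeric(pka2),
         bp = as.numeric(bp), fu = as.numeric(fu), psa = as.numeric(psa),
         hbd = as.numeric(hbd), papp = as.numeric(papp),
         papp_assay = as.character(papp_assay),
         liver_clint = liver_clint, gut_clint = gut_clint),
    class = "compound_record")
  validate_compound_record(rec)
}

.compound_types <- c("neutral", "monoprotic acid", "monoprotic base",
                     "diprotic acid", "diprotic base", "ampholyte")

#' Validate a compound record against its invariants
#'
#' Checks positivity of MW and B/P, `fu` in (0, 1], non-negative PSA, an
#' integral non-negative HBD count, and that pKa fields are present exactly
#' as the compound type requires (both an acidic and a basic pKa for an
#' ampholyte, one pKa for monoprotic species, none for neutrals).
#'
#' @param rec a `compound_record`.
#' @return `rec`, invisibly unchanged, if valid; otherwise an error naming the
#'   offending field.
#' @export
validate_compound_record <- function(rec) {
  stopifnot(inherits(rec, "compound_record"))
  err <- function(...) stop("compound '", rec$name, "': ", ..., call. = FALSE)
  if (!is.finite(rec$mw) || rec$mw <= 0) err("mw must be > 0")
  if (!is.finite(rec$fu) || rec$fu <= 0 || rec$fu > 1) err("fu must be in (0, 1]")
  if (!is.finite(rec$bp) || rec$bp <= 0) err("bp must be > 0")
  if (!is.finite(rec$psa) || rec$psa < 0) err("psa must be >= 0")
  if (!is.finite(rec$hbd) || rec$hbd < 0 || rec$hbd != round(rec$hbd)) {
    err("hbd must be a non-negative integer")
  }
  if (!rec$compound_type %in% .compound_types) {
    err("unknown compound_type '", rec$compound_type, "'")
  }
  n_pka <- sum(is.finite(c(rec$pka1, rec$pka2)))
  need <- switch(rec$compound_type,
                 "neutral" = 0L, "monoprotic acid" = 1L, "monoprotic base" = 1L,
                 "diprotic acid" = 2L, "diprotic base" = 2L, "ampholyte" = 2L)
  if (n_pka != need) {
    err("compound_type '", rec$compound_type, "' requires ", need,
        " pKa value(s), got ", n_pka)
  }
  if (!is.na(rec$papp) && rec$papp <= 0) err("papp must be > 0 when present")
  if (is.null(rec$liver_clint)) err("liver_clint is mandatory")
  validate_clearance_spec(rec$liver_clint)
  if (rec$liver_clint$organ != "liver") err("liver_clint must have organ 'liver'")
  if (!is.null(rec$gut_clint)) {
    validate_clearance_spec(rec$gut_clint)
    if (rec$gut_clint$organ != "intestine") {
      err("gut_clint must have organ 'intestine'")
    }
  }
  invisible(rec)
}

#' Intrinsic clearance specification
#'
#' Describes a metabolic stability measurement: either a linear intrinsic
#' clearance or a Michaelis-Menten (Vmax, Km) pair, with its in vitro unit
#' tag and the fraction unbound in the incubation.
#'
#' @param organ `"liver"` or `"intestine"`.
#' @param clint linear intrinsic clearance value (exclusive with `vmax`/`km`).
#' @param unit unit tag for `clint` (and `vmax` scaling basis):
#'   `"ul/min/mg"` (microsomal protein), `"ul/min/1e6 cells"` (hepatocytes) or
#'   `"ul/min/g intestine"`.
#' @param vmax Michaelis-Menten maximum rate, pmol/min/mg microsomal protein.
#' @param km Michaelis constant, uM.
#' @param fu_inc fraction unbound in the incubation, (0, 1]; default 1.
#' @return an object of class `clearance_spec`.
#' @export
clearance_spec <- function(organ, clint = NA_real_, unit = "ul/min/mg",
                           vmax = NA_real_, km = NA_real_, fu_inc = 1) {
  spec <- structure(
    list(organ = match.arg(organ, c("liver", "intestine")),
         kind = if (is.finite(vmax) || is.finite(km)) "michaelis_menten" else "linear",
         clint = as.numeric(clint), unit = as.character(unit),
         vmax = as.numeric(vmax), km = as.numeric(km),
         fu_inc = as.numeric(fu_inc)),
    class = "clearance_spec")
  validate_clearance_spec(spec)
}

#' @rdname clearance_spec
#' @param spec a `clearance_spec` to validate.
#' @export
validate_clearance_spec <- function(spec) {
  stopifnot(inherits(spec, "clearance_spec"))
  if (spec$kind == "linear") {
    if (!is.finite(spec$clint) || spec$clint < 0) {
      stop("linear clearance_spec requires clint >= 0", call. = FALSE)
    }
    if (is.finite(spec$vmax) || is.finite(spec$km)) {
      stop("clearance_spec must have exactly one of clint or (vmax, km)",
           call. = FALSE)
    }
  } else {
    if (!is.finite(spec$vmax) || !is.finite(spec$km) ||
        spec$vmax < 0 || spec$km <= 0) {
      stop("michaelis_menten clearance_spec requires vmax >= 0 and km > 0",
           call. = FALSE)
    }
    if (is.finite(spec$clint)) {
      stop("clearance_spec must have exactly one of clint or (vmax, km)",
           call. = FALSE)
    }
  }
  if (!is.finite(spec$fu_inc) || spec$fu_inc <= 0 || spec$fu_inc > 1) {
    stop("fu_inc must be in (0, 1]", call. = FALSE)
  }
  invisible(spec)
}

#' @export
print.compound_record <- function(x, ...) {
  cat("<compound_record>", x$name, "\n")
  cat(sprintf("  MW %.2f g/mol | logP %.2f | %s", x$mw, x$logp, x$compound_type))
  if (is.finite(x$pka1)) cat(sprintf(" | pKa %s", paste(
    stats::na.omit(c(x$pka1, x$pka2)), collapse = "/")))
  cat("\n")
  cat(sprintf("  B/P %.2f | fu %.3f | PSA %.2f A^2 | HBD %d\n",
              x$bp, x$fu, x$psa, as.integer(x$hbd)))
  cl <- x$liver_clint
  if (cl$kind == "linear") {
    cat(sprintf("  liver CLint %.3g %s\n", cl$clint, cl$unit))
  } else {
    cat(sprintf("  liver Vmax %.3g pmol/min/mg, Km %.3g uM\n", cl$vmax, cl$km))
  }
  if (!is.null(x$gut_clint)) {
    g <- x$gut_clint
    if (g$kind == "linear") {
      cat(sprintf("  gut CLint %.3g %s\n", g$clint, g$unit))
    } else {
      cat(sprintf("  gut Vmax %.3g pmol/min/mg, Km %.3g uM\n", g$vmax, g$km))
    }
  }
  invisible(x)
}

.row_to_compound <- function(row) {
  num <- function(f) suppressWarnings(as.numeric(row[[f]]))
  chr <- function(f) {
    v <- row[[f]]
    if (is.null(v) || is.na(v) || !nzchar(as.character(v))) NA_character_
    else as.character(v)
  }
  liver <- if (is.finite(num("liver_vmax")) || is.finite(num("liver_km"))) {
    clearance_spec("liver", vmax = num("liver_vmax"), km = num("liver_km"),
                   fu_inc = if (is.finite(num("liver_fu_inc"))) num("liver_fu_inc") else 1)
  } else {
    clearance_spec("liver", clint = num("liver_clint"),
                   unit = chr("liver_clint_unit"),
                   fu_inc = if (is.finite(num("liver_fu_inc"))) num("liver_fu_inc") else 1)
  }
  gut <- NULL
  gut_fu_inc <- if (is.finite(num("gut_fu_inc"))) num("gut_fu_inc") else 1
  if (is.finite(num("gut_vmax")) || is.finite(num("gut_km"))) {
    gut <- clearance_spec("intestine", vmax = num("gut_vmax"), km = num("gut_km"),
                          fu_inc = gut_fu_inc)
  } else if (is.finite(num("gut_clint"))) {
    gut <- clearance_spec("intestine", clint = num("gut_clint"),
                          unit = chr("gut_clint_unit"), fu_inc = gut_fu_inc)
  }
  compound_record(
    name = chr("name"), mw = num("mw"), logp = num("logp"),
    compound_type = chr("compound_type"), pka1 = num("pka1"), pka2 = num("pka2"),
    bp = num("bp"), fu = num("fu"), psa = num("psa"), hbd = num("hbd"),
    papp = num("papp"), papp_assay = chr("papp_assay"),
    liver_clint = liver, gut_clint = gut)
}

#' Load compound records from CSV or JSON
#'
#' Reads one or more compound records from a `compounds.csv` file (columns as
#' in the packaged fixture) or from a JSON file containing a single record or
#' an array of records with the same field names. Every record is validated
#' against the `compound_record` invariants before being returned.
#'
#' @param path path to a `.csv` or `.json` file.
#' @return a named list of `compound_record` objects.
#' @export
load_compound <- function(path) {
  if (!file.exists(path)) stop("compound file not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    df <- if (is.data.frame(raw)) raw else as.data.frame(raw, stringsAsFactors = FALSE)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  mandatory <- c("name", "mw", "logp", "compound_type", "bp", "fu", "psa", "hbd")
  missing <- setdiff(mandatory, names(df))
  if (length(missing)) {
    stop("compound source is missing mandatory field(s): ",
         paste(missing, collapse = ", "))
  }
  recs <- lapply(seq_len(nrow(df)), function(i) .row_to_compound(df[i, , drop = FALSE]))
  stats::setNames(recs, vapply(recs, `[[`, "", "name"))
}

#' Write compound records back to CSV
#'
#' Inverse of [load_compound()]: the packaged fixtures round-trip identically
#' through `write_compounds()` followed by `load_compound()`.
#'
#' @param records a list of `compound_record` objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_compounds <- function(records, path) {
  rows <- lapply(records, function(r) {
    lc <- r$liver_clint
    gc <- r$gut_clint
    data.frame(
      name = r$name, mw = r$mw, logp = r$logp, compound_type = r$compound_type,
      pka1 = r$pka1, pka2 = r$pka2, bp = r$bp, fu = r$fu, psa = r$psa,
      hbd = r$hbd, papp = r$papp, papp_assay = r$papp_assay,
      liver_clint = if (lc$kind == "linear") lc$clint else NA_real_,
      liver_clint_unit = if (lc$kind == "linear") lc$unit else NA_character_,
      liver_vmax = lc$vmax, liver_km = lc$km, liver_fu_inc = lc$fu_inc,
      gut_clint = if (!is.null(gc) && gc$kind == "linear") gc$clint else NA_real_,
      gut_clint_unit = if (!is.null(gc) && gc$kind == "linear") gc$unit else NA_character_,
      gut_vmax = if (!is.null(gc)) gc$vmax else NA_real_,
      gut_km = if (!is.null(gc)) gc$km else NA_real_,
      gut_fu_inc = if (!is.null(gc)) gc$fu_inc else NA_real_,
      stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Packaged compound fixtures
#'
#' Returns the bundled in vitro input sets for the seven CYP/UGT probe
#' substrates (phenacetin, tolbutamide, omeprazole, metoprolol, chlorzoxazone,
#' nifedipine, baicalein).
#'
#' @param name optional compound name; if omitted, all records are returned.
#' @return a `compound_record` (when `name` is given) or a named list of them.
#' @export
pbpk_compound <- function(name = NULL) {
  path <- system.file("extdata", "compounds.csv", package = "rpbpk")
  recs <- load_compound(path)
  if (is.null(name)) return(recs)
  key <- tolower(name)
  if (!key %in% names(recs)) {
    stop("unknown packaged compound '", name, "'; available: ",
         paste(names(recs), collapse = ", "))
  }
  recs[[key]]
}
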