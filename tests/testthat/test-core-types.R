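test_that("rate and concentration unit conversions are exact and invertible", {
  expect_equal(convert_rate_units(1935.2, "ul/min", "L/h"), 0.116112)
  expect_equal(convert_rate_units(0, "ul/min", "L/h"), 0)
  expect_equal(convert_rate_units(6.97, "uM", "ug/ml", mw = 345.42),
               2.4075774, tolerance = 1e-10)
  # round trips to 1e-12 relative
  for (pair in list(c("ul/min", "L/h"), c("uM", "ug/ml"),
                    c("pmol/min", "mg/h"))) {
    x <- 137.5
    back <- convert_rate_units(
      convert_rate_units(x, pair[1], pair[2], mw = 250), pair[2], pair[1],
      mw = 250)
    expect_equal(back, x, tolerance = 1e-12)
  }
  expect_error(convert_rate_units(1, "furlong/fortnight", "L/h"),
               "furlong/fortnight")
  expect_error(convert_rate_units(1, "uM", "ug/ml"), "molecular weight")
})

test_that("packaged compound fixtures carry the published in vitro inputs", {
  tol <- compounds_default$tolbutamide
  expect_equal(tol$mw, 270.35)
  expect_equal(tol$logp, 2.34)
  expect_equal(tol$compound_type, "monoprotic acid")
  expect_equal(tol$pka1, 5.16)
  expect_equal(tol$bp, 1.33)
  expect_equal(tol$fu, 0.048)
  expect_equal(tol$psa, 80.65)
  expect_equal(tol$hbd, 2)
  expect_equal(tol$liver_clint$clint, 4.7)
  expect_equal(tol$liver_clint$unit, "ul/min/mg")

  phe <- compounds_default$phenacetin
  expect_equal(phe$liver_clint$unit, "ul/min/1e6 cells")
  expect_equal(phe$liver_clint$clint, 27)
  expect_equal(phe$gut_clint$kind, "michaelis_menten")
  expect_equal(phe$gut_clint$vmax, 0.25)
  expect_equal(phe$gut_clint$km, 56.7)

  ome <- compounds_default$omeprazole
  expect_equal(ome$compound_type, "ampholyte")
  expect_equal(c(ome$pka1, ome$pka2), c(8.8, 4.2))
  expect_equal(ome$gut_clint$vmax, 780)
  expect_equal(ome$gut_clint$km, 6.97)

  # every fixture satisfies all record invariants
  for (rec in compounds_default) expect_silent(validate_compound_record(rec))
  # nifedipine-style optionality: no gut spec for pure-liver compounds
  expect_null(compounds_default$tolbutamide$gut_clint)
  expect_null(compounds_default$chlorzoxazone$gut_clint)
})

test_that("compound validation rejects malformed records distinctly", {
  base <- make_simple_compound()
  bad_fu <- base; bad_fu$fu <- 0
  expect_error(validate_compound_record(bad_fu), "fu")
  bad_pka <- base; bad_pka$compound_type <- "monoprotic acid"
  expect_error(validate_compound_record(bad_pka), "pKa")
  bad_hbd <- base; bad_hbd$hbd <- 1.5
  expect_error(validate_compound_record(bad_hbd), "hbd")
  expect_error(clearance_spec("liver", clint = 5, vmax = 10, km = 2),
               "exactly one")
  expect_error(clearance_spec("liver", clint = 5, fu_inc = 0), "fu_inc")
})

test_that("compound fixtures round-trip through write-then-read identically", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_compounds(compounds_default, tmp)
  back <- load_compound(tmp)
  expect_identical(names(back), names(compounds_default))
  for (nm in names(back)) {
    expect_equal(back[[nm]], compounds_default[[nm]], tolerance = 1e-12)
  }
})

test_that("observed PK records load with range parsing and row validation", {
  obs <- load_observed()
  expect_s3_class(obs, "observed_pk")
  # tolbutamide 50 mg/kg observation 1
  row <- obs[obs$compound == "tolbutamide" & obs$obs_id == 1, ]
  expect_equal(row$tmax, 0.91)
  expect_equal(row$cmax, 232.00)
  expect_equal(row$auc0t, 1309.00)
  # a tmax range parses into bounds
  phe5 <- obs[obs$compound == "phenacetin" & obs$dose_mg_per_kg == 5, ]
  expect_equal(c(phe5$tmax_lo, phe5$tmax_hi), c(0.33, 0.50))
  # empty file gives an empty record set
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(paste("compound,dose_mg_per_kg,obs_id,tmax_h,tmax_sd,cmax_ug_ml",
                   "cmax_sd,auc_ug_h_ml,auc_sd,reference", sep = ","), tmp)
  expect_equal(nrow(load_observed(tmp)), 0)
})

test_that("range parser handles points, hyphens, en-dashes and rejects junk", {
  expect_equal(parse_range("0.33-0.50"), list(lo = 0.33, hi = 0.5, mid = 0.415))
  expect_equal(parse_range("0.33–0.50")$hi, 0.5)  # en-dash
  expect_equal(parse_range("1.5")$mid, 1.5)
  expect_error(parse_range("abc"), "unparsable")
  expect_error(parse_range("0.5-0.3"), "inverted")
})

test_that("physiology configuration loads, validates, and rejects bad values", {
  expect_s3_class(phys_default, "rat_physiology")
  expect_lt(phys_default$villous_blood_flow, phys_default$hepatic_blood_flow)
  expect_true(all(c("liver", "muscle", "plasma", "erythrocyte") %in%
                    phys_default$tissue_composition$tissue))
  bad <- phys_default
  bad$villous_blood_flow <- bad$hepatic_blood_flow * 2
  expect_error(validate_physiology(bad), "villous")
  # reproducible: loading twice gives identical objects
  expect_identical(rat_physiology(), phys_default)
})

test_that("dose regimen derives the absolute dose", {
  d <- dose_regimen(50, 0.25)
  expect_equal(d$dose_amount, 12.5)
  expect_error(dose_regimen(-1), "dose_per_kg")
})
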