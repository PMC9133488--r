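# Shared fixtures, loaded once per test file. The default physiology and the
# packaged compound set are pure data; building them here keeps individual
# tests fast and byte-identical.
phys_default <- rat_physiology()
compounds_default <- pbpk_compound()
reference_predictions <- pbpk_reference_predictions()

# a small neutral test compound with round-number inputs for hand arithmetic
make_simple_compound <- function(fu = 0.5, clint = 10, logp = 2,
                                 gut_clint = NULL) {
  compound_record(
    name = "simple", mw = 300, logp = logp, compound_type = "neutral",
    bp = 1, fu = fu, psa = 60, hbd = 1,
    liver_clint = clearance_spec("liver", clint = clint, unit = "ul/min/mg"),
    gut_clint = gut_clint)
}

predict_pk_cached <- local({
  cache <- new.env(parent = emptyenv())
  function(name, dose, ...) {
    key <- paste(name, dose, sep = "@")
    if (is.null(cache[[key]])) {
      cache[[key]] <- predict_pk(compounds_default[[name]], dose,
                                 phys_default, ...)
    }
    cache[[key]]
  }
})
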