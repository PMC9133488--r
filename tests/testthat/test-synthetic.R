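test_that("virtual compounds are deterministic per seed and always valid", {
  expect_equal(generate_virtual_compound(11), generate_virtual_compound(11))
  expect_false(identical(generate_virtual_compound(1),
                         generate_virtual_compound(2)))
  for (seed in 1:500) {
    expect_silent(validate_compound_record(
      suppressWarnings(generate_virtual_compound(seed))))
  }
})

test_that("a virtual compound with a saturable gut shows supra-proportional
           dose-normalised exposure", {
  cmp <- make_simple_compound(
    gut_clint = clearance_spec("intestine", vmax = 600, km = 5))
  aucn <- vapply(c(5, 20, 80), function(d) {
    pk <- predict_pk(cmp, d, phys_default, duration = 12, grid_step = 0.02)
    pk$auc0t / d
  }, 0)
  expect_true(all(diff(aucn) > 0))
})

test_that("noiseless synthetic studies reproduce the model exactly through the
           whole validation pipeline", {
  spec <- synthetic_study_spec(compounds_default$metoprolol, jitter_cv = 0,
                               residual_cv = 0, n_replicates = 3, seed = 5)
  gen <- generate_observed_study(spec, 10, phys_default)
  expect_equal(gen$studies$cmax_ug_ml, rep(gen$truth$cmax, 3))
  expect_equal(gen$studies$auc_ug_h_ml, rep(gen$truth$auc0t, 3))
  # full pipeline: fold errors all 1 and perfect performance metrics
  pred <- data.frame(compound = "metoprolol", dose_mg_per_kg = 10,
                     tmax_h = gen$truth$tmax, cmax_ug_ml = gen$truth$cmax,
                     auc_ug_h_ml = gen$truth$auc0t)
  obs <- gen$studies
  obs$tmax <- obs$tmax_lo <- obs$tmax_hi <- as.numeric(obs$tmax_h)
  obs$cmax <- obs$cmax_ug_ml; obs$auc0t <- obs$auc_ug_h_ml
  rep <- validate_predictions(pred, obs)
  expect_equal(rep$fold_error, rep(1, nrow(rep)))
  expect_true(all(rep$within_2))
  pm <- performance_metrics(c(obs$cmax, obs$auc0t),
                            rep(c(gen$truth$cmax, gen$truth$auc0t), each = 3))
  expect_equal(c(pm$r2, pm$mae, pm$rmse), c(1, 0, 0))
})

test_that("seeded noise is reproducible and different across seeds", {
  spec1 <- synthetic_study_spec(compounds_default$metoprolol, seed = 9)
  spec2 <- synthetic_study_spec(compounds_default$metoprolol, seed = 10)
  g1 <- generate_observed_study(spec1, 10, phys_default)
  g1b <- generate_observed_study(spec1, 10, phys_default)
  g2 <- generate_observed_study(spec2, 10, phys_default)
  expect_identical(g1$studies, g1b$studies)
  expect_false(identical(g1$studies$cmax_ug_ml, g2$studies$cmax_ug_ml))
})

test_that("mean AUC fold error under residual noise matches a direct
           Monte-Carlo construction on the same schedule", {
  spec <- synthetic_study_spec(compounds_default$metoprolol, jitter_cv = 0,
                               residual_cv = 0.2, n_replicates = 400,
                               seed = 123)
  gen <- generate_observed_study(spec, 10, phys_default)
  fe_pipeline <- mean(fold_error(gen$studies$auc_ug_h_ml, gen$truth$auc0t))
  # oracle: apply the same log-normal residual model directly to the frozen
  # noise-free sampled concentrations and re-derive the trapezoid AUC
  sched <- spec$schedule
  base <- attr(predict_pk(compounds_default$metoprolol, 10, phys_default,
                          duration = 24), "profile")
  idx <- vapply(sched, function(s) which.min(abs(base$time_h - s)), 0L)
  c0 <- base$conc_ug_ml[idx]
  w <- c(diff(sched) / 2, 0) + c(0, diff(sched) / 2)  # trapezoid weights
  auc0 <- sum(w * c0)
  set.seed(999)
  sdlog <- sqrt(log(1 + 0.2^2))
  fe_mc <- mean(replicate(4000, {
    auc <- sum(w * c0 * exp(stats::rnorm(length(c0), 0, sdlog)))
    max(auc, auc0) / min(auc, auc0)
  }))
  expect_equal(fe_pipeline, fe_mc, tolerance = 0.02)
})

test_that("the within-two-fold fraction is non-increasing in residual noise", {
  fractions <- vapply(c(0, 0.4, 1.2), function(cv) {
    spec <- synthetic_study_spec(compounds_default$metoprolol, jitter_cv = 0,
                                 residual_cv = cv, n_replicates = 150,
                                 seed = 77)
    gen <- generate_observed_study(spec, 10, phys_default)
    mean(fold_error(gen$studies$auc_ug_h_ml, gen$truth$auc0t) <= 2)
  }, 0)
  expect_true(all(diff(fractions) <= 0))
  expect_equal(fractions[1], 1)
})

test_that("hepatic CLint is recoverable from oral AUC by simulator inversion", {
  cmp <- compounds_default$metoprolol
  spec <- synthetic_study_spec(cmp, jitter_cv = 0, residual_cv = 0, seed = 3)
  gen <- generate_observed_study(spec, 10, phys_default)
  rec <- recover_clint_from_auc(gen$truth$auc0t, cmp, 10, phys_default)
  expect_lt(abs(rec / cmp$liver_clint$clint - 1), 0.01)
  # monotone inverse: doubling the observed AUC lowers the recovered CLint
  rec2 <- recover_clint_from_auc(2 * gen$truth$auc0t, cmp, 10, phys_default)
  expect_lt(rec2, rec)
  # unreachable AUC is rejected with the bracketing bounds
  expect_error(recover_clint_from_auc(1e6, cmp, 10, phys_default),
               "achievable range")
  # median recovery error under 20% noise stays within 10% (fixed seed)
  spec <- synthetic_study_spec(cmp, jitter_cv = 0, residual_cv = 0.2,
                               n_replicates = 9, seed = 31)
  gen <- generate_observed_study(spec, 10, phys_default)
  errs <- vapply(gen$studies$auc_ug_h_ml, function(a) {
    abs(recover_clint_from_auc(a, cmp, 10, phys_default, grid_step = 0.05) /
          cmp$liver_clint$clint - 1)
  }, 0)
  expect_lt(stats::median(errs), 0.10)
})
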