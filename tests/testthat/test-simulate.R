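test_that("mass balance holds over the fixtures and randomized compounds", {
  for (nm in c("tolbutamide", "omeprazole", "baicalein")) {
    prof <- attr(predict_pk_cached(nm, 10), "profile")
    expect_lt(attr(prof, "mass_imbalance"), 1e-6)
    expect_true(all(prof$conc_ug_ml >= 0))
    expect_equal(prof$conc_ug_ml[1], 0)
  }
  # randomized synthetic compounds, coarse output grid for speed
  for (seed in 1:100) {
    cmp <- suppressWarnings(generate_virtual_compound(seed))
    m <- suppressWarnings(build_model(cmp, phys_default))
    prof <- simulate_oral(m, 10, duration = 12, grid_step = 0.1)
    expect_lt(attr(prof, "mass_imbalance"), 1e-6)
    states <- attr(prof, "states")
    expect_true(all(as.matrix(states[, -1]) > -1e-9))
  }
})

test_that("dose linearity is exact for all-linear models and broken only by
           the saturable gut", {
  # phenacetin's gut Vmax is negligible; doubling dose doubles the profile
  p1 <- attr(predict_pk_cached("tolbutamide", 25), "profile")
  p2 <- attr(predict_pk_cached("tolbutamide", 50), "profile")
  expect_equal(p2$conc_ug_ml, 2 * p1$conc_ug_ml, tolerance = 1e-6)
  # Tmax invariant under dose scaling for linear kinetics
  expect_equal(predict_pk_cached("metoprolol", 2.5)$tmax,
               predict_pk_cached("metoprolol", 10)$tmax, tolerance = 1e-3)
  # omeprazole violates superposition in the supra-proportional direction
  a10 <- predict_pk_cached("omeprazole", 10)$auc0t / 10
  a20 <- predict_pk_cached("omeprazole", 20)$auc0t / 20
  a40 <- predict_pk_cached("omeprazole", 40)$auc0t / 40
  expect_lt(a10, a20)
  expect_lt(a20, a40)
})

test_that("zero dose is rejected and absent gut spec leaves a pure transit
           enterocyte", {
  expect_error(dose_regimen(0))
  m <- build_model(compounds_default$tolbutamide, phys_default)
  expect_null(m$gut)
  expect_equal(m$fg_linear, 1)
  prof <- simulate_oral(m, 50, duration = 6, grid_step = 0.05)
  states <- attr(prof, "states")
  expect_equal(max(states$met_gut), 0)
})

test_that("the ODE system reduces to the Bateman closed form in the
           one-compartment limit", {
  m <- build_model(compounds_default$chlorzoxazone, phys_default)
  # limit: no gut metabolism, instantaneous enterocyte transit, vanishing
  # liver volume, all distribution volume lumped systemically
  m$q_v <- 1e6; m$v_ent <- 1e-5; m$v_liver_p <- 1e-9
  m$v_sys <- m$vss_l; m$gut <- NULL
  prof <- simulate_oral(m, 50, duration = 12, grid_step = 0.01,
                        rtol = 1e-11, atol = 1e-13)
  f_sys <- m$fa * m$hepatic$bioavailability_fraction
  ke <- m$hepatic$cl_plasma / m$vss_l
  bat <- bateman_reference(f_sys, 12.5, m$ka + m$kt, ke, m$vss_l, prof$time_h)
  expect_lt(max(abs(prof$conc_ug_ml - bat$conc_ug_ml)), 1e-6)
})

test_that("Bateman reference has the textbook Tmax and AUC", {
  times <- seq(0, 60, by = 0.005)
  bat <- bateman_reference(1, 1, ka = 2, ke = 1, v = 1, times = times)
  expect_equal(attr(bat, "tmax"), log(2), tolerance = 1e-12)
  auc <- sum(diff(times) * (head(bat$conc_ug_ml, -1) +
                            tail(bat$conc_ug_ml, -1)) / 2)
  expect_equal(auc, 1, tolerance = 1e-4)  # AUCinf = F D / (ke V)
  # ka = ke limiting form peaks at t = 1/ka
  lim <- bateman_reference(1, 1, ka = 2, ke = 2, v = 1, times = times)
  expect_equal(lim$time_h[which.max(lim$conc_ug_ml)], 0.5, tolerance = 0.01)
})

test_that("PK parameter extraction matches hand-computed oracles", {
  tri <- data.frame(time_h = c(0, 1, 2), conc_ug_ml = c(0, 2, 0))
  pk <- pk_parameters(tri)
  expect_equal(pk$cmax, 2)
  expect_equal(pk$tmax, 1)
  expect_equal(pk$auc0t, 2)
  # exponential decay: trapezoid AUC within 1e-4 of the analytic integral
  t <- seq(0, 20, by = 0.01)
  pk <- pk_parameters(data.frame(time_h = t, conc_ug_ml = exp(-t)))
  expect_equal(pk$auc0t, 1 - exp(-20), tolerance = 1e-4)
  # truncation: AUC non-decreasing in the last time
  pk12 <- pk_parameters(data.frame(time_h = t, conc_ug_ml = exp(-t)),
                        auc_last_time = 12)
  expect_lte(pk12$auc0t, pk$auc0t)
  # quadratic refinement recovers an off-grid peak of a smooth curve
  tt <- seq(0, 5, by = 0.25)
  prof <- data.frame(time_h = tt, conc_ug_ml = exp(-(tt - 1.37)^2))
  pk <- pk_parameters(prof)
  expect_equal(pk$tmax, 1.37, tolerance = 0.02)
  expect_warning(pk0 <- pk_parameters(data.frame(time_h = 0:2,
                                                 conc_ug_ml = c(0, 0, 0))),
                 "all-zero")
  expect_equal(pk0$cmax, 0)
})

test_that("simulations are deterministic and the AUC identity links the
           simulator to the clearance algebra", {
  m <- build_model(compounds_default$metoprolol, phys_default)
  p1 <- simulate_oral(m, 10, duration = 24)
  p2 <- simulate_oral(m, 10, duration = 24)
  expect_identical(p1$conc_ug_ml, p2$conc_ug_ml)
  # AUC(0-inf) ~= fa * Fg * Dose / (fu * CLint_u) for linear kinetics
  pk <- pk_parameters(simulate_oral(m, 10, duration = 300, grid_step = 0.05))
  ident <- m$fa * m$fg_linear * 2.5 / (m$fu * m$clint_liver)
  expect_equal(pk$auc0t, ident, tolerance = 0.01)
})
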