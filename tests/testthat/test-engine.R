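# whole-body ODE engine: derivative structure, RK4 integration, events

zero_clearance <- local({
  cl <- ref_clearance
  cl$clu_int_total <- 0
  cl
})

test_that("rhs is zero at the origin and conserves total mass", {
  n <- length(pbpk_rhs(numeric(15), ref_phys, ref_drug, ref_clearance))
  expect_equal(n, 15L)
  expect_equal(unname(pbpk_rhs(numeric(15), ref_phys, ref_drug,
                               ref_clearance)),
               numeric(15))
  # with the eliminated slot included, d(total)/dt = 0 for any state
  set.seed(5)
  for (i in 1:10) {
    x <- runif(15, 0, 1e6)
    d <- pbpk_rhs(x, ref_phys, ref_drug, ref_clearance)
    expect_equal(sum(d), 0, tolerance = 1e-6 * sum(abs(d)))
  }
})

test_that("system matrix reproduces the rhs on arbitrary states", {
  A <- pbpk_matrix(ref_phys, ref_drug, ref_clearance)
  set.seed(6)
  x <- runif(15, 0, 1e6)
  expect_equal(drop(A %*% x),
               unname(pbpk_rhs(x, ref_phys, ref_drug, ref_clearance)),
               tolerance = 1e-12, ignore_attr = TRUE)
  # flow-balance structure: columns of the blood pools sum to zero
  expect_equal(sum(A[, "venous"]), 0, tolerance = 1e-15)
  expect_equal(sum(A[, "arterial"]), 0, tolerance = 1e-15)
})

test_that("propagator-based simulation equals naive stepwise RK4", {
  dt <- 0.5
  regimen <- dose_regimen(40)
  sim <- pbpk_simulate(regimen, ref_phys, ref_drug, ref_clearance,
                       t_end_min = 10, dt = dt)
  # naive RK4 with the pure rhs
  x <- numeric(15)
  names(x) <- colnames(sim$amounts)
  x[["absorption"]] <- ref_drug$fa * 4e7
  naive <- matrix(0, 21, 15)
  naive[1, ] <- x
  f <- function(s) pbpk_rhs(s, ref_phys, ref_drug, ref_clearance)
  for (i in 1:20) {
    k1 <- f(x)
    k2 <- f(x + dt / 2 * k1)
    k3 <- f(x + dt / 2 * k2)
    k4 <- f(x + dt * k3)
    x <- x + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    naive[i + 1, ] <- x
  }
  expect_equal(unname(sim$amounts), unname(naive), tolerance = 1e-12)
})

test_that("mass balance holds at every output time", {
  sim <- pbpk_simulate(dose_regimen(40, n_doses = 3, tau_h = 24),
                       ref_phys, ref_drug, ref_clearance,
                       t_end_min = 96 * 60, dt = 0.5)
  rel <- abs(rowSums(sim$amounts) - sim$input_ng) / max(sim$input_ng)
  expect_lt(max(rel), 1e-6)
  # absorbed amount equals input minus what is left in the gut
  expect_equal(sim$absorbed_ng,
               sim$input_ng - sim$amounts[, "absorption"])
  expect_true(all(sim$plasma_conc_ng_ml >= 0))
})

test_that("a closed system conserves total drug to high precision", {
  sim <- pbpk_simulate(dose_regimen(40), ref_phys, ref_drug,
                       zero_clearance, t_end_min = 24 * 60, dt = 0.5)
  total <- rowSums(sim$amounts)
  expect_lt(max(abs(total - total[1])) / total[1], 1e-10)
  expect_equal(max(sim$amounts[, "eliminated"]), 0)
})

test_that("closed system relaxes to a flow equilibrium", {
  # without elimination every tissue's emergent blood concentration
  # C_T * R / Kp_T converges to the common arterial/venous level
  sim <- pbpk_simulate(dose_regimen(40, route = "iv"), ref_phys, ref_drug,
                       zero_clearance, t_end_min = 14 * 24 * 60, dt = 0.5)
  last <- sim$amounts[nrow(sim$amounts), ]
  c_ven <- last[["venous"]] / ref_phys$venous_blood_volume
  c_art <- last[["arterial"]] / ref_phys$arterial_blood_volume
  expect_equal(c_art, c_ven, tolerance = 1e-6)
  for (t in pbpk_tissues()) {
    v <- ref_phys$tissues$volume_ml[ref_phys$tissues$name == t]
    c_t <- last[[t]] / v * ref_drug$blood_plasma_ratio / ref_drug$kp[[t]]
    expect_equal(c_t, c_ven, tolerance = 1e-4, label = t)
  }
})

test_that("concentrations scale exactly with dose (linear kinetics)", {
  s1 <- pbpk_simulate(dose_regimen(20), ref_phys, ref_drug, ref_clearance,
                      t_end_min = 1440, dt = 0.5)
  s2 <- pbpk_simulate(dose_regimen(40), ref_phys, ref_drug, ref_clearance,
                      t_end_min = 1440, dt = 0.5)
  expect_equal(2 * s1$plasma_conc_ng_ml, s2$plasma_conc_ng_ml,
               tolerance = 1e-12)
})

test_that("independent stiff solver reproduces the plasma curve", {
  skip_if_not_installed("deSolve")
  A <- pbpk_matrix(ref_phys, ref_drug, ref_clearance)
  x0 <- numeric(15)
  x0[1] <- ref_drug$fa * 4e7
  out <- deSolve::ode(y = x0, times = seq(0, 1440, by = 10),
                      func = function(t, y, p) list(drop(A %*% y)),
                      parms = NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-4)
  sim <- pbpk_simulate(dose_regimen(40), ref_phys, ref_drug,
                       ref_clearance, t_end_min = 1440, dt = 0.5)
  idx <- match(seq(0, 1440, by = 10), sim$time_min)
  mine <- sim$amounts[idx, "venous"]
  oracle <- out[, 14] # column 1 is time, venous amount is state 13
  expect_equal(mine, oracle, tolerance = 1e-5, ignore_attr = TRUE)
})

test_that("IV bolus enters the venous pool at full dose", {
  sim <- pbpk_simulate(dose_regimen(40, route = "iv"), ref_phys, ref_drug,
                       ref_clearance, t_end_min = 60, dt = 0.5)
  expect_equal(unname(sim$amounts[1, "venous"]), 4e7)
  expect_equal(sim$plasma_conc_ng_ml[1],
               4e7 / ref_phys$venous_blood_volume /
                 ref_drug$blood_plasma_ratio)
  # oral dosing is attenuated by Fa before entering the gut
  sim_po <- pbpk_simulate(dose_regimen(40), ref_phys, ref_drug,
                          ref_clearance, t_end_min = 60, dt = 0.5)
  expect_equal(unname(sim_po$amounts[1, "absorption"]), ref_drug$fa * 4e7)
})

test_that("node-wise fast path matches full-grid sampling", {
  times <- c(15, 30, 60, 240, 720, 1440, 2000, 2880)
  regimen <- dose_regimen(40, n_doses = 2, tau_h = 24)
  fast <- pbpk_plasma_at(times, regimen, ref_phys, ref_drug,
                         ref_clearance, dt = 0.5)
  sim <- pbpk_simulate(regimen, ref_phys, ref_drug, ref_clearance,
                       t_end_min = 2880, dt = 0.5)
  expect_equal(fast, sim$plasma_conc_ng_ml[match(times, sim$time_min)],
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("step-halving convergence check flags coarse steps", {
  ok <- convergence_check(dose_regimen(40), ref_phys, ref_drug,
                          ref_clearance, t_end_min = 1440, dt = 0.5)
  expect_lt(ok$max_rel_dev, 1e-3)
  expect_false(ok$flagged)
  # a 60-min step is far beyond the explicit integrator's stability limit
  bad <- suppressWarnings(
    convergence_check(dose_regimen(40), ref_phys, ref_drug,
                      ref_clearance, t_end_min = 1440, dt = 60))
  expect_true(bad$flagged)
})

test_that("simulation guards its inputs", {
  expect_error(pbpk_simulate(dose_regimen(40, n_doses = 2, tau_h = 24),
                             ref_phys, ref_drug, ref_clearance,
                             t_end_min = 1000), "precedes")
  expect_error(pbpk_simulate(dose_regimen(40), ref_phys, ref_drug,
                             ref_clearance, t_end_min = 100, dt = -1),
               "dt")
})
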