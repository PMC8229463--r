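# domain types, built-in parameter tables, config and CSV round-trips

test_that("default physiology reproduces the reference tissue table", {
  expect_equal(ref_phys$tissues$name, ref_table1$name)
  expect_equal(ref_phys$tissues$volume_ml, ref_table1$volume_ml)
  expect_equal(ref_phys$tissues$blood_flow_ml_min,
               ref_table1$blood_flow_ml_min)
  expect_equal(ref_phys$venous_blood_volume, 3470)
  expect_equal(ref_phys$arterial_blood_volume, 1730)
  expect_equal(ref_phys$cardiac_output, 5200)
  expect_equal(ref_phys$hematocrit, 0.45)
})

test_that("residual flow closes the arterial flow balance", {
  # Q_RE = Q_CO - (adipose + adrenal + brain + heart + kidney + liver)
  expect_equal(ref_phys$q_residual,
               5200 - (270 + 15.6 + 593 + 208 + 910 + 1326))
  sys <- c("adipose", "adrenal_gland", "brain", "heart", "kidney", "liver")
  q_sys <- sum(ref_phys$tissues$blood_flow_ml_min[
    ref_phys$tissues$name %in% sys])
  expect_equal(ref_phys$q_residual + q_sys, ref_phys$cardiac_output,
               tolerance = 1e-12)
})

test_that("physiology validation names the offending field", {
  bad <- ref_table1
  bad$blood_flow_ml_min[bad$name == "kidney"] <- -1
  expect_error(
    physiology_set(bad, 3470, 1730, 5200, 0.45),
    "kidney")
  expect_error(
    physiology_set(ref_table1[ref_table1$name != "liver", ],
                   3470, 1730, 5200, 0.45),
    "liver")
  expect_error(physiology_set(ref_table1, 3470, 1730, 5200, 1.2),
               "hematocrit")
  # residual flow must be non-negative
  expect_error(physiology_set(ref_table1, 3470, 1730, 3000, 0.45),
               "lung|residual")
})

test_that("default drug parameters carry the reference values", {
  expect_equal(ref_drug$fup, 0.0645)
  expect_equal(ref_drug$blood_plasma_ratio, 0.8)
  expect_equal(ref_drug$ka, 0.0606)
  expect_equal(ref_drug$fa, 0.761)
  expect_equal(ref_drug$fu_mic, 0.904)
  expect_equal(ref_drug$clu_add, 12900)
  ep <- ref_drug$enzyme_pathways
  expect_equal(ep$vmax_nmol_min[ep$label == "M14"], 248)
  expect_equal(ep$km_um[ep$label == "M14"], 0.093)
  expect_equal(ep$vmax_nmol_min[ep$label == "M11"], 800)
  expect_equal(ep$km_um[ep$label == "M11"], 15.95)
  expect_equal(unname(ref_drug$kp["stomach"]), 193)
  expect_equal(unname(ref_drug$kp["adrenal_gland"]), 20.8)
  expect_equal(unname(ref_drug$kp["liver"]), 303)
  expect_equal(unname(ref_drug$kp["small_intestine"]), 124)
})

test_that("drug parameter validation rejects out-of-range values", {
  expect_error(load_drug_parameters(list(
    fup = 1.5, blood_plasma_ratio = 0.8, ka = 0.06, fa = 0.7,
    fu_mic = 0.9, clu_add = 100,
    enzyme_pathways = data.frame(label = "X", vmax_nmol_min = 1,
                                 km_um = 1),
    kp = ref_drug$kp)), "fup")
  expect_error(drug_parameters(
    fup = 0.1, blood_plasma_ratio = 0.8, ka = 0.06, fa = 0.7,
    fu_mic = 0.9, clu_add = 100,
    enzyme_pathways = data.frame(label = "X", vmax_nmol_min = 1,
                                 km_um = 1),
    kp = c(ref_drug$kp[-1], nonsense = 2)), "unknown tissue|tissue")
})

test_that("rat Kp table and preclinical Vss points match the fixtures", {
  kp <- rat_kp_ss()
  expect_equal(unname(kp["liver"]), 417)
  expect_equal(unname(kp["small_intestine"]), 637)
  expect_equal(unname(kp["adrenal_gland"]), 56.1)
  expect_equal(length(kp), 11L)
  pv <- preclinical_vss()
  expect_equal(pv$vss_l_per_kg, c(20.2, 9.17, 12.6))
  expect_equal(pv$bw_kg, c(0.25, 4, 10))
})

test_that("physiology and drug configs round-trip through YAML", {
  pf <- tempfile(fileext = ".yaml")
  write_physiology(ref_phys, pf)
  back <- load_physiology(pf)
  expect_equal(back$tissues$volume_ml, ref_phys$tissues$volume_ml)
  expect_equal(back$q_residual, ref_phys$q_residual)

  df <- tempfile(fileext = ".yaml")
  write_drug_parameters(ref_drug, df)
  back_d <- load_drug_parameters(df)
  expect_equal(back_d$kp, ref_drug$kp)
  expect_equal(back_d$clu_add, ref_drug$clu_add)
  expect_equal(back_d$enzyme_pathways, ref_drug$enzyme_pathways)
  # L/min accepted at the config boundary
  cfg <- yaml::read_yaml(df)
  cfg$clu_add <- NULL
  cfg$clu_add_l_min <- 12.9
  expect_equal(load_drug_parameters(cfg)$clu_add, 12900)
})

test_that("concentration tables round-trip and reject malformed input", {
  s1 <- conc_time_series("a", 40, c(10, 20, 30), c(1.25, 2.5, 0.125))
  s2 <- conc_time_series("b", 80, c(15, 45), c(3.75, 1.875))
  path <- tempfile(fileext = ".csv")
  write_conc_table(list(s1, s2), path)
  back <- read_conc_table(path)
  expect_length(back, 2L)
  expect_equal(back[[1]]$conc_ng_ml, s1$conc_ng_ml)
  expect_equal(back[[2]]$times_min, s2$times_min)
  expect_equal(back[[2]]$dose_mg, 80)

  # shuffled times are rejected with a row reference
  lines <- readLines(path)
  writeLines(lines[c(1, 3, 2, 4:6)], path)
  expect_error(read_conc_table(path), "row")

  # unparseable number
  writeLines(c("subject_id,dose_mg,time_min,conc_ng_per_ml",
               "a,40,10,oops"), path)
  expect_error(read_conc_table(path), "unparseable")
})

test_that("dose regimens validate ordering, sign and route", {
  r <- dose_regimen(40, n_doses = 3, tau_h = 24)
  expect_equal(r$time_min, c(0, 1440, 2880))
  expect_equal(r$amount_ng, rep(4e7, 3))
  expect_error(dose_regimen(-1), "positive")
  expect_error(regimen_events(data.frame(time_min = c(0, 0),
                                         route = "po",
                                         amount_ng = 1e6)),
               "strictly increasing")
  expect_error(regimen_events(data.frame(time_min = 0, route = "im",
                                         amount_ng = 1e6)), "route")
})
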