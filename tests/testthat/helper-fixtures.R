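# shared fixtures built in code

ref_phys <- default_physiology()
ref_drug <- default_drug_parameters()
ref_clearance <- build_clu_int(ref_drug)

# reference tissue volume/flow cells of the default physiology
ref_table1 <- data.frame(
  name = c("adipose", "adrenal_gland", "brain", "heart", "kidney",
           "large_intestine", "liver", "lung", "small_intestine",
           "spleen", "stomach"),
  volume_ml = c(15000, 14, 1400, 329, 308, 371, 1800, 532, 520, 182, 147),
  blood_flow_ml_min = c(270, 15.6, 593, 208, 910, 208, 1326, 5200, 520,
                        104, 52),
  stringsAsFactors = FALSE
)

# a short noiseless simulated subject, reused by fitting tests
noiseless_subject <- function(dose_mg = 40, fa = 0.761,
                              clu_add = 12900,
                              times_min = c(15, 30, 60, 90, 120, 180,
                                            240, 360, 480, 720, 1440)) {
  d <- ref_drug
  d$fa <- fa
  d$clu_add <- clu_add
  conc <- pbpk_plasma_at(times_min, dose_regimen(dose_mg), ref_phys, d,
                         clearance = build_clu_int(d))
  conc_time_series("truth", dose_mg, times_min, conc)
}
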