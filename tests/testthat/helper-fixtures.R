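# Shared fixtures, built in code.

# a variance-free design: test and retest scans are identical
quiet_design <- function(n_subjects = 2,
                         region_ki_map = c(pons = 0.0119, cerebellum = 0.0159,
                                           putamen = 0.0198),
                         ...) {
  study_design(n_subjects = n_subjects, region_ki_map = region_ki_map,
               sigma_inter = 0, sigma_intra = 0, global_scale_cv = 0,
               region_scale_cv = 0, noise_cv = 0, glycemia_sd = 0,
               venous_resid_sd = 0, dose_sd = 0, weight_sd = 0, ...)
}

# a deterministic single scan's worth of inputs for quantification tests
flat_scan <- function(suv_levels = c(pons = 2, cerebellum = 2, putamen = 2),
                      dose = 180, weight = 6, gly = 4.5) {
  sch <- default_frame_schedule()
  ratio <- dose / weight  # kBq/mL at SUV 1
  tacs <- do.call(rbind, lapply(names(suv_levels), function(r)
    new_tac(r, sch, rep(suv_levels[[r]] * ratio, nrow(sch)))))
  aif <- new_aif(default_blood_times(),
                 rep(ratio, length(default_blood_times())))
  meta <- scan_meta("s1", "test", dose, weight, gly)
  list(tacs = tacs, aif = aif, meta = meta)
}

# memoised heavy Monte-Carlo runs shared by the acceptance blocks
.mc_cache <- new.env(parent = emptyenv())

default_mc <- function(n = 200, seed = 1000) {
  key <- sprintf("default_%d_%d", n, seed)
  if (is.null(.mc_cache[[key]]))
    .mc_cache[[key]] <- replicate_studies(study_design(), n, seed = seed,
                                          robustness_n = 4)
  .mc_cache[[key]]
}

recovery_mc <- function(n = 200, seed = 2000) {
  key <- sprintf("recovery_%d_%d", n, seed)
  if (is.null(.mc_cache[[key]])) {
    des <- study_design(sigma_intra = 0.18, sigma_inter = 0.15,
                        global_scale_cv = 0, region_scale_cv = 0, noise_cv = 0,
                        glycemia_sd = 0, dose_sd = 0, weight_sd = 0,
                        region_ki_map = c(pons = 0.0119, cerebellum = 0.0159,
                                          frontal_cortex = 0.0199))
    .mc_cache[[key]] <- replicate_studies(des, n, seed = seed)
  }
  .mc_cache[[key]]
}
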