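test_that("AIF model peaks where calibrated and honours its limits", {
  m <- aif_model()
  expect_gt(aif_peak_time(m), 0.5)
  expect_lt(aif_peak_time(m), 1.0)
  expect_equal(aif_peak_time(m), 0.73, tolerance = 0.05)

  # zero before appearance, non-negative everywhere
  t <- seq(0, 60, by = 0.01)
  v <- aif_value(m, t)
  expect_true(all(v >= 0))
  expect_identical(unique(v[t < m$appearance_delay]), 0)

  # bolus-only limit: single mode, vanishing late activity
  mb <- aif_model(tail_fractions = c(0, 0), bolus_amplitude = 1)
  vb <- aif_value(mb, t)
  peak_idx <- which.max(vb)
  expect_true(all(diff(vb[1:peak_idx]) >= 0))
  expect_true(all(diff(vb[peak_idx:length(vb)]) <= 0))
  expect_lt(vb[length(vb)], 1e-4 * max(vb))

  expect_error(aif_model(tail_rates = c(0.3, -1)), class = "fdgrepeat_input_error")
  expect_error(simulate_aif(m, c(2, 1, 3), dose = 170, weight = 5),
               class = "fdgrepeat_input_error")
  expect_error(simulate_aif(m, c(-1, 0, 1), dose = 170, weight = 5),
               class = "fdgrepeat_input_error")
})

test_that("sampled AIF reproduces the target SUV-unit exposure", {
  m <- aif_model()
  t <- seq(0, 60, by = 0.001)
  v <- aif_value(m, t)
  dense_auc <- sum((v[-1] + v[-length(v)]) / 2) * 0.001
  expect_equal(dense_auc, m$target_exposure, tolerance = 1e-3)

  aif <- simulate_aif(m, dose = 169.2, weight = 5.8)
  meta <- scan_meta("a", "test", 169.2, 5.8, 4.5)
  # schedule-sampled trapezoid within 3% of the fine-grid quadrature
  expect_equal(plasma_exposure(aif, meta), dense_auc, tolerance = 0.03)
  # exposure in SUV units does not depend on dose or weight
  aif2 <- simulate_aif(m, dose = 300, weight = 4)
  meta2 <- scan_meta("b", "test", 300, 4, 4.5)
  expect_equal(plasma_exposure(aif2, meta2), plasma_exposure(aif, meta))
  # a per-session scale multiplies the exposure linearly
  aif3 <- simulate_aif(m, dose = 169.2, weight = 5.8, scale = 1.2)
  expect_equal(plasma_exposure(aif3, meta), 1.2 * plasma_exposure(aif, meta))
})

test_that("2TCM forward model matches the closed-form single-exponential solution", {
  td <- seq(0, 60, by = 0.01)
  lam <- 0.0114
  K1 <- 0.10; k2 <- 0.13; k3 <- 0.016; a <- k2 + k3
  cp <- exp(-lam * td)
  ct <- tissue_curve(kinetic_params(K1, k2, k3), td, cp)
  C1 <- K1 * (exp(-lam * td) - exp(-a * td)) / (a - lam)
  C2 <- k3 * K1 / (a - lam) * ((1 - exp(-lam * td)) / lam - (1 - exp(-a * td)) / a)
  expect_equal(ct, C1 + C2, tolerance = 1e-6)

  # trapped compartment never decreases
  expect_true(all(diff(C2) >= 0))

  # constant input: late slope of Ct/c converges to Ki
  ctc <- tissue_curve(kinetic_params(K1, k2, k3), td, rep(2, length(td)))
  late <- (ctc[6001] - ctc[5001]) / 10 / 2
  expect_equal(late, K1 * k3 / (k2 + k3), tolerance = 0.01)

  # no trapping: tissue reduces to the reversible free compartment
  ct0 <- tissue_curve(kinetic_params(K1, k2, 1e-12), td, cp)
  C1_free <- K1 * (exp(-lam * td) - exp(-k2 * td)) / (k2 - lam)
  expect_equal(ct0, C1_free, tolerance = 1e-6)

  expect_error(tissue_curve(kinetic_params(K1, k2, k3), seq(0, 60, by = 0.02),
                            rep(1, 3001)),
               class = "fdgrepeat_config_error")
})

test_that("frame binning averages correctly and conserves the integral", {
  sch <- default_frame_schedule()
  expect_identical(nrow(sch), 21L)
  expect_identical(max(sch$end_s), 3600)
  expect_identical(nrow(default_frame_schedule(120)), 27L)

  td <- seq(0, 60, by = 0.005)
  # constant curve: every frame equals the constant
  tac_c <- bin_to_frames(td, rep(5, length(td)), sch)
  expect_equal(tac_c$activity_kbq_per_ml, rep(5, 21))
  # linear curve: frame value is the frame midpoint
  tac_l <- bin_to_frames(td, td, sch)
  expect_equal(tac_l$activity_kbq_per_ml, frame_midpoints_min(sch), tolerance = 1e-9)

  # integral conservation to < 0.1%
  ct <- sqrt(td) * exp(-td / 40)
  tac <- bin_to_frames(td, ct, sch)
  binned <- sum(tac$activity_kbq_per_ml * frame_durations_s(sch) / 60)
  dense <- sum((ct[-1] + ct[-length(ct)]) / 2 * 0.005)
  expect_equal(binned, dense, tolerance = 1e-3)

  expect_error(bin_to_frames(seq(0, 30, by = 0.005), rep(1, 6001), sch),
               class = "fdgrepeat_input_error")
  expect_error(frame_schedule(c(0, 20), c(15, 30)), class = "fdgrepeat_input_error")
  expect_error(frame_schedule(c(5, 15), c(15, 30)), class = "fdgrepeat_input_error")
})

test_that("frame noise has the nominal CV, clips at zero, and 0 is the identity", {
  sch <- default_frame_schedule()
  tac <- new_tac("r", sch, rep(10, nrow(sch)))
  expect_identical(add_measurement_noise(tac, 0), tac)
  expect_error(add_measurement_noise(tac, -0.1), class = "fdgrepeat_input_error")

  # Monte-Carlo: empirical CV of the longest frame within 10% of nominal
  set.seed(42)
  last <- replicate(1e4, add_measurement_noise(tac, 0.05)$activity_kbq_per_ml[21])
  expect_equal(sd(last) / mean(last), 0.05, tolerance = 0.1)

  # short frames are noisier by sqrt(duration ratio)
  first <- replicate(1e4, add_measurement_noise(tac, 0.05)$activity_kbq_per_ml[1])
  expect_equal(sd(first) / mean(first), 0.05 * sqrt(600 / 15), tolerance = 0.1)

  # clipping: huge noise never yields negative activity
  set.seed(1)
  big <- add_measurement_noise(tac, 5)
  expect_true(all(big$activity_kbq_per_ml >= 0))
})

test_that("glycemia generator reproduces its moments and the arterio-venous link", {
  des0 <- study_design(venous_slope = 1, venous_resid_sd = 0)
  set.seed(7)
  g0 <- simulate_glycemia(des0, 24)
  expect_equal(g0$venous, g0$arterial)
  expect_equal(spearman_cor(g0$arterial, g0$venous)$rho, 1)

  set.seed(11)
  g <- simulate_glycemia(study_design(), 2000)
  expect_equal(mean(g$arterial), 4.5, tolerance = 3 * 0.7 / sqrt(2000) / 4.5)
  expect_true(all(g$arterial > 0.5))

  # default link: median Spearman rho across replicate cohorts >= 0.9
  set.seed(13)
  rhos <- replicate(40, {
    gg <- simulate_glycemia(study_design(), 24)
    spearman_cor(gg$arterial, gg$venous)$rho
  })
  expect_gte(median(rhos), 0.9)
})

test_that("study simulation is deterministic and exact in the no-variance limit", {
  des <- quiet_design()
  s1 <- simulate_study(des)
  s2 <- simulate_study(des)
  expect_identical(s1, s2)
  # with stochastic components active, the seed drives the data
  noisy <- study_design(n_subjects = 2,
                        region_ki_map = c(pons = 0.0119, cerebellum = 0.0159))
  expect_false(identical(simulate_study(noisy, seed = 98L)$tacs,
                         simulate_study(noisy, seed = 99L)$tacs))
  expect_identical(simulate_study(noisy, seed = 98L),
                   simulate_study(noisy, seed = 98L))

  # truth covers every scan x region
  expect_identical(nrow(s1$truth),
                   des$n_subjects * des$n_sessions * length(des$region_ki_map))
  expect_true(all(s1$truth$Ki < des$K1))

  # no variance components: test and retest quantifications identical
  q <- quantify_study(s1)
  pairs <- paired_values(q)
  expect_equal(pairs$test_value, pairs$retest_value, tolerance = 1e-12)
  d <- decompose_variability(q)
  expect_equal(d$absvar_mean, rep(0, nrow(d)), tolerance = 1e-9)
})
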