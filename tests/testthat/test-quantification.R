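test_that("trapezoidal AUC handles rectangles, triangles and the leading segment", {
  expect_equal(integrate_trapezoid(c(0, 60), c(2, 2), 60), 120)
  expect_equal(integrate_trapezoid(c(0, 1, 2), c(0, 2, 0), 2), 2)
  # first sample after t = 0: linear rise from (0, 0) is prepended
  expect_equal(integrate_trapezoid(c(1, 2), c(2, 0), 2), 2)
  # partial end segment by interpolation
  expect_equal(integrate_trapezoid(c(0, 2), c(2, 2), 1), 2)
  expect_error(integrate_trapezoid(c(0, 2), c(1, 1), 3),
               class = "fdgrepeat_input_error")
})

test_that("SUV normalization follows the dose-per-weight definition", {
  meta <- list(injected_dose = 185, body_weight = 5)
  expect_equal(normalize_to_suv(37, meta), 1.0)
  # activity equal to dose/weight concentration gives SUV 1
  expect_equal(normalize_to_suv(180 / 6, list(injected_dose = 180, body_weight = 6)), 1)
  # doubling the dose alone halves SUV; doubling activity with it restores it
  expect_equal(normalize_to_suv(37, list(injected_dose = 370, body_weight = 5)), 0.5)
  expect_equal(normalize_to_suv(74, list(injected_dose = 370, body_weight = 5)), 1.0)
  expect_error(normalize_to_suv(1, list(injected_dose = 0, body_weight = 5)),
               class = "fdgrepeat_input_error")
})

test_that("plasma exposure integrates the SUV-normalized input function", {
  fx <- flat_scan()
  expect_equal(plasma_exposure(fx$aif, fx$meta), 60)
  zero <- new_aif(c(0, 10, 30, 60), rep(0, 4))
  expect_equal(plasma_exposure(zero, fx$meta), 0)
  short <- new_aif(c(0, 10, 20, 40), c(1, 1, 1, 1))
  expect_error(plasma_exposure(short, fx$meta), class = "fdgrepeat_input_error")
})

test_that("plateau SUV is the duration-weighted mean over the 30-60 min window", {
  sch <- frame_schedule(c(0, 1800, 2400), c(1800, 2400, 3600))
  meta <- scan_meta("s", "test", 180, 6, 4.5)
  ratio <- 180 / 6
  # frames at 30-40 min (SUV 2) and 40-60 min (SUV 3): (10*2 + 20*3)/30
  tac <- new_tac("r", sch, c(9 * ratio, 2 * ratio, 3 * ratio))
  expect_equal(suv_plateau(tac, meta), (10 * 2 + 20 * 3) / 30)

  # constant plateau returns the normalized constant
  tac_c <- new_tac("r", sch, rep(2.5 * ratio, 3))
  expect_equal(suv_plateau(tac_c, meta), 2.5)

  # a frame ending exactly at 30 min (midpoint < 30) is excluded
  sch2 <- frame_schedule(c(0, 1200, 1800), c(1200, 1800, 3600))
  tac2 <- new_tac("r", sch2, c(9, 9, 2 * ratio) )
  expect_equal(suv_plateau(tac2, meta), 2)
  # and if no frame qualifies, an error is raised
  sch3 <- frame_schedule(0, 1800)
  expect_error(suv_plateau(new_tac("r", sch3, 1), meta),
               class = "fdgrepeat_input_error")
})

test_that("Patlak transform identities hold exactly", {
  sch <- default_frame_schedule()
  mids <- frame_midpoints_min(sch)
  bt <- default_blood_times()
  # constant input: x(T) = T
  aif_c <- new_aif(bt, rep(3, length(bt)))
  tac <- new_tac("r", sch, rep(1, 21))
  pts <- patlak_points(tac, aif_c)
  expect_equal(pts$x, mids, tolerance = 1e-9)

  # pure trapping, Ct = kappa * integral of Cp: exact line through origin
  t <- bt
  cp <- 5 * exp(-0.05 * t)
  aif <- new_aif(t, cp)
  cumgrid <- c(0, cumsum((cp[-1] + cp[-length(cp)]) / 2 * diff(t)))
  cum <- approx(t, cumgrid, xout = mids)$y
  tac2 <- new_tac("r", sch, 0.01 * cum)
  pts2 <- patlak_points(tac2, aif)
  fit <- patlak_fit(pts2)
  expect_equal(fit$Ki, 0.01, tolerance = 1e-9)
  expect_equal(fit$intercept, 0, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1)

  expect_error(patlak_points(tac, new_aif(c(0, 5, 20, 40), rep(1, 4))),
               class = "fdgrepeat_input_error")
})

test_that("Patlak OLS fit recovers exact lines and enforces its contract", {
  x <- c(35, 40, 45, 50, 55)
  pts <- data.frame(t_mid = x, x = x, y = 0.012 * x + 0.5)
  fit <- patlak_fit(pts)
  expect_equal(fit$Ki, 0.012)
  expect_equal(fit$intercept, 0.5)
  expect_equal(fit$r_squared, 1)
  expect_identical(fit$n_points, 5L)

  expect_error(patlak_fit(pts[1:2, ]), class = "fdgrepeat_input_error")
  same_x <- data.frame(t_mid = c(35, 45, 55), x = rep(2, 3), y = 1:3)
  expect_error(patlak_fit(same_x), class = "fdgrepeat_input_error")
})

test_that("CMRglu formula, defaults and error paths", {
  meta <- scan_meta("a", "test", 170, 5.8, glycemia_arterial = 4.5)
  expect_equal(cmrglu(list(Ki = 0.01511), meta), 20.0, tolerance = 1e-3)
  expect_equal(cmrglu(list(Ki = 0), meta), 0)
  # linear in glycemia and Ki; halving LC doubles the value
  m2 <- scan_meta("a", "test", 170, 5.8, glycemia_arterial = 9.0)
  expect_equal(cmrglu(list(Ki = 0.01511), m2) / cmrglu(list(Ki = 0.01511), meta),
               2, tolerance = 1e-9)
  expect_equal(cmrglu(list(Ki = 0.01511), meta, quant_config(lumped_constant = 0.17)),
               2 * cmrglu(list(Ki = 0.01511), meta))
  # venous source requested but absent
  expect_error(cmrglu(list(Ki = 0.01), meta,
                      quant_config(glycemia_source = "venous")),
               class = "fdgrepeat_input_error")
})

test_that("scan quantification: SUVR structure, products and invariances", {
  des <- quiet_design()
  st <- simulate_study(des)
  q <- quantify_study(st)

  # homogeneous SUV levels: every SUVR equals 1 (flat-scan SUVs are equal)
  suv_vals <- q[q$parameter == "suv" & q$session == "test" &
                q$subject_id == "S01", ]
  suvr_p <- q[q$parameter == "suvr_pons" & q$session == "test" &
              q$subject_id == "S01", ]
  expect_equal(suvr_p$value[suvr_p$region == "putamen"],
               suv_vals$value[suv_vals$region == "putamen"] /
               suv_vals$value[suv_vals$region == "pons"])
  # self-ratio is omitted from the long table
  expect_false(any(q$parameter == "suvr_pons" & q$region == "pons"))

  # SUV x Gly is the literal product
  gly <- st$meta$glycemia_arterial_mmol_l[1]
  sg <- q[q$parameter == "suv_gly" & q$session == "test" & q$subject_id == "S01", ]
  expect_equal(sg$value[sg$region == "putamen"],
               suv_vals$value[suv_vals$region == "putamen"] * gly)

  # regional rank order of CMRglu follows the design Ki map
  cm <- q[q$parameter == "cmrglu" & q$session == "test" & q$subject_id == "S01", ]
  expect_identical(cm$region[order(cm$value)],
                   names(sort(des$region_ki_map)))

  # missing reference region
  tacs_nr <- st$tacs[st$tacs$region != "pons", ]
  bl <- st$blood[st$blood$subject_id == "S01" & st$blood$session == "test", ]
  aif <- new_aif(bl$time_min, bl$plasma_kbq_per_ml)
  meta <- scan_meta("S01", "test", st$meta$injected_dose_mbq[1],
                    st$meta$body_weight_kg[1], gly)
  expect_error(quantify_scan(tacs_nr[tacs_nr$subject_id == "S01" &
                                     tacs_nr$session == "test", ], aif, meta),
               class = "fdgrepeat_input_error")

  # SUVR is invariant to a global scan-scale factor; SUV is not
  scan_tacs <- st$tacs[st$tacs$subject_id == "S01" & st$tacs$session == "test", ]
  q1 <- quantify_scan(scan_tacs, aif, meta)
  scan_tacs2 <- scan_tacs
  scan_tacs2$activity_kbq_per_ml <- scan_tacs2$activity_kbq_per_ml * 1.3
  aif2 <- new_aif(aif$time_min, aif$plasma_kbq_per_ml * 1.3)
  q2 <- quantify_scan(scan_tacs2, aif2, meta)
  expect_equal(q2$params$suvr_pons, q1$params$suvr_pons, tolerance = 1e-9)
  expect_equal(q2$params$suv, 1.3 * q1$params$suv, tolerance = 1e-9)
})
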