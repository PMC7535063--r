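#' Default regional net-influx (Ki) map
#'
#' Reference Ki values (1/min) for ten macaque brain regions, calibrated so
#' that CMRglu = Ki x glycemia / LC x 100 lands in the 15-27 umol/min/100 g
#' range at the default glycemia (4.5 mmol/L) and lumped constant (0.34),
#' with the regional rank order seen in healthy cynomolgus FDG data:
#' highest in caudate, putamen and frontal cortex, lowest in the pons.
#'
#' @return named numeric vector of Ki (1/min).
#' @export
default_region_ki <- function() {
  c(thalamus        = 0.0156,
    globus_pallidum = 0.0147,
    caudate         = 0.0188,
    putamen         = 0.0198,
    cortex          = 0.0147,
    midbrain        = 0.0154,
    pons            = 0.0119,
    cerebellum      = 0.0159,
    frontal_cortex  = 0.0199,
    occipital_cortex = 0.0128)
}

#' Test-retest study design for the synthetic FDG generator
#'
#' Collects every knob of the synthetic study generator: cohort size,
#' regional kinetics, the separable intra-/inter-subject variance
#' components, plasma-exposure scaling, glycemia, dosimetry and frame
#' noise. Defaults emulate a standardized test-retest FDG protocol in six
#' cynomolgus macaques (two sessions each).
#'
#' Variance components (all multiplicative / lognormal, so positivity is
#' preserved):
#' \itemize{
#'   \item `sigma_inter`: log-scale SD of the subject effect on Ki.
#'   \item `sigma_intra`: log-scale SD of the session effect on Ki, common
#'     to all regions of a scan (a global, not regional, test-retest
#'     difference; it cancels in reference-region ratios).
#'   \item `global_scale_cv`: CV of the per-session plasma exposure scale
#'     (affects AIF and, through the kinetics, all tissue curves).
#'   \item `region_scale_cv`: CV of a per-scan, per-region multiplicative
#'     factor emulating ROI delineation and residual co-registration
#'     variability (the component that does not cancel in SUVR).
#'   \item `noise_cv`: frame-level measurement CV on the longest frame.
#' }
#'
#' @param n_subjects number of subjects, >= 1.
#' @param n_sessions 2 for test-retest, 1 for a single-scan group.
#' @param region_ki_map named Ki vector; must include pons and cerebellum.
#' @param sigma_inter,sigma_intra log-scale SDs, >= 0.
#' @param global_scale_cv,region_scale_cv,noise_cv unitless CVs, >= 0.
#' @param glycemia_mean,glycemia_sd arterial glycemia (mmol/L).
#' @param venous_slope,venous_resid_sd venous = slope x arterial + noise.
#' @param dose_mean,dose_sd injected dose (MBq).
#' @param weight_mean,weight_sd body weight (kg).
#' @param K1,k2 fixed rate constants tying regional k3 to the Ki map.
#' @param vB blood volume fraction used in the forward model.
#' @param aif an [aif_model()].
#' @param frame_schedule a [frame_schedule()].
#' @param blood_times arterial sampling times (min).
#' @param dense_dt_min forward-model grid step (min), <= 0.01.
#' @param rng_seed integer seed making the whole study reproducible.
#' @return A `study_design` list.
#' @export
study_design <- function(n_subjects = 6,
                         n_sessions = 2,
                         region_ki_map = default_region_ki(),
                         sigma_inter = 0.10,
                         sigma_intra = 0.18,
                         global_scale_cv = 0.145,
                         region_scale_cv = 0.06,
                         noise_cv = 0.04,
                         glycemia_mean = 4.5,
                         glycemia_sd = 0.7,
                         venous_slope = 0.972,
                         venous_resid_sd = 0.25,
                         dose_mean = 169.2,
                         dose_sd = 9.0,
                         weight_mean = 5.8,
                         weight_sd = 1.1,
                         K1 = 0.10,
                         k2 = 0.13,
                         vB = 0,
                         aif = aif_model(),
                         frame_schedule = default_frame_schedule(),
                         blood_times = default_blood_times(),
                         dense_dt_min = 0.01,
                         rng_seed = 20201005L) {
  if (n_subjects < 1) stop_input("n_subjects must be >= 1")
  if (!n_sessions %in% c(1L, 2L)) stop_input("n_sessions must be 1 or 2")
  if (is.null(names(region_ki_map)) ||
      !all(c("pons", "cerebellum") %in% names(region_ki_map)))
    stop_input("region_ki_map must be named and include pons and cerebellum")
  sds <- c(sigma_inter, sigma_intra, global_scale_cv, region_scale_cv, noise_cv,
           glycemia_sd, venous_resid_sd, dose_sd, weight_sd)
  if (any(sds < 0)) stop_input("all SD/CV components must be >= 0")
  if (any(region_ki_map <= 0) || any(region_ki_map >= K1))
    stop_input("every regional Ki must lie in (0, K1)")
  structure(list(n_subjects = as.integer(n_subjects),
                 n_sessions = as.integer(n_sessions),
                 region_ki_map = region_ki_map,
                 sigma_inter = sigma_inter, sigma_intra = sigma_intra,
                 global_scale_cv = global_scale_cv,
                 region_scale_cv = region_scale_cv,
                 noise_cv = noise_cv,
                 glycemia_mean = glycemia_mean, glycemia_sd = glycemia_sd,
                 venous_slope = venous_slope, venous_resid_sd = venous_resid_sd,
                 dose_mean = dose_mean, dose_sd = dose_sd,
                 weight_mean = weight_mean, weight_sd = weight_sd,
                 K1 = K1, k2 = k2, vB = vB,
                 aif = aif,
                 frame_schedule = frame_schedule,
                 blood_times = blood_times,
                 dense_dt_min = dense_dt_min,
                 rng_seed = as.integer(rng_seed)),
            class = "study_design")
}

# lognormal draw with unit mean and given CV (returns 1s when cv == 0)
rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -s^2 / 2, sdlog = s)
}

#' Draw paired arterial and venous glycemia
#'
#' Arterial glycemia is normal (truncated above 0.5 mmol/L); venous values
#' follow the arterial ones through a linear link with slope close to one,
#' reproducing the tight arterio-venous agreement seen in macaque data.
#'
#' @param design a [study_design()].
#' @param n number of paired draws.
#' @return data frame with columns `arterial`, `venous` (mmol/L).
#' @export
simulate_glycemia <- function(design, n = 1) {
  art <- stats::rnorm(n, design$glycemia_mean, design$glycemia_sd)
  while (any(art <= 0.5))
    art[art <= 0.5] <- stats::rnorm(sum(art <= 0.5),
                                    design$glycemia_mean, design$glycemia_sd)
  ven <- design$venous_slope * art + stats::rnorm(n, 0, design$venous_resid_sd)
  data.frame(arterial = art, venous = pmax(ven, 0.1))
}

#' Simulate a complete synthetic FDG study
#'
#' Generates, for every subject and session: scan metadata (dose, weight,
#' arterial/venous glycemia), an arterial input function sampled on the
#' blood schedule, and frame-binned regional time-activity curves from the
#' irreversible 2TCM, together with the ground-truth kinetic parameters and
#' realized random effects.
#'
#' Per subject i, session s and region r the true influx rate is
#' \deqn{K_i(i,s,r) = \mathrm{map}[r] \exp(b_i) \exp(e_{is})}
#' with \eqn{b_i \sim N(0,\sigma_{inter}^2)} and
#' \eqn{e_{is} \sim N(0,\sigma_{intra}^2)}; k3 is tied to Ki at fixed K1 and
#' k2. Each session carries a lognormal plasma-exposure scale (CV
#' `global_scale_cv`) applied to the AIF (and hence to all tissue curves),
#' and each (scan, region) a lognormal ROI factor (CV `region_scale_cv`)
#' applied to the tissue curve only. Frame noise is added last.
#'
#' Draw order (fixed; determinism from `rng_seed`): subject weights,
#' subject effects b, then per scan in subject-major order: dose, plasma
#' scale, session effect e, glycemia pair, then per region in map order:
#' ROI factor, frame noise.
#'
#' @param design a [study_design()].
#' @param seed overrides `design$rng_seed` when not `NULL`.
#' @param subject_prefix prefix for generated subject ids.
#' @return An `fdg_study` list with elements `tacs`, `blood`, `meta`,
#'   `truth` (long data frames) and `design`.
#' @export
simulate_study <- function(design, seed = NULL, subject_prefix = "S") {
  set.seed(if (is.null(seed)) design$rng_seed else seed)
  ns <- design$n_subjects
  sessions <- if (design$n_sessions == 2L) c("test", "retest") else "single"
  regions <- names(design$region_ki_map)

  weights <- pmax(stats::rnorm(ns, design$weight_mean, design$weight_sd), 1)
  b <- stats::rnorm(ns, 0, design$sigma_inter)
  ids <- sprintf("%s%02d", subject_prefix, seq_len(ns))

  t_dense <- seq(0, max(design$frame_schedule$end_s) / 60, by = design$dense_dt_min)
  shape_suv <- aif_value(design$aif, t_dense)
  shape_blood <- aif_value(design$aif, design$blood_times)

  tacs <- list(); blood <- list(); meta <- list(); truth <- list()
  k <- 0L
  for (i in seq_len(ns)) {
    for (s in sessions) {
      k <- k + 1L
      dose <- max(stats::rnorm(1, design$dose_mean, design$dose_sd), 1)
      gscale <- rlnorm_cv(1, design$global_scale_cv)
      e <- stats::rnorm(1, 0, design$sigma_intra)
      gly <- simulate_glycemia(design, 1)
      suv_norm <- dose / weights[i]  # kBq/mL per SUV unit
      cp_dense <- shape_suv * gscale * suv_norm
      blood[[k]] <- data.frame(subject_id = ids[i], session = s,
                               time_min = design$blood_times,
                               plasma_kbq_per_ml = shape_blood * gscale * suv_norm)
      meta[[k]] <- data.frame(subject_id = ids[i], session = s,
                              injected_dose_mbq = dose,
                              body_weight_kg = weights[i],
                              glycemia_arterial_mmol_l = gly$arterial,
                              glycemia_venous_mmol_l = gly$venous)
      for (r in regions) {
        ki <- design$region_ki_map[[r]] * exp(b[i] + e)
        if (ki >= design$K1)
          stop_input("realized Ki reached K1; reduce effect sizes or Ki map")
        k3 <- k3_for_ki(ki, design$K1, design$k2)
        pars <- kinetic_params(design$K1, design$k2, k3, design$vB)
        ct <- tissue_curve(pars, t_dense, cp_dense)
        rho <- rlnorm_cv(1, design$region_scale_cv)
        tac <- bin_to_frames(t_dense, ct * rho, design$frame_schedule, region = r)
        tac <- add_measurement_noise(tac, design$noise_cv)
        tacs[[length(tacs) + 1L]] <-
          cbind(subject_id = ids[i], session = s, tac)
        truth[[length(truth) + 1L]] <-
          data.frame(subject_id = ids[i], session = s, region = r,
                     K1 = pars$K1, k2 = pars$k2, k3 = pars$k3, Ki = pars$Ki,
                     subject_effect = b[i], session_effect = e,
                     scan_scale = gscale, region_scale = rho)
      }
    }
  }
  structure(list(tacs = do.call(rbind, tacs),
                 blood = do.call(rbind, blood),
                 meta = do.call(rbind, meta),
                 truth = do.call(rbind, truth),
                 design = design),
            class = "fdg_study")
}

#' @export
print.fdg_study <- function(x, ...) {
  cat(sprintf("Synthetic FDG study: %d subject(s) x %d session(s), %d region(s)\n",
              x$design$n_subjects, x$design$n_sessions,
              length(x$design$region_ki_map)))
  cat(sprintf("  frames: %d, blood samples: %d, seed: %d\n",
              nrow(x$design$frame_schedule), length(x$design$blood_times),
              x$design$rng_seed))
  invisible(x)
}
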