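#' Quantification configuration
#'
#' @param lumped_constant unitless FDG lumped constant in (0, 1\], default
#'   0.34, converting FDG influx to glucose consumption.
#' @param t_star Patlak linearization start (min), default 30.
#' @param plateau_window min window for the plateau SUV, default c(30, 60).
#' @param reference_regions labels of the SUVR reference regions.
#' @param glycemia_source "arterial" (default) or "venous".
#' @param tissue_density g/mL used for the per-100 g conversion, default 1.
#' @return A `quant_config` list.
#' @export
quant_config <- function(lumped_constant = 0.34,
                         t_star = 30,
                         plateau_window = c(30, 60),
                         reference_regions = c("pons", "cerebellum"),
                         glycemia_source = c("arterial", "venous"),
                         tissue_density = 1.0) {
  if (lumped_constant <= 0 || lumped_constant > 1)
    stop_config("lumped_constant must be in (0, 1]")
  if (length(plateau_window) != 2L || plateau_window[1] >= plateau_window[2])
    stop_config("plateau_window must be an increasing pair of minutes")
  if (tissue_density <= 0) stop_config("tissue_density must be > 0")
  glycemia_source <- match.arg(glycemia_source)
  structure(list(lumped_constant = lumped_constant,
                 t_star = t_star,
                 plateau_window = as.numeric(plateau_window),
                 reference_regions = reference_regions,
                 glycemia_source = glycemia_source,
                 tissue_density = tissue_density),
            class = "quant_config")
}

#' Scan metadata
#'
#' @param subject_id subject label.
#' @param session one of "test", "retest", "single".
#' @param injected_dose MBq, > 0.
#' @param body_weight kg, > 0.
#' @param glycemia_arterial mmol/L, > 0.
#' @param glycemia_venous mmol/L or NA (optional).
#' @return A `scan_meta` list.
#' @export
scan_meta <- function(subject_id, session, injected_dose, body_weight,
                      glycemia_arterial, glycemia_venous = NA_real_) {
  if (!session %in% c("test", "retest", "single"))
    stop_input("session must be one of test, retest, single")
  if (injected_dose <= 0 || body_weight <= 0)
    stop_input("dose and weight must be > 0")
  if (!is.na(glycemia_arterial) && glycemia_arterial <= 0)
    stop_input("glycemia must be > 0")
  structure(list(subject_id = subject_id, session = session,
                 injected_dose = injected_dose, body_weight = body_weight,
                 glycemia_arterial = glycemia_arterial,
                 glycemia_venous = glycemia_venous),
            class = "scan_meta")
}

#' Trapezoidal area under a sampled curve
#'
#' AUC from 0 to `t_end`. When the first sample is later than t = 0 a
#' leading segment rising linearly from (0, 0) to the first sample is
#' included; no extrapolation beyond the last sample is allowed.
#'
#' @param times sample times (min), sorted increasing.
#' @param values sampled values.
#' @param t_end integration end (min), <= last sample time.
#' @return the integral (value units x min).
#' @examples
#' integrate_trapezoid(c(0, 60), c(2, 2), 60)  # 120
#' @export
integrate_trapezoid <- function(times, values, t_end = max(times)) {
  if (length(times) != length(values) || length(times) < 2L)
    stop_input("need >= 2 samples")
  if (is.unsorted(times, strictly = TRUE)) stop_input("times must be strictly increasing")
  if (t_end > max(times) + 1e-9)
    stop_input("t_end beyond the sampled range; no extrapolation")
  if (times[1] > 0) {
    times <- c(0, times)
    values <- c(0, values)
  }
  keep <- times <= t_end + 1e-12
  t <- times[keep]; v <- values[keep]
  if (t[length(t)] < t_end) {  # partial final segment by interpolation
    vend <- stats::approx(times, values, xout = t_end)$y
    t <- c(t, t_end); v <- c(v, vend)
  }
  sum((v[-1] + v[-length(v)]) / 2 * diff(t))
}

#' Normalize an activity concentration to SUV
#'
#' SUV (g/mL) = tissue activity (kBq/mL) / (injected dose (kBq) / body
#' weight (g)).
#'
#' @param activity kBq/mL (vectorized).
#' @param meta a [scan_meta()] (or any list with `injected_dose` MBq and
#'   `body_weight` kg).
#' @return SUV in g/mL.
#' @examples
#' normalize_to_suv(37, list(injected_dose = 185, body_weight = 5))  # 1.0
#' @export
normalize_to_suv <- function(activity, meta) {
  if (meta$injected_dose <= 0 || meta$body_weight <= 0)
    stop_input("dose and weight must be > 0")
  activity * (meta$body_weight * 1000) / (meta$injected_dose * 1000)
}

#' Plasma exposure (AUC of the SUV-normalized input function)
#'
#' @param aif an `fdg_aif` spanning at least 60 min.
#' @param meta a [scan_meta()].
#' @param t_end end of integration (min), default 60.
#' @return plasma exposure in SUV x min.
#' @export
plasma_exposure <- function(aif, meta, t_end = 60) {
  if (max(aif$time_min) < t_end - 1e-9)
    stop_input("AIF must span the full integration window")
  integrate_trapezoid(aif$time_min,
                      normalize_to_suv(aif$plasma_kbq_per_ml, meta),
                      t_end)
}

#' Plateau SUV of a regional TAC
#'
#' Duration-weighted mean of frame SUVs whose midpoints lie inside the
#' plateau window (default 30-60 min post-injection, where brain FDG
#' kinetics have flattened).
#'
#' @param tac an `fdg_tac`.
#' @param meta a [scan_meta()].
#' @param cfg a [quant_config()].
#' @return SUV (g/mL).
#' @export
suv_plateau <- function(tac, meta, cfg = quant_config()) {
  mid <- (tac$frame_start_s + tac$frame_end_s) / 2 / 60
  sel <- mid >= cfg$plateau_window[1] & mid <= cfg$plateau_window[2]
  if (!any(sel)) stop_input("no frame midpoint inside the plateau window")
  dur <- (tac$frame_end_s - tac$frame_start_s)[sel]
  suv <- normalize_to_suv(tac$activity_kbq_per_ml[sel], meta)
  sum(suv * dur) / sum(dur)
}

#' Patlak transform of a regional TAC
#'
#' Builds the Patlak coordinates at the frame midpoints T:
#' \deqn{x(T) = \int_0^T C_p \,dt \,/\, C_p(T), \qquad y(T) = C_t(T)/C_p(T)}
#' with Cp linearly interpolated between arterial samples. Points whose
#' interpolated Cp falls below a positivity floor (1e-6 of the plasma peak)
#' are dropped.
#'
#' @param tac an `fdg_tac`.
#' @param aif an `fdg_aif` covering all frame midpoints.
#' @return data frame with columns `t_mid` (min), `x` (min), `y` (unitless).
#' @export
patlak_points <- function(tac, aif) {
  mid <- (tac$frame_start_s + tac$frame_end_s) / 2 / 60
  if (max(mid) > max(aif$time_min) + 1e-9)
    stop_input("AIF does not cover all frame midpoints")
  t <- aif$time_min; cp <- aif$plasma_kbq_per_ml
  if (t[1] > 0) { t <- c(0, t); cp <- c(0, cp) }
  cp_mid <- stats::approx(t, cp, xout = mid)$y
  cum <- cumtrapz(t, cp)
  cum_mid <- stats::approx(t, cum, xout = mid)$y
  floor_cp <- 1e-6 * max(cp)
  keep <- cp_mid > floor_cp
  if (!any(keep)) stop_input("all Patlak points dropped (Cp below positivity floor)")
  data.frame(t_mid = mid[keep],
             x = cum_mid[keep] / cp_mid[keep],
             y = tac$activity_kbq_per_ml[keep] / cp_mid[keep])
}

#' Ordinary least-squares Patlak fit
#'
#' Fits y on x over points with frame midpoint at or after `t_star`;
#' the slope estimates the net influx rate Ki, the intercept the effective
#' distribution volume.
#'
#' @param points output of [patlak_points()].
#' @param cfg a [quant_config()] (uses `t_star`).
#' @return A `patlak_fit` list: `Ki`, `intercept`, `n_points`, `r_squared`,
#'   `t_star`.
#' @export
patlak_fit <- function(points, cfg = quant_config()) {
  sel <- points$t_mid >= cfg$t_star - 1e-9
  pts <- points[sel, , drop = FALSE]
  if (nrow(pts) < 3L) stop_input("need >= 3 Patlak points at or after t_star")
  if (stats::sd(pts$x) < 1e-12) stop_input("zero variance in Patlak x")
  fit <- stats::lm(y ~ x, data = pts)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((pts$y - mean(pts$y))^2)
  r2 <- if (ss_tot < 1e-300) 1 else max(0, min(1, 1 - ss_res / ss_tot))
  structure(list(Ki = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 n_points = nrow(pts),
                 r_squared = r2,
                 t_star = cfg$t_star),
            class = "patlak_fit")
}

#' Cerebral metabolic rate of glucose from a Patlak fit
#'
#' CMRglu = Ki x glycemia / LC x 100 / tissue density, in
#' umol / min / 100 g (glycemia in mmol/L is numerically umol/mL).
#'
#' @param fit a `patlak_fit` (or a list with element `Ki`).
#' @param meta a [scan_meta()].
#' @param cfg a [quant_config()] (lumped constant, glycemia source,
#'   tissue density).
#' @return CMRglu in umol/min/100 g.
#' @examples
#' cmrglu(list(Ki = 0.01511),
#'        scan_meta("a", "test", 170, 5.8, glycemia_arterial = 4.5))  # 20.0
#' @export
cmrglu <- function(fit, meta, cfg = quant_config()) {
  gly <- switch(cfg$glycemia_source,
                arterial = meta$glycemia_arterial,
                venous = meta$glycemia_venous)
  if (is.null(gly) || is.na(gly))
    stop_input(sprintf("missing %s glycemia", cfg$glycemia_source))
  fit$Ki * gly / cfg$lumped_constant * 100 / cfg$tissue_density
}

#' Quantify one scan: the five outcome parameters per region
#'
#' Computes, for every region of a scan, CMRglu (Patlak), plateau SUV,
#' SUV x glycemia, and SUVR against each reference region, plus the scan's
#' plasma exposure. The SUVR of a reference region against itself is left
#' `NA` (it is identically 1 and carries no information).
#'
#' @param tacs long data frame of frames for one scan: columns `region`,
#'   `frame_start_s`, `frame_end_s`, `activity_kbq_per_ml`.
#' @param aif the scan's `fdg_aif`.
#' @param meta a [scan_meta()].
#' @param cfg a [quant_config()].
#' @return An `fdg_quant_scan` list: `params` (data frame region x
#'   parameter), `plasma_exposure` (SUV min), `fits` (per-region
#'   `patlak_fit`s).
#' @export
quantify_scan <- function(tacs, aif, meta, cfg = quant_config()) {
  regions <- unique(tacs$region)
  missing_ref <- setdiff(cfg$reference_regions, regions)
  if (length(missing_ref))
    stop_input(sprintf("reference region(s) missing from TACs: %s",
                       paste(missing_ref, collapse = ", ")))
  gly <- switch(cfg$glycemia_source,
                arterial = meta$glycemia_arterial, venous = meta$glycemia_venous)
  fits <- list(); suv <- numeric(length(regions)); cm <- numeric(length(regions))
  for (j in seq_along(regions)) {
    tac <- tacs[tacs$region == regions[j], , drop = FALSE]
    fits[[regions[j]]] <- patlak_fit(patlak_points(tac, aif), cfg)
    suv[j] <- suv_plateau(tac, meta, cfg)
    cm[j] <- cmrglu(fits[[regions[j]]], meta, cfg)
  }
  params <- data.frame(region = regions, cmrglu = cm, suv = suv,
                       suv_gly = suv * gly)
  for (ref in cfg$reference_regions) {
    col <- paste0("suvr_", ref)
    params[[col]] <- suv / suv[regions == ref]
    params[[col]][regions == ref] <- NA_real_
  }
  structure(list(params = params,
                 plasma_exposure = plasma_exposure(aif, meta),
                 fits = fits),
            class = "fdg_quant_scan")
}

#' Quantify every scan of a study
#'
#' Runs [quantify_scan()] over all (subject, session) pairs of a simulated
#' or loaded study and returns the long quantification table. Plasma
#' exposure is reported as its own parameter with region label `"plasma"`.
#'
#' @param study an `fdg_study` (or a list with `tacs`, `blood`, `meta`
#'   long data frames).
#' @param cfg a [quant_config()].
#' @return long data frame: `subject_id`, `session`, `region`, `parameter`,
#'   `value`.
#' @export
quantify_study <- function(study, cfg = quant_config()) {
  meta <- study$meta
  out <- vector("list", nrow(meta))
  for (k in seq_len(nrow(meta))) {
    id <- meta$subject_id[k]; ses <- meta$session[k]
    m <- scan_meta(id, ses, meta$injected_dose_mbq[k], meta$body_weight_kg[k],
                   meta$glycemia_arterial_mmol_l[k], meta$glycemia_venous_mmol_l[k])
    tacs <- study$tacs[study$tacs$subject_id == id & study$tacs$session == ses, ]
    bl <- study$blood[study$blood$subject_id == id & study$blood$session == ses, ]
    aif <- new_aif(bl$time_min, bl$plasma_kbq_per_ml)
    q <- quantify_scan(tacs, aif, m, cfg)
    long <- stats::reshape(q$params, direction = "long",
                           varying = setdiff(names(q$params), "region"),
                           v.names = "value", timevar = "parameter",
                           times = setdiff(names(q$params), "region"),
                           idvar = "region")
    rownames(long) <- NULL
    long <- long[!is.na(long$value), c("region", "parameter", "value")]
    long <- rbind(long, data.frame(region = "plasma", parameter = "plasma_exposure",
                                   value = q$plasma_exposure))
    out[[k]] <- cbind(subject_id = id, session = ses, long)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
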