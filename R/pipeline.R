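#' Read a pipeline configuration from YAML
#'
#' The YAML mirrors the programmatic interface with three sections:
#' `design` (arguments of [study_design()], including an optional
#' `robustness_n_subjects`), `quantification` (arguments of
#' [quant_config()]) and `io` (e.g. `qc_plots: true`). All fields are
#' optional; omitted ones take the package defaults.
#'
#' @param path YAML file.
#' @return list with elements `design` (a `study_design`),
#'   `quantification` (a `quant_config`), `robustness_n_subjects`, `io`.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  d <- raw$design %||% list()
  rob <- d$robustness_n_subjects %||% 4L
  d$robustness_n_subjects <- NULL
  if (!is.null(d$region_ki_map)) d$region_ki_map <- unlist(d$region_ki_map)
  if (!is.null(d$frame_schedule))
    d$frame_schedule <- frame_schedule(d$frame_schedule$start_s,
                                       d$frame_schedule$end_s)
  if (!is.null(d$aif)) d$aif <- do.call(aif_model, d$aif)
  q <- raw$quantification %||% list()
  if (!is.null(q$reference_regions)) q$reference_regions <- unlist(q$reference_regions)
  design <- do.call(study_design, d)
  cfg <- do.call(quant_config, q)
  missing_ref <- setdiff(cfg$reference_regions, names(design$region_ki_map))
  if (length(missing_ref))
    stop_config(sprintf("reference region(s) absent from the design Ki map: %s",
                        paste(missing_ref, collapse = ", ")))
  list(design = design, quantification = cfg,
       robustness_n_subjects = as.integer(rob), io = raw$io %||% list())
}

#' Run the full synthetic test-retest pipeline
#'
#' simulate -> quantify -> repeatability -> robustness, writing every
#' intermediate and final table plus a provenance log to `out_dir`.
#' Re-running with the same configuration and seed reproduces the outputs
#' byte-identically.
#'
#' @param config path to a YAML configuration, a list as returned by
#'   [read_pipeline_config()], or `NULL` for all defaults.
#' @param out_dir output directory.
#' @param seed overrides the design seed when not `NULL`.
#' @return invisibly, a list with the in-memory results (`study`, `quant`,
#'   `decomposition`, `correlations`, `robustness`).
#' @export
run_pipeline <- function(config = NULL, out_dir, seed = NULL) {
  cfg <- if (is.character(config)) read_pipeline_config(config)
         else if (is.null(config)) read_pipeline_config(NULL)
         else config
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- if (is.null(seed)) cfg$design$rng_seed else as.integer(seed)
  cfg$design$rng_seed <- seed

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  study <- stage("simulate", simulate_study(cfg$design))
  write_study(study, file.path(out_dir, "study"))

  quant <- stage("quantify", quantify_study(study, cfg$quantification))
  utils::write.csv(quant, file.path(out_dir, "quantification.csv"),
                   row.names = FALSE)

  decomp <- stage("repeatability", decompose_variability(quant))
  utils::write.csv(decomp, file.path(out_dir, "decomposition.csv"),
                   row.names = FALSE)
  corr <- stage("repeatability", parameter_correlations(quant))
  utils::write.csv(data.frame(parameter = rownames(corr$rho),
                              round(corr$rho, 4)),
                   file.path(out_dir, "correlations.csv"), row.names = FALSE)

  rob <- NULL
  if (cfg$robustness_n_subjects >= 1) {
    rdesign <- cfg$design
    rdesign$n_subjects <- cfg$robustness_n_subjects
    rdesign$n_sessions <- 1L
    rstudy <- stage("robustness",
                    simulate_study(rdesign, seed = seed + 1L, subject_prefix = "N"))
    rquant <- stage("robustness", quantify_study(rstudy, cfg$quantification))
    rob <- stage("robustness", robustness_check(decomp, rquant))
    utils::write.csv(as.data.frame(rob), file.path(out_dir, "robustness.csv"),
                     row.names = FALSE)
  }

  if (isTRUE(cfg$io$qc_plots)) {
    stage("qc_plots", write_qc_plots(study, cfg$quantification,
                                     file.path(out_dir, "qc")))
  }

  prov <- c(sprintf("fdgrepeat %s", as.character(utils::packageVersion("fdgrepeat"))),
            sprintf("R %s", paste(R.version$major, R.version$minor, sep = ".")),
            sprintf("seed %d", seed),
            sprintf("tacs md5 %s",
                    unname(tools::md5sum(file.path(out_dir, "study", "tacs.csv")))))
  writeLines(prov, file.path(out_dir, "provenance.txt"))

  invisible(list(study = study, quant = quant, decomposition = decomp,
                 correlations = corr, robustness = rob))
}

#' QC figures: TACs and a Patlak plot
#'
#' Writes one PNG of all regional TACs (SUV vs time) and one Patlak plot
#' for the first scan of the study.
#'
#' @param study an `fdg_study`.
#' @param cfg a [quant_config()].
#' @param dir output directory for the PNGs.
#' @return invisibly, the paths written.
#' @export
write_qc_plots <- function(study, cfg = quant_config(), dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- study$meta[1, ]
  m <- scan_meta(meta$subject_id, meta$session, meta$injected_dose_mbq,
                 meta$body_weight_kg, meta$glycemia_arterial_mmol_l)
  tacs <- study$tacs[study$tacs$subject_id == meta$subject_id &
                     study$tacs$session == meta$session, ]
  bl <- study$blood[study$blood$subject_id == meta$subject_id &
                    study$blood$session == meta$session, ]
  aif <- new_aif(bl$time_min, bl$plasma_kbq_per_ml)
  regions <- unique(tacs$region)

  p1 <- file.path(dir, "tacs.png")
  grDevices::png(p1, width = 900, height = 600)
  mids <- (tacs$frame_start_s + tacs$frame_end_s) / 2 / 60
  suv <- normalize_to_suv(tacs$activity_kbq_per_ml, m)
  graphics::plot(range(mids), range(suv), type = "n",
                 xlab = "time (min)", ylab = "SUV (g/mL)",
                 main = sprintf("TACs, %s %s", meta$subject_id, meta$session))
  for (j in seq_along(regions)) {
    sel <- tacs$region == regions[j]
    graphics::lines(mids[sel], suv[sel], col = j)
  }
  graphics::legend("bottomright", legend = regions, col = seq_along(regions),
                   lty = 1, cex = 0.7)
  grDevices::dev.off()

  p2 <- file.path(dir, "patlak.png")
  grDevices::png(p2, width = 700, height = 600)
  tac1 <- tacs[tacs$region == regions[1], ]
  pts <- patlak_points(tac1, aif)
  fit <- patlak_fit(pts, cfg)
  graphics::plot(pts$x, pts$y, pch = 19,
                 xlab = "normalized time (min)", ylab = "Ct/Cp",
                 main = sprintf("Patlak, %s: Ki = %.4f /min", regions[1], fit$Ki))
  graphics::abline(fit$intercept, fit$Ki, col = 2)
  grDevices::dev.off()
  invisible(c(p1, p2))
}
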