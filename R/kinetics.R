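#' Irreversible two-tissue-compartment kinetic parameters
#'
#' Rate constants of the irreversible 2TCM for FDG: K1 (plasma to tissue),
#' k2 (tissue to plasma), k3 (phosphorylation / trapping), and a fractional
#' blood volume vB. The net influx (trapping) rate is
#' \eqn{K_i = K_1 k_3 / (k_2 + k_3)}.
#'
#' @param K1 mL plasma / min / mL tissue, > 0.
#' @param k2,k3 1/min, > 0.
#' @param vB blood volume fraction in \[0, 1).
#' @return A `kinetic_params` list with an added `Ki` element.
#' @examples
#' kinetic_params(0.10, 0.13, 0.016)$Ki  # 0.01096
#' @export
kinetic_params <- function(K1, k2, k3, vB = 0) {
  if (K1 <= 0 || k2 <= 0 || k3 <= 0) stop_input("K1, k2, k3 must be > 0")
  if (vB < 0 || vB >= 1) stop_input("vB must be in [0, 1)")
  Ki <- K1 * k3 / (k2 + k3)
  structure(list(K1 = K1, k2 = k2, k3 = k3, vB = vB, Ki = Ki),
            class = "kinetic_params")
}

#' Solve for k3 given a target net influx rate
#'
#' Inverts \eqn{K_i = K_1 k_3/(k_2+k_3)} at fixed K1 and k2, the convention
#' used by the study generator to tie regional kinetics to a Ki map.
#'
#' @param Ki target influx rate (1/min), must satisfy `Ki < K1`.
#' @param K1,k2 fixed rate constants.
#' @return k3 (1/min).
#' @export
k3_for_ki <- function(Ki, K1 = 0.10, k2 = 0.13) {
  if (any(Ki <= 0) || any(Ki >= K1))
    stop_input("Ki must lie in (0, K1) to be reachable")
  k2 * Ki / (K1 - Ki)
}

#' Forward model: tissue curve of the irreversible 2TCM
#'
#' Computes \eqn{C_t(t) = (1-v_B)(C_1+C_2) + v_B C_p} on a uniform fine grid
#' by exact exponential update (the convolution
#' \eqn{C_1 = K_1 C_p \otimes e^{-(k_2+k_3)t}} is integrated analytically
#' per step for piecewise-linear \eqn{C_p}), with
#' \eqn{C_2 = k_3 \int_0^t C_1}. The grid step must be at most 0.01 min; a
#' coarser grid would not honour the accuracy contract of the downstream
#' Patlak oracle and raises a configuration error.
#'
#' @param params a [kinetic_params()].
#' @param times uniform time grid (min), step <= 0.01.
#' @param cp plasma activity on `times` (same units as the result).
#' @return numeric vector, tissue activity on `times`.
#' @export
tissue_curve <- function(params, times, cp) {
  n <- length(times)
  if (n < 2L || length(cp) != n) stop_input("times and cp must be equal-length, n >= 2")
  dt <- diff(times)
  if (any(abs(dt - dt[1]) > 1e-9)) stop_config("time grid must be uniform")
  dt <- dt[1]
  if (dt > 0.01 + 1e-12)
    stop_config("grid step must be <= 0.01 min for the 2TCM forward model")
  a <- params$k2 + params$k3
  E <- exp(-a * dt)
  # exact step integrals for linear cp: weights of cp at step start/end
  g1 <- 1 / a - (1 - E) / (a^2 * dt)
  g0 <- (1 - E) / a - g1
  inc <- params$K1 * (g0 * cp[-n] + g1 * cp[-1])
  C1 <- c(0, as.numeric(stats::filter(inc, E, method = "recursive")))
  C2 <- params$k3 * cumtrapz(times, C1)
  ct <- (1 - params$vB) * (C1 + C2) + params$vB * cp
  pmax(ct, 0)
}

# cumulative trapezoidal integral, same length as x
cumtrapz <- function(x, y) {
  n <- length(x)
  c(0, cumsum((y[-1] + y[-n]) / 2 * diff(x)))
}

#' Bin a dense tissue curve into acquisition frames
#'
#' Each frame value is the duration-weighted time average of the dense curve
#' over \[start, end\] (trapezoidal integral divided by frame duration).
#'
#' @param times dense time grid (min).
#' @param activity dense tissue activity (kBq/mL).
#' @param schedule a [frame_schedule()]; must lie within the dense span.
#' @param region region label carried into the result.
#' @return An `fdg_tac` data frame with columns `region`, `frame_start_s`,
#'   `frame_end_s`, `activity_kbq_per_ml`.
#' @export
bin_to_frames <- function(times, activity, schedule, region = "region") {
  if (max(schedule$end_s) / 60 > max(times) + 1e-9 ||
      min(schedule$start_s) / 60 < min(times) - 1e-9)
    stop_input("frame schedule exceeds the span of the dense curve")
  cum <- cumtrapz(times, activity)
  cum_at <- stats::approx(times, cum, xout = c(schedule$start_s, schedule$end_s) / 60,
                          rule = 2)$y
  k <- nrow(schedule)
  integ <- cum_at[(k + 1):(2 * k)] - cum_at[1:k]
  vals <- integ / ((schedule$end_s - schedule$start_s) / 60)
  new_tac(region, schedule, vals)
}

#' Construct a regional time-activity curve
#'
#' @param region region label.
#' @param schedule a [frame_schedule()].
#' @param activity decay-corrected frame activity (kBq/mL), one per frame.
#' @return An `fdg_tac` data frame.
#' @export
new_tac <- function(region, schedule, activity) {
  if (length(activity) != nrow(schedule))
    stop_input("activity must have one value per frame")
  if (any(activity < 0)) stop_input("TAC activity must be >= 0")
  structure(data.frame(region = region,
                       frame_start_s = schedule$start_s,
                       frame_end_s = schedule$end_s,
                       activity_kbq_per_ml = as.numeric(activity)),
            class = c("fdg_tac", "data.frame"))
}

tac_schedule <- function(tac) frame_schedule(tac$frame_start_s, tac$frame_end_s)

#' Add frame-level measurement noise to a TAC
#'
#' Multiplicative Gaussian noise whose standard deviation scales with
#' 1/sqrt(frame duration) relative to the longest frame, mimicking count
#' statistics; negative draws are clipped at zero. `noise_cv = 0` returns
#' the input unchanged.
#'
#' @param tac an `fdg_tac`.
#' @param noise_cv unitless CV of the noise on the longest frame, >= 0.
#' @return An `fdg_tac` with perturbed activities.
#' @export
add_measurement_noise <- function(tac, noise_cv) {
  if (noise_cv < 0) stop_input("noise_cv must be >= 0")
  if (noise_cv == 0) return(tac)
  dur <- tac$frame_end_s - tac$frame_start_s
  sd_i <- noise_cv * sqrt(max(dur) / dur)
  tac$activity_kbq_per_ml <- pmax(0, tac$activity_kbq_per_ml *
                                     (1 + stats::rnorm(length(dur), 0, sd_i)))
  tac
}
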