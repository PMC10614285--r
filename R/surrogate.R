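# Synthetic occupant surrogate: a deterministic planar double inverted
# pendulum (pelvis->T1, T1->head CG) on a decelerating base, with passive
# spring-dampers, gravity-balancing feedforward and delayed, saturated PD
# postural control. It stands in for a finite-element occupant so the full
# sensitivity pipeline is executable at desk scale; its constants are
# synthetic and make no claim about any particular body model.

#' Braking pulse specification
#'
#' Trapezoidal deceleration profile: linear ramp up over `ramp_time`, plateau
#' at `amplitude`, linear ramp down ending at `duration`, zero after. The
#' velocity change is `amplitude * (duration - ramp_time)`.
#'
#' @param amplitude plateau deceleration, m/s^2.
#' @param duration total pulse duration, s.
#' @param ramp_time ramp duration at each end, s (< duration/2).
#' @param sample_rate reporting sample rate, Hz.
#' @return A `braking_pulse` list.
#' @export
braking_pulse <- function(amplitude = 10, duration = 1.3, ramp_time = 0.1,
                          sample_rate = 2000) {
  stopifnot(amplitude > 0, ramp_time > 0, ramp_time < duration / 2,
            sample_rate > 0)
  structure(list(amplitude = amplitude, duration = duration,
                 ramp_time = ramp_time, sample_rate = sample_rate),
            class = "braking_pulse")
}

#' Evaluate a braking pulse at given times
#'
#' @param p a `braking_pulse`.
#' @param t times, s.
#' @return Deceleration values, m/s^2.
#' @export
pulse_at <- function(p, t) {
  a <- numeric(length(t))
  up <- t >= 0 & t < p$ramp_time
  flat <- t >= p$ramp_time & t <= p$duration - p$ramp_time
  down <- t > p$duration - p$ramp_time & t < p$duration
  a[up] <- p$amplitude * t[up] / p$ramp_time
  a[flat] <- p$amplitude
  a[down] <- p$amplitude * (p$duration - t[down]) / p$ramp_time
  a
}

#' Surrogate occupant constants
#'
#' Baseline masses, joint stiffnesses, controller gains and geometry plumbing
#' for the double-pendulum surrogate. `tissue_weights` blends the adipose,
#' passive-muscle and skin stiffness scales into one passive joint-stiffness
#' factor. All values are golden-fixture configuration data, not physiology.
#'
#' @param ... overrides for individual entries.
#' @return A named list.
#' @export
surrogate_config <- function(...) {
  cfg <- list(
    m1_kg = 34, m2_kg = 4.5,
    k1_Nm = 60, c1_Nms = 10, k2_Nm = 15, c2_Nms = 1.5,
    kp1_Nm = 600, kd1_Nms = 80, kp2_Nm = 40, kd2_Nms = 2,
    tmax1_Nm = 900, tmax2_Nm = 120,
    belt_engage_rad = 0.6, belt_k_Nm = 3000, belt_c_Nms = 150,
    neck_stop_engage_rad = 0.8, neck_stop_k_Nm = 300, neck_stop_c_Nms = 15,
    tissue_weights = c(adipose = 0.45, muscle = 0.45, skin = 0.10),
    head_cg_offset_mm = 60,
    neck_delay_nominal_ms = 20, lumbar_delay_nominal_ms = 25,
    dt_s = 5e-4, horizon_s = 1.5,
    peak_window_s = c(0.1, 0.8), peak_prominence_mm = 1)
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

# parameter rows (matrix with the 7 named columns) -> occupant state matrix
# for the C++ integrator; vectorised over rows.
occupant_state_matrix <- function(X, shape, config = surrogate_config(),
                                  params = build_parameter_set()) {
  need <- names(build_parameter_set())
  if (is.null(dim(X))) X <- matrix(X, nrow = 1, dimnames = list(NULL, names(X)))
  if (!all(need %in% colnames(X)))
    stop("parameter matrix must have columns ", paste(need, collapse = ", "))
  scores <- cbind(X[, "spine_pc1"], X[, "spine_pc2"])
  if (ncol(shape$loadings) != 2)
    stop("surrogate geometry expects a 2-PC shape model")
  base <- matrix(shape$mean, nrow = nrow(X), ncol = length(shape$mean),
                 byrow = TRUE)
  nodes <- base + (scores %*% diag(shape$sds)) %*% t(shape$loadings)
  ix <- function(lv) 2 * match(lv, shape$levels) - 1
  t1x <- nodes[, ix("T1")]; t1z <- nodes[, ix("T1") + 1]
  c2x <- nodes[, ix("C2")]; c2z <- nodes[, ix("C2") + 1]
  hx <- c2x; hz <- c2z + config$head_cg_offset_mm
  L1 <- sqrt(t1x^2 + t1z^2) / 1000
  L2 <- sqrt((hx - t1x)^2 + (hz - t1z)^2) / 1000
  th1 <- atan2(t1x, t1z)
  th2 <- atan2(hx - t1x, hz - t1z)
  pcsa <- X[, "muscle_pcsa"]
  if (any(pcsa <= 0)) stop("muscle_pcsa must be positive")
  skin <- X[, "skin_mu"]
  skin_spec <- params$skin_mu
  along <- coupled_partner_value(skin_spec, skin)
  skin_f <- 0.5 * (skin / skin_spec$nominal +
                   along / skin_spec$partner$params["mean"])
  w <- config$tissue_weights
  tissue <- w["adipose"] * X[, "adipose_props"] +
    w["muscle"] * X[, "muscle_props"] + w["skin"] * skin_f
  delay_neck_ms <- X[, "neural_delay"]
  if (any(delay_neck_ms <= 0)) stop("neural_delay must be positive")
  delay_lumbar_ms <- delay_neck_ms *
    config$lumbar_delay_nominal_ms / config$neck_delay_nominal_ms
  dt_ms <- config$dt_s * 1000
  n <- nrow(X)
  cbind(L1 = L1, L2 = L2, th1_0 = th1, th2_0 = th2,
        m1 = rep(config$m1_kg, n), m2 = rep(config$m2_kg, n),
        k1 = config$k1_Nm * tissue, c1 = config$c1_Nms * tissue,
        k2 = config$k2_Nm * tissue, c2 = config$c2_Nms * tissue,
        kp1 = config$kp1_Nm * pcsa, kd1 = config$kd1_Nms * pcsa,
        kp2 = config$kp2_Nm * pcsa, kd2 = config$kd2_Nms * pcsa,
        tmax1 = config$tmax1_Nm * pcsa, tmax2 = config$tmax2_Nm * pcsa,
        d1 = round(delay_lumbar_ms / dt_ms),
        d2 = round(delay_neck_ms / dt_ms),
        be1 = rep(config$belt_engage_rad, n),
        bk1 = rep(config$belt_k_Nm, n), bc1 = rep(config$belt_c_Nms, n),
        be2 = rep(config$neck_stop_engage_rad, n),
        bk2 = rep(config$neck_stop_k_Nm, n),
        bc2 = rep(config$neck_stop_c_Nms, n))
}

#' Map a seven-parameter vector to an occupant state
#'
#' Link geometry (lengths and initial angles) comes from the shape model at
#' the two spine PC scores; controller gains and torque bounds scale with the
#' PCSA factor; passive joint stiffness and damping scale with a weighted
#' blend of the adipose, muscle and skin stiffness factors; the neck and
#' lumbar neural delays follow the delay parameter at their 20:25 nominal
#' ratio.
#'
#' @param x named numeric vector with the seven parameters in physical units
#'   (`spine_pc1`, `spine_pc2`, `neural_delay`, `muscle_pcsa`,
#'   `adipose_props`, `muscle_props`, `skin_mu`).
#' @param shape a 2-PC `shape_model`.
#' @param config surrogate constants, see [surrogate_config()].
#' @param params the `parameter_set` (supplies nominals and the skin
#'   coupling).
#' @return An `occupant_state` list.
#' @export
occupant_from_parameters <- function(x, shape, config = surrogate_config(),
                                     params = build_parameter_set()) {
  m <- occupant_state_matrix(x, shape, config, params)
  st <- as.list(m[1, ])
  st$config <- config
  structure(st, class = "occupant_state")
}

#' @export
print.occupant_state <- function(x, ...) {
  cat(sprintf(paste0("<occupant_state> L1 %.0f mm @ %.1f deg, L2 %.0f mm @ ",
                     "%.1f deg; kp1 %.0f N.m/rad, delays %g/%g steps\n"),
              x$L1 * 1000, x$th1_0 * 180 / pi, x$L2 * 1000,
              x$th2_0 * 180 / pi, x$kp1, x$d1, x$d2))
  invisible(x)
}

state_vector <- function(state) {
  as.numeric(unlist(state[c("L1", "L2", "th1_0", "th2_0", "m1", "m2",
                            "k1", "c1", "k2", "c2", "kp1", "kd1",
                            "kp2", "kd2", "tmax1", "tmax2", "d1", "d2",
                            "be1", "bk1", "bc1", "be2", "bk2", "bc2")]))
}

#' Simulate an occupant's response to a braking pulse
#'
#' Fixed-step semi-implicit Euler integration of the surrogate, deterministic
#' for identical inputs. Displacements are reported in the vehicle frame
#' (x forward, z downward, mm) relative to the position at maneuver onset;
#' the lateral (y) component is identically zero in this planar model and is
#' reported for interface completeness.
#'
#' @param state an `occupant_state`.
#' @param pulse a [braking_pulse()].
#' @param dt integration step, s (<= 1 ms; delays are rounded to whole
#'   steps).
#' @param horizon simulated duration, s.
#' @return A `response_record` data frame: `time_s`, `head_x_mm`,
#'   `head_y_mm`, `head_z_mm`, `t1_x_mm`, `t1_y_mm`, `t1_z_mm`.
#' @export
simulate_occupant <- function(state, pulse = braking_pulse(),
                              dt = state$config$dt_s %||% 5e-4,
                              horizon = state$config$horizon_s %||% 1.5) {
  stopifnot(dt <= 1e-3, dt > 0)
  n <- round(horizon / dt)
  tt <- (0:n) * dt
  acc <- pulse_at(pulse, tt[-length(tt)])
  sv <- state_vector(state)
  sv[17] <- round(sv[17] * (state$config$dt_s %||% 5e-4) / dt)
  sv[18] <- round(sv[18] * (state$config$dt_s %||% 5e-4) / dt)
  traj <- tryCatch(.sim_traj_cpp(sv, acc, dt), error = function(e)
    stop("unstable occupant simulation (L1 = ", signif(state$L1, 3),
         " m, kp1 = ", signif(state$kp1, 3), " N.m/rad): ",
         conditionMessage(e)))
  out <- data.frame(time_s = tt,
                    head_x_mm = traj[, "head_x_mm"], head_y_mm = 0,
                    head_z_mm = traj[, "head_z_mm"],
                    t1_x_mm = traj[, "t1_x_mm"], t1_y_mm = 0,
                    t1_z_mm = traj[, "t1_z_mm"])
  class(out) <- c("response_record", "data.frame")
  out
}

# batch metric evaluation through the C++ integrator; X is a matrix of
# parameter rows. Returns a matrix with the four metric columns.
surrogate_metrics <- function(X, shape, pulse = braking_pulse(),
                              config = surrogate_config(),
                              params = build_parameter_set()) {
  states <- occupant_state_matrix(X, shape, config, params)
  n <- round(config$horizon_s / config$dt_s)
  acc <- pulse_at(pulse, (0:(n - 1)) * config$dt_s)
  .sim_metrics_cpp(states, acc, config$dt_s,
                   config$peak_window_s[1], config$peak_window_s[2],
                   pulse$duration, config$peak_prominence_mm)
}

#' Monte-Carlo first-order Sobol indices of a surrogate metric
#'
#' Pick-freeze (Saltelli) estimator of the first-order Sobol indices of a
#' kinematic metric of the surrogate under the seven parameter
#' distributions: two independent sample matrices A and B of size `n` plus
#' the seven hybrid matrices AB_i give `n * 9` simulator runs. Serves as the
#' stochastic reference the M-DRM estimates are compared against.
#'
#' @param shape a 2-PC `shape_model`.
#' @param params a `parameter_set`.
#' @param metric one of `"head_peak_fwd_mm"`, `"t1_peak_fwd_mm"`,
#'   `"head_avg_vert_mm"`, `"t1_avg_vert_mm"`.
#' @param n Monte-Carlo sample size per matrix (>= 1000).
#' @param seed RNG seed (all randomness flows from it).
#' @param pulse,config surrogate settings.
#' @return Data frame `parameter`, `S`, `se` (standard error), with
#'   attribute `"variance"` (total output variance).
#' @export
ground_truth_sobol <- function(shape, params, metric = "head_peak_fwd_mm",
                               n = 10000, seed = 1,
                               pulse = braking_pulse(),
                               config = surrogate_config()) {
  stopifnot(n >= 1000)
  metric <- match.arg(metric, c("head_peak_fwd_mm", "t1_peak_fwd_mm",
                                "head_avg_vert_mm", "t1_avg_vert_mm"))
  set.seed(seed)
  k <- length(params)
  nms <- vapply(params, `[[`, "", "name")
  draw <- function() {
    m <- vapply(params, parameter_sample, numeric(n), n = n)
    colnames(m) <- nms
    m
  }
  A <- draw(); B <- draw()
  X <- rbind(A, B)
  for (i in seq_len(k)) {
    ABi <- A
    ABi[, i] <- B[, i]
    X <- rbind(X, ABi)
  }
  y <- surrogate_metrics(X, shape, pulse, config, params)[, metric]
  fA <- y[seq_len(n)]
  fB <- y[n + seq_len(n)]
  V <- var(c(fA, fB))
  S <- numeric(k); se <- numeric(k)
  for (i in seq_len(k)) {
    fAB <- y[(i + 1) * n + seq_len(n)]
    u <- fB * (fAB - fA)
    S[i] <- mean(u) / V
    se[i] <- sd(u) / sqrt(n) / V
  }
  structure(data.frame(parameter = nms, S = S, se = se),
            variance = V, n = n, metric = metric)
}
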