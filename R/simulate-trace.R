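# Synthetic tribometer trace generator.
#
# The simulated physics is the quasi-static force balance of a sphere dragged
# over an inclined surface: with local surface angle th(x) = atan(h'(x)), a
# vertical-force servo holding |Fz| at its setpoint, and interfacial friction
# coefficient mu, the contact normal force is N = |Fz| / (cos th - mu sin th)
# and the measured lateral force Fx = N (mu cos th + sin th). To first order
# this is Fx = (mu + h'(x)) |Fz|, the familiar slope-coupled friction.

surface_height <- function(x, tilt, depth, L) {
  u <- x - L / 2
  tilt * x + depth * (u / (L / 2))^4
}

surface_slope <- function(x, tilt, depth, L) {
  u <- x - L / 2
  tilt + 4 * depth * u^3 / (L / 2)^4
}

# Interior zero-slope position of the combined tilt + meniscus profile, or NA.
zero_slope_position <- function(tilt, depth, L) {
  if (depth == 0) {
    return(if (tilt == 0) L / 2 else NA_real_)
  }
  v <- -tilt * (L / 2)^4 / (4 * depth)
  u0 <- sign(v) * abs(v)^(1 / 3)
  if (abs(u0) < L / 2) L / 2 + u0 else NA_real_
}

# Lateral force from the exact quasi-static balance.
balance_fx <- function(mu, slope, N_vert) {
  th <- atan(slope)
  N_contact <- N_vert / (cos(th) - mu * sin(th))
  N_contact * (mu * cos(th) + sin(th))
}

#' Simulate one tribometer slide
#'
#' Generates a raw tribometer trace for a single slide: a pre-movement loading
#' dwell with the lateral force fluctuating about its sensor baseline, a
#' static-friction peak at motion onset, and a stick-slip dynamic sliding
#' regime whose lateral force couples to the local surface slope (tilt plus
#' meniscus). The normal-force channel is servo-regulated towards its setpoint
#' with a first-order lag and AR(1) noise.
#'
#' Ground truth (true onset and static-peak indices, true friction
#' coefficients, zero-slope position) is attached and retrievable with
#' [ground_truth()], so downstream estimators can be validated exactly.
#'
#' @param scenario A [trace_scenario()].
#' @param ramp_dist Stage travel in mm over which the lateral force ramps up
#'   to the static peak (elastic pre-sliding loading).
#' @param decay_dist Exponential decay length in mm of the post-peak
#'   transition to dynamic sliding.
#' @return A [as_tribo_trace()] tibble with ground-truth annotations.
#' @examples
#' tr <- generate_trace(trace_scenario(seed = 1))
#' ground_truth(tr)$mu_d
#' @export
generate_trace <- function(scenario, ramp_dist = 0.1, decay_dist = 0.05) {
  stopifnot(inherits(scenario, "trace_scenario"))
  s <- scenario
  with_seed_maybe(s$seed, {
    dt <- 1 / s$rate
    t_total <- s$t_pre + s$slide_length / s$v_t
    time_s <- seq(0, t_total, by = dt)
    n <- length(time_s)
    x <- pmin(pmax(time_s - s$t_pre, 0) * s$v_t, s$slide_length)
    moving <- x > 0

    # servo-regulated normal force: first-order lag from touch to setpoint
    tau_servo <- 0.5
    fz_det <- -(s$F_N_set - (s$F_N_set - s$F_touch) * exp(-time_s / tau_servo))
    fz_noise <- numeric(n)
    if (s$noise_sd_F > 0) {
      phi <- 0.8
      innov <- rnorm(n, 0, s$noise_sd_F * sqrt(1 - phi^2))
      fz_noise <- as.numeric(stats::filter(innov, phi, method = "recursive"))
    }
    fz <- fz_det + fz_noise
    N_vert <- abs(fz)

    slope <- surface_slope(x, s$tilt, s$meniscus_depth, s$slide_length)

    # stick-slip: sawtooth on mu_d between Poisson-spaced release events
    mu_eff <- rep(s$mu_d, n)
    if (s$stickslip_amp > 0) {
      gaps <- rexp(ceiling(4 * s$slide_length / s$slip_dist) + 10, 1 / s$slip_dist)
      bounds <- c(0, cumsum(gaps))
      bounds <- c(bounds[bounds < s$slide_length], s$slide_length)
      idx <- findInterval(x, bounds, rightmost.closed = TRUE)
      frac <- (x - bounds[idx]) / (bounds[idx + 1L] - bounds[idx])
      saw <- 2 * frac - 1
      mu_eff <- s$mu_d * (1 + s$stickslip_amp * saw)
    }

    # dynamic lateral force from the exact balance
    fx_dyn <- balance_fx(mu_eff, slope, N_vert)

    # static peak at the end of the pre-sliding ramp
    peak_i <- which(x >= ramp_dist)[1]
    if (is.na(peak_i)) peak_i <- n
    fx_peak <- balance_fx(s$mu_s, slope[peak_i], N_vert[peak_i])

    fx <- rep(0, n)
    ramp_sel <- moving & x <= x[peak_i]
    fx[ramp_sel] <- (x[ramp_sel] / x[peak_i]) * fx_peak
    post <- moving & x > x[peak_i]
    decay <- exp(-(x[post] - x[peak_i]) / decay_dist)
    fx[post] <- fx_dyn[post] +
      (fx_peak - balance_fx(s$mu_d, slope[peak_i], N_vert[peak_i])) * decay
    fx <- fx + s$fx_baseline
    if (s$noise_sd_F > 0) fx <- fx + rnorm(n, 0, s$noise_sd_F)

    h_m <- surface_height(x, s$tilt, s$meniscus_depth, s$slide_length)
    if (s$noise_sd_h > 0) h_m <- h_m + rnorm(n, 0, s$noise_sd_h)

    gt <- list(
      onset_index = which(moving)[1],
      static_peak_index = peak_i,
      mu_s = s$mu_s,
      mu_d = s$mu_d,
      zero_slope_x = zero_slope_position(s$tilt, s$meniscus_depth,
                                         s$slide_length),
      tilt = s$tilt,
      fx_baseline = s$fx_baseline,
      fx_static_peak = fx_peak + s$fx_baseline
    )

    as_tribo_trace(
      tibble::tibble(time_s = time_s, x_mm = x, h_mm = h_m,
                     fx_mN = fx, fz_mN = fz),
      F_N_set = s$F_N_set, v_t = s$v_t, rate = s$rate,
      ground_truth = gt, scenario = s
    )
  })
}
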