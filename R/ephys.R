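## Seal-test synthesis, resistance estimation from the filtered current,
## the pipette/membrane impedance simulator, and the adaptive-suction seal
## and break-in logic. Units: mV, nA, MOhm (mV / nA = MOhm), kPa, s.

#' Seal-test signal configuration
#'
#' A small square wave continuously monitors pipette impedance: 10 mV
#' amplitude at 10 Hz, digitized at 20 kHz and low-pass filtered with a
#' digital Bessel filter. The filter cutoff must be strictly below the
#' Nyquist frequency; the default sits at 0.45 of the sample rate.
#'
#' @param amplitude square-wave amplitude (mV peak-to-peak).
#' @param frequency square-wave frequency (Hz).
#' @param sample_rate digitizer rate (Hz).
#' @param filter_cutoff Bessel low-pass cutoff (Hz, < sample_rate / 2).
#' @param holding_potential holding voltage the test rides on (mV; 0 in
#'   the bath, -70 during sealing).
#' @param noise_floor smallest measurable peak-to-peak current (nA);
#'   below it the resistance is reported as unmeasurable.
#' @return a list of class `seal_test_config`.
#' @export
seal_test_config <- function(amplitude = 10, frequency = 10,
                             sample_rate = 20000, filter_cutoff = 9000,
                             holding_potential = 0,
                             noise_floor = 1e-4) {
  stopifnot(amplitude > 0, frequency > 0, sample_rate > 0)
  if (filter_cutoff >= sample_rate / 2)
    stop("filter_cutoff must be below the Nyquist frequency")
  structure(list(amplitude = amplitude, frequency = frequency,
                 sample_rate = sample_rate, filter_cutoff = filter_cutoff,
                 holding_potential = holding_potential,
                 noise_floor = noise_floor),
            class = "seal_test_config")
}

#' Generate the seal-test voltage waveform
#'
#' Square wave alternating between `holding_potential` and
#' `holding_potential + amplitude`, starting high.
#'
#' @param config a [seal_test_config()].
#' @param duration trace length (s, at least one period).
#' @return numeric voltage trace (mV) at `sample_rate`.
#' @export
seal_test_waveform <- function(config, duration) {
  if (duration < 1 / config$frequency)
    stop("duration must cover at least one seal-test period")
  n <- round(duration * config$sample_rate)
  phase <- ((seq_len(n) - 1) / config$sample_rate * config$frequency) %% 1
  config$holding_potential + config$amplitude * (phase < 0.5)
}

## Order-n reverse Bessel polynomial coefficients (ascending powers).
reverse_bessel_poly <- function(order) {
  th0 <- 1
  th1 <- c(1, 1)
  if (order == 0) return(th0)
  for (n in 2:max(order, 2)) {
    ## theta_n = (2n - 1) theta_{n-1} + s^2 theta_{n-2}
    a <- (2 * n - 1) * th1
    b <- c(0, 0, th0)
    len <- max(length(a), length(b))
    th <- c(a, numeric(len - length(a))) + c(b, numeric(len - length(b)))
    th0 <- th1; th1 <- th
    if (n == order) return(th1)
  }
  th1
}

## Analytic squared magnitude of the normalized analog prototype at w.
bessel_prototype_mag2 <- function(w, coefs) {
  c0 <- coefs[1]
  jw <- vapply(w, function(wi)
    sum(coefs * (1i * wi)^(seq_along(coefs) - 1)), complex(1))
  (c0 / Mod(jw))^2
}

bessel_w3db <- function(coefs) {
  uniroot(function(w) bessel_prototype_mag2(w, coefs) - 0.5,
          c(1e-6, 20), tol = 1e-12)$root
}

bessel_design <- function(cutoff_hz, sample_rate, order = 4) {
  coefs <- reverse_bessel_poly(order)
  poles <- polyroot(coefs)
  w3 <- bessel_w3db(coefs)
  wa <- 2 * sample_rate * tan(pi * cutoff_hz / sample_rate)  # prewarp
  sp <- poles * (wa / w3)
  sg <- Re(prod(-sp))                       # unity DC gain
  zpg <- signal::bilinear(Sz = complex(0), Sp = sp, Sg = sg,
                          T = 1 / sample_rate)
  signal::as.Arma(zpg)
}

#' Digital Bessel low-pass filter
#'
#' Order-4 Bessel response designed from the analog prototype (reverse
#' Bessel polynomial poles, -3 dB normalization, bilinear transform with
#' prewarping). DC gain is exactly 1.
#'
#' The filter state is initialized at steady state for the trace's first
#' sample, so short traces riding on a large holding current are not
#' distorted by a start-up transient.
#'
#' @param x input trace sampled at `config$sample_rate`.
#' @param config a [seal_test_config()] carrying sample rate and cutoff.
#' @param order filter order.
#' @return the filtered trace.
#' @export
bessel_lowpass <- function(x, config, order = 4) {
  if (config$filter_cutoff >= config$sample_rate / 2)
    stop("filter_cutoff must be below the Nyquist frequency")
  arma <- bessel_design(config$filter_cutoff, config$sample_rate, order)
  if (length(x) == 0) return(numeric(0))
  npad <- 200L
  y <- Re(signal::filter(arma, c(rep(x[1], npad), x)))
  as.numeric(y[-seq_len(npad)])
}

#' Analytic Bessel magnitude response
#'
#' Magnitude of the analog prototype at frequency `f` for a filter with
#' the given cutoff; used as the reference the digital implementation must
#' attenuate at least as much as.
#'
#' @param f frequency (Hz).
#' @param cutoff -3 dB cutoff (Hz).
#' @param order filter order.
#' @return magnitude gain in (0, 1].
#' @export
bessel_magnitude <- function(f, cutoff, order = 4) {
  coefs <- reverse_bessel_poly(order)
  w3 <- bessel_w3db(coefs)
  sqrt(bessel_prototype_mag2(f / cutoff * w3, coefs))
}

#' Estimate pipette resistance from the seal-test current
#'
#' Per cycle, the resistance is the applied voltage amplitude over the
#' peak-to-peak current. The peak-to-peak value is measured between the
#' two plateau levels (medians of the upper and lower half-cycle samples),
#' which makes it insensitive to the filter's edge transients. Cycles whose
#' current swing falls below the noise floor are reported as `Inf`
#' (unmeasurable, open-circuit / gigaohm regime).
#'
#' @param amplitude applied square-wave amplitude (mV).
#' @param current filtered current trace (nA) spanning >= 1 full cycle.
#' @param config a [seal_test_config()].
#' @return a list with `per_cycle` (MOhm) and their median `resistance`;
#'   attribute `unmeasurable` is TRUE when every cycle is below the floor.
#' @export
estimate_resistance <- function(amplitude, current, config) {
  spc <- round(config$sample_rate / config$frequency)
  ncyc <- length(current) %/% spc
  if (ncyc < 1) stop("current trace must span at least one full cycle")
  per <- vapply(seq_len(ncyc), function(k) {
    seg <- current[((k - 1) * spc + 1):(k * spc)]
    mid <- (max(seg) + min(seg)) / 2
    hi <- median(seg[seg >= mid])
    lo <- median(seg[seg < mid])
    ipp <- hi - lo
    if (!is.finite(ipp) || ipp < config$noise_floor) Inf
    else amplitude / ipp
  }, numeric(1))
  r <- median(per)
  out <- list(per_cycle = per, resistance = r)
  attr(out, "unmeasurable") <- !any(is.finite(per))
  out
}

#' Pipette/membrane impedance simulator
#'
#' Piecewise resistance dynamics through the patching stages. In `bath`
#' the resistance is the open-pipette value; on membrane `contact` it
#' rises by `contact_factor`; during `sealing` it grows logistically
#' toward `seal_resistance_target` at a rate multiplied by
#' `g = (1 + suction_gain * |P_neg|) * (1 + holding_gain * |V_hold| / 70)`
#' — gentle suction and hyperpolarization both speed seal formation; in
#' `wholecell` it collapses to the access resistance; `clogged` is a step
#' increase far from any target.
#'
#' @param r_bath open pipette resistance (MOhm, 5-7 typical).
#' @param contact_factor relative resistance rise on membrane contact
#'   (> 1).
#' @param seal_resistance_target saturation of the seal growth (MOhm).
#' @param seal_rate base logistic growth constant (1/s).
#' @param suction_gain seal-rate gain per kPa of suction (1/kPa).
#' @param holding_gain seal-rate gain at -70 mV holding (dimensionless).
#' @param r_access_wholecell access (series) resistance after break-in
#'   (MOhm).
#' @param clog_factor relative resistance rise when clogged.
#' @param rate_factor per-experiment multiplier on `seal_rate` (drawn by
#'   the rig to emulate cell-to-cell variability).
#' @param rupture_threshold cumulative suction-pulse amplitude (kPa) at
#'   which the membrane patch ruptures.
#' @param current_noise_sd measurement noise on the current trace (nA).
#' @param stage initial stage.
#' @return a list of class `impedance_model`.
#' @export
impedance_model <- function(r_bath = 6, contact_factor = 1.3,
                            seal_resistance_target = 1500,
                            seal_rate = 0.35, suction_gain = 0.5,
                            holding_gain = 1, r_access_wholecell = 16,
                            clog_factor = 2.5, rate_factor = 1,
                            rupture_threshold = 30,
                            current_noise_sd = 0,
                            stage = c("bath", "contact", "sealing",
                                      "sealed", "wholecell", "clogged")) {
  stage <- match.arg(stage)
  stopifnot(r_bath > 0, contact_factor > 1,
            seal_resistance_target > r_bath * contact_factor,
            seal_rate > 0, r_access_wholecell > 0)
  m <- structure(list(r_bath = r_bath, contact_factor = contact_factor,
                      seal_resistance_target = seal_resistance_target,
                      seal_rate = seal_rate, suction_gain = suction_gain,
                      holding_gain = holding_gain,
                      r_access_wholecell = r_access_wholecell,
                      clog_factor = clog_factor,
                      rate_factor = rate_factor,
                      rupture_threshold = rupture_threshold,
                      current_noise_sd = current_noise_sd,
                      pulse_stress = 0, stage = "bath", resistance = r_bath),
                 class = "impedance_model")
  set_stage(m, stage)
}

#' Switch the impedance simulator's stage
#'
#' @param model an `impedance_model`.
#' @param stage new stage.
#' @return the updated model with its resistance adjusted to the stage's
#'   entry value (sealing continues from the current resistance).
#' @export
set_stage <- function(model, stage) {
  stage <- match.arg(stage, c("bath", "contact", "sealing", "sealed",
                              "wholecell", "clogged"))
  model$resistance <- switch(
    stage,
    bath = model$r_bath,
    contact = model$r_bath * model$contact_factor,
    sealing = max(model$resistance, model$r_bath * model$contact_factor),
    sealed = model$resistance,
    wholecell = model$r_access_wholecell,
    clogged = model$r_bath * model$clog_factor)
  model$stage <- stage
  model
}

seal_g <- function(model, pressure, holding) {
  (1 + model$suction_gain * max(0, -pressure)) *
    (1 + model$holding_gain * abs(holding) / 70)
}

#' Simulate the current response to an applied voltage trace
#'
#' Returns `current = voltage / R(t)` (mV / MOhm = nA) while evolving the
#' resistance according to the active stage over the trace duration. During
#' sealing the logistic growth rate depends on the pipette pressure and on
#' the holding potential (inferred from the waveform's lower level unless
#' given).
#'
#' @param model an `impedance_model`.
#' @param voltage applied voltage trace (mV) at `config$sample_rate`.
#' @param pressure pipette internal pressure over the trace (kPa).
#' @param config a [seal_test_config()].
#' @param holding holding potential (mV); default inferred as `min(voltage)`.
#' @return a list with `current` (nA) and the evolved `model`.
#' @export
impedance_response <- function(model, voltage, pressure, config,
                               holding = NULL) {
  n <- length(voltage)
  dt_total <- n / config$sample_rate
  if (is.null(holding)) holding <- min(voltage)
  r0 <- model$resistance
  r1 <- r0
  if (model$stage == "sealing") {
    K <- model$seal_resistance_target
    rate <- model$seal_rate * model$rate_factor *
      seal_g(model, pressure, holding)
    ## exact logistic propagation over the trace duration
    r1 <- K / (1 + (K / r0 - 1) * exp(-rate * dt_total))
    model$resistance <- r1
  }
  r_t <- seq(r0, r1, length.out = n)
  current <- voltage / r_t
  if (model$current_noise_sd > 0)
    current <- current + rnorm(n, 0, model$current_noise_sd)
  list(current = current, model = model)
}

#' Detect target engagement from the resistance history
#'
#' Engagement (tip on membrane) is confirmed when the running resistance
#' exceeds its pre-approach baseline by `rel_increase`, sustained for
#' `dwell` consecutive samples.
#'
#' @param r_history resistance samples (MOhm), oldest first.
#' @param baseline_n leading samples forming the baseline.
#' @param rel_increase required relative increase (default 20%).
#' @param dwell consecutive samples the increase must persist.
#' @return TRUE or FALSE.
#' @export
detect_engagement <- function(r_history, baseline_n = 5L,
                              rel_increase = 0.2, dwell = 3L) {
  if (length(r_history) < baseline_n + dwell) return(FALSE)
  baseline <- median(r_history[seq_len(baseline_n)])
  recent <- tail(r_history, dwell)
  all(recent >= baseline * (1 + rel_increase))
}

#' Adaptive suction policy for seal enhancement
#'
#' @param s_th minimum resistance increase (MOhm) expected over `t_seal`.
#' @param t_seal evaluation window (s).
#' @param low_fraction fraction of the target seal resistance below which
#'   suction may be deepened (0.15).
#' @param suction_step setpoint decrement per firing (kPa, negative).
#' @param seal_threshold resistance declaring a gigaseal (MOhm, within
#'   1000-1500).
#' @param max_suction deepest allowed suction setpoint (kPa, negative).
#' @param time_limit time allowed to attain a seal before the attempt is
#'   reported failed (s).
#' @param min_interval minimum time between deepenings (s).
#' @return a list of class `suction_policy`.
#' @export
suction_policy <- function(s_th = 5, t_seal = 2, low_fraction = 0.15,
                           suction_step = -1, seal_threshold = 1000,
                           max_suction = -10, time_limit = 60,
                           min_interval = NULL) {
  stopifnot(low_fraction > 0, low_fraction < 1, time_limit > t_seal,
            suction_step < 0, max_suction < 0,
            seal_threshold >= 1000, seal_threshold <= 1500)
  structure(list(s_th = s_th, t_seal = t_seal, low_fraction = low_fraction,
                 suction_step = suction_step,
                 seal_threshold = seal_threshold,
                 max_suction = max_suction, time_limit = time_limit,
                 min_interval = min_interval %||% t_seal),
            class = "suction_policy")
}

#' One evaluation of the adaptive suction rule
#'
#' Suction is deepened if and only if the resistance is below
#' `low_fraction` of the target seal resistance AND it has failed to grow
#' by at least `s_th` over the trailing `t_seal` window (and at least
#' `min_interval` has passed since the last deepening). Otherwise the
#' current setpoint is held.
#'
#' @param policy a [suction_policy()].
#' @param history data.frame with columns `t`, `r` (MOhm), oldest first.
#' @param t current time (s).
#' @param setpoint current pressure setpoint (kPa).
#' @param last_change time of the previous deepening (s; `-Inf` if none).
#' @return a list with `setpoint` (possibly deepened) and `fired`.
#' @export
adaptive_suction_step <- function(policy, history, t, setpoint,
                                  last_change = -Inf) {
  hold <- list(setpoint = setpoint, fired = FALSE)
  if (nrow(history) < 2) return(hold)
  if (max(history$t) - min(history$t) < policy$t_seal) return(hold)
  r_now <- history$r[nrow(history)]
  r_then <- stats::approx(history$t, history$r, xout = t - policy$t_seal,
                          rule = 2)$y
  fire <- r_now < policy$low_fraction * policy$seal_threshold &&
    (r_now - r_then) < policy$s_th &&
    (t - last_change) >= policy$min_interval
  if (!fire) return(hold)
  list(setpoint = max(policy$max_suction, setpoint + policy$suction_step),
       fired = TRUE)
}

#' Declare a gigaseal
#' @param r current resistance (MOhm).
#' @param policy a [suction_policy()].
#' @return TRUE when `r >= seal_threshold`.
#' @export
detect_seal <- function(r, policy) r >= policy$seal_threshold

#' Detect break-in from the resistance history
#'
#' Break-in (membrane patch rupture) shows as a sharp resistance drop: the
#' latest sample at least `factor` times below the maximum of the
#' preceding `window` samples.
#'
#' @param r_history resistance samples (MOhm), oldest first.
#' @param factor minimum drop ratio (default 10x).
#' @param window look-back window (samples).
#' @return TRUE or FALSE.
#' @export
detect_breakin <- function(r_history, factor = 10, window = 5L) {
  n <- length(r_history)
  if (n < 2) return(FALSE)
  ref <- max(r_history[max(1, n - window):(n - 1)])
  r_history[n] <= ref / factor
}

#' Apply a series of suction pulses until break-in
#'
#' Pulses of escalating amplitude are applied through the pressure
#' controller, with a resistance check between pulses; stops at break-in
#' detection or when the pulse budget is exhausted.
#'
#' @param apply_pulse `function(amplitude_kPa, duration_s)` that drives
#'   the pneumatics and the membrane model.
#' @param measure_r `function()` returning the current resistance (MOhm).
#' @param start_amplitude first pulse amplitude (kPa, negative).
#' @param escalation amplitude increment per pulse (kPa, <= 0).
#' @param duration pulse duration (s).
#' @param budget maximum number of pulses.
#' @param factor,window break-in detection parameters
#'   (see [detect_breakin()]).
#' @return a list with `success`, `pulses` applied, and the `r_history`.
#' @export
breakin_pulses <- function(apply_pulse, measure_r, start_amplitude = -15,
                           escalation = -5, duration = 0.3, budget = 10L,
                           factor = 10, window = 5L) {
  stopifnot(start_amplitude < 0, escalation <= 0, duration > 0,
            budget >= 1)
  hist <- measure_r()
  for (i in seq_len(budget)) {
    amp <- start_amplitude + escalation * (i - 1)
    apply_pulse(amp, duration)
    hist <- c(hist, measure_r())
    if (detect_breakin(hist, factor, window))
      return(list(success = TRUE, pulses = i, r_history = hist))
  }
  list(success = FALSE, pulses = budget, r_history = hist)
}

#' Check the pipette for clogging
#'
#' While far from any target, a resistance at or above `factor` times the
#' open-pipette baseline means the tip is clogged (boundary inclusive).
#'
#' @param r measured resistance (MOhm).
#' @param baseline open-pipette baseline (MOhm).
#' @param factor clog threshold factor.
#' @return `"ok"` or `"clogged"`.
#' @export
check_pipette <- function(r, baseline, factor = 1.5) {
  if (r >= factor * baseline) "clogged" else "ok"
}
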