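## Closed-loop pipette internal pressure: a discrete PID controller with
## anti-windup and derivative-on-measurement, driving a signed first-order
## pneumatic plant. The physical valve network (positive branch, Venturi
## vacuum branch, 3-port selector) is collapsed into one saturating
## first-order system; the commanded pressure is scaled by the ratio of
## actual to nominal supply pressure, so supply fluctuations act as a real
## disturbance that only closed-loop control rejects.

#' PID controller gains and limits
#'
#' Defaults are tuned for settling within about 1 s of simulated time on
#' the default plant (tau = 0.1 s); the controller runs at a typical
#' microcontroller loop rate of 1 kHz.
#'
#' @param kp,ki,kd proportional, integral, derivative gains.
#' @param output_limits command clamp (kPa).
#' @param integral_limit anti-windup bound on the integral term (kPa).
#' @param sample_dt controller period (s).
#' @return a list of class `pid_gains`.
#' @export
pid_gains <- function(kp = 3, ki = 30, kd = 0,
                      output_limits = c(-85, 55), integral_limit = 85,
                      sample_dt = 0.001) {
  stopifnot(sample_dt > 0, integral_limit > 0,
            output_limits[1] < output_limits[2])
  structure(list(kp = kp, ki = ki, kd = kd,
                 output_limits = output_limits,
                 integral_limit = integral_limit, sample_dt = sample_dt),
            class = "pid_gains")
}

#' Create a PID controller state
#' @param gains a [pid_gains()].
#' @return a list of class `pid_state`.
#' @export
pid_new <- function(gains = pid_gains()) {
  structure(list(gains = gains, integral = 0, prev_meas = NA_real_),
            class = "pid_state")
}

#' One PID update
#'
#' Standard discrete PID with clamped integral (anti-windup), clamped
#' output, and the derivative taken on the measurement (avoiding setpoint
#' kick).
#'
#' @param pid a `pid_state`.
#' @param setpoint desired pressure (kPa).
#' @param measurement measured pressure (kPa).
#' @return a list with the updated `pid` and the `command` (kPa).
#' @export
pid_step <- function(pid, setpoint, measurement) {
  g <- pid$gains
  e <- setpoint - measurement
  pid$integral <- pid$integral + g$ki * e * g$sample_dt
  pid$integral <- max(-g$integral_limit, min(g$integral_limit, pid$integral))
  d <- if (is.na(pid$prev_meas) || g$kd == 0) 0 else
    -g$kd * (measurement - pid$prev_meas) / g$sample_dt
  pid$prev_meas <- measurement
  u <- g$kp * e + pid$integral + d
  u <- max(g$output_limits[1], min(g$output_limits[2], u))
  list(pid = pid, command = u)
}

#' Pneumatic plant parameters and state
#'
#' @param tau first-order time constant (s).
#' @param supply_pressure positive-branch supply (kPa).
#' @param vacuum_limit Venturi branch limit (kPa, negative).
#' @param supply_nominal nominal supply the commanded pressure is
#'   calibrated against (kPa).
#' @param noise_sd pressure process noise (kPa / sqrt(s)).
#' @param pressure initial pressure (kPa).
#' @return a list of class `plant_state`.
#' @export
plant_new <- function(tau = 0.1, supply_pressure = 50, vacuum_limit = -80,
                      supply_nominal = 50, noise_sd = 0, pressure = 0) {
  stopifnot(tau > 0, vacuum_limit < 0, supply_pressure > 0,
            pressure >= vacuum_limit, pressure <= supply_pressure)
  structure(list(pressure = pressure, tau = tau,
                 supply_pressure = supply_pressure,
                 vacuum_limit = vacuum_limit,
                 supply_nominal = supply_nominal, noise_sd = noise_sd,
                 branch = if (pressure < 0) "negative" else "positive"),
            class = "plant_state")
}

#' Advance the plant by dt under a command
#'
#' Exact discretization of `dP/dt = (u_eff - P) / tau` with
#' `u_eff = command * supply_pressure / supply_nominal`, plus optional
#' process noise, clipped to `[vacuum_limit, supply_pressure]`. The branch
#' (positive / Venturi vacuum) follows the sign of the demanded pressure.
#'
#' @param plant a `plant_state`.
#' @param command commanded pressure (kPa).
#' @param dt time step (s, > 0).
#' @return the updated plant.
#' @export
plant_step <- function(plant, command, dt) {
  stopifnot(dt > 0)
  u_eff <- command * plant$supply_pressure / plant$supply_nominal
  alpha <- 1 - exp(-dt / plant$tau)
  p <- plant$pressure + alpha * (u_eff - plant$pressure)
  if (plant$noise_sd > 0) p <- p + rnorm(1, 0, plant$noise_sd * sqrt(dt))
  plant$pressure <- max(plant$vacuum_limit, min(plant$supply_pressure, p))
  plant$branch <- if (command < 0) "negative" else "positive"
  plant
}

#' Run the closed loop until the pressure settles
#'
#' Simulates controller + plant at the controller rate until the pressure
#' stays within `tolerance` of the setpoint for a `dwell` window, or until
#' `timeout`. Optionally perturbs the supply pressure mid-run.
#'
#' @param pid a `pid_state`.
#' @param plant a `plant_state`.
#' @param setpoint target pressure (kPa).
#' @param tolerance settling band (kPa, > 0).
#' @param timeout maximum simulated time (s).
#' @param dwell time the pressure must stay in band (s).
#' @param disturb optional `list(t =, supply =)`: at time `t` the supply
#'   pressure jumps to `supply`.
#' @return a list with `settled`, `elapsed`, the `trace` data.frame
#'   (t, setpoint, pressure, command), and the final `pid` and `plant`.
#' @export
settle <- function(pid, plant, setpoint, tolerance = 0.5, timeout = 3,
                   dwell = 0.05, disturb = NULL) {
  stopifnot(tolerance > 0, timeout > 0)
  dt <- pid$gains$sample_dt
  n <- ceiling(timeout / dt)
  need <- max(1L, ceiling(dwell / dt))
  tr_t <- numeric(n); tr_p <- numeric(n); tr_u <- numeric(n)
  inband <- 0L; settled <- FALSE; i <- 0L
  while (i < n) {
    i <- i + 1L
    t <- i * dt
    if (!is.null(disturb) && t >= disturb$t && !is.na(disturb$supply)) {
      plant$supply_pressure <- disturb$supply
      disturb$supply <- NA_real_
    }
    st <- pid_step(pid, setpoint, plant$pressure)
    pid <- st$pid
    plant <- plant_step(plant, st$command, dt)
    tr_t[i] <- t; tr_p[i] <- plant$pressure; tr_u[i] <- st$command
    inband <- if (abs(plant$pressure - setpoint) <= tolerance)
      inband + 1L else 0L
    if (inband >= need) { settled <- TRUE; break }
  }
  list(settled = settled, elapsed = i * dt,
       trace = data.frame(t = tr_t[seq_len(i)], setpoint = setpoint,
                          pressure = tr_p[seq_len(i)],
                          command = tr_u[seq_len(i)]),
       pid = pid, plant = plant)
}
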