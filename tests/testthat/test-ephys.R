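cfg_st <- seal_test_config()

test_that("the seal-test waveform has the stated shape", {
  v <- seal_test_waveform(cfg_st, 1)
  expect_length(v, 20000)
  expect_setequal(unique(v), c(0, 10))
  expect_equal(diff(range(v)), 10)                   # peak-to-peak 10 mV
  ## 10 cycles in 1 s: 10 rising edges
  expect_equal(sum(diff(v) > 0), 10 - 1 + 1, tolerance = 1)
  ## holding offsets shift both levels
  ch <- seal_test_config(holding_potential = -70)
  vh <- seal_test_waveform(ch, 0.2)
  expect_setequal(unique(vh), c(-70, -60))
  expect_error(seal_test_waveform(cfg_st, 0.05), "one seal-test period")
})

test_that("the Bessel low-pass passes DC and beats its analog envelope", {
  expect_equal(tail(bessel_lowpass(rep(3.7, 2000), cfg_st), 1), 3.7,
               tolerance = 1e-6)
  expect_true(all(bessel_lowpass(numeric(1000), cfg_st) == 0))

  cfg2 <- seal_test_config(filter_cutoff = 2000)
  t <- (0:19999) / 20000
  for (f in c(5000, 8000)) {
    y <- bessel_lowpass(sin(2 * pi * f * t), cfg2)
    out_amp <- max(abs(tail(y, 10000)))
    expect_lte(out_amp, bessel_magnitude(f, 2000))
  }
  expect_error(seal_test_config(filter_cutoff = 10000), "Nyquist")
  bad <- cfg_st; bad$filter_cutoff <- 10000
  expect_error(bessel_lowpass(rnorm(100), bad), "Nyquist")
})

test_that("resistance estimation inverts Ohm's law exactly", {
  spc <- 2000                                  # samples per 10 Hz cycle
  ## ideal 2 nA peak-to-peak square current: 10 mV / 2 nA = 5 MOhm
  i1 <- rep(c(rep(2, spc / 2), rep(0, spc / 2)), 3)
  est1 <- estimate_resistance(10, i1, cfg_st)
  expect_equal(est1$resistance, 5)
  expect_equal(unique(est1$per_cycle), 5)

  ## 10 pA peak-to-peak: 1 GOhm
  i2 <- rep(c(rep(0.01, spc / 2), rep(0, spc / 2)), 2)
  expect_equal(estimate_resistance(10, i2, cfg_st)$resistance, 1000)

  ## below the noise floor: unmeasurable sentinel
  i3 <- rep(c(rep(5e-5, spc / 2), rep(0, spc / 2)), 2)
  est3 <- estimate_resistance(10, i3, cfg_st)
  expect_true(is.infinite(est3$resistance))
  expect_true(attr(est3, "unmeasurable"))
})

test_that("the full measurement chain recovers the simulator's resistance", {
  for (r in c(5, 6, 7, 250)) {
    m <- impedance_model(r_bath = 6)
    m$resistance <- r; m$stage <- "bath"
    v <- seal_test_waveform(cfg_st, 0.3)
    resp <- impedance_response(m, v, 0, cfg_st)
    filt <- bessel_lowpass(resp$current, cfg_st)
    est <- estimate_resistance(cfg_st$amplitude, filt, cfg_st)
    expect_equal(est$resistance, r, tolerance = r * 1e-3)
  }
})

test_that("sealing dynamics respond to suction and hyperpolarization", {
  mk <- function() {
    m <- impedance_model()
    m <- set_stage(m, "contact")
    set_stage(m, "sealing")
  }
  first_crossing <- function(pressure, holding) {
    m <- mk()
    t <- 0
    while (m$resistance < 1000 && t < 500) {
      v <- seal_test_waveform(seal_test_config(
        holding_potential = holding), 0.1)
      m <- impedance_response(m, v, pressure, cfg_st,
                              holding = holding)$model
      t <- t + 0.1
    }
    t
  }
  t_plain <- first_crossing(0, 0)
  t_helped <- first_crossing(-2, -70)
  expect_lt(t_helped, t_plain)

  ## bath stage resistance stays constant
  m0 <- impedance_model()
  r0 <- m0$resistance
  m0 <- impedance_response(m0, seal_test_waveform(cfg_st, 0.2), -5,
                           cfg_st)$model
  expect_equal(m0$resistance, r0)

  ## whole-cell collapses to the access resistance
  mw <- set_stage(impedance_model(), "wholecell")
  expect_lte(mw$resistance, 2 * mw$r_access_wholecell)

  ## sealing resistance never decreases
  m <- mk(); rs <- m$resistance
  for (k in 1:50) {
    m <- impedance_response(m, seal_test_waveform(cfg_st, 0.1),
                            -2, cfg_st, holding = -70)$model
    rs <- c(rs, m$resistance)
  }
  expect_true(all(diff(rs) >= 0))
})

test_that("engagement detection needs a sustained relative rise", {
  expect_false(detect_engagement(rep(6, 20)))
  expect_true(detect_engagement(c(rep(6, 10), rep(7.8, 3))))
  ## single-sample spike: rejected by the dwell rule
  expect_false(detect_engagement(c(rep(6, 10), 9, 6, 6)))
  ## sub-threshold rise: 15% < 20%
  expect_false(detect_engagement(c(rep(6, 10), rep(6.9, 5))))
})

test_that("the adaptive suction rule fires iff low R and stalled growth", {
  pol <- suction_policy(s_th = 5, t_seal = 2, seal_threshold = 1000)
  hist_flat_low <- data.frame(t = seq(0, 4, 0.5), r = 50)
  hist_flat_high <- data.frame(t = seq(0, 4, 0.5), r = 200)
  hist_rising_low <- data.frame(t = seq(0, 4, 0.5),
                                r = 50 + 6 * seq(0, 4, 0.5))
  hist_rising_high <- data.frame(t = seq(0, 4, 0.5),
                                 r = 200 + 10 * seq(0, 4, 0.5))

  ## R = 50 (5% of 1 GOhm target) and stalled: deepen
  a1 <- adaptive_suction_step(pol, hist_flat_low, 4, 0)
  expect_true(a1$fired)
  expect_equal(a1$setpoint, -1)
  ## R = 200 (20% > 15%): hold even if stalled
  expect_false(adaptive_suction_step(pol, hist_flat_high, 4, 0)$fired)
  ## rising faster than s_th per t_seal: hold
  expect_false(adaptive_suction_step(pol, hist_rising_low, 4, 0)$fired)
  expect_false(adaptive_suction_step(pol, hist_rising_high, 4, 0)$fired)
  ## suction never deepens beyond the configured limit
  a2 <- adaptive_suction_step(pol, hist_flat_low, 4, -9.8)
  expect_gte(a2$setpoint, pol$max_suction)
})

test_that("seal and break-in detection follow their thresholds", {
  pol <- suction_policy(seal_threshold = 1000)
  expect_true(detect_seal(1200, pol))
  expect_false(detect_seal(900, pol))

  ## sealed at 1.5 GOhm dropping to 16 MOhm: a clear break-in
  expect_true(detect_breakin(c(rep(1500, 5), 16)))
  expect_false(detect_breakin(c(rep(1500, 5), 1400)))
  expect_false(detect_breakin(1500))
})

test_that("break-in pulse scheduling stops on rupture or budget", {
  mk_rig <- function(rupture_at) {
    env <- new.env()
    env$stress <- 0; env$broken <- FALSE; env$n <- 0
    list(
      pulse = function(amp, dur) {
        env$n <- env$n + 1
        if (env$n >= rupture_at) env$broken <- TRUE
      },
      measure = function() if (env$broken) 16 else 1500,
      env = env)
  }
  r3 <- mk_rig(3)
  out <- breakin_pulses(r3$pulse, r3$measure)
  expect_true(out$success)
  expect_equal(out$pulses, 3)

  r1 <- mk_rig(1)
  out1 <- breakin_pulses(r1$pulse, r1$measure)
  expect_true(out1$success)
  expect_equal(out1$pulses, 1)

  never <- mk_rig(Inf)
  outn <- breakin_pulses(never$pulse, never$measure, budget = 10)
  expect_false(outn$success)
  expect_equal(outn$pulses, 10)
})

test_that("clog checking uses an inclusive factor threshold", {
  expect_equal(check_pipette(6, 6), "ok")
  expect_equal(check_pipette(12, 6), "clogged")
  expect_equal(check_pipette(9, 6), "clogged")      # boundary inclusive
  expect_equal(check_pipette(8.9, 6), "ok")
})
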