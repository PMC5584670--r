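## Orchestration of the full visually guided patching procedure against the
## virtual rig: positioning -> approach -> engagement -> seal -> break-in ->
## whole-cell, with an append-only event log, Fig-style traces, and seeded
## determinism. All timing is simulated seconds at fixed ticks; there is no
## wall-clock dependence.

#' Experiment configuration
#'
#' Bundles every sub-configuration of the virtual rig. The seed is
#' mandatory: every stochastic element of a run (scene layout, imaging
#' noise, membrane variability) derives from it, so identical
#' configurations with identical seeds produce identical event logs.
#'
#' @param scene a [scene_config()].
#' @param seg a [seg_config()].
#' @param approach an [approach_config()].
#' @param gains a [pid_gains()].
#' @param plant a [plant_new()] initial plant state.
#' @param seal_test a [seal_test_config()].
#' @param policy a [suction_policy()].
#' @param impedance an [impedance_model()] template; per-run variability
#'   (rate factor, rupture threshold) is drawn on top of it.
#' @param mode `"targeted"` (visual servoing), `"blind"` (impedance-only
#'   descent is out of the acceptance path and kept minimal), or
#'   `"manual_assist"`.
#' @param seed integer seed (mandatory).
#' @param frame_period imaging frame period (s).
#' @param initial_focal_z focal plane the operator starts on (um);
#'   defaults to the configured target depth.
#' @param target_point (x, y) um selection point for the target click.
#' @param target_rule `"nearest"` (to `target_point`) or `"brightest"`.
#' @param miss_budget tracker miss budget (frames).
#' @param breakin_budget maximum suction pulses.
#' @param noise logical, render imaging noise.
#' @param outdir optional directory for event log / trace / trajectory
#'   files.
#' @return a list of class `experiment_config`.
#' @export
experiment_config <- function(scene = scene_config(), seg = seg_config(),
                              approach = approach_config(),
                              gains = pid_gains(), plant = plant_new(),
                              seal_test = seal_test_config(),
                              policy = suction_policy(),
                              impedance = impedance_model(
                                current_noise_sd = 0.002),
                              mode = c("targeted", "blind",
                                       "manual_assist"),
                              seed = NULL, frame_period = 0.25,
                              initial_focal_z = NULL,
                              target_point = c(0, 0),
                              target_rule = c("nearest", "brightest"),
                              miss_budget = 5L, breakin_budget = 10L,
                              noise = TRUE, outdir = NULL) {
  mode <- match.arg(mode)
  target_rule <- match.arg(target_rule)
  if (is.null(seed)) stop("seed is mandatory")
  structure(list(scene = scene, seg = seg, approach = approach,
                 gains = gains, plant = plant, seal_test = seal_test,
                 policy = policy, impedance = impedance, mode = mode,
                 seed = as.integer(seed), frame_period = frame_period,
                 initial_focal_z = initial_focal_z %||%
                   scene$target_center[3],
                 target_point = target_point, target_rule = target_rule,
                 miss_budget = as.integer(miss_budget),
                 breakin_budget = as.integer(breakin_budget),
                 noise = noise, outdir = outdir),
            class = "experiment_config")
}

#' Read an experiment configuration from YAML
#'
#' Scalar fields in the file override the package defaults; nested blocks
#' (`scene`, `approach`, `policy`, ...) override the corresponding
#' constructor arguments.
#'
#' @param path YAML file.
#' @return an [experiment_config()].
#' @export
read_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  build <- function(ctor, block) do.call(ctor, block %||% list())
  experiment_config(
    scene = build(scene_config, y$scene),
    seg = build(seg_config, y$seg),
    approach = build(approach_config, y$approach),
    gains = build(pid_gains, y$gains),
    plant = build(plant_new, y$plant),
    seal_test = build(seal_test_config, y$seal_test),
    policy = build(suction_policy, y$policy),
    impedance = build(impedance_model, y$impedance),
    mode = y$mode %||% "targeted",
    seed = y$seed,
    frame_period = y$frame_period %||% 0.25,
    initial_focal_z = y$initial_focal_z,
    target_point = y$target_point %||% c(0, 0),
    target_rule = y$target_rule %||% "nearest",
    miss_budget = y$miss_budget %||% 5L,
    breakin_budget = y$breakin_budget %||% 10L,
    noise = y$noise %||% TRUE,
    outdir = y$outdir)
}

#' Select the target object in a frame
#'
#' Targeted mode: the object nearest to the selection point (ties by lower
#' label), mirroring an operator's screen click; or the object with the
#' highest contrast under `rule = "brightest"`.
#'
#' @param objects a `tp_objects` list (non-empty).
#' @param frame the `tp_frame` they came from.
#' @param point (x, y) selection point in um.
#' @param rule `"nearest"` or `"brightest"`.
#' @return the selected `detected_object`.
#' @export
select_target <- function(objects, frame, point = c(0, 0),
                          rule = c("nearest", "brightest")) {
  rule <- match.arg(rule)
  if (length(objects) == 0) stop("no detected objects to select from")
  lbl <- vapply(objects, function(o) o$label, numeric(1))
  if (rule == "brightest") {
    cfs <- vapply(objects, function(o) ifelse(is.na(o$cfs), -Inf, o$cfs),
                  numeric(1))
    return(objects[[order(-cfs, lbl)[1]]])
  }
  cen <- t(vapply(objects, function(o)
    px_to_um(o$centroid[["x"]], o$centroid[["y"]], frame$imaging,
             frame$stage_xy)[1, ], numeric(2)))
  d <- sqrt((cen[, 1] - point[1])^2 + (cen[, 2] - point[2])^2)
  objects[[order(round(d, 9), lbl)[1]]]
}

## -- rig state (mutable environment) ---------------------------------------

new_rig_state <- function(config) {
  st <- new.env(parent = emptyenv())
  st$config <- config
  st$t <- 0
  st$stage <- "init"
  st$events <- list()
  st$trace <- list()
  st$traj <- list()
  st$r_hist <- data.frame(t = numeric(), r = numeric())
  st$setpoint <- 0
  st$holding <- 0
  st$steps <- 0L
  st$status <- "running"
  st$reason <- NA_character_
  st$t_sealed <- NA_real_
  st$t_wholecell <- NA_real_
  st$corrected <- FALSE
  st
}

log_event <- function(st, event, payload = list()) {
  st$events[[length(st$events) + 1L]] <-
    list(t = st$t, stage = st$stage, event = event, payload = payload)
  invisible(NULL)
}

enter_stage <- function(st, stage) {
  st$stage <- stage
  log_event(st, "stage_entered")
}

rig_acquire <- function(st) {
  function(focal_z) {
    st$t <- st$t + st$config$frame_period
    render_frame(st$scene, focal_z, st$t, noise = st$config$noise)
  }
}

## advance the pressure closed loop for `duration` simulated seconds
run_loop <- function(st, duration) {
  dt <- st$config$gains$sample_dt
  n <- max(1L, round(duration / dt))
  for (k in seq_len(n)) {
    step <- pid_step(st$pid, st$setpoint, st$plant$pressure)
    st$pid <- step$pid
    st$plant <- plant_step(st$plant, step$command, dt)
  }
  st$t <- st$t + n * dt
  invisible(NULL)
}

set_pressure <- function(st, setpoint, settle_first = TRUE) {
  st$setpoint <- setpoint
  log_event(st, "pressure_setpoint", list(setpoint = setpoint))
  if (settle_first) {
    out <- settle(st$pid, st$plant, setpoint, tolerance = 0.5,
                  timeout = 1.5)
    st$pid <- out$pid
    st$plant <- out$plant
    st$t <- st$t + out$elapsed
  }
  invisible(NULL)
}

## one seal-test measurement: waveform -> membrane current -> Bessel filter
## -> per-cycle resistance; appends to the resistance history and trace
measure_r <- function(st, duration = 0.1) {
  cfg <- st$config$seal_test
  cfg$holding_potential <- st$holding
  v <- seal_test_waveform(cfg, duration)
  resp <- impedance_response(st$model, v, st$plant$pressure, cfg,
                             holding = st$holding)
  st$model <- resp$model
  filt <- bessel_lowpass(resp$current, cfg)
  est <- estimate_resistance(cfg$amplitude, filt, cfg)
  st$t <- st$t + duration
  r <- est$resistance
  st$r_hist <- rbind(st$r_hist, data.frame(t = st$t, r = r))
  st$trace[[length(st$trace) + 1L]] <- data.frame(
    t = st$t, resistance = r,
    current_pp = cfg$amplitude / r,
    holding = st$holding, pressure = st$plant$pressure,
    depth = if (!is.null(st$pose)) st$pose$tip[3] else NA_real_)
  r
}

rig_fail <- function(st, reason) {
  st$status <- "fail"
  st$reason <- reason
  log_event(st, "fail", list(reason = reason))
  invisible(FALSE)
}

## -- stages -----------------------------------------------------------------

stage_positioning <- function(st) {
  cf <- st$config
  enter_stage(st, "positioning")
  acquire <- rig_acquire(st)
  fr <- acquire(cf$initial_focal_z)
  objs <- segment_frame(fr, cf$seg)
  if (length(objs) == 0) return(rig_fail(st, "no_target"))
  obj <- select_target(objs, fr, cf$target_point, cf$target_rule)
  st$track <- new_track(obj, fr, t = st$t,
                        search_radius =
                          cf$approach$smallest_target_diameter / 2,
                        miss_budget = cf$miss_budget)
  tp <- track_position(st$track)
  log_event(st, "target_selected",
            list(x = tp[["x"]], y = tp[["y"]], z = tp[["z"]],
                 label = obj$label))
  truth <- cell_centers(st$scene, st$t, physio = FALSE)
  st$target_cell <- which.min(sqrt((truth[, 1] - tp[["x"]])^2 +
                                     (truth[, 2] - tp[["y"]])^2 +
                                     (truth[, 3] - tp[["z"]])^2))
  plan <- plan_entry(st$scene$pipette$tip, st$scene$pipette$axis,
                     as.numeric(tp), cf$approach)
  log_event(st, "aligned",
            list(move = vnorm(plan$alignment_move)))
  st$pose <- list(tip = plan$standoff_point, axis = plan$axis)
  log_event(st, "rapid_move",
            list(tip = plan$standoff_point,
                 distance_to_target = vnorm(plan$standoff_point -
                                              as.numeric(tp))))
  TRUE
}

stage_check <- function(st) {
  set_pressure(st, st$config$approach$high_pressure)
  r <- measure_r(st)
  st$baseline_r <- r
  verdict <- check_pipette(r, st$model$r_bath)
  log_event(st, "pipette_checked", list(resistance = r, verdict = verdict))
  if (verdict == "clogged") return(rig_fail(st, "clogged"))
  TRUE
}

#' Run the closed-loop approach on a rig state
#'
#' Loops bounded insertion steps, each followed by mandatory target
#' re-acquisition (the servo never steps while the target is not visible),
#' with per-step trajectory re-aiming and the two-level pressure staging
#' (high, then low within 20 um of the target, latched). Terminates when
#' the tip-to-track distance reaches the contact distance; a single bounded
#' final correction is permitted if the step budget runs out close to the
#' target.
#'
#' Normally called through [run_experiment()]; exposed for approach-only
#' studies on a state prepared by the positioning stage.
#'
#' @param st a rig state (internal environment created by
#'   [run_experiment()]).
#' @return a list with `success`, `final_distance`, `steps`, `corrected`.
#' @export
run_approach <- function(st) {
  cf <- st$config
  ac <- cf$approach
  enter_stage(st, "approach")
  acquire <- rig_acquire(st)
  ideal <- ceiling((ac$standoff_distance - ac$contact_distance) /
                     ac$step_length)
  budget <- ceiling(ideal * ac$step_budget_factor)
  low_latched <- FALSE
  tracker_log <- function(ev, pl) {
    if (ev == "autofocus") st$since_sweep <- 0L
    log_event(st, ev, pl)
  }
  repeat {
    tp <- as.numeric(track_position(st$track))
    dist <- vnorm(st$pose$tip - tp)
    if (dist <= ac$contact_distance) {
      log_event(st, "approach_done",
                list(distance = dist, steps = st$steps))
      return(list(success = TRUE, final_distance = dist,
                  steps = st$steps, corrected = st$corrected))
    }
    sp <- pressure_for_distance(dist, ac)
    if (sp == ac$low_pressure) low_latched <- TRUE
    if (low_latched) sp <- ac$low_pressure
    if (sp != st$setpoint) set_pressure(st, sp)
    if (st$steps >= budget) {
      if (dist <= ac$contact_distance + ac$max_manual_correction) {
        ## bounded final correction closing the residual gap
        old <- st$pose$tip
        dirv <- (tp - old) / dist
        st$pose$tip <- tp - ac$contact_distance * dirv
        st$pose$axis <- unitize(dirv)
        st$scene <- apply_insertion_step(st$scene, old, st$pose$tip, st$t)
        st$corrected <- TRUE
        log_event(st, "correction",
                  list(length = vnorm(st$pose$tip - old)))
        log_event(st, "approach_done",
                  list(distance = ac$contact_distance, steps = st$steps))
        return(list(success = TRUE,
                    final_distance = ac$contact_distance,
                    steps = st$steps, corrected = TRUE))
      }
      rig_fail(st, "step_budget")
      return(list(success = FALSE, final_distance = dist,
                  steps = st$steps, corrected = st$corrected))
    }
    old <- st$pose$tip
    st$pose <- approach_step(st$pose, tp, ac)
    st$scene <- apply_insertion_step(st$scene, old, st$pose$tip, st$t)
    st$steps <- st$steps + 1L
    log_event(st, "insert_step",
              list(length = st$pose$step_length_taken,
                   tip = st$pose$tip, distance = dist,
                   pressure = st$plant$pressure))
    measure_r(st)
    ## bound axial staleness: per-step target migration grows as the tip
    ## closes in, so forced refocus sweeps become more frequent
    st$since_sweep <- (st$since_sweep %||% 0L) + 1L
    refocus_every <- if (dist > 60) 8L else if (dist > 25) 4L else 2L
    force <- st$since_sweep >= refocus_every
    st$track <- reacquire_after_step(st$track, acquire, cf$seg,
                                     force_refocus = force,
                                     log_fn = tracker_log)
    truth <- cell_centers(st$scene, st$t, physio = FALSE)[st$target_cell, ]
    tracked <- as.numeric(track_position(st$track))
    st$traj[[length(st$traj) + 1L]] <- data.frame(
      step = st$steps, tip_x = st$pose$tip[1], tip_y = st$pose$tip[2],
      tip_z = st$pose$tip[3], tracked_x = tracked[1],
      tracked_y = tracked[2], tracked_z = tracked[3],
      true_x = truth[1], true_y = truth[2], true_z = truth[3],
      distance = vnorm(st$pose$tip - tracked),
      pressure = st$plant$pressure,
      visible = st$track$status == "visible")
    if (st$track$status == "lost") {
      rig_fail(st, "lost_target")
      return(list(success = FALSE, final_distance = dist,
                  steps = st$steps, corrected = st$corrected))
    }
  }
}

stage_engagement <- function(st) {
  enter_stage(st, "engagement")
  pre <- tail(st$r_hist$r, 5)
  st$model <- set_stage(st$model, "contact")
  for (i in 1:20) {
    run_loop(st, 0.05)
    measure_r(st)
    window <- c(pre, tail(st$r_hist$r, i))
    if (detect_engagement(window, baseline_n = length(pre),
                          rel_increase = 0.2, dwell = 3L)) {
      log_event(st, "engaged",
                list(resistance = tail(st$r_hist$r, 1)))
      return(TRUE)
    }
  }
  rig_fail(st, "no_engagement")
}

stage_seal <- function(st) {
  cf <- st$config
  enter_stage(st, "seal")
  set_pressure(st, 0)
  log_event(st, "pressure_released")
  st$holding <- -70
  log_event(st, "holding_set", list(holding = -70))
  st$model <- set_stage(st$model, "sealing")
  seal_start <- st$t
  last_fired <- -Inf
  repeat {
    run_loop(st, 0.1)
    r <- measure_r(st)
    if (detect_seal(r, cf$policy)) {
      st$model <- set_stage(st$model, "sealed")
      st$t_sealed <- st$t
      log_event(st, "sealed", list(resistance = r))
      return(TRUE)
    }
    hist <- st$r_hist[st$r_hist$t >= seal_start, ]
    ad <- adaptive_suction_step(cf$policy, hist, st$t, st$setpoint,
                                last_fired)
    if (ad$fired) {
      last_fired <- st$t
      st$setpoint <- ad$setpoint
      log_event(st, "suction_deepened", list(setpoint = ad$setpoint))
      log_event(st, "pressure_setpoint", list(setpoint = ad$setpoint))
    }
    if (st$t - seal_start > cf$policy$time_limit)
      return(rig_fail(st, "seal_timeout"))
  }
}

stage_breakin <- function(st) {
  cf <- st$config
  enter_stage(st, "breakin")
  pulse_i <- 0L
  apply_pulse <- function(amplitude, duration) {
    pulse_i <<- pulse_i + 1L
    st$setpoint <- amplitude
    log_event(st, "suction_pulse",
              list(index = pulse_i, amplitude = amplitude))
    run_loop(st, duration)
    st$model$pulse_stress <- st$model$pulse_stress + abs(amplitude)
    if (st$model$stage == "sealed" &&
        st$model$pulse_stress >= st$model$rupture_threshold)
      st$model <- set_stage(st$model, "wholecell")
    st$setpoint <- 0
    run_loop(st, 0.2)
  }
  bp <- breakin_pulses(apply_pulse, function() measure_r(st),
                       budget = cf$breakin_budget)
  if (!bp$success) return(rig_fail(st, "breakin_budget"))
  log_event(st, "breakin_detected",
            list(pulses = bp$pulses,
                 resistance = tail(bp$r_history, 1)))
  enter_stage(st, "wholecell")
  st$t_wholecell <- st$t
  st$status <- "wholecell"
  log_event(st, "wholecell",
            list(access_resistance = tail(bp$r_history, 1)))
  TRUE
}

## -- top level --------------------------------------------------------------

#' Run one end-to-end virtual patching experiment
#'
#' Executes the full state machine — positioning, approach, engagement,
#' seal, break-in, whole-cell — against the virtual scene, deterministic
#' for a given configuration and seed. On failure the log carries a
#' machine-readable terminal reason (`no_target`, `clogged`,
#' `lost_target`, `step_budget`, `no_engagement`, `seal_timeout`,
#' `breakin_budget`).
#'
#' @param config an [experiment_config()].
#' @return a list of class `patch_experiment`: `status` (`"wholecell"` or
#'   `"fail"`), `reason`, the event log, the resistance/pressure/depth
#'   trace, the approach trajectory, timings, and the final track.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  set.seed(config$seed)
  st <- new_rig_state(config)
  st$scene <- make_scene(config$scene, config$seed)
  st$pid <- pid_new(config$gains)
  st$plant <- config$plant
  st$model <- config$impedance
  ## per-run membrane variability, drawn from the experiment seed
  st$model$rate_factor <- rlnorm(1, 0, 0.25)
  st$model$rupture_threshold <- rlnorm(1, log(30), 0.4)
  ok <- stage_positioning(st)
  if (ok) ok <- stage_check(st)
  if (ok) ok <- isTRUE(run_approach(st)$success)
  if (ok) ok <- stage_engagement(st)
  if (ok) ok <- stage_seal(st)
  if (ok) ok <- stage_breakin(st)
  res <- structure(list(
    status = st$status, reason = st$reason, seed = config$seed,
    events = st$events,
    trace = if (length(st$trace)) do.call(rbind, st$trace) else NULL,
    trajectory = if (length(st$traj)) do.call(rbind, st$traj) else NULL,
    steps = st$steps, corrected = st$corrected,
    t_sealed = st$t_sealed, t_wholecell = st$t_wholecell,
    final_resistance = tail(st$r_hist$r, 1),
    track = st$track, config = config),
    class = "patch_experiment")
  if (!is.null(config$outdir)) write_experiment(res, config$outdir)
  res
}

#' Tabulate an experiment's event log
#' @param x a `patch_experiment` (or its raw event list).
#' @return data.frame with columns t, stage, event.
#' @export
events_table <- function(x) {
  ev <- if (inherits(x, "patch_experiment")) x$events else x
  data.frame(t = vapply(ev, function(e) e$t, numeric(1)),
             stage = vapply(ev, function(e) e$stage, character(1)),
             event = vapply(ev, function(e) e$event, character(1)))
}

#' Extract a payload field across events
#' @param x a `patch_experiment`.
#' @param event event name to filter on.
#' @param field payload field.
#' @return numeric vector of the field's values.
#' @export
event_values <- function(x, event, field) {
  ev <- Filter(function(e) e$event == event, x$events)
  vapply(ev, function(e) as.numeric(e$payload[[field]]), numeric(1))
}

#' Validate an event log's structural invariants
#'
#' Checks append-only monotone timestamps, exactly one terminal event
#' (`wholecell` or `fail`), and that every event carries `t`, `stage`,
#' `event` fields.
#'
#' @param x a `patch_experiment`.
#' @return TRUE, or a character vector of violations.
#' @export
validate_event_log <- function(x) {
  ev <- x$events
  bad <- character()
  if (!all(vapply(ev, function(e)
    all(c("t", "stage", "event") %in% names(e)), logical(1))))
    bad <- c(bad, "event missing required fields")
  tt <- vapply(ev, function(e) e$t, numeric(1))
  if (is.unsorted(tt)) bad <- c(bad, "timestamps not monotone")
  nm <- vapply(ev, function(e) e$event, character(1))
  if (sum(nm %in% c("wholecell", "fail")) != 1L)
    bad <- c(bad, "log must contain exactly one terminal event")
  if (length(bad)) bad else TRUE
}

#' Stage names in the order they were entered
#' @param x a `patch_experiment`.
#' @return character vector of stages.
#' @export
stages_visited <- function(x) {
  ev <- Filter(function(e) e$event == "stage_entered", x$events)
  vapply(ev, function(e) e$stage, character(1))
}

write_experiment <- function(res, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  con <- file(file.path(outdir, "events.jsonl"), "w")
  on.exit(close(con))
  for (e in res$events)
    writeLines(jsonlite::toJSON(e, auto_unbox = TRUE, digits = NA), con)
  if (!is.null(res$trace))
    write.csv(res$trace, file.path(outdir, "trace.csv"),
              row.names = FALSE)
  if (!is.null(res$trajectory))
    write.csv(res$trajectory, file.path(outdir, "trajectory.csv"),
              row.names = FALSE)
  invisible(outdir)
}

#' Run a seeded batch of experiments
#'
#' Runs seeds `1..n_seeds` of the same configuration and aggregates
#' engagement / seal / whole-cell rates, step counts and simulated
#' times-to-seal.
#'
#' @param config an [experiment_config()] (its seed field is overridden
#'   per run).
#' @param n_seeds number of seeded runs.
#' @return a list with `runs` (one row per seed) and `summary`.
#' @export
run_batch <- function(config, n_seeds) {
  stopifnot(n_seeds >= 1)
  rows <- vector("list", n_seeds)
  results <- vector("list", n_seeds)
  for (s in seq_len(n_seeds)) {
    cfg <- config
    cfg$seed <- as.integer(s)
    res <- run_experiment(cfg)
    results[[s]] <- res
    stg <- stages_visited(res)
    err <- if (!is.null(res$trajectory)) {
      with(res$trajectory,
           max(sqrt((tracked_x - true_x)^2 + (tracked_y - true_y)^2 +
                      (tracked_z - true_z)^2)))
    } else NA_real_
    rows[[s]] <- data.frame(
      seed = s, status = res$status, reason = res$reason,
      engaged = "engagement" %in% stg && !identical(res$reason,
                                                    "no_engagement"),
      sealed = !is.na(res$t_sealed), steps = res$steps,
      time_to_seal = res$t_sealed, time_to_wholecell = res$t_wholecell,
      max_tracking_error = err)
  }
  runs <- do.call(rbind, rows)
  summary <- list(
    n = n_seeds,
    engagement_rate = mean(runs$engaged),
    seal_rate = mean(runs$sealed),
    wholecell_rate = mean(runs$status == "wholecell"),
    mean_steps = mean(runs$steps),
    mean_time_to_seal = mean(runs$time_to_seal, na.rm = TRUE),
    mean_max_tracking_error = mean(runs$max_tracking_error, na.rm = TRUE))
  list(runs = runs, summary = summary, results = results)
}
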