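## Entry planning and the closed-loop approach: align the pipette axis with
## the target, rapid-advance to a standoff point, then interleave bounded
## insertion steps with target re-acquisition, re-aiming the step direction
## at the tracked position each time, with distance-dependent pressure
## staging (high far from the cell, low within 20 um).

#' Approach configuration
#'
#' Numeric staging of the approach. `step_length` must not exceed half the
#' smallest targeted soma diameter, so that the worst-case migration induced
#' by a single step cannot carry the target out of the association gate.
#'
#' @param standoff_distance distance from the target at which the rapid
#'   advance stops and stepping begins (um, 200-300).
#' @param step_length individual insertion step (um, 3-4 and at most
#'   `smallest_target_diameter / 2`).
#' @param near_cell_distance distance below which internal pressure drops
#'   to the low setting (um).
#' @param high_pressure,low_pressure pressure setpoints (kPa) far from /
#'   near the cell.
#' @param contact_distance tip-target distance taken as membrane contact
#'   (um, about a cell radius).
#' @param max_manual_correction largest single end-of-approach correction
#'   (um).
#' @param smallest_target_diameter diameter of the smallest structures
#'   targeted (um).
#' @param max_lateral_correction largest lateral re-aim per step (um).
#' @param step_budget_factor step budget as a multiple of the ideal
#'   (no-deformation) step count.
#' @return a list of class `approach_config`.
#' @export
approach_config <- function(standoff_distance = 250, step_length = 3,
                            near_cell_distance = 20, high_pressure = 25,
                            low_pressure = 7.5, contact_distance = 3,
                            max_manual_correction = 8,
                            smallest_target_diameter = 6,
                            max_lateral_correction = 1.5,
                            step_budget_factor = 3) {
  stopifnot(standoff_distance > 0, step_length > 0,
            low_pressure < high_pressure,
            contact_distance < near_cell_distance,
            near_cell_distance < standoff_distance,
            max_manual_correction >= 0, step_budget_factor >= 1)
  if (step_length > smallest_target_diameter / 2)
    stop("step_length must not exceed half the smallest target diameter")
  structure(list(standoff_distance = standoff_distance,
                 step_length = step_length,
                 near_cell_distance = near_cell_distance,
                 high_pressure = high_pressure,
                 low_pressure = low_pressure,
                 contact_distance = contact_distance,
                 max_manual_correction = max_manual_correction,
                 smallest_target_diameter = smallest_target_diameter,
                 max_lateral_correction = max_lateral_correction,
                 step_budget_factor = step_budget_factor),
            class = "approach_config")
}

#' Plan the entry trajectory
#'
#' Keeps the manipulator axis direction fixed, translates the tip laterally
#' so the target lies on the axis, and returns the standoff point on that
#' axis at `standoff_distance` from the target. The rapid move to standoff
#' is only permitted along the aligned axis (or outside the tissue).
#'
#' @param tip current tip position (um), above the surface (z > 0).
#' @param axis unit insertion direction (z component negative).
#' @param target target position (um), below the surface (z < 0).
#' @param config an [approach_config()].
#' @return a list with `aligned_tip`, `alignment_move` (the lateral
#'   translation), `standoff_point`, and `axis`.
#' @export
plan_entry <- function(tip, axis, target, config = approach_config()) {
  tip <- as.numeric(tip); target <- as.numeric(target)
  axis <- unitize(axis)
  if (axis[3] >= 0) stop("entry planning error: axis must point downward")
  if (target[3] >= 0) stop("target must be below the surface")
  if (tip[3] <= 0) stop("tip must start above the surface")
  u <- target - tip
  along <- sum(u * axis)
  if (along <= 0)
    stop("entry planning error: target behind the pipette axis")
  lateral <- u - along * axis
  aligned <- tip + lateral
  list(aligned_tip = aligned, alignment_move = lateral,
       standoff_point = target - config$standoff_distance * axis,
       axis = axis)
}

#' Pressure setpoint as a function of tip-target distance
#'
#' High positive pressure keeps the tip clear of debris during navigation;
#' within `near_cell_distance` (boundary inclusive) it drops to the low
#' setting to avoid blasting the target. Monotone non-increasing in
#' proximity.
#'
#' @param distance tip-target distance (um, >= 0).
#' @param config an [approach_config()].
#' @return setpoint in kPa.
#' @export
pressure_for_distance <- function(distance, config = approach_config()) {
  stopifnot(distance >= 0)
  if (distance > config$near_cell_distance) config$high_pressure
  else config$low_pressure
}

#' One re-aimed insertion step
#'
#' Re-aims the motion direction at the tracked target position, bounding
#' the lateral correction per step, and advances
#' `min(step_length, distance - contact_distance)` along the corrected
#' direction.
#'
#' @param pose a list with `tip` and `axis` (unit vector).
#' @param target_pos tracked target position (um).
#' @param config an [approach_config()].
#' @return the updated pose, with `step_vector` and `step_length_taken`
#'   attached.
#' @export
approach_step <- function(pose, target_pos, config = approach_config()) {
  desired <- as.numeric(target_pos) - pose$tip
  dist <- vnorm(desired)
  L <- min(config$step_length, max(dist - config$contact_distance, 0))
  if (L <= 0) {
    pose$step_vector <- c(0, 0, 0)
    pose$step_length_taken <- 0
    return(pose)
  }
  dir <- desired / dist
  v <- dir * L
  perp <- v - sum(v * pose$axis) * pose$axis
  pn <- vnorm(perp)
  if (pn > config$max_lateral_correction)
    v <- sum(v * pose$axis) * pose$axis +
      perp * (config$max_lateral_correction / pn)
  v <- unitize(v) * L
  pose$axis <- unitize(v)
  pose$tip <- pose$tip + v
  pose$step_vector <- v
  pose$step_length_taken <- L
  pose
}
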