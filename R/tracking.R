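## Inter-frame correspondence for the selected target. Step-synchronized
## acquisition keeps per-frame target displacement below half a small soma
## diameter, so the correspondence problem is solved locally: the nearest
## detection within a fixed gate, with no motion model. Brief disappearances
## (breathing/heartbeat) are ridden out as "occluded" until a miss budget is
## exhausted.

#' Start a track on a detected object
#'
#' @param object a `detected_object`.
#' @param frame the `tp_frame` it was detected in.
#' @param t time (s).
#' @param search_radius association gate (um); defaults to half of the
#'   smallest targeted soma diameter, the worst-case per-step migration the
#'   approach is designed around.
#' @param miss_budget consecutive misses tolerated before the track is
#'   declared lost.
#' @return a list of class `tp_track`.
#' @export
new_track <- function(object, frame, t = 0, search_radius = 3,
                      miss_budget = 5L) {
  stopifnot(inherits(object, "detected_object"))
  cen <- px_to_um(object$centroid[["x"]], object$centroid[["y"]],
                  frame$imaging, frame$stage_xy)[1, ]
  pos <- data.frame(t = t, x = cen[["x"]], y = cen[["y"]],
                    z = frame$focal_z,
                    cfs = ifelse(is.na(object$cfs), 0, object$cfs))
  structure(list(target_id = object$label, positions = pos,
                 last_object = object, search_radius = search_radius,
                 miss_budget = as.integer(miss_budget),
                 consecutive_misses = 0L, status = "visible",
                 best_cfs = ifelse(is.na(object$cfs), 0, object$cfs)),
            class = "tp_track")
}

#' Last known 3D position of a track
#' @param track a `tp_track`.
#' @return named vector `c(x, y, z)` in um.
#' @export
track_position <- function(track) {
  p <- track$positions[nrow(track$positions), ]
  c(x = p$x, y = p$y, z = p$z)
}

#' Associate current-frame detections with a track
#'
#' Returns the detection whose centroid (in um) is nearest to the track's
#' last (x, y) and within `search_radius`; ties are broken by larger CFS,
#' then lower label. `NULL` if no detection qualifies.
#'
#' @param track a `tp_track`.
#' @param detections a `tp_objects` list from the current frame.
#' @param frame the `tp_frame` they came from (for pixel-to-um geometry).
#' @return a `detected_object` or `NULL`.
#' @export
associate <- function(track, detections, frame) {
  last <- track_position(track)
  nearest_object(detections, frame, last[c("x", "y")],
                 track$search_radius)
}

#' Update a track with a match (or a miss)
#'
#' On a match the centroid is appended at time `t` with depth `focal_z`,
#' misses reset, and the track is visible. On a miss the miss counter
#' increments; the track stays "occluded" while within budget (breathing
#' and heartbeat make targets periodically disappear and reappear at the
#' same point) and becomes "lost" beyond it.
#'
#' @param track a `tp_track`.
#' @param match a `detected_object` from [associate()], or `NULL`.
#' @param frame the current `tp_frame`.
#' @param focal_z depth assigned to the new fix (um).
#' @param t time (s).
#' @return the updated track.
#' @export
update_track <- function(track, match, frame, focal_z, t) {
  if (!is.null(match)) {
    cen <- px_to_um(match$centroid[["x"]], match$centroid[["y"]],
                    frame$imaging, frame$stage_xy)[1, ]
    cfs <- ifelse(is.na(match$cfs), 0, match$cfs)
    track$positions <- rbind(track$positions,
                             data.frame(t = t, x = cen[["x"]],
                                        y = cen[["y"]], z = focal_z,
                                        cfs = cfs))
    track$last_object <- match
    track$consecutive_misses <- 0L
    track$status <- "visible"
    track$best_cfs <- max(track$best_cfs, cfs)
  } else {
    track$consecutive_misses <- track$consecutive_misses + 1L
    track$status <- if (track$consecutive_misses > track$miss_budget)
      "lost" else "occluded"
  }
  track
}

#' Re-acquire the target after an insertion step
#'
#' Called once after every insertion step, before the next step is
#' permitted. Segments the current frame and tries a lateral match; on
#' failure (or when the matched CFS has decayed below
#' `refocus_frac * best_cfs`, indicating axial migration) an autofocus
#' sweep re-finds the focal plane and the match is retried there. Misses
#' are re-tried on fresh frames within the miss budget. The returned track
#' is `visible` (with an updated 3D fix) or `lost`; the servo must not step
#' while the track is not visible.
#'
#' @param track a `tp_track`.
#' @param acquire `function(focal_z)` frame source (advances the virtual
#'   clock).
#' @param seg a [seg_config()].
#' @param af_half_range,af_step autofocus sweep geometry (um).
#' @param refocus_frac CFS decay fraction that triggers a refocus.
#' @param force_refocus run an autofocus sweep regardless of the CFS (used
#'   by the servo to bound axial staleness when per-step migration is
#'   large).
#' @param log_fn optional `function(event, payload)` sink for tracker
#'   events (`target_miss`, `autofocus`, `target_reacquired`,
#'   `target_lost`).
#' @return the updated track.
#' @export
reacquire_after_step <- function(track, acquire, seg = seg_config(),
                                 af_half_range = 6, af_step = 2,
                                 refocus_frac = 0.85,
                                 force_refocus = FALSE, log_fn = NULL) {
  say <- function(ev, pl = list()) if (!is.null(log_fn)) log_fn(ev, pl)
  z <- track_position(track)[["z"]]
  repeat {
    fr <- acquire(z)
    objs <- segment_frame(fr, seg)
    m <- associate(track, objs, fr)
    needs_refocus <- force_refocus ||
      (!is.null(m) && !is.na(m$cfs) && track$best_cfs > 0 &&
         m$cfs < refocus_frac * track$best_cfs)
    force_refocus <- FALSE
    if (!is.null(m) && !needs_refocus) {
      track <- update_track(track, m, fr, z, fr$timestamp)
      say("target_reacquired",
          list(x = track_position(track)[["x"]],
               y = track_position(track)[["y"]], z = z, cfs = m$cfs))
      return(track)
    }
    ## lateral miss or defocus: try to recover the focal plane
    af <- autofocus_target(track, acquire, seg,
                           half_range = af_half_range, step = af_step)
    say("autofocus", list(lost = af$lost, focal_z = af$focal_z,
                          retried = af$retried))
    if (af$lost && !is.null(m)) {
      ## the sweep found nothing better; keep the lateral match
      track <- update_track(track, m, fr, z, fr$timestamp)
      say("target_reacquired",
          list(x = track_position(track)[["x"]],
               y = track_position(track)[["y"]], z = z, cfs = m$cfs))
      return(track)
    }
    if (!af$lost) {
      z <- af$focal_z
      fr <- acquire(z)
      objs <- segment_frame(fr, seg)
      m <- associate(track, objs, fr)
      if (!is.null(m)) {
        track <- update_track(track, m, fr, z, fr$timestamp)
        say("target_reacquired",
            list(x = track_position(track)[["x"]],
                 y = track_position(track)[["y"]], z = z, cfs = m$cfs))
        return(track)
      }
    }
    track <- update_track(track, NULL, fr, z, fr$timestamp)
    say("target_miss", list(misses = track$consecutive_misses))
    if (track$status == "lost") {
      say("target_lost", list())
      return(track)
    }
  }
}

#' Export a track as a data.frame
#' @param track a `tp_track`.
#' @return data.frame with columns t, x, y, z, cfs.
#' @export
track_table <- function(track) track$positions
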