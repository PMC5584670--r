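## Contrast-based autofocus: sweep the (virtual) objective in z over the
## target's region of interest, score each plane by the target's CFS, and
## take the best focal distance as the peak of a Gaussian fitted to the
## focus scores. Sweeps are centered and bidirectional.

#' Sweep the focal plane and score the target's focus
#'
#' Acquires one frame per plane of a centered z-grid, segments it, matches
#' the detection nearest to the region of interest (within `gate` um), and
#' records its CFS. Planes with no qualifying detection score 0. If no
#' plane sees the target the sweep is flagged lost.
#'
#' @param acquire `function(focal_z)` returning a `tp_frame` (typically a
#'   closure over the virtual scene and clock).
#' @param roi_center target (x, y) in um.
#' @param z_center sweep center (um).
#' @param half_range half extent of the sweep (um).
#' @param step plane spacing (um, > 0); at least 5 planes are required.
#' @param seg a [seg_config()].
#' @param gate lateral match radius (um).
#' @param margin half-width (um) of the dilated region of interest the
#'   segmentation is restricted to.
#' @return a list of class `focus_sweep` with `z`, `scores`, `roi_center`,
#'   and `lost`.
#' @export
sweep_focus <- function(acquire, roi_center, z_center, half_range = 10,
                        step = 2, seg = seg_config(), gate = 4,
                        margin = 8) {
  stopifnot(step > 0)
  z <- seq(z_center - half_range, z_center + half_range, by = step)
  if (length(z) < 5) stop("focus sweep needs at least 5 planes")
  scores <- numeric(length(z))
  for (i in seq_along(z)) {
    fr <- crop_frame(acquire(z[i]), roi_center, margin)
    objs <- segment_frame(fr, seg)
    m <- nearest_object(objs, fr, roi_center, gate)
    s <- if (is.null(m)) 0 else m$cfs
    scores[i] <- if (is.na(s)) 0 else max(s, 0)
  }
  structure(list(z = z, scores = scores,
                 roi_center = as.numeric(roi_center), step = step,
                 lost = all(scores == 0)),
            class = "focus_sweep")
}

## nearest detection to a um point, within gate; ties by larger CFS then
## lower label
nearest_object <- function(objs, frame, point, gate) {
  if (length(objs) == 0) return(NULL)
  cen <- t(vapply(objs, function(o)
    px_to_um(o$centroid[["x"]], o$centroid[["y"]], frame$imaging,
             frame$stage_xy)[1, ], numeric(2)))
  d <- sqrt((cen[, 1] - point[1])^2 + (cen[, 2] - point[2])^2)
  keep <- which(d <= gate)
  if (length(keep) == 0) return(NULL)
  cfs <- vapply(objs, function(o) ifelse(is.na(o$cfs), -Inf, o$cfs),
                numeric(1))
  lbl <- vapply(objs, function(o) o$label, numeric(1))
  ord <- order(round(d[keep], 9), -cfs[keep], lbl[keep])
  objs[[keep[ord[1]]]]
}

#' Fit a Gaussian to a focus sweep and return the best focal plane
#'
#' Least-squares fit of `a * exp(-(z - peak)^2 / (2 w^2)) + c` to the
#' CFS-versus-z samples. The fit is rejected (falling back to the argmax
#' sample) when it fails to converge, the peak leaves the sweep range, the
#' width collapses below the plane spacing, or the residual norm exceeds
#' `max_resid_frac` of the score range. Fewer than 4 non-zero scores also
#' fall back to the argmax, flagged low confidence.
#'
#' @param sweep a `focus_sweep`.
#' @param max_resid_frac residual-norm rejection threshold, as a fraction
#'   of the score range.
#' @return a list with `best_z`, `method` (`"gaussian"` or `"argmax"`),
#'   `low_confidence`, and the fitted coefficients (or `NULL`).
#' @export
fit_focus_gaussian <- function(sweep, max_resid_frac = 0.5) {
  z <- sweep$z; s <- sweep$scores
  argmax_z <- z[which.max(s)]
  fallback <- function(lc) list(best_z = argmax_z, method = "argmax",
                                low_confidence = lc, fit = NULL)
  if (sum(s > 0) < 4) return(fallback(TRUE))
  rng <- diff(range(s))
  if (rng <= 0) return(fallback(TRUE))
  start <- list(a = max(s) - min(s), mu = argmax_z, w = 2 * sweep$step,
                c0 = min(s))
  fit <- tryCatch(
    minpack.lm::nlsLM(s ~ a * exp(-(z - mu)^2 / (2 * w^2)) + c0,
                      start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(fallback(TRUE))
  cf <- coef(fit)
  resid_norm <- sqrt(sum(stats::resid(fit)^2))
  if (cf[["mu"]] < min(z) || cf[["mu"]] > max(z) ||
      abs(cf[["w"]]) < sweep$step || resid_norm > max_resid_frac * rng)
    return(fallback(FALSE))
  list(best_z = unname(cf[["mu"]]), method = "gaussian",
       low_confidence = FALSE, fit = cf)
}

#' Refocus on a tracked target
#'
#' Sweeps around the track's last known z and fits the focus Gaussian. A
#' lost sweep is retried once with the half-range doubled before the loss
#' is reported upward.
#'
#' @param track a `tp_track`.
#' @param acquire `function(focal_z)` frame source.
#' @param seg a [seg_config()].
#' @param half_range,step sweep geometry (um).
#' @param gate lateral match radius (um).
#' @return a list with `lost`, `focal_z` (best plane; `NA` when lost),
#'   `sweep`, and `retried`.
#' @export
autofocus_target <- function(track, acquire, seg = seg_config(),
                             half_range = 10, step = 2, gate = 4) {
  last <- track_position(track)
  sw <- sweep_focus(acquire, last[c("x", "y")], last[["z"]],
                    half_range, step, seg, gate)
  retried <- FALSE
  if (sw$lost) {
    retried <- TRUE
    sw <- sweep_focus(acquire, last[c("x", "y")], last[["z"]],
                      2 * half_range, step, seg, gate)
  }
  if (sw$lost)
    return(list(lost = TRUE, focal_z = NA_real_, sweep = sw,
                retried = retried))
  ft <- fit_focus_gaussian(sw)
  list(lost = FALSE, focal_z = ft$best_z, sweep = sw, retried = retried,
       fit = ft)
}
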