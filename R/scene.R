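## Virtual preparation: fluorescent somata in a 3D volume, a dye-filled
## pipette cone, viscoelastic deformation in response to pipette insertion,
## and periodic breathing/heartbeat motion. All distances in micrometres,
## times in seconds, intensities in 16-bit units. z is negative going deeper
## from the pial surface (z = 0).

#' Imaging parameters for the virtual two-photon microscope
#'
#' The optical model is deliberately simple: each soma is rendered as a 2D
#' Gaussian blob whose lateral width grows linearly with defocus and whose
#' amplitude decays as a Gaussian of the axial distance between the cell and
#' the focal plane. The narrow `axial_visibility_sigma` emulates the shallow
#' depth of field of two-photon excitation: a cell a few micrometres from the
#' focal plane fades to invisibility.
#'
#' @param field_of_view width/height of the imaged field (um).
#' @param pixels image width/height in pixels.
#' @param z_sigma0 in-focus lateral Gaussian width (um).
#' @param z_defocus_rate lateral width growth per um of defocus
#'   (dimensionless).
#' @param axial_visibility_sigma axial intensity decay constant (um); a few
#'   um, matching the small two-photon depth of field.
#' @param background_level uniform ambient fluorescence floor (intensity
#'   units) from dye accumulation and autofluorescence; gives defocused
#'   cells something to disappear into.
#' @param shot_noise_scale intensity units per detected photon; sets the
#'   signal-dependent (Poisson-like) noise scale.
#' @param read_noise_sd Gaussian read noise standard deviation (intensity
#'   units).
#' @param poisson_threshold expected photon count below which an exact
#'   Poisson draw is used instead of the Gaussian approximation.
#' @param bit_depth bits per pixel (fixed at 16).
#' @return a list of class `imaging_params`.
#' @export
imaging_params <- function(field_of_view = c(80, 80), pixels = c(96L, 96L),
                           z_sigma0 = 1, z_defocus_rate = 0.6,
                           axial_visibility_sigma = 3,
                           background_level = 1500,
                           shot_noise_scale = 2, read_noise_sd = 80,
                           poisson_threshold = 30, bit_depth = 16L) {
  stopifnot(all(pixels > 0), axial_visibility_sigma > 0,
            z_sigma0 > 0, z_defocus_rate >= 0, background_level >= 0,
            bit_depth == 16L)
  structure(list(field_of_view = field_of_view, pixels = as.integer(pixels),
                 z_sigma0 = z_sigma0, z_defocus_rate = z_defocus_rate,
                 axial_visibility_sigma = axial_visibility_sigma,
                 background_level = background_level,
                 shot_noise_scale = shot_noise_scale,
                 read_noise_sd = read_noise_sd,
                 poisson_threshold = poisson_threshold,
                 bit_depth = bit_depth),
            class = "imaging_params")
}

#' Tissue deformation parameters
#'
#' Pipette insertion pushes tissue ahead of and around the tip. Each
#' insertion step displaces every cell by
#' `push_gain * exp(-r / decay_length)` times the tip step vector, where `r`
#' is the distance from the pre-step tip position to the cell. A fraction
#' `relaxation_fraction` of each displacement then decays back toward rest
#' with time constant `relaxation_tau` (viscoelastic recoil).
#'
#' Defaults are calibrated so that a 3-4 um step next to the target moves it
#' by roughly half of a small (6 um) soma diameter, the worst-case migration
#' the approach controller is designed around.
#'
#' @param push_gain fraction of the tip step transferred at zero distance,
#'   in `[0, 1]`.
#' @param decay_length exponential decay length of the push field (um).
#' @param relaxation_fraction fraction of each displacement that recoils,
#'   in `[0, 1]`.
#' @param relaxation_tau recoil time constant (s).
#' @param max_step largest tip step the tissue model accepts (um); the servo
#'   must never request more.
#' @return a list of class `deformation_params`.
#' @export
deformation_params <- function(push_gain = 0.75, decay_length = 25,
                               relaxation_fraction = 0.3,
                               relaxation_tau = 5, max_step = 8) {
  stopifnot(push_gain >= 0, push_gain <= 1, decay_length > 0,
            relaxation_fraction >= 0, relaxation_fraction <= 1,
            relaxation_tau > 0, max_step > 0)
  structure(list(push_gain = push_gain, decay_length = decay_length,
                 relaxation_fraction = relaxation_fraction,
                 relaxation_tau = relaxation_tau, max_step = max_step),
            class = "deformation_params")
}

#' Breathing and heartbeat motion parameters
#'
#' Physiological motion is modeled as the sum of two zero-mean sinusoids
#' along a common axis, displacing every cell rigidly. Periods default to an
#' anesthetized-mouse regime (breathing ~1 Hz, heartbeat ~8 Hz).
#'
#' @param breathing_amplitude,heartbeat_amplitude peak displacement (um).
#' @param breathing_period,heartbeat_period oscillation period (s).
#' @param motion_axis direction of motion (normalized internally); mostly
#'   axial by default.
#' @return a list of class `physio_motion_params`.
#' @export
physio_motion_params <- function(breathing_amplitude = 0.6,
                                 breathing_period = 1.0,
                                 heartbeat_amplitude = 0.25,
                                 heartbeat_period = 0.12,
                                 motion_axis = c(0.3, 0.1, 0.95)) {
  stopifnot(breathing_amplitude >= 0, heartbeat_amplitude >= 0,
            breathing_period > 0, heartbeat_period > 0)
  structure(list(breathing_amplitude = breathing_amplitude,
                 breathing_period = breathing_period,
                 heartbeat_amplitude = heartbeat_amplitude,
                 heartbeat_period = heartbeat_period,
                 motion_axis = unitize(motion_axis)),
            class = "physio_motion_params")
}

#' Dye-filled pipette geometry
#'
#' @param tip tip position (um), initially above the surface.
#' @param axis unit insertion direction (normalized internally); must point
#'   downward (negative z component).
#' @param tip_diameter tip opening diameter (um).
#' @param cone_half_angle taper half angle (degrees).
#' @param cone_length rendered shank length behind the tip (um).
#' @param dye_channel imaging channel carrying the pipette dye; normally
#'   different from the target label channel.
#' @param dye_intensity peak dye intensity (16-bit units).
#' @return a list of class `pipette_geometry`.
#' @export
pipette_geometry <- function(tip = c(205, 0, 22.5),
                             axis = c(-0.82, 0, -0.5724),
                             tip_diameter = 1.5, cone_half_angle = 4,
                             cone_length = 400,
                             dye_channel = c("red", "green"),
                             dye_intensity = 25000) {
  dye_channel <- match.arg(dye_channel)
  axis <- unitize(axis)
  stopifnot(tip_diameter > 0, cone_half_angle > 0, cone_length > 0,
            dye_intensity > 0, dye_intensity <= 65535)
  if (axis[3] >= 0) stop("pipette axis must point downward (negative z)")
  structure(list(tip = as.numeric(tip), axis = axis,
                 tip_diameter = tip_diameter,
                 cone_half_angle = cone_half_angle,
                 cone_length = cone_length, dye_channel = dye_channel,
                 dye_intensity = dye_intensity),
            class = "pipette_geometry")
}

#' Scene configuration for the virtual preparation
#'
#' If `cells` is `NULL`, a default study scene is generated at
#' [make_scene()] time: one target soma (10 um, green, peak 40000) at
#' `target_center`, plus `n_distractors` distractor somata placed from the
#' seed at least 20 um away from the target.
#'
#' @param cells `NULL`, or a data.frame with columns `id, x, y, z, diameter,
#'   channel, peak_intensity`.
#' @param target_center 3D position (um) of the default target cell.
#' @param n_distractors number of seeded distractor cells in the default
#'   scene.
#' @param volume_bounds axis-aligned box `c(xmin, xmax, ymin, ymax, zmin,
#'   zmax)` (um).
#' @param imaging an [imaging_params()] list.
#' @param deformation a [deformation_params()] list.
#' @param motion a [physio_motion_params()] list.
#' @param pipette a [pipette_geometry()] list.
#' @return a list of class `scene_config`.
#' @export
scene_config <- function(cells = NULL, target_center = c(0, 0, -120),
                         n_distractors = 3L,
                         volume_bounds = c(-40, 40, -40, 40, -200, 30),
                         imaging = imaging_params(),
                         deformation = deformation_params(),
                         motion = physio_motion_params(),
                         pipette = pipette_geometry()) {
  structure(list(cells = cells, target_center = as.numeric(target_center),
                 n_distractors = as.integer(n_distractors),
                 volume_bounds = as.numeric(volume_bounds),
                 imaging = imaging, deformation = deformation,
                 motion = motion, pipette = pipette),
            class = "scene_config")
}

default_cells <- function(config) {
  tc <- config$target_center
  cells <- data.frame(id = 1L, x = tc[1], y = tc[2], z = tc[3],
                      diameter = 10, channel = "green",
                      peak_intensity = 40000)
  nd <- config$n_distractors
  if (nd > 0) {
    placed <- 0L
    while (placed < nd) {
      cand <- c(runif(1, -32, 32), runif(1, -32, 32), runif(1, -150, -90))
      if (vnorm(cand - tc) < 25) next
      ok <- all(vapply(seq_len(nrow(cells)), function(i) {
        vnorm(cand - c(cells$x[i], cells$y[i], cells$z[i])) >= 18
      }, logical(1)))
      if (!ok) next
      placed <- placed + 1L
      cells <- rbind(cells, data.frame(
        id = placed + 1L, x = cand[1], y = cand[2], z = cand[3],
        diameter = runif(1, 6, 14), channel = "green",
        peak_intensity = runif(1, 20000, 45000)))
    }
  }
  cells
}

#' Build a virtual scene
#'
#' Deterministic for a fixed `(config, seed)` pair: every stochastic draw in
#' the scene (distractor placement, rendering noise) derives from `seed`.
#' At construction each cell's rest position equals its current position.
#'
#' @param config a [scene_config()].
#' @param seed integer RNG seed for the scene.
#' @return a list of class `tp_scene` holding the cell table (with rest
#'   anchors), the parameter blocks, the pipette, the seed, and an (empty)
#'   list of deformation events.
#' @export
make_scene <- function(config, seed) {
  stopifnot(inherits(config, "scene_config"))
  stopifnot_scalar(seed, "seed")
  cells <- config$cells
  if (is.null(cells)) cells <- with_local_seed(seed, default_cells(config))
  req <- c("id", "x", "y", "z", "diameter", "channel", "peak_intensity")
  if (!all(req %in% names(cells)))
    stop("cells must have columns: ", paste(req, collapse = ", "))
  if (nrow(cells) < 1) stop("scene must contain at least one cell")
  stopifnot(all(cells$diameter > 0),
            all(cells$peak_intensity > 0 & cells$peak_intensity <= 65535),
            all(cells$channel %in% c("red", "green")))
  vb <- config$volume_bounds
  inside <- cells$x >= vb[1] & cells$x <= vb[2] &
    cells$y >= vb[3] & cells$y <= vb[4] &
    cells$z >= vb[5] & cells$z <= vb[6]
  if (!all(inside))
    stop(sprintf("cell id %s lies outside volume_bounds",
                 paste(cells$id[!inside], collapse = ", ")))
  cells$rest_x <- cells$x; cells$rest_y <- cells$y; cells$rest_z <- cells$z
  structure(list(cells = cells, volume_bounds = vb,
                 imaging = config$imaging, deformation = config$deformation,
                 motion = config$motion, pipette = config$pipette,
                 rng_seed = as.integer(seed %% 2147483647),
                 deform_events = list()),
            class = "tp_scene")
}

#' Rigid physiological offset at time t
#' @param motion a [physio_motion_params()].
#' @param t time (s).
#' @return 3-vector displacement (um).
#' @export
physio_offset <- function(motion, t) {
  d <- motion$breathing_amplitude * sin(2 * pi * t / motion$breathing_period) +
    motion$heartbeat_amplitude * sin(2 * pi * t / motion$heartbeat_period)
  d * motion$motion_axis
}

## Current cell centers: rest + deformation history (with viscoelastic
## recoil) + optional physiological motion. Returns an n x 3 matrix.
cell_centers <- function(scene, t, physio = TRUE) {
  pos <- as.matrix(scene$cells[, c("rest_x", "rest_y", "rest_z")])
  colnames(pos) <- c("x", "y", "z")
  f <- scene$deformation$relaxation_fraction
  tau <- scene$deformation$relaxation_tau
  for (ev in scene$deform_events) {
    dt <- max(t - ev$t0, 0)
    w <- (1 - f) + f * exp(-dt / tau)
    pos <- pos + w * ev$D
  }
  if (physio) pos <- sweep(pos, 2, physio_offset(scene$motion, t), "+")
  pos
}

#' Register a pipette insertion step and its tissue deformation
#'
#' Every cell is displaced immediately by
#' `push_gain * exp(-r / decay_length) * (new_tip - old_tip)`, with `r` the
#' distance from the pre-step tip to the cell's current (deformed) center.
#' A relaxation schedule is registered so that `relaxation_fraction` of the
#' displacement decays back toward rest with time constant `relaxation_tau`
#' on subsequent renders.
#'
#' @param scene a `tp_scene`.
#' @param old_tip,new_tip tip position before/after the step (um).
#' @param t time of the step (s).
#' @return the scene with the deformation event appended.
#' @export
apply_insertion_step <- function(scene, old_tip, new_tip, t = 0) {
  stopifnot(inherits(scene, "tp_scene"))
  step <- as.numeric(new_tip) - as.numeric(old_tip)
  len <- vnorm(step)
  if (len > scene$deformation$max_step + 1e-9)
    stop(sprintf("insertion step of %.2f um exceeds configured max step (%.2f um)",
                 len, scene$deformation$max_step))
  if (len == 0) return(scene)
  pos <- cell_centers(scene, t, physio = FALSE)
  r <- sqrt(rowSums(sweep(pos, 2, as.numeric(old_tip), "-")^2))
  gain <- scene$deformation$push_gain * exp(-r / scene$deformation$decay_length)
  D <- outer(gain, step)
  colnames(D) <- c("x", "y", "z")
  scene$deform_events[[length(scene$deform_events) + 1L]] <-
    list(t0 = t, D = D)
  scene
}

## -- frame geometry ---------------------------------------------------------

## pixel index (1-based, x index first) <-> volume um
px_to_um <- function(ix, iy, imaging, stage_xy = c(0, 0)) {
  fw <- imaging$field_of_view[1]; fh <- imaging$field_of_view[2]
  W <- imaging$pixels[1]; H <- imaging$pixels[2]
  cbind(x = stage_xy[1] - fw / 2 + (ix - 0.5) * fw / W,
        y = stage_xy[2] - fh / 2 + (iy - 0.5) * fh / H)
}

um_to_px <- function(x, y, imaging, stage_xy = c(0, 0)) {
  fw <- imaging$field_of_view[1]; fh <- imaging$field_of_view[2]
  W <- imaging$pixels[1]; H <- imaging$pixels[2]
  cbind(ix = (x - stage_xy[1] + fw / 2) * W / fw + 0.5,
        iy = (y - stage_xy[2] + fh / 2) * H / fh + 0.5)
}

render_pipette <- function(img, scene, focal_z, stage_xy) {
  pip <- scene$pipette
  im <- scene$imaging
  W <- im$pixels[1]; H <- im$pixels[2]
  env <- exp(-(pip$tip[3] - focal_z)^2 / (2 * im$axial_visibility_sigma^2))
  amp <- pip$dye_intensity * env
  if (amp < 0.5) return(img)
  ix <- matrix(seq_len(W), W, H)
  iy <- matrix(rep(seq_len(H), each = W), W, H)
  uv <- px_to_um(as.vector(ix), as.vector(iy), im, stage_xy)
  dx <- uv[, 1] - pip$tip[1]
  dy <- uv[, 2] - pip$tip[2]
  dz <- focal_z - pip$tip[3]
  a <- pip$axis
  s <- -(dx * a[1] + dy * a[2] + dz * a[3])     # distance behind the tip
  px <- dx + s * a[1]; py <- dy + s * a[2]; pz <- dz + s * a[3]
  rho <- sqrt(px^2 + py^2 + pz^2)
  rad <- pip$tip_diameter / 2 + s * tan(pip$cone_half_angle * pi / 180)
  inside <- s >= 0 & s <= pip$cone_length & rho <= rad
  img + matrix(ifelse(inside, amp, 0), W, H)
}

#' Crop a frame around a point of interest
#'
#' Returns a valid frame restricted to a square window, with its geometry
#' (pixel grid, field of view, stage offset) adjusted so pixel-to-um
#' mapping stays exact. Used to localize segmentation to a region of
#' interest, e.g. during focus sweeps.
#'
#' @param frame a `tp_frame`.
#' @param center (x, y) window center in um.
#' @param half_width half window size in um.
#' @return a cropped `tp_frame`.
#' @export
crop_frame <- function(frame, center, half_width) {
  im <- frame$imaging
  pxw <- im$field_of_view[1] / im$pixels[1]
  p <- um_to_px(center[1], center[2], im, frame$stage_xy)
  ix0 <- max(1L, round(p[1, 1] - half_width / pxw))
  ix1 <- min(im$pixels[1], round(p[1, 1] + half_width / pxw))
  iy0 <- max(1L, round(p[1, 2] - half_width / pxw))
  iy1 <- min(im$pixels[2], round(p[1, 2] + half_width / pxw))
  if (ix0 > ix1 || iy0 > iy1) stop("crop window outside the frame")
  W <- ix1 - ix0 + 1L; H <- iy1 - iy0 + 1L
  im2 <- im
  im2$pixels <- c(W, H)
  im2$field_of_view <- c(W * pxw, H * pxw)
  cx <- frame$stage_xy[1] - im$field_of_view[1] / 2 + ((ix0 + ix1) / 2 - 0.5) * pxw
  cy <- frame$stage_xy[2] - im$field_of_view[2] / 2 + ((iy0 + iy1) / 2 - 0.5) * pxw
  structure(list(red = frame$red[ix0:ix1, iy0:iy1, drop = FALSE],
                 green = frame$green[ix0:ix1, iy0:iy1, drop = FALSE],
                 focal_z = frame$focal_z, timestamp = frame$timestamp,
                 stage_xy = c(cx, cy), imaging = im2),
            class = "tp_frame")
}

#' Render one synthetic two-photon frame
#'
#' Each cell in the focal neighborhood is rendered as a Gaussian blob whose
#' lateral sigma combines the soma extent with the defocus blur,
#' `sqrt((diameter / 4)^2 + (z_sigma0 + z_defocus_rate * |dz|)^2)`, and whose
#' amplitude is
#' `peak_intensity * exp(-dz^2 / (2 * axial_visibility_sigma^2))`, with `dz`
#' the axial distance to the focal plane. The pipette is rendered as the
#' cross-section of its cone with the focal plane, scaled by the same axial
#' envelope evaluated at the tip depth. With `noise = TRUE`, Poisson-like
#' shot noise (exact Poisson at low expected counts, Gaussian approximation
#' above `poisson_threshold`) and Gaussian read noise are added. The noise
#' field is a deterministic function of the scene seed, `t` and `focal_z`.
#'
#' @param scene a `tp_scene`.
#' @param focal_z focal plane depth (um), within the volume z-range.
#' @param t acquisition time (s); sets physiological motion and relaxation.
#' @param noise logical, add shot/read noise.
#' @param stage_xy lateral field-of-view offset (um).
#' @return a list of class `tp_frame` with integer-valued `red` and `green`
#'   width-by-height matrices in `[0, 65535]`, plus `focal_z`, `timestamp`,
#'   `stage_xy` and the imaging geometry.
#' @export
render_frame <- function(scene, focal_z, t = 0, noise = TRUE,
                         stage_xy = c(0, 0)) {
  stopifnot(inherits(scene, "tp_scene"))
  vb <- scene$volume_bounds
  if (focal_z < vb[5] || focal_z > vb[6])
    stop("focal_z outside the volume z-range")
  im <- scene$imaging
  W <- im$pixels[1]; H <- im$pixels[2]
  chans <- list(red = matrix(im$background_level, W, H),
                green = matrix(im$background_level, W, H))
  pos <- cell_centers(scene, t, physio = TRUE)
  pxw <- im$field_of_view[1] / W
  pxh <- im$field_of_view[2] / H
  xs <- px_to_um(seq_len(W), rep(1, W), im, stage_xy)[, 1]
  ys <- px_to_um(rep(1, H), seq_len(H), im, stage_xy)[, 2]
  for (i in seq_len(nrow(pos))) {
    dz <- pos[i, 3] - focal_z
    A <- scene$cells$peak_intensity[i] *
      exp(-dz^2 / (2 * im$axial_visibility_sigma^2))
    if (A < 0.5) next
    blur <- im$z_sigma0 + im$z_defocus_rate * abs(dz)
    sig <- sqrt((scene$cells$diameter[i] / 4)^2 + blur^2)
    gx <- exp(-(xs - pos[i, 1])^2 / (2 * sig^2))
    gy <- exp(-(ys - pos[i, 2])^2 / (2 * sig^2))
    ch <- scene$cells$channel[i]
    chans[[ch]] <- chans[[ch]] + A * outer(gx, gy)
  }
  dch <- scene$pipette$dye_channel
  chans[[dch]] <- render_pipette(chans[[dch]], scene, focal_z, stage_xy)
  if (noise) {
    chans <- with_local_seed(hash_seed(scene$rng_seed, t, focal_z), {
      lapply(chans, function(img) {
        g <- im$shot_noise_scale
        nexp <- img / g
        out <- img
        lo <- nexp < im$poisson_threshold
        if (any(lo)) out[lo] <- g * rpois(sum(lo), nexp[lo])
        if (any(!lo)) out[!lo] <- img[!lo] +
            g * sqrt(nexp[!lo]) * rnorm(sum(!lo))
        out + rnorm(length(out), 0, im$read_noise_sd)
      })
    })
  }
  chans <- lapply(chans, function(img) {
    img <- round(img)
    img[img < 0] <- 0
    img[img > 65535] <- 65535
    img
  })
  structure(list(red = chans$red, green = chans$green, focal_z = focal_z,
                 timestamp = t, stage_xy = as.numeric(stage_xy),
                 imaging = im),
            class = "tp_frame")
}
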