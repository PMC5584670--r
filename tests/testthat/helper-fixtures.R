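# Shared fixtures for the suite, generated in code.

vnorm_test <- function(v) sqrt(sum(v^2))

# A single-cell scene at a known position; noise-free unless asked.
one_cell_scene <- function(z = -120, diameter = 10, peak = 40000,
                           seed = 7, background = 1500, ...) {
  cells <- data.frame(id = 1L, x = 0, y = 0, z = z, diameter = diameter,
                      channel = "green", peak_intensity = peak)
  make_scene(scene_config(cells = cells,
                          imaging = imaging_params(
                            background_level = background, ...),
                          n_distractors = 0L),
             seed)
}

# Brute-force Otsu: exhaustive scan of all cutpoints, direct two-class
# variance computation on the raw pixel values. Independent of the
# histogram/cumulative-sum implementation under test.
otsu_brute <- function(image) {
  v <- as.integer(round(image))
  cand <- sort(unique(v))
  cand <- cand[-length(cand)]          # threshold below the max
  best <- -Inf; best_t <- NA_integer_
  for (t in cand) {
    lo <- v[v <= t]; hi <- v[v > t]
    if (!length(lo) || !length(hi)) next
    sb <- length(lo) * length(hi) * (mean(lo) - mean(hi))^2
    if (sb > best + 1e-9) { best <- sb; best_t <- t }
  }
  best_t
}

# Digital disk mask of the given radius centered in a d x d matrix.
disk_mask <- function(radius, pad = 2L) {
  r <- ceiling(radius) + pad
  d <- 2L * r + 1L
  off <- seq(-r, r)
  outer(off^2, off^2, "+") <= radius^2
}

# Tiny fast experiment configuration for rig-level unit tests (short
# standoff keeps a full run under a second).
fast_config <- function(seed, standoff = 40, ...) {
  experiment_config(
    approach = approach_config(standoff_distance = standoff),
    policy = suction_policy(time_limit = 40),
    seed = seed, ...)
}

unitize_test <- function(v) v / sqrt(sum(v^2))

# um centroid of a detected object on its frame
px_to_um_test <- function(obj, frame) {
  im <- frame$imaging
  pxw <- im$field_of_view[1] / im$pixels[1]
  pxh <- im$field_of_view[2] / im$pixels[2]
  c(frame$stage_xy[1] - im$field_of_view[1] / 2 +
      (obj$centroid[["x"]] - 0.5) * pxw,
    frame$stage_xy[2] - im$field_of_view[2] / 2 +
      (obj$centroid[["y"]] - 0.5) * pxh)
}
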