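## On-line quantification of two-photon frames: channel separation,
## background-corrected Otsu segmentation, hole filling, per-object erosion
## masks, particle analysis, and the contrast-focus score (CFS).
##
## The CFS of object i is (⟨I⟩internal - ⟨I⟩external) / ⟨I⟩internal, where
## the internal region is the object eroded by `erosion_radius` and the
## external ring is the band between the original and eroded boundaries.
## Being a ratio it is invariant to overall intensity scaling, and it peaks
## when the object is in focus, which is what makes it usable both as a
## detection contrast measure and as the autofocus objective.

#' Segmentation configuration
#'
#' @param channel_mode which plane the chain runs on: `"red"`, `"green"`,
#'   or the saturating per-pixel `"sum"`.
#' @param background_window full width (pixels) of the local-median
#'   background estimator; must comfortably exceed a cell diameter.
#' @param erosion_radius disk radius (pixels) used to split each particle
#'   into internal mask and external ring.
#' @param min_particle_area,max_particle_area particle area filter (pixels).
#' @param noise_floor_k robustness guard: the working threshold is never
#'   below `noise_floor_k` times the median absolute deviation of the
#'   corrected image, so a signal-free frame (where Otsu would happily
#'   split the noise distribution in half) yields no particles.
#' @return a list of class `seg_config`.
#' @export
seg_config <- function(channel_mode = c("green", "red", "sum"),
                       background_window = 31L, erosion_radius = 2L,
                       min_particle_area = 15L, max_particle_area = 5000L,
                       noise_floor_k = 5) {
  channel_mode <- match.arg(channel_mode)
  stopifnot(background_window >= 3, erosion_radius >= 1,
            min_particle_area >= 1,
            max_particle_area >= min_particle_area, noise_floor_k >= 0)
  structure(list(channel_mode = channel_mode,
                 background_window = as.integer(background_window),
                 erosion_radius = as.integer(erosion_radius),
                 min_particle_area = as.integer(min_particle_area),
                 max_particle_area = as.integer(max_particle_area),
                 noise_floor_k = noise_floor_k),
            class = "seg_config")
}

#' Select or combine imaging channels
#'
#' @param frame a `tp_frame`.
#' @param mode `"red"`, `"green"`, or `"sum"` (per-pixel sum saturating at
#'   65535).
#' @return a width-by-height intensity matrix.
#' @export
split_channels <- function(frame, mode = c("green", "red", "sum")) {
  mode <- match.arg(mode)
  switch(mode,
         red = frame$red,
         green = frame$green,
         sum = pmin(frame$red + frame$green, 65535))
}

#' Subtract a smooth local background
#'
#' Estimates non-uniform background as a large-window local median and
#' subtracts it, flooring at zero. A constant image maps to all zeros;
#' compact bright blobs much smaller than the window are preserved.
#'
#' @param image intensity matrix in `[0, 65535]`.
#' @param window full width of the median window (pixels).
#' @return background-corrected matrix, same size.
#' @export
background_correct <- function(image, window = 31L) {
  stopifnot(is.matrix(image), window >= 3)
  rad <- min(window %/% 2L, (min(dim(image)) - 1L) %/% 2L)
  med <- EBImage::medianFilter(image / 65535, max(1L, rad)) * 65535
  out <- image - med
  out[out < 0] <- 0
  out
}

#' Otsu threshold on the 16-bit histogram
#'
#' Picks the integer threshold maximizing the between-class variance of the
#' image histogram; the foreground mask is `image > threshold`. Ties are
#' broken toward the lowest threshold. A constant image yields an empty
#' mask flagged `constant`.
#'
#' @param image intensity matrix with integer-valued pixels in
#'   `[0, 65535]`.
#' @return a list with `threshold`, logical `mask`, and `constant` flag.
#' @export
otsu_threshold <- function(image) {
  v <- as.integer(round(image))
  if (min(v) < 0 || max(v) > 65535)
    stop("image values must lie in [0, 65535]")
  lo <- min(v); hi <- max(v)
  if (lo == hi)
    return(list(threshold = NA_real_,
                mask = matrix(FALSE, nrow(image), ncol(image)),
                constant = TRUE))
  h <- tabulate(v - lo + 1L, hi - lo + 1L)
  lev <- lo:hi
  n <- length(v)
  w0 <- cumsum(h)
  m0 <- cumsum(h * lev)
  mt <- m0[length(m0)]
  ## candidate thresholds t = lev[k]: class 0 is <= t, class 1 is > t
  k <- seq_len(length(lev) - 1L)
  w0k <- w0[k]; w1k <- n - w0k
  valid <- w0k > 0 & w1k > 0
  mu0 <- m0[k] / w0k
  mu1 <- (mt - m0[k]) / w1k
  sb <- w0k * w1k * (mu0 - mu1)^2
  sb[!valid] <- -Inf
  thr <- lev[k[which.max(sb)]]   # which.max returns the first (lowest) tie
  list(threshold = as.numeric(thr), mask = matrix(v > thr, nrow(image)),
       constant = FALSE)
}

#' Fill holes in a binary mask
#'
#' Background regions not connected to the image border become foreground.
#' Idempotent.
#'
#' @param mask logical or 0/1 matrix.
#' @return logical matrix.
#' @export
fill_holes <- function(mask) {
  m <- matrix(as.integer(mask != 0), nrow(mask))
  EBImage::fillHull(m) != 0
}

disk_kernel <- function(radius) {
  r <- as.integer(radius)
  d <- 2L * r + 1L
  off <- seq(-r, r)
  k <- outer(off^2, off^2, "+") <= radius^2
  matrix(as.integer(k), d, d)
}

#' Morphological erosion with a disk structuring element
#'
#' @param mask logical or 0/1 matrix.
#' @param radius disk radius in pixels (>= 1); the element contains the
#'   integer offsets with `dx^2 + dy^2 <= radius^2`.
#' @return logical matrix, a subset of the input.
#' @export
erode_mask <- function(mask, radius = 2L) {
  stopifnot(radius >= 1)
  m <- matrix(as.integer(mask != 0), nrow(mask))
  EBImage::erode(m, disk_kernel(radius)) != 0
}

## 8-connected labeling: 4-connected pass, then merge labels touching
## diagonally until stable; relabel compactly in first-pixel order.
label8 <- function(mask) {
  m <- matrix(as.integer(mask != 0), nrow(mask))
  lab <- EBImage::bwlabel(m)
  lab <- matrix(as.integer(lab), nrow(m))
  nr <- nrow(lab); nc <- ncol(lab)
  if (max(lab) > 1L && nr > 1L && nc > 1L) {
    repeat {
      a <- c(lab[-nr, -nc], lab[-nr, -1])
      b <- c(lab[-1, -1],  lab[-1, -nc])
      sel <- a > 0L & b > 0L & a != b
      if (!any(sel)) break
      map <- seq_len(max(lab))
      pairs <- unique(cbind(pmin(a[sel], b[sel]), pmax(a[sel], b[sel])))
      for (i in seq_len(nrow(pairs))) {
        lo <- map[pairs[i, 1]]; hi <- map[pairs[i, 2]]
        m2 <- min(lo, hi)
        map[map == lo | map == hi] <- m2
      }
      lab[lab > 0L] <- map[lab[lab > 0L]]
    }
  }
  ids <- unique(lab[lab > 0L])       # column-major first-occurrence order
  if (length(ids)) {
    remap <- integer(max(ids))
    remap[ids] <- seq_along(ids)
    lab[lab > 0L] <- remap[lab[lab > 0L]]
  }
  lab
}

#' Contrast-focus score of a detected object
#'
#' `(mean(internal) - mean(external ring)) / mean(internal)`; may be
#' negative. If the internal mask is empty or its mean is zero the score is
#' undefined and `NA` is returned (the object is unusable for focusing).
#'
#' @param image the intensity matrix the object was segmented from.
#' @param object a `detected_object` (see [particle_analysis()]).
#' @return the score, or `NA_real_` when undefined.
#' @export
compute_cfs <- function(image, object) {
  cfs_from_masks(image, object$internal_idx, object$ring_idx)
}

cfs_from_masks <- function(image, internal_idx, ring_idx) {
  if (length(internal_idx) == 0 || length(ring_idx) == 0) return(NA_real_)
  mi <- mean(image[internal_idx])
  if (!is.finite(mi) || mi <= 0) return(NA_real_)
  me <- mean(image[ring_idx])
  (mi - me) / mi
}

#' Particle analysis of a segmented mask
#'
#' Labels 8-connected components, filters them by area, and measures each:
#' area, binary center of mass, bounding box, boundary contour, and the
#' internal/ring masks obtained by eroding the component with a disk of
#' `config$erosion_radius`. The CFS is computed from `image` on those
#' masks. Components are labeled in deterministic first-pixel scan order.
#'
#' @param mask logical foreground mask (after hole filling).
#' @param image intensity matrix probed for the CFS.
#' @param config a [seg_config()].
#' @return a list of `detected_object`s (possibly empty), class
#'   `tp_objects`.
#' @export
particle_analysis <- function(mask, image, config = seg_config()) {
  lab <- label8(mask)
  W <- nrow(lab); H <- ncol(lab)
  nlab <- max(lab)
  out <- list()
  if (nlab > 0) {
    rad <- config$erosion_radius
    for (id in seq_len(nlab)) {
      idx <- which(lab == id)
      area <- length(idx)
      if (area < config$min_particle_area ||
          area > config$max_particle_area) next
      ix <- ((idx - 1L) %% W) + 1L
      iy <- ((idx - 1L) %/% W) + 1L
      x0 <- min(ix); x1 <- max(ix); y0 <- min(iy); y1 <- max(iy)
      ## erode the component inside a padded crop
      cw <- x1 - x0 + 1L + 2L * rad
      ch <- y1 - y0 + 1L + 2L * rad
      sub <- matrix(0L, cw, ch)
      sub[cbind(ix - x0 + 1L + rad, iy - y0 + 1L + rad)] <- 1L
      er <- erode_mask(sub, rad)
      eidx <- which(er)
      eix <- ((eidx - 1L) %% cw) + x0 - rad
      eiy <- ((eidx - 1L) %/% cw) + y0 - rad
      internal_idx <- (eiy - 1L) * W + eix
      ring_idx <- setdiff(idx, internal_idx)
      obj <- structure(list(
        label = id, area = area,
        centroid = c(x = mean(ix), y = mean(iy)),
        bbox = c(xmin = x0, xmax = x1, ymin = y0, ymax = y1),
        contour = contour_of(sub, x0 - rad - 1L, y0 - rad - 1L),
        internal_idx = as.integer(internal_idx),
        ring_idx = as.integer(ring_idx),
        cfs = NA_real_), class = "detected_object")
      obj$cfs <- cfs_from_masks(image, obj$internal_idx, obj$ring_idx)
      out[[length(out) + 1L]] <- obj
    }
  }
  ## compact relabel of the kept objects, preserving scan order
  for (i in seq_along(out)) out[[i]]$label <- i
  structure(out, class = "tp_objects")
}

contour_of <- function(submask, xoff, yoff) {
  oc <- EBImage::ocontour(matrix(as.integer(submask), nrow(submask)))
  if (length(oc) == 0) return(matrix(numeric(0), 0, 2))
  ct <- oc[[1]]
  cbind(x = ct[, 1] + 1L + xoff, y = ct[, 2] + 1L + yoff)
}

#' Run the full segmentation chain on a frame
#'
#' Channel separation, background correction, Otsu thresholding, hole
#' filling, and particle analysis with per-object erosion masks and CFS, in
#' that order. Segmentation runs on the background-corrected plane while
#' the CFS probes the original intensities. A constant (e.g. fully
#' saturated or empty) plane yields an empty object list.
#'
#' @param frame a `tp_frame`.
#' @param config a [seg_config()].
#' @return a `tp_objects` list; attribute `"threshold"` carries the Otsu
#'   cut.
#' @export
segment_frame <- function(frame, config = seg_config()) {
  img <- split_channels(frame, config$channel_mode)
  bg <- background_correct(img, config$background_window)
  ot <- otsu_threshold(bg)
  if (ot$constant) {
    out <- structure(list(), class = "tp_objects")
    attr(out, "threshold") <- NA_real_
    return(out)
  }
  ## never threshold inside the noise distribution of a signal-free plane;
  ## the raw plane's MAD estimates the noise scale (cells occupy too few
  ## pixels to move it)
  guard <- config$noise_floor_k * stats::mad(img)
  thr <- max(ot$threshold, guard)
  mask <- fill_holes(bg > thr)
  ## masks come from the corrected image; intensities are probed on the
  ## original plane, so the ambient floor tempers the score of dim,
  ## defocused objects
  out <- particle_analysis(mask, img, config)
  attr(out, "threshold") <- thr
  out
}

#' Tabulate detected objects
#'
#' @param objects a `tp_objects` list.
#' @return a data.frame with one row per object (label, area, centroid,
#'   bbox, cfs).
#' @export
objects_table <- function(objects) {
  if (length(objects) == 0)
    return(data.frame(label = integer(), area = integer(),
                      centroid_x = numeric(), centroid_y = numeric(),
                      bbox_xmin = integer(), bbox_xmax = integer(),
                      bbox_ymin = integer(), bbox_ymax = integer(),
                      cfs = numeric()))
  do.call(rbind, lapply(objects, function(o)
    data.frame(label = o$label, area = o$area,
               centroid_x = o$centroid[["x"]], centroid_y = o$centroid[["y"]],
               bbox_xmin = o$bbox[["xmin"]], bbox_xmax = o$bbox[["xmax"]],
               bbox_ymin = o$bbox[["ymin"]], bbox_ymax = o$bbox[["ymax"]],
               cfs = o$cfs)))
}
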