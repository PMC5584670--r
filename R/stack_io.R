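## Multi-page 16-bit TIFF I/O for frame streams.
##
## Dialect: channels are interleaved as pages (red page then green page per
## frame). Because the TIFF writer in use cannot emit description tags,
## per-frame metadata (focal_z, timestamp, stage_xy) travels in a JSON
## sidecar file "<path>.json". Stacks without a sidecar are read as
## single-channel (green) frames, one per page, with NA focal depth.

#' Write a frame stream to a multi-page 16-bit TIFF
#'
#' @param frames a list of `tp_frame` objects.
#' @param path output TIFF path; a metadata sidecar is written to
#'   `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_stack <- function(frames, path) {
  if (inherits(frames, "tp_frame")) frames <- list(frames)
  stopifnot(length(frames) >= 1,
            all(vapply(frames, inherits, logical(1), "tp_frame")))
  pages <- list()
  for (fr in frames) {
    pages[[length(pages) + 1L]] <- fr$red / 65535
    pages[[length(pages) + 1L]] <- fr$green / 65535
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L,
                  compression = "none", reduce = FALSE)
  meta <- list(
    format = "patchrig-stack-v1",
    n_frames = length(frames),
    channels = c("red", "green"),
    frames = lapply(frames, function(fr)
      list(focal_z = fr$focal_z, timestamp = fr$timestamp,
           stage_xy = fr$stage_xy)),
    imaging = unclass(frames[[1]]$imaging))
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a frame stream from a multi-page 16-bit TIFF
#'
#' Round-trips [write_stack()] output losslessly (16-bit pixels and
#' per-frame metadata). Plain third-party stacks (no sidecar) are read one
#' page per frame into the green channel.
#'
#' @param path TIFF path.
#' @return a list of `tp_frame` objects.
#' @export
read_stack <- function(path) {
  if (!file.exists(path)) stop("cannot read stack: ", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e)
                      stop("unreadable TIFF '", path, "': ",
                           conditionMessage(e)))
  if (is.matrix(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]
    round(p * 65535)
  })
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = FALSE)
    n <- meta$n_frames
    if (length(pages) != 2L * n)
      stop(sprintf("truncated stack '%s': expected %d pages, found %d (frame %d incomplete)",
                   path, 2L * n, length(pages),
                   length(pages) %/% 2L + 1L))
    imf <- meta$imaging
    im <- imaging_params(
      field_of_view = as.numeric(unlist(imf$field_of_view)),
      pixels = as.integer(unlist(imf$pixels)),
      z_sigma0 = imf$z_sigma0, z_defocus_rate = imf$z_defocus_rate,
      axial_visibility_sigma = imf$axial_visibility_sigma,
      background_level = imf$background_level,
      shot_noise_scale = imf$shot_noise_scale,
      read_noise_sd = imf$read_noise_sd,
      poisson_threshold = imf$poisson_threshold)
    lapply(seq_len(n), function(i) {
      fm <- meta$frames[[i]]
      structure(list(red = pages[[2L * i - 1L]], green = pages[[2L * i]],
                     focal_z = as.numeric(fm$focal_z),
                     timestamp = as.numeric(fm$timestamp),
                     stage_xy = as.numeric(unlist(fm$stage_xy)),
                     imaging = im),
                class = "tp_frame")
    })
  } else {
    lapply(seq_along(pages), function(i) {
      W <- nrow(pages[[i]]); H <- ncol(pages[[i]])
      structure(list(red = matrix(0, W, H), green = pages[[i]],
                     focal_z = NA_real_, timestamp = i - 1,
                     stage_xy = c(0, 0),
                     imaging = imaging_params(pixels = c(W, H))),
                class = "tp_frame")
    })
  }
}
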