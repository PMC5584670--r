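# Build a detected object at a given um position on a synthetic frame.
frame_with_objects <- function(xy_list, peaks = NULL) {
  n <- length(xy_list)
  if (is.null(peaks)) peaks <- rep(40000, n)
  cells <- do.call(rbind, lapply(seq_len(n), function(i)
    data.frame(id = i, x = xy_list[[i]][1], y = xy_list[[i]][2],
               z = -120, diameter = 9, channel = "green",
               peak_intensity = peaks[i])))
  sc <- make_scene(scene_config(cells = cells, n_distractors = 0L), 3)
  fr <- render_frame(sc, -120, 0, noise = FALSE)
  list(frame = fr, objects = segment_frame(fr, seg_config()))
}

test_that("association gates on distance and breaks ties by contrast", {
  fx <- frame_with_objects(list(c(0, 0)))
  tr <- new_track(fx$objects[[1]], fx$frame, search_radius = 3)

  ## detection 1 um away: matched
  fx1 <- frame_with_objects(list(c(1, 0)))
  expect_false(is.null(associate(tr, fx1$objects, fx1$frame)))

  ## nearest detection 5 um away with a 3 um gate: none
  fx5 <- frame_with_objects(list(c(5, 0)))
  expect_null(associate(tr, fx5$objects, fx5$frame))

  ## two equidistant detections: the higher-CFS one wins
  fx2 <- frame_with_objects(list(c(-2, 0), c(2, 0)),
                            peaks = c(15000, 45000))
  m <- associate(tr, fx2$objects, fx2$frame)
  cfs <- vapply(fx2$objects, `[[`, numeric(1), "cfs")
  expect_equal(m$cfs, max(cfs))
})

test_that("misses ride out the budget as occlusion before loss", {
  fx <- frame_with_objects(list(c(0, 0)))
  tr <- new_track(fx$objects[[1]], fx$frame, miss_budget = 5)
  p0 <- track_position(tr)
  for (k in 1:3) tr <- update_track(tr, NULL, fx$frame, -120, k)
  expect_equal(tr$status, "occluded")
  expect_equal(track_position(tr), p0)      # position unchanged

  ## reappearance at the same point: visible again, no jump
  m <- associate(tr, fx$objects, fx$frame)
  tr <- update_track(tr, m, fx$frame, -120, 4)
  expect_equal(tr$status, "visible")
  expect_lt(vnorm_test(track_position(tr) - p0), 1)

  ## budget exhausted: lost
  for (k in 5:10) tr <- update_track(tr, NULL, fx$frame, -120, k)
  expect_equal(tr$status, "lost")
})

test_that("reacquisition absorbs lateral migration within the gate", {
  sc <- one_cell_scene()
  fr <- render_frame(sc, -120, 0, noise = FALSE)
  tr <- new_track(segment_frame(fr, seg_config())[[1]], fr)

  ## displace the cell 2.5 um laterally (half of a 5 um soma)
  sc$cells$rest_x <- 2.5
  clock <- new.env(); clock$t <- 0
  acq <- function(z) { clock$t <- clock$t + 0.25
    render_frame(sc, z, clock$t, noise = FALSE) }
  events <- character()
  tr <- reacquire_after_step(tr, acq, log_fn = function(e, p)
    events <<- c(events, e))
  expect_equal(tr$status, "visible")
  expect_equal(track_position(tr)[["x"]], 2.5, tolerance = 0.5)
  expect_false("autofocus" %in% events)     # purely lateral: no sweep
})

test_that("axial migration is recovered through an autofocus sweep", {
  sc <- one_cell_scene()
  fr <- render_frame(sc, -120, 0, noise = FALSE)
  tr <- new_track(segment_frame(fr, seg_config())[[1]], fr)

  sc$cells$rest_z <- -123                   # 3 um deeper
  clock <- new.env(); clock$t <- 0
  acq <- function(z) { clock$t <- clock$t + 0.25
    render_frame(sc, z, clock$t, noise = FALSE) }
  events <- character()
  ## a bright soma stays laterally matchable at 3 um of defocus, so the
  ## axial fix comes from the sweep the servo schedules
  tr <- reacquire_after_step(tr, acq, force_refocus = TRUE,
                             log_fn = function(e, p)
                               events <<- c(events, e))
  expect_equal(tr$status, "visible")
  expect_true("autofocus" %in% events)
  expect_lte(abs(track_position(tr)[["z"]] - (-123)), 1)
})

test_that("a deleted target raises a lost event", {
  sc <- one_cell_scene()
  fr <- render_frame(sc, -120, 0, noise = FALSE)
  tr <- new_track(segment_frame(fr, seg_config())[[1]], fr,
                  miss_budget = 2)
  sc$cells <- sc$cells[0, ]
  clock <- new.env(); clock$t <- 0
  acq <- function(z) { clock$t <- clock$t + 0.25
    render_frame(sc, z, clock$t, noise = FALSE) }
  events <- character()
  tr <- reacquire_after_step(tr, acq, log_fn = function(e, p)
    events <<- c(events, e))
  expect_equal(tr$status, "lost")
  expect_true("target_lost" %in% events)
})

test_that("identical frame sequences produce identical tracks", {
  sc <- one_cell_scene()
  run_once <- function() {
    scl <- sc
    fr <- render_frame(scl, -120, 0, noise = TRUE)
    tr <- new_track(segment_frame(fr, seg_config())[[1]], fr)
    clock <- new.env(); clock$t <- 0
    acq <- function(z) { clock$t <- clock$t + 0.25
      render_frame(scl, z, clock$t, noise = TRUE) }
    for (k in 1:3) tr <- reacquire_after_step(tr, acq)
    tr
  }
  expect_identical(track_table(run_once()), track_table(run_once()))
})
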