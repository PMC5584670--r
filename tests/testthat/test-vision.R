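test_that("channel selection returns planes and saturating sums", {
  sc <- one_cell_scene()
  fr <- render_frame(sc, -120, 0, noise = FALSE)
  expect_identical(split_channels(fr, "green"), fr$green)
  expect_identical(split_channels(fr, "red"), fr$red)
  fr$red[] <- 40000; fr$green[] <- 40000
  expect_true(all(split_channels(fr, "sum") == 65535))
})

test_that("background correction removes smooth structure, keeps blobs", {
  flat <- matrix(500, 64, 64)
  expect_true(all(background_correct(flat) == 0))

  ## adding a ramp changes the corrected interior only within tolerance
  blob <- matrix(0, 64, 64)
  blob[28:36, 28:36] <- 8000
  ramp <- outer(seq(0, 2000, length.out = 64), rep(1, 64))
  c1 <- background_correct(blob)
  c2 <- background_correct(blob + ramp)
  interior <- 20:44
  expect_lt(max(abs(c1[interior, interior] - c2[interior, interior])), 120)

  ## an isolated bright blob survives nearly unchanged
  expect_equal(max(c1), 8000, tolerance = 0.02)
})

test_that("otsu splits a two-level histogram exactly", {
  img <- matrix(c(rep(10, 50), rep(200, 50)), 10, 10)
  res <- otsu_threshold(img)
  ## every cut between the two levels ties; the documented rule takes the
  ## lowest, and the strict mask comparison still isolates the upper class
  expect_gte(res$threshold, 10)
  expect_lt(res$threshold, 200)
  expect_equal(sum(res$mask), 50)

  ## symmetric swap of class counts gives the same cut
  img2 <- matrix(c(rep(10, 30), rep(200, 70)), 10, 10)
  img3 <- matrix(c(rep(10, 70), rep(200, 30)), 10, 10)
  expect_equal(otsu_threshold(img2)$threshold,
               otsu_threshold(img3)$threshold)

  ## constant image: empty mask, flagged
  res0 <- otsu_threshold(matrix(7, 5, 5))
  expect_true(res0$constant)
  expect_false(any(res0$mask))
})

test_that("otsu equals the exhaustive between-class maximizer", {
  set.seed(11)
  for (k in 1:40) {
    vals <- sample(0:255, sample(2:6, 1))
    img <- matrix(sample(vals, 144, replace = TRUE), 12, 12)
    expect_equal(otsu_threshold(img)$threshold, otsu_brute(img),
                 info = sprintf("case %d", k))
  }
})

test_that("hole filling closes interior background and is idempotent", {
  ann <- disk_mask(8) & !disk_mask(4, pad = 6L)
  filled <- fill_holes(ann)
  expect_equal(sum(filled), sum(disk_mask(8)))
  expect_identical(fill_holes(filled), filled)
  solid <- disk_mask(5)
  expect_identical(fill_holes(solid), solid)
})

test_that("disk erosion shrinks radius and never adds pixels", {
  d5 <- disk_mask(5, pad = 3L)       # 17 x 17
  er <- erode_mask(d5, 2)
  ## result sandwiched between radius-2 and radius-4 disks (+-1 px)
  expect_equal(sum(er & !disk_mask(4, pad = 4L)), 0)
  expect_true(all(er[disk_mask(2, pad = 6L)]))
  expect_true(all(d5[er]))                   # anti-extensive
  expect_false(any(erode_mask(matrix(FALSE, 9, 9), 2)))
})

test_that("particle analysis measures, filters, and orders components", {
  mask <- matrix(FALSE, 60, 60)
  mask[6:15, 6:15] <- TRUE             # 100 px
  mask[36:45, 36:45] <- TRUE           # 100 px
  mask[52:53, 52] <- TRUE              # 2 px, filtered out
  img <- matrix(100, 60, 60)
  cfg <- seg_config(min_particle_area = 20)
  objs <- particle_analysis(mask, img, cfg)
  expect_length(objs, 2)
  expect_equal(vapply(objs, `[[`, numeric(1), "area"), c(100, 100))
  expect_equal(vapply(objs, `[[`, numeric(1), "label"), c(1, 2))

  ## centroid of a symmetric disk sits at its center
  dm <- matrix(FALSE, 100, 120)
  dm[outer((1:100 - 50)^2, (1:120 - 60)^2, "+") <= 36] <- TRUE
  obj <- particle_analysis(dm, matrix(1000, 100, 120), cfg)[[1]]
  expect_equal(unname(obj$centroid), c(50, 60), tolerance = 0.5)
  ## masks are disjoint and the centroid lies inside the bbox
  expect_length(intersect(obj$internal_idx, obj$ring_idx), 0)
  expect_true(obj$centroid[["x"]] >= obj$bbox[["xmin"]] &&
                obj$centroid[["x"]] <= obj$bbox[["xmax"]])
})

test_that("diagonally touching components are one 8-connected particle", {
  mask <- matrix(FALSE, 20, 20)
  mask[5:8, 5:8] <- TRUE
  mask[9:12, 9:12] <- TRUE             # touches only at the corner
  objs <- particle_analysis(mask, matrix(1, 20, 20),
                            seg_config(min_particle_area = 5))
  expect_length(objs, 1)
  expect_equal(objs[[1]]$area, 32)
})

test_that("the CFS follows its defining ratio and flags degeneracy", {
  img <- matrix(0, 40, 40)
  dm <- matrix(FALSE, 40, 40)
  dm[outer((1:40 - 20)^2, (1:40 - 20)^2, "+") <= 64] <- TRUE
  obj <- particle_analysis(dm, img, seg_config())[[1]]

  img[obj$internal_idx] <- 1000
  img[obj$ring_idx] <- 0
  expect_equal(compute_cfs(img, obj), 1.0)

  img[obj$ring_idx] <- 1000
  expect_equal(compute_cfs(img, obj), 0.0)

  img[obj$internal_idx] <- 800
  img[obj$ring_idx] <- 200
  expect_equal(compute_cfs(img, obj), 0.75)

  ## scale invariance under positive scaling
  for (k in c(0.5, 2, 10))
    expect_equal(compute_cfs(img * k, obj), 0.75, tolerance = 1e-12)

  ## zero interior mean is undefined
  img[] <- 0
  expect_true(is.na(compute_cfs(img, obj)))
})

test_that("the full chain finds rendered cells deterministically", {
  cells <- data.frame(id = 1:3, x = c(-20, 5, 22), y = c(-15, 18, -8),
                      z = -120, diameter = c(8, 10, 12),
                      channel = "green",
                      peak_intensity = c(30000, 40000, 35000))
  sc <- make_scene(scene_config(cells = cells, n_distractors = 0L), 5)
  fr <- render_frame(sc, -120, 0, noise = TRUE)
  objs <- segment_frame(fr, seg_config())
  expect_length(objs, 3)
  expect_equal(vapply(objs, `[[`, numeric(1), "label"), 1:3)

  ## identical frame and config give identical object lists
  objs2 <- segment_frame(fr, seg_config())
  expect_identical(objects_table(objs), objects_table(objs2))

  ## a cell-free noise frame yields no particles at default config
  sc0 <- one_cell_scene()
  sc0$cells <- sc0$cells[0, ]
  fr0 <- render_frame(sc0, -120, 0, noise = TRUE)
  expect_length(segment_frame(fr0, seg_config()), 0)
})
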