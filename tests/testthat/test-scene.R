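test_that("scene construction is seeded, deterministic, and anchored", {
  cfg <- scene_config()
  s1 <- make_scene(cfg, 42)
  s2 <- make_scene(cfg, 42)
  expect_identical(s1, s2)

  expect_equal(unlist(s1$cells[1, c("rest_x", "rest_y", "rest_z")],
                      use.names = FALSE),
               c(0, 0, -120))
  expect_equal(s1$cells$x, s1$cells$rest_x)

  ## different seeds with noise enabled give different frame streams
  s3 <- make_scene(cfg, 43)
  f1 <- render_frame(s1, -120, 0, noise = TRUE)
  f3 <- render_frame(s3, -120, 0, noise = TRUE)
  expect_false(identical(f1$green, f3$green))

  ## and an identical seed renders bitwise-identically
  expect_identical(f1, render_frame(make_scene(cfg, 42), -120, 0,
                                    noise = TRUE))
})

test_that("cells outside the volume are rejected by id", {
  cells <- data.frame(id = c(1L, 9L), x = c(0, 500), y = 0,
                      z = c(-120, -120), diameter = 10,
                      channel = "green", peak_intensity = 40000)
  expect_error(make_scene(scene_config(cells = cells), 1),
               "cell id 9")
})

test_that("rendering follows the stated blur and visibility laws", {
  ## place the cell exactly on a pixel center so the peak lands on it
  im <- imaging_params(background_level = 0)
  pxw <- im$field_of_view[1] / im$pixels[1]
  cx <- -im$field_of_view[1] / 2 + (48 - 0.5) * pxw
  cells <- data.frame(id = 1L, x = cx, y = cx, z = -120, diameter = 10,
                      channel = "green", peak_intensity = 40000)
  sc <- make_scene(scene_config(cells = cells, imaging = im,
                                n_distractors = 0L,
                                pipette = pipette_geometry(
                                  tip = c(205, 0, 22.5),
                                  dye_intensity = 100)),
                   1)
  fr <- render_frame(sc, -120, 0, noise = FALSE)
  expect_equal(fr$green[48, 48], 40000)

  ## at 3 axial sigmas the peak obeys the visibility envelope
  sa <- im$axial_visibility_sigma
  fr3 <- render_frame(sc, -120 + 3 * sa, 0, noise = FALSE)
  expect_lte(max(fr3$green), 40000 * exp(-4.5) + 1)

  ## defocus monotonicity of the peak intensity
  peaks <- vapply(seq(0, 8, by = 1), function(dz)
    max(render_frame(sc, -120 + dz, 0, noise = FALSE)$green),
    numeric(1))
  expect_true(all(diff(peaks) <= 0))

  ## a cell-free scene with no visible pipette renders the flat floor only
  sc0 <- sc
  sc0$cells <- sc0$cells[0, ]
  fr0 <- render_frame(sc0, -120, 0, noise = FALSE)
  expect_true(all(fr0$green == 0))
})

test_that("insertion steps displace cells by the exponential push law", {
  sc <- one_cell_scene()
  sc$deformation <- deformation_params(push_gain = 0.8, decay_length = 25,
                                       relaxation_fraction = 0)
  tip0 <- c(0, 0, -120)          # at the cell: r = 0
  sc1 <- apply_insertion_step(sc, tip0, tip0 + c(0, 0, -4), t = 0)
  p <- cell_centers(sc1, 0, physio = FALSE)
  expect_equal(unname(p[1, ]), c(0, 0, -123.2))

  ## at r = decay_length the displacement shrinks by 1/e
  sc2 <- apply_insertion_step(sc, c(25, 0, -120), c(25, 0, -124), t = 0)
  p2 <- cell_centers(sc2, 0, physio = FALSE)
  expect_equal(vnorm_test(p2[1, ] - c(0, 0, -120)), 3.2 / exp(1),
               tolerance = 1e-10)

  ## zero-length step leaves the scene unchanged
  expect_identical(apply_insertion_step(sc, tip0, tip0, 0), sc)

  ## oversized steps are refused
  expect_error(apply_insertion_step(sc, tip0, tip0 + c(0, 0, -20), 0),
               "exceeds configured max step")
})

test_that("repeated steps match a brute-force re-evaluation (no recoil)", {
  sc <- one_cell_scene()
  sc$deformation <- deformation_params(push_gain = 0.6, decay_length = 20,
                                       relaxation_fraction = 0)
  tip <- c(10, 0, -140)
  step <- c(0, 0, 3)
  pos_brute <- c(0, 0, -120)
  for (k in 1:6) {
    r <- vnorm_test(pos_brute - tip)
    pos_brute <- pos_brute + 0.6 * exp(-r / 20) * step
    sc <- apply_insertion_step(sc, tip, tip + step, t = k)
    tip <- tip + step
  }
  expect_equal(unname(cell_centers(sc, 6, physio = FALSE)[1, ]),
               pos_brute, tolerance = 1e-12)
})

test_that("viscoelastic recoil decays the configured fraction", {
  sc <- one_cell_scene()
  sc$deformation <- deformation_params(push_gain = 1, decay_length = 25,
                                       relaxation_fraction = 0.4,
                                       relaxation_tau = 2)
  sc <- apply_insertion_step(sc, c(0, 0, -120), c(0, 0, -124), t = 0)
  z_at <- function(t) unname(cell_centers(sc, t, physio = FALSE)[1, 3])
  expect_equal(z_at(0), -124)
  ## after many taus only the permanent 60% remains
  expect_equal(z_at(100), -120 - 0.6 * 4, tolerance = 1e-6)
  ## monotone recoil in between
  zz <- vapply(c(0, 1, 2, 4, 8), z_at, numeric(1))
  expect_true(all(diff(zz) > 0))
})

test_that("physiological motion is zero-mean over integer periods", {
  sc <- one_cell_scene()
  sc$motion <- physio_motion_params(breathing_amplitude = 1,
                                    breathing_period = 1,
                                    heartbeat_amplitude = 0.5,
                                    heartbeat_period = 0.25)
  ts <- seq(0, 1, length.out = 401)[-401]   # one breath, four beats
  pos <- vapply(ts, function(t) cell_centers(sc, t)[1, ], numeric(3))
  expect_equal(unname(rowMeans(pos)),
               unname(cell_centers(sc, 0, physio = FALSE)[1, ]),
               tolerance = 1e-6)
})
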