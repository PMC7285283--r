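test_that("scene generation is deterministic and respects bundling structure", {
  cfg <- small_scene_config(seed = 11, n_fibers = 8L, bundling_factor = 2L)
  s1 <- generate_fiber_scene(cfg)
  s2 <- generate_fiber_scene(cfg)
  expect_identical(s1, s2)
  expect_identical(render_scene(s1)$pixels, render_scene(s2)$pixels)

  expect_length(s1$backbones, 4L)         # ceil(8 / 2)
  b8 <- generate_fiber_scene(small_scene_config(seed = 11, n_fibers = 8L,
                                                bundling_factor = 8L))
  expect_length(b8$backbones, 1L)
  b1 <- generate_fiber_scene(small_scene_config(seed = 11, n_fibers = 8L,
                                                bundling_factor = 1L))
  expect_length(b1$backbones, 8L)
  # with b = 1 apparent and fluorophore lengths coincide
  expect_equal(b1$true_apparent_length_um, b1$true_total_length_um)
  # with b = 8 the fluorophore length is 8x the apparent length
  expect_equal(b8$true_total_length_um, 8 * b8$true_apparent_length_um)
})

test_that("an empty scene has no fibers and zero length", {
  sc <- generate_fiber_scene(small_scene_config(seed = 2, n_fibers = 0L))
  expect_length(sc$polylines, 0L)
  expect_identical(sc$true_total_length_um, 0)
  img <- render_scene(sc, noise = FALSE)
  expect_true(all(img$pixels == sc$config$background_level))
})

test_that("config validation rejects impossible scenes", {
  expect_error(fiber_scene_config(n_fibers = 4, bundling_factor = 5),
               class = "cwrq_config_error")
  expect_error(fiber_scene_config(pixel_size_um = 0),
               class = "cwrq_config_error")
  cfg <- fiber_scene_config(cell_radius_px = 3, n_fibers = 2,
                            fiber_width_px = 3, curve_step_px = 4)
  expect_error(generate_fiber_scene(cfg), class = "cwrq_placement_error")
})

test_that("rendering conserves total fluorophore independent of bundling", {
  cfg1 <- small_scene_config(seed = 7, n_fibers = 8L, bundling_factor = 1L,
                             read_noise_sd = 0)
  sc1 <- generate_fiber_scene(cfg1)
  img1 <- render_scene(sc1, noise = FALSE)
  tot1 <- sum(img1$pixels - cfg1$background_level)
  expected <- cfg1$fiber_intensity * sc1$true_total_length_um / cfg1$pixel_size_um
  expect_lt(abs(tot1 / expected - 1), 0.02)

  cfg2 <- small_scene_config(seed = 7, n_fibers = 8L, bundling_factor = 2L,
                             read_noise_sd = 0)
  sc2 <- generate_fiber_scene(cfg2)
  img2 <- render_scene(sc2, noise = FALSE)
  tot2 <- sum(img2$pixels - cfg2$background_level)
  # same fluorophore within anti-aliasing tolerance, but brighter peaks
  expect_lt(abs(tot2 / tot1 - 1), 0.02)
  expect_gt(max(img2$pixels), max(img1$pixels))
})

test_that("a horizontal fiber renders only near its backbone and inside the disc", {
  sc <- straight_fiber_scene(len = 80, width = 3, psf = 0, background = 0)
  img <- render_scene(sc, noise = FALSE)
  nz <- which(img$pixels > 1e-9, arr.ind = TRUE)
  r0 <- nrow(img$pixels) / 2
  expect_true(all(abs(nz[, 1] - r0) <= 3))

  cfg <- small_scene_config(seed = 5, n_fibers = 10L, psf_sigma_px = 0,
                            background_level = 0)
  sc2 <- generate_fiber_scene(cfg)
  img2 <- render_scene(sc2, noise = FALSE)
  nz2 <- which(img2$pixels > 1e-9)
  expect_true(all(sc2$mask$keep[nz2]))
})

test_that("SEM scenes are deterministic and recover the diameter mixture", {
  cfg <- sem_scene_config(seed = 9, n_fibers = 30L)
  a <- generate_sem_image(cfg)
  b <- generate_sem_image(cfg)
  expect_identical(a$true_diameters_nm, b$true_diameters_nm)
  expect_identical(a$image$pixels, b$image$pixels)

  # mixture weight recovery at n = 500 draws within binomial error
  draws <- unlist(lapply(1:13, function(s) {
    generate_sem_image(sem_scene_config(seed = s, n_fibers = 40L))$true_diameters_nm
  }))
  draws <- draws[1:500]
  # component 1: N(25, 3.5) with weight 0.6; P(20 <= d < 30) under the
  # mixture is ~0.52, so the observed fraction should be within 4 binomial
  # sd of it
  p <- 0.6 * diff(pnorm(c(20, 30), 25, 3.5)) +
       0.2 * diff(pnorm(c(20, 30), 15, 2.5)) +
       0.2 * diff(pnorm(c(20, 30), 40, 7))
  obs <- mean(draws >= 20 & draws < 30)
  expect_lt(abs(obs - p), 4 * sqrt(p * (1 - p) / 500))

  expect_error(generate_sem_image(sem_scene_config(nm_per_px = 30)),
               class = "cwrq_config_error")
})

test_that("rupture-count simulation follows the binomial model", {
  r1 <- simulate_rupture_counts(1, 500, seed = 1)
  expect_identical(r1$n30, r1$n0)
  r0 <- simulate_rupture_counts(0, 500, seed = 1)
  expect_identical(r0$n30, 0L)
  expect_error(simulate_rupture_counts(1.5, 100), class = "cwrq_config_error")
  expect_error(simulate_rupture_counts(-0.1, 100), class = "cwrq_config_error")

  ratios <- vapply(1:200, function(s)
    osmotic_stability(simulate_rupture_counts(0.3, 10000, seed = s)),
    numeric(1))
  expect_lt(abs(mean(ratios) - 0.3), 0.01)
})

test_that("scene serialisation writes image, mask and ground truth", {
  d <- withr::local_tempdir()
  sc <- generate_fiber_scene(small_scene_config(seed = 3, n_fibers = 3L))
  write_scene(sc, d)
  expect_true(file.exists(file.path(d, "image.tif")))
  expect_true(file.exists(file.path(d, "mask.png")))
  truth <- jsonlite::read_json(file.path(d, "truth.json"), simplifyVector = TRUE)
  expect_equal(truth$true_apparent_length_um, sc$true_apparent_length_um)
  mk <- read_mask(file.path(d, "mask.png"))
  expect_identical(mk$keep, sc$mask$keep)
})
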