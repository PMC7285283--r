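test_that("a constant image yields an empty skeleton and non-finite pixels error", {
  img <- image2d(matrix(100, 64, 64), 0.124)
  sk <- extract_lines(img)
  expect_identical(sk$n_pixels, 0L)

  bad <- img
  bad$pixels[5, 5] <- NA
  expect_error(extract_lines(bad), class = "cwrq_format_error")
})

test_that("a straight fiber at SNR >= 10 is recovered with few spurious pixels", {
  sc <- straight_fiber_scene(len = 100, width = 3, intensity = 900,
                             background = 50, seed = 4)
  img <- render_scene(sc)
  sk <- extract_lines(img)
  r0 <- nrow(img$pixels) / 2
  c0 <- (ncol(img$pixels) - 100) / 2
  on_line <- abs(sk$pixels[, "row"] - r0) <= 1 &
    sk$pixels[, "col"] >= c0 - 1 & sk$pixels[, "col"] <= c0 + 101
  expect_gte(sum(on_line), 90)
  # spurious = skeleton pixels with no appreciable rendered fiber signal
  # (above the shot-noise scale, ~5% of peak here); the ridge legitimately
  # continues a couple of pixels past the backbone ends, by the reach of
  # the point-spread function
  signal <- render_scene(sc, noise = FALSE)$pixels - sc$config$background_level
  supported <- signal[sk$pixels] > 0.05 * max(signal)
  expect_lte(sum(!supported), 5)
})

test_that("extraction is deterministic", {
  sc <- generate_fiber_scene(small_scene_config(seed = 13))
  img <- render_scene(sc)
  expect_identical(extract_lines(img, sc$mask), extract_lines(img, sc$mask))
})

test_that("the skeleton is one pixel wide (no 2x2 block)", {
  for (s in c(3, 14)) {
    sc <- generate_fiber_scene(small_scene_config(seed = s, n_fibers = 10L))
    sk <- extract_lines(render_scene(sc), sc$mask)
    B <- matrix(FALSE, sk$dim[1], sk$dim[2])
    B[sk$pixels] <- TRUE
    solid <- B[-nrow(B), -ncol(B)] & B[-1, -ncol(B)] &
             B[-nrow(B), -1] & B[-1, -1]
    expect_false(any(solid))
  }
})

test_that("raising the response threshold never enlarges the skeleton", {
  sc <- generate_fiber_scene(small_scene_config(seed = 21))
  img <- render_scene(sc)
  n_px <- vapply(c(2, 3.5, 5, 8), function(k)
    extract_lines(img, sc$mask,
                  line_extract_params(threshold_k = k))$n_pixels,
    integer(1))
  expect_true(all(diff(n_px) <= 0))
})

test_that("pruning removes short spurs and flecks but keeps long paths", {
  # identity at zero lengths
  B <- matrix(FALSE, 20, 30); B[10, 3:25] <- TRUE
  sk <- skeleton_from_binary(B)
  expect_identical(prune_skeleton(sk, 0, 0)$pixels, sk$pixels)

  # a lone 3-px component dies under del_len = 5
  B3 <- matrix(FALSE, 10, 10); B3[5, 4:6] <- TRUE
  expect_identical(prune_skeleton(skeleton_from_binary(B3), 5, 5)$n_pixels, 0L)
  # a 4-px isolated fleck (< del_len) is removed even with shave_len = 0
  B4 <- matrix(FALSE, 10, 10); B4[5, 3:6] <- TRUE
  expect_identical(prune_skeleton(skeleton_from_binary(B4), 0, 5)$n_pixels, 0L)

  # T fixture: stem 20 px, arm 4 px; arm shaved, stem intact
  BT <- matrix(FALSE, 30, 30)
  BT[15, 5:24] <- TRUE      # stem
  BT[11:14, 15] <- TRUE     # 4-px arm meeting the stem mid-span at (15, 15)
  pruned <- prune_skeleton(skeleton_from_binary(BT), 5, 5)
  expect_identical(pruned$n_pixels, 20L)
  expect_true(all(pruned$pixels[, "row"] == 15))

  # a 9-px arm (>= shave_len) survives
  BT2 <- matrix(FALSE, 30, 30)
  BT2[15, 5:24] <- TRUE
  BT2[6:14, 15] <- TRUE
  expect_identical(prune_skeleton(skeleton_from_binary(BT2), 5, 5)$n_pixels, 29L)

  # idempotence
  once <- prune_skeleton(skeleton_from_binary(BT), 5, 5)
  twice <- prune_skeleton(once, 5, 5)
  expect_identical(once$pixels, twice$pixels)
})

test_that("params validation enforces the supported pickup mode", {
  expect_error(line_extract_params(pickup = "below"),
               class = "cwrq_config_error")
  expect_error(line_extract_params(ridge_sigma_px = 0),
               class = "cwrq_config_error")
})

test_that("skeletons serialise to JSON and back unchanged", {
  d <- withr::local_tempdir()
  sc <- generate_fiber_scene(small_scene_config(seed = 17))
  sk <- extract_lines(render_scene(sc), sc$mask)
  f <- file.path(d, "sk.json")
  write_skeleton(sk, f)
  back <- read_skeleton(f)
  expect_identical(back$pixels, sk$pixels)
  expect_identical(back$intensities, sk$intensities)
  expect_identical(back$pixel_size_um, sk$pixel_size_um)
})
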