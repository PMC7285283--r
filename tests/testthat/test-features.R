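test_that("hand-worked feature values are reproduced exactly", {
  expect_identical(mean_intensity(skeleton_from_intensities(c(7, 7, 7))), 7)
  expect_identical(mean_intensity(skeleton_from_intensities(c(2, 4))), 3)
  expect_equal(coefficient_of_variation(skeleton_from_intensities(c(1, 3))), 0.5)
  expect_equal(skewness(skeleton_from_intensities(c(1, 2, 3))), 0)
  expect_equal(skewness(skeleton_from_intensities(c(0, 0, 1))),
               0.707107, tolerance = 1e-6)
  # odd-moment sign flip: S(c - x) = -S(x)
  x <- c(0, 0, 1)
  expect_equal(skewness(skeleton_from_intensities(1 - x)),
               -skewness(skeleton_from_intensities(x)))
})

test_that("features agree with naive loop oracles on random skeletons", {
  set.seed(101)
  for (i in 1:50) {
    n <- sample(2:200, 1)
    x <- round(runif(n, 1, 4095))
    if (sd(x) == 0) x[1] <- x[1] + 1
    sk <- skeleton_from_intensities(x, pixel_size_um = 0.124)
    o <- oracle_features(x, 0.124)
    expect_equal(total_length(sk), o$total_length_mm, tolerance = 1e-12)
    expect_equal(mean_intensity(sk), o$mean, tolerance = 1e-12)
    expect_equal(coefficient_of_variation(sk), o$cv, tolerance = 1e-12)
    expect_equal(skewness(sk), o$skew, tolerance = 1e-12)
  }
})

test_that("total length is the calibrated pixel count", {
  empty <- skeleton_network(matrix(integer(0), 0, 2), numeric(0), 0.124,
                            c(10L, 10L))
  expect_identical(total_length(empty), 0)
  sk <- skeleton_from_intensities(rep(1, 1000), pixel_size_um = 0.124)
  expect_equal(total_length(sk), 0.124)
  sk2 <- skeleton_from_intensities(rep(1, 1000), pixel_size_um = 0.248)
  expect_equal(total_length(sk2), 2 * total_length(sk))
  uncal <- skeleton_from_intensities(1:5, pixel_size_um = NA_real_)
  expect_error(total_length(uncal), class = "cwrq_calibration_error")
})

test_that("CV is scale-invariant and intensity features fail typed on degenerate input", {
  x <- runif(50, 10, 100)
  expect_equal(coefficient_of_variation(skeleton_from_intensities(7.3 * x)),
               coefficient_of_variation(skeleton_from_intensities(x)))

  empty <- skeleton_network(matrix(integer(0), 0, 2), numeric(0), 0.124,
                            c(10L, 10L))
  expect_error(mean_intensity(empty), class = "cwrq_undefined_feature")
  expect_error(coefficient_of_variation(skeleton_from_intensities(5)),
               class = "cwrq_undefined_feature")
  expect_error(coefficient_of_variation(skeleton_from_intensities(c(0, 0))),
               class = "cwrq_undefined_feature")
  expect_error(skewness(skeleton_from_intensities(c(4, 4, 4))),
               class = "cwrq_undefined_feature")
})

test_that("feature tables keep degenerate cells as flagged rows", {
  sks <- list(skeleton_from_intensities(c(10, 20, 30)),
              skeleton_network(matrix(integer(0), 0, 2), numeric(0), 0.124,
                               c(5L, 5L)),
              skeleton_from_intensities(rep(9, 4)))
  tab <- feature_table(sks, cell_id = c("a", "b", "c"),
                       condition = c("WT", "WT", "mut"))
  expect_identical(nrow(tab), 3L)
  expect_identical(tab$flags,
                   c("", "undefined_intensity_features",
                     "undefined_intensity_features"))
  expect_identical(tab$total_length_mm[2], 0)
  expect_true(is.na(tab$cv[2]))
  # constant-intensity cell: mean and CV defined, skewness not
  expect_identical(tab$mean_intensity[3], 9)
  expect_true(is.na(tab$skewness[3]))

  expect_error(feature_table(sks, cell_id = c("a", "b")),
               class = "cwrq_format_error")
})

test_that("the feature table is reproducible from serialised skeletons", {
  d <- withr::local_tempdir()
  sc <- generate_fiber_scene(small_scene_config(seed = 19))
  sk <- extract_lines(render_scene(sc), sc$mask)
  tab1 <- feature_table(list(sk))
  f <- file.path(d, "sk.json")
  write_skeleton(sk, f)
  tab2 <- feature_table(list(read_skeleton(f)))
  expect_identical(tab1, tab2)
})
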