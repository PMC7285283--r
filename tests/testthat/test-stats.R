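test_that("osmotic stability is the N30/N0 ratio with guarded edge cases", {
  expect_identical(osmotic_stability(stability_record(200, 100)), 0.5)
  expect_identical(osmotic_stability(stability_record(150, 150)), 1)
  expect_error(stability_record(0, 10), class = "cwrq_config_error")
  expect_warning(r <- osmotic_stability(stability_record(100, 105)),
                 "stability > 1")
  expect_identical(r, 1.05)
})

test_that("Mann-Whitney matches hand enumeration and symmetry conventions", {
  mw0 <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_identical(mw0$statistic, 0)
  expect_equal(mw0$p_value, 0.1)
  expect_true(mw0$exact)

  same <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 4.5)
  expect_equal(same$p_value, 1)

  expect_error(mann_whitney(numeric(0), 1:3), class = "cwrq_stat_error")
})

test_that("Mann-Whitney agrees with wilcox.test in both exact and approximate regimes", {
  set.seed(7)
  for (i in 1:20) {
    a <- round(rnorm(sample(3:6, 1)), 6)
    b <- round(rnorm(sample(3:6, 1)), 6)   # continuous: no ties, exact path
    mw <- mann_whitney(a, b)
    wt <- suppressWarnings(wilcox.test(a, b, exact = TRUE))
    expect_equal(mw$statistic, unname(wt$statistic))
    expect_equal(mw$p_value, wt$p.value, tolerance = 1e-10)
  }
  for (i in 1:20) {
    a <- sample(1:8, 25, replace = TRUE)   # heavy ties: normal approximation
    b <- sample(2:9, 30, replace = TRUE)
    mw <- mann_whitney(a, b)
    wt <- suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = TRUE))
    expect_equal(mw$statistic, unname(wt$statistic))
    expect_equal(mw$p_value, wt$p.value, tolerance = 1e-10)
  }
})

test_that("Mann-Whitney is invariant under strictly monotone transforms", {
  set.seed(11)
  a <- rlnorm(18); b <- rlnorm(22) * 1.4
  p0 <- mann_whitney(a, b)$p_value
  expect_identical(mann_whitney(log(a), log(b))$p_value, p0)
  expect_identical(mann_whitney(a^3, b^3)$p_value, p0)
})

test_that("Student's t matches the hand-worked example and errors on zero variance", {
  tt <- students_t(c(1, 2, 3), c(2, 3, 4))
  expect_equal(tt$statistic, -1.224745, tolerance = 1e-6)
  expect_identical(tt$df, 4)
  expect_equal(tt$p_value, 2 * pt(-sqrt(1.5), 4), tolerance = 1e-10)

  eq <- students_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p_value, 1)

  expect_error(students_t(c(2, 2, 2), c(2, 2, 2)), class = "cwrq_stat_error")
  expect_error(students_t(1, c(1, 2)), class = "cwrq_stat_error")
})

test_that("Tukey-Kramer reduces to the pooled t-test for two groups", {
  set.seed(13)
  g1 <- rnorm(12, 0); g2 <- rnorm(17, 0.8)
  tk <- tukey_kramer(list(a = g1, b = g2))
  tt <- t.test(g1, g2, var.equal = TRUE)
  expect_equal(tk$comparisons$p_value, tt$p.value, tolerance = 1e-6)
  expect_equal(tk$comparisons$q, abs(unname(tt$statistic)) * sqrt(2),
               tolerance = 1e-10)
})

test_that("Tukey-Kramer agrees with the aov/TukeyHSD oracle for unequal groups", {
  set.seed(17)
  groups <- list(a = rnorm(8, 0), b = rnorm(14, 0.5), c = rnorm(11, 1.5))
  tk <- tukey_kramer(groups)
  y <- unlist(groups)
  g <- factor(rep(names(groups), lengths(groups)))
  hsd <- TukeyHSD(aov(y ~ g))$g
  expect_equal(tk$comparisons$p_value[1], hsd["b-a", "p adj"], tolerance = 1e-6)
  expect_equal(tk$comparisons$p_value[2], hsd["c-a", "p adj"], tolerance = 1e-6)
  expect_equal(tk$comparisons$p_value[3], hsd["c-b", "p adj"], tolerance = 1e-6)
})

test_that("Tukey-Kramer letters separate clearly shifted groups", {
  set.seed(19)
  base <- rnorm(20)
  groups <- list(g1 = base, g2 = rnorm(20, 0.1),
                 g3 = rnorm(20) + 10 * sd(base))
  tk <- tukey_kramer(groups, alpha = 0.01)
  expect_identical(tk$letters[["g1"]], tk$letters[["g2"]])
  expect_false(grepl(tk$letters[["g3"]], tk$letters[["g1"]], fixed = TRUE))

  ident <- tukey_kramer(list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3)))
  expect_true(all(ident$comparisons$p_value >= 0.999))
  expect_identical(unname(unique(ident$letters)), "a")

  expect_error(tukey_kramer(list(a = 1:3)), class = "cwrq_stat_error")
})

test_that("Pearson correlation matches its moment oracle and handles edge cases", {
  x <- 1:10
  expect_equal(pearson_correlation(x, 2 * x + 1), 1)
  expect_equal(pearson_correlation(x, -x), -1)
  set.seed(23)
  u <- rnorm(40); v <- rnorm(40)
  oracle <- sum((u - mean(u)) * (v - mean(v))) /
    sqrt(sum((u - mean(u))^2) * sum((v - mean(v))^2))
  expect_equal(pearson_correlation(u, v), oracle, tolerance = 1e-12)
  expect_error(pearson_correlation(c(1, 1, 1), 1:3), class = "cwrq_stat_error")
  expect_error(pearson_correlation(1:2, 1:2), class = "cwrq_stat_error")
})

test_that("significance stars follow the figure-caption convention", {
  expect_identical(significance_stars(0.005), "**")
  expect_identical(significance_stars(0.03), "*")
  expect_identical(significance_stars(0.2), "")
  expect_identical(significance_stars(0.01), "*")
})
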