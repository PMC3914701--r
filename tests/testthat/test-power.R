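test_that("the power factor matches normal-quantile arithmetic", {
  # unadjusted, p = 0.5: u_{2(1-p)} = 0, so f = qnorm(0.975)^2
  expect_equal(power_constant(0.05, 0.5, 1), qnorm(0.975)^2, tolerance = 1e-10)
  # f is strictly increasing in the target power
  f <- vapply(c(0.5, 0.6, 0.7, 0.8, 0.9, 0.95), function(p)
    power_constant(0.05, p, 100), numeric(1))
  expect_true(all(diff(f) > 0))
  # and increasing in the number of Bonferroni tests
  expect_gt(power_constant(0.05, 0.9, 16386), power_constant(0.05, 0.9, 1))
  expect_error(power_constant(0, 0.9, 1), "alpha")
  expect_error(power_constant(0.05, 1, 1), "p")
  expect_error(power_constant(0.05, 0.3, 1), "p")
  expect_error(power_constant(0.05, 0.9, 0), "n_points")
})

test_that("sample-size maps scale with delta^-2 and flag zero variance", {
  d <- matrix(c(-1, 0, 1), 3, 6)  # every column has variance exactly 1
  m1 <- sample_size_map(d, delta_mm = 1, alpha = 0.05, p = 0.9)
  m2 <- sample_size_map(d, delta_mm = 2, alpha = 0.05, p = 0.9)
  expect_equal(m2$n_raw, m1$n_raw / 4)

  z <- matrix(0, 3, 4)
  mz <- sample_size_map(z)
  expect_true(all(mz$n_raw == 0))
  expect_true(all(mz$zero_variance))
  expect_error(sample_size_map(matrix(1, 1, 3)), "two subjects")
  expect_error(sample_size_map(d, delta_mm = 0), "delta")
})

test_that("sample-size maps commute with point relabeling", {
  withr::with_seed(21, {
    d <- matrix(rnorm(8 * 30), 8, 30)
  })
  perm <- sample(30)
  m <- sample_size_map(d)
  mp <- sample_size_map(d[, perm])
  expect_equal(mp$n_raw, m$n_raw[perm])
  red <- percent_reduction(sample_size_map(d * 2), m)
  redp <- percent_reduction(sample_size_map(d[, perm] * 2), mp)
  expect_equal(redp, red[perm])
})

test_that("percentage reduction follows its defining arithmetic", {
  mk <- function(n_raw) {
    d <- matrix(c(-1, 0, 1), 3) %*% sqrt(n_raw / (2 * power_constant(0.05, 0.9, length(n_raw))))
    sample_size_map(d)
  }
  m2d <- mk(c(100, 50, 80))
  m3d <- mk(c(56, 50, 100))
  red <- percent_reduction(m2d, m3d)
  expect_equal(red, c(44, 0, -25))

  withr::with_seed(5, {
    a <- matrix(rnorm(6 * 20), 6, 20); b <- matrix(rnorm(6 * 20), 6, 20)
  })
  ma <- sample_size_map(a); mb <- sample_size_map(b)
  expect_equal(percent_reduction(ma, mb),
               100 * (ma$n_raw - mb$n_raw) / ma$n_raw)

  z <- sample_size_map(matrix(0, 3, 20))
  expect_true(all(is.na(percent_reduction(z, mb))))
  expect_error(percent_reduction(ma, sample_size_map(a[, 1:5])), "different")
})

test_that("normality screen: Gaussian nulls pass, heavy tails fail", {
  withr::with_seed(14, {
    g <- matrix(rnorm(20 * 200), 20, 200)
  })
  scr <- normality_screen(g)
  # Bonferroni-adjusted level 0.05/200: essentially no false failures
  expect_lte(sum(scr$fail), 1L)
  expect_equal(attr(scr, "threshold"), 0.05 / 200)

  withr::with_seed(15, {
    cau <- cbind(rcauchy(200), matrix(rnorm(200 * 3), 200, 3))
  })
  scr2 <- normality_screen(cau)
  expect_true(scr2$fail[1])

  const <- cbind(rep(1, 10), rnorm(10))
  scr3 <- normality_screen(const)
  expect_true(is.na(scr3$p_value[1]))
  # P = 1: unadjusted threshold
  expect_equal(attr(normality_screen(matrix(rnorm(10), 10, 1)), "threshold"),
               0.05)
})

test_that("Wilcoxon map matches exhaustive sign-pattern enumeration at N = 6", {
  d <- c(1.3, -0.7, 2.1, 0.4, -1.8, 0.9)
  a <- matrix(0, 6, 1); b <- matrix(-d, 6, 1)
  res <- wilcoxon_significance_map(a, b)
  expect_equal(res$p_value[1], wilcoxon_exact_enum(d), tolerance = 1e-10)

  d2 <- c(0.5, 0.8, 1.1, 1.7, 2.3, 2.9)  # all positive
  res2 <- wilcoxon_significance_map(matrix(d2, 6, 1), matrix(0, 6, 1))
  expect_equal(res2$p_value[1], wilcoxon_exact_enum(d2), tolerance = 1e-10)
})

test_that("Wilcoxon map masks degenerate points and reports the -ln threshold", {
  x <- matrix(rep(c(5, 6, 7, 8, 9), 3), 5, 3)
  res <- wilcoxon_significance_map(x, x)
  expect_true(all(is.na(res$p_value)))
  expect_true(all(is.na(res$minus_ln_p)))
  expect_error(wilcoxon_significance_map(x[1:4, ], x[1:4, ]), "5 paired")
  expect_error(wilcoxon_significance_map(x, x[, 1:2]), "equal shape")
})

test_that("empirical power behaves like an operating characteristic", {
  # enormous sample: power ~ 1 even at a Bonferroni-tight level
  expect_gt(empirical_power(400, n_replicates = 400, seed = 2), 0.999)
  # tiny sample at a tight level: almost never rejects
  expect_lt(empirical_power(3, n_replicates = 400, seed = 2), 0.05)
  # t-test variant runs and is close to z at large N
  expect_equal(empirical_power(400, n_replicates = 400, seed = 2, test = "t"),
               1, tolerance = 0.01)
})

test_that("difference fields validate shape and carry the modality tag", {
  x <- matrix(rnorm(12), 3, 4); y <- matrix(rnorm(12), 3, 4)
  df <- difference_field(x, y, modality = "2D")
  expect_equal(df$d, x - y)
  expect_equal(df$modality, "2D")
  expect_error(difference_field(matrix(c(1, NA, 3, 4), 2)), "finite")
})
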