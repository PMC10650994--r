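# The 20 CGSD parameters and the two normality tests.

test_that("hand-countable statistics on a tiny multiset", {
  img <- canopy_from_values(c(10L, 10L, 20L))
  row <- compute_cgsd(img)
  expect_equal(row$R_Mean, 40 / 3)
  expect_equal(row$R_Median, 10)
  expect_equal(row$R_Mode, 10)
})

test_that("two-point symmetric distributions have skewness 0 and kurtosis 1", {
  img <- canopy_from_values(rep(c(50L, 150L), each = 30))
  row <- compute_cgsd(img)
  expect_equal(row$R_Skewness, 0)
  expect_equal(row$R_Kurtosis, 1)
})

test_that("histogram-weighted statistics equal the per-pixel oracle", {
  # right-skewed synthetic draws, large n: moments to 1e-12 relative
  set.seed(31)
  vals <- as.integer(pmin(255, round(stats::rgamma(10000, shape = 2, scale = 20))))
  img <- canopy_from_values(vals)
  row <- compute_cgsd(img)
  o <- oracle_moments(vals)
  expect_equal(row$R_Mean, o$mean, tolerance = 1e-12)
  expect_equal(row$R_Median, o$median)
  expect_equal(row$R_Mode, o$mode)
  expect_equal(row$R_Skewness, o$skewness, tolerance = 1e-12)
  expect_equal(row$R_Kurtosis, o$kurtosis, tolerance = 1e-12)
  expect_gt(row$R_Skewness, 0)
})

test_that("gradation fast path equals expansion on arbitrary histograms", {
  # constant channel: mean/median/mode defined, moments flagged NA
  img <- canopy_from_values(rep(7L, 40))
  s <- cgsd_from_gradation(gradation_array(img, "R"))
  expect_equal(unname(s[c("Mean", "Median", "Mode")]), c(7, 7, 7))
  expect_true(is.na(s[["Skewness"]]) && is.na(s[["Kurtosis"]]))

  # symmetric two-level histogram
  s2 <- cgsd_from_gradation(gradation_array(
    canopy_from_values(rep(c(10L, 20L), 50)), "R"))
  expect_equal(s2[["Skewness"]], 0)

  set.seed(32)
  for (i in 1:20) {
    vals <- sample(0:255, sample(50:500, 1), replace = TRUE,
                   prob = stats::rbeta(256, 0.4, 2))
    s3 <- cgsd_from_gradation(gradation_array(canopy_from_values(vals), "R"))
    o <- oracle_moments(vals)
    expect_equal(s3[["Mean"]], o$mean, tolerance = 1e-13)
    expect_equal(s3[["Median"]], o$median)
    expect_equal(s3[["Mode"]], o$mode)
    expect_equal(s3[["Skewness"]], o$skewness, tolerance = 1e-12)
    expect_equal(s3[["Kurtosis"]], o$kurtosis, tolerance = 1e-12)
  }
})

test_that("mode ties break toward the smallest level; even-n medians are half-integer", {
  s <- cgsd_from_gradation(gradation_array(
    canopy_from_values(c(30L, 30L, 12L, 12L, 200L)), "R"))
  expect_equal(s[["Mode"]], 12)
  s2 <- cgsd_from_gradation(gradation_array(
    canopy_from_values(c(10L, 11L, 20L, 30L)), "R"))
  expect_equal(s2[["Median"]], 15.5)
})

test_that("location shift moves Mean/Median/Mode and fixes Skewness/Kurtosis", {
  set.seed(33)
  vals <- sample(0:200, 300, replace = TRUE,
                 prob = stats::rbeta(201, 0.5, 3))
  delta <- 40L
  s0 <- cgsd_from_gradation(gradation_array(canopy_from_values(vals), "R"))
  s1 <- cgsd_from_gradation(gradation_array(canopy_from_values(vals + delta), "R"))
  expect_equal(s1[["Mean"]], s0[["Mean"]] + delta, tolerance = 1e-12)
  expect_equal(s1[["Median"]], s0[["Median"]] + delta)
  expect_equal(s1[["Mode"]], s0[["Mode"]] + delta)
  expect_equal(s1[["Skewness"]], s0[["Skewness"]], tolerance = 1e-12)
  expect_equal(s1[["Kurtosis"]], s0[["Kurtosis"]], tolerance = 1e-12)
})

test_that("mirroring intensities negates skewness and preserves kurtosis", {
  set.seed(34)
  for (i in 1:10) {
    vals <- sample(0:255, 200, replace = TRUE,
                   prob = stats::rbeta(256, 0.4, 2.5))
    s0 <- cgsd_from_gradation(gradation_array(canopy_from_values(vals), "R"))
    s1 <- cgsd_from_gradation(gradation_array(
      canopy_from_values(255L - vals), "R"))
    expect_equal(s1[["Skewness"]], -s0[["Skewness"]], tolerance = 1e-12)
    expect_equal(s1[["Kurtosis"]], s0[["Kurtosis"]], tolerance = 1e-12)
    # moment inequality on every non-constant fixture
    expect_gte(s0[["Kurtosis"]], s0[["Skewness"]]^2 + 1)
  }
})

test_that("compute_cgsd needs at least 2 foreground pixels", {
  expect_error(compute_cgsd(canopy_from_values(5L)), "2 foreground")
})

test_that("Jarque-Bera equals its moment formula, with exact zero at S=0, K=3", {
  # exactly symmetric mesokurtic sample: +-1 (x2 each) plus 8 zeros gives
  # population skewness 0 and kurtosis N/(2*n1) = 12/4 = 3 exactly
  x <- c(1, 1, -1, -1, rep(0, 8))
  jb <- jarque_bera_test(x)
  expect_equal(jb$statistic, 0, tolerance = 1e-14)
  expect_equal(jb$p_value, 1)
  expect_false(jb$reject)

  set.seed(35)
  for (i in 1:10) {
    v <- stats::rlnorm(500)
    r <- jarque_bera_test(v)
    o <- oracle_moments(v)
    expect_equal(r$statistic,
                 500 / 6 * (o$skewness^2 + (o$kurtosis - 3)^2 / 4),
                 tolerance = 1e-10)
    expect_equal(r$p_value,
                 stats::pchisq(r$statistic, 2, lower.tail = FALSE))
  }
  # strongly skewed large sample -> reject
  expect_true(jarque_bera_test(stats::rlnorm(5000))$reject)
  expect_error(jarque_bera_test(1:5), "n >= 8")
})

test_that("Lilliefors D matches the reference implementation; MC p-values calibrate", {
  skip_if_not_installed("nortest")
  set.seed(36)
  for (i in 1:5) {
    x <- stats::rnorm(200)
    mine <- lilliefors_test(x, n_null = 200, seed = i)
    ref <- nortest::lillie.test(x)
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
  }
  # a strongly right-skewed large sample is rejected
  set.seed(37)
  expect_true(lilliefors_test(stats::rlnorm(5000), n_null = 500, seed = 1)$reject)
  expect_error(lilliefors_test(c(1, 2, 3)), "n >= 4")

  # reduced-size calibration: null rejection rate near alpha (full-size
  # calibration runs in the acceptance suite)
  set.seed(38)
  rejections <- vapply(1:60, function(i) {
    lilliefors_test(stats::rnorm(100), n_null = 400, seed = 1000 + i)$reject
  }, logical(1))
  ci <- stats::qbinom(c(0.005, 0.995), 60, 0.05)
  expect_gte(sum(rejections), ci[1])
  expect_lte(sum(rejections), ci[2])
})

test_that("all four channels of a skewed synthetic canopy image reject normality", {
  sc <- synthetic_scenario(301, days = 1, hours = 12)
  st <- generate_study(sc)
  res <- test_image_normality(st$images[[1]], n_null = 500, seed = 2)
  expect_true(all(res$reject))
})
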