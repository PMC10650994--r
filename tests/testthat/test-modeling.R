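# Correlation screening, partial-F stepwise selection, fit statistics and
# model evaluation.

fake_cgsd <- function(n, fill = NULL) {
  out <- data.frame(sample_id = seq_len(n))
  for (pm in cgsd_parameter_names()) {
    out[[pm]] <- if (is.null(fill)) stats::rnorm(n) else fill(pm, n)
  }
  out
}

fake_meteo <- function(n) {
  data.frame(T_h = stats::rnorm(n, 25, 4), RH_h = stats::runif(n, 40, 95),
             AP_h = stats::rnorm(n, 1005, 2), TD_h = stats::rnorm(n, 18, 3),
             VP_h = stats::rnorm(n, 22, 3))
}

test_that("correlation screen recovers exact linearity and matches the formula oracle", {
  set.seed(41)
  mt <- fake_meteo(10)
  cg <- fake_cgsd(10)
  cg$R_Mean <- 2 * mt$VP_h  # exact linearity
  cm <- correlation_screen(cg, mt)
  expect_equal(dim(cm$r), c(20L, 5L))
  expect_equal(cm$r["R_Mean", "VP_h"], 1, tolerance = 1e-12)
  expect_lt(cm$p["R_Mean", "VP_h"], 1e-9)

  # direct covariance/SD oracle on an arbitrary cell
  x <- cg$G_Skewness; y <- mt$RH_h
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(cm$r["G_Skewness", "RH_h"], r_oracle, tolerance = 1e-12)
  tt <- r_oracle * sqrt(8 / (1 - r_oracle^2))
  expect_equal(cm$p["G_Skewness", "RH_h"], 2 * stats::pt(-abs(tt), 8),
               tolerance = 1e-12)

  # constant column -> flagged NA, not an error
  cg$B_Mode <- 5
  cm2 <- correlation_screen(cg, mt)
  expect_true(is.na(cm2$r["B_Mode", "T_h"]))
  expect_true(cm2$flagged["B_Mode", "T_h"])

  # undefined-moment samples dropped pairwise with reduced n
  cg$Y_Skewness[c(2, 5)] <- NA
  cm3 <- correlation_screen(cg, mt)
  expect_equal(cm3$n["Y_Skewness", "T_h"], 8L)
})

test_that("null correlations give uniform p-values", {
  set.seed(42)
  pvals <- replicate(200, {
    x <- stats::rnorm(50); y <- stats::rnorm(50)
    r <- stats::cor(x, y)
    tt <- r * sqrt(48 / (1 - r^2))
    2 * stats::pt(-abs(tt), 48)
  })
  ks <- stats::ks.test(pvals, "punif")
  expect_gt(ks$p.value, 0.001)
})

test_that("stepwise recovers a planted single signal and its coefficients", {
  # the true predictor must always be selected with its coefficients
  # recovered; spurious extra terms are admitted at about the entry level
  # per null candidate (a property of F-to-enter selection, not a defect),
  # so exact-set selection is checked as a majority, not a certainty
  set.seed(43)
  hits <- 0L; exact <- 0L
  for (i in 1:50) {
    X <- as.data.frame(matrix(stats::rnorm(100 * 5), 100, 5))
    names(X) <- paste0("x", 1:5)
    y <- 3 + 2 * X$x1 + stats::rnorm(100, 0, 1e-4)
    m <- stepwise_fit(y, X)
    if ("x1" %in% names(m$terms) &&
        abs(m$intercept - 3) < 1e-2 && abs(m$terms[["x1"]] - 2) < 1e-2) {
      hits <- hits + 1L
    }
    if (identical(names(m$terms), "x1")) exact <- exact + 1L
    # any spurious term is fitting pure sigma = 1e-4 noise
    for (nm in setdiff(names(m$terms), "x1")) {
      expect_lt(abs(m$terms[[nm]]), 1e-3)
    }
  }
  expect_gte(hits, 48L)
  expect_gte(exact, 30L)
})

test_that("single-predictor stepwise equals the closed-form OLS slope", {
  set.seed(44)
  x <- stats::rnorm(60)
  y <- 1.5 + 0.8 * x + stats::rnorm(60, 0, 0.1)
  m <- stepwise_fit(y, data.frame(x = x))
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(unname(m$terms[["x"]]), slope, tolerance = 1e-10)
  expect_equal(m$intercept, mean(y) - slope * mean(x), tolerance = 1e-10)
})

test_that("pure-noise responses are mostly unable to model", {
  # candidates are the five (mutually correlated) weather factors; the
  # response is fresh noise each repetition
  mt <- as.data.frame(generate_weather(synthetic_scenario(4401, days = 20)))
  X <- mt[, c("T_h", "RH_h", "AP_h", "VP_h", "TD_h")]
  set.seed(45)
  unable <- vapply(1:60, function(i) {
    m <- stepwise_fit(stats::rnorm(nrow(X)), X)
    m$status == "unable_to_model"
  }, logical(1))
  expect_gte(mean(unable), 0.75)
})

test_that("stepwise agrees with the exhaustive stable-subset oracle on planted data", {
  set.seed(46)
  agree <- 0L
  for (i in 1:40) {
    X <- as.data.frame(matrix(stats::rnorm(80 * 4), 80, 4))
    names(X) <- paste0("x", 1:4)
    y <- 1 + 1.5 * X$x2 + stats::rnorm(80, 0, 0.05)
    m <- stepwise_fit(y, X)
    o <- oracle_best_subset(y, X)
    if (identical(sort(names(m$terms)), o)) agree <- agree + 1L
  }
  expect_gte(agree, 38L)
})

test_that("OLS residuals are orthogonal to every selected predictor", {
  set.seed(47)
  X <- as.data.frame(matrix(stats::rnorm(100 * 3), 100, 3))
  names(X) <- c("a", "b", "c")
  y <- 2 + X$a - 0.5 * X$b + stats::rnorm(100, 0, 0.2)
  m <- stepwise_fit(y, X)
  resid <- y - evaluate_model(m, X)
  for (nm in names(m$terms)) {
    expect_lt(abs(sum(resid * X[[nm]])),
              1e-8 * length(y) * stats::sd(X[[nm]]))
  }
  expect_lt(abs(sum(resid)), 1e-8 * length(y))
})

test_that("rank-deficient selected designs raise a degenerate-design error", {
  set.seed(48)
  x <- stats::rnorm(30)
  X <- data.frame(x1 = x, x2 = 2 * x)  # perfectly collinear
  y <- 1 + x
  expect_error(stepwise_fit(y, X, forced_entry = TRUE), "collinear")
})

test_that("fit statistics match hand-computed values and the perfect-fit limit", {
  # noiseless planted line: R2 = 1, RMSE = 0
  x <- seq(0, 10, length.out = 20)
  m <- stepwise_fit(3 + 2 * x, data.frame(x = x))
  expect_equal(m$r2, 1, tolerance = 1e-12)
  expect_equal(m$rmse, 0, tolerance = 1e-6)

  # fixture with known SSE/SST
  set.seed(49)
  x2 <- stats::rnorm(40)
  y2 <- 1 + x2 + stats::rnorm(40, 0, 0.5)
  m2 <- stepwise_fit(y2, data.frame(x = x2), response = "y")
  pred <- m2$intercept + m2$terms[["x"]] * x2
  sse <- sum((y2 - pred)^2)
  sst <- sum((y2 - mean(y2))^2)
  expect_equal(m2$r2, 1 - sse / sst, tolerance = 1e-12)
  expect_equal(m2$adj_r2, 1 - (1 - m2$r2) * 39 / 38, tolerance = 1e-12)
  expect_equal(m2$rmse, sqrt(sse / 38), tolerance = 1e-12)
  expect_equal(m2$f, ((sst - sse) / 1) / (sse / 38), tolerance = 1e-10)
  expect_equal(m2$sig_f, stats::pf(m2$f, 1, 38, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("a pure-noise predictor cannot decrease R2 but lowers adjusted R2 on average", {
  set.seed(50)
  dr2 <- dadj <- numeric(100)
  for (i in 1:100) {
    x <- stats::rnorm(40)
    z <- stats::rnorm(40)
    y <- 1 + x + stats::rnorm(40, 0, 1)
    m1 <- stepwise_fit(y, data.frame(x = x), forced_entry = TRUE)
    m2 <- stepwise_fit(y, data.frame(x = x, z = z), forced_entry = TRUE)
    dr2[i] <- m2$r2 - m1$r2
    dadj[i] <- m2$adj_r2 - m1$adj_r2
  }
  expect_true(all(dr2 >= -1e-12))
  expect_lt(mean(dadj), 0)
})

test_that("published pepper equations evaluate to independent arithmetic", {
  resp <- pepper_response_models()
  # at VP_h = 0 the R_Mean response returns its printed intercept
  expect_equal(evaluate_model(resp$R_Mean, c(VP_h = 0)), 29.094,
               tolerance = 1e-9)
  expect_equal(evaluate_model(resp$G_Median, c(RH_h = 50, TD_h = 10)),
               46.048 + 0.214 * 50 + 0.705 * 10, tolerance = 1e-9)
  expect_error(evaluate_model(resp$G_Median, c(RH_h = 50)), "TD_h")
  expect_error(evaluate_model(resp$B_Mean, c(VP_h = 1)), "unable")

  inv <- pepper_inversion_models()
  expect_equal(evaluate_model(inv$T_h, c(B_Mode = 100, G_Median = 60)),
               42.866 + 0.174 * 100 - 0.232 * 60, tolerance = 1e-9)
  # all-zero inputs return the intercept
  expect_equal(evaluate_model(inv$AP_h, c(B_Mode = 0)), 1003.672,
               tolerance = 1e-12)
})

test_that("response/inversion batch fits propagate status and log dropped rows", {
  set.seed(51)
  mt <- fake_meteo(40)
  cg <- fake_cgsd(40)
  cg$G_Mean <- 60 + 0.3 * mt$RH_h + stats::rnorm(40, 0, 0.1)
  cg$B_Mean <- 40 + stats::rnorm(40, 0, 0.2)        # no factor signal
  cg$Y_Skewness[c(3, 7)] <- NA                      # undefined moments
  models <- fit_all_response_models(cg, mt)
  expect_length(models, 20L)
  expect_equal(models$G_Mean$status, "fitted")
  expect_true("RH_h" %in% names(models$G_Mean$terms))
  expect_equal(attr(models$Y_Skewness, "n_dropped"), 2L)
  expect_equal(models$Y_Skewness$n, 38L)

  mt$RH_h <- 60 + 0.4 * cg$G_Median + stats::rnorm(40, 0, 0.5)
  invm <- fit_all_inversion_models(mt, cg)
  expect_length(invm, 5L)
  expect_equal(invm$RH_h$status, "fitted")
  expect_true("G_Median" %in% names(invm$RH_h$terms))

  # direction consistency: fitted slope sign equals the correlation sign
  cm <- correlation_screen(cg, mt)
  expect_equal(sign(models$G_Mean$terms[["RH_h"]]),
               sign(cm$r["G_Mean", "RH_h"]))
})

test_that("models serialize to the documented JSON shape", {
  m <- linear_model("G_Mean", 63.842, c(RH_h = 0.183), n = 35L,
                    r2 = 0.272, adj_r2 = 0.250, rmse = 3.007,
                    f = 12.310, sig_f = 0.001)
  js <- jsonlite::fromJSON(models_to_json(list(G_Mean = m)),
                           simplifyVector = FALSE)[[1]]
  expect_equal(js$response, "G_Mean")
  expect_equal(js$status, "fitted")
  expect_equal(js$intercept, 63.842)
  expect_equal(js$terms[[1]]$name, "RH_h")
  expect_equal(js$terms[[1]]$coef, 0.183)
  expect_equal(js$r2, 0.272)

  un <- jsonlite::fromJSON(models_to_json(
    fit_all_response_models(fake_cgsd(20), fake_meteo(20))["B_Mean"]),
    simplifyVector = FALSE)[[1]]
  expect_true(un$status %in% c("fitted", "unable_to_model"))
  if (un$status == "unable_to_model") expect_length(un$terms, 0L)
})
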