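# The 20 CGSD (color gradation skewness-distribution) parameters: mean,
# median, mode, skewness and kurtosis of the foreground pixel-intensity
# distribution for each of R, G, B and the gray-level (Y) channel, plus the
# two normality tests applied to gradation data.

CGSD_STATS <- c("Mean", "Median", "Mode", "Skewness", "Kurtosis")

#' Names of the 20 CGSD parameters
#'
#' `R_Mean, R_Median, R_Mode, R_Skewness, R_Kurtosis, G_Mean, ...,
#' Y_Kurtosis` in channel-major order (R, G, B, Y). This fixed order is
#' also the candidate order used by the inversion models.
#'
#' @return character vector of length 20.
#' @export
cgsd_parameter_names <- function() {
  as.vector(t(outer(CHANNELS, CGSD_STATS, paste, sep = "_")))
}

# Five distribution statistics of an integer intensity multiset, from its
# 256-bin histogram (frequency-weighted formulas). Skewness and kurtosis use
# population central moments m_k = mean((x - xbar)^k); kurtosis is
# non-excess (normal -> 3). A constant channel has undefined
# skewness/kurtosis, returned as NA.
stats_from_counts <- function(counts) {
  n <- sum(counts)
  stopifnot(n >= 1)
  levels <- 0:255
  mu <- sum(levels * counts) / n
  # weighted order-statistic median of the multiset
  cum <- cumsum(counts)
  if (n %% 2L == 1L) {
    med <- levels[which(cum >= (n + 1L) / 2L)[1L]]
  } else {
    lo <- levels[which(cum >= n / 2L)[1L]]
    hi <- levels[which(cum >= n / 2L + 1L)[1L]]
    med <- (lo + hi) / 2
  }
  mode <- levels[which.max(counts)]  # first max: ties break to smallest level
  d <- levels - mu
  m2 <- sum(counts * d^2) / n
  if (m2 == 0) {
    skew <- NA_real_
    kurt <- NA_real_
  } else {
    m3 <- sum(counts * d^3) / n
    m4 <- sum(counts * d^4) / n
    skew <- m3 / m2^1.5
    kurt <- m4 / m2^2
  }
  c(Mean = mu, Median = med, Mode = mode, Skewness = skew, Kurtosis = kurt)
}

#' CGSD statistics of one gradation array
#'
#' Frequency-weighted fast path: identical to computing the statistics over
#' the expanded pixel multiset. Mean, median (average of the two central
#' order statistics when n is even), mode (most frequent level, ties broken
#' toward the smallest level), population skewness `m3/m2^1.5` and
#' non-excess population kurtosis `m4/m2^2`. A constant channel has
#' `NA` skewness/kurtosis.
#'
#' @param g a [gradation_array()].
#' @return named numeric vector `Mean, Median, Mode, Skewness, Kurtosis`.
#' @export
cgsd_from_gradation <- function(g) {
  stopifnot(inherits(g, "gradation_array"))
  stats_from_counts(g$counts)
}

#' Compute the 20 CGSD parameters of a canopy image
#'
#' For each channel (R, G, B and gray-level Y) the mean, median, mode,
#' skewness and kurtosis of the foreground pixel intensities. Statistics
#' are computed on foreground pixels only.
#'
#' @param image a [canopy_image()].
#' @param sample_id optional sample identifier stored in the output row.
#' @param timestamp optional POSIXct/character acquisition time.
#' @return One-row data.frame with columns `sample_id`, `timestamp` and the
#'   20 parameters named `R_Mean` .. `Y_Kurtosis`.
#' @export
compute_cgsd <- function(image, sample_id = NA_character_, timestamp = NA) {
  stopifnot(inherits(image, "canopy_image"))
  if (n_foreground(image) < 2L) {
    stop("need at least 2 foreground pixels for distribution statistics",
         call. = FALSE)
  }
  out <- list(sample_id = sample_id,
              timestamp = if (all(is.na(timestamp))) as.POSIXct(NA)
                          else parse_iso8601(timestamp))
  for (ch in CHANNELS) {
    s <- cgsd_from_gradation(gradation_array(image, ch))
    names(s) <- paste(ch, CGSD_STATS, sep = "_")
    out <- c(out, as.list(s))
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' CGSD table for a set of canopy images
#'
#' @param images list of [canopy_image()] objects.
#' @param sample_ids optional character vector of identifiers.
#' @param timestamps optional acquisition times.
#' @return data.frame with one row per image (see [compute_cgsd()]).
#' @export
cgsd_table <- function(images, sample_ids = NULL, timestamps = NULL) {
  if (is.null(sample_ids)) sample_ids <- sprintf("img_%03d", seq_along(images))
  if (is.null(timestamps)) timestamps <- rep(NA, length(images))
  rows <- mapply(function(im, id, ts) compute_cgsd(im, id, ts),
                 images, sample_ids, timestamps, SIMPLIFY = FALSE)
  do.call(rbind, rows)
}

#' Write a CGSD table to CSV
#' @param x CGSD data.frame from [cgsd_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cgsd_csv <- function(x, path) {
  out <- x
  if ("timestamp" %in% names(out) && inherits(out$timestamp, "POSIXct")) {
    out$timestamp <- format_iso8601(out$timestamp)
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# --- normality tests --------------------------------------------------------

new_normality_result <- function(test, statistic, p_value, alpha) {
  structure(list(test = test, statistic = statistic, p_value = p_value,
                 alpha = alpha, reject = p_value < alpha),
            class = "normality_result")
}

#' @export
print.normality_result <- function(x, ...) {
  cat(sprintf("%s test: statistic = %.6g, p = %.4g, %s normality at alpha = %g\n",
              x$test, x$statistic, x$p_value,
              if (x$reject) "REJECT" else "do not reject", x$alpha))
  invisible(x)
}

# Lilliefors D: sup-distance between the empirical CDF and the normal CDF
# with estimated mean and (unbiased) SD.
lilliefors_statistic <- function(x) {
  n <- length(x)
  z <- pnorm(sort(x), mean = mean(x), sd = stats::sd(x))
  i <- seq_len(n)
  max(i / n - z, z - (i - 1) / n)
}

#' Lilliefors test of normality with a Monte-Carlo null
#'
#' Kolmogorov-Smirnov distance against a normal with mean and SD estimated
#' from the data. Because the parameters are estimated, the classical KS
#' null does not apply; the p-value is obtained by simulating `n_null`
#' standard-normal samples of the same size (the D statistic is
#' location-scale invariant) and counting null statistics at least as
#' large: `p = (1 + #{D* >= D}) / (n_null + 1)`. This is honest at any n,
#' including the very large pixel counts of image data where table-based
#' p-values are off-table.
#'
#' @param values numeric sample (n >= 4).
#' @param alpha significance level (default 0.05).
#' @param n_null number of Monte-Carlo null replicates (default 10000).
#' @param seed optional integer seed for the null simulation.
#' @return A `normality_result` (test, statistic, p_value, reject).
#' @export
lilliefors_test <- function(values, alpha = 0.05, n_null = 10000,
                            seed = NULL) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 4L) stop("Lilliefors test needs n >= 4", call. = FALSE)
  if (stats::sd(values) == 0) stop("constant sample", call. = FALSE)
  d <- lilliefors_statistic(values)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  d_null <- vapply(seq_len(n_null),
                   function(i) lilliefors_statistic(stats::rnorm(n)),
                   numeric(1))
  p <- (1 + sum(d_null >= d)) / (n_null + 1)
  new_normality_result("lilliefors", d, p, alpha)
}

#' Jarque-Bera test of normality
#'
#' `JB = n/6 * (S^2 + (K - 3)^2 / 4)` with S and K the population (biased)
#' sample skewness and non-excess kurtosis; p-value from the chi-square
#' distribution with 2 degrees of freedom.
#'
#' @param values numeric sample (n >= 8).
#' @param alpha significance level (default 0.05).
#' @return A `normality_result`.
#' @export
jarque_bera_test <- function(values, alpha = 0.05) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 8L) stop("Jarque-Bera test needs n >= 8", call. = FALSE)
  m <- mean(values)
  d <- values - m
  m2 <- mean(d^2)
  if (m2 == 0) stop("constant sample", call. = FALSE)
  s <- mean(d^3) / m2^1.5
  k <- mean(d^4) / m2^2
  jb <- n / 6 * (s^2 + (k - 3)^2 / 4)
  p <- stats::pchisq(jb, df = 2, lower.tail = FALSE)
  new_normality_result("jarque_bera", jb, p, alpha)
}

#' Run both normality tests on every channel of a canopy image
#'
#' @param image a [canopy_image()].
#' @param alpha significance level.
#' @param n_null Monte-Carlo replicates for the Lilliefors null.
#' @param seed optional seed for the Lilliefors null simulation.
#' @return data.frame with columns `channel`, `test`, `statistic`,
#'   `p_value`, `reject`.
#' @export
test_image_normality <- function(image, alpha = 0.05, n_null = 2000,
                                 seed = NULL) {
  rows <- list()
  for (ch in CHANNELS) {
    v <- channel_values(image, ch)
    lt <- lilliefors_test(v, alpha = alpha, n_null = n_null, seed = seed)
    jb <- jarque_bera_test(v, alpha = alpha)
    rows[[length(rows) + 1L]] <- data.frame(
      channel = ch,
      test = c(lt$test, jb$test),
      statistic = c(lt$statistic, jb$statistic),
      p_value = c(lt$p_value, jb$p_value),
      reject = c(lt$reject, jb$reject))
  }
  do.call(rbind, rows)
}
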