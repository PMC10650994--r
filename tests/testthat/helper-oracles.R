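# Independent oracles and fixture builders. These deliberately avoid the
# package's own code paths: statistics by direct per-pixel summation,
# clustering by exhaustive enumeration or Lloyd iterations, subsets by
# exhaustive search.

# Direct-summation moments of a raw value vector (population form,
# non-excess kurtosis), written without reusing package internals.
oracle_moments <- function(x) {
  n <- length(x)
  mu <- sum(x) / n
  d <- x - mu
  m2 <- sum(d^2) / n
  m3 <- sum(d^3) / n
  m4 <- sum(d^4) / n
  list(mean = mu,
       median = stats::median(x),
       mode = {
         tb <- table(x)
         as.numeric(names(tb)[which.max(tb)])  # ties -> smallest value
       },
       skewness = if (m2 == 0) NA_real_ else m3 / m2^1.5,
       kurtosis = if (m2 == 0) NA_real_ else m4 / m2^2)
}

# Expand a 256-bin histogram back to the pixel multiset.
oracle_expand_counts <- function(counts) rep(0:255, times = counts)

# Brute-force per-pixel histogram tally.
oracle_tally <- function(values) {
  counts <- integer(256)
  for (v in values) counts[v + 1L] <- counts[v + 1L] + 1L
  counts
}

# Random small canopy image with an irregular mask.
random_canopy <- function(h = 12, w = 15, p_fg = 0.7,
                          rmax = 255, gmax = 255, bmax = 255) {
  repeat {
    mask <- matrix(stats::runif(h * w) < p_fg, h, w)
    if (any(mask)) break
  }
  canopy_image(matrix(sample(0:rmax, h * w, replace = TRUE), h, w),
               matrix(sample(0:gmax, h * w, replace = TRUE), h, w),
               matrix(sample(0:bmax, h * w, replace = TRUE), h, w),
               mask)
}

# Image whose foreground channels are set from explicit vectors.
canopy_from_values <- function(r, g = r, b = r) {
  n <- length(r)
  w <- ceiling(sqrt(n))
  h <- ceiling(n / w)
  pad <- function(v) matrix(c(v, rep(0L, h * w - n)), h, w)
  mask <- matrix(c(rep(TRUE, n), rep(FALSE, h * w - n)), h, w)
  canopy_image(pad(as.integer(r)), pad(as.integer(g)), pad(as.integer(b)),
               mask)
}

# Lloyd's algorithm for 1-D k=2 from a random initialization.
oracle_lloyd_2means <- function(x, iters = 100) {
  cent <- sample(x, 2)
  if (cent[1] == cent[2]) cent[2] <- cent[2] + 1e-9
  for (i in seq_len(iters)) {
    assign1 <- abs(x - cent[1]) <= abs(x - cent[2])
    if (all(assign1) || !any(assign1)) break
    new_cent <- c(mean(x[assign1]), mean(x[!assign1]))
    if (all(new_cent == cent)) break
    cent <- new_cent
  }
  assign1 <- abs(x - cent[1]) <= abs(x - cent[2])
  if (all(assign1) || !any(assign1)) return(Inf)
  sum((x[assign1] - mean(x[assign1]))^2) +
    sum((x[!assign1] - mean(x[!assign1]))^2)
}

# Exhaustive minimum within-cluster SS over every 2-labelling (n <= 12).
oracle_exhaustive_2means <- function(x) {
  n <- length(x)
  best <- Inf
  best_lab <- NULL
  for (code in 1:(2^n - 2)) {
    lab <- as.logical(bitwAnd(code, 2^(0:(n - 1))))
    a <- x[lab]; b <- x[!lab]
    wss <- sum((a - mean(a))^2) + sum((b - mean(b))^2)
    if (wss < best - 1e-12) {
      best <- wss
      best_lab <- lab
    }
  }
  list(wss = best, labels = best_lab)
}

# Exhaustive "stable subset" search matching the stepwise entry criterion:
# every included predictor significant at p_enter given the others, no
# excluded candidate significant if added; returns the stable subset with
# the highest R^2 (names, sorted).
oracle_best_subset <- function(y, X, p_enter = 0.05) {
  k <- ncol(X)
  nms <- names(X)
  n <- length(y)
  sse_of <- function(sel) {
    if (length(sel) == 0) return(sum((y - mean(y))^2))
    fit <- stats::lm(y ~ ., data = X[, sel, drop = FALSE])
    sum(stats::residuals(fit)^2)
  }
  partial_p <- function(sse0, sse1, df1) {
    stats::pf((sse0 - sse1) / (sse1 / df1), 1, df1, lower.tail = FALSE)
  }
  best <- NULL; best_r2 <- -Inf
  sst <- sum((y - mean(y))^2)
  for (code in 0:(2^k - 1)) {
    sel <- nms[as.logical(bitwAnd(code, 2^(0:(k - 1))))]
    sse <- sse_of(sel)
    df1 <- n - length(sel) - 1
    stable <- TRUE
    for (nm in sel) {
      p <- partial_p(sse_of(setdiff(sel, nm)), sse, df1)
      if (p >= p_enter) { stable <- FALSE; break }
    }
    if (stable) {
      for (nm in setdiff(nms, sel)) {
        p <- partial_p(sse, sse_of(c(sel, nm)), n - length(sel) - 2)
        if (p < p_enter) { stable <- FALSE; break }
      }
    }
    if (stable) {
      r2 <- 1 - sse / sst
      if (r2 > best_r2) { best_r2 <- r2; best <- sort(sel) }
    }
  }
  best
}
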