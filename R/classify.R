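# Temperature-regime classification: exact one-dimensional 2-means on the
# hourly air temperature, and bubble-chart data export.

#' Split samples into temperature regimes by exact 1-D k-means (k = 2)
#'
#' Optimal one-dimensional 2-means: sort the temperatures, scan every
#' contiguous 2-partition and pick the split minimizing the within-cluster
#' sum of squares. For k = 2 in one dimension the optimal clusters are
#' always contiguous in sorted order, so this scan is provably optimal and
#' fully deterministic (no seed, no initialization). The cluster with the
#' higher mean temperature is labelled `T1` ("normal temperature group"),
#' the lower one `T2` ("low temperature group"); `T0` conventionally
#' denotes the unsplit sample set.
#'
#' @param t_h numeric vector of hourly air temperatures (degrees C).
#' @param k number of clusters; only `k = 2` is supported.
#' @return A `temperature_classification`: list with `labels` (factor
#'   `T1`/`T2` per sample, input order), `centers` (named means, degrees
#'   C), `ranges` (min/max per cluster), `n` (sizes), `wss` (optimal
#'   within-cluster sum of squares) and `boundary` (c(max of T2, min of
#'   T1)).
#' @export
classify_by_temperature <- function(t_h, k = 2) {
  if (k != 2) stop("only k = 2 is supported", call. = FALSE)
  t_h <- as.numeric(t_h)
  if (any(!is.finite(t_h))) stop("temperatures must be finite", call. = FALSE)
  n <- length(t_h)
  if (n < 2 * k) stop("need at least 2k samples", call. = FALSE)
  if (diff(range(t_h)) == 0) {
    stop("degenerate clustering: all temperatures identical", call. = FALSE)
  }
  ord <- order(t_h)
  x <- t_h[ord]
  s1 <- cumsum(x)
  s2 <- cumsum(x^2)
  tot1 <- s1[n]; tot2 <- s2[n]
  i <- seq_len(n - 1)
  # WSS(left 1..i) + WSS(right i+1..n), each sum(x^2) - sum(x)^2 / size
  wss <- (s2[i] - s1[i]^2 / i) +
    ((tot2 - s2[i]) - (tot1 - s1[i])^2 / (n - i))
  split <- which.min(wss)  # first minimum: deterministic tie-break
  low_idx <- ord[seq_len(split)]
  high_idx <- ord[(split + 1):n]
  labels <- character(n)
  labels[high_idx] <- "T1"  # higher-temperature cluster = normal group
  labels[low_idx] <- "T2"
  structure(list(
    labels = factor(labels, levels = c("T1", "T2")),
    centers = c(T1 = mean(t_h[high_idx]), T2 = mean(t_h[low_idx])),
    ranges = rbind(T1 = range(t_h[high_idx]), T2 = range(t_h[low_idx])),
    n = c(T1 = length(high_idx), T2 = length(low_idx)),
    wss = wss[split],
    boundary = c(T2_upper = max(t_h[low_idx]), T1_lower = min(t_h[high_idx]))),
    class = "temperature_classification")
}

#' @export
print.temperature_classification <- function(x, ...) {
  cat(sprintf(
    "Temperature regimes: T1 (normal) n = %d, T >= %.2f C; T2 (low) n = %d, T <= %.2f C\n",
    x$n[["T1"]], x$boundary[["T1_lower"]],
    x$n[["T2"]], x$boundary[["T2_upper"]]))
  cat(sprintf("  centers: T1 = %.2f C, T2 = %.2f C; within-cluster SS = %.3f\n",
              x$centers[["T1"]], x$centers[["T2"]], x$wss))
  invisible(x)
}

#' Bubble-chart data for a temperature classification
#'
#' Projects each classified sample onto the plotting variables of the
#' regime bubble chart: dew-point temperature (x), relative humidity (y),
#' air temperature (bubble size) and the regime label (color). Values are
#' carried verbatim; rows with a missing factor are flagged.
#'
#' @param classification a [classify_by_temperature()] result.
#' @param meteo data.frame with columns `TD_h`, `RH_h`, `T_h`, one row per
#'   classified sample (same order).
#' @return data.frame with columns `TD_h`, `RH_h`, `T_h`, `label`,
#'   `flagged`.
#' @export
bubble_chart_data <- function(classification, meteo) {
  stopifnot(inherits(classification, "temperature_classification"))
  need <- c("TD_h", "RH_h", "T_h")
  stopifnot(all(need %in% names(meteo)))
  if (nrow(meteo) != length(classification$labels)) {
    stop("classification does not cover all samples", call. = FALSE)
  }
  out <- data.frame(TD_h = meteo$TD_h, RH_h = meteo$RH_h, T_h = meteo$T_h,
                    label = classification$labels)
  out$flagged <- !stats::complete.cases(out[, need])
  out
}

#' Export a classification as a CSV-ready table
#' @param classification a [classify_by_temperature()] result.
#' @param t_h the temperatures that were classified.
#' @param sample_ids optional identifiers.
#' @return data.frame with `sample_id`, `T_h`, `label`.
#' @export
classification_table <- function(classification, t_h, sample_ids = NULL) {
  if (is.null(sample_ids)) sample_ids <- seq_along(t_h)
  data.frame(sample_id = sample_ids, T_h = t_h,
             label = classification$labels)
}
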