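# Prediction-accuracy statistic, outlier flagging and holdout validation
# reports.

#' Relative-error prediction accuracy, in percent
#'
#' `accuracy = (1 - |predicted - measured| / |measured|) * 100`.
#' Exact predictions score 100%; a prediction of zero scores 0%; relative
#' errors above 100% give negative accuracies. The denominator uses the
#' absolute measured value so the statistic is well-defined for negative
#' responses (e.g. skewness). Measured values within `eps` of zero make
#' the statistic non-computable and return NA (callers report such samples
#' separately).
#'
#' @param predicted predicted value(s).
#' @param measured measured value(s).
#' @param eps near-zero-denominator guard (default 1e-9, measurement
#'   units).
#' @return accuracy in percent (vectorized; NA where non-computable).
#' @export
prediction_accuracy <- function(predicted, measured, eps = 1e-9) {
  out <- (1 - abs(predicted - measured) / abs(measured)) * 100
  out[abs(measured) <= eps] <- NA_real_
  out
}

#' Validate a fitted model on holdout samples
#'
#' Computes per-sample prediction accuracies, flags outliers (default
#' rule: accuracy below 0, i.e. relative error above 100%), and reports
#' the mean accuracy over non-outlier samples (the headline statistic)
#' alongside the inclusive mean over all computable samples. Samples with
#' a near-zero measured value are non-computable and counted separately.
#'
#' @param model a fitted `cgsd_model`.
#' @param holdout data.frame containing the model's predictor columns and
#'   the measured response column (named as `model$response`).
#' @param outlier_threshold accuracy (%) below which a sample is flagged
#'   (default 0).
#' @param eps near-zero-denominator guard passed to
#'   [prediction_accuracy()].
#' @return An `accuracy_report`: list with `model` (response name),
#'   `samples` (data.frame: predicted, measured, accuracy, outlier),
#'   `n`, `n_outliers`, `n_noncomputable`, `mean_accuracy` (excluding
#'   outliers), `mean_accuracy_inclusive`, and the rule in force.
#' @export
validate_model <- function(model, holdout, outlier_threshold = 0,
                           eps = 1e-9) {
  stopifnot(inherits(model, "cgsd_model"))
  if (model$status != "fitted") {
    stop("cannot validate a model with status ", model$status, call. = FALSE)
  }
  if (!is.data.frame(holdout) || nrow(holdout) == 0L) {
    stop("holdout data must be a non-empty data.frame", call. = FALSE)
  }
  if (!model$response %in% names(holdout)) {
    stop("holdout data lacks measured column ", model$response, call. = FALSE)
  }
  measured <- holdout[[model$response]]
  predicted <- evaluate_model(model, holdout)
  ok <- is.finite(measured)
  acc <- rep(NA_real_, length(measured))
  acc[ok] <- prediction_accuracy(predicted[ok], measured[ok], eps = eps)
  computable <- is.finite(acc)
  outlier <- computable & acc < outlier_threshold
  keep <- computable & !outlier
  samples <- data.frame(
    sample_id = if ("sample_id" %in% names(holdout)) holdout$sample_id
                else seq_along(measured),
    predicted = predicted, measured = measured, accuracy = acc,
    outlier = outlier)
  structure(list(
    model = model$response,
    samples = samples,
    n = length(measured),
    n_outliers = sum(outlier),
    n_noncomputable = sum(!computable),
    mean_accuracy = if (any(keep)) mean(acc[keep]) else NA_real_,
    mean_accuracy_inclusive = if (any(computable)) mean(acc[computable])
                              else NA_real_,
    outlier_threshold = outlier_threshold),
    class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf("%s: n = %d, outliers = %d, mean accuracy = %.2f%% (incl. outliers %.2f%%)",
              x$model, x$n, x$n_outliers, x$mean_accuracy,
              x$mean_accuracy_inclusive), "\n")
  if (x$n_noncomputable > 0) {
    cat(sprintf("  %d sample(s) non-computable (measured ~ 0)\n",
                x$n_noncomputable))
  }
  invisible(x)
}

#' Summarise accuracy reports as a validation table
#'
#' One row per model with outlier counts and mean accuracies, the layout
#' of a holdout validation table.
#'
#' @param reports list of `accuracy_report` objects.
#' @return data.frame with columns `model`, `n`, `n_outliers`,
#'   `mean_accuracy`, `mean_accuracy_inclusive`, `n_noncomputable`.
#' @export
accuracy_summary <- function(reports) {
  do.call(rbind, lapply(reports, function(r) {
    data.frame(model = r$model, n = r$n, n_outliers = r$n_outliers,
               mean_accuracy = r$mean_accuracy,
               mean_accuracy_inclusive = r$mean_accuracy_inclusive,
               n_noncomputable = r$n_noncomputable)
  }))
}

#' Write per-sample accuracy details and a summary to CSV
#' @param reports list of `accuracy_report` objects.
#' @param dir output directory.
#' @param prefix filename prefix.
#' @return paths written, invisibly.
#' @export
write_accuracy_csv <- function(reports, dir, prefix = "accuracy") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (r in reports) {
    p <- file.path(dir, sprintf("%s_%s.csv", prefix, r$model))
    utils::write.csv(r$samples, p, row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)
  }
  sp <- file.path(dir, sprintf("%s_summary.csv", prefix))
  utils::write.csv(accuracy_summary(reports), sp, row.names = FALSE,
                   quote = FALSE)
  invisible(c(paths, sp))
}
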