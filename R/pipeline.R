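# End-to-end orchestration: simulate a study to disk, extract CGSD tables
# from an image directory, fit response/inversion models (optionally per
# temperature regime), and validate models on holdout data. These
# functions are thin compositions of the module functions and write the
# pipeline's CSV/JSON outputs deterministically.

image_filename <- function(id, timestamp) {
  sprintf("%s_%s.png", id, format(timestamp, "%Y%m%d_%H%M", tz = "UTC"))
}

# Recover the acquisition time from a pipeline image filename.
timestamp_from_filename <- function(path) {
  m <- regmatches(basename(path),
                  regexpr("[0-9]{8}_[0-9]{4}", basename(path)))
  if (length(m) == 0L) return(as.POSIXct(NA))
  as.POSIXct(m, format = "%Y%m%d_%H%M", tz = "UTC")
}

#' Write a synthetic study to disk
#'
#' Emits one RGBA PNG per observation hour (background transparent), the
#' weather CSV in the standard dialect, and the planted-truth CSV.
#'
#' @param scenario a [synthetic_scenario()].
#' @param out_dir output directory (created if needed).
#' @return list with the generated `study` and the written `paths`,
#'   invisibly.
#' @export
run_simulate <- function(scenario, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  study <- generate_study(scenario)
  img_paths <- character(0)
  for (i in seq_along(study$images)) {
    p <- file.path(out_dir, image_filename(study$sample_ids[i],
                                           study$meteo$timestamp[i]))
    write_canopy_png(study$images[[i]], p)
    img_paths <- c(img_paths, p)
  }
  meteo_path <- file.path(out_dir, "meteo.csv")
  write_meteo_csv(study$meteo, meteo_path)
  truth_path <- file.path(out_dir, "truth.csv")
  utils::write.csv(study$truth, truth_path, row.names = FALSE, quote = FALSE)
  invisible(list(study = study,
                 paths = list(images = img_paths, meteo = meteo_path,
                              truth = truth_path)))
}

#' Extract CGSD parameters (and normality results) from an image directory
#'
#' Reads every `*.png` in `image_dir`, computes the 20 CGSD parameters per
#' image and runs both normality tests on each channel. Unreadable images
#' are logged and skipped (reported in `skipped`), never silently dropped.
#'
#' @param image_dir directory of background-removed PNG images.
#' @param alpha_threshold foreground alpha cut (see
#'   [load_masked_image()]).
#' @param normality run the per-image normality tests (default TRUE).
#' @param n_null Lilliefors Monte-Carlo replicates.
#' @param seed seed for the Lilliefors null simulation.
#' @param out_dir optional directory to write `cgsd.csv` and
#'   `normality.csv`.
#' @return list with `cgsd` (data.frame), `normality` (data.frame or
#'   NULL), `skipped` (character paths).
#' @export
run_extract <- function(image_dir, alpha_threshold = 0, normality = TRUE,
                        n_null = 2000, seed = 1, out_dir = NULL) {
  paths <- sort(list.files(image_dir, pattern = "\\.png$", full.names = TRUE))
  if (length(paths) == 0L) stop("no PNG images in ", image_dir, call. = FALSE)
  rows <- list(); norm_rows <- list(); skipped <- character(0)
  for (p in paths) {
    img <- tryCatch(load_masked_image(p, alpha_threshold),
                    error = function(e) {
                      warning("skipping unreadable image ", p, ": ",
                              conditionMessage(e), call. = FALSE)
                      NULL
                    })
    if (is.null(img)) { skipped <- c(skipped, p); next }
    id <- sub("\\.png$", "", basename(p))
    ts <- timestamp_from_filename(p)
    rows[[length(rows) + 1L]] <- compute_cgsd(img, sample_id = id,
                                              timestamp = ts)
    if (normality) {
      nr <- test_image_normality(img, n_null = n_null, seed = seed)
      nr$sample_id <- id
      norm_rows[[length(norm_rows) + 1L]] <- nr
    }
  }
  if (length(rows) == 0L) stop("no readable images in ", image_dir,
                               call. = FALSE)
  cgsd <- do.call(rbind, rows)
  normality_tab <- if (normality) do.call(rbind, norm_rows) else NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_cgsd_csv(cgsd, file.path(out_dir, "cgsd.csv"))
    if (!is.null(normality_tab)) {
      utils::write.csv(normality_tab, file.path(out_dir, "normality.csv"),
                       row.names = FALSE, quote = FALSE)
    }
  }
  list(cgsd = cgsd, normality = normality_tab, skipped = skipped)
}

#' Pair a CGSD table with hourly records and fit all models
#'
#' Pairs images to observation hours, runs the correlation screen, and
#' fits the 20 response and 5 inversion models. With `classify = TRUE`
#' the samples are additionally split into temperature regimes and the
#' models are refit within each regime (`T0` = all samples, `T1` =
#' normal-temperature group, `T2` = low-temperature group).
#'
#' @param cgsd CGSD data.frame with a `timestamp` column.
#' @param meteo a [meteo_table()].
#' @param max_gap_min image-record pairing bound, minutes.
#' @param p_enter,p_remove stepwise thresholds.
#' @param classify refit per temperature regime.
#' @param out_dir optional directory for `correlation.csv`,
#'   `response_models*.json`, `inversion_models*.json`,
#'   `classification.csv`, `bubble.csv`.
#' @return list with `paired` (aligned cgsd/meteo data.frames),
#'   `correlation`, `groups` (per-regime list: response and inversion
#'   model lists), `classification` (or NULL), `unmatched`.
#' @export
run_fit <- function(cgsd, meteo, max_gap_min = 30, p_enter = 0.05,
                    p_remove = 0.10, classify = FALSE, out_dir = NULL) {
  pairing <- match_images_to_hours(cgsd$timestamp, meteo, max_gap_min)
  if (nrow(pairing$pairs) == 0L) stop("no image could be paired", call. = FALSE)
  cg <- cgsd[pairing$pairs$image, , drop = FALSE]
  mt <- as.data.frame(meteo)[pairing$pairs$record, , drop = FALSE]
  rownames(cg) <- rownames(mt) <- NULL
  corr <- correlation_screen(cg, mt)
  groups <- list(T0 = list(
    response = fit_all_response_models(cg, mt, p_enter, p_remove),
    inversion = fit_all_inversion_models(mt, cg, p_enter, p_remove),
    n = nrow(cg)))
  classification <- NULL
  if (classify) {
    classification <- classify_by_temperature(mt$T_h)
    for (lab in c("T1", "T2")) {
      sel <- classification$labels == lab
      if (sum(sel) >= 4L) {
        groups[[lab]] <- list(
          response = fit_all_response_models(cg[sel, ], mt[sel, ],
                                             p_enter, p_remove),
          inversion = fit_all_inversion_models(mt[sel, ], cg[sel, ],
                                               p_enter, p_remove),
          n = sum(sel))
      }
    }
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_correlation_csv(corr, file.path(out_dir, "correlation.csv"))
    for (lab in names(groups)) {
      models_to_json(groups[[lab]]$response,
                     file.path(out_dir, sprintf("response_models_%s.json", lab)))
      models_to_json(groups[[lab]]$inversion,
                     file.path(out_dir, sprintf("inversion_models_%s.json", lab)))
    }
    if (!is.null(classification)) {
      utils::write.csv(classification_table(classification, mt$T_h,
                                            cg$sample_id),
                       file.path(out_dir, "classification.csv"),
                       row.names = FALSE, quote = FALSE)
      utils::write.csv(bubble_chart_data(classification, mt),
                       file.path(out_dir, "bubble.csv"),
                       row.names = FALSE, quote = FALSE)
    }
  }
  list(paired = list(cgsd = cg, meteo = mt), correlation = corr,
       groups = groups, classification = classification,
       unmatched = pairing$unmatched)
}

#' Validate fitted models against a holdout study
#'
#' Runs [validate_model()] for every fitted model in `models` against the
#' holdout data (skipping `unable_to_model` entries) and returns the
#' per-model reports plus a summary table shaped like a holdout
#' validation table.
#'
#' @param models named list of `cgsd_model` objects.
#' @param holdout data.frame containing measured responses and all
#'   predictor columns (e.g. a paired cgsd+meteo table).
#' @param outlier_threshold accuracy (%) below which a sample is an
#'   outlier.
#' @param out_dir optional directory for per-model and summary CSVs.
#' @return list with `reports` (named list) and `summary` (data.frame).
#' @export
run_validate <- function(models, holdout, outlier_threshold = 0,
                         out_dir = NULL) {
  if (nrow(holdout) == 0L) stop("holdout data is empty", call. = FALSE)
  reports <- list()
  for (m in models) {
    if (m$status != "fitted") next
    reports[[m$response]] <- validate_model(m, holdout,
                                            outlier_threshold = outlier_threshold)
  }
  if (length(reports) == 0L) stop("no fitted model to validate", call. = FALSE)
  if (!is.null(out_dir)) write_accuracy_csv(reports, out_dir)
  list(reports = reports, summary = accuracy_summary(reports))
}

#' Combine a paired study into one analysis data.frame
#'
#' Convenience: binds the CGSD columns and factor columns of a paired
#' study (e.g. for [run_validate()]).
#'
#' @param cgsd CGSD data.frame.
#' @param meteo factor data.frame (row-aligned).
#' @return combined data.frame.
#' @export
bind_study <- function(cgsd, meteo) {
  stopifnot(nrow(cgsd) == nrow(meteo))
  cbind(cgsd, as.data.frame(meteo)[, METEO_FACTORS])
}
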