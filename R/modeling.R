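# Correlation screening and stepwise least-squares model fitting in both
# directions: leaf-color response models (CGSD parameter ~ meteorological
# factors) and meteorological inversion models (factor ~ CGSD parameters).

# Candidate order is fixed for deterministic tie-breaks: factors in the
# order T_h, RH_h, AP_h, VP_h, TD_h; CGSD parameters in channel-major order.
FACTOR_CANDIDATE_ORDER <- c("T_h", "RH_h", "AP_h", "VP_h", "TD_h")

#' Pearson correlation screen of CGSD parameters against hourly factors
#'
#' Pairwise Pearson r between each of the 20 CGSD parameters and each of
#' the five hourly meteorological factors, with two-tailed p-values from
#' the t distribution on n - 2 degrees of freedom. Samples with undefined
#' (NA) CGSD moments are dropped pairwise per cell; cells with a constant
#' column are returned as NA and flagged.
#'
#' @param cgsd CGSD data.frame (one row per image, columns
#'   `R_Mean` .. `Y_Kurtosis`), row-aligned with `meteo`.
#' @param meteo data.frame with the five factor columns, one row per image
#'   (e.g. built from [match_images_to_hours()] pairs).
#' @return A `correlation_matrix`: list with matrices `r` and `p`
#'   (20 x 5), integer matrix `n`, and `flagged` (logical, TRUE where r is
#'   undefined).
#' @export
correlation_screen <- function(cgsd, meteo) {
  params <- cgsd_parameter_names()
  factors <- METEO_FACTORS
  stopifnot(all(params %in% names(cgsd)), all(factors %in% names(meteo)),
            nrow(cgsd) == nrow(meteo))
  if (nrow(cgsd) < 3L) stop("need at least 3 paired samples", call. = FALSE)
  r <- p <- matrix(NA_real_, length(params), length(factors),
                   dimnames = list(params, factors))
  n <- matrix(0L, length(params), length(factors),
              dimnames = list(params, factors))
  for (pm in params) {
    for (fc in factors) {
      x <- cgsd[[pm]]; y <- meteo[[fc]]
      ok <- is.finite(x) & is.finite(y)
      ni <- sum(ok)
      n[pm, fc] <- ni
      if (ni < 3L) next
      if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) next  # flagged NA
      ri <- stats::cor(x[ok], y[ok])
      tt <- ri * sqrt((ni - 2) / (1 - ri^2))
      r[pm, fc] <- ri
      p[pm, fc] <- if (is.finite(tt)) 2 * stats::pt(-abs(tt), df = ni - 2) else 0
    }
  }
  structure(list(r = r, p = p, n = n, flagged = is.na(r)),
            class = "correlation_matrix")
}

#' Write a correlation matrix as CSV (r block then p block)
#' @param x a `correlation_matrix`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_correlation_csv <- function(x, path) {
  stopifnot(inherits(x, "correlation_matrix"))
  rb <- data.frame(block = "r", parameter = rownames(x$r), x$r,
                   check.names = FALSE)
  pb <- data.frame(block = "p", parameter = rownames(x$p), x$p,
                   check.names = FALSE)
  utils::write.csv(rbind(rb, pb), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# --- linear models ----------------------------------------------------------

new_linear_model <- function(response, status, intercept = NA_real_,
                             terms = numeric(0), n = NA_integer_,
                             r2 = NA_real_, adj_r2 = NA_real_,
                             rmse = NA_real_, f = NA_real_,
                             sig_f = NA_real_) {
  structure(list(response = response, status = status,
                 intercept = intercept, terms = terms, n = n,
                 r2 = r2, adj_r2 = adj_r2, rmse = rmse, f = f,
                 sig_f = sig_f),
            class = "cgsd_model")
}

#' Build a linear model object from printed coefficients
#'
#' Constructs a fitted `cgsd_model` directly from an intercept and named
#' coefficients (plus optional published fit statistics), e.g. to evaluate
#' equations reported in the literature.
#'
#' @param response response name.
#' @param intercept intercept value.
#' @param terms named numeric vector of coefficients.
#' @param ... optional `n`, `r2`, `adj_r2`, `rmse`, `f`, `sig_f`.
#' @return A `cgsd_model` with status `"fitted"`.
#' @export
linear_model <- function(response, intercept, terms = numeric(0), ...) {
  extra <- list(...)
  args <- c(list(response = response, status = "fitted",
                 intercept = intercept, terms = terms), extra)
  do.call(new_linear_model, args)
}

#' @export
print.cgsd_model <- function(x, ...) {
  if (x$status != "fitted") {
    cat(sprintf("%s: unable to model\n", x$response))
    return(invisible(x))
  }
  eq <- sprintf("%.4g", x$intercept)
  for (nm in names(x$terms)) {
    co <- x$terms[[nm]]
    eq <- paste0(eq, if (co >= 0) " + " else " - ", sprintf("%.4g", abs(co)),
                 " ", nm)
  }
  cat(sprintf("%s = %s\n", x$response, eq))
  if (is.finite(x$r2)) {
    cat(sprintf("  n = %d, R2 = %.3f, adj R2 = %.3f, RMSE = %.3f, F = %.3f, sig F = %.3g\n",
                x$n, x$r2, x$adj_r2, x$rmse, x$f, x$sig_f))
  }
  invisible(x)
}

# OLS on a selected set of predictors; returns coefficients and SSE, or
# errors on a rank-deficient design naming the collinear columns.
ols_fit <- function(y, X) {
  Xm <- cbind(`(Intercept)` = 1, as.matrix(X))
  qrx <- qr(Xm)
  if (qrx$rank < ncol(Xm)) {
    dropped <- colnames(Xm)[qrx$pivot[(qrx$rank + 1):ncol(Xm)]]
    stop("degenerate (rank-deficient) design; collinear predictor(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  fit <- stats::lm.fit(Xm, y)
  list(coef = fit$coefficients, sse = sum(fit$residuals^2),
       residuals = fit$residuals, fitted = fit$fitted.values)
}

#' Stepwise least-squares regression with partial-F entry and removal
#'
#' The SPSS-style stepwise procedure: at each step, among excluded
#' candidates compute each one's partial-F p-value given the current
#' model; enter the candidate with the smallest p if it is below
#' `p_enter` (ties broken by candidate column order). After every entry,
#' repeatedly remove any included predictor whose partial-F p-value
#' exceeds `p_remove` (largest p first). Iterate until no entry or removal
#' applies; the final coefficients are the ordinary least-squares fit on
#' the selected set. If no candidate ever enters, the result has status
#' `"unable_to_model"` with no terms.
#'
#' @param y numeric response vector.
#' @param candidates data.frame of candidate predictors (column order is
#'   the tie-break order).
#' @param p_enter probability-of-F to enter (default 0.05).
#' @param p_remove probability-of-F to remove (default 0.10); must exceed
#'   `p_enter`.
#' @param response name recorded on the model.
#' @param forced_entry if TRUE, skip selection and fit all candidates.
#' @return A `cgsd_model` with fit statistics (see [fit_statistics()]).
#' @export
stepwise_fit <- function(y, candidates, p_enter = 0.05, p_remove = 0.10,
                         response = "y", forced_entry = FALSE) {
  stopifnot(is.data.frame(candidates))
  ok <- is.finite(y) & Reduce(`&`, lapply(candidates, is.finite))
  y <- y[ok]
  candidates <- candidates[ok, , drop = FALSE]
  n <- length(y)
  k <- ncol(candidates)
  if (n <= k + 1L && forced_entry) {
    stop("need n > number of candidates + 1", call. = FALSE)
  }
  if (!forced_entry && p_enter >= p_remove) {
    stop("p_enter must be smaller than p_remove", call. = FALSE)
  }
  cand_names <- names(candidates)
  # candidates that never vary cannot enter
  usable <- vapply(candidates, function(x) stats::sd(x) > 0, logical(1))

  sse_of <- function(sel) {
    if (length(sel) == 0L) sum((y - mean(y))^2)
    else ols_fit(y, candidates[, sel, drop = FALSE])$sse
  }
  partial_p <- function(sse0, sse1, df_resid1) {
    # F for adding exactly one predictor: df 1 and n - p1 - 1
    if (df_resid1 <= 0 || sse1 <= 0) return(0)
    fstat <- (sse0 - sse1) / (sse1 / df_resid1)
    stats::pf(fstat, 1, df_resid1, lower.tail = FALSE)
  }

  selected <- character(0)
  if (forced_entry) {
    selected <- cand_names[usable]
  } else {
    repeat {
      changed <- FALSE
      excluded <- setdiff(cand_names[usable], selected)
      if (length(excluded) > 0L && n - length(selected) - 2L > 0L) {
        sse0 <- sse_of(selected)
        pvals <- vapply(excluded, function(nm) {
          sse1 <- tryCatch(sse_of(c(selected, nm)), error = function(e) NA_real_)
          if (!is.finite(sse1)) return(NA_real_)
          partial_p(sse0, sse1, n - length(selected) - 2L)
        }, numeric(1))
        pvals <- pvals[is.finite(pvals)]
        if (length(pvals) > 0L && min(pvals) < p_enter) {
          # which.min takes the first minimum -> candidate-order tie-break
          selected <- c(selected, names(pvals)[which.min(pvals)])
          changed <- TRUE
        }
      }
      # removal pass after every entry
      repeat {
        if (length(selected) == 0L) break
        sse_full <- sse_of(selected)
        df_resid <- n - length(selected) - 1L
        p_rem <- vapply(selected, function(nm) {
          sse_red <- sse_of(setdiff(selected, nm))
          partial_p(sse_red, sse_full, df_resid)
        }, numeric(1))
        worst <- which.max(p_rem)
        if (p_rem[worst] > p_remove) {
          selected <- setdiff(selected, names(p_rem)[worst])
          changed <- TRUE
        } else break
      }
      if (!changed) break
    }
  }

  if (length(selected) == 0L) {
    return(new_linear_model(response, "unable_to_model", n = n))
  }
  # keep selected terms in candidate column order for reproducible output
  selected <- cand_names[cand_names %in% selected]
  fit <- ols_fit(y, candidates[, selected, drop = FALSE])
  model <- new_linear_model(response, "fitted",
                            intercept = unname(fit$coef[1]),
                            terms = fit$coef[-1], n = n)
  fit_statistics(model, y, candidates)
}

#' Goodness-of-fit statistics of a fitted linear model
#'
#' Recomputes `R2 = 1 - SSE/SST`, adjusted
#' `R2 = 1 - (1 - R2)(n-1)/(n-p-1)`, the regression standard error
#' `RMSE = sqrt(SSE/(n-p-1))`, the overall `F = (SSR/p)/(SSE/(n-p-1))` and
#' its upper-tail p-value (significance F) on the supplied data, and
#' returns the updated model.
#'
#' @param model a fitted `cgsd_model`.
#' @param y response vector.
#' @param data data.frame containing the model's predictor columns.
#' @return The model with `r2`, `adj_r2`, `rmse`, `f`, `sig_f` and `n` set.
#' @export
fit_statistics <- function(model, y, data) {
  stopifnot(inherits(model, "cgsd_model"))
  if (model$status != "fitted") {
    stop("fit statistics require a fitted model", call. = FALSE)
  }
  pred <- evaluate_model(model, data)
  ok <- is.finite(y) & is.finite(pred)
  y <- y[ok]; pred <- pred[ok]
  n <- length(y)
  p <- length(model$terms)
  if (n <= p + 1L) stop("need n > p + 1 for fit statistics", call. = FALSE)
  sse <- sum((y - pred)^2)
  sst <- sum((y - mean(y))^2)
  ssr <- sst - sse
  r2 <- 1 - sse / sst
  model$n <- n
  model$r2 <- r2
  model$adj_r2 <- 1 - (1 - r2) * (n - 1) / (n - p - 1)
  model$rmse <- sqrt(sse / (n - p - 1))
  model$f <- (ssr / p) / (sse / (n - p - 1))
  model$sig_f <- stats::pf(model$f, p, n - p - 1, lower.tail = FALSE)
  model
}

#' Evaluate a linear model at given predictor values
#'
#' `intercept + sum(coefficient * input)`. Inputs may be a named list,
#' named vector, or data.frame (vectorized over rows).
#'
#' @param model a fitted `cgsd_model`.
#' @param inputs named values for every term predictor.
#' @return predicted value(s).
#' @export
evaluate_model <- function(model, inputs) {
  stopifnot(inherits(model, "cgsd_model"))
  if (model$status != "fitted") {
    stop("cannot evaluate a model with status ", model$status, call. = FALSE)
  }
  if (is.data.frame(inputs)) {
    missing_terms <- setdiff(names(model$terms), names(inputs))
    if (length(missing_terms) > 0L) {
      stop("missing predictor(s): ", paste(missing_terms, collapse = ", "),
           call. = FALSE)
    }
    out <- rep(model$intercept, nrow(inputs))
    for (nm in names(model$terms)) out <- out + model$terms[[nm]] * inputs[[nm]]
    return(out)
  }
  inputs <- as.list(inputs)
  missing_terms <- setdiff(names(model$terms), names(inputs))
  if (length(missing_terms) > 0L) {
    stop("missing predictor(s): ", paste(missing_terms, collapse = ", "),
         call. = FALSE)
  }
  model$intercept + sum(vapply(names(model$terms),
                               function(nm) model$terms[[nm]] * inputs[[nm]],
                               numeric(1)))
}

#' Fit all 20 leaf-color response models
#'
#' One stepwise model per CGSD parameter with the five hourly factors as
#' candidates (in the order `T_h, RH_h, AP_h, VP_h, TD_h`). Rows with an
#' undefined (NA) value of the response are dropped pairwise; the dropped
#' count is recorded as attribute `n_dropped` on each model.
#'
#' @param cgsd CGSD data.frame, row-aligned with `meteo`.
#' @param meteo data.frame with the five factor columns.
#' @param p_enter,p_remove stepwise thresholds.
#' @param forced_entry fit all candidates without selection.
#' @return named list of 20 `cgsd_model` objects.
#' @export
fit_all_response_models <- function(cgsd, meteo, p_enter = 0.05,
                                    p_remove = 0.10, forced_entry = FALSE) {
  stopifnot(nrow(cgsd) == nrow(meteo))
  candidates <- meteo[, FACTOR_CANDIDATE_ORDER]
  models <- list()
  for (pm in cgsd_parameter_names()) {
    y <- cgsd[[pm]]
    n_dropped <- sum(!is.finite(y))
    m <- stepwise_fit(y, candidates, p_enter = p_enter, p_remove = p_remove,
                      response = pm, forced_entry = forced_entry)
    attr(m, "n_dropped") <- n_dropped
    models[[pm]] <- m
  }
  models
}

#' Fit the five meteorological inversion models
#'
#' One stepwise model per hourly factor with the 20 CGSD parameters as
#' candidates (channel-major order). Rows with any undefined CGSD
#' candidate are dropped pairwise with a logged count.
#'
#' @param meteo data.frame with the five factor columns, row-aligned with
#'   `cgsd`.
#' @param cgsd CGSD data.frame.
#' @param p_enter,p_remove stepwise thresholds.
#' @param forced_entry fit all candidates without selection.
#' @return named list of 5 `cgsd_model` objects.
#' @export
fit_all_inversion_models <- function(meteo, cgsd, p_enter = 0.05,
                                     p_remove = 0.10, forced_entry = FALSE) {
  stopifnot(nrow(cgsd) == nrow(meteo))
  candidates <- cgsd[, cgsd_parameter_names()]
  models <- list()
  for (fc in FACTOR_CANDIDATE_ORDER) {
    y <- meteo[[fc]]
    m <- stepwise_fit(y, candidates, p_enter = p_enter, p_remove = p_remove,
                      response = fc, forced_entry = forced_entry)
    attr(m, "n_dropped") <- nrow(cgsd) - m$n
    models[[fc]] <- m
  }
  models
}

#' Serialize fitted models to JSON
#'
#' Each model becomes
#' `{response, status, intercept, terms: [{name, coef}], n, r2, adj_r2,
#' rmse, f, sig_f}`.
#'
#' @param models a `cgsd_model` or list of them.
#' @param path optional output file.
#' @return JSON string (invisibly if written to `path`).
#' @export
models_to_json <- function(models, path = NULL) {
  if (inherits(models, "cgsd_model")) models <- list(models)
  enc <- lapply(models, function(m) {
    list(response = m$response, status = m$status,
         intercept = if (is.finite(m$intercept)) m$intercept else NULL,
         terms = if (length(m$terms) > 0)
           lapply(names(m$terms),
                  function(nm) list(name = nm, coef = unname(m$terms[[nm]])))
           else list(),
         n = m$n, r2 = m$r2, adj_r2 = m$adj_r2, rmse = m$rmse,
         f = m$f, sig_f = m$sig_f)
  })
  js <- jsonlite::toJSON(enc, auto_unbox = TRUE, digits = NA, null = "null",
                         na = "null", pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

# --- published greenhouse-pepper models -------------------------------------

#' Published greenhouse-pepper leaf-color response models
#'
#' The 20 canopy color-meteorological response equations reported for
#' greenhouse pepper (n = 35), transcribed from the published table as
#' evaluable models: e.g. `R_Mean = 29.094 + 0.298 VP_h`. `B_Mean` could
#' not be modeled and is returned with status `"unable_to_model"`. These
#' are reference inputs (the underlying images were never deposited), kept
#' for worked examples and evaluation checks.
#'
#' @return named list of 20 `cgsd_model` objects.
#' @export
pepper_response_models <- function() {
  m <- function(response, intercept, terms, r2, adj_r2, rmse, f, sig_f) {
    linear_model(response, intercept, terms, n = 35L, r2 = r2,
                 adj_r2 = adj_r2, rmse = rmse, f = f, sig_f = sig_f)
  }
  list(
    R_Mean = m("R_Mean", 29.094, c(VP_h = 0.298), 0.128, 0.102, 2.702, 4.849, 0.035),
    R_Median = m("R_Median", 22.373, c(VP_h = 0.462), 0.219, 0.196, 3.028, 9.276, 0.005),
    R_Mode = m("R_Mode", -22.105, c(VP_h = 1.687), 0.252, 0.229, 10.096, 11.107, 0.002),
    R_Skewness = m("R_Skewness", 2.465, c(TD_h = -0.060), 0.256, 0.233, 0.210, 11.357, 0.002),
    R_Kurtosis = m("R_Kurtosis", 9.624, c(VP_h = -0.122), 0.166, 0.140, 0.947, 6.555, 0.015),
    G_Mean = m("G_Mean", 63.842, c(RH_h = 0.183), 0.272, 0.250, 3.007, 12.310, 0.001),
    G_Median = m("G_Median", 46.048, c(RH_h = 0.214, TD_h = 0.705), 0.448, 0.414, 3.438, 13.004, 0.000),
    G_Mode = m("G_Mode", 33.5, c(RH_h = 0.745), 0.270, 0.248, 12.290, 12.194, 0.001),
    G_Skewness = m("G_Skewness", 2.069, c(RH_h = -0.015, T_h = -0.03), 0.610, 0.585, 0.096, 24.980, 0.000),
    G_Kurtosis = m("G_Kurtosis", 3.948, c(RH_h = -0.014), 0.571, 0.558, 0.118, 43.895, 0.000),
    B_Mean = new_linear_model("B_Mean", "unable_to_model", n = 35L),
    B_Median = m("B_Median", 31.828, c(VP_h = 0.379), 0.184, 0.159, 2.772, 7.450, 0.010),
    B_Mode = m("B_Mode", -46.707, c(T_h = 2.392), 0.327, 0.306, 8.273, 16.012, 0.000),
    B_Skewness = m("B_Skewness", 1.523, c(TD_h = -0.026, RH_h = -0.005), 0.387, 0.349, 0.111, 10.099, 0.000),
    B_Kurtosis = m("B_Kurtosis", 4.862, c(RH_h = -0.021), 0.267, 0.245, 0.343, 12.009, 0.001),
    Y_Mean = m("Y_Mean", 45.433, c(VP_h = 0.678), 0.202, 0.178, 2.773, 8.369, 0.007),
    Y_Median = m("Y_Median", 38.077, c(VP_h = 0.981), 0.260, 0.238, 3.404, 11.612, 0.002),
    Y_Mode = m("Y_Mode", -27.897, c(TD_h = 3.930), 0.224, 0.201, 15.042, 9.552, 0.004),
    Y_Skewness = m("Y_Skewness", 1.722, c(TD_h = -0.036, RH_h = -0.007), 0.529, 0.500, 0.117, 17.969, 0.000),
    Y_Kurtosis = m("Y_Kurtosis", 5.398, c(RH_h = -0.017, VP_h = -0.027), 0.465, 0.431, 0.239, 13.898, 0.000)
  )
}

#' Published greenhouse-pepper meteorological inversion models
#'
#' The five meteorological fitting equations reported for greenhouse
#' pepper, predicting each hourly factor from CGSD parameters, e.g.
#' `T_h = 42.866 + 0.174 B_Mode - 0.232 G_Median`.
#'
#' @return named list of 5 `cgsd_model` objects.
#' @export
pepper_inversion_models <- function() {
  m <- function(response, intercept, terms, r2, adj_r2, rmse, f, sig_f) {
    linear_model(response, intercept, terms, n = 35L, r2 = r2,
                 adj_r2 = adj_r2, rmse = rmse, f = f, sig_f = sig_f)
  }
  list(
    T_h = m("T_h", 42.866, c(B_Mode = 0.174, G_Median = -0.232),
            0.495, 0.463, 1.739, 15.677, 0.000),
    RH_h = m("RH_h", 166.136,
             c(G_Kurtosis = -31.418, B_Mean = -1.815, G_Median = 1.061),
             0.707, 0.679, 5.598, 24.932, 0.000),
    AP_h = m("AP_h", 1003.672, c(B_Mode = -0.108),
             0.116, 0.089, 3.006, 4.320, 0.046),
    VP_h = m("VP_h", 21.555, c(Y_Skewness = -21.771, B_Kurtosis = 4.583),
             0.433, 0.397, 2.656, 12.195, 0.000),
    TD_h = m("TD_h", 19.041, c(Y_Skewness = -13.163, B_Kurtosis = 2.731),
             0.455, 0.421, 1.543, 13.376, 0.000)
  )
}
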