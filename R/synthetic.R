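# Synthetic study generator: hourly weather series with diurnal cycles and
# cold waves, plus canopy images whose per-channel intensity distributions
# are skewed (scaled Beta on 0..255) with locations planted as linear maps
# of the weather factors. Every stage of the pipeline is thereby testable
# against known truth.

#' Define a synthetic study scenario
#'
#' A scenario fixes the observation design (days x hours), the weather
#' dynamics, the planted weather-to-color maps, and the image geometry.
#' All randomness flows from the single `seed` through named substreams
#' (one for the weather, one per image), so each stage is independently
#' reproducible.
#'
#' Weather model: `T_h = t_mean + day offset + t_amplitude *
#' sin(diurnal phase peaking at 15:00) - cold-wave deficit + noise`;
#' `RH_h = rh_base - rh_slope * (T_h - t_mean) + noise`, clipped to
#' \[5, 100\]; `TD_h` from [dew_point_from_t_rh()]; `VP_h` from
#' [vapor_pressure_from_td()]; `AP_h = ap_base + slow drift + noise`.
#'
#' Image model: foreground pixels of channel c are
#' `round(255 * Beta(m*kappa, (1-m)*kappa) + N(0, pixel_noise_sd))`
#' clipped to 0..255, with planted location
#' `mu_c = a_c + sum(b_c[f] * factor_f)` and `m = mu_c / 255`. The Y
#' channel is derived from R, G, B by [gray_channel()], never drawn
#' directly. Default channel maps: R responds to `VP_h`, G to `RH_h` and
#' `VP_h`, B to nothing (a flat channel, so its mean carries no weather
#' signal).
#'
#' @param seed integer master seed.
#' @param days number of observation days (default 7).
#' @param hours observation hours within each day (default
#'   `c(7, 9, 12, 15, 18)`, five shots per day).
#' @param weather list overriding any of: `t_mean`, `t_amplitude`,
#'   `t_day_sd`, `t_noise_sd`, `rh_base`, `rh_slope`, `rh_noise_sd`,
#'   `ap_base`, `ap_drift`, `ap_noise_sd`, `cold_wave` (NULL or
#'   `list(onset_day, depth_c, duration_days)`).
#' @param response list per channel (`R`, `G`, `B`) overriding `a`
#'   (location intercept, intensity), `b` (named factor coefficients) and
#'   `kappa` (Beta concentration; smaller = more dispersed/skewed).
#' @param image list overriding `width`, `height`, `fg_width`,
#'   `fg_height` (the centred foreground rectangle) and `pixel_noise_sd`.
#' @param start_date first observation day (ISO date, default
#'   "2021-06-13").
#' @return A `synthetic_scenario` list.
#' @export
synthetic_scenario <- function(seed, days = 7, hours = c(7, 9, 12, 15, 18),
                               weather = list(), response = list(),
                               image = list(), start_date = "2021-06-13") {
  w <- utils::modifyList(list(
    t_mean = 26, t_amplitude = 5, t_day_sd = 2, t_noise_sd = 0.5,
    rh_base = 75, rh_slope = 3, rh_noise_sd = 5,
    ap_base = 1005, ap_drift = 3, ap_noise_sd = 0.5,
    cold_wave = NULL), weather)
  r_def <- list(
    R = list(a = 30, b = c(VP_h = 0.3), kappa = 10),
    G = list(a = 55, b = c(RH_h = 0.2, VP_h = 0.5), kappa = 8),
    B = list(a = 40, b = numeric(0), kappa = 10))
  for (ch in names(response)) {
    r_def[[ch]] <- utils::modifyList(r_def[[ch]], response[[ch]])
  }
  im <- utils::modifyList(list(
    width = 120, height = 120, fg_width = 100, fg_height = 100,
    pixel_noise_sd = 2), image)
  stopifnot(im$fg_width <= im$width, im$fg_height <= im$height,
            days >= 1, length(hours) >= 1)
  structure(list(seed = as.integer(seed), days = days, hours = hours,
                 weather = w, response = r_def, image = im,
                 start_date = start_date),
            class = "synthetic_scenario")
}

# Named substream seeds derived once from the master seed.
scenario_substreams <- function(scenario) {
  n_img <- scenario$days * length(scenario$hours)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(scenario$seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n_img + 1L)
  list(weather = seeds[1L], images = seeds[-1L])
}

#' Generate the hourly weather series of a scenario
#'
#' Deterministic given the scenario seed. Synthetic tables are validated
#' with the strict physical-consistency rules (`TD_h <= T_h` is an
#' error, not a warning).
#'
#' @param scenario a [synthetic_scenario()].
#' @return A [meteo_table()] with `source = "synthetic"`, one row per
#'   observation hour.
#' @export
generate_weather <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  w <- scenario$weather
  ss <- scenario_substreams(scenario)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(ss$weather)

  day <- rep(seq_len(scenario$days), each = length(scenario$hours))
  hour <- rep(scenario$hours, times = scenario$days)
  n <- length(day)
  day_offset <- stats::rnorm(scenario$days, 0, w$t_day_sd)[day]
  deficit <- rep(0, n)
  cw <- w$cold_wave
  if (!is.null(cw)) {
    hit <- day >= cw$onset_day & day < cw$onset_day + cw$duration_days
    deficit[hit] <- cw$depth_c
  }
  t_h <- w$t_mean + day_offset +
    w$t_amplitude * sin(2 * pi * (hour - 9) / 24) -
    deficit + stats::rnorm(n, 0, w$t_noise_sd)
  rh <- w$rh_base - w$rh_slope * (t_h - w$t_mean) + stats::rnorm(n, 0, w$rh_noise_sd)
  rh <- pmin(100, pmax(5, rh))
  td <- dew_point_from_t_rh(t_h, rh)
  vp <- vapor_pressure_from_td(td)
  ap <- w$ap_base + w$ap_drift * sin(2 * pi * day / max(scenario$days, 2)) +
    stats::rnorm(n, 0, w$ap_noise_sd)

  ts <- as.POSIXct(scenario$start_date, tz = "UTC") +
    (day - 1) * 86400 + hour * 3600
  meteo_table(data.frame(timestamp = ts, T_h = t_h, RH_h = rh, AP_h = ap,
                         TD_h = td, VP_h = vp),
              source = "synthetic")
}

#' Closed-form moments of the scaled-Beta pixel family
#'
#' Mean, variance and skewness of `255 * Beta(m*kappa, (1-m)*kappa)` with
#' `m = mu/255`; reference values for convergence checks of generated
#' images (before pixel noise and integer rounding, which perturb the
#' moments only marginally at the default settings).
#'
#' @param mu planted location, intensity units (0..255).
#' @param kappa Beta concentration.
#' @return named vector `mean`, `var`, `skewness`.
#' @export
beta_channel_moments <- function(mu, kappa) {
  m <- mu / 255
  a <- m * kappa
  b <- (1 - m) * kappa
  v <- a * b / ((a + b)^2 * (a + b + 1))
  skew <- 2 * (b - a) * sqrt(a + b + 1) / ((a + b + 2) * sqrt(a * b))
  c(mean = 255 * m, var = 255^2 * v, skewness = skew)
}

# Planted location of one channel at one record; errors when the linear
# map leaves the Beta domain.
planted_location <- function(conf, record) {
  mu <- conf$a
  for (nm in names(conf$b)) mu <- mu + conf$b[[nm]] * record[[nm]]
  if (mu / 255 <= 0.02 || mu / 255 >= 0.98) {
    stop(sprintf(
      "planted map leaves the Beta domain (location %.2f) at T_h=%.2f RH_h=%.2f VP_h=%.2f TD_h=%.2f",
      mu, record$T_h, record$RH_h, record$VP_h, record$TD_h), call. = FALSE)
  }
  mu
}

#' Generate one canopy image from a weather record
#'
#' Draws foreground pixels per channel from the scenario's scaled-Beta
#' family at the planted location for this record's factors, adds pixel
#' noise, and rounds to 0..255. Background pixels (outside the centred
#' foreground rectangle) are masked out. The planted per-channel truth is
#' attached as attribute `truth`.
#'
#' @param record one-row data.frame with the five factor columns (e.g. a
#'   [meteo_table()] row).
#' @param scenario a [synthetic_scenario()].
#' @param seed substream seed for this image (defaults to the scenario's
#'   first image substream).
#' @return A [canopy_image()] with attribute `truth` (data.frame:
#'   channel, location, kappa).
#' @export
generate_canopy_image <- function(record, scenario, seed = NULL) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  im <- scenario$image
  if (is.null(seed)) seed <- scenario_substreams(scenario)$images[1L]
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  h <- im$height; wd <- im$width
  mask <- matrix(FALSE, h, wd)
  r0 <- floor((h - im$fg_height) / 2)
  c0 <- floor((wd - im$fg_width) / 2)
  mask[r0 + seq_len(im$fg_height), c0 + seq_len(im$fg_width)] <- TRUE
  n_fg <- sum(mask)

  draw <- function(conf) {
    mu <- planted_location(conf, record)
    m <- mu / 255
    v <- 255 * stats::rbeta(n_fg, m * conf$kappa, (1 - m) * conf$kappa)
    if (im$pixel_noise_sd > 0) v <- v + stats::rnorm(n_fg, 0, im$pixel_noise_sd)
    as.integer(pmin(255, pmax(0, round_half_away(v))))
  }
  chans <- list()
  truth <- list()
  for (ch in c("R", "G", "B")) {
    conf <- scenario$response[[ch]]
    mu <- planted_location(conf, record)
    full <- matrix(0L, h, wd)
    full[mask] <- draw(conf)
    chans[[ch]] <- full
    truth[[ch]] <- data.frame(channel = ch, location = mu,
                              kappa = conf$kappa)
  }
  img <- canopy_image(chans$R, chans$G, chans$B, mask)
  attr(img, "truth") <- do.call(rbind, truth)
  img
}

#' Generate a complete synthetic study
#'
#' One canopy image per observation hour, the matching weather table, and
#' the planted-truth tables used by parameter-recovery tests. Fully
#' deterministic from the scenario seed.
#'
#' @param scenario a [synthetic_scenario()].
#' @return list with `images` (list of [canopy_image()]), `meteo`
#'   ([meteo_table()]), `sample_ids`, `truth` (long data.frame of planted
#'   coefficients: channel, term, value) and `locations` (per image x
#'   channel planted location).
#' @export
generate_study <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  meteo <- generate_weather(scenario)
  ss <- scenario_substreams(scenario)
  n <- nrow(meteo)
  images <- vector("list", n)
  locs <- list()
  for (i in seq_len(n)) {
    img <- generate_canopy_image(meteo[i, ], scenario, seed = ss$images[i])
    tr <- attr(img, "truth")
    tr$image <- i
    locs[[i]] <- tr
    images[[i]] <- img
  }
  truth <- do.call(rbind, lapply(c("R", "G", "B"), function(ch) {
    conf <- scenario$response[[ch]]
    rbind(data.frame(channel = ch, term = "(Intercept)", value = conf$a),
          if (length(conf$b) > 0)
            data.frame(channel = ch, term = names(conf$b),
                       value = unname(conf$b)),
          data.frame(channel = ch, term = "kappa", value = conf$kappa))
  }))
  list(images = images, meteo = meteo,
       sample_ids = sprintf("img_%03d", seq_len(n)),
       truth = truth, locations = do.call(rbind, locs))
}

#' A winter open-air scenario with cold waves
#'
#' Convenience wrapper: low mean temperature, reduced diurnal amplitude,
#' and a multi-day cold wave, producing the bimodal temperature marginal
#' that temperature-regime classification is designed for.
#'
#' @param seed integer master seed.
#' @param days observation days (default 12).
#' @param depth_c cold-wave depth, degrees C (default 7).
#' @param ... passed on to [synthetic_scenario()].
#' @return A `synthetic_scenario`.
#' @export
winter_scenario <- function(seed, days = 12, depth_c = 7, ...) {
  synthetic_scenario(
    seed, days = days, hours = c(8, 9, 10, 16),
    weather = list(t_mean = 8, t_amplitude = 3, t_day_sd = 1,
                   rh_base = 70, rh_slope = 2.5,
                   ap_base = 1020, ap_drift = 4,
                   cold_wave = list(onset_day = max(3, days %/% 3),
                                    depth_c = depth_c,
                                    duration_days = max(2, days %/% 4))),
    response = list(
      R = list(a = 60, b = c(VP_h = 1.2), kappa = 9),
      G = list(a = 70, b = c(RH_h = 0.25, VP_h = 1.0), kappa = 8),
      B = list(a = 50, b = c(T_h = 0.8), kappa = 10)),
    start_date = "2018-12-01", ...)
}
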