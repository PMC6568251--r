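#' Simulate a stationary VAR process
#'
#' Draws Gaussian innovations with the given covariance, iterates the VAR
#' recursion from a zero initial state, and discards a burn-in prefix so the
#' retained sample is (approximately) a draw from the stationary
#' distribution. Deterministic given `seed`.
#'
#' @param coeffs List of m x m lag matrices (row = equation), e.g. from
#'   [soil_reference_var()].
#' @param sigma Innovation covariance (m x m, PSD; `0` gives a noiseless
#'   recursion).
#' @param n Length of the retained sample.
#' @param intercept Optional intercept vector (default zero).
#' @param seed Integer seed (optional).
#' @param burn_in Number of initial draws discarded (default 500).
#' @param allow_unstable Permit simulation from an unstable coefficient set
#'   (default `FALSE`: raises an `unstable` error).
#' @return An `n x m` numeric matrix with variable column names.
#' @export
simulate_var <- function(coeffs, sigma, n, intercept = NULL, seed = NULL,
                         burn_in = 500L, allow_unstable = FALSE) {
  coeffs <- coeff_list(coeffs)
  n <- check_count(n, "n", min = 1L)
  burn_in <- check_count(burn_in, "burn_in", min = 0L)
  m <- nrow(coeffs[[1]])
  p <- length(coeffs)
  if (is.null(intercept)) intercept <- rep(0, m)
  sigma <- if (length(sigma) == 1L) diag(as.numeric(sigma), m) else as.matrix(sigma)
  if (!is_psd(sigma)) stop_soil("argument", "`sigma` must be symmetric PSD.")
  stab <- stability_check(coeffs)
  if (!stab$stable && !allow_unstable) {
    stop_soil("unstable", sprintf(
      "coefficients are unstable (max |eigenvalue| = %.3f); pass allow_unstable = TRUE to force.",
      stab$moduli[1]))
  }
  if (!is.null(seed)) withr::local_seed(seed)
  total <- n + burn_in
  if (all(sigma == 0)) {
    innov <- matrix(0, total, m)
  } else {
    # PSD square root via eigen so semi-definite covariances are accepted
    es <- eigen(sigma, symmetric = TRUE)
    rt <- es$vectors %*% diag(sqrt(pmax(es$values, 0)), m) %*% t(es$vectors)
    innov <- matrix(rnorm(total * m), total, m) %*% rt
  }
  y <- matrix(0, total + p, m)
  for (t in seq_len(total)) {
    acc <- intercept + innov[t, ]
    for (s in seq_len(p)) {
      acc <- acc + coeffs[[s]] %*% y[p + t - s, ]
    }
    y[p + t, ] <- acc
  }
  out <- y[(p + burn_in + 1L):(p + total), , drop = FALSE]
  colnames(out) <- colnames(coeffs[[1]]) %||% paste0("y", seq_len(m))
  out
}

#' Configuration of the synthetic soil-profile generator
#'
#' Describes a coupled hourly temperature/moisture dataset with known ground
#' truth: per-depth baselines and diurnal harmonics (amplitude decaying and
#' phase retarding with depth, as heat and moisture waves do in a soil
#' profile), a shared slow piecewise-linear seasonal trend (cooling into
#' mid-winter, warming into spring; slight moisture drawdown from root
#' uptake), a stationary bivariate VAR residual pair per depth riding on a
#' 24-hour seasonal integration (so that seasonal differencing recovers the
#' VAR process exactly), and sporadic irrigation step events in moisture
#' with exponential decay. Defaults emulate a 160-day December-May winter
#' wheat season on loam with the [soil_reference_var()] coefficient sets as
#' residual truth.
#'
#' @param days Number of simulated days (hourly sampling).
#' @param start First timestamp.
#' @param depths Depths (cm) to generate.
#' @param profile Per-depth tibble: `depth`, `temp_base` (degC), `temp_amp`
#'   (degC), `moist_base` (%), `moist_amp` (%), `phase_h` (hours the diurnal
#'   peak lags the surface).
#' @param trend Named list (`temperature`, `moisture`) of piecewise-linear
#'   anchor tibbles `day`/`value` (offsets added to the baseline).
#' @param var_coeffs Named list (by depth) of lag-matrix lists for the
#'   deseasonalized residual pair, variable order (moisture, temperature).
#' @param innovation_sd Named list (by depth) of length-2 innovation
#'   standard deviations (moisture %, temperature degC).
#' @param innovation_cor Contemporaneous innovation correlation.
#' @param irrigation_events Tibble `day`, `jump` (moisture %), `max_depth`
#'   (cm; events reach depths at or above it), `half_life` (hours).
#' @param seed Integer master seed; all randomness derives from it.
#' @return A list of class `soil_synth_config`.
#' @export
synthetic_config <- function(days = 160L,
                             start = "2017-12-19 00:00",
                             depths = c(10L, 30L, 90L),
                             profile = NULL,
                             trend = NULL,
                             var_coeffs = NULL,
                             innovation_sd = NULL,
                             innovation_cor = 0.3,
                             irrigation_events = NULL,
                             seed = 1L) {
  days <- check_count(days, "days", min = 8L)
  seed <- check_count(seed, "seed", min = 0L)
  profile <- profile %||% tibble(
    depth = c(10L, 30L, 90L),
    temp_base = c(6, 7, 9), temp_amp = c(3, 1, 0.15),
    moist_base = c(28, 30, 33), moist_amp = c(0.6, 0.15, 0.03),
    phase_h = c(2, 5, 9))
  trend <- trend %||% list(
    temperature = tibble(day = c(0, 45, days), value = c(3, -3, 9)),
    moisture = tibble(day = c(0, days), value = c(0, -2)))
  var_coeffs <- var_coeffs %||% setNames(
    lapply(c(10L, 30L, 90L), function(d) soil_reference_var(d)$coeffs),
    c("10", "30", "90"))
  # chosen so the stationary residual pairs fluctuate at the magnitude of
  # field deseasonalized series (a few tenths of a unit) and their seasonal
  # integrals stay well inside the instrument ranges despite the extreme
  # persistence of the shallow temperature dynamics
  innovation_sd <- innovation_sd %||% list(
    "10" = c(0.005, 0.015), "30" = c(0.01, 0.02), "90" = c(0.005, 0.01))
  if (is.null(irrigation_events)) {
    irrigation_events <- tibble(
      day = c(73, 90), jump = c(5, 4), max_depth = c(50, 50),
      half_life = c(120, 120)) %>%
      filter(.data$day < days)   # short runs simply end before the events
  }
  if (any(profile$temp_amp < 0) || any(profile$moist_amp < 0)) {
    stop_soil("argument", "diurnal amplitudes must be nonnegative.")
  }
  missing_depths <- setdiff(as.character(depths),
                            intersect(names(var_coeffs), names(innovation_sd)))
  if (length(missing_depths) || !all(depths %in% profile$depth)) {
    stop_soil("argument", "every requested depth needs profile, var_coeffs and innovation_sd entries.")
  }
  for (d in as.character(depths)) {
    stab <- stability_check(var_coeffs[[d]])
    if (!stab$stable) {
      stop_soil("unstable", sprintf(
        "residual VAR at %s cm is unstable (max |eigenvalue| = %.3f).",
        d, stab$moduli[1]))
    }
  }
  innovation_cor <- check_number(innovation_cor, "innovation_cor",
                                 min = -0.99, max = 0.99)
  structure(list(days = days, start = as_hour_posix(start),
                 depths = as.integer(depths), profile = profile, trend = trend,
                 var_coeffs = var_coeffs, innovation_sd = innovation_sd,
                 innovation_cor = innovation_cor,
                 irrigation_events = irrigation_events, seed = seed),
            class = "soil_synth_config")
}

#' Deterministic component of a synthetic series
#'
#' Baseline plus piecewise-linear seasonal trend plus a cosine diurnal
#' harmonic of exact 24-hour period with the configured amplitude and phase.
#' Because the harmonic is exactly 24-periodic, seasonal differencing
#' annihilates it; a linear trend of slope `s` per hour differences to the
#' constant `24 s`.
#'
#' @param config A [synthetic_config()].
#' @param depth Depth in cm.
#' @param variable `"temperature"` or `"moisture"`.
#' @return Tibble with `timestamp` and `value`.
#' @export
compose_deterministic <- function(config, depth,
                                  variable = c("temperature", "moisture")) {
  variable <- arg_match(variable)
  row <- config$profile %>% filter(.data$depth == !!depth)
  if (!nrow(row)) stop_soil("argument", sprintf("depth %s not in profile.", depth))
  n <- config$days * 24L
  hours <- seq_len(n) - 1L
  anchors <- config$trend[[variable]]
  trend <- stats::approx(anchors$day * 24, anchors$value, xout = hours,
                         rule = 2)$y
  base <- if (variable == "temperature") row$temp_base else row$moist_base
  amp <- if (variable == "temperature") row$temp_amp else row$moist_amp
  # deep layers feel a damped version of the seasonal swing
  damp <- exp(-depth / 120)
  value <- base + damp * trend + amp * cos(2 * pi * (hours - row$phase_h) / 24)
  tibble(timestamp = hour_seq(config$start, n), value = value)
}

#' Add irrigation step events to a moisture series
#'
#' Each event adds an instantaneous moisture jump at its hour followed by
#' exponential decay with the configured half-life, applied only to moisture
#' series at the affected depths (drip irrigation wets the upper profile and
#' drains away over days).
#'
#' @param series A `soil_hourly` series.
#' @param events Tibble with `time` (timestamp) or `day` (days after series
#'   start), `jump` (%), `max_depth` (cm), `half_life` (hours).
#' @return The series with events applied (unchanged if none apply).
#' @export
inject_irrigation_events <- function(series, events) {
  if (is.null(events) || !nrow(events)) return(series)
  if (!identical(attr(series, "variable"), "moisture")) return(series)
  value <- series$value
  n <- length(value)
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    if (!is.null(ev$max_depth) && attr(series, "depth") > ev$max_depth) next
    idx <- if (!is.null(ev[["time"]])) {
      as.numeric(difftime(as_hour_posix(ev$time), series$timestamp[1],
                          units = "hours")) + 1
    } else {
      ev$day * 24 + 1
    }
    if (is.na(idx) || idx < 1 || idx > n) {
      stop_soil("range", sprintf("irrigation event %d falls outside the series range.", i))
    }
    tail_idx <- idx:n
    value[tail_idx] <- value[tail_idx] +
      ev$jump * 0.5^((tail_idx - idx) / ev$half_life)
  }
  out <- series
  out$value <- value
  validate_hourly_series(out)
  out
}

# cumulative sum within each of the 24 hour-of-day phases: the discrete
# integral of the period-24 difference operator
seasonal_integrate <- function(v, period = 24L) {
  out <- v
  for (phase in seq_len(min(period, length(v)))) {
    idx <- seq(phase, length(v), by = period)
    out[idx] <- cumsum(v[idx])
  }
  out
}

#' Generate a synthetic coupled soil dataset
#'
#' For each depth: simulate the stationary VAR residual pair, seasonally
#' integrate it (so the period-24 difference of the generated series
#' recovers the VAR process exactly), add the deterministic component, and
#' apply irrigation events to moisture. Regenerating with the same config
#' is bit-identical; per-depth random streams derive from the master seed.
#'
#' @param config A [synthetic_config()].
#' @return A tibble (one row per series; columns `label`, `variable`,
#'   `depth`, `n`, `start`, `series`) of class `soil_synth_dataset`, with
#'   the generating config in the `truth` attribute.
#' @examples
#' ds <- generate_dataset(synthetic_config(days = 20, seed = 7))
#' ds$series[[1]]
#' @export
generate_dataset <- function(config) {
  if (!inherits(config, "soil_synth_config")) {
    stop_soil("argument", "`config` must come from synthetic_config().")
  }
  n <- config$days * 24L
  rows <- purrr::imap_dfr(as.character(config$depths), function(d_chr, rank) {
    d <- as.integer(d_chr)
    sds <- config$innovation_sd[[d_chr]]
    R <- matrix(c(1, config$innovation_cor, config$innovation_cor, 1), 2)
    sigma <- diag(sds) %*% R %*% diag(sds)
    v <- simulate_var(config$var_coeffs[[d_chr]], sigma, n,
                      seed = child_seed(config$seed, rank))
    resid <- apply(v, 2, seasonal_integrate)
    make_one <- function(variable, col) {
      det <- compose_deterministic(config, d, variable)
      s <- hourly_series(det$value + resid[, col], config$start, variable, d)
      inject_irrigation_events(s, config$irrigation_events)
    }
    moist <- make_one("moisture", 1L)
    temp <- make_one("temperature", 2L)
    tibble(label = c(attr(moist, "label"), attr(temp, "label")),
           variable = c("moisture", "temperature"),
           depth = d, n = n, start = config$start,
           series = list(moist, temp))
  })
  new_series_tbl(rows, class = "soil_synth_dataset", truth = config)
}

#' Write a synthetic dataset as a long hourly table
#'
#' Emits the long CSV dialect (`timestamp, depth, variable, value`) that
#' [read_hourly_table()] reads back.
#'
#' @param dataset A [generate_dataset()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_hourly_table <- function(dataset, path) {
  long <- purrr::pmap_dfr(dataset[, c("depth", "variable", "series")],
    function(depth, variable, series) {
      tibble(timestamp = format(series$timestamp, "%Y-%m-%d %H:%M"),
             depth = depth, variable = variable, value = series$value)
    })
  readr::write_csv(long, path)
  invisible(path)
}
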