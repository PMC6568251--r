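#' Construct an hourly soil series
#'
#' An hourly series is one physical variable (soil temperature in degrees
#' Celsius or volumetric soil moisture in percent) observed at one depth on a
#' strict one-hour grid. It is stored as a tibble with `timestamp` and
#' `value` columns plus metadata attributes, so it pipes into dplyr verbs
#' while the constructor and validator enforce the measurement contract:
#' exact hourly spacing, no gaps or duplicates, and values inside the
#' instrument range (moisture in \[0, 100\] %, temperature in \[-20, 60\] degC).
#'
#' @param value Numeric vector of observations at one-hour spacing.
#' @param start Timestamp of the first observation (POSIXct or a string such
#'   as `"2017-12-19 00:00"`); stored time-zone naive (UTC internally) since
#'   only spacing matters downstream.
#' @param variable `"temperature"` or `"moisture"`.
#' @param depth Sensor depth in cm (positive integer).
#' @param label Short identifier, e.g. `"ST10"` or `"MC30"`. Defaults to the
#'   conventional `ST`/`MC` prefix plus depth.
#' @return A tibble of class `soil_hourly` with columns `timestamp`, `value`.
#' @examples
#' x <- hourly_series(20 + sin(2 * pi * (0:71) / 24), "2018-01-01 00:00",
#'                    "temperature", depth = 10)
#' seasonal_difference(x)
#' @export
hourly_series <- function(value, start, variable = c("temperature", "moisture"),
                          depth, label = NULL) {
  variable <- arg_match(variable)
  depth <- check_count(depth, "depth", min = 1L)
  start <- as_hour_posix(start)
  if (length(start) != 1L || is.na(start)) {
    stop_soil("format", "`start` is not a parseable timestamp.")
  }
  value <- as.numeric(value)
  if (is.null(label)) {
    label <- paste0(if (variable == "temperature") "ST" else "MC", depth)
  }
  out <- new_series_tbl(tibble(timestamp = hour_seq(start, length(value)),
                               value = value),
                        class = "soil_hourly",
                        variable = variable, depth = depth, label = label)
  validate_hourly_series(out)
  out
}

new_series_tbl <- function(df, class, ...) {
  out <- as_tibble(df)
  attrs <- list(...)
  for (nm in names(attrs)) attr(out, nm) <- attrs[[nm]]
  class(out) <- c(class, class(out))
  out
}

series_meta <- function(x) {
  list(variable = attr(x, "variable"), depth = attr(x, "depth"),
       label = attr(x, "label"), period = attr(x, "period"))
}

instrument_range <- function(variable) {
  switch(variable, moisture = c(0, 100), temperature = c(-20, 60))
}

validate_hourly_series <- function(x) {
  if (any(is.na(x$value))) {
    stop_soil("format", sprintf("series '%s' contains missing values.",
                                attr(x, "label")))
  }
  steps <- diff(as.numeric(x$timestamp))
  if (length(steps) && any(steps != 3600)) {
    bad <- which(steps != 3600)[1]
    if (steps[bad] <= 0) {
      stop_soil("duplicate", sprintf(
        "series '%s' has a duplicate or out-of-order timestamp at %s.",
        attr(x, "label"), format(x$timestamp[bad + 1], "%Y-%m-%d %H:%M")))
    }
    missing_at <- x$timestamp[bad] + 3600
    stop_soil("gap", sprintf("series '%s' has a gap: hour %s is missing.",
                             attr(x, "label"),
                             format(missing_at, "%Y-%m-%d %H:%M")))
  }
  rng <- instrument_range(attr(x, "variable"))
  if (any(x$value < rng[1] | x$value > rng[2])) {
    stop_soil("format", sprintf(
      "series '%s' has values outside the instrument range [%g, %g].",
      attr(x, "label"), rng[1], rng[2]))
  }
  invisible(x)
}

#' Read hourly soil series from a delimited text table
#'
#' Accepts the two dialects in which station exports commonly arrive: long
#' (one row per timestamp/depth/variable/value) and wide (a timestamp column
#' plus one column per labelled series such as `ST10`, `MC30`, or their
#' deseasonalized counterparts `STSD10`, `MCSD30`). The hourly-grid contract
#' is enforced on read: a missing hour raises a `gap` error naming the first
#' missing timestamp, a repeated timestamp raises a `duplicate` error, and an
#' unparseable value raises a `format` error with its row number.
#'
#' @param path Path to a CSV or TSV file (UTF-8, decimal point; ISO-8601
#'   timestamps or `"YYYY-MM-DD HH:MM"`).
#' @param col_map Named list resolving the required roles for long tables:
#'   `timestamp`, `depth`, `variable`, `value` (values are column names in
#'   the file). For wide tables only `timestamp` is used.
#' @param format `"auto"` (default), `"long"`, or `"wide"`.
#' @param already_deseasonalized If `TRUE`, columns are treated as series
#'   that were already seasonally differenced (period 24); they bypass
#'   [seasonal_difference()] and are returned as deseasonalized series.
#' @param interpolate_gaps If `TRUE`, interior gaps of at most `max_gap`
#'   consecutive missing hours are filled by linear interpolation (and
#'   reported); longer gaps still error.
#' @param max_gap Longest gap (hours) the interpolator may bridge.
#' @return A tibble (one row per series) with columns `label`, `variable`,
#'   `depth`, `n`, `start`, and a `series` list-column of
#'   `soil_hourly`/`soil_deseason` objects.
#' @export
read_hourly_table <- function(path,
                              col_map = list(timestamp = "timestamp",
                                             depth = "depth",
                                             variable = "variable",
                                             value = "value"),
                              format = c("auto", "long", "wide"),
                              already_deseasonalized = FALSE,
                              interpolate_gaps = FALSE, max_gap = 2L) {
  format <- arg_match(format)
  if (!file.exists(path)) stop_soil("format", sprintf("file '%s' not found.", path))
  delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, comment = "#",
                           col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE, show_col_types = FALSE)
  if (format == "auto") {
    long_roles <- unlist(col_map[c("depth", "variable", "value")])
    format <- if (all(long_roles %in% names(raw))) "long" else "wide"
  }
  if (format == "long") {
    series_list <- parse_long_table(raw, col_map, already_deseasonalized,
                                    interpolate_gaps, max_gap)
  } else {
    series_list <- parse_wide_table(raw, col_map, already_deseasonalized,
                                    interpolate_gaps, max_gap)
  }
  tibble(
    label = purrr::map_chr(series_list, ~ attr(.x, "label")),
    variable = purrr::map_chr(series_list, ~ attr(.x, "variable")),
    depth = purrr::map_int(series_list, ~ as.integer(attr(.x, "depth"))),
    n = purrr::map_int(series_list, nrow),
    start = as.POSIXct(purrr::map_dbl(series_list, ~ as.numeric(.x$timestamp[1])),
                       origin = "1970-01-01", tz = "UTC"),
    series = series_list
  )
}

parse_value_column <- function(chr, what) {
  val <- suppressWarnings(as.numeric(chr))
  bad <- which(is.na(val) & !is.na(chr) & chr != "")
  if (length(bad)) {
    stop_soil("format", sprintf("unparseable %s '%s' at row %d.",
                                what, chr[bad[1]], bad[1]))
  }
  if (anyNA(val)) {
    stop_soil("format", sprintf("missing %s at row %d.", what, which(is.na(val))[1]))
  }
  val
}

parse_timestamp_column <- function(chr) {
  ts <- as_hour_posix(chr)
  bad <- which(is.na(ts))
  if (length(bad)) {
    stop_soil("format", sprintf("unparseable timestamp '%s' at row %d.",
                                chr[bad[1]], bad[1]))
  }
  ts
}

parse_long_table <- function(raw, col_map, deseason, interpolate, max_gap) {
  need <- unlist(col_map[c("timestamp", "depth", "variable", "value")])
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    stop_soil("format", sprintf("long table lacks column(s): %s.",
                                paste(missing_cols, collapse = ", ")))
  }
  df <- tibble(
    timestamp = parse_timestamp_column(raw[[col_map$timestamp]]),
    depth = as.integer(parse_value_column(raw[[col_map$depth]], "depth")),
    variable = normalize_variable(raw[[col_map$variable]]),
    value = parse_value_column(raw[[col_map$value]], "value")
  )
  groups <- df %>% distinct(.data$variable, .data$depth) %>%
    arrange(.data$variable, .data$depth)
  purrr::pmap(groups, function(variable, depth) {
    sub <- df %>% filter(.data$variable == !!variable, .data$depth == !!depth) %>%
      arrange(.data$timestamp)
    build_series(sub$timestamp, sub$value, variable, depth,
                 label = default_label(variable, depth, deseason),
                 deseason = deseason, interpolate = interpolate, max_gap = max_gap)
  })
}

parse_wide_table <- function(raw, col_map, deseason, interpolate, max_gap) {
  ts_col <- col_map$timestamp %||% "timestamp"
  if (!ts_col %in% names(raw)) {
    ts_col <- names(raw)[1]
  }
  ts <- parse_timestamp_column(raw[[ts_col]])
  value_cols <- setdiff(names(raw), ts_col)
  if (!length(value_cols)) stop_soil("format", "wide table has no series columns.")
  ord <- order(ts)
  purrr::map(value_cols, function(nm) {
    info <- parse_series_label(nm)
    build_series(ts[ord], parse_value_column(raw[[nm]], "value")[ord],
                 info$variable, info$depth, label = nm,
                 deseason = deseason || info$deseason,
                 interpolate = interpolate, max_gap = max_gap)
  })
}

normalize_variable <- function(x) {
  x <- tolower(trimws(x))
  out <- dplyr::case_when(
    x %in% c("temperature", "temp", "st", "soil_temperature") ~ "temperature",
    x %in% c("moisture", "mc", "soil_moisture", "water", "vwc") ~ "moisture",
    TRUE ~ NA_character_
  )
  if (anyNA(out)) {
    stop_soil("format", sprintf("unrecognized variable name '%s' at row %d.",
                                x[which(is.na(out))[1]], which(is.na(out))[1]))
  }
  out
}

parse_series_label <- function(label) {
  m <- regmatches(label, regexec("^(MCSD|STSD|MC|ST)([0-9]+)$", label))[[1]]
  if (!length(m)) {
    stop_soil("format", sprintf(
      "cannot infer variable/depth from column '%s'; use the long dialect or ST/MC[SD]<depth> names.",
      label))
  }
  list(variable = if (startsWith(m[2], "MC")) "moisture" else "temperature",
       depth = as.integer(m[3]),
       deseason = grepl("SD", m[2], fixed = TRUE))
}

default_label <- function(variable, depth, deseason) {
  paste0(if (variable == "temperature") "ST" else "MC",
         if (deseason) "SD" else "", depth)
}

build_series <- function(ts, value, variable, depth, label, deseason,
                         interpolate, max_gap) {
  dup <- which(duplicated(ts))
  if (length(dup)) {
    stop_soil("duplicate", sprintf("series '%s' has a duplicate timestamp at %s.",
                                   label, format(ts[dup[1]], "%Y-%m-%d %H:%M")))
  }
  full <- hour_seq(ts[1], as.numeric(difftime(ts[length(ts)], ts[1], units = "hours")) + 1)
  if (length(full) != length(ts)) {
    missing_idx <- which(!full %in% ts)
    runs <- split(missing_idx, cumsum(c(1, diff(missing_idx) != 1)))
    too_long <- !interpolate || any(lengths(runs) > max_gap)
    if (too_long) {
      stop_soil("gap", sprintf("series '%s' has a gap: hour %s is missing.",
                               label,
                               format(full[missing_idx[1]], "%Y-%m-%d %H:%M")))
    }
    filled <- stats::approx(as.numeric(ts), value, xout = as.numeric(full))$y
    rlang::inform(sprintf(
      "series '%s': linearly interpolated %d missing hour(s) in %d run(s).",
      label, length(missing_idx), length(runs)))
    ts <- full
    value <- filled
  }
  if (deseason) {
    new_series_tbl(tibble(timestamp = ts, value = value),
                   class = "soil_deseason", variable = variable,
                   depth = as.integer(depth), label = label, period = 24L,
                   parent_head = NULL, parent_label = NA_character_)
  } else {
    hourly_series(value, ts[1], variable, depth, label)
  }
}

#' Remove the diurnal cycle by seasonal differencing
#'
#' Computes the period-`S` seasonal difference `y[t] = x[t] - x[t - S]`
#' (default `S = 24` hours), the transform that removes a repeating daily
#' pattern from hourly environmental series and yields the stationary-ish
#' substrate on which unit-root tests and vector autoregressions operate.
#' The first `S` parent values are retained as an attribute so the parent
#' series can be reconstructed exactly with [reconstruct_series()].
#'
#' @param series A [hourly_series()] object (or plain numeric vector).
#' @param period Seasonal period in hours; 24 for a diurnal cycle.
#' @return A tibble of class `soil_deseason`, `period` hours shorter than the
#'   parent and starting `period` hours later.
#' @export
seasonal_difference <- function(series, period = 24L) {
  period <- check_count(period, "period", min = 1L)
  if (is.numeric(series)) {
    series <- tibble(timestamp = hour_seq(as_hour_posix("2000-01-01 00:00"),
                                          length(series)),
                     value = as.numeric(series))
    attr(series, "variable") <- "temperature"
    attr(series, "depth") <- 1L
    attr(series, "label") <- "x"
  }
  n <- nrow(series)
  if (n <= period) {
    stop_soil("too-short", sprintf(
      "series '%s' has %d observations; need more than period = %d.",
      attr(series, "label") %||% "x", n, period))
  }
  x <- series$value
  y <- x[(period + 1L):n] - x[seq_len(n - period)]
  label <- deseason_label(attr(series, "label"))
  new_series_tbl(tibble(timestamp = series$timestamp[(period + 1L):n], value = y),
                 class = "soil_deseason",
                 variable = attr(series, "variable"),
                 depth = attr(series, "depth"),
                 label = label, period = period,
                 parent_head = x[seq_len(period)],
                 parent_label = attr(series, "label"))
}

deseason_label <- function(label) {
  if (is.null(label)) return("xSD")
  m <- regexec("^(MC|ST)([0-9]+)$", label)[[1]]
  if (m[1] > 0) sub("^(MC|ST)", "\\1SD", label) else paste0(label, "SD")
}

#' Rebuild the parent hourly series from a seasonal difference
#'
#' Inverts [seasonal_difference()] using the retained first `period` parent
#' values: `x[t] = y[t] + x[t - period]`.
#'
#' @param deseason A `soil_deseason` produced by [seasonal_difference()].
#' @return The parent `soil_hourly` series, exactly.
#' @export
reconstruct_series <- function(deseason) {
  head_vals <- attr(deseason, "parent_head")
  if (is.null(head_vals)) {
    stop_soil("format",
              "series was ingested already deseasonalized; parent values unavailable.")
  }
  period <- attr(deseason, "period")
  x <- c(head_vals, rep(NA_real_, nrow(deseason)))
  for (t in seq_len(nrow(deseason))) {
    x[period + t] <- deseason$value[t] + x[t]
  }
  hourly_series(x, deseason$timestamp[1] - 3600 * period,
                attr(deseason, "variable"), attr(deseason, "depth"),
                attr(deseason, "parent_label"))
}

#' Align two deseasonalized series on their common hours
#'
#' Restricts both series to the intersection of their timestamp ranges so
#' they form a strictly paired bivariate sample for VAR fitting and Granger
#' testing.
#'
#' @param a,b `soil_deseason` series with the same period.
#' @return A tibble of class `soil_pair` with columns `timestamp` and one
#'   value column per series (named by label).
#' @export
align_pair <- function(a, b) {
  pa <- attr(a, "period") %||% 24L
  pb <- attr(b, "period") %||% 24L
  if (pa != pb) stop_soil("argument", "series have different seasonal periods.")
  la <- attr(a, "label") %||% "x"
  lb <- attr(b, "label") %||% "y"
  if (identical(la, lb)) lb <- paste0(lb, ".2")
  common <- intersect(as.numeric(a$timestamp), as.numeric(b$timestamp))
  if (!length(common)) {
    stop_soil("disjoint", sprintf("series '%s' and '%s' share no timestamps.", la, lb))
  }
  common <- sort(common)
  out <- tibble(timestamp = as.POSIXct(common, origin = "1970-01-01", tz = "UTC"))
  out[[la]] <- a$value[match(common, as.numeric(a$timestamp))]
  out[[lb]] <- b$value[match(common, as.numeric(b$timestamp))]
  new_series_tbl(out, class = "soil_pair",
                 labels = c(la, lb),
                 variables = c(attr(a, "variable") %||% NA_character_,
                               attr(b, "variable") %||% NA_character_),
                 depth = attr(a, "depth") %||% attr(b, "depth"),
                 period = pa)
}

# numeric T x 2 matrix view of a pair (labels preserved as colnames)
pair_matrix <- function(pair) {
  if (inherits(pair, "soil_pair")) {
    m <- as.matrix(pair[, attr(pair, "labels"), drop = FALSE])
  } else if (is.matrix(pair)) {
    m <- pair
    if (is.null(colnames(m))) colnames(m) <- paste0("y", seq_len(ncol(m)))
  } else {
    stop_soil("argument", "expected a soil_pair or a numeric matrix.")
  }
  storage.mode(m) <- "double"
  m
}

#' Write a deseasonalized series as two-column CSV
#'
#' Emits `timestamp,value` rows preceded by a `#` comment recording the
#' parent label and differencing period, the same dialect
#' [read_hourly_table()] reads back.
#'
#' @param deseason A `soil_deseason`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_deseasonalized <- function(deseason, path) {
  header <- sprintf("# label: %s; parent: %s; period: %d",
                    attr(deseason, "label"),
                    attr(deseason, "parent_label") %||% "NA",
                    attr(deseason, "period") %||% 24L)
  writeLines(header, path)
  readr::write_csv(
    tibble(timestamp = format(deseason$timestamp, "%Y-%m-%d %H:%M"),
           value = deseason$value),
    path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @export
print.soil_hourly <- function(x, ...) {
  cat(sprintf("<hourly series '%s': %s at %d cm, %d hours from %s>\n",
              attr(x, "label"), attr(x, "variable"), attr(x, "depth"),
              nrow(x), format(x$timestamp[1], "%Y-%m-%d %H:%M")))
  NextMethod()
}

#' @export
print.soil_deseason <- function(x, ...) {
  cat(sprintf("<deseasonalized series '%s' (period %d h): %d values from %s>\n",
              attr(x, "label"), attr(x, "period") %||% 24L,
              nrow(x), format(x$timestamp[1], "%Y-%m-%d %H:%M")))
  NextMethod()
}
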