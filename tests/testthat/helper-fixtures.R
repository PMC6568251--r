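# Shared fixtures, all generated in code at test time.

# a small stable bivariate VAR used across modules
fixture_phi <- function() {
  list(matrix(c(0.5, 0.1, 0.2, 0.4), 2, byrow = TRUE),
       matrix(c(0.2, -0.1, 0.05, 0.1), 2, byrow = TRUE))
}

fixture_sigma <- function(rho = 0.3) {
  matrix(c(1, rho, rho, 1), 2)
}

# write a long-dialect hourly CSV and return its path
write_long_csv <- function(df, path = tempfile(fileext = ".csv")) {
  readr::write_csv(df, path)
  path
}

long_table <- function(n = 48, start = "2018-01-01 00:00",
                       variable = "temperature", depth = 10,
                       values = NULL) {
  ts <- seq(as.POSIXct(start, tz = "UTC"), by = "hour", length.out = n)
  tibble::tibble(
    timestamp = format(ts, "%Y-%m-%d %H:%M"),
    depth = depth, variable = variable,
    value = values %||% round(10 + sin(2 * pi * seq_len(n) / 24), 3))
}

`%||%` <- rlang::`%||%`
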