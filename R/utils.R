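# Classed conditions: every error the package raises carries a short
# machine-readable class ("gap", "duplicate", "format", ...) so callers and
# tests can dispatch on the failure mode rather than on message text.
stop_soil <- function(class, message, ...) {
  rlang::abort(message, class = paste0("soilcoupling_error_", class), ...)
}

warn_soil <- function(class, message, ...) {
  rlang::warn(message, class = paste0("soilcoupling_warning_", class), ...)
}

# scalar checks -------------------------------------------------------------

check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) || x < min) {
    stop_soil("argument", sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  as.integer(x)
}

check_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max) {
    stop_soil("argument", sprintf("`%s` must be a single number in [%s, %s].",
                                  name, format(min), format(max)))
  }
  as.numeric(x)
}

# Derive a child seed from a base seed and a stream index, kept inside the
# 32-bit integer range R's RNG accepts.
child_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 1000003 + stream * 7919) %% 2147483647)
}

# hour grid helpers ----------------------------------------------------------

as_hour_posix <- function(x) {
  if (inherits(x, "POSIXct")) return(as.POSIXct(format(x, tz = "UTC"), tz = "UTC"))
  x <- as.character(x)
  out <- as.POSIXct(x, tz = "UTC",
                    tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%dT%H:%M",
                                   "%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M",
                                   "%Y/%m/%d %H:%M", "%Y-%m-%d"))
  out
}

hour_seq <- function(start, length_out) {
  start + 3600 * (seq_len(length_out) - 1L)
}

is_psd <- function(sigma, tol = 1e-10) {
  if (!isTRUE(all.equal(sigma, t(sigma), tolerance = 1e-8))) return(FALSE)
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  all(ev > -tol * max(1, abs(ev[1])))
}
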