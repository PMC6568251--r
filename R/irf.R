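#' Moving-average coefficients of a VAR
#'
#' For a stable VAR the process has an infinite moving-average expansion
#' `y_t = sum_i Psi_i e_{t-i}` whose coefficient matrices obey the
#' recursion `Psi_0 = I`, `Psi_i = sum_{s=1..min(i,p)} Phi_s Psi_{i-s}`.
#' All impulse-response schemes are linear transforms of these matrices.
#'
#' @param model A fitted `soil_var` (or any object carrying `coeffs`).
#' @param H Largest horizon (hours).
#' @return List of `H + 1` matrices, `Psi[[i + 1]]` being the horizon-`i`
#'   coefficient.
#' @export
ma_coefficients <- function(model, H) {
  H <- check_count(H, "H", min = 0L)
  phis <- coeff_list(model)
  m <- nrow(phis[[1]])
  p <- length(phis)
  Psi <- vector("list", H + 1L)
  Psi[[1]] <- diag(m)
  for (i in seq_len(H)) {
    acc <- matrix(0, m, m)
    for (s in seq_len(min(i, p))) {
      acc <- acc + phis[[s]] %*% Psi[[i - s + 1L]]
    }
    Psi[[i + 1L]] <- acc
  }
  Psi
}

irf_schemes <- c("generalized", "cholesky", "reduced")

#' Unit-shock impulse-response functions
#'
#' Computes the response of every variable at horizons `0..H` to a one-unit
#' positive shock in each variable, under one of three identification
#' schemes:
#' \describe{
#'   \item{`"reduced"`}{unit shocks to the reduced-form errors;
#'     `phi(i) = Psi_i`, so cross-responses are zero at horizon 0.}
#'   \item{`"cholesky"`}{orthogonalized shocks from the lower Cholesky
#'     factor of the residual covariance, rescaled so each variable's own
#'     contemporaneous response is one unit; depends on variable order.}
#'   \item{`"generalized"` (default)}{order-invariant shocks through the
#'     residual covariance: column `k` is `Psi_i Sigma e_k / sigma_kk`, the
#'     expected response to a one-unit shock in variable `k` given the
#'     correlation between innovations. Both contemporaneous
#'     cross-responses can be nonzero, which is what correlated
#'     moisture-temperature innovations produce in the field.}
#' }
#' Response units follow the variables: a moisture response to a
#' temperature shock is percent per degree Celsius, and vice versa.
#'
#' @param model A fitted `soil_var` (for `"reduced"` a coefficient-only
#'   object suffices).
#' @param scheme Identification scheme.
#' @param H Largest horizon in hours (default 120).
#' @param epsilon_frac Threshold fraction of the intensity used by the
#'   time-lag summary (see [response_time_lag()]).
#' @return Object of class `soil_irf`: `responses` array of dim
#'   `(H + 1, m, m)` (`[i + 1, j, k]` = response of variable `j` at horizon
#'   `i` to a unit shock in `k`), `scheme`, `horizon`, `labels`,
#'   `intensity` and `time_lag` matrices, and optionally `bands` (see
#'   [bootstrap_bands()]).
#' @export
unit_shock_irf <- function(model, scheme = irf_schemes, H = 120L,
                           epsilon_frac = 0.05) {
  scheme <- arg_match(scheme)
  H <- check_count(H, "H", min = 0L)
  phis <- coeff_list(model)
  m <- nrow(phis[[1]])
  labels <- model$labels %||% paste0("y", seq_len(m))
  stab <- stability_check(model)
  if (!stab$stable) {
    warn_soil("unstable", sprintf(
      "model is not stable (max |eigenvalue| = %.3f); responses will not decay.",
      stab$moduli[1]))
  }
  Wk <- diag(m)
  if (scheme != "reduced") {
    sigma <- model$sigma
    if (is.null(sigma) || !is_psd(sigma) ||
        any(diag(sigma) <= 0) || det(sigma) <= 0) {
      stop_soil("degenerate",
                "a positive-definite residual covariance is required for this scheme.")
    }
    Wk <- if (scheme == "cholesky") {
      P <- t(chol(sigma))
      P %*% diag(1 / diag(P), m)
    } else {
      sigma %*% diag(1 / diag(sigma), m)
    }
  }
  Psi <- ma_coefficients(model, H)
  responses <- array(0, dim = c(H + 1L, m, m),
                     dimnames = list(NULL, labels, labels))
  for (i in 0:H) {
    responses[i + 1L, , ] <- Psi[[i + 1L]] %*% Wk
  }
  out <- structure(list(scheme = scheme, horizon = H, labels = labels,
                        responses = responses, bands = NULL,
                        epsilon_frac = epsilon_frac),
                   class = "soil_irf")
  out$intensity <- summary_matrix(out, response_intensity)
  out$time_lag <- summary_matrix(out, function(irf, j, k)
    response_time_lag(irf, j, k, epsilon_frac))
  out
}

summary_matrix <- function(irf, f) {
  m <- length(irf$labels)
  out <- matrix(0, m, m, dimnames = list(irf$labels, irf$labels))
  for (j in seq_len(m)) for (k in seq_len(m)) out[j, k] <- f(irf, j, k)
  out
}

resolve_index <- function(irf, idx, name) {
  if (is.character(idx)) {
    pos <- match(idx, irf$labels)
    if (is.na(pos)) stop_soil("argument", sprintf("unknown %s '%s'.", name, idx))
    return(pos)
  }
  check_count(idx, name, min = 1L)
}

#' Cumulative impulse response
#'
#' Partial sum of the response of variable `j` to a unit shock in `k` over
#' horizons `0..n` — the accumulated deviation caused by the shock.
#'
#' @param irf A `soil_irf`.
#' @param j,k Responding and shocked variable (index or label).
#' @param n Last horizon included (`n <= H`).
#' @return A scalar.
#' @export
cumulative_response <- function(irf, j, k, n = irf$horizon) {
  j <- resolve_index(irf, j, "j"); k <- resolve_index(irf, k, "k")
  n <- check_count(n, "n", min = 0L)
  if (n > irf$horizon) stop_soil("argument", "`n` exceeds the computed horizon.")
  sum(irf$responses[seq_len(n + 1L), j, k])
}

#' Impulse-response intensity
#'
#' The gap between the largest positive and largest negative response value
#' over the computed horizons, with each extreme clamped at zero:
#' `max(0, max_i phi(i)) - min(0, min_i phi(i))`. A one-signed response
#' curve therefore has intensity equal to its largest absolute value. Units
#' are those of the responding variable per unit shock.
#'
#' @inheritParams cumulative_response
#' @return A nonnegative scalar.
#' @export
response_intensity <- function(irf, j, k) {
  j <- resolve_index(irf, j, "j"); k <- resolve_index(irf, k, "k")
  curve <- irf$responses[, j, k]
  max(0, max(curve)) - min(0, min(curve))
}

#' Impulse-response time lag
#'
#' The persistence summary: the smallest horizon `i*` from which the
#' response stays within `epsilon_frac` of its intensity of zero for all
#' remaining computed horizons, operationalizing "the response approximates
#' zero". Returns 0 for an identically zero curve and `H + 1` (flagged with
#' attribute `censored = TRUE`) when the response has not settled by the
#' last computed horizon.
#'
#' @inheritParams cumulative_response
#' @param epsilon_frac Threshold as a fraction of the intensity.
#' @return Integer horizon (hours), possibly with attribute `censored`.
#' @export
response_time_lag <- function(irf, j, k, epsilon_frac = 0.05) {
  j <- resolve_index(irf, j, "j"); k <- resolve_index(irf, k, "k")
  epsilon_frac <- check_number(epsilon_frac, "epsilon_frac", min = 0)
  curve <- irf$responses[, j, k]
  intensity <- max(0, max(curve)) - min(0, min(curve))
  if (intensity == 0) return(0L)
  ok <- abs(curve) <= epsilon_frac * intensity
  # last run of consecutive TRUE reaching the end
  if (!ok[length(ok)]) {
    return(structure(irf$horizon + 1L, censored = TRUE))
  }
  first_bad_from_end <- max(c(0L, which(!ok)))
  as.integer(first_bad_from_end)   # horizons are 0-based: index i+1 -> horizon i
}

#' Residual-bootstrap confidence bands for impulse responses
#'
#' Nonparametric residual resampling: fitted residuals are re-drawn with
#' replacement, a bootstrap series is rebuilt from the fitted model, the VAR
#' is refit at the same order, and its impulse responses recomputed.
#' Percentile bands are taken pointwise per (response, shock, horizon).
#' Bootstrap refits that are themselves unstable are discarded (with a
#' `fragile` warning when more than 20% are).
#'
#' @inheritParams unit_shock_irf
#' @param level Band coverage (default 0.90).
#' @param B Number of bootstrap replicates (>= 100 recommended).
#' @param seed Integer seed; the bands are deterministic given it.
#' @return The point `soil_irf` with a `bands` element: `level`, `lower`
#'   and `upper` arrays shaped like `responses`, `B_used`, `discarded`.
#' @export
bootstrap_bands <- function(model, scheme = irf_schemes, H = 120L,
                            level = 0.90, B = 1000L, seed = NULL,
                            epsilon_frac = 0.05) {
  scheme <- arg_match(scheme)
  level <- check_number(level, "level", min = 0.5, max = 0.999)
  B <- check_count(B, "B", min = 2L)
  if (!inherits(model, "soil_var")) {
    stop_soil("argument", "bootstrap bands need a fitted `soil_var`.")
  }
  irf <- unit_shock_irf(model, scheme, H, epsilon_frac = epsilon_frac)
  if (!is.null(seed)) withr::local_seed(seed)
  E <- sweep(model$residuals, 2, colMeans(model$residuals))   # recentre
  Y <- model$data
  n <- model$n
  draws <- array(NA_real_, dim = c(B, dim(irf$responses)))
  discarded <- 0L
  for (b in seq_len(B)) {
    Eb <- E[sample.int(n, n, replace = TRUE), , drop = FALSE]
    Yb <- rebuild_var_series(model, Eb)
    fit_b <- fit_var(Yb, model$p, intercept = !is.null(model$intercept),
                     trim = model$trim)
    if (!stability_check(fit_b)$stable) {
      discarded <- discarded + 1L
      next
    }
    draws[b, , , ] <- unit_shock_irf(fit_b, scheme, H)$responses
  }
  if (discarded > 0.2 * B) {
    warn_soil("fragile", sprintf(
      "%d of %d bootstrap refits were unstable and discarded; bands are fragile.",
      discarded, B))
  }
  alpha <- (1 - level) / 2
  lower <- apply(draws, c(2, 3, 4), quantile, probs = alpha, na.rm = TRUE)
  upper <- apply(draws, c(2, 3, 4), quantile, probs = 1 - alpha, na.rm = TRUE)
  dimnames(lower) <- dimnames(upper) <- dimnames(irf$responses)
  irf$bands <- list(level = level, lower = lower, upper = upper,
                    B_used = B - discarded, discarded = discarded)
  irf
}

# Rebuild a series from the fitted model and an innovation matrix, keeping
# the original presample rows as initial conditions.
rebuild_var_series <- function(model, innov) {
  Y <- model$data
  p <- model$p
  trim <- model$trim
  out <- Y
  for (t in seq_len(nrow(innov))) {
    row <- trim + t
    acc <- innov[t, ]
    for (s in seq_len(p)) {
      acc <- acc + model$coeffs[[s]] %*% out[row - s, ]
    }
    if (!is.null(model$intercept)) acc <- acc + model$intercept
    out[row, ] <- acc
  }
  out
}

#' @export
print.soil_irf <- function(x, ...) {
  cat(sprintf("Impulse responses (%s scheme), horizons 0..%d on (%s)\n",
              x$scheme, x$horizon, paste(x$labels, collapse = ", ")))
  cat("Intensity matrix (row responds to a unit shock in column):\n")
  print(round(x$intensity, 4))
  cat("Time-lag matrix (hours):\n")
  print(x$time_lag)
  invisible(x)
}

#' @rdname unit_shock_irf
#' @param x A `soil_irf` object.
#' @param ... Unused.
#' @export
tidy.soil_irf <- function(x, ...) {
  m <- length(x$labels)
  out <- tidyr::expand_grid(shock = x$labels, response = x$labels,
                            horizon = 0:x$horizon) %>%
    mutate(value = purrr::pmap_dbl(
      list(.data$horizon, .data$response, .data$shock),
      function(h, j, k) x$responses[h + 1L, j, k]))
  if (!is.null(x$bands)) {
    out <- out %>% mutate(
      lower = purrr::pmap_dbl(list(.data$horizon, .data$response, .data$shock),
                              function(h, j, k) x$bands$lower[h + 1L, j, k]),
      upper = purrr::pmap_dbl(list(.data$horizon, .data$response, .data$shock),
                              function(h, j, k) x$bands$upper[h + 1L, j, k]))
  }
  out %>% select("response", "shock", "horizon", dplyr::everything())
}

#' Plot impulse-response curves
#'
#' One panel per (response, shock) combination: solid point estimate, zero
#' reference line, and dashed percentile bands when present.
#'
#' @param object A `soil_irf`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.soil_irf <- function(object, ...) {
  df <- tidy(object) %>%
    mutate(panel = paste0(.data$response, " to shock in ", .data$shock))
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$horizon, y = .data$value)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60", linewidth = 0.3) +
    ggplot2::geom_line(colour = "#2166ac") +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::labs(x = "horizon (hours)", y = "response per unit shock",
                  title = sprintf("Impulse responses (%s scheme)", object$scheme)) +
    ggplot2::theme_minimal()
  if (!is.null(object$bands)) {
    gg <- gg +
      ggplot2::geom_line(ggplot2::aes(y = .data$lower), linetype = "dashed",
                         colour = "#b2182b") +
      ggplot2::geom_line(ggplot2::aes(y = .data$upper), linetype = "dashed",
                         colour = "#b2182b")
  }
  gg
}

#' Plot the companion eigenvalues against the unit circle
#'
#' @param object A `soil_stability`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.soil_stability <- function(object, ...) {
  circ <- tibble(theta = seq(0, 2 * pi, length.out = 361)) %>%
    mutate(re = cos(.data$theta), im = sin(.data$theta))
  pts <- tibble(re = Re(object$eigenvalues), im = Im(object$eigenvalues))
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$re, y = .data$im)) +
    ggplot2::geom_path(data = circ, colour = "grey50") +
    ggplot2::geom_point(colour = "#2166ac", size = 2) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Re", y = "Im",
                  title = sprintf("Companion eigenvalues (max modulus %.3f)",
                                  object$moduli[1])) +
    ggplot2::theme_minimal()
}
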