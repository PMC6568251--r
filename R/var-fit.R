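#' Fit a bivariate VAR(p) by conditional Gaussian maximum likelihood
#'
#' Estimates `y_t = c + Phi_1 y_{t-1} + ... + Phi_p y_{t-p} + e_t` by
#' equation-wise least squares on the common regressor set, which is the
#' conditional Gaussian ML estimator. The residual covariance uses the ML
#' divisor `n` (not `n - k`), so the maximized log-likelihood has the closed
#' form `-(n/2) (m log 2pi + log det Sigma + m)`.
#'
#' @param pair A `soil_pair` from [align_pair()] or a numeric T x m matrix.
#' @param p Lag order (>= 1).
#' @param intercept Include an intercept vector (default `TRUE`).
#' @param trim Number of initial observations reserved as presample
#'   (default `p`); pass `p_max` to make likelihoods comparable across
#'   lag orders.
#' @return Object of class `soil_var`: lag matrices `coeffs` (row =
#'   equation), `intercept`, ML residual covariance `sigma`, residuals,
#'   fitted sample size `n`, `loglik`, variable `labels`, and the data
#'   matrix used.
#' @examples
#' sim <- simulate_var(list(matrix(c(0.5, 0, 0.1, 0.3), 2)),
#'                     sigma = diag(2), n = 400, seed = 1)
#' fit_var(sim, p = 1)
#' @export
fit_var <- function(pair, p, intercept = TRUE, trim = p) {
  if (!is.numeric(p) || length(p) != 1L || p < 1 || p != round(p)) {
    stop_soil("order", "`p` must be an integer lag order >= 1.")
  }
  p <- as.integer(p)
  trim <- check_count(trim, "trim", min = p)
  Y <- pair_matrix(pair)
  m <- ncol(Y)
  Tn <- nrow(Y)
  n <- Tn - trim
  if (n <= m * p + 1L) {
    stop_soil("insufficient-data",
              sprintf("need more than m*p + 1 = %d fitted rows; have %d.",
                      m * p + 1L, n))
  }
  rows <- (trim + 1L):Tn
  X <- do.call(cbind, lapply(seq_len(p), function(s) Y[rows - s, , drop = FALSE]))
  if (intercept) X <- cbind(1, X)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    stop_soil("collinear", "VAR regressor matrix is rank deficient.")
  }
  B <- qr.coef(qr_x, Y[rows, , drop = FALSE])       # (const + m*p) x m
  E <- Y[rows, , drop = FALSE] - X %*% B
  sigma <- crossprod(E) / n
  labels <- colnames(Y)
  dimnames(sigma) <- list(labels, labels)
  off <- if (intercept) 1L else 0L
  coeffs <- lapply(seq_len(p), function(s) {
    Phi <- t(B[off + (s - 1L) * m + seq_len(m), , drop = FALSE])
    dimnames(Phi) <- list(labels, labels)
    Phi
  })
  model <- structure(list(
    m = m, p = p,
    intercept = if (intercept) setNames(as.numeric(B[1L, ]), labels) else NULL,
    coeffs = coeffs, sigma = sigma, n = n,
    residuals = unname(E), labels = labels,
    data = Y, trim = trim
  ), class = "soil_var")
  model$loglik <- gaussian_loglik(model)
  model
}

#' Maximized Gaussian log-likelihood of a fitted VAR
#'
#' With the ML covariance (residual cross-product divided by `n`), the
#' quadratic term collapses to `n * m` and the log-likelihood is
#' `-(n/2) (m log 2pi + log det Sigma + m)`.
#'
#' @param model A `soil_var`.
#' @return The log-likelihood (a scalar).
#' @export
gaussian_loglik <- function(model) {
  ld <- determinant(model$sigma, logarithm = TRUE)
  if (ld$sign <= 0 || !is.finite(ld$modulus)) {
    stop_soil("degenerate", "residual covariance is singular.")
  }
  -(model$n / 2) * (model$m * log(2 * pi) + as.numeric(ld$modulus) + model$m)
}

#' Akaike and Bayesian information criteria
#'
#' `AIC = 2k - 2 loglik` and `BIC = log(n) k - 2 loglik`, with
#' `k = m (m p + 1)` parameters (intercept plus lag coefficients; the
#' residual covariance is excluded from the count).
#'
#' @param loglik Maximized log-likelihood.
#' @param p Lag order.
#' @param m Number of variables (2 for the bivariate pipeline).
#' @param n Observation count entering the BIC penalty.
#' @return One-row tibble with `k`, `aic`, `bic`.
#' @export
information_criteria <- function(loglik, p, m = 2L, n) {
  p <- check_count(p, "p", min = 1L)
  m <- check_count(m, "m", min = 1L)
  n <- check_number(n, "n", min = 1 + 1e-9)
  k <- m * (m * p + 1)
  tibble(k = k, aic = 2 * k - 2 * loglik, bic = log(n) * k - 2 * loglik)
}

#' Lag-order selection table
#'
#' Fits the VAR at every order `p = 1..p_max` on the same trimmed sample
#' (the first `p_max` observations are reserved for all fits) so the
#' information criteria are comparable, and records log-likelihood, AIC and
#' BIC per order. The chosen order follows [select_lag_order()]'s parsimony
#' rule.
#'
#' @inheritParams fit_var
#' @param p_max Largest lag order to entertain.
#' @param n_ic Observation count used in the criteria (defaults to the full
#'   paired series length; the count is a reporting convention, kept
#'   explicit because published tables differ in it).
#' @return A tibble of class `soil_lagsel` with columns `p`, `loglik`,
#'   `aic`, `bic` and attributes `chosen_p` and `rule`.
#' @export
lag_selection_table <- function(pair, p_max = 8L, intercept = TRUE, n_ic = NULL) {
  p_max <- check_count(p_max, "p_max", min = 1L)
  Y <- pair_matrix(pair)
  n_ic <- n_ic %||% nrow(Y)
  rows <- purrr::map_dfr(seq_len(p_max), function(p) {
    fit <- fit_var(Y, p, intercept = intercept, trim = p_max)
    ic <- information_criteria(fit$loglik, p, m = fit$m, n = n_ic)
    tibble(p = p, loglik = fit$loglik, aic = ic$aic, bic = ic$bic)
  })
  sel <- select_lag_order(rows)
  new_series_tbl(rows, class = "soil_lagsel",
                 chosen_p = sel, rule = attr(sel, "rule"), n_ic = n_ic)
}

#' Choose the lag order from a selection table
#'
#' If AIC and BIC agree on the minimizing order, that order is returned;
#' otherwise the smaller of the two minimizers is taken, preferring the more
#' parsimonious model (fewer parameters, smaller estimation error).
#'
#' @param rows A tibble with columns `p`, `aic`, `bic` (e.g. a
#'   [lag_selection_table()]).
#' @return The chosen integer order, with attribute `rule` describing the
#'   decision.
#' @export
select_lag_order <- function(rows) {
  if (!nrow(rows)) stop_soil("argument", "empty lag-selection table.")
  p_aic <- rows$p[which.min(rows$aic)]
  p_bic <- rows$p[which.min(rows$bic)]
  if (p_aic == p_bic) {
    structure(as.integer(p_aic), rule = sprintf("AIC and BIC agree at p = %d", p_aic))
  } else {
    structure(as.integer(min(p_aic, p_bic)),
              rule = sprintf("AIC min at p = %d, BIC min at p = %d; taking the more parsimonious p = %d",
                             p_aic, p_bic, min(p_aic, p_bic)))
  }
}

coeff_list <- function(x) {
  if (inherits(x, "soil_var") || (is.list(x) && !is.null(x$coeffs))) x$coeffs
  else if (is.list(x) && all(vapply(x, is.matrix, logical(1)))) x
  else stop_soil("argument", "expected a fitted VAR or a list of lag matrices.")
}

#' Companion matrix of a VAR(p)
#'
#' Stacks the lag matrices into the `m p x m p` block form that rewrites the
#' VAR(p) as a VAR(1): top block-row `[Phi_1 ... Phi_p]`, identity blocks on
#' the subdiagonal, zeros elsewhere.
#'
#' @param x A fitted `soil_var`, a reference coefficient set, or a plain
#'   list of m x m lag matrices.
#' @return The companion matrix.
#' @export
companion_matrix <- function(x) {
  phis <- coeff_list(x)
  m <- nrow(phis[[1]])
  p <- length(phis)
  F <- matrix(0, m * p, m * p)
  F[seq_len(m), ] <- do.call(cbind, phis)
  if (p > 1L) {
    F[(m + 1L):(m * p), seq_len(m * (p - 1L))] <- diag(m * (p - 1L))
  }
  F
}

#' Stability (unit-circle) check of a VAR
#'
#' A VAR is stable when every eigenvalue of its companion matrix lies
#' strictly inside the unit circle; stability guarantees the moving-average
#' expansion converges and impulse responses decay.
#'
#' @inheritParams companion_matrix
#' @return Object of class `soil_stability`: `companion`, sorted eigenvalue
#'   `moduli` (decreasing), `eigenvalues`, and logical `stable`.
#' @export
stability_check <- function(x) {
  F <- companion_matrix(x)
  ev <- eigen(F, only.values = TRUE)$values
  moduli <- sort(Mod(ev), decreasing = TRUE)
  structure(list(companion = F, eigenvalues = ev, moduli = moduli,
                 stable = moduli[1] < 1),
            class = "soil_stability")
}

#' @export
print.soil_stability <- function(x, ...) {
  cat(sprintf("VAR stability: max |eigenvalue| = %.4f -> %s\n",
              x$moduli[1], if (x$stable) "stable" else "UNSTABLE"))
  invisible(x)
}

#' @export
print.soil_var <- function(x, ...) {
  cat(sprintf("Bivariate VAR(%d) on (%s), n = %d, loglik = %.1f\n",
              x$p, paste(x$labels, collapse = ", "), x$n, x$loglik))
  cat("Lag-1 coefficient matrix:\n")
  print(round(x$coeffs[[1]], 3))
  invisible(x)
}

#' @rdname fit_var
#' @param x A `soil_var` object.
#' @param ... Unused.
#' @export
tidy.soil_var <- function(x, ...) {
  lag_rows <- purrr::map_dfr(seq_len(x$p), function(s) {
    Phi <- x$coeffs[[s]]
    tidyr::expand_grid(equation = x$labels, term_var = x$labels) %>%
      mutate(lag = s,
             estimate = purrr::map2_dbl(.data$equation, .data$term_var,
                                        ~ Phi[.x, .y]))
  })
  out <- lag_rows %>%
    mutate(term = paste0(.data$term_var, ".l", .data$lag)) %>%
    select("equation", "term", "lag", "estimate")
  if (!is.null(x$intercept)) {
    out <- bind_rows(
      tibble(equation = x$labels, term = "(Intercept)", lag = 0L,
             estimate = unname(x$intercept)),
      out)
  }
  out
}

#' @rdname fit_var
#' @export
glance.soil_var <- function(x, ...) {
  ic <- information_criteria(x$loglik, x$p, x$m, x$n)
  stab <- stability_check(x)
  tibble(p = x$p, n = x$n, loglik = x$loglik, aic = ic$aic, bic = ic$bic,
         max_modulus = stab$moduli[1], stable = stab$stable)
}

# One-step in-sample predictions (used for the companion-form equivalence
# property and by the residual bootstrap).
var_one_step <- function(model, Y = model$data) {
  Tn <- nrow(Y)
  rows <- (model$trim + 1L):Tn
  pred <- matrix(0, length(rows), model$m)
  for (s in seq_len(model$p)) {
    pred <- pred + Y[rows - s, , drop = FALSE] %*% t(model$coeffs[[s]])
  }
  if (!is.null(model$intercept)) {
    pred <- sweep(pred, 2, model$intercept, `+`)
  }
  pred
}
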