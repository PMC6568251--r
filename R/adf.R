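# Augmented Dickey-Fuller unit-root testing in three regression variants:
#   "ar"  - no deterministic term (null: driftless random walk)
#   "ard" - constant (drift) included
#   "ts"  - constant and linear trend included
# Critical values and p-values come from MacKinnon's published
# response-surface regressions (2010 critical-value surfaces; 1994
# normal-quantile p-value polynomials), the same tables every mainstream
# implementation ships. A seeded Monte-Carlo evaluation of the
# Dickey-Fuller null is available as a cross-check / fallback.

adf_variants <- c("ar", "ard", "ts")

# cv_surface[[variant]][[level]] = b0 + b1/n + b2/n^2 + b3/n^3
mackinnon_cv <- list(
  ar = list("0.01" = c(-2.56574, -2.2358, -3.627, 0),
            "0.05" = c(-1.94100, -0.2686, -3.365, 31.223),
            "0.1"  = c(-1.61682, 0.2656, -2.714, 25.364)),
  ard = list("0.01" = c(-3.43035, -6.5393, -16.786, -79.433),
             "0.05" = c(-2.86154, -2.8903, -4.234, -40.040),
             "0.1"  = c(-2.56677, -1.5384, -2.809, 0)),
  ts = list("0.01" = c(-3.95877, -9.0531, -28.428, -134.155),
            "0.05" = c(-3.41049, -4.3904, -9.036, -45.374),
            "0.1"  = c(-3.12705, -2.5856, -3.925, -22.380))
)

# p-value polynomials: Phi(poly(tau)) with a small-|tau| / large-|tau| split
mackinnon_p <- list(
  ar  = list(star = -1.04, min = -19.04, max = Inf,
             small = c(0.6344, 1.2378, 0.032496),
             large = c(0.4797, 0.93557, -0.06999, 0.033066)),
  ard = list(star = -1.61, min = -18.83, max = 2.74,
             small = c(2.1659, 1.4412, 0.038269),
             large = c(1.7339, 0.93202, -0.12745, -0.010368)),
  ts  = list(star = -2.89, min = -16.18, max = 0.70,
             small = c(3.2512, 1.6047, 0.049588),
             large = c(2.5261, 0.61654, -0.37956, -0.060285))
)

#' Dickey-Fuller critical values
#'
#' Finite-sample critical values of the Dickey-Fuller t-statistic for the
#' three test variants, from response-surface regressions in `1/n`; a seeded
#' Monte-Carlo simulation of the null (a driftless random walk) is available
#' as an independent check.
#'
#' @param variant `"ar"` (no constant), `"ard"` (constant), `"ts"` (constant
#'   and trend).
#' @param n Sample size (>= 25).
#' @param level Significance level(s); any of 0.01, 0.05, 0.10.
#' @param method `"surface"` (default) or `"simulation"`.
#' @param nrep,seed Replicates and seed for `method = "simulation"`.
#' @return Named numeric vector of critical values, one per level.
#' @examples
#' adf_critical_values("ar", n = 3888)
#' @export
adf_critical_values <- function(variant = adf_variants, n,
                                level = c(0.01, 0.05, 0.10),
                                method = c("surface", "simulation"),
                                nrep = 100000L, seed = 20101231L) {
  variant <- arg_match(variant)
  method <- arg_match(method)
  n <- check_count(n, "n", min = 25L)
  bad <- setdiff(level, c(0.01, 0.05, 0.10))
  if (length(bad)) {
    stop_soil("level", sprintf("unsupported level(s): %s.",
                               paste(bad, collapse = ", ")))
  }
  if (method == "surface") {
    out <- vapply(level, function(l) {
      b <- mackinnon_cv[[variant]][[format(l)]]
      b[1] + b[2] / n + b[3] / n^2 + b[4] / n^3
    }, numeric(1))
  } else {
    stats <- simulate_df_null(variant, n, nrep, seed)
    out <- unname(quantile(stats, probs = level, names = FALSE, type = 8))
  }
  setNames(out, paste0(level * 100, "%"))
}

# Vectorized simulation of the Dickey-Fuller t-statistic under the null
# (pure random walk, no augmentation), in memory-bounded chunks.
simulate_df_null <- function(variant, n, nrep, seed) {
  withr::local_seed(seed)
  chunk <- max(1L, min(nrep, as.integer(2e7 / n)))
  out <- numeric(0)
  remaining <- nrep
  while (remaining > 0L) {
    b <- min(chunk, remaining)
    e <- matrix(rnorm(n * b), nrow = n)
    y <- apply(e, 2, cumsum)
    ylag <- y[-n, , drop = FALSE]          # y_{t-1}, t = 2..n
    dy <- e[-1, , drop = FALSE]            # Delta y_t
    nn <- n - 1L
    if (variant == "ard") {
      ylag <- sweep(ylag, 2, colMeans(ylag))
      dy <- sweep(dy, 2, colMeans(dy))
      npar <- 2L
    } else if (variant == "ts") {
      tt <- seq_len(nn)
      X <- cbind(1, tt)
      H <- X %*% solve(crossprod(X), t(X))
      ylag <- ylag - H %*% ylag
      dy <- dy - H %*% dy
      npar <- 3L
    } else {
      npar <- 1L
    }
    sxx <- colSums(ylag^2)
    rho <- colSums(ylag * dy) / sxx
    rss <- colSums(dy^2) - rho^2 * sxx
    s2 <- rss / (nn - npar)
    out <- c(out, rho * sqrt(sxx / s2))
    remaining <- remaining - b
  }
  out
}

#' MacKinnon-style p-value for a Dickey-Fuller t-statistic
#'
#' Maps the test statistic through the published response-surface polynomial
#' to a standard-normal quantile and returns the implied tail probability.
#' Values below 0.001 are best reported as "< 0.001" (the [print][print.soil_adf]
#' method does); the numeric value is returned untruncated.
#'
#' @param t_stat Dickey-Fuller t-statistic.
#' @param variant Test variant, as in [adf_critical_values()].
#' @return p-value in \[0, 1\].
#' @export
adf_pvalue <- function(t_stat, variant = adf_variants) {
  variant <- arg_match(variant)
  cfg <- mackinnon_p[[variant]]
  if (t_stat <= cfg$min) return(0)
  if (t_stat >= cfg$max) return(1)
  co <- if (t_stat <= cfg$star) cfg$small else cfg$large
  z <- sum(co * t_stat^(seq_along(co) - 1))
  pnorm(z)
}

#' Augmented Dickey-Fuller regression
#'
#' Ordinary least squares of `diff(y)[t]` on `y[t-1]` and `q` lagged
#' differences (plus a constant for `"ard"`, a constant and linear trend for
#' `"ts"`). The t-statistic of the `y[t-1]` coefficient is the unit-root
#' test statistic.
#'
#' @param y Numeric vector or `soil_deseason` series.
#' @param variant Test variant.
#' @param aug_lags Number `q >= 0` of lagged-difference (augmentation) terms.
#' @return List of class `soil_adf_reg`: `t_stat`, `rho`, `se`, `residuals`,
#'   `n_used`, `rss`, `bic`, `variant`, `aug_lags`.
#' @export
adf_regression <- function(y, variant = adf_variants, aug_lags = 0L) {
  variant <- arg_match(variant)
  q <- check_count(aug_lags, "aug_lags", min = 0L)
  yv <- if (is.numeric(y)) as.numeric(y) else y$value
  n <- length(yv)
  if (n <= q + 2L) {
    stop_soil("insufficient-data",
              sprintf("need length(y) > aug_lags + 2 (got %d with q = %d).", n, q))
  }
  dy <- diff(yv)
  idx <- (q + 1L):(n - 1L)                      # response rows: Delta y_{q+2..n}
  resp <- dy[idx]
  X <- yv[idx]                                  # y_{t-1}
  if (q > 0L) {
    X <- cbind(X, vapply(seq_len(q), function(j) dy[idx - j], numeric(length(idx))))
  }
  X <- as.matrix(X)
  if (variant == "ard") X <- cbind(X, 1)
  if (variant == "ts") X <- cbind(X, 1, seq_along(idx))
  npar <- ncol(X)
  if (length(resp) <= npar) {
    stop_soil("insufficient-data", "too few observations for this lag order.")
  }
  qr_x <- qr(X)
  if (qr_x$rank < npar) stop_soil("collinear", "ADF design matrix is rank deficient.")
  beta <- qr.coef(qr_x, resp)
  res <- resp - X %*% beta
  rss <- sum(res^2)
  df <- length(resp) - npar
  s2 <- rss / df
  xtx_inv_11 <- chol2inv(qr.R(qr_x))[1, 1]
  se <- sqrt(s2 * xtx_inv_11)
  nobs <- length(resp)
  structure(list(
    t_stat = unname(beta[1] / se), rho = unname(beta[1]), se = se,
    coefficients = beta, residuals = as.numeric(res), n_used = nobs,
    rss = rss, sigma2 = s2,
    bic = nobs * log(rss / nobs) + npar * log(nobs),
    variant = variant, aug_lags = q
  ), class = "soil_adf_reg")
}

#' Choose the ADF augmentation lag by residual whiteness
#'
#' Returns the smallest `q <= q_max` whose ADF-regression residuals pass a
#' Ljung-Box portmanteau test at 24 lags (p > 0.05). If no `q` passes, the
#' BIC-minimizing `q` is returned with a warning.
#'
#' @inheritParams adf_regression
#' @param q_max Largest augmentation lag to consider.
#' @return Integer lag, with attribute `whitened` (logical).
#' @export
select_adf_lags <- function(y, variant = adf_variants, q_max = 8L) {
  variant <- arg_match(variant)
  q_max <- check_count(q_max, "q_max", min = 0L)
  bics <- numeric(q_max + 1L)
  for (q in 0:q_max) {
    reg <- adf_regression(y, variant, q)
    bics[q + 1L] <- reg$bic
    lb <- suppressWarnings(
      Box.test(reg$residuals, lag = 24L, type = "Ljung-Box", fitdf = q))
    if (is.finite(lb$p.value) && lb$p.value > 0.05) {
      return(structure(q, whitened = TRUE))
    }
  }
  best <- which.min(bics) - 1L
  warn_soil("whiteness", sprintf(
    "no augmentation lag <= %d whitens the residuals; using BIC-minimizing q = %d.",
    q_max, best))
  structure(best, whitened = FALSE)
}

#' Augmented Dickey-Fuller unit-root test
#'
#' Composes [select_adf_lags()], [adf_regression()], [adf_critical_values()]
#' and [adf_pvalue()] into a complete test: a series is judged stationary at
#' a level when the t-statistic falls below the level's critical value
#' (left-tail rejection of the unit-root null).
#'
#' @inheritParams select_adf_lags
#' @param lags Fix the augmentation lag instead of selecting it.
#' @return Object of class `soil_adf` with fields `label`, `variant`,
#'   `aug_lags`, `t_stat`, `p_value`, `critical_values`, `n_used`,
#'   `decision` (named character, `"stationary"`/`"non-stationary"` per
#'   level).
#' @examples
#' set.seed(1)
#' adf_test(rnorm(300), variant = "ar")
#' @export
adf_test <- function(y, variant = adf_variants, q_max = 8L, lags = NULL) {
  variant <- arg_match(variant)
  q <- if (is.null(lags)) select_adf_lags(y, variant, q_max) else
    check_count(lags, "lags", min = 0L)
  reg <- adf_regression(y, variant, q)
  cvs <- adf_critical_values(variant, n = reg$n_used)
  decision <- ifelse(reg$t_stat < cvs, "stationary", "non-stationary")
  structure(list(
    label = attr(y, "label") %||% "y",
    variant = variant, aug_lags = as.integer(q),
    t_stat = reg$t_stat, p_value = adf_pvalue(reg$t_stat, variant),
    critical_values = cvs, n_used = reg$n_used,
    decision = decision, regression = reg
  ), class = "soil_adf")
}

#' @export
print.soil_adf <- function(x, ...) {
  pshow <- if (x$p_value < 0.001) "< 0.001" else sprintf("%.3f", x$p_value)
  cat(sprintf("ADF test for '%s': %s(%d), t = %.3f, p %s\n",
              x$label, toupper(x$variant), x$aug_lags, x$t_stat,
              if (x$p_value < 0.001) pshow else paste("=", pshow)))
  cat(sprintf("  critical values: %s\n",
              paste(sprintf("%s %.3f", names(x$critical_values),
                            x$critical_values), collapse = ", ")))
  cat(sprintf("  decision at 5%%: %s\n", x$decision[["5%"]]))
  invisible(x)
}

#' @rdname adf_test
#' @param x A `soil_adf` object.
#' @param ... Unused.
#' @export
tidy.soil_adf <- function(x, ...) {
  tibble(level = c(0.01, 0.05, 0.10),
         critical_value = unname(x$critical_values),
         decision = unname(x$decision))
}

#' @rdname adf_test
#' @export
glance.soil_adf <- function(x, ...) {
  tibble(label = x$label, t_stat = x$t_stat,
         variant = toupper(x$variant), aug_lags = x$aug_lags,
         p_value = x$p_value, n_used = x$n_used,
         stationary_05 = x$decision[["5%"]] == "stationary")
}

#' Unit-root report table for a set of series
#'
#' One row per tested series: statistic, variant and augmentation lag,
#' p-value, the three critical values, and the 5% conclusion.
#'
#' @param tests List of `soil_adf` objects.
#' @return A tibble with columns `label`, `t_stat`, `model`, `p_value`,
#'   `cv_1`, `cv_5`, `cv_10`, `conclusion`.
#' @export
adf_report <- function(tests) {
  purrr::map_dfr(tests, function(tst) {
    tibble(label = tst$label, t_stat = tst$t_stat,
           model = sprintf("%s(%d)", toupper(tst$variant), tst$aug_lags),
           p_value = tst$p_value,
           cv_1 = tst$critical_values[["1%"]],
           cv_5 = tst$critical_values[["5%"]],
           cv_10 = tst$critical_values[["10%"]],
           conclusion = ifelse(tst$decision[["5%"]] == "stationary",
                               "Stationary", "Non-stationary"))
  })
}
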