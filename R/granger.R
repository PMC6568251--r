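#' Bivariate Granger causality F-test
#'
#' Tests whether past values of `y` help predict `x`. The unrestricted
#' regression of `x_t` on a constant, `p` lags of `x` and `p` lags of `y`
#' yields residual sum `RSS_0`; dropping the `y` lags yields `RSS_1`; the
#' statistic
#' `F = ((RSS_1 - RSS_0) / p) / (RSS_0 / (T - 2p - 1))`
#' is compared with F(p, T - 2p - 1) critical values at the 1%, 5% and 10%
#' levels. `y` "Granger-causes" `x` at a level when F exceeds that level's
#' critical value — a temporal, not mechanistic, notion of causality.
#' Both regressions use the same `T` rows (those with all lags available).
#'
#' @param x Predictand series (`soil_deseason` or numeric vector).
#' @param y Candidate predictor series.
#' @param p Lag order for both lag blocks.
#' @return Object of class `soil_granger`: `predictand`, `predictor`, `p`,
#'   `T_used`, `rss_unrestricted`, `rss_restricted`, `f_stat`, `p_value`,
#'   `critical_values`, `decisions` (`"causes"`/`"does-not-cause"` per
#'   level).
#' @examples
#' set.seed(2)
#' y <- as.numeric(stats::filter(rnorm(400), 0.5, "recursive"))
#' x <- as.numeric(stats::filter(0.4 * dplyr::lag(y, 1, default = 0) +
#'                               rnorm(400), 0.5, "recursive"))
#' granger_f_test(x, y, p = 1)
#' @export
granger_f_test <- function(x, y, p) {
  p <- check_count(p, "p", min = 1L)
  xl <- attr(x, "label") %||% "x"
  yl <- attr(y, "label") %||% "y"
  xv <- if (is.numeric(x)) as.numeric(x) else x$value
  yv <- if (is.numeric(y)) as.numeric(y) else y$value
  if (length(xv) != length(yv)) {
    stop_soil("argument", "series must be aligned to equal length (see align_pair()).")
  }
  n <- length(xv)
  Tn <- n - p
  df2 <- Tn - 2L * p - 1L
  if (df2 <= 0L) {
    stop_soil("insufficient-data",
              sprintf("T - 2p - 1 = %d must be positive.", df2))
  }
  rows <- (p + 1L):n
  lags <- function(v) vapply(seq_len(p), function(s) v[rows - s], numeric(Tn))
  X_unres <- cbind(1, lags(xv), lags(yv))
  X_res <- cbind(1, lags(xv))
  rss <- function(X) {
    qr_x <- qr(X)
    if (qr_x$rank < ncol(X)) stop_soil("collinear", "Granger design is rank deficient.")
    sum(qr.resid(qr_x, xv[rows])^2)
  }
  rss0 <- rss(X_unres)
  rss1 <- rss(X_res)
  f_stat <- ((rss1 - rss0) / p) / (rss0 / df2)
  levels <- c(0.01, 0.05, 0.10)
  cvs <- setNames(qf(1 - levels, p, df2), paste0(levels * 100, "%"))
  structure(list(
    predictand = xl, predictor = yl, p = p, T_used = Tn, df2 = df2,
    rss_unrestricted = rss0, rss_restricted = rss1,
    f_stat = f_stat, p_value = pf(f_stat, p, df2, lower.tail = FALSE),
    critical_values = cvs,
    decisions = setNames(ifelse(f_stat > cvs, "causes", "does-not-cause"),
                         names(cvs))
  ), class = "soil_granger")
}

#' @export
print.soil_granger <- function(x, ...) {
  cat(sprintf("Granger test: does '%s' help predict '%s'? (p = %d, T = %d)\n",
              x$predictor, x$predictand, x$p, x$T_used))
  cat(sprintf("  F = %.4f, p-value = %.4g\n", x$f_stat, x$p_value))
  for (lv in names(x$critical_values)) {
    cat(sprintf("  %4s: critical value %.4f -> %s\n", lv,
                x$critical_values[[lv]], x$decisions[[lv]]))
  }
  invisible(x)
}

#' @rdname granger_f_test
#' @param x A `soil_granger` object.
#' @param ... Unused.
#' @export
tidy.soil_granger <- function(x, ...) {
  tibble(predictand = x$predictand, predictor = x$predictor,
         level = c(0.01, 0.05, 0.10),
         f_stat = x$f_stat,
         critical_value = unname(x$critical_values),
         conclusion = ifelse(unname(x$decisions) == "causes", "Yes", "No"))
}

#' @rdname granger_f_test
#' @export
glance.soil_granger <- function(x, ...) {
  tibble(predictand = x$predictand, predictor = x$predictor, p = x$p,
         T_used = x$T_used, f_stat = x$f_stat, p_value = x$p_value,
         rss_unrestricted = x$rss_unrestricted,
         rss_restricted = x$rss_restricted)
}

#' Two-directional Granger decision table
#'
#' Runs the test in both directions on an aligned pair and formats the
#' decision rows (level, F, critical value, Yes/No conclusion) for each.
#' Lag orders may differ per direction; the VAR's selected order is the
#' natural default, but published decision tables often reflect
#' direction-specific whitening lags, so both are explicit.
#'
#' @param pair A `soil_pair` from [align_pair()].
#' @param p_forward Lag order for "second variable predicts the first".
#' @param p_reverse Lag order for "first variable predicts the second".
#' @return A tibble of class `soil_granger_table` (columns `direction`,
#'   `level`, `f_stat`, `critical_value`, `conclusion`) with the two
#'   `soil_granger` fits in the `tests` attribute.
#' @export
granger_table <- function(pair, p_forward, p_reverse = p_forward) {
  labs <- attr(pair, "labels")
  a <- pair[[labs[1]]]
  b <- pair[[labs[2]]]
  attr(a, "label") <- labs[1]
  attr(b, "label") <- labs[2]
  fwd <- granger_f_test(a, b, p_forward)   # does labs[2] cause labs[1]?
  rev <- granger_f_test(b, a, p_reverse)   # does labs[1] cause labs[2]?
  rows <- bind_rows(
    tidy(fwd) %>% mutate(direction = paste(fwd$predictor, "->", fwd$predictand)),
    tidy(rev) %>% mutate(direction = paste(rev$predictor, "->", rev$predictand))
  ) %>% select("direction", "level", "f_stat", "critical_value", "conclusion")
  new_series_tbl(rows, class = "soil_granger_table",
                 tests = list(forward = fwd, reverse = rev))
}
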