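# helper: a hand-built fitted-model stand-in with known coefficients
toy_var1 <- function(Phi = matrix(c(0.5, 0.1, 0.2, 0.4), 2, byrow = TRUE),
                     Sigma = fixture_sigma()) {
  labels <- c("y1", "y2")
  dimnames(Phi) <- list(labels, labels)
  dimnames(Sigma) <- list(labels, labels)
  structure(list(m = 2L, p = 1L, intercept = NULL, coeffs = list(Phi),
                 sigma = Sigma, n = 1000L, labels = labels),
            class = "soil_var")
}

test_that("moving-average coefficients follow the recursion exactly", {
  model <- toy_var1()
  Psi <- ma_coefficients(model, 10)
  expect_equal(Psi[[1]], diag(2))
  # VAR(1): Psi_i = Phi^i
  P <- diag(2)
  for (i in 1:10) {
    P <- model$coeffs[[1]] %*% P
    expect_equal(unname(Psi[[i + 1]]), unname(P), tolerance = 1e-12)
  }
  # spectral decay for a stable model
  Psi_far <- ma_coefficients(model, 1000)
  expect_lt(norm(Psi_far[[1001]], "F"), 1e-6)
})

test_that("identification schemes have their defining horizon-0 behavior", {
  model <- toy_var1()
  red <- unit_shock_irf(model, "reduced", H = 20)
  expect_equal(red$responses[1, , ], diag(2), ignore_attr = TRUE)

  gen <- unit_shock_irf(model, "generalized", H = 20)
  # response of y1 to a unit shock in y2 at horizon 0 is sigma_12 / sigma_22
  expect_equal(gen$responses[1, "y1", "y2"], 0.3)
  expect_equal(gen$responses[1, "y2", "y1"], 0.3)
  # own responses are one unit under every scheme
  chol_irf <- unit_shock_irf(model, "cholesky", H = 20)
  expect_equal(diag(chol_irf$responses[1, , ]), c(1, 1), ignore_attr = TRUE)
  expect_equal(diag(gen$responses[1, , ]), c(1, 1), ignore_attr = TRUE)

  # degenerate covariance rejected for covariance-based schemes
  broken <- toy_var1(Sigma = matrix(c(1, 1, 1, 1), 2))
  expect_error(unit_shock_irf(broken, "generalized"),
               class = "soilcoupling_error_degenerate")

  unstable <- toy_var1(Phi = diag(c(1.05, 0.2)))
  expect_warning(unit_shock_irf(unstable, "reduced", H = 5),
                 class = "soilcoupling_warning_unstable")
})

test_that("generalized responses equal a brute-force shocked-minus-baseline simulation", {
  model <- toy_var1()
  H <- 8
  gen <- unit_shock_irf(model, "generalized", H = H)
  set.seed(71)
  R <- 10000
  k <- 2 # shock the second variable by one unit
  Sigma <- unname(model$sigma)
  Phi <- unname(model$coeffs[[1]])
  cond_sd <- sqrt(Sigma[1, 1] - Sigma[1, 2]^2 / Sigma[2, 2])
  acc <- matrix(0, H + 1, 2)
  rt <- chol(Sigma)
  for (r in seq_len(R)) {
    e_base <- drop(rnorm(2) %*% rt)
    e_shock <- c(Sigma[1, 2] / Sigma[2, 2] * 1 + cond_sd * rnorm(1), 1)
    shared <- matrix(rnorm(2 * H), 2, H)
    yb <- e_base; ys <- e_shock
    acc[1, ] <- acc[1, ] + (ys - yb)
    for (i in seq_len(H)) {
      fut <- drop(shared[, i] %*% rt)
      yb <- drop(Phi %*% yb) + fut
      ys <- drop(Phi %*% ys) + fut
      acc[i + 1, ] <- acc[i + 1, ] + (ys - yb)
    }
  }
  sim_irf <- acc / R
  expect_equal(sim_irf[, 1], unname(gen$responses[, "y1", "y2"]), tolerance = 0.05)
  expect_equal(sim_irf[, 2], unname(gen$responses[, "y2", "y2"]), tolerance = 0.05)
})

test_that("the generalized scheme is order-invariant, Cholesky is not", {
  Y <- simulate_var(fixture_phi(), fixture_sigma(0.5), 1500, seed = 72)
  fit12 <- fit_var(Y, 2)
  fit21 <- fit_var(Y[, 2:1], 2)
  g12 <- unit_shock_irf(fit12, "generalized", H = 30)
  g21 <- unit_shock_irf(fit21, "generalized", H = 30)
  expect_equal(g12$responses[, "y1", "y2"], g21$responses[, "y1", "y2"],
               tolerance = 1e-10)
  c12 <- unit_shock_irf(fit12, "cholesky", H = 30)
  c21 <- unit_shock_irf(fit21, "cholesky", H = 30)
  expect_gt(max(abs(c12$responses[, "y1", "y2"] - c21$responses[, "y1", "y2"])),
            1e-3)
})

test_that("cumulative responses sum the curve, matching the geometric closed form", {
  model <- toy_var1(Phi = diag(c(0.9, 0.2)))
  irf <- unit_shock_irf(model, "reduced", H = 60)
  for (n in c(0, 5, 20)) {
    expect_equal(cumulative_response(irf, "y1", "y1", n),
                 (1 - 0.9^(n + 1)) / (1 - 0.9), tolerance = 1e-12)
  }
  expect_equal(cumulative_response(irf, 1, 2, 10), 0)
  expect_equal(cumulative_response(irf, 1, 1, 0), 1)
})

test_that("intensity is the zero-clamped gap between curve extremes", {
  mk_irf <- function(curve, H = length(curve) - 1) {
    arr <- array(0, dim = c(H + 1, 2, 2),
                 dimnames = list(NULL, c("a", "b"), c("a", "b")))
    arr[, 1, 2] <- curve
    structure(list(scheme = "reduced", horizon = H, labels = c("a", "b"),
                   responses = arr), class = "soil_irf")
  }
  # two-signed curves: gap between the clamped extremes
  curve30 <- c(-0.0077, seq(-0.005, 0.0086, length.out = 30), 0.003, 0.001)
  expect_equal(response_intensity(mk_irf(curve30), "a", "b"), 0.0163)
  curve90 <- c(-0.0033, seq(-0.002, 0.0017, length.out = 20), 0.001)
  expect_equal(response_intensity(mk_irf(curve90), "a", "b"), 0.0050)
  # one-signed curve: intensity is its largest magnitude
  expect_equal(response_intensity(mk_irf(c(0.1, 0.4, 0.2)), "a", "b"), 0.4)
  expect_equal(response_intensity(mk_irf(rep(0, 10)), "a", "b"), 0)
})

test_that("the time lag is the settling horizon of the response", {
  model <- toy_var1(Phi = diag(c(0.9, 0.2)))
  irf <- unit_shock_irf(model, "reduced", H = 120)
  # 0.9^i first stays below 5% of the unit intensity at i = 29
  expect_equal(response_time_lag(irf, "y1", "y1", 0.05), 29L, ignore_attr = TRUE)
  expect_equal(response_time_lag(irf, "y1", "y2"), 0L) # identically zero curve

  # censoring when the curve has not settled inside the horizon
  short <- unit_shock_irf(model, "reduced", H = 10)
  lag_flagged <- response_time_lag(short, "y1", "y1", 0.05)
  expect_equal(as.integer(lag_flagged), 11L)
  expect_true(isTRUE(attr(lag_flagged, "censored")))

  # a stable model either settles by H = 120 or is flagged
  lag_default <- irf$time_lag["y1", "y1"]
  expect_true(lag_default <= 120 || !is.null(attr(lag_default, "censored")))
})

test_that("bootstrap bands are seeded, bracket the point estimate, and stabilize in B", {
  Y <- simulate_var(fixture_phi(), fixture_sigma(), 400, seed = 73)
  fit <- fit_var(Y, 2)
  b1 <- bootstrap_bands(fit, "generalized", H = 20, B = 100, seed = 99)
  b2 <- bootstrap_bands(fit, "generalized", H = 20, B = 100, seed = 99)
  expect_identical(b1$bands, b2$bands)
  expect_equal(b1$responses, unit_shock_irf(fit, "generalized", H = 20)$responses)

  inside <- mean(b1$responses >= b1$bands$lower & b1$responses <= b1$bands$upper)
  expect_gte(inside, 0.85)

  b3 <- bootstrap_bands(fit, "generalized", H = 20, B = 300, seed = 100)
  w1 <- mean(b1$bands$upper - b1$bands$lower)
  w3 <- mean(b3$bands$upper - b3$bands$lower)
  expect_lt(abs(w1 - w3) / w3, 0.2)

  td <- tidy(b1)
  expect_true(all(c("lower", "upper") %in% names(td)))
  expect_s3_class(autoplot(b1), "ggplot")
  expect_s3_class(autoplot(stability_check(fit)), "ggplot")
})
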