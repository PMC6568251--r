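no_event_config <- function(days = 40, depths = 10L, seed = 3, ...) {
  synthetic_config(
    days = days, depths = depths, seed = seed,
    trend = list(temperature = tibble::tibble(day = c(0, days), value = c(0, 0)),
                 moisture = tibble::tibble(day = c(0, days), value = c(0, 0))),
    irrigation_events = tibble::tibble(day = numeric(0), jump = numeric(0),
                                       max_depth = numeric(0),
                                       half_life = numeric(0)),
    ...)
}

test_that("simulate_var is seeded, rejects unstable truths, and has the right moments", {
  phis <- fixture_phi()
  # noiseless recursion from a zero state stays at zero
  Y0 <- simulate_var(phis, 0, 50, seed = 1)
  expect_true(all(Y0 == 0))
  # determinism
  expect_identical(simulate_var(phis, fixture_sigma(), 200, seed = 4),
                   simulate_var(phis, fixture_sigma(), 200, seed = 4))
  expect_error(simulate_var(list(diag(c(1.2, 0.5))), diag(2), 100, seed = 1),
               class = "soilcoupling_error_unstable")
  expect_silent(simulate_var(list(diag(c(1.2, 0.5))), 0, 10, seed = 1,
                             allow_unstable = TRUE))

  # stationary mean matches (I - sum Phi_s)^{-1} c
  mu_true <- solve(diag(2) - Reduce(`+`, phis), c(1, -0.5))
  Y <- simulate_var(phis, fixture_sigma(), 50000, intercept = c(1, -0.5), seed = 5)
  expect_equal(colMeans(Y), mu_true, tolerance = 0.05, ignore_attr = TRUE)

  # VAR(1) lag-1 autocovariance matches the Yule-Walker solution
  Phi <- matrix(c(0.5, 0.1, 0.2, 0.4), 2, byrow = TRUE)
  Sig <- fixture_sigma()
  G0 <- matrix(solve(diag(4) - kronecker(Phi, Phi), as.numeric(Sig)), 2)
  G1 <- Phi %*% G0
  Y1 <- simulate_var(list(Phi), Sig, 50000, seed = 6)
  emp_G1 <- crossprod(Y1[-1, ], Y1[-nrow(Y1), ]) / (nrow(Y1) - 1)
  expect_equal(emp_G1, G1, tolerance = 0.08, ignore_attr = TRUE)
})

test_that("the deterministic component has the advertised differencing behavior", {
  days <- 10
  cfg <- no_event_config(days = days)
  cfg$profile$temp_amp <- 0
  det <- compose_deterministic(cfg, 10, "temperature")
  expect_true(all(det$value == det$value[1])) # flat trend + zero amplitude

  cfg2 <- no_event_config(days = days)
  det2 <- compose_deterministic(cfg2, 10, "temperature")
  expect_equal(seasonal_difference(det2$value)$value, rep(0, (days - 1) * 24),
               tolerance = 1e-10) # exact 24-periodicity annihilated

  # linear trend of slope s per hour differences to the constant 24 s
  cfg3 <- synthetic_config(
    days = days, depths = 10L,
    trend = list(temperature = tibble::tibble(day = c(0, days),
                                              value = c(0, days * 24 * 0.01)),
                 moisture = tibble::tibble(day = c(0, days), value = c(0, 0))),
    irrigation_events = tibble::tibble(day = numeric(0), jump = numeric(0),
                                       max_depth = numeric(0),
                                       half_life = numeric(0)))
  cfg3$profile$temp_amp <- 0
  det3 <- compose_deterministic(cfg3, 10, "temperature")
  slope <- (det3$value[49] - det3$value[25]) / 24
  d3 <- seasonal_difference(det3$value)$value
  expect_equal(d3, rep(24 * slope, length(d3)), tolerance = 1e-10)
  expect_gt(slope, 0)
})

test_that("irrigation events jump then decay with the configured half-life", {
  s <- hourly_series(rep(30, 400), "2018-03-01", "moisture", 10)
  ev <- tibble::tibble(day = 2, jump = 5, max_depth = 50, half_life = 100)
  out <- inject_irrigation_events(s, ev)
  at <- 2 * 24 + 1
  expect_equal(out$value[at], 35)
  expect_equal(out$value[at + 100], 30 + 2.5, tolerance = 1e-9)
  expect_equal(out$value[seq_len(at - 1)], rep(30, at - 1))

  # no events, deep layers, and temperature series are untouched
  expect_identical(inject_irrigation_events(s, ev[0, ]), s)
  deep <- hourly_series(rep(30, 400), "2018-03-01", "moisture", 90)
  expect_identical(inject_irrigation_events(deep, ev)$value, deep$value)
  tmp <- hourly_series(rep(10, 400), "2018-03-01", "temperature", 10)
  expect_identical(inject_irrigation_events(tmp, ev)$value, tmp$value)

  expect_error(inject_irrigation_events(s, tibble::tibble(
    day = 30, jump = 5, max_depth = 50, half_life = 100)),
    class = "soilcoupling_error_range")
})

test_that("datasets are bit-identical under the same config and satisfy the grid contract", {
  cfg <- synthetic_config(days = 30, seed = 17)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(purrr::map(d1$series, "value"), purrr::map(d2$series, "value"))
  expect_equal(nrow(d1), 6L) # two variables at three depths
  for (s in d1$series) {
    expect_silent(soilcoupling:::validate_hourly_series(s))
  }
  d3 <- generate_dataset(synthetic_config(days = 30, seed = 18))
  expect_false(identical(d1$series[[1]]$value, d3$series[[1]]$value))
})

test_that("with flat trend and no events, differencing recovers the VAR process exactly", {
  cfg <- no_event_config(days = 40, seed = 3)
  ds <- generate_dataset(cfg)
  sds <- cfg$innovation_sd[["10"]]
  R <- matrix(c(1, cfg$innovation_cor, cfg$innovation_cor, 1), 2)
  v <- simulate_var(cfg$var_coeffs[["10"]], diag(sds) %*% R %*% diag(sds),
                    40 * 24, seed = soilcoupling:::child_seed(3, 1))
  d_moist <- seasonal_difference(ds$series[[which(ds$variable == "moisture")]])
  expect_equal(d_moist$value, unname(v[25:(40 * 24), 1]), tolerance = 1e-10)
})

test_that("the full pipeline recovers the generating coefficients and coupling direction", {
  # recovery of the near-unit-root reference truth from a clean season
  cfg <- no_event_config(days = 160, depths = 10L, seed = 11)
  ds <- generate_dataset(cfg)
  pair <- align_pair(seasonal_difference(ds$series[[1]]),
                     seasonal_difference(ds$series[[2]]))
  fit <- fit_var(pair, 5)
  err <- max(abs(unlist(fit$coeffs) - unlist(cfg$var_coeffs[["10"]])))
  expect_lt(err, 0.15)

  # one-way coupling (moisture drives temperature) is detected as Yes/No
  # moisture equation depends only on itself; temperature carries 0.3 * moisture lag
  one_way <- list(matrix(c(0.6, 0.0, 0.3, 0.5), 2, byrow = TRUE))
  hits <- vapply(1:10, function(seed) {
    cfg1 <- no_event_config(days = 80, depths = 10L, seed = seed,
                            var_coeffs = list("10" = one_way),
                            innovation_cor = 0)
    ds1 <- generate_dataset(cfg1)
    pair1 <- align_pair(seasonal_difference(ds1$series[[1]]),
                        seasonal_difference(ds1$series[[2]]))
    tests <- attr(granger_table(pair1, 1), "tests")
    # forward: does temperature cause moisture? (should not)
    # reverse: does moisture cause temperature? (should)
    tests$reverse$decisions[["1%"]] == "causes" &&
      tests$forward$decisions[["1%"]] == "does-not-cause"
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
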