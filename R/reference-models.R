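#' Reference VAR coefficient sets for a winter-wheat soil profile
#'
#' Published coefficient estimates of the deseasonalized bivariate
#' moisture-temperature VAR at three representative depths of a loam soil
#' profile under winter wheat (10 cm topsoil, 30 cm subsoil, 90 cm
#' substratum; hourly data over a December-May growing season). The three
#' sets are near-unit-root but stable, which makes them realistic defaults
#' for the synthetic generator and convenient fixtures for stability and
#' impulse-response checks. Variable order is (moisture, temperature); the
#' 90 cm set was reported without an intercept.
#'
#' @param depth One of 10, 30, 90 (cm).
#' @return A list of class `soil_var_spec`: `coeffs` (list of 2 x 2 lag
#'   matrices, row = equation), `intercept` (or `NULL`), `p`, `m`,
#'   `labels`, `depth`.
#' @examples
#' stability_check(soil_reference_var(10))
#' @export
soil_reference_var <- function(depth = c(10, 30, 90)) {
  depth <- as.integer(depth[1])
  spec <- switch(as.character(depth),
    "10" = list(
      intercept = c(-0.002, 0.005),
      coeffs = list(
        matrix(c(1.593, 0.167, -0.026, 1.754), 2),
        matrix(c(-0.631, -0.205, 0.019, -0.816), 2),
        matrix(c(0.274, -0.061, 0.012, 0.026), 2),
        matrix(c(-0.526, -0.094, 0.024, -0.060), 2),
        matrix(c(0.257, 0.008, -0.031, 0.068), 2))),
    "30" = list(
      intercept = c(-0.002, 0.001),
      coeffs = list(
        matrix(c(1.182, -0.006, 0.117, 0.559), 2),
        matrix(c(-0.173, -0.022, -0.090, 0.344), 2),
        matrix(c(-0.016, 0.042, 0.020, 0.228), 2),
        matrix(c(-0.002, -0.003, -0.054, 0.149), 2),
        matrix(c(0.000, -0.022, 0.013, 0.012), 2),
        matrix(c(-0.006, 0.019, -0.014, -0.074), 2),
        matrix(c(0.012, -0.010, 0.040, -0.082), 2),
        matrix(c(-0.027, -0.002, -0.029, -0.148), 2))),
    "90" = list(
      intercept = NULL,
      coeffs = list(
        matrix(c(0.690, 0.133, 0.058, 0.345), 2),
        matrix(c(0.336, 0.026, 0.025, 0.200), 2),
        matrix(c(0.130, 0.045, -0.001, 0.191), 2),
        matrix(c(-0.024, 0.079, -0.010, 0.103), 2),
        matrix(c(-0.061, -0.166, -0.031, 0.039), 2),
        matrix(c(-0.004, -0.132, -0.008, 0.056), 2),
        matrix(c(-0.071, 0.011, -0.032, 0.058), 2))),
    stop_soil("argument", "`depth` must be 10, 30, or 90.")
  )
  labels <- paste0(c("MCSD", "STSD"), depth)
  spec$coeffs <- lapply(spec$coeffs, function(Phi) {
    dimnames(Phi) <- list(labels, labels)
    Phi
  })
  if (!is.null(spec$intercept)) spec$intercept <- setNames(spec$intercept, labels)
  structure(list(coeffs = spec$coeffs, intercept = spec$intercept,
                 p = length(spec$coeffs), m = 2L, labels = labels,
                 depth = depth),
            class = "soil_var_spec")
}
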