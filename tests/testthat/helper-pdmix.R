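# shared helpers for the test suite

expect_rel <- function(actual, expected, tol = 0.01) {
  expect_true(all(abs(actual - expected) <= tol * abs(expected)),
              label = sprintf("%s within %g%% of %s",
                              paste(signif(actual, 6), collapse = ", "),
                              100 * tol,
                              paste(signif(expected, 6), collapse = ", ")))
}

# short obstructed channel sharing the device's transverse dimensions
short_geometry <- function(n_obstacles = 10) {
  build_geometry(obstacle_count = n_obstacles, total_length = NULL,
                 pitch = (47.5e-3 - 1.5e-3) / 90)
}

# straight rectangular channel
straight_geometry <- function(length = 2e-3) {
  build_geometry(obstacle_count = 0, total_length = length)
}

# a tiny property table with scaled diffusivity, for limit studies
scaled_diffusivity_model <- function(factor) {
  tab <- water_ethanol_table()
  tab$diffusivity <- tab$diffusivity * factor
  property_model(tab)
}
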