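props <- property_model()

test_that("mixing efficiency is 0 when segregated and 100 when uniform", {
  seg <- rep(c(1, 0), each = 25)          # fully segregated, p = 0.5
  s0 <- section_variance(seg)
  expect_equal(s0, 0.25)
  expect_equal(mixing_efficiency(section_variance(seg), s0), 0)
  expect_equal(mixing_efficiency(section_variance(rep(0.5, 50)), s0), 100)
  expect_error(mixing_efficiency(0.1, 0), class = "pdmix_undefined_me")
})

test_that("a segregated 50x50 section with a quarter organic has the
           brute-force variance", {
  grid_vals <- c(rep(1, 625), rep(0, 1875)) # 2500 elements, 25% ones
  # brute-force oracle
  m <- mean(grid_vals)
  oracle <- sum((grid_vals - m)^2) / length(grid_vals)
  expect_equal(oracle, 0.1875)
  expect_equal(section_variance(grid_vals), oracle)
})

test_that("threshold distances interpolate between stations", {
  fake <- structure(
    data.frame(station = 1:5, position_mm = (1:5) * 2,
               sigma2 = 0, me_percent = c(0, 0, 0, 0, 100)),
    class = c("mixing_profile", "data.frame")
  )
  d <- distance_to_threshold(fake, 90)
  # hand interpolation: crossing between 8 mm (0%) and 10 mm (100%)
  expect_equal(d$distance_mm, 8 + 0.9 * 2)
  expect_false(d$censored)

  mono <- structure(
    data.frame(station = 1:4, position_mm = 1:4,
               sigma2 = 0, me_percent = c(20, 50, 80, 95)),
    class = c("mixing_profile", "data.frame")
  )
  d2 <- distance_to_threshold(mono, 90)
  expect_equal(d2$distance_mm, 3 + (90 - 80) / (95 - 80))

  flat <- structure(
    data.frame(station = 1:3, position_mm = 1:3,
               sigma2 = 0.1, me_percent = c(10, 20, 30)),
    class = c("mixing_profile", "data.frame")
  )
  d3 <- distance_to_threshold(flat, 90)
  expect_true(d3$censored)
  expect_true(is.na(d3$distance_mm))
  expect_error(distance_to_threshold(flat, 0), class = "pdmix_invalid_argument")
})

# one shared solve over a short section of the device for the profile tests
geom <- short_geometry(8)
grid <- discretize_geometry(geom, ny = 30)
flow <- solve_flow(geom, tfr = 18, frr = 1, properties = props, grid = grid)

test_that("mixing efficiency rises monotonically along the channel", {
  for (f in c(1, 3)) {
    tr <- solve_transport(flow, properties = props, frr = f)
    pr <- mixing_profile(tr, stations = 20)
    expect_true(all(diff(pr$me_percent) > -1)) # 1 percentage point slack
    expect_true(all(pr$me_percent >= 0 & pr$me_percent <= 100))
    expect_lt(pr$me_percent[1], 100)
  }
})

test_that("higher flow rate ratios reach the mixing threshold sooner", {
  study <- mixing_study(frr_values = c(1, 3, 5, 9), tfr = 18, geom = geom,
                        properties = props, ny = 30, stations = 40)
  expect_false(any(study$censored))
  expect_true(all(diff(study$distance_mm) <= 1e-9))
  expect_gt(study$distance_mm[1], study$distance_mm[4])
})

test_that("higher flow rate ratios leave less uniform transverse profiles", {
  tr1 <- solve_transport(flow, properties = props, frr = 1)
  tr3 <- solve_transport(flow, properties = props, frr = 3)
  cv1 <- transverse_nonuniformity(tr1, stations = 20)
  cv3 <- transverse_nonuniformity(tr3, stations = 20)
  early <- 1:5 # stations before mixing is complete
  expect_true(all(cv3$cv[early] > cv1$cv[early]))
})

test_that("outlet mixing efficiency is stable under grid refinement", {
  g <- straight_geometry(2e-3)
  me_out <- vapply(c(16, 32), function(ny) {
    fl <- solve_flow(g, tfr = 18, frr = 1, properties = props, ny = ny)
    tr <- solve_transport(fl, properties = props)
    pr <- mixing_profile(tr)
    pr$me_percent[nrow(pr)]
  }, numeric(1))
  expect_lt(abs(diff(me_out)), 3)
})
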