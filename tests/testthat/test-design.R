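test_that("rotatable axial distance follows (2^k)^(1/4)", {
  expect_equal(round(compute_alpha(2), 2), 1.41)
  expect_identical(compute_alpha(4), 2)
  expect_equal(round(compute_alpha(3), 2), 1.68)
  expect_equal(compute_alpha(1), 2^(1 / 4))
  expect_error(compute_alpha(0), class = "pdmix_invalid_argument")
  expect_error(compute_alpha(2.5), class = "pdmix_invalid_argument")
})

test_that("the study design reproduces the measured 29-run layout", {
  d <- build_cccr_design(pdm_design_spec(seed = 11))
  expect_s3_class(d, "run_table")
  expect_identical(nrow(d), 29L)

  pts <- unique(d[c("frr", "tfr")])
  expect_identical(nrow(pts), 9L)
  measured <- unique(pdm_runs()[c("frr", "tfr")])
  key <- function(x) sort(paste(x$frr, x$tfr))
  expect_identical(key(pts), key(measured))

  # factorial level of FRR at coded -1 sits inside the axial extremes
  expect_equal(sort(unique(d$frr[abs(d$frr_coded + 1) < 1e-6])), 2.6)
  expect_equal(sort(unique(d$tfr[abs(d$tfr_coded - 1) < 1e-6])), 15.8)
  expect_identical(sum(d$frr_coded == 0 & d$tfr_coded == 0), 5L)
})

test_that("replication scheme controls the run count", {
  sp <- design_spec(
    list(factor_spec("FRR", 1, 12), factor_spec("TFR", 3, 18)),
    cube_reps = 1, axial_reps = 1, center_reps = 1
  )
  expect_identical(nrow(build_cccr_design(sp)), 9L)
  expect_error(
    design_spec(list(factor_spec("A", 0, 1)), cube_reps = 0),
    class = "pdmix_invalid_argument"
  )
})

test_that("design points are rotatable in coded space", {
  d <- build_cccr_design(pdm_design_spec())
  r <- sqrt(d$frr_coded^2 + d$tfr_coded^2)
  alpha <- compute_alpha(2)
  expect_true(all(abs(r) < 1e-6 | abs(r - alpha) < 1e-4))
})

test_that("coded/natural conversion reproduces the printed settings", {
  sp <- pdm_design_spec()
  centre <- coded_to_natural(c(0, 0), sp)
  expect_equal(unname(centre[1, ]), c(6.5, 10.5))
  expect_equal(unname(coded_to_natural(c(-sp$alpha, 0), sp)[1, 1]), 1.0)
  expect_equal(unname(coded_to_natural(c(0, 1), sp)[1, 2]), 15.8)
  # independent arithmetic: centre + half-range / alpha, rounded to 1 dp
  expect_equal(round(10.5 + 7.5 / sqrt(2), 1), 15.8)
})

test_that("coded/natural round trip is exact up to the pump rounding", {
  sp <- pdm_design_spec()
  set.seed(42)
  coded <- matrix(runif(40, -sp$alpha, sp$alpha), ncol = 2)
  nat <- coded_to_natural(coded, sp, round = FALSE)
  expect_equal(unname(natural_to_coded(nat, sp)), unname(coded),
               tolerance = 1e-12)
  # with rounding the error is bounded by half a decimal step per factor
  nat_r <- coded_to_natural(coded, sp)
  back <- natural_to_coded(nat_r, sp)
  units <- c(5.5, 7.5) / sp$alpha
  for (k in 1:2) {
    expect_true(all(abs(back[, k] - coded[, k]) <= 0.05 / units[k] + 1e-12))
  }
})

test_that("flow splitting matches the syringe-pump arithmetic", {
  expect_equal(unlist(split_flows(18, 1)), c(q_as = 9, q_os = 9))
  centre <- split_flows(10.5, 6.5)
  expect_equal(round(centre$q_as, 1), 9.1)
  expect_equal(round(centre$q_os, 1), 1.4)

  set.seed(7)
  tfr <- runif(50, 0.5, 30); frr <- runif(50, 0.1, 20)
  fl <- split_flows(tfr, frr)
  expect_equal(fl$q_as + fl$q_os, tfr)
  expect_equal(fl$q_as / fl$q_os, frr)
  inv <- flows_to_tfr_frr(fl$q_as, fl$q_os)
  expect_equal(inv$tfr, tfr)
  expect_equal(inv$frr, frr)

  expect_error(split_flows(-1, 2), class = "pdmix_invalid_argument")
  expect_error(split_flows(10, 0), class = "pdmix_invalid_argument")
})

test_that("run-order randomisation is seeded and uniform-ish", {
  d <- build_cccr_design(pdm_design_spec(seed = NULL))
  r1 <- randomize_run_order(d, seed = 5)
  r2 <- randomize_run_order(d, seed = 5)
  expect_identical(r1, r2)
  expect_identical(randomize_run_order(d[1, ], seed = 9)$frr, d$frr[1])
  perms <- vapply(1:10, function(s) {
    paste(randomize_run_order(d, seed = s)$frr, collapse = ",")
  }, "")
  expect_gt(length(unique(perms)), 1)
  # caller RNG state untouched
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(randomize_run_order(d, seed = 1)); after <- runif(1)
  expect_identical(before, after)
})
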