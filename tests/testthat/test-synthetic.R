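design <- build_cccr_design(pdm_design_spec(seed = 8))

test_that("zero noise reproduces the generating surfaces exactly", {
  truth <- truth_spec(sd_size = 0, sd_pdi = 0, zeta_sd = 0)
  tab <- generate_run_table(design, truth, seed = 1)
  size_ref <- 236.3 - 26.95 * tab$frr - 4.437 * tab$tfr + 1.573 * tab$frr^2
  pdi_ref <- 0.0663 + 0.03181 * tab$frr + 0.00319 * tab$tfr -
    0.001905 * tab$frr^2
  expect_equal(tab$z_average_nm, size_ref, tolerance = 1e-12)
  expect_equal(tab$pdi, pdi_ref, tolerance = 1e-12)
  expect_equal(tab$zeta_mv, rep(-31.5, nrow(tab)))
})

test_that("generation is deterministic per seed and leaves the RNG alone", {
  a <- generate_run_table(design, seed = 42)
  b <- generate_run_table(design, seed = 42)
  expect_identical(a, b)
  c <- generate_run_table(design, seed = 43)
  expect_false(identical(a$z_average_nm, c$z_average_nm))
  set.seed(1); r1 <- runif(1)
  set.seed(1); invisible(generate_run_table(design, seed = 42)); r2 <- runif(1)
  expect_identical(r1, r2)
})

test_that("replicate size SDs fall in the observed experimental envelope", {
  frac_in <- mean(vapply(seq_len(100), function(s) {
    tab <- generate_run_table(design, seed = 1000 + s)
    sds <- run_conditions(tab, "z_average_nm")$sd
    mean(sds >= 0.43 & sds <= 11.48)
  }, numeric(1)))
  expect_gte(frac_in, 0.9)
})

test_that("coefficient confidence intervals show nominal coverage", {
  truth <- truth_spec()
  true_b <- truth$size_coef
  hits <- matrix(NA, 200, 4)
  for (s in seq_len(200)) {
    tab <- generate_run_table(design, truth, seed = 3000 + s)
    m <- fit_quadratic(tab, "z_average_nm", c("FRR", "TFR", "FRR^2"))
    ci <- confint(m$fit, level = 0.95)
    hits[s, ] <- ci[, 1] <= true_b & true_b <= ci[, 2]
  }
  coverage <- colMeans(hits)
  expect_true(all(coverage >= 0.91 & coverage <= 0.99))
})

test_that("backward elimination recovers the generating term set", {
  drops <- vapply(seq_len(100), function(s) {
    tab <- generate_run_table(design, seed = 5000 + s)
    red <- reduce_model(tab, "z_average_nm", alpha = 0.05)
    all(c("TFR^2", "FRR:TFR") %in% red$dropped)
  }, logical(1))
  expect_gte(mean(drops), 0.8)
})

test_that("generated zeta potential shows no condition structure", {
  single <- vapply(seq_len(100), function(s) {
    tab <- generate_run_table(design, seed = 7000 + s)
    attr(tukey_groups(tab, "zeta_mv"), "n_classes") == 1L
  }, logical(1))
  expect_gte(mean(single), 0.9)
})

test_that("validation sweeps have the requested layout and behaviour", {
  frr <- c(1, 3, 5, 7, 9, 12)
  sw <- generate_validation_sweep(frr, tfr = 18,
                                  truth = truth_spec(sd_size = 0, sd_pdi = 0,
                                                     zeta_sd = 0),
                                  seed = 2)
  expect_identical(nrow(sw), 18L)
  expect_true(all(sw$tfr == 18))
  means <- tapply(sw$z_average_nm, sw$frr, mean)
  # noise-free curve decreases towards the stationary point near FRR 8.6
  expect_true(all(diff(means[as.character(c(1, 3, 5, 7))]) < 0))
  expect_lt(means["9"], means["1"])
  expect_gt(means["12"], means["9"]) # rebound past the minimum
  stationary <- 26.95 / (2 * 1.573)
  expect_equal(round(stationary, 1), 8.6)

  expect_identical(generate_validation_sweep(frr, seed = 5),
                   generate_validation_sweep(frr, seed = 5))
  expect_error(generate_validation_sweep(numeric(0)),
               class = "pdmix_invalid_argument")
})

test_that("PDI clipping is applied and reported", {
  noisy <- truth_spec(sd_pdi = 0.5)
  expect_message(tab <- generate_run_table(design, noisy, seed = 11), "clipped")
  expect_true(all(tab$pdi > 0 & tab$pdi < 1))
})
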