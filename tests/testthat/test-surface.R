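runs <- pdm_runs()

test_that("the reduced size model reproduces the published coefficients", {
  m <- fit_quadratic(runs, "z_average_nm", c("FRR", "TFR", "FRR^2"))
  expect_rel(coef(m), c(236.3, -26.95, -4.437, 1.573), tol = 0.01)

  red <- reduce_model(runs, "z_average_nm")
  expect_setequal(red$model$terms, c("FRR", "TFR", "FRR^2"))
  expect_setequal(red$dropped, c("TFR^2", "FRR:TFR"))
  expect_rel(100 * red$anova$r_squared, 78.89, tol = 0.01)
  expect_rel(red$anova$model_f, 31.14, tol = 0.01)
  expect_true(red$significant)
})

test_that("the reduced PDI model reproduces the published coefficients", {
  m <- fit_quadratic(runs, "pdi", c("FRR", "TFR", "FRR^2"))
  expect_rel(coef(m), c(0.0663, 0.03181, 0.00319, -0.001905), tol = 0.01)

  red <- reduce_model(runs, "pdi")
  expect_setequal(red$model$terms, c("FRR", "TFR", "FRR^2"))
  expect_setequal(red$dropped, c("TFR^2", "FRR:TFR"))
  expect_rel(100 * red$anova$r_squared, 46.22, tol = 0.01)
  expect_rel(red$anova$model_f, 7.16, tol = 0.01)
  expect_rel(100 * red$anova$r_squared_pred, 24.55, tol = 0.01)
})

test_that("zeta potential supports no significant model", {
  red <- reduce_model(runs, "zeta_mv")
  expect_length(red$model$terms, 0)
  expect_false(red$significant)
})

test_that("PRESS relates to leave-one-out residuals and bounds R2-pred", {
  red <- reduce_model(runs, "pdi")
  a <- red$anova
  # brute-force leave-one-out oracle
  dat <- red$model$data
  loo <- vapply(seq_len(nrow(dat)), function(i) {
    f <- lm(.response ~ frr + tfr + I(frr^2), data = dat[-i, ])
    dat$.response[i] - predict(f, dat[i, ])
  }, numeric(1))
  expect_equal(a$press, sum(loo^2), tolerance = 1e-10)
  expect_gte(a$press, a$sse)
  expect_lte(a$r_squared_adj, a$r_squared)
  expect_gte(a$r_squared, 0)
})

test_that("noise-free synthetic data is recovered to machine precision", {
  design <- build_cccr_design(pdm_design_spec(seed = 2))
  truth <- truth_spec(sd_size = 0, sd_pdi = 0, zeta_sd = 0)
  tab <- generate_run_table(design, truth, seed = 1)
  m <- fit_quadratic(tab, "z_average_nm", c("FRR", "TFR", "FRR^2"))
  expect_equal(unname(coef(m)), c(236.3, -26.95, -4.437, 1.573),
               tolerance = 1e-8)
  # exact fit: zero covariance, degenerate interval at the mean
  pr <- predict(m, data.frame(frr = 6.5, tfr = 10.5))
  expect_lt(pr$se_fit, 1e-8)
  expect_equal(pr$lwr, pr$fit, tolerance = 1e-6)
})

test_that("fits are invariant to the factor coding", {
  # recode exactly (the printed coded column is itself rounded, so the exact
  # affine image of the realised natural settings is used here)
  sp <- pdm_design_spec()
  exact <- runs
  cc <- natural_to_coded(as.matrix(runs[c("frr", "tfr")]), sp)
  exact$frr_coded <- cc[, 1]
  exact$tfr_coded <- cc[, 2]
  for (resp in c("z_average_nm", "pdi")) {
    nat <- fit_quadratic(exact, resp, c("FRR", "TFR", "FRR^2"))
    cod <- fit_quadratic(exact, resp, c("FRR", "TFR", "FRR^2"),
                         factor_values = "coded")
    gn <- goodness_of_fit(nat); gc <- goodness_of_fit(cod)
    expect_equal(gn$r_squared, gc$r_squared, tolerance = 1e-10)
    expect_equal(gn$model_f, gc$model_f, tolerance = 1e-8)
    pts <- data.frame(frr = c(2.6, 8.56), tfr = c(5.2, 18))
    cpts <- as.data.frame(natural_to_coded(as.matrix(pts), sp))
    names(cpts) <- c("frr", "tfr")
    expect_equal(predict(nat, pts)$fit, predict(cod, cpts)$fit,
                 tolerance = 1e-6)
  }
})

test_that("model reduction is idempotent and respects hierarchy", {
  red <- reduce_model(runs, "z_average_nm")
  again <- reduce_model(runs, "z_average_nm", terms = red$model$terms)
  expect_identical(again$model$terms, red$model$terms)
  expect_length(again$dropped, 0)

  # FRR stays while FRR^2 survives even where its own p would evict it
  p <- summary(red$model$fit)$coefficients[, 4]
  expect_true("FRR" %in% red$model$terms)
})

test_that("degenerate fits raise classed errors", {
  few <- runs[1:3, ]
  expect_error(fit_quadratic(few, "pdi", full_quadratic_terms()),
               class = "pdmix_invalid_argument")
  const <- runs
  const$frr <- 5
  expect_error(fit_quadratic(const, "pdi", c("FRR", "FRR^2")),
               class = "pdmix_singular_design")
  expect_error(fit_quadratic(runs, "nope"), class = "pdmix_invalid_argument")
})

test_that("prediction at the reported optimum matches the published numbers", {
  m <- fit_quadratic(runs, "z_average_nm", c("FRR", "TFR", "FRR^2"))
  pr <- predict(m, data.frame(frr = 8.56, tfr = 18))
  expect_rel(pr$fit, 41.07, tol = 0.01)
  expect_rel(pr$lwr, 25.10, tol = 0.01)
  expect_rel(pr$upr, 57.03, tol = 0.01)
  # the confidence-of-mean interval matches the published range; the
  # prediction interval is necessarily wider
  expect_lt(pr$pi_lwr, pr$lwr)
  # independent arithmetic on the published surface at (FRR 3, TFR 18)
  eq9 <- 236.3 - 26.95 * 3 - 4.437 * 18 + 1.573 * 9
  expect_rel(predict(m, data.frame(frr = 3, tfr = 18))$fit, eq9, tol = 0.01)
  expect_warning(predict(m, data.frame(frr = 20, tfr = 18)), "extrapolation")
})

test_that("constrained optimisation finds the published minimum", {
  m <- fit_quadratic(runs, "z_average_nm", c("FRR", "TFR", "FRR^2"))
  opt <- optimize_response(m, list(frr = c(1, 12), tfr = c(3, 18)), "min")
  expect_equal(round(opt$frr, 2), 8.56)
  expect_identical(opt$tfr, 18)
  expect_false(opt$at_bound["frr"][[1]])
  expect_true(opt$at_bound["tfr"][[1]])
  expect_rel(opt$predicted, 41.07, tol = 0.01)
  expect_rel(opt$ci, c(25.10, 57.03), tol = 0.01)

  # closed-form stationary point in FRR
  b <- coef(m)
  expect_equal(opt$frr, unname(-b["FRR"] / (2 * b["FRR^2"])), tolerance = 1e-9)

  # dense grid-scan oracle
  gr <- expand.grid(frr = seq(1, 12, by = 0.005), tfr = c(3, 18))
  val <- b[1] + b["FRR"] * gr$frr + b["TFR"] * gr$tfr + b["FRR^2"] * gr$frr^2
  k <- which.min(val)
  expect_lt(abs(opt$frr - gr$frr[k]), 0.005)
  expect_identical(gr$tfr[k], 18)
  expect_lte(opt$predicted, min(val) + 1e-9)
})

test_that("linear responses are pushed to the favourable corner", {
  design <- build_cccr_design(pdm_design_spec(seed = 4))
  truth <- truth_spec(size_coef = c("(Intercept)" = 100, "FRR" = -3, "TFR" = 2),
                      sd_size = 0, sd_pdi = 0, zeta_sd = 0)
  tab <- generate_run_table(design, truth, seed = 1)
  m <- fit_quadratic(tab, "z_average_nm", c("FRR", "TFR"))
  opt <- optimize_response(m, list(frr = c(1, 12), tfr = c(3, 18)), "min")
  expect_equal(c(opt$frr, opt$tfr), c(12, 3))
  opt2 <- optimize_response(m, list(frr = c(1, 12), tfr = c(3, 18)), "max")
  expect_equal(c(opt2$frr, opt2$tfr), c(1, 18))
  expect_error(
    optimize_response(m, list(frr = c(-Inf, Inf), tfr = c(3, 18)), "min"),
    class = "pdmix_invalid_argument"
  )
})

test_that("optimisation handles an interaction surface against a grid scan", {
  design <- build_cccr_design(pdm_design_spec(seed = 4))
  truth <- truth_spec(
    size_coef = c("(Intercept)" = 150, "FRR" = -20, "TFR" = -3,
                  "FRR^2" = 1.2, "TFR^2" = 0.15, "FRR:TFR" = 0.4),
    sd_size = 0, sd_pdi = 0, zeta_sd = 0
  )
  tab <- generate_run_table(design, truth, seed = 1)
  m <- fit_quadratic(tab, "z_average_nm", full_quadratic_terms())
  opt <- optimize_response(m, list(frr = c(1, 12), tfr = c(3, 18)), "min")
  gr <- expand.grid(frr = seq(1, 12, 0.01), tfr = seq(3, 18, 0.01))
  b <- truth$size_coef
  val <- b[1] + b[2] * gr$frr + b[3] * gr$tfr + b[4] * gr$frr^2 +
    b[5] * gr$tfr^2 + b[6] * gr$frr * gr$tfr
  expect_lte(opt$predicted, min(val) + 1e-6)
})
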