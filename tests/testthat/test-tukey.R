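runs <- pdm_runs()

test_that("PDI conditions fall into three letter classes with one isolate", {
  tg <- tukey_groups(runs, "pdi")
  expect_identical(attr(tg, "n_classes"), 3L)
  iso <- tg[tg$frr == 1.0 & tg$tfr == 10.5, ]
  expect_identical(nrow(iso), 1L)
  expect_equal(iso$mean, 0.07)
  # its letter appears nowhere else
  others <- tg$letters[!(tg$frr == 1.0 & tg$tfr == 10.5)]
  expect_false(any(grepl(iso$letters, others, fixed = TRUE)))
  expect_identical(nchar(iso$letters), 1L)
  # every condition carries at least one letter
  expect_true(all(nchar(tg$letters) >= 1))
})

test_that("zeta potential conditions share a single letter", {
  tz <- tukey_groups(runs, "zeta_mv")
  expect_identical(attr(tz, "n_classes"), 1L)
  expect_true(all(tz$letters == "A"))
})

test_that("with equal replication the Kramer form reduces to Tukey HSD", {
  eq <- runs[!(runs$run_order %in% c(28, 29)), ] # trim centre to n = 3
  tg <- tukey_groups(eq, "pdi")
  fit <- aov(pdi ~ cond, data = transform(as.data.frame(eq),
                                          cond = interaction(frr, tfr, sep = "|")))
  hsd <- TukeyHSD(fit)$cond
  p_pkg <- attr(tg, "p_matrix")
  pick <- function(code) {
    ft <- as.numeric(strsplit(code, "|", fixed = TRUE)[[1]])
    which(abs(tg$frr - ft[1]) < 1e-9 & abs(tg$tfr - ft[2]) < 1e-9)
  }
  # compare every pairwise p-value with the reference implementation
  for (r in rownames(hsd)) {
    lv <- strsplit(r, "-", fixed = TRUE)[[1]]
    expect_equal(p_pkg[pick(lv[1]), pick(lv[2])], hsd[r, "p adj"],
                 tolerance = 1e-6)
  }
})

test_that("letter assignment is invariant to input row order", {
  set.seed(99)
  shuffled <- runs[sample.int(nrow(runs)), ]
  a <- tukey_groups(runs, "pdi")
  b <- tukey_groups(shuffled, "pdi")
  expect_identical(a$condition, b$condition)
  expect_identical(a$letters, b$letters)
})

test_that("raising alpha can only split groups further", {
  classes <- vapply(c(0.01, 0.05, 0.2), function(a) {
    attr(tukey_groups(runs, "pdi", alpha = a), "n_classes")
  }, integer(1))
  expect_true(all(diff(classes) >= 0))
})

test_that("degenerate inputs are grouped by exact equality", {
  d <- data.frame(frr = rep(c(1, 2, 3), each = 3), tfr = 10,
                  pdi = rep(0.2, 9))
  d <- as_run_table(d)
  expect_message(tg <- tukey_groups(d, "pdi"), "zero")
  expect_identical(attr(tg, "n_classes"), 1L)
  d2 <- d; d2$pdi <- rep(c(0.1, 0.2, 0.3), each = 3)
  expect_message(tg2 <- tukey_groups(d2, "pdi"), "zero")
  expect_identical(attr(tg2, "n_classes"), 3L)
  expect_error(tukey_groups(d[1:3, ], "pdi"), class = "pdmix_invalid_argument")
})

test_that("paired stability test behaves at its boundaries", {
  x <- c(50, 60, 70, 80)
  res <- paired_t(x, x)
  expect_identical(res$t, 0)
  expect_identical(res$p, 1)

  # a shift of ten within-pair SDs is detected decisively
  set.seed(1)
  before <- rnorm(10, 100, 5)
  after <- before + 10 * 1 + rnorm(10, 0, 1)
  expect_lt(paired_t(before, after)$p, 1e-3)
  expect_gt(paired_t(before, after)$mean_difference, 0)

  expect_warning(res0 <- paired_t(c(1, 2, 3), c(2, 3, 4)), "exact limit")
  expect_identical(res0$p, 0)
  expect_error(paired_t(1, 2), class = "pdmix_invalid_argument")
  expect_error(paired_t(c(1, 2), c(1, 2, 3)), class = "pdmix_invalid_argument")
})

test_that("the paired test holds its nominal type-I rate", {
  set.seed(2024)
  rejections <- mean(vapply(seq_len(500), function(s) {
    before <- rnorm(8, 100, 10)
    after <- before + rnorm(8, 0, 4)
    paired_t(before, after)$p < 0.05
  }, logical(1)))
  expect_gt(rejections, 0.02)
  expect_lt(rejections, 0.09)
})

test_that("agreement with the reference paired t-test on regular data", {
  set.seed(3)
  before <- rnorm(12, 80, 6)
  after <- before + rnorm(12, 1, 2)
  res <- paired_t(before, after)
  ref <- t.test(after, before, paired = TRUE)
  expect_equal(res$t, unname(ref$statistic))
  expect_equal(res$p, ref$p.value)
  expect_equal(res$mean_difference, unname(ref$estimate))
})
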