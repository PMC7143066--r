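QUAD_TERMS <- c("FRR", "TFR", "FRR^2", "TFR^2", "FRR:TFR")

term_to_formula <- function(term) {
  switch(term,
    "FRR" = "frr", "TFR" = "tfr",
    "FRR^2" = "I(frr^2)", "TFR^2" = "I(tfr^2)",
    "FRR:TFR" = "frr:tfr",
    stop_invalid("unknown model term '", term, "'")
  )
}

term_parents <- function(term) {
  switch(term,
    "FRR^2" = "FRR", "TFR^2" = "TFR", "FRR:TFR" = c("FRR", "TFR"),
    character(0)
  )
}

#' The full quadratic term set
#'
#' Terms available to the response-surface models: the two main effects, both
#' pure quadratics and the interaction (the intercept is always present and is
#' not listed).
#'
#' @return Character vector of term labels.
#' @export
full_quadratic_terms <- function() QUAD_TERMS

#' Fit a quadratic response-surface model
#'
#' Ordinary least squares on the natural (pump-realisable, rounded) factor
#' settings of a run table, for a chosen subset of the quadratic terms. Rows
#' with a missing response are skipped with a message. The returned model
#' carries the coefficient covariance `sigma^2 (X'X)^{-1}`, residuals and
#' per-observation leverages used by [goodness_of_fit()] and
#' [predict.surface_model()].
#'
#' @param runs a run table with the response measured.
#' @param response response column name (e.g. `"z_average_nm"`, `"pdi"`).
#' @param terms character vector of term labels from [full_quadratic_terms()];
#'   may be empty for an intercept-only model.
#' @param factor_values fit on `"natural"` (default) or `"coded"` factor
#'   values. Fit statistics and predictions are invariant to this choice; only
#'   the coefficient scale changes.
#' @return An object of class `surface_model`.
#' @examples
#' m <- fit_quadratic(pdm_runs(), "z_average_nm", c("FRR", "TFR", "FRR^2"))
#' coef(m)
#' @export
fit_quadratic <- function(runs, response, terms = full_quadratic_terms(),
                          factor_values = c("natural", "coded")) {
  stopifnot(is.data.frame(runs))
  factor_values <- match.arg(factor_values)
  if (!response %in% names(runs)) {
    stop_invalid("no response column '", response, "'")
  }
  terms <- unique(as.character(terms))
  bad <- setdiff(terms, QUAD_TERMS)
  if (length(bad)) stop_invalid("unknown term(s): ", paste(bad, collapse = ", "))

  dat <- data.frame(
    frr = if (factor_values == "natural") runs$frr else runs$frr_coded,
    tfr = if (factor_values == "natural") runs$tfr else runs$tfr_coded,
    .response = runs[[response]]
  )
  n_dropped <- sum(!complete.cases(dat))
  if (n_dropped > 0) {
    message(n_dropped, " run(s) without a measured ", response, " skipped")
    dat <- dat[complete.cases(dat), , drop = FALSE]
  }
  rhs <- if (length(terms)) vapply(terms, term_to_formula, "") else "1"
  if (nrow(dat) < length(terms) + 2L) {
    stop_invalid("need at least ", length(terms) + 2L,
                 " measured runs to fit ", length(terms) + 1L,
                 " coefficients with a residual degree of freedom")
  }
  fit <- lm(reformulate(rhs, ".response"), data = dat)
  # summary()/vcov() warn on interpolating fits, which are legitimate here
  # (noise-free synthetic data)
  sfit <- suppressWarnings(summary(fit))
  if (fit$rank < length(terms) + 1L) {
    stop(errorCondition(
      paste0("singular design: the runs do not support the term set {",
             paste(terms, collapse = ", "), "}"),
      class = c("pdmix_singular_design", "error")
    ))
  }
  coefs <- coef(fit)
  names(coefs) <- c("(Intercept)", terms)
  structure(
    list(
      response = response, terms = terms, factor_values = factor_values,
      coefficients = coefs, covariance = suppressWarnings(vcov(fit)),
      df_residual = fit$df.residual, residuals = resid(fit),
      leverage = hatvalues(fit), sigma = sfit$sigma,
      n = nrow(dat), n_dropped = n_dropped, data = dat, fit = fit,
      summary = sfit
    ),
    class = "surface_model"
  )
}

#' @export
coef.surface_model <- function(object, ...) object$coefficients

#' @export
print.surface_model <- function(x, digits = 4, ...) {
  b <- signif(x$coefficients, digits)
  rhs <- paste0(
    c(format(b[1]), paste0(ifelse(b[-1] >= 0, " + ", " - "),
                           vapply(abs(b[-1]), format, ""), " ", x$terms)),
    collapse = ""
  )
  cat(sprintf("Quadratic response-surface model for %s (%s factor values)\n",
              x$response, x$factor_values))
  cat("  ", x$response, " = ", rhs, "\n", sep = "")
  cat(sprintf("  n = %d, residual df = %d, residual SD = %.4g\n",
              x$n, x$df_residual, x$sigma))
  invisible(x)
}

term_pvalues <- function(model) {
  cf <- model$summary$coefficients
  p <- cf[, 4]
  names(p) <- c("(Intercept)", model$terms)
  p
}

#' Reduce a quadratic model by backward elimination
#'
#' Starting from the full quadratic term set, repeatedly refits and drops the
#' least significant removable term whose partial p-value exceeds `alpha`,
#' stopping when every remaining term is below the threshold (or only the
#' intercept is left, in which case the model is flagged not significant).
#' Removability respects hierarchy: a main effect is never dropped while its
#' square or an interaction containing it remains in the model. Term p-values
#' are partial (type-III) tests, which for OLS coincide with the coefficient
#' t-tests. The default threshold is the conventional backward-elimination
#' alpha-to-remove of 0.1; model and term significance in reports is still
#' judged at 0.05.
#'
#' @inheritParams fit_quadratic
#' @param alpha removal threshold for the partial p-values.
#' @param terms starting term set.
#' @return A list of class `reduced_model` with elements `model` (the final
#'   [fit_quadratic()] fit), `anova` (its [goodness_of_fit()] report),
#'   `dropped` (term labels in removal order) and `significant` (overall model
#'   F-test at 0.05).
#' @examples
#' r <- reduce_model(pdm_runs(), "z_average_nm")
#' r$model$terms   # FRR, TFR, FRR^2
#' r$dropped       # TFR^2 and FRR:TFR
#' @export
reduce_model <- function(runs, response, alpha = 0.1,
                         terms = full_quadratic_terms(),
                         factor_values = c("natural", "coded")) {
  factor_values <- match.arg(factor_values)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop_invalid("'alpha' must be in (0, 1)")
  }
  terms <- unique(as.character(terms))
  dropped <- character(0)
  repeat {
    model <- fit_quadratic(runs, response, terms, factor_values)
    if (!length(terms)) break
    p <- term_pvalues(model)[-1]
    protected <- unique(unlist(lapply(terms, term_parents)))
    removable <- setdiff(terms[p > alpha], protected)
    if (!length(removable)) break
    worst <- removable[which.max(p[removable])]
    dropped <- c(dropped, worst)
    terms <- setdiff(terms, worst)
  }
  report <- goodness_of_fit(model)
  structure(
    list(
      model = model, anova = report, dropped = dropped,
      significant = length(terms) > 0 && is.finite(report$model_p) &&
        report$model_p < 0.05
    ),
    class = "reduced_model"
  )
}

#' @export
print.reduced_model <- function(x, ...) {
  print(x$model)
  if (length(x$dropped)) {
    cat("  dropped:", paste(x$dropped, collapse = ", "), "\n")
  }
  if (!x$significant) cat("  model NOT significant at the 0.05 level\n")
  print(x$anova)
  invisible(x)
}

#' Goodness-of-fit and ANOVA report for a surface model
#'
#' Computes the coefficient table with partial F/p per term, the model-level
#' F-test, and the R-squared trio: `R2 = 1 - SSE/SST`, the
#' degrees-of-freedom-adjusted value, and the PRESS-based predicted R-squared
#' `1 - PRESS/SST` with `PRESS = sum((e_i / (1 - h_ii))^2)` from the
#' leave-one-out residuals. A negative predicted R-squared is floored at zero
#' for reporting (the raw value is kept in `r2_pred_raw`).
#'
#' @param model a `surface_model`.
#' @return A list of class `anova_report`.
#' @export
goodness_of_fit <- function(model) {
  stopifnot(inherits(model, "surface_model"))
  e <- model$residuals
  h <- model$leverage
  y <- model$data$.response
  n <- model$n
  p <- length(model$coefficients)
  sse <- sum(e^2)
  sst <- sum((y - mean(y))^2)
  ssr <- sst - sse
  r2 <- 1 - sse / sst
  r2_adj <- 1 - (sse / (n - p)) / (sst / (n - 1))
  if (any(h >= 1 - 1e-10)) {
    stop(errorCondition(
      "a leverage equals 1: PRESS (and predicted R-squared) is undefined",
      class = c("pdmix_press_undefined", "error")
    ))
  }
  press <- sum((e / (1 - h))^2)
  r2_pred_raw <- 1 - press / sst
  model_f <- if (p > 1) (ssr / (p - 1)) / (sse / (n - p)) else NA_real_
  model_p <- if (p > 1) pf(model_f, p - 1, n - p, lower.tail = FALSE) else NA_real_
  cf <- model$summary$coefficients
  term_table <- data.frame(
    term = c("(Intercept)", model$terms),
    estimate = cf[, 1], se = cf[, 2],
    f = cf[, 3]^2, p = cf[, 4], row.names = NULL
  )
  structure(
    list(
      response = model$response, terms = model$terms, term_table = term_table,
      sse = sse, ssr = ssr, sst = sst, press = press,
      r_squared = r2, r_squared_adj = r2_adj,
      r_squared_pred = max(0, r2_pred_raw), r2_pred_raw = r2_pred_raw,
      model_f = model_f, model_p = model_p, n = n, df_residual = n - p
    ),
    class = "anova_report"
  )
}

#' @export
print.anova_report <- function(x, ...) {
  cat(sprintf("ANOVA for %s: R2 = %.2f%%, R2-adj = %.2f%%, R2-pred = %.2f%%\n",
              x$response, 100 * x$r_squared, 100 * x$r_squared_adj,
              100 * x$r_squared_pred))
  if (is.finite(x$model_f)) {
    cat(sprintf("  model F = %.2f on %d and %d df, p = %.3g\n",
                x$model_f, length(x$terms), x$df_residual, x$model_p))
  } else {
    cat("  intercept-only model (no F-test)\n")
  }
  tt <- x$term_table
  tt$estimate <- signif(tt$estimate, 5)
  tt$se <- signif(tt$se, 4)
  tt$f <- round(tt$f, 2)
  tt$p <- signif(tt$p, 3)
  print(tt, row.names = FALSE)
  invisible(x)
}

#' Predict from a surface model with confidence bounds
#'
#' The mean prediction is `x'beta` with standard error
#' `SE_fit = sqrt(x' Cov x)`; the 95% (or `level`) confidence interval for the
#' mean is `fit +/- t(1 - (1-level)/2, df) * SE_fit`. A prediction interval for
#' a single new observation (adding the residual variance) is also returned,
#' since both conventions are in routine use. Points outside the fitted factor
#' ranges trigger an extrapolation warning.
#'
#' @param object a `surface_model`.
#' @param newdata data frame with columns `frr` and `tfr` (on the scale the
#'   model was fitted on).
#' @param level confidence level, default 0.95.
#' @param ... unused.
#' @return Data frame with `fit`, `se_fit`, `lwr`, `upr` (confidence of the
#'   mean) and `pi_lwr`, `pi_upr` (prediction interval).
#' @examples
#' m <- fit_quadratic(pdm_runs(), "z_average_nm", c("FRR", "TFR", "FRR^2"))
#' predict(m, data.frame(frr = 8.56, tfr = 18))
#' @export
predict.surface_model <- function(object, newdata, level = 0.95, ...) {
  stopifnot(is.data.frame(newdata), all(c("frr", "tfr") %in% names(newdata)))
  rng_f <- range(object$data$frr)
  rng_t <- range(object$data$tfr)
  if (any(newdata$frr < rng_f[1] | newdata$frr > rng_f[2] |
          newdata$tfr < rng_t[1] | newdata$tfr > rng_t[2])) {
    warning("prediction outside the fitted factor region (extrapolation)",
            call. = FALSE)
  }
  pr <- predict(object$fit, newdata = newdata, se.fit = TRUE)
  tq <- qt(1 - (1 - level) / 2, object$df_residual)
  se_pred <- sqrt(pr$se.fit^2 + object$sigma^2)
  data.frame(
    fit = unname(pr$fit), se_fit = unname(pr$se.fit),
    lwr = unname(pr$fit - tq * pr$se.fit),
    upr = unname(pr$fit + tq * pr$se.fit),
    pi_lwr = unname(pr$fit - tq * se_pred),
    pi_upr = unname(pr$fit + tq * se_pred)
  )
}

quad_coef <- function(model) {
  b <- model$coefficients
  g <- function(term) if (term %in% names(b)) unname(b[term]) else 0
  list(b0 = unname(b["(Intercept)"]), bf = g("FRR"), bt = g("TFR"),
       bff = g("FRR^2"), btt = g("TFR^2"), bft = g("FRR:TFR"))
}

eval_quad <- function(q, frr, tfr) {
  q$b0 + q$bf * frr + q$bt * tfr + q$bff * frr^2 + q$btt * tfr^2 +
    q$bft * frr * tfr
}

#' Optimise a fitted response over a rectangular factor region
#'
#' Exact constrained optimisation of a (bi)quadratic surface over a box. The
#' candidate set is closed-form: the unconstrained stationary point (when the
#' quadratic part is invertible) clamped to the box, the stationary point of
#' each one-dimensional edge restriction, and the four corners; the best
#' candidate in the requested sense is returned with its prediction, SE-fit and
#' confidence interval, and per-factor boundary flags. For a factor that enters
#' only linearly the optimum is pushed to the bound favoured by the coefficient
#' sign, as expected.
#'
#' @param model a `surface_model` fitted on natural factor values.
#' @param bounds named list with elements `frr` and `tfr`, each `c(lower,
#'   upper)`.
#' @param sense `"min"` or `"max"`.
#' @param level confidence level for the interval at the optimum.
#' @return A list of class `optimum_result` with `frr`, `tfr`, `predicted`,
#'   `se_fit`, `ci`, `at_bound` (named logical) and `candidates`.
#' @examples
#' m <- fit_quadratic(pdm_runs(), "z_average_nm", c("FRR", "TFR", "FRR^2"))
#' optimize_response(m, list(frr = c(1, 12), tfr = c(3, 18)), "min")
#' @export
optimize_response <- function(model, bounds, sense = c("min", "max"),
                              level = 0.95) {
  stopifnot(inherits(model, "surface_model"))
  sense <- match.arg(sense)
  if (!is.list(bounds) || !all(c("frr", "tfr") %in% names(bounds))) {
    stop_invalid("'bounds' must be a list with elements 'frr' and 'tfr'")
  }
  bf <- sort(as.numeric(bounds$frr))
  bt <- sort(as.numeric(bounds$tfr))
  if (length(bf) != 2 || length(bt) != 2 || any(!is.finite(c(bf, bt)))) {
    q <- quad_coef(model)
    if ((q$bff == 0 && q$bf != 0) || (q$btt == 0 && q$bt != 0)) {
      stop_invalid("unbounded linear response requires finite bounds")
    }
    stop_invalid("bounds must be finite intervals")
  }
  q <- quad_coef(model)
  clamp <- function(x, b) min(max(x, b[1]), b[2])
  cand <- list()
  add <- function(f, t) cand[[length(cand) + 1]] <<- c(frr = f, tfr = t)

  # unconstrained stationary point of the full quadratic, when it exists
  H <- matrix(c(2 * q$bff, q$bft, q$bft, 2 * q$btt), 2, 2)
  if (abs(det(H)) > 1e-12) {
    st <- solve(H, -c(q$bf, q$bt))
    add(clamp(st[1], bf), clamp(st[2], bt))
  }
  # edge restrictions: fix one factor at a bound, optimise the 1-D quadratic
  for (t0 in bt) { # frr free
    a2 <- q$bff
    a1 <- q$bf + q$bft * t0
    if (a2 != 0) add(clamp(-a1 / (2 * a2), bf), t0)
  }
  for (f0 in bf) { # tfr free
    a2 <- q$btt
    a1 <- q$bt + q$bft * f0
    if (a2 != 0) add(f0, clamp(-a1 / (2 * a2), bt))
  }
  for (f0 in bf) for (t0 in bt) add(f0, t0)

  cmat <- unique(do.call(rbind, cand))
  vals <- eval_quad(q, cmat[, "frr"], cmat[, "tfr"])
  best <- if (sense == "min") which.min(vals) else which.max(vals)
  opt <- cmat[best, ]
  pr <- suppressWarnings(
    predict(model, data.frame(frr = opt["frr"], tfr = opt["tfr"]), level = level)
  )
  tol <- 1e-8
  structure(
    list(
      frr = unname(opt["frr"]), tfr = unname(opt["tfr"]),
      predicted = pr$fit, se_fit = pr$se_fit, ci = c(pr$lwr, pr$upr),
      sense = sense, bounds = list(frr = bf, tfr = bt),
      at_bound = c(
        frr = any(abs(opt["frr"] - bf) < tol),
        tfr = any(abs(opt["tfr"] - bt) < tol)
      ),
      candidates = data.frame(cmat, value = vals)
    ),
    class = "optimum_result"
  )
}

#' @export
print.optimum_result <- function(x, ...) {
  cat(sprintf("%s of the fitted response at FRR = %.2f%s, TFR = %.2f%s\n",
              if (x$sense == "min") "Minimum" else "Maximum",
              x$frr, if (x$at_bound["frr"]) " (bound)" else "",
              x$tfr, if (x$at_bound["tfr"]) " (bound)" else ""))
  cat(sprintf("  predicted %.2f (SE fit %.2f), 95%% CI [%.2f, %.2f]\n",
              x$predicted, x$se_fit, x$ci[1], x$ci[2]))
  invisible(x)
}
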