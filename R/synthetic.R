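#' Generating truth for synthetic run tables
#'
#' The default generating surfaces are the study's fitted reduced models: size
#' `236.3 - 26.95 FRR - 4.437 TFR + 1.573 FRR^2` (nm) and PDI
#' `0.0663 + 0.03181 FRR + 0.00319 TFR - 0.001905 FRR^2`, with homoscedastic
#' Gaussian replicate noise, and a factor-independent Gaussian zeta potential.
#' The default noise levels emulate the measured study: a size SD of 6 nm
#' (mid-range of the observed replicate SDs of 0.43-11.48 nm), a PDI SD of
#' 0.02 and zeta potential at -31.5 +/- 4 mV, matching the replicate spread of
#' the measured table.
#'
#' @param size_coef,pdi_coef named coefficients over `(Intercept)`, `FRR`,
#'   `TFR`, `FRR^2` (and optionally `TFR^2`, `FRR:TFR`).
#' @param sd_size,sd_pdi replicate noise SDs (`>= 0`), nm and dimensionless.
#' @param zeta_mean,zeta_sd zeta potential distribution (mV).
#' @return An object of class `truth_spec`.
#' @export
truth_spec <- function(size_coef = c("(Intercept)" = 236.3, "FRR" = -26.95,
                                     "TFR" = -4.437, "FRR^2" = 1.573),
                       pdi_coef = c("(Intercept)" = 0.0663, "FRR" = 0.03181,
                                    "TFR" = 0.00319, "FRR^2" = -0.001905),
                       sd_size = 6, sd_pdi = 0.02,
                       zeta_mean = -31.5, zeta_sd = 4) {
  for (s in c(sd_size, sd_pdi, zeta_sd)) {
    if (!is.numeric(s) || length(s) != 1 || s < 0) {
      stop_invalid("noise SDs must be non-negative numbers")
    }
  }
  check_coef <- function(b, what) {
    allowed <- c("(Intercept)", QUAD_TERMS)
    if (is.null(names(b)) || !all(names(b) %in% allowed)) {
      stop_invalid(what, " coefficients must be named among: ",
                   paste(allowed, collapse = ", "))
    }
    b
  }
  structure(
    list(size_coef = check_coef(size_coef, "size"),
         pdi_coef = check_coef(pdi_coef, "PDI"),
         sd_size = sd_size, sd_pdi = sd_pdi,
         zeta_mean = zeta_mean, zeta_sd = zeta_sd),
    class = "truth_spec"
  )
}

eval_truth_surface <- function(coefs, frr, tfr) {
  basis <- cbind("(Intercept)" = 1, "FRR" = frr, "TFR" = tfr,
                 "FRR^2" = frr^2, "TFR^2" = tfr^2, "FRR:TFR" = frr * tfr)
  drop(basis[, names(coefs), drop = FALSE] %*% coefs)
}

#' Simulate responses for a design
#'
#' Fills the response columns of a design run table from a [truth_spec()]:
#' size and PDI are the generating surfaces plus i.i.d. Gaussian noise (PDI
#' clipped into (0, 1), clip events reported via a message), and zeta
#' potential is drawn independently of the factors. Deterministic for a fixed
#' seed; the caller's RNG state is untouched.
#'
#' @param design a run table with natural factor values (responses ignored).
#' @param truth a [truth_spec()].
#' @param seed integer seed.
#' @return The run table with `z_average_nm`, `pdi` and `zeta_mv` filled.
#' @examples
#' tab <- generate_run_table(build_cccr_design(pdm_design_spec()), seed = 7)
#' @export
generate_run_table <- function(design, truth = truth_spec(), seed = NULL) {
  stopifnot(is.data.frame(design))
  if (!inherits(truth, "truth_spec")) stop_invalid("'truth' must be a truth_spec")
  n <- nrow(design)
  out <- design
  vals <- with_seed(seed, {
    list(
      size = eval_truth_surface(truth$size_coef, design$frr, design$tfr) +
        rnorm(n, 0, truth$sd_size),
      pdi = eval_truth_surface(truth$pdi_coef, design$frr, design$tfr) +
        rnorm(n, 0, truth$sd_pdi),
      zeta = rnorm(n, truth$zeta_mean, truth$zeta_sd)
    )
  })
  eps <- 1e-6
  n_clip <- sum(vals$pdi <= 0 | vals$pdi >= 1)
  if (n_clip > 0) message(n_clip, " PDI value(s) clipped into (0, 1)")
  out$z_average_nm <- vals$size
  out$pdi <- pmin(pmax(vals$pdi, eps), 1 - eps)
  out$zeta_mv <- vals$zeta
  as_run_table(out)
}

#' Simulate a validation sweep at fixed TFR
#'
#' Replicated runs along a list of FRR values at one TFR, generated by the
#' same mechanism as [generate_run_table()] — the design used to validate the
#' fitted size model around its predicted minimum.
#'
#' @param frr_values FRR settings to visit.
#' @param tfr fixed total flow rate (mL/h).
#' @param truth a [truth_spec()].
#' @param n_rep replicates per FRR value, default 3.
#' @param seed integer seed.
#' @return A run table with `n_rep * length(frr_values)` rows.
#' @examples
#' sweep <- generate_validation_sweep(c(1, 3, 5, 7, 9, 12), tfr = 18, seed = 1)
#' @export
generate_validation_sweep <- function(frr_values, tfr = 18,
                                      truth = truth_spec(), n_rep = 3,
                                      seed = NULL) {
  if (!is.numeric(frr_values) || !length(frr_values) || any(frr_values <= 0)) {
    stop_invalid("'frr_values' must be positive numbers")
  }
  if (!is_count(n_rep)) stop_invalid("'n_rep' must be a positive integer")
  frr <- rep(as.numeric(frr_values), each = n_rep)
  design <- data.frame(run_order = seq_along(frr), frr = frr, tfr = tfr)
  generate_run_table(as_run_table(design), truth = truth, seed = seed)
}
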