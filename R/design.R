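#' Describe a design factor
#'
#' A factor is described by its name, the natural-unit extremes of the
#' experimental region, and the rounding precision at which settings can
#' actually be realised (syringe pumps resolve 0.1 mL/h, hence the default of
#' one decimal). For the rotatable composite design built by
#' [build_cccr_design()] the extremes are interpreted as the *axial* positions
#' (coded +/- alpha); the factorial "cube" levels are derived inside them.
#'
#' @param name factor name; lower-cased to form the run-table column name.
#' @param low,high natural-unit extremes of the region (`low < high`).
#' @param decimals non-negative integer; settings are rounded to this many
#'   decimals before being stored.
#' @return An object of class `factor_spec`.
#' @examples
#' factor_spec("FRR", 1, 12)
#' @export
factor_spec <- function(name, low, high, decimals = 1) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop_invalid("'name' must be a non-empty string")
  }
  if (!is.numeric(low) || !is.numeric(high) || length(low) != 1L ||
      length(high) != 1L || !is.finite(low) || !is.finite(high) ||
      low >= high) {
    stop_invalid("factor '", name, "': need finite low < high")
  }
  if (!is.numeric(decimals) || length(decimals) != 1L || decimals < 0 ||
      decimals != round(decimals)) {
    stop_invalid("factor '", name, "': 'decimals' must be a non-negative integer")
  }
  structure(
    list(name = name, low = low, high = high, decimals = as.integer(decimals)),
    class = "factor_spec"
  )
}

#' Axial distance of a rotatable central composite design
#'
#' The coded distance from the centre to an axial point that makes a central
#' composite design rotatable is `(2^k)^(1/4)` for `k` factors. The value is
#' conventionally reported at two decimals (1.41 for two factors) but used at
#' full precision in all conversions.
#'
#' @param k integer number of factors, `k >= 1`.
#' @return The axial distance in coded units.
#' @examples
#' compute_alpha(2) # sqrt(sqrt(4)) = 1.4142...
#' @export
compute_alpha <- function(k) {
  if (!is_count(k)) stop_invalid("'k' must be a positive integer")
  (2^k)^(1 / 4)
}

#' Specify a central composite rotatable design
#'
#' Bundles the factors with the replication scheme and the coded axial
#' distance. The default `alpha` is the rotatable value [compute_alpha()] for
#' the number of factors supplied. The total run count is
#' `2k * axial_reps + 2^k * cube_reps + center_reps`.
#'
#' @param factors list of [factor_spec()] objects.
#' @param alpha coded axial distance; default rotatable.
#' @param cube_reps,axial_reps,center_reps replicate counts (each `>= 1`).
#' @param seed optional integer recorded in the design and used by
#'   [build_cccr_design()] to randomise the run order.
#' @return An object of class `design_spec`.
#' @seealso [pdm_design_spec()] for the study's own design.
#' @export
design_spec <- function(factors, alpha = NULL, cube_reps = 1, axial_reps = 1,
                        center_reps = 1, seed = NULL) {
  if (!is.list(factors) || !length(factors) ||
      !all(vapply(factors, inherits, logical(1), "factor_spec"))) {
    stop_invalid("'factors' must be a non-empty list of factor_spec objects")
  }
  k <- length(factors)
  if (is.null(alpha)) alpha <- compute_alpha(k)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0) {
    stop_invalid("'alpha' must be a positive number")
  }
  for (r in c(cube_reps, axial_reps, center_reps)) {
    if (!is_count(r)) stop_invalid("replicate counts must be positive integers")
  }
  structure(
    list(
      factors = factors, k = k, alpha = alpha,
      cube_reps = as.integer(cube_reps), axial_reps = as.integer(axial_reps),
      center_reps = as.integer(center_reps), seed = seed
    ),
    class = "design_spec"
  )
}

#' The study's two-factor design
#'
#' Convenience constructor for the design actually run on the
#' periodic-disturbance micromixer: FRR from 1.0 to 12.0 and TFR from 3.0 to
#' 18.0 mL/h as axial extremes, three replicates of each cube and axial point
#' and five centre replicates — 29 runs over 9 distinct conditions.
#'
#' @param seed run-order randomisation seed.
#' @return A `design_spec`.
#' @export
pdm_design_spec <- function(seed = 1L) {
  design_spec(
    factors = list(
      factor_spec("FRR", 1.0, 12.0, decimals = 1),
      factor_spec("TFR", 3.0, 18.0, decimals = 1)
    ),
    cube_reps = 3, axial_reps = 3, center_reps = 5, seed = seed
  )
}

#' @export
print.design_spec <- function(x, ...) {
  n <- 2 * x$k * x$axial_reps + 2^x$k * x$cube_reps + x$center_reps
  cat(sprintf(
    "Central composite rotatable design: %d factor(s), alpha = %.2f, %d runs\n",
    x$k, x$alpha, n
  ))
  for (f in x$factors) {
    cat(sprintf("  %s: axial extremes [%g, %g], %d decimal(s)\n",
                f$name, f$low, f$high, f$decimals))
  }
  invisible(x)
}

factor_columns <- function(spec) tolower(vapply(spec$factors, `[[`, "", "name"))

#' Convert coded design coordinates to natural units
#'
#' The centre is the midpoint of the axial extremes and one coded unit equals
#' `half_axial_range / alpha`, so the extremes sit at coded +/- alpha. Natural
#' values are rounded to each factor's realisable precision;
#' [natural_to_coded()] inverts the unrounded mapping exactly, so a round trip
#' is accurate to the rounding precision.
#'
#' @param coded numeric vector (one point) or matrix (points in rows) of coded
#'   coordinates, one column per factor.
#' @param spec a [design_spec()].
#' @param round round to the factors' `decimals`? Default `TRUE`.
#' @return Matrix of natural coordinates with factor-named columns.
#' @examples
#' sp <- pdm_design_spec()
#' coded_to_natural(c(0, 0), sp)       # the centre point: FRR 6.5, TFR 10.5
#' coded_to_natural(c(-1, -1), sp)     # cube corner: FRR 2.6, TFR 5.2
#' @export
coded_to_natural <- function(coded, spec, round = TRUE) {
  stopifnot(inherits(spec, "design_spec"))
  m <- to_point_matrix(coded, spec)
  out <- m
  for (j in seq_len(spec$k)) {
    f <- spec$factors[[j]]
    centre <- (f$low + f$high) / 2
    unit <- (f$high - f$low) / 2 / spec$alpha
    out[, j] <- centre + m[, j] * unit
    if (round) out[, j] <- round(out[, j], f$decimals)
  }
  colnames(out) <- factor_columns(spec)
  out
}

#' @rdname coded_to_natural
#' @param natural numeric vector or matrix of natural coordinates.
#' @export
natural_to_coded <- function(natural, spec) {
  stopifnot(inherits(spec, "design_spec"))
  m <- to_point_matrix(natural, spec)
  out <- m
  for (j in seq_len(spec$k)) {
    f <- spec$factors[[j]]
    centre <- (f$low + f$high) / 2
    unit <- (f$high - f$low) / 2 / spec$alpha
    out[, j] <- (m[, j] - centre) / unit
  }
  colnames(out) <- paste0(factor_columns(spec), "_coded")
  out
}

to_point_matrix <- function(x, spec) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  if (ncol(x) != spec$k) {
    stop_invalid("point has ", ncol(x), " column(s); design has ", spec$k,
                 " factor(s)")
  }
  storage.mode(x) <- "double"
  x
}

#' Build the central composite rotatable run table
#'
#' Lays out `2^k` factorial (cube) points at coded +/- 1, `2k` axial points at
#' coded +/- alpha and the centre point, replicates each according to the
#' design's scheme, converts to rounded natural units and randomises the run
#' order with the design's seed. For [pdm_design_spec()] this reproduces the
#' study's 29-run table over the 9 distinct (FRR, TFR) conditions.
#'
#' @param spec a [design_spec()].
#' @return A [run_table()] with empty (`NA`) response columns.
#' @examples
#' d <- build_cccr_design(pdm_design_spec(seed = 7))
#' nrow(d)                       # 29
#' nrow(unique(d[c("frr", "tfr")])) # 9
#' @export
build_cccr_design <- function(spec) {
  stopifnot(inherits(spec, "design_spec"))
  k <- spec$k
  cube <- as.matrix(expand.grid(rep(list(c(-1, 1)), k)))
  axial <- matrix(0, nrow = 2 * k, ncol = k)
  for (j in seq_len(k)) {
    axial[2 * j - 1, j] <- -spec$alpha
    axial[2 * j, j] <- spec$alpha
  }
  centre <- matrix(0, nrow = 1, ncol = k)
  coded <- rbind(
    cube[rep(seq_len(nrow(cube)), each = spec$cube_reps), , drop = FALSE],
    axial[rep(seq_len(nrow(axial)), each = spec$axial_reps), , drop = FALSE],
    centre[rep(1, spec$center_reps), , drop = FALSE]
  )
  natural <- coded_to_natural(coded, spec)
  coded <- round(coded, 6)
  colnames(coded) <- paste0(factor_columns(spec), "_coded")
  tab <- data.frame(run_order = seq_len(nrow(coded)), natural, coded,
                    check.names = FALSE)
  if (spec$k == 2 && identical(factor_columns(spec), c("frr", "tfr"))) {
    tab$z_average_nm <- NA_real_
    tab$pdi <- NA_real_
    tab$zeta_mv <- NA_real_
  }
  tab <- as_run_table(tab, factors = factor_columns(spec))
  attr(tab, "design") <- spec
  randomize_run_order(tab, seed = spec$seed)
}

#' Randomise the run order of a run table
#'
#' Draws a uniform permutation of the rows from a seeded generator and renumbers
#' `run_order` 1..n in the new order. The caller's RNG state is left untouched.
#'
#' @param table a [run_table()].
#' @param seed integer seed; `NULL` leaves the order unchanged.
#' @return The permuted run table.
#' @export
randomize_run_order <- function(table, seed = NULL) {
  stopifnot(is.data.frame(table))
  if (!nrow(table)) stop_invalid("run table is empty")
  if (is.null(seed)) return(table)
  perm <- with_seed(seed, sample.int(nrow(table)))
  out <- table[perm, , drop = FALSE]
  out$run_order <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Split a total flow rate into aqueous and organic inlet flows
#'
#' The aqueous (water) and organic (lipid-in-ethanol) syringe flows that
#' realise a total flow rate TFR at aqueous:organic flow rate ratio FRR are
#' `Q_as = FRR * TFR / (1 + FRR)` and `Q_os = TFR / (1 + FRR)`. They sum to
#' TFR exactly and their ratio is FRR; [flows_to_tfr_frr()] is the exact
#' inverse.
#'
#' @param tfr total flow rate (mL/h), `> 0`. Vectorised.
#' @param frr flow rate ratio (dimensionless), `> 0`. Vectorised.
#' @return A data frame with columns `q_as` and `q_os` (mL/h).
#' @examples
#' split_flows(18, 1)      # symmetric 9 + 9
#' split_flows(10.5, 6.5)  # the centre condition
#' @export
split_flows <- function(tfr, frr) {
  if (!is.numeric(tfr) || !is.numeric(frr) || any(!is.finite(tfr)) ||
      any(!is.finite(frr)) || any(tfr <= 0) || any(frr <= 0)) {
    stop_invalid("'tfr' and 'frr' must be positive and finite")
  }
  data.frame(q_as = frr * tfr / (1 + frr), q_os = tfr / (1 + frr))
}

#' @rdname split_flows
#' @param q_as,q_os aqueous and organic flows (mL/h), `> 0`.
#' @export
flows_to_tfr_frr <- function(q_as, q_os) {
  if (!is.numeric(q_as) || !is.numeric(q_os) || any(!is.finite(q_as)) ||
      any(!is.finite(q_os)) || any(q_as <= 0) || any(q_os <= 0)) {
    stop_invalid("flows must be positive and finite")
  }
  data.frame(tfr = q_as + q_os, frr = q_as / q_os)
}
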