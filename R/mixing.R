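#' Danckwerts intensity-of-segregation mixing efficiency
#'
#' `section_variance()` samples a cross-section on a regular grid and returns
#' the concentration variance (the intensity of segregation before
#' normalisation); `mixing_efficiency()` converts a section variance into the
#' mixing-efficiency percentage `ME = (1 - sigma2 / sigma0_2) * 100`, clamped
#' to [0, 100], where `sigma0_2` is the variance at the channel start with the
#' streams fully unmixed (for a segregated binary section with organic
#' fraction p this is `p (1 - p)`).
#'
#' @param values concentration samples over the section grid.
#' @return `section_variance()`: the population variance of the samples.
#' @export
section_variance <- function(values) {
  values <- values[!is.na(values)]
  if (!length(values)) stop_invalid("no samples in section")
  mean((values - mean(values))^2)
}

#' @rdname section_variance
#' @param sigma2 section concentration variance.
#' @param sigma0_2 unmixed-inlet concentration variance (`> 0`).
#' @export
mixing_efficiency <- function(sigma2, sigma0_2) {
  if (!is.numeric(sigma0_2) || any(sigma0_2 <= 0)) {
    stop(errorCondition(
      "sigma0^2 must be positive: mixing efficiency is undefined for an already uniform inlet",
      class = c("pdmix_undefined_me", "error")
    ))
  }
  pmin(pmax((1 - sigma2 / sigma0_2) * 100, 0), 100)
}

# Sample a transport field's cross-section at streamwise position x on `grid`
# equally spaced transverse points (points falling in an obstacle are dropped,
# i.e. the section is the open part of the channel).
sample_section <- function(field, x, grid = 50) {
  g <- field$grid
  i <- min(max(1L, ceiling(x / g$dx)), g$nx)
  ys <- (seq_len(grid) - 0.5) * g$geom$width / grid
  j <- pmin(pmax(1L, ceiling(ys / g$dy)), g$ny)
  field$c[cbind(i, j)]
}

#' Mixing-efficiency profile along the channel
#'
#' Evaluates the Danckwerts mixing efficiency at `stations` cross-sections
#' spaced evenly along the channel (10 by default). The reference variance
#' `sigma0^2` is taken at the channel entry, where the aqueous and organic
#' streams are fully segregated with the organic stream occupying the area
#' below the streamline carrying the organic flux fraction `1 / (1 + FRR)`.
#'
#' @param field a [solve_transport()] result.
#' @param stations number of stations along the path.
#' @param grid transverse sample points per section. (The published
#'   three-dimensional analysis uses a 50 x 50 section grid; in the planar
#'   model the section is a line, sampled at `grid` points.)
#' @return A data frame of class `mixing_profile` with `station`,
#'   `position_mm`, `sigma2` and `me_percent`; the unmixed variance is in
#'   `attr(, "sigma0_2")`.
#' @export
mixing_profile <- function(field, stations = 10, grid = 50) {
  stopifnot(inherits(field, "transport_field"))
  if (!is_count(stations)) stop_invalid("'stations' must be a positive integer")
  g <- field$grid
  w <- g$geom$width
  # unmixed inlet variance from the inlet interface position in area terms:
  # psi is the cumulative flux, so the interface sits where psi crosses the
  # organic flux fraction of the total
  psi_in <- field$flow$psi[1, ]
  q2 <- field$flow$q2
  y_star <- approx(psi_in, g$yn, xout = q2 / (1 + field$frr), ties = "ordered")$y
  ys <- (seq_len(grid) - 0.5) * w / grid
  sigma0_2 <- section_variance(as.numeric(ys < y_star))
  if (sigma0_2 <= 0) {
    stop(errorCondition("unmixed inlet variance is zero",
                        class = c("pdmix_undefined_me", "error")))
  }
  xs <- seq_len(stations) / stations * g$geom$total_length
  sigma2 <- vapply(xs, function(x) section_variance(sample_section(field, x, grid)),
                   numeric(1))
  out <- data.frame(
    station = seq_len(stations), position_mm = xs * 1e3,
    sigma2 = sigma2, me_percent = mixing_efficiency(sigma2, sigma0_2)
  )
  attr(out, "sigma0_2") <- sigma0_2
  attr(out, "grid") <- grid
  attr(out, "frr") <- field$frr
  class(out) <- c("mixing_profile", "data.frame")
  out
}

#' Path distance at which a mixing threshold is reached
#'
#' Linear interpolation of the mixing-efficiency profile (anchored at ME = 0
#' at the channel entry) to find where it first crosses the threshold. A
#' profile that never reaches the threshold yields a censored result, not an
#' error.
#'
#' @param profile a [mixing_profile()].
#' @param threshold mixing-efficiency threshold in percent (default 90).
#' @return A list with `distance_mm` (`NA` when censored), `censored` and
#'   `threshold`.
#' @export
distance_to_threshold <- function(profile, threshold = 90) {
  stopifnot(inherits(profile, "mixing_profile"))
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 100) {
    stop_invalid("'threshold' must be in (0, 100]")
  }
  x <- c(0, profile$position_mm)
  me <- c(0, profile$me_percent)
  k <- which(me >= threshold)[1]
  if (is.na(k)) {
    return(list(distance_mm = NA_real_, censored = TRUE, threshold = threshold))
  }
  if (k == 1) {
    return(list(distance_mm = x[1], censored = FALSE, threshold = threshold))
  }
  frac <- (threshold - me[k - 1]) / (me[k] - me[k - 1])
  list(distance_mm = x[k - 1] + frac * (x[k] - x[k - 1]),
       censored = FALSE, threshold = threshold)
}

#' Transverse non-uniformity of the concentration profile
#'
#' Coefficient of variation of the sampled cross-section concentrations at
#' each station — a scalar summary of how non-uniform the transverse
#' concentration profile is, used to compare mixing uniformity across flow
#' rate ratios.
#'
#' @inheritParams mixing_profile
#' @return Data frame with `station`, `position_mm` and `cv`.
#' @export
transverse_nonuniformity <- function(field, stations = 10, grid = 50) {
  stopifnot(inherits(field, "transport_field"))
  g <- field$grid
  xs <- seq_len(stations) / stations * g$geom$total_length
  cv <- vapply(xs, function(x) {
    v <- sample_section(field, x, grid)
    v <- v[!is.na(v)]
    sqrt(mean((v - mean(v))^2)) / mean(v)
  }, numeric(1))
  data.frame(station = seq_len(stations), position_mm = xs * 1e3, cv = cv)
}

#' Mixing study across flow rate ratios
#'
#' Runs the desk-scale simulator at a fixed total flow rate for several flow
#' rate ratios and reports, for each, the path distance at which the mixing
#' efficiency first reaches a threshold. The flow field is solved once (it
#' depends only on TFR) and the species transport once per FRR.
#'
#' @param frr_values flow rate ratios to simulate.
#' @param tfr total flow rate (mL/h).
#' @param geom channel geometry.
#' @param properties property model (its `dispersion_factor` can add
#'   effective transverse diffusivity; see the vignette for why the default
#'   keeps the molecular value).
#' @param ny transverse cells.
#' @param stations stations per profile; the default places roughly one per
#'   obstacle so the threshold crossing is resolved.
#' @param threshold mixing-efficiency threshold (percent).
#' @return A data frame with one row per FRR: `frr`, `distance_mm`,
#'   `censored`, `me_outlet`; profiles in `attr(, "profiles")`.
#' @export
mixing_study <- function(frr_values = c(1, 3, 5, 9), tfr = 18,
                         geom = build_geometry(),
                         properties = property_model(),
                         ny = 30, stations = NULL, threshold = 90) {
  if (is.null(stations)) stations <- max(20L, geom$obstacle_count + 5L)
  grid <- discretize_geometry(geom, ny = ny)
  flow <- solve_flow(geom, tfr = tfr, frr = frr_values[1],
                     properties = properties, grid = grid)
  profiles <- list()
  rows <- lapply(frr_values, function(f) {
    tr <- solve_transport(flow, properties = properties, frr = f)
    pr <- mixing_profile(tr, stations = stations)
    profiles[[as.character(f)]] <<- pr
    d <- distance_to_threshold(pr, threshold)
    data.frame(frr = f, distance_mm = d$distance_mm, censored = d$censored,
               me_outlet = pr$me_percent[nrow(pr)])
  })
  out <- do.call(rbind, rows)
  attr(out, "profiles") <- profiles
  attr(out, "tfr") <- tfr
  attr(out, "threshold") <- threshold
  out
}
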