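#' Packaged water-ethanol mixture property table
#'
#' Loads the packaged 25 C table of density, dynamic viscosity and mutual
#' diffusivity of the water-ethanol binary versus ethanol mass fraction,
#' converted to SI units (kg/m3, Pa s, m2/s). The file header documents the
#' provenance of the values.
#'
#' @return Data frame with columns `c` (ethanol mass fraction), `density`,
#'   `viscosity`, `diffusivity`.
#' @export
water_ethanol_table <- function() {
  path <- system.file("extdata", "water_ethanol_properties_25C.csv",
                      package = "pdmix", mustWork = TRUE)
  raw <- read.csv(path, comment.char = "#")
  data.frame(
    c = raw$w_ethanol,
    density = raw$density_kg_m3,
    viscosity = raw$viscosity_mpa_s * 1e-3,
    diffusivity = raw$diffusivity_1e9_m2_s * 1e-9
  )
}

#' Fit a property polynomial in composition
#'
#' Least-squares polynomial (default order 5) for a fluid property as a
#' function of ethanol mass fraction `c` in [0, 1], as used to give the
#' single-phase mixing model concentration-dependent density, viscosity and
#' diffusivity.
#'
#' @param table data frame whose first column is the composition `c` and
#'   second column the property value (any further columns ignored), or a
#'   two-column matrix.
#' @param order polynomial order; needs at least `order + 1` distinct
#'   compositions.
#' @return An object of class `property_poly` with the coefficients (constant
#'   term first), residuals and a `predict()` method.
#' @examples
#' tab <- water_ethanol_table()
#' rho <- fit_property_polynomial(tab[c("c", "density")], order = 5)
#' predict(rho, c(0, 0.5, 1))
#' @export
fit_property_polynomial <- function(table, order = 5) {
  table <- as.data.frame(table)
  if (ncol(table) < 2) stop_invalid("'table' needs composition and value columns")
  cc <- as.numeric(table[[1]])
  val <- as.numeric(table[[2]])
  if (anyNA(cc) || anyNA(val)) stop_invalid("property table contains NA")
  if (!is_count(order + 1)) stop_invalid("'order' must be a non-negative integer")
  if (length(unique(cc)) < order + 1) {
    stop_invalid("need at least ", order + 1, " distinct compositions for an ",
                 "order-", order, " polynomial")
  }
  X <- outer(cc, 0:order, `^`)
  fit <- lm.fit(X, val)
  structure(
    list(coefficients = setNames(fit$coefficients, paste0("c^", 0:order)),
         order = order, residuals = fit$residuals,
         rms_residual = sqrt(mean(fit$residuals^2)), data = data.frame(c = cc, value = val)),
    class = "property_poly"
  )
}

#' @export
predict.property_poly <- function(object, newdata, ...) {
  cc <- as.numeric(if (is.data.frame(newdata)) newdata[[1]] else newdata)
  drop(outer(cc, 0:object$order, `^`) %*% object$coefficients)
}

#' @export
print.property_poly <- function(x, ...) {
  cat(sprintf("Order-%d property polynomial, RMS residual %.3g\n",
              x$order, x$rms_residual))
  print(signif(x$coefficients, 5))
  invisible(x)
}

#' Bundle the binary-mixture property model
#'
#' Fits order-5 polynomials to the packaged water-ethanol tables (or to
#' user-supplied tables) for density, viscosity and mutual diffusivity, and
#' carries the transverse dispersion factor applied to the diffusivity in the
#' planar transport model. The fitted curves are checked to be positive on
#' [0, 1] and to match the pure-component table entries within 1%.
#'
#' @param table property table as from [water_ethanol_table()].
#' @param order polynomial order.
#' @param dispersion_factor multiplier (`>= 1`) on the molecular diffusivity
#'   representing transverse stirring by the out-of-plane secondary
#'   (Dean-type) flow that a planar model cannot resolve; see the package
#'   vignette for the calibration argument. Default 1 (molecular only).
#' @return An object of class `property_model`.
#' @export
property_model <- function(table = water_ethanol_table(), order = 5,
                           dispersion_factor = 1) {
  if (!is.numeric(dispersion_factor) || dispersion_factor < 1) {
    stop_invalid("'dispersion_factor' must be >= 1")
  }
  polys <- list(
    density = fit_property_polynomial(table[c("c", "density")], order),
    viscosity = fit_property_polynomial(table[c("c", "viscosity")], order),
    diffusivity = fit_property_polynomial(table[c("c", "diffusivity")], order)
  )
  grid <- seq(0, 1, length.out = 101)
  for (nm in names(polys)) {
    v <- predict(polys[[nm]], grid)
    if (any(v <= 0)) stop_invalid(nm, " polynomial is non-positive on [0, 1]")
    ends <- predict(polys[[nm]], c(0, 1))
    ref <- table[[nm]][match(c(0, 1), table$c)]
    if (any(abs(ends - ref) / ref > 0.01)) {
      stop_invalid(nm, " polynomial misses a pure-component table entry by > 1%")
    }
  }
  structure(c(polys, list(dispersion_factor = dispersion_factor)),
            class = "property_model")
}

#' Evaluate mixture properties at a composition
#'
#' @param properties a [property_model()].
#' @param c ethanol mass fraction(s) in [0, 1] (values outside are clamped).
#' @return Data frame with `density` (kg/m3), `viscosity` (Pa s) and
#'   `diffusivity` (m2/s, including the dispersion factor).
#' @export
mixture_properties <- function(properties, c) {
  stopifnot(inherits(properties, "property_model"))
  cc <- pmin(pmax(as.numeric(c), 0), 1)
  data.frame(
    density = predict(properties$density, cc),
    viscosity = predict(properties$viscosity, cc),
    diffusivity = properties$dispersion_factor *
      predict(properties$diffusivity, cc)
  )
}
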