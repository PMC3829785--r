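#' Fluid property set for atomization calculations
#'
#' Bundles the liquid properties the droplet-size machinery needs: density,
#' surface tension and a viscosity model, either Newtonian (a single constant
#' viscosity) or power-law (consistency index `K` and flow index `n`, with
#' apparent viscosity \eqn{\mu = K \dot\gamma^{n-1}}).
#'
#' @param density Liquid density, kg/m^3.
#' @param surface_tension Surface tension, N/m.
#' @param viscosity Newtonian (zero-shear) viscosity, Pa s. Optional when `K`
#'   and `n` are supplied; kept alongside them as the zero-shear value where
#'   available (used by the "zero-shear" viscosity policy).
#' @param K Power-law consistency index, Pa s^n. Optional.
#' @param n Power-law flow index, dimensionless, in (0, 1]. Required with `K`.
#' @param concentration Polymer concentration, % w/w. Optional bookkeeping.
#'
#' @return An object of class `fluid_properties`.
#' @examples
#' alginate <- fluid_properties(density = 1004, surface_tension = 0.07,
#'                              viscosity = 0.13, K = 0.205, n = 0.854,
#'                              concentration = 1.5)
#' @export
fluid_properties <- function(density, surface_tension, viscosity = NULL,
                             K = NULL, n = NULL, concentration = NULL) {
  check_positive(density, "density")
  check_positive(surface_tension, "surface_tension")
  if (is.null(viscosity) && is.null(K)) {
    stop_input("supply `viscosity` (Newtonian) and/or `K` with `n` (power law)")
  }
  if (!is.null(viscosity)) check_positive(viscosity, "viscosity")
  if (!is.null(K)) {
    check_positive(K, "K")
    if (is.null(n)) stop_input("power-law model needs both `K` and `n`")
    check_flow_index(n)
  }
  if (!is.null(concentration)) check_positive(concentration, "concentration")
  structure(
    list(density = density, surface_tension = surface_tension,
         viscosity = viscosity, K = K, n = n, concentration = concentration),
    class = "fluid_properties"
  )
}

#' @export
print.fluid_properties <- function(x, ...) {
  cat("Fluid properties\n")
  cat(sprintf("  density:         %g kg/m^3\n", x$density))
  cat(sprintf("  surface tension: %g N/m\n", x$surface_tension))
  if (!is.null(x$viscosity))
    cat(sprintf("  viscosity (zero-shear): %g Pa s\n", x$viscosity))
  if (!is.null(x$K))
    cat(sprintf("  power law: K = %g Pa s^n, n = %g\n", x$K, x$n))
  if (!is.null(x$concentration))
    cat(sprintf("  concentration: %g %% w/w\n", x$concentration))
  invisible(x)
}

range_warn <- function(c) {
  out <- c < 1 | c > 3
  if (any(out)) {
    warning("concentration ", paste(format(c[out]), collapse = ", "),
            " % w/w is outside the 1-3% range of the alginate fits; ",
            "extrapolating", call. = FALSE)
  }
}

#' Alginate power-law parameters from concentration
#'
#' Empirical fits of the power-law consistency index K and flow index n of
#' sodium alginate (Manugel GHB) solutions as a function of concentration:
#' \eqn{K(c) = 0.0619\, c^{2.953}} (Pa s^n) and
#' \eqn{n(c) = 0.9635\, e^{-0.08 c}}. The fits hold for c between 1 and 3 %
#' w/w; outside that range a warning is issued and the fit extrapolated.
#'
#' @param c Alginate concentration, % w/w (positive; vectorised).
#' @return Consistency index in Pa s^n, or flow index (dimensionless).
#' @examples
#' consistency_index_from_concentration(1.5) # 0.205 Pa s^n
#' flow_index_from_concentration(1.5)        # 0.854
#' @export
consistency_index_from_concentration <- function(c) {
  check_positive(c, "c")
  range_warn(c)
  0.0619 * c^2.953
}

#' @rdname consistency_index_from_concentration
#' @export
flow_index_from_concentration <- function(c) {
  check_nonnegative(c, "c")
  range_warn(c[c > 0])
  0.9635 * exp(-0.08 * c)
}

#' Apparent viscosity of a power-law fluid
#'
#' \eqn{\mu = K \dot\gamma^{n-1}}. For a shear-thinning fluid (n < 1) the
#' apparent viscosity diverges at zero shear; pass the measured zero-shear
#' viscosity directly in that regime instead.
#'
#' @param K Consistency index, Pa s^n.
#' @param n Flow index, in (0, 1].
#' @param shear_rate Shear rate, 1/s (strictly positive when n < 1).
#' @return Apparent viscosity, Pa s.
#' @examples
#' apparent_viscosity(K = 0.205, n = 0.854, shear_rate = 333) # 0.088 Pa s
#' @export
apparent_viscosity <- function(K, n, shear_rate) {
  check_positive(K, "K")
  check_flow_index(n)
  check_nonnegative(shear_rate, "shear_rate")
  if (any(shear_rate == 0) && any(n < 1)) {
    stop_input("apparent viscosity is undefined at zero shear for n < 1; ",
               "use the measured zero-shear viscosity instead")
  }
  K * shear_rate^(n - 1)
}

#' Wall shear rate of a power-law fluid in a circular tube
#'
#' Rabinowitsch-Mooney wall shear rate for volumetric flow `Q` through a tube
#' of radius `R`: \eqn{\dot\gamma_W = (3 + 1/n)\, Q / (\pi R^3)}. At n = 1 this
#' reduces to the Newtonian \eqn{4Q/(\pi R^3)}.
#'
#' `as_printed = TRUE` raises the whole bracket to the power n, a variant that
#' appears in some sources; it is dimensionally inconsistent for a shear rate
#' and is provided for comparison only.
#'
#' @param Q Volumetric flow rate, m^3/s.
#' @param R Tube radius, m.
#' @param n Flow index, in (0, 1].
#' @param as_printed Apply the outer exponent n to the bracket (default FALSE).
#' @return Wall shear rate, 1/s.
#' @examples
#' wall_shear_rate(Q = 7e-8, R = 6.54e-4, n = 0.854) # about 333 1/s
#' @export
wall_shear_rate <- function(Q, R, n, as_printed = FALSE) {
  check_positive(Q, "Q")
  check_positive(R, "R")
  check_flow_index(n)
  g <- (3 + 1 / n) * Q / (pi * R^3)
  if (as_printed) g^n else g
}
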