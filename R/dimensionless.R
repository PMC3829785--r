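#' Classical atomization dimensionless numbers
#'
#' Reynolds \eqn{Re = \rho u d_p / \mu}, Weber
#' \eqn{We = \rho u^2 d_p / \sigma} and Ohnesorge
#' \eqn{Oh = \sqrt{We}/Re = \mu / \sqrt{\rho \sigma d_p}} for a liquid jet or
#' drop of characteristic diameter `d_p` moving at velocity `u`.
#'
#' @param rho Liquid density, kg/m^3 (>= 0 where a ratio allows it).
#' @param u Liquid velocity, m/s (>= 0).
#' @param d_p Jet or drop diameter, m.
#' @param mu Liquid viscosity, Pa s.
#' @param sigma Surface tension, N/m.
#' @return Dimensionless number(s); vectorised.
#' @examples
#' reynolds(1000, 1, 1e-3, 1e-3)        # 1000
#' ohnesorge_classic(1e-3, 1000, 0.072, 1e-4)
#' @export
reynolds <- function(rho, u, d_p, mu) {
  check_nonnegative(rho, "rho"); check_nonnegative(u, "u")
  check_nonnegative(d_p, "d_p"); check_positive(mu, "mu")
  rho * u * d_p / mu
}

#' @rdname reynolds
#' @export
weber_classic <- function(rho, u, d_p, sigma) {
  check_nonnegative(rho, "rho"); check_nonnegative(u, "u")
  check_positive(d_p, "d_p"); check_positive(sigma, "sigma")
  rho * u^2 * d_p / sigma
}

#' @rdname reynolds
#' @export
ohnesorge_classic <- function(mu, rho, sigma, d_p) {
  check_positive(mu, "mu"); check_positive(rho, "rho")
  check_positive(sigma, "sigma"); check_positive(d_p, "d_p")
  mu / sqrt(rho * sigma * d_p)
}

#' Ultrasonic-modified dimensionless numbers
#'
#' For a liquid film atomized from a vibrating surface the classical groups
#' are recast in terms of the feed flow rate Q, driving frequency f and
#' surface vibration amplitude Am:
#' \itemize{
#'   \item Weber: \eqn{We = f Q \rho / \sigma}; the critical flow rate is the
#'     Q at which We = 1.
#'   \item Ohnesorge: \eqn{Oh = \mu / (f\, Am^2 \rho)}, viscous damping of the
#'     amplitude-driven capillary-wave growth.
#'   \item Intensity number: \eqn{I_N = f^2 Am^4 / (C Q)}, energy density
#'     delivered per unit liquid throughput.
#' }
#'
#' @param f Frequency, Hz.
#' @param Q Volumetric flow rate, m^3/s.
#' @param rho Liquid density, kg/m^3.
#' @param sigma Surface tension, N/m.
#' @param mu Viscosity, Pa s (>= 0).
#' @param Am Vibration amplitude, m.
#' @param C Speed of sound, m/s.
#' @return Dimensionless number(s); vectorised.
#' @examples
#' weber_us(25000, 7e-8, 1004, 0.07)   # 25.1
#' @export
weber_us <- function(f, Q, rho, sigma) {
  check_nonnegative(f, "f"); check_nonnegative(Q, "Q")
  check_nonnegative(rho, "rho"); check_positive(sigma, "sigma")
  f * Q * rho / sigma
}

#' @rdname weber_us
#' @export
ohnesorge_us <- function(mu, f, Am, rho) {
  check_nonnegative(mu, "mu"); check_positive(f, "f")
  check_positive(Am, "Am"); check_positive(rho, "rho")
  mu / (f * Am^2 * rho)
}

#' @rdname weber_us
#' @export
intensity_number <- function(f, Am, C, Q) {
  check_nonnegative(f, "f"); check_nonnegative(Am, "Am")
  check_positive(C, "C"); check_positive(Q, "Q")
  f^2 * Am^4 / (C * Q)
}

#' Full dimensionless set for an atomization case
#'
#' Computes the ultrasonic Weber, Ohnesorge and Intensity numbers for a fluid /
#' setup / flow combination, recording the inputs (Q, mu, Am) used so a report
#' can state which policies produced each value.
#'
#' @param fluid A [fluid_properties()].
#' @param setup An [ultrasonic_setup()].
#' @param flow A [flow_config()] (or a single flow rate in m^3/s).
#' @param viscosity_policy `"apparent"` uses the power-law apparent viscosity
#'   at `shear_rate` (requires `K`, `n`); `"zero_shear"` uses the Newtonian /
#'   zero-shear `viscosity` field.
#' @param shear_rate Wall shear rate for the apparent-viscosity policy, 1/s.
#' @return An object of class `dimensionless_set`: `We`, `Oh`, `I_N` and a
#'   `provenance` list (`Q`, `mu`, `Am`, policies).
#' @export
dimensionless_set <- function(fluid, setup, flow,
                              viscosity_policy = c("apparent", "zero_shear"),
                              shear_rate = NULL) {
  viscosity_policy <- match.arg(viscosity_policy)
  if (is.numeric(flow)) flow <- flow_config(Q_shell = flow)
  Q <- flow$Q_effective
  mu <- resolve_viscosity(fluid, viscosity_policy, shear_rate)
  Am <- setup$amplitude
  structure(
    list(
      We = weber_us(setup$frequency, Q, fluid$density, fluid$surface_tension),
      Oh = ohnesorge_us(mu, setup$frequency, Am, fluid$density),
      I_N = intensity_number(setup$frequency, Am, setup$sound_speed, Q),
      provenance = list(Q = Q, flow_policy = flow$policy, mu = mu,
                        viscosity_policy = viscosity_policy,
                        shear_rate = shear_rate, Am = Am)
    ),
    class = "dimensionless_set"
  )
}

resolve_viscosity <- function(fluid, policy, shear_rate = NULL) {
  if (policy == "apparent") {
    if (is.null(fluid$K)) {
      if (is.null(fluid$viscosity)) {
        stop_config("viscosity policy 'apparent' needs power-law K and n")
      }
      return(fluid$viscosity)  # Newtonian fluid: apparent == constant
    }
    if (is.null(shear_rate)) {
      stop_config("viscosity policy 'apparent' needs a `shear_rate` (1/s)")
    }
    apparent_viscosity(fluid$K, fluid$n, shear_rate)
  } else {
    if (is.null(fluid$viscosity)) {
      stop_config("viscosity policy 'zero_shear' needs the `viscosity` field")
    }
    fluid$viscosity
  }
}

#' @export
print.dimensionless_set <- function(x, ...) {
  cat("Ultrasonic dimensionless numbers\n")
  cat(sprintf("  We  = %.4g\n", x$We))
  cat(sprintf("  Oh  = %.4g   (mu = %.4g Pa s, policy '%s')\n",
              x$Oh, x$provenance$mu, x$provenance$viscosity_policy))
  cat(sprintf("  I_N = %.4g\n", x$I_N))
  cat(sprintf("  inputs: Q = %.4g m^3/s ('%s'), Am = %.4g m\n",
              x$provenance$Q, x$provenance$flow_policy, x$provenance$Am))
  invisible(x)
}
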