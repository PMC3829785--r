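#' Ultrasonic atomizer setup
#'
#' Describes the ultrasonic source: driving frequency, power delivered at the
#' atomizing surface, the vibrating area (given directly or derived from a
#' [nozzle_geometry()]), the speed of sound in the coupling liquid, and the
#' density used in the vibration-amplitude formula (by default the atomized
#' liquid's own density; water can be configured instead).
#'
#' @param frequency Driving frequency, Hz.
#' @param power Power delivered at the surface, W (>= 0).
#' @param area Vibrating surface area, m^2. Omit when `geometry` is given.
#' @param geometry Optional [nozzle_geometry()]; its [vibrating_area()] is used.
#' @param sound_speed Speed of sound in the coupling liquid, m/s.
#' @param coupling_density Density in the amplitude formula, kg/m^3.
#' @return An object of class `ultrasonic_setup`, with derived `intensity`
#'   (W/m^2) and `amplitude` (m) fields.
#' @examples
#' us <- ultrasonic_setup(frequency = 25000, power = 10, area = 1.38e-3,
#'                        sound_speed = 1497, coupling_density = 1004)
#' us$amplitude # about 6.25e-7 m
#' @export
ultrasonic_setup <- function(frequency, power, area = NULL, geometry = NULL,
                             sound_speed, coupling_density) {
  check_positive(frequency, "frequency")
  check_nonnegative(power, "power")
  check_positive(sound_speed, "sound_speed")
  check_positive(coupling_density, "coupling_density")
  if (is.null(area)) {
    if (is.null(geometry)) stop_input("supply `area` or `geometry`")
    area <- vibrating_area(geometry)
  }
  check_positive(area, "area")
  I <- power_intensity(power, area)
  Am <- vibration_amplitude(I, coupling_density, sound_speed, frequency)
  structure(
    list(frequency = frequency, power = power, area = area,
         geometry = geometry, sound_speed = sound_speed,
         coupling_density = coupling_density, intensity = I, amplitude = Am),
    class = "ultrasonic_setup"
  )
}

#' @export
print.ultrasonic_setup <- function(x, ...) {
  cat("Ultrasonic setup\n")
  cat(sprintf("  frequency:     %g Hz\n", x$frequency))
  cat(sprintf("  power:         %g W\n", x$power))
  cat(sprintf("  vibrating area:%g m^2\n", x$area))
  cat(sprintf("  sound speed:   %g m/s\n", x$sound_speed))
  cat(sprintf("  intensity:     %.4g W/m^2\n", x$intensity))
  cat(sprintf("  amplitude:     %.4g m\n", x$amplitude))
  invisible(x)
}

#' Power surface intensity
#'
#' Power delivered per unit vibrating area, I = P / A.
#'
#' @param P Delivered power, W (>= 0).
#' @param A Vibrating area, m^2 (> 0).
#' @return Intensity, W/m^2.
#' @examples
#' power_intensity(10, 1.38e-3) # 7.25e3 W/m^2
#' @export
power_intensity <- function(P, A) {
  check_nonnegative(P, "P")
  check_positive(A, "A")
  P / A
}

#' Vibration amplitude of the atomizing surface
#'
#' Displacement amplitude of a surface radiating intensity I into a liquid of
#' density rho with sound speed C at frequency f:
#' \eqn{Am = \frac{1}{2\pi f} \sqrt{2 I / (\rho C)}}.
#'
#' @param I Power surface intensity, W/m^2 (>= 0).
#' @param rho Liquid density, kg/m^3.
#' @param C Speed of sound, m/s.
#' @param f Frequency, Hz.
#' @return Amplitude, m.
#' @examples
#' vibration_amplitude(7.25e3, 1004, 1497, 25000) # about 6.25e-7 m
#' @export
vibration_amplitude <- function(I, rho, C, f) {
  check_nonnegative(I, "I")
  check_positive(rho, "rho")
  check_positive(C, "C")
  check_positive(f, "f")
  sqrt(2 * I / (rho * C)) / (2 * pi * f)
}

#' Coaxial nozzle geometry
#'
#' Dimensions of a dual-feed ultrasonic nozzle tip whose vibrating surface is
#' the sum of two truncated-cone lateral surfaces and an annulus: the actuating
#' cone from `D_i_nozzle` to `D_f_nozzle` over axial height `L_act`, the tip
#' cone from `D_tip` to `D_o` over `H_tip`, and the annulus between `D_tip`
#' (outer) and `D_f_nozzle` (inner).
#'
#' @param D_i_nozzle,D_f_nozzle Base diameters of the actuating cone, m.
#' @param D_tip,D_o Base diameters of the tip cone, m.
#' @param L_act,H_tip Axial heights of the two cones, m.
#' @return An object of class `nozzle_geometry`.
#' @export
nozzle_geometry <- function(D_i_nozzle, D_f_nozzle, D_tip, D_o, L_act, H_tip) {
  for (nm in c("D_i_nozzle", "D_f_nozzle", "D_tip", "D_o", "L_act", "H_tip")) {
    check_positive(get(nm), nm)
  }
  if (D_tip < D_f_nozzle) {
    stop_input("`D_tip` must be >= `D_f_nozzle` (annulus cannot be negative)")
  }
  structure(
    list(D_i_nozzle = D_i_nozzle, D_f_nozzle = D_f_nozzle, D_tip = D_tip,
         D_o = D_o, L_act = L_act, H_tip = H_tip),
    class = "nozzle_geometry"
  )
}

cone_lateral_area <- function(D1, D2, h) {
  # slant height from axial height and radius difference
  s <- sqrt(h^2 + ((D1 - D2) / 2)^2)
  pi * (D1 + D2) / 2 * s
}

#' Vibrating area of a coaxial nozzle
#'
#' Sum of the two truncated-cone lateral areas and the tip annulus of a
#' [nozzle_geometry()]. Cone lateral areas use the slant height computed from
#' the axial height and the radius difference.
#'
#' @param g A [nozzle_geometry()].
#' @return Area, m^2.
#' @export
vibrating_area <- function(g) {
  if (!inherits(g, "nozzle_geometry")) stop_input("`g` must be a nozzle_geometry")
  cone_lateral_area(g$D_i_nozzle, g$D_f_nozzle, g$L_act) +
    cone_lateral_area(g$D_tip, g$D_o, g$H_tip) +
    pi / 4 * (g$D_tip^2 - g$D_f_nozzle^2)
}

#' Critical flow rate for ultrasonic atomization
#'
#' The flow rate at which the ultrasonic Weber number equals one,
#' \eqn{Q_c = \sigma / (f \rho)}. Below it the liquid cannot cover the whole
#' atomizing surface and no effective atomization occurs.
#'
#' @param sigma Surface tension, N/m.
#' @param rho Liquid density, kg/m^3.
#' @param f Frequency, Hz.
#' @return Critical flow rate, m^3/s.
#' @examples
#' critical_flow_rate(0.07, 1004, 25000) # 2.8e-9 m^3/s
#' @export
critical_flow_rate <- function(sigma, rho, f) {
  check_positive(sigma, "sigma")
  check_positive(rho, "rho")
  check_positive(f, "f")
  sigma / (f * rho)
}

#' Maximum flow rate of a vibrating surface
#'
#' Volumetric displacement rate of the vibrating surface, Q_max = f * Am * A.
#' Above it the surface cannot keep up with the feed and dripping occurs.
#'
#' @param f Frequency, Hz (>= 0).
#' @param Am Vibration amplitude, m (>= 0).
#' @param A Vibrating area, m^2 (>= 0).
#' @return Maximum flow rate, m^3/s.
#' @export
max_flow_rate <- function(f, Am, A) {
  check_nonnegative(f, "f")
  check_nonnegative(Am, "Am")
  check_nonnegative(A, "A")
  f * Am * A
}

#' Operating-window verdict for a feed flow rate
#'
#' Classifies a flow rate against the good-atomization window
#' (Q_c, Q_max): `"below_critical"` when Q < Q_c, `"dripping"` when Q > Q_max,
#' `"good_atomization"` otherwise. Bounds are echoed in the result.
#'
#' @param Q Feed flow rate, m^3/s (>= 0).
#' @param Q_c Critical flow rate, m^3/s.
#' @param Q_max Maximum flow rate, m^3/s (must exceed `Q_c`).
#' @return A list with `verdict` (character), `Q`, `Q_c`, `Q_max`.
#' @examples
#' operating_window(7e-8, 2.8e-9, 2.2e-5)$verdict # "good_atomization"
#' @export
operating_window <- function(Q, Q_c, Q_max) {
  check_nonnegative(Q, "Q")
  check_positive(Q_c, "Q_c")
  check_positive(Q_max, "Q_max")
  if (Q_c >= Q_max) {
    stop_input("inconsistent configuration: Q_c (", format(Q_c),
               ") must be below Q_max (", format(Q_max), ")")
  }
  verdict <- ifelse(Q < Q_c, "below_critical",
                    ifelse(Q > Q_max, "dripping", "good_atomization"))
  list(verdict = verdict, Q = Q, Q_c = Q_c, Q_max = Q_max)
}

#' Per-channel feed flow configuration
#'
#' Flow rates of the core and shell channels of a dual-feed nozzle, and the
#' policy choosing which value feeds the dimensionless numbers and
#' correlations. The default policy is `"shell"`: with identical solutions in
#' both channels the shell flow dominates and the spray behaves as a single
#' feed at the shell rate.
#'
#' @param Q_core,Q_shell Channel flow rates, m^3/s (>= 0).
#' @param policy One of `"shell"`, `"core"`, `"total"`.
#' @return An object of class `flow_config` with an `Q_effective` field.
#' @examples
#' flow_config(Q_core = 1.83e-8, Q_shell = 7e-8)$Q_effective # 7e-8
#' @export
flow_config <- function(Q_core = 0, Q_shell = 0,
                        policy = c("shell", "core", "total")) {
  check_nonnegative(Q_core, "Q_core")
  check_nonnegative(Q_shell, "Q_shell")
  policy <- match.arg(policy)
  Q_eff <- switch(policy, shell = Q_shell, core = Q_core,
                  total = Q_core + Q_shell)
  if (Q_eff <= 0) stop_input("effective flow rate must be positive under policy '",
                             policy, "'")
  structure(list(Q_core = Q_core, Q_shell = Q_shell, policy = policy,
                 Q_effective = Q_eff),
            class = "flow_config")
}

#' @export
print.flow_config <- function(x, ...) {
  cat(sprintf("Flow config: core %.3g, shell %.3g m^3/s; policy '%s' -> Q = %.3g m^3/s\n",
              x$Q_core, x$Q_shell, x$policy, x$Q_effective))
  invisible(x)
}
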