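#' Physical properties of Manugel GHB sodium alginate solutions
#'
#' Published property table for aqueous Manugel GHB sodium alginate at 0.5 to
#' 5.0 % w/w: density (kg/m^3), zero-shear viscosity (Pa s) and surface
#' tension (N/m).
#'
#' @param concentration Optional; when given, returns the
#'   [fluid_properties()] for the matching table row (exact match required),
#'   with power-law K and n filled in from the concentration fits.
#' @return A data frame (no `concentration`) or a [fluid_properties()].
#' @examples
#' alginate_properties()
#' alginate_properties(1.5)
#' @export
alginate_properties <- function(concentration = NULL) {
  tab <- data.frame(
    concentration = c(0.5, 1.5, 2.5, 4.0, 5.0),
    density = c(999, 1004, 1008, 1017, 1023),
    viscosity = c(0.038, 0.13, 0.56, 2.7, 4.7),
    surface_tension = c(0.071, 0.07, 0.069, 0.057, 0.047)
  )
  if (is.null(concentration)) return(tab)
  i <- match(concentration, tab$concentration)
  if (is.na(i)) {
    stop_input("no tabulated alginate row at c = ", concentration,
               " % w/w; available: ", paste(tab$concentration, collapse = ", "))
  }
  row <- tab[i, ]
  suppressWarnings(fluid_properties(
    density = row$density, surface_tension = row$surface_tension,
    viscosity = row$viscosity,
    K = consistency_index_from_concentration(concentration),
    n = flow_index_from_concentration(concentration),
    concentration = concentration
  ))
}

#' Built-in worked case: 1.5% alginate shell-core atomization at 25 kHz
#'
#' The complete reference case shipped with the package: a 1.5 % w/w Manugel
#' GHB alginate solution (density 1004 kg/m^3, surface tension 0.07 N/m,
#' zero-shear viscosity 0.13 Pa s, power-law K = 0.205 Pa s^n, n = 0.854)
#' atomized by a 25 kHz, 10 W dual-feed nozzle with vibrating area
#' 1.38e-3 m^2 and sound speed 1497 m/s, feeding 1.1 mL/min (core) and
#' 4.2 mL/min (shell), with a wall shear rate of 333 1/s and measured
#' fresh/dried particle sizes of 78/41 um (shell-core) and 76/40 um (matrix).
#'
#' @return A named list with components `fluid`, `setup`, `flow`,
#'   `shear_rate` and `particles`, ready to feed [atomization_report()].
#' @examples
#' case <- reference_case()
#' rep <- atomization_report(case$fluid, case$setup, case$flow,
#'                           shear_rate = case$shear_rate,
#'                           particles = case$particles)
#' @export
reference_case <- function() {
  list(
    fluid = fluid_properties(density = 1004, surface_tension = 0.07,
                             viscosity = 0.13, K = 0.205, n = 0.854,
                             concentration = 1.5),
    setup = ultrasonic_setup(frequency = 25000, power = 10, area = 1.38e-3,
                             sound_speed = 1497, coupling_density = 1004),
    flow = flow_config(Q_core = to_si("1.1 mL/min", "flow"),
                       Q_shell = to_si("4.2 mL/min", "flow"),
                       policy = "shell"),
    shear_rate = 333,
    particles = data.frame(
      label = c("shell-core", "matrix"),
      fresh = c(78, 76), dried = c(41, 40),
      stringsAsFactors = FALSE
    )
  )
}
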