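# Boundary unit handling. Config files and the CLI accept quantities as
# "value unit" strings (e.g. "4.2 mL/min", "25 kHz", "70 mN/m"); everything
# internal is SI. The table below covers the units this tool's users write;
# it is a conversion map, not a general unit algebra.

.unit_factors <- list(
  flow = c("m3/s" = 1, "m^3/s" = 1, "mL/min" = 1e-6 / 60, "ml/min" = 1e-6 / 60,
           "L/min" = 1e-3 / 60, "l/min" = 1e-3 / 60, "mL/s" = 1e-6,
           "L/h" = 1e-3 / 3600),
  frequency = c("Hz" = 1, "kHz" = 1e3, "KHz" = 1e3, "MHz" = 1e6),
  length = c("m" = 1, "mm" = 1e-3, "um" = 1e-6, "µm" = 1e-6, "nm" = 1e-9,
             "cm" = 1e-2),
  area = c("m2" = 1, "m^2" = 1, "mm2" = 1e-6, "mm^2" = 1e-6,
           "cm2" = 1e-4, "cm^2" = 1e-4),
  viscosity = c("Pa.s" = 1, "Pa*s" = 1, "Pa s" = 1, "mPa.s" = 1e-3,
                "mPa*s" = 1e-3, "cP" = 1e-3, "P" = 0.1),
  surface_tension = c("N/m" = 1, "mN/m" = 1e-3, "dyn/cm" = 1e-3),
  density = c("kg/m3" = 1, "kg/m^3" = 1, "g/mL" = 1e3, "g/ml" = 1e3,
              "g/cm3" = 1e3, "g/cm^3" = 1e3),
  power = c("W" = 1, "kW" = 1e3, "mW" = 1e-3),
  velocity = c("m/s" = 1, "cm/s" = 1e-2, "mm/s" = 1e-3),
  percent = c("%" = 1, "% w/w" = 1, "%w/w" = 1),
  shear_rate = c("1/s" = 1, "s-1" = 1, "s^-1" = 1),
  dimensionless = stats::setNames(c(1, 1), c("", "1"))
)

#' Convert a quantity to SI units
#'
#' Accepts either a bare number (assumed already SI for the given dimension)
#' or a string `"value unit"` such as `"4.2 mL/min"` or `"25 kHz"`, and
#' returns the value in the SI unit of that dimension.
#'
#' @param x Numeric, or a character scalar `"value unit"`, or a list
#'   `list(value=, unit=)`.
#' @param dimension One of `"flow"`, `"frequency"`, `"length"`, `"area"`,
#'   `"viscosity"`, `"surface_tension"`, `"density"`, `"power"`,
#'   `"velocity"`, `"percent"`, `"shear_rate"`, `"dimensionless"`.
#' @param field Field name used in error messages.
#' @return Numeric value in SI units.
#' @examples
#' to_si("4.2 mL/min", "flow")  # 7e-8
#' to_si("25 kHz", "frequency") # 25000
#' @export
to_si <- function(x, dimension, field = dimension) {
  factors <- .unit_factors[[dimension]]
  if (is.null(factors)) stop_input("unknown dimension `", dimension, "`")
  if (is.list(x) && !is.null(x$value)) {
    unit <- if (is.null(x$unit)) names(factors)[1] else x$unit
    x <- paste(x$value, unit)
  }
  if (is.numeric(x)) return(x)
  if (!is.character(x) || length(x) != 1L) {
    stop_config("field `", field, "`: expected a number or 'value unit' string")
  }
  m <- regmatches(x, regexec("^\\s*([-+0-9.eE]+)\\s*(.*?)\\s*$", x))[[1]]
  if (length(m) != 3L || is.na(suppressWarnings(as.numeric(m[2])))) {
    stop_config("field `", field, "`: cannot parse quantity '", x, "'")
  }
  value <- as.numeric(m[2])
  unit <- m[3]
  if (unit == "") return(value)  # unitless string: assume SI
  idx <- match(unit, names(factors))
  if (is.na(idx)) {
    stop_config("field `", field, "`: unknown ", dimension, " unit '", unit,
                "' (accepted: ", paste(names(factors), collapse = ", "), ")")
  }
  value * factors[[idx]]
}
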