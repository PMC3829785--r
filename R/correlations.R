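#' Shared base term of the ultrasonic droplet-size correlations
#'
#' All the empirical correlations scale with the capillary length of the
#' vibrating film, \eqn{(\pi\sigma/(\rho f^2))^e}. The exponent `e` is printed
#' as 0.33 in the correlation family; `exponent = 1/3` gives the exact
#' capillary-wavelength form.
#'
#' @param sigma Surface tension, N/m.
#' @param rho Liquid density, kg/m^3.
#' @param f Frequency, Hz.
#' @param exponent Base exponent, 0.33 (default) or 1/3.
#' @return Length, m.
#' @export
correlation_base_term <- function(sigma, rho, f, exponent = 0.33) {
  check_positive(sigma, "sigma"); check_positive(rho, "rho")
  check_positive(f, "f"); check_positive(exponent, "exponent")
  (pi * sigma / (rho * f^2))^exponent
}

#' Lang median droplet diameter
#'
#' Capillary-wave prediction for low-viscosity liquids where flow rate has no
#' effect: \eqn{d_p = 0.34\,(8\pi\sigma/(\rho f^2))^{1/3}}, i.e. 0.34 times
#' the Kelvin capillary wavelength.
#'
#' @inheritParams correlation_base_term
#' @return Droplet diameter, m.
#' @examples
#' lang_diameter(0.07, 1004, 25000) # about 48 um
#' @export
lang_diameter <- function(sigma, rho, f) {
  check_positive(sigma, "sigma"); check_positive(rho, "rho")
  check_positive(f, "f")
  0.34 * (8 * pi * sigma / (rho * f^2))^(1 / 3)
}

#' Rajan-Pandit droplet-size correlation
#'
#' \eqn{d_p = (\pi\sigma/(\rho f^2))^{0.33}\,[1 + a\, We^{0.22} Oh^{0.166}
#' I_N^{-0.0277}]}. The prefactor `a_rp` of the dimensionless correction was
#' fitted to experimental observations and no universal value exists; it must
#' be supplied by the user.
#'
#' @inheritParams correlation_base_term
#' @param We,Oh,I_N Ultrasonic Weber, Ohnesorge and Intensity numbers.
#' @param a_rp Correction-term prefactor (dimensionless). Required; `a_rp = 0`
#'   collapses the bracket to the bare base term.
#' @return Droplet diameter, m.
#' @export
rajan_pandit_diameter <- function(sigma, rho, f, We, Oh, I_N, a_rp = NULL,
                                  exponent = 0.33) {
  if (is.null(a_rp)) {
    stop_config("the Rajan-Pandit correlation needs `a_rp`: its experimental ",
                "prefactor has no universal published value")
  }
  check_nonnegative(a_rp, "a_rp")
  base <- correlation_base_term(sigma, rho, f, exponent)
  base * (1 + a_rp * We^0.22 * Oh^0.166 * I_N^(-0.0277))
}

#' Ramisetty droplet-size correlation
#'
#' \eqn{d_p = 0.00154\,(\pi\sigma/(\rho f^2))^{0.33}\,[1 +
#' (\pi\sigma/(\rho f^2))^{-0.2} We^{0.154} Oh^{-0.111} I_N^{-0.033}]}.
#' Fitted over f = 20-130 kHz, rho = 912-1151 kg/m^3, sigma = 0.0029-0.073
#' N/m, Oh = 2.71-161.64, We = 14.8-571, I_N = 3.65e-13 - 1.92e-9; use
#' [check_validity()] to test whether a case sits inside that envelope.
#'
#' @inheritParams rajan_pandit_diameter
#' @return Droplet diameter, m.
#' @export
ramisetty_diameter <- function(sigma, rho, f, We, Oh, I_N, exponent = 0.33) {
  base <- correlation_base_term(sigma, rho, f, exponent)
  raw <- pi * sigma / (rho * f^2)
  0.00154 * base * (1 + raw^(-0.2) * We^0.154 * Oh^(-0.111) * I_N^(-0.033))
}

#' Avvaru non-Newtonian droplet-size correlation
#'
#' Extension for pseudo-plastic (shear-thinning) liquids with flow index n,
#' fitted on aqueous CMC: \eqn{d_p = (\pi\sigma/(\rho f^2))^{e} +
#' 0.0013\, We^{0.008} Oh^{-0.14/n} I_N^{0.28}}. The second term is additive
#' and carries units of metres as printed.
#'
#' @inheritParams rajan_pandit_diameter
#' @param n Power-law flow index, in (0, 1].
#' @param exponent Base exponent; exact 1/3 reproduces the published
#'   alginate prediction (default), 0.33 matches the printed form.
#' @return Droplet diameter, m.
#' @export
avvaru_diameter <- function(sigma, rho, f, We, Oh, I_N, n, exponent = 1 / 3) {
  check_flow_index(n)
  base <- correlation_base_term(sigma, rho, f, exponent)
  base + 0.0013 * We^0.008 * Oh^(-0.14 / n) * I_N^0.28
}

#' Barba droplet-size correlation for alginate solutions
#'
#' Pure power-law form tuned on ultrasonic atomization of alginate:
#' \eqn{d_p = 0.058\,(\pi\sigma/(\rho f^2))^{0.33} We^{0.151} Oh^{0.192}
#' I_N^{-0.02}}.
#'
#' @inheritParams rajan_pandit_diameter
#' @return Droplet diameter, m.
#' @export
barba_diameter <- function(sigma, rho, f, We, Oh, I_N, exponent = 0.33) {
  base <- correlation_base_term(sigma, rho, f, exponent)
  0.058 * base * We^0.151 * Oh^0.192 * I_N^(-0.02)
}

#' Validity envelope of the Ramisetty correlation
#'
#' Closed intervals on frequency, density, surface tension and the three
#' ultrasonic dimensionless numbers inside which the Ramisetty fit was
#' calibrated. All bounds can be overridden.
#'
#' @param f_range Hz. @param rho_range kg/m^3. @param sigma_range N/m.
#' @param Oh_range,We_range,I_N_range Dimensionless.
#' @return An object of class `validity_envelope` (named list of length-2
#'   numeric ranges).
#' @export
ramisetty_envelope <- function(f_range = c(20e3, 130e3),
                               rho_range = c(912, 1151),
                               sigma_range = c(0.0029, 0.073),
                               Oh_range = c(2.71, 161.64),
                               We_range = c(14.8, 571),
                               I_N_range = c(3.65e-13, 1.92e-9)) {
  env <- list(f = f_range, rho = rho_range, sigma = sigma_range,
              Oh = Oh_range, We = We_range, I_N = I_N_range)
  for (nm in names(env)) {
    r <- env[[nm]]
    if (!is.numeric(r) || length(r) != 2L || anyNA(r) || r[1] > r[2]) {
      stop_input("`", nm, "_range` must be a valid closed interval")
    }
  }
  structure(env, class = "validity_envelope")
}

#' Check a case against a correlation's validity envelope
#'
#' Tests each supplied quantity against its closed interval; values exactly on
#' a bound pass. Quantities not present in the envelope are ignored.
#'
#' @param values Named list/vector of quantities (`f`, `rho`, `sigma`, `Oh`,
#'   `We`, `I_N`).
#' @param envelope A [ramisetty_envelope()] (default) or compatible envelope.
#' @return A data frame of violations with columns `quantity`, `value`,
#'   `lower`, `upper`; zero rows means the case is fully inside the envelope.
#' @examples
#' check_validity(list(Oh = 1.32e4, We = 25.1))  # Oh flagged, We fine
#' @export
check_validity <- function(values, envelope = ramisetty_envelope()) {
  values <- as.list(values)
  out <- lapply(intersect(names(values), names(envelope)), function(nm) {
    v <- values[[nm]]; r <- envelope[[nm]]
    if (!is.na(v) && (v < r[1] || v > r[2])) {
      data.frame(quantity = nm, value = v, lower = r[1], upper = r[2],
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(quantity = character(), value = numeric(),
                      lower = numeric(), upper = numeric(),
                      stringsAsFactors = FALSE)
  }
  out
}
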