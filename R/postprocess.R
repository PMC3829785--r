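#' Volumetric shrinkage on drying
#'
#' Percentage volume lost when a fresh (wet) particle of diameter `d_fresh`
#' dries to diameter `d_dry`, assuming isotropic (spherical) volume reduction:
#' \eqn{S = 100\,(1 - (d_{dry}/d_{fresh})^3)}. Any length unit works as long
#' as both diameters use the same one. A dried diameter larger than the fresh
#' one (swelling) yields a negative shrinkage with a warning.
#'
#' @param d_fresh Fresh particle diameter (> 0).
#' @param d_dry Dried particle diameter (> 0), same unit as `d_fresh`.
#' @return Shrinkage, percent; vectorised.
#' @examples
#' volumetric_shrinkage(76, 40) # about 85%
#' @export
volumetric_shrinkage <- function(d_fresh, d_dry) {
  check_positive(d_fresh, "d_fresh")
  check_positive(d_dry, "d_dry")
  if (any(d_dry > d_fresh)) {
    warning("dried diameter exceeds fresh diameter: particle swelled, ",
            "shrinkage is negative", call. = FALSE)
  }
  100 * (1 - (d_dry / d_fresh)^3)
}

#' Dried diameter from fresh diameter and volumetric shrinkage
#'
#' Inverse of [volumetric_shrinkage()]:
#' \eqn{d_{dry} = d_{fresh} (1 - S/100)^{1/3}}.
#'
#' @param d_fresh Fresh particle diameter (> 0).
#' @param S Volumetric shrinkage, percent, in [0, 100).
#' @return Dried diameter, same unit as `d_fresh`.
#' @examples
#' dried_diameter_from_shrinkage(76, 85) # about 40.3
#' @export
dried_diameter_from_shrinkage <- function(d_fresh, S) {
  check_positive(d_fresh, "d_fresh")
  if (!is.numeric(S) || anyNA(S) || any(S < 0) || any(S >= 100)) {
    stop_input("`S` must be a shrinkage percentage in [0, 100)")
  }
  d_fresh * (1 - S / 100)^(1 / 3)
}
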