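#' Sulfide speciation parameters
#'
#' Bundles the conditions needed to split total dissolved sulfide
#' (S_tot = H2S + HS- + S2-) into its species. Only the first dissociation
#' (H2S <-> HS- + H+) is carried: at the pH of sulfidic spring mats (< 9)
#' the S2- contribution is below 1e-4 of S_tot and is neglected.
#'
#' @param temperature water temperature in degrees C (-2 to 40)
#' @param salinity practical salinity (>= 0)
#' @param pK1 optional override for the first dissociation exponent of H2S;
#'   when `NULL` it is computed from `temperature` and `salinity` with
#'   [pk1_h2s()]
#' @return an object of class `speciation_params`
#' @seealso [h2s_fraction()], [stot_from_h2s()]
#' @export
#' @examples
#' speciation_params(temperature = 14, salinity = 1)
speciation_params <- function(temperature = 14, salinity = 1, pK1 = NULL) {
  .check_number(temperature, "temperature", -2, 40)
  .check_number(salinity, "salinity", 0, 45)
  if (is.null(pK1)) pK1 <- pk1_h2s(temperature, salinity)
  .check_number(pK1, "pK1", 0, 14, strict_lower = TRUE, strict_upper = TRUE)
  structure(list(temperature = temperature, salinity = salinity,
                 pK1 = pK1, pK2_neglected = TRUE),
            class = "speciation_params")
}

#' @export
print.speciation_params <- function(x, ...) {
  cat(sprintf("H2S speciation: pK1 = %.3f (T = %g C, S = %g); S2- neglected\n",
              x$pK1, x$temperature, x$salinity))
  invisible(x)
}

#' First dissociation exponent of hydrogen sulfide
#'
#' Millero (1988) parameterization of the stoichiometric first dissociation
#' constant of H2S in water as a function of temperature and salinity:
#' `ln K1 = 225.838 - 13275.3/T - 34.6435 ln T + 0.3449 S^0.5 - 0.0274 S`
#' with T in kelvin. For fresh water at 25 C this gives pK1 = 6.98.
#'
#' @inheritParams speciation_params
#' @return pK1 (dimensionless)
#' @export
#' @examples
#' pk1_h2s(25, 0)   # ~6.98
#' pk1_h2s(25, 35)  # lower: salinity lowers the apparent pK
pk1_h2s <- function(temperature, salinity) {
  .check_number(temperature, "temperature", -2, 40)
  .check_number(salinity, "salinity", 0, 45)
  tk <- temperature + 273.15
  lnk <- 225.838 - 13275.3 / tk - 34.6435 * log(tk) +
    0.3449 * sqrt(salinity) - 0.0274 * salinity
  -lnk / log(10)
}

#' Fraction of total sulfide present as H2S
#'
#' The H2S microsensor senses only the protonated species. Given the local
#' pH, the mole fraction of S_tot present as H2S is
#' `alpha0 = 1 / (1 + 10^(pH - pK1))`.
#'
#' @param pH local pH, in (0, 14); vectorized
#' @param params a [speciation_params()] object
#' @return alpha0, in (0, 1); decreasing in pH
#' @export
#' @examples
#' p <- speciation_params(pK1 = 7.05)
#' h2s_fraction(7.05, p) # 0.5 at the half-dissociation point
h2s_fraction <- function(pH, params = speciation_params()) {
  stopifnot(inherits(params, "speciation_params"))
  .check_number(pH, "pH", 0, 14, strict_lower = TRUE, strict_upper = TRUE)
  1 / (1 + 10^(pH - params$pK1))
}

#' Total sulfide from measured H2S and pH
#'
#' Reconstructs S_tot (= H2S + HS-; S2- neglected) from an H2S microsensor
#' reading and the co-located pH: `S_tot = [H2S] / alpha0(pH)`.
#'
#' @param h2s H2S concentration, umol L^-1 (>= 0); vectorized
#' @param pH co-located pH; recycled against `h2s`
#' @inheritParams h2s_fraction
#' @return S_tot in umol L^-1, always >= `h2s`
#' @export
#' @examples
#' p <- speciation_params(pK1 = 7.05)
#' stot_from_h2s(100, 7.05, p) # 200
stot_from_h2s <- function(h2s, pH, params = speciation_params()) {
  .check_number(h2s, "h2s", 0)
  h2s / h2s_fraction(pH, params)
}

#' Molecular diffusion coefficients for mat solutes
#'
#' Returns D for the supported analytes. At the reference condition
#' (14 C, salinity 1 -- karst sulfidic spring water) the temperature- and
#' salinity-corrected values used for the flux calculations are returned
#' directly: 1.35e-5 cm^2 s^-1 for total sulfide and 1.78e-5 cm^2 s^-1 for
#' O2. At other temperatures a Stokes-Einstein rescaling
#' `D(T) = D_ref * (T_K / T_ref_K) * (eta(T_ref) / eta(T))` is applied,
#' with the dynamic viscosity of water from the Vogel-type correlation
#' `eta(T) = 2.414e-5 * 10^(247.8 / (T_K - 140))`.
#'
#' @param analyte one of `"sulfide"`, `"O2"`, `"generic"`
#' @param temperature degrees C
#' @param salinity practical salinity (carried for documentation; the
#'   reference values already include the salinity correction)
#' @param D_generic user-supplied D at the reference temperature for
#'   `analyte = "generic"` (e.g. 1e-5 cm^2 s^-1 for acetate)
#' @param reference_temperature temperature at which the tabulated /
#'   user-supplied values apply
#' @return D in cm^2 s^-1
#' @export
#' @examples
#' diffusion_coefficient("sulfide") # 1.35e-5
#' diffusion_coefficient("O2")      # 1.78e-5
diffusion_coefficient <- function(analyte = c("sulfide", "O2", "generic"),
                                  temperature = 14, salinity = 1,
                                  D_generic = NULL,
                                  reference_temperature = 14) {
  analyte <- match.arg(analyte)
  .check_number(temperature, "temperature", -2, 40)
  .check_number(salinity, "salinity", 0, 45)
  d_ref <- switch(analyte,
    sulfide = 1.35e-5,
    O2      = 1.78e-5,
    generic = {
      if (is.null(D_generic))
        .stopf("invalid input: analyte 'generic' requires D_generic")
      .check_number(D_generic, "D_generic", 0, 1e-4,
                    strict_lower = TRUE, strict_upper = TRUE)
      D_generic
    })
  if (temperature == reference_temperature) return(d_ref)
  eta <- function(tc) 2.414e-5 * 10^(247.8 / (tc + 273.15 - 140))
  d <- d_ref * ((temperature + 273.15) / (reference_temperature + 273.15)) *
    (eta(reference_temperature) / eta(temperature))
  .check_number(d, "D", 0, 1e-4, strict_lower = TRUE, strict_upper = TRUE)
  d
}

#' Characteristic diffusion time over a length scale
#'
#' Mean-squared-displacement convention for 1D diffusion, `t = L^2 / (2 D)`.
#' For a small organic solute (D = 1e-5 cm^2 s^-1) crossing 1 mm this gives
#' 500 s, about 8 minutes -- short enough to couple a photosynthetic layer to
#' a sulfide-production zone a millimetre below within the same light phase.
#' The alternative convention `L^2 / D` is available via `convention`.
#'
#' @param length_mm distance in mm (>= 0); vectorized
#' @param D diffusion coefficient, cm^2 s^-1 (> 0)
#' @param convention `"msd"` for L^2/(2D) (default) or `"plain"` for L^2/D
#' @return a list with elements `seconds` and `minutes`
#' @export
#' @examples
#' diffusion_time(1, 1e-5)$minutes # 8.33
diffusion_time <- function(length_mm, D, convention = c("msd", "plain")) {
  convention <- match.arg(convention)
  .check_number(length_mm, "length_mm", 0)
  .check_number(D, "D", 0, strict_lower = TRUE)
  l_cm <- cm_from_mm(length_mm)
  secs <- l_cm^2 / if (convention == "msd") (2 * D) else D
  list(seconds = secs, minutes = secs / 60)
}
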