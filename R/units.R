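# Unit conventions used throughout:
#   depth          mm at the user interface, cm internally (positive downward,
#                  0 at the mat surface, overlying water negative)
#   concentration  umol L^-1  (numerically identical to nmol cm^-3)
#   D              cm^2 s^-1
#   flux J         nmol cm^-2 s^-1, positive downward
#   volumetric R   nmol cm^-3 s^-1, positive = production

cm_from_mm <- function(x) x / 10
mm_from_cm <- function(x) x * 10

#' Convert a diffusive flux to daily areal units
#'
#' @param j flux in nmol cm^-2 s^-1
#' @return flux in mmol m^-2 d^-1
#' @export
#' @examples
#' flux_mmol_m2_d(1) # 864
flux_mmol_m2_d <- function(j) j * 864

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

.check_number <- function(x, name, lower = -Inf, upper = Inf,
                          strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || anyNA(x))
    .stopf("invalid input: '%s' must be numeric and non-missing", name)
  bad <- if (strict_lower) any(x <= lower) else any(x < lower)
  bad <- bad || if (strict_upper) any(x >= upper) else any(x > upper)
  if (bad)
    .stopf("invalid input: '%s' must lie in %s%g, %g%s", name,
           if (strict_lower) "(" else "[", lower, upper,
           if (strict_upper) ")" else "]")
  invisible(x)
}
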