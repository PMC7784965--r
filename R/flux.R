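#' Diffusive flux from a local linear profile segment (Fick's first law)
#'
#' Fits a least-squares line to the concentrations inside a depth window and
#' returns `J = -D dC/dz`, positive downward. The classic application is the
#' diffusive boundary layer (DBL), where transport is purely diffusive and
#' the steady profile is linear.
#'
#' @param profile a [depth_profile()] of a concentration analyte
#' @param D diffusion coefficient, cm^2 s^-1
#' @param window depth window `c(min_mm, max_mm)`; must contain >= 3 points
#' @param r2_warn lack-of-fit threshold: a warning is attached when the
#'   window R-squared falls below this value (profile curved, Fick's first
#'   law questionable)
#' @return an object of class `flux_estimate`: a list with `J`
#'   (nmol cm^-2 s^-1), `J_mmol_m2_d`, `se` (slope standard error propagated
#'   to flux units), `depth_mm` (window midpoint), `window`, `r_squared`,
#'   `n`
#' @export
#' @examples
#' pr <- depth_profile("O2", seq(-0.5, 0, 0.1), 100 + 100 * seq(-0.5, 0, 0.1))
#' local_flux(pr, 1.78e-5, c(-0.5, 0))
local_flux <- function(profile, D, window = range(profile$depth_mm),
                       r2_warn = 0.98) {
  stopifnot(inherits(profile, "depth_profile"))
  .check_number(D, "D", 0, strict_lower = TRUE)
  keep <- profile$depth_mm >= window[1] & profile$depth_mm <= window[2]
  if (sum(keep) < 3)
    .stopf("invalid input: flux window contains %d points (need >= 3)",
           sum(keep))
  z <- cm_from_mm(profile$depth_mm[keep])
  y <- profile$value[keep]
  fit <- stats::lm.fit(cbind(1, z), y)
  slope <- unname(fit$coefficients[2])
  rss <- sum(fit$residuals^2)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - rss / tss else 1
  n <- length(y)
  se_slope <- if (n > 2 && sum((z - mean(z))^2) > 0)
    sqrt(rss / (n - 2) / sum((z - mean(z))^2)) else 0
  if (tss > 0 && r2 < r2_warn)
    .warnf("flux window is curved (R^2 = %.3f < %.2f); Fick's first law fit doubtful",
           r2, r2_warn)
  out <- list(J = unname(-D * slope), J_mmol_m2_d = flux_mmol_m2_d(-D * slope),
              se = unname(D * se_slope), depth_mm = mean(window),
              window = window, r_squared = r2, n = n)
  class(out) <- "flux_estimate"
  out
}

#' @export
print.flux_estimate <- function(x, ...) {
  cat(sprintf(
    "J = %.4g nmol cm-2 s-1 (%.4g mmol m-2 d-1), window [%g, %g] mm, n = %d, R^2 = %.3f\n",
    x$J, x$J_mmol_m2_d, x$window[1], x$window[2], x$n, x$r_squared))
  invisible(x)
}

#' Auto-detect the diffusive boundary layer window
#'
#' Scans windows of overlying-water points ending at the mat surface and
#' returns the longest one whose linear fit has R^2 >= `r2_min` (minimum 3
#' points). Used to pick the flux window for interfacial fluxes.
#'
#' @inheritParams local_flux
#' @param r2_min linearity requirement
#' @return `c(min_mm, max_mm)` suitable as the `window` of [local_flux()]
#' @export
dbl_window <- function(profile, r2_min = 0.98) {
  stopifnot(inherits(profile, "depth_profile"))
  idx <- which(profile$depth_mm <= 0)
  if (length(idx) < 3)
    .stopf("invalid input: fewer than 3 overlying-water points")
  last <- max(idx)
  best <- NULL
  for (first in sort(idx)) {
    if (last - first + 1 < 3) break
    z <- profile$depth_mm[first:last]; y <- profile$value[first:last]
    fit <- stats::lm.fit(cbind(1, z), y)
    tss <- sum((y - mean(y))^2)
    r2 <- if (tss > 0) 1 - sum(fit$residuals^2) / tss else 1
    if (r2 >= r2_min) { best <- c(z[1], z[length(z)]); break }
  }
  if (is.null(best))
    .stopf("no near-linear DBL segment found (R^2 >= %g)", r2_min)
  best
}

#' Net consumption in a depth layer from boundary fluxes
#'
#' At steady state the net rate inside a layer equals the difference of the
#' diffusive fluxes across its boundaries: with depth positive downward and
#' `J = -D dC/dz`, net consumption in `[z_top, z_bottom)` is
#' `J(z_top) - J(z_bottom)`. A sulfide-producing layer with fluxes diverging
#' upward and downward therefore yields a negative consumption whose
#' magnitude is the summed outgoing fluxes.
#'
#' @inheritParams local_flux
#' @param layer `c(z_top, z_bottom)` in mm
#' @param window_mm half-width of the flux windows fitted just above `z_top`
#'   and just below `z_bottom`; each window is widened until it holds 3
#'   points
#' @return a list with `consumption` and `production`
#'   (nmol cm^-2 s^-1, `production = -consumption`), plus the two
#'   [local_flux()] estimates `flux_top`, `flux_bottom`
#' @export
layer_balance <- function(profile, D, layer, window_mm = 0.5) {
  stopifnot(inherits(profile, "depth_profile"), length(layer) == 2)
  widen <- function(w) {
    repeat {
      n <- sum(profile$depth_mm >= w[1] & profile$depth_mm <= w[2])
      if (n >= 3) return(w)
      w2 <- c(w[1] - 0.25 * window_mm, w[2] + 0.25 * window_mm)
      if (w2[1] < min(profile$depth_mm) - 1 &&
          w2[2] > max(profile$depth_mm) + 1)
        .stopf("invalid input: cannot place a 3-point flux window at %g mm",
               mean(w))
      w <- w2
    }
  }
  top <- local_flux(profile, D, widen(c(layer[1] - window_mm, layer[1])))
  bot <- local_flux(profile, D, widen(c(layer[2], layer[2] + window_mm)))
  cons <- top$J - bot$J
  list(consumption = cons, production = -cons,
       flux_top = top, flux_bottom = bot)
}

#' Gross photosynthesis rate from a light-dark shift transient
#'
#' Immediately after darkening, diffusion has not yet re-equilibrated, so
#' the instantaneous concentration change at a depth equals the gross rate
#' that was running there: O2 declines at the gross oxygenic photosynthesis
#' (OP) rate, total sulfide rises at the gross anoxygenic photosynthesis
#' (AP) rate. The rate is the magnitude of the initial slope over a short
#' fit window (default 3 s). Longer windows systematically underestimate the
#' rate because diffusive relaxation sets in.
#'
#' @param time_s sample times in seconds, starting at the dark transition
#' @param conc concentrations at one depth, umol L^-1
#' @param direction `"OP"` (O2 decrease) or `"AP"` (S_tot increase)
#' @param window_s fit window length in seconds (default 3)
#' @param curvature_warn warn when a quadratic term changes the fitted
#'   initial slope by more than this fraction (detectably nonlinear window)
#' @return gross rate, nmol cm^-3 s^-1 (>= 0)
#' @export
#' @examples
#' t <- seq(0, 3, 0.5)
#' gross_rate_lightdark(t, 100 - 2 * t, "OP") # 2
gross_rate_lightdark <- function(time_s, conc, direction = c("OP", "AP"),
                                 window_s = 3, curvature_warn = 0.25) {
  direction <- match.arg(direction)
  if (length(time_s) != length(conc) || anyNA(time_s) || anyNA(conc))
    .stopf("invalid input: time_s and conc must be equal-length, non-missing")
  t0 <- time_s[1]
  if (window_s > max(time_s) - t0)
    .stopf("invalid input: fit window (%g s) exceeds the series", window_s)
  keep <- time_s - t0 <= window_s + 1e-9
  if (sum(keep) < 3)
    .stopf("invalid input: fewer than 3 samples in the fit window")
  tt <- time_s[keep] - t0; y <- conc[keep]
  slope <- stats::lm.fit(cbind(1, tt), y)$coefficients[2]
  if (sum(keep) > 3) {
    s2 <- stats::lm.fit(cbind(1, tt, tt^2), y)$coefficients[2]
    floor_slope <- 1e-8 * max(abs(y), 1) / window_s
    if (abs(slope) > floor_slope &&
        abs(s2 - slope) / abs(slope) > curvature_warn)
      .warnf("light-dark window detectably nonlinear (initial slope shifts %.0f%% with a quadratic term); consider a shorter window",
             100 * abs(s2 - slope) / abs(slope))
  }
  expected_sign <- if (direction == "OP") -1 else 1
  if (slope * expected_sign < 0 && abs(slope) > .Machine$double.eps)
    .warnf("%s transient has the wrong sign (slope %.3g); returning its magnitude",
           direction, slope)
  unname(abs(slope))
}

.trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

#' Depth-integrate a volumetric rate profile to an areal rate
#'
#' For a fitted [fit_rate_profile()] model the piecewise-constant rates are
#' integrated exactly; for a discrete rate-versus-depth table (e.g. gross
#' light-dark shift rates) the trapezoidal rule is used. Depths in mm,
#' rates in nmol cm^-3 s^-1; the result is in nmol cm^-2 s^-1.
#'
#' @param rates a `rate_profile` object, or a data.frame with columns
#'   `depth_mm` and `rate`
#' @param interval `c(top_mm, bottom_mm)`; defaults to full coverage
#' @return areal rate, nmol cm^-2 s^-1
#' @export
depth_integrate <- function(rates, interval = NULL) UseMethod("depth_integrate")

#' @export
depth_integrate.data.frame <- function(rates, interval = NULL) {
  if (!all(c("depth_mm", "rate") %in% names(rates)))
    .stopf("invalid input: need columns depth_mm and rate")
  ord <- order(rates$depth_mm)
  z <- rates$depth_mm[ord]; r <- rates$rate[ord]
  if (is.null(interval)) interval <- range(z)
  if (interval[1] >= interval[2]) .stopf("invalid input: empty interval")
  lo <- max(interval[1], min(z)); hi <- min(interval[2], max(z))
  if (lo >= hi) .stopf("invalid input: interval outside rate coverage")
  zz <- sort(unique(c(lo, hi, z[z > lo & z < hi])))
  rr <- stats::approx(z, r, xout = zz)$y
  .trapz(cm_from_mm(zz), rr)
}

#' @export
depth_integrate.rate_profile <- function(rates, interval = NULL) {
  kn <- rates$knots_mm
  if (is.null(interval)) interval <- range(kn)
  if (interval[1] >= interval[2]) .stopf("invalid input: empty interval")
  tot <- 0
  for (k in seq_along(rates$rates)) {
    lo <- max(interval[1], kn[k]); hi <- min(interval[2], kn[k + 1])
    if (hi > lo) tot <- tot + rates$rates[k] * cm_from_mm(hi - lo)
  }
  tot
}
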