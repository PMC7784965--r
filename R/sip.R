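# 13C/12C of the VPDB standard
R_VPDB <- 0.0111802

#' Time series of the isotopic composition of one carbon pool
#'
#' @param pool pool label: `"mat_bulk"`, `"DIC"`, `"DOC"` or `"FA:<name>"`
#' @param time_h sampling times, hours, strictly increasing
#' @param value delta 13C (permil vs VPDB) or 13C atom fraction, per `scale`
#' @param scale `"delta"` or `"atom_fraction"`
#' @param replicate_id optional label
#' @return an object of class `sip_series` (also a data.frame)
#' @export
sip_series <- function(pool, time_h, value,
                       scale = c("delta", "atom_fraction"),
                       replicate_id = "r1") {
  scale <- match.arg(scale)
  if (length(time_h) != length(value) || anyNA(time_h) || anyNA(value))
    .stopf("invalid input: time_h and value must be equal-length, non-missing")
  ord <- order(time_h)
  time_h <- time_h[ord]; value <- value[ord]
  if (any(diff(time_h) <= 0))
    .stopf("invalid input: times must be strictly increasing")
  if (scale == "atom_fraction")
    .check_number(value, "atom fraction", 0, 1,
                  strict_lower = TRUE, strict_upper = TRUE)
  else .check_number(value, "delta", -1000, Inf, strict_lower = TRUE)
  structure(data.frame(time_h = time_h, value = value),
            pool = pool, scale = scale, replicate_id = replicate_id,
            class = c("sip_series", "data.frame"))
}

#' @export
print.sip_series <- function(x, ...) {
  cat(sprintf("<sip_series> %s (%s): %d time points, %g to %g h\n",
              attr(x, "pool"), attr(x, "scale"), nrow(x),
              min(x$time_h), max(x$time_h)))
  invisible(x)
}

#' Convert delta 13C to 13C atom fraction
#'
#' `R = R_VPDB (delta/1000 + 1)`, `x = R / (1 + R)`, with
#' `R_VPDB = 0.0111802`.
#'
#' @param delta delta 13C in permil vs VPDB (> -1000); vectorized
#' @return atom fraction in (0, 1)
#' @export
#' @examples
#' delta_to_atom_fraction(0) # 0.011056
delta_to_atom_fraction <- function(delta) {
  .check_number(delta, "delta", -1000, Inf, strict_lower = TRUE)
  r <- R_VPDB * (delta / 1000 + 1)
  r / (1 + r)
}

#' Convert 13C atom fraction to delta 13C
#'
#' Inverse of [delta_to_atom_fraction()].
#'
#' @param x atom fraction in (0, 1); vectorized
#' @return delta 13C, permil vs VPDB
#' @export
atom_fraction_to_delta <- function(x) {
  .check_number(x, "atom fraction", 0, 1, strict_lower = TRUE,
                strict_upper = TRUE)
  (x / (1 - x) / R_VPDB - 1) * 1000
}

#' Label increase relative to the first time point
#'
#' Subtracts the natural-abundance baseline, taken as each series' own first
#' time point: `Delta delta13C(t) = delta13C(t) - delta13C(t0)`.
#'
#' @param series a [sip_series()] on the delta scale with >= 2 points
#' @return a `sip_series` of Delta delta13C, first element exactly 0
#' @export
delta_delta <- function(series) {
  stopifnot(inherits(series, "sip_series"))
  if (attr(series, "scale") != "delta")
    .stopf("scale mismatch: delta_delta needs a delta-scale series")
  if (nrow(series) < 2) .stopf("invalid input: need >= 2 time points")
  out <- series
  out$value <- series$value - series$value[1]
  attr(out, "scale") <- "delta"
  attr(out, "baseline") <- series$value[1]
  out
}

#' Bulk-mat CO2 assimilation flux from 13C labelling
#'
#' The label accumulation rate of the bulk mat, scaled by the mat's areal
#' carbon content and normalised by the label strength of the DIC source
#' pool: `F = (dx_mat/dt) * C_areal / mean(x_DIC - x_nat)`, where `x_nat` is
#' the mat's own atom fraction at the first time point. The mat slope is a
#' finite difference between the interval endpoints (values interpolated
#' linearly when the endpoints are not sampled); the DIC excess is averaged
#' over the interval by the trapezoidal rule.
#'
#' @param mat,dic [sip_series()] objects on the atom-fraction scale
#' @param areal_carbon areal carbon content of the mat, mmol C m^-2
#' @param interval `c(t1, t2)` in hours; defaults to the overlapping range
#' @return assimilation flux, mmol C m^-2 h^-1
#' @export
mat_cfix_flux <- function(mat, dic, areal_carbon, interval = NULL) {
  stopifnot(inherits(mat, "sip_series"), inherits(dic, "sip_series"))
  if (attr(mat, "scale") != "atom_fraction" ||
      attr(dic, "scale") != "atom_fraction")
    .stopf("scale mismatch: mat_cfix_flux needs atom-fraction series")
  .check_number(areal_carbon, "areal_carbon", 0, strict_lower = TRUE)
  lo <- max(min(mat$time_h), min(dic$time_h))
  hi <- min(max(mat$time_h), max(dic$time_h))
  if (lo >= hi) .stopf("invalid input: mat and DIC series do not overlap")
  if (is.null(interval)) interval <- c(lo, hi)
  if (interval[1] < lo - 1e-9 || interval[2] > hi + 1e-9 ||
      interval[1] >= interval[2])
    .stopf("invalid input: interval outside the shared time coverage")
  x_nat <- mat$value[1]
  xm <- stats::approx(mat$time_h, mat$value, xout = interval)$y
  slope <- (xm[2] - xm[1]) / (interval[2] - interval[1])
  td <- sort(unique(c(interval, dic$time_h[dic$time_h > interval[1] &
                                             dic$time_h < interval[2]])))
  xd <- stats::approx(dic$time_h, dic$value, xout = td)$y
  excess <- .trapz(td, xd - x_nat) / (interval[2] - interval[1])
  if (excess <= 0)
    .stopf("invalid input: DIC label excess <= 0 over the interval; labelling uninterpretable")
  slope * areal_carbon / excess
}

#' Relative 13C/12C change of the DOC pool
#'
#' DOC cannot be quantified absolutely here (conversion efficiencies differ
#' across compounds), so only the isotope ratio relative to the first time
#' point is reported: `rel(t) = R(t) / R(t0)` with `R` the 13C/12C ratio.
#' The first element is exactly 1 (or exactly 0 with
#' `output = "difference"`).
#'
#' @param doc a [sip_series()] (either scale) with >= 2 points
#' @param output `"ratio"` (default) or `"difference"` (`rel - 1`)
#' @return data.frame with `time_h` and `rel`
#' @export
doc_relative_enrichment <- function(doc, output = c("ratio", "difference")) {
  output <- match.arg(output)
  stopifnot(inherits(doc, "sip_series"))
  if (nrow(doc) < 2) .stopf("invalid input: need >= 2 time points")
  r <- if (attr(doc, "scale") == "delta") R_VPDB * (doc$value / 1000 + 1)
       else doc$value / (1 - doc$value)
  rel <- r / r[1]
  rel[1] <- 1
  if (output == "difference") rel <- rel - 1
  data.frame(time_h = doc$time_h, rel = rel)
}

#' Relative 13C uptake-rate contribution of fatty acids (FA-RUR)
#'
#' For one interval between consecutive sampling times, each fatty acid's
#' labelling rate `Delta delta13C / Delta t` is normalised by the summed
#' rates of the group:
#' `FA-RUR_k = (Ddelta_k/Dt) / sum_j (Ddelta_j/Dt)`.
#' Slopes keep their sign; when the summed rate is not positive the
#' statistic is undefined and is returned as such (all `NA`, with
#' `defined = FALSE`) rather than renormalised --- censoring negative slopes
#' would fabricate signal.
#'
#' @param fa_series named list of [sip_series()] (delta or Delta-delta
#'   scale), one per fatty acid
#' @param interval `c(t1, t2)`: both endpoints must be sampled in every
#'   member series
#' @param members which fatty acids form the group (default: all of
#'   `fa_series`)
#' @return an object of class `fa_rur`: list with `rur` (named, sums to 1
#'   when defined), `slopes` (permil h^-1), `denominator`, `defined`,
#'   `interval`
#' @export
#' @examples
#' s <- function(nm, v) sip_series(paste0("FA:", nm), c(0, 2), c(0, v))
#' fa_rur(list(a = s("a", 4), b = s("b", 2), c = s("c", 2)), c(0, 2))
fa_rur <- function(fa_series, interval, members = names(fa_series)) {
  if (is.null(names(fa_series)) || any(names(fa_series) == ""))
    .stopf("invalid input: fa_series must be a named list")
  missing <- setdiff(members, names(fa_series))
  if (length(missing))
    .stopf("invalid input: fatty acid(s) %s not measured",
           paste(missing, collapse = ", "))
  dt <- interval[2] - interval[1]
  if (!(dt > 0)) .stopf("invalid input: interval must have t2 > t1")
  slopes <- vapply(members, function(nm) {
    s <- fa_series[[nm]]
    stopifnot(inherits(s, "sip_series"))
    i1 <- which(abs(s$time_h - interval[1]) < 1e-9)
    i2 <- which(abs(s$time_h - interval[2]) < 1e-9)
    if (!length(i1) || !length(i2))
      .stopf("invalid input: '%s' is not measured at both interval endpoints",
             nm)
    (s$value[i2[1]] - s$value[i1[1]]) / dt
  }, numeric(1))
  denom <- sum(slopes)
  defined <- denom > 0
  rur <- if (defined) slopes / denom else stats::setNames(
    rep(NA_real_, length(slopes)), names(slopes))
  structure(list(rur = rur, slopes = slopes, denominator = denom,
                 defined = defined, interval = interval),
            class = "fa_rur")
}

#' @export
print.fa_rur <- function(x, ...) {
  cat(sprintf("FA-RUR over [%g, %g] h", x$interval[1], x$interval[2]))
  if (!x$defined) {
    cat(" -- undefined (summed labelling rate <= 0)\n")
  } else {
    cat(":\n"); print(round(x$rur, 4))
  }
  invisible(x)
}

# Fixed guild assignments (lipid biomarker literature); "w" = omega.
.fa_guilds <- local({
  cyano <- c("C16:1w9", "C18:1w9", "C16:2", "C18:2")
  srb <- c("aiC15:0", "iC15:0", "10Me-C16:0", "aiC17:0", "iC17:0", "iC17:1",
           "C15:1", "C17:0", "C17:1")
  sob <- c("C16:1w7", "C18:1w7")
  sub <- c("10Me-C16:0" = "SRB-FA1", "iC17:1" = "SRB-FA1",
           "aiC17:0" = "SRB-FA2", "iC17:0" = "SRB-FA2", "C17:1" = "SRB-FA2",
           "aiC15:0" = "SRB-FA3", "iC15:0" = "SRB-FA3", "C15:1" = "SRB-FA3",
           "C17:0" = "SRB-FA3")
  list(cyano = cyano, srb = srb, sob = sob, sub = sub)
})

#' Assign fatty acids to source guilds
#'
#' Fixed biomarker table: cyanobacteria (even-numbered omega-9
#' monounsaturated and polyunsaturated FAs), sulfate/sulfur-reducing
#' bacteria (odd-numbered, iso/anteiso and 10-methyl branched FAs, split
#' into three response subgroups SRB-FA1..3), and sulfur-oxidizing bacteria
#' (even-numbered omega-7 monounsaturated FAs). Omega may be written `w` or
#' the Greek letter. Unknown names map to guild `"other"` with a warning.
#'
#' @param fa_names character vector of fatty-acid names, e.g. `"10Me-C16:0"`
#' @return data.frame with columns `fa`, `guild`
#'   (`cyanobacteria|SRB|SOB|other`) and `subgroup` (`SRB-FA1..3` or
#'   `"ungrouped"`)
#' @export
#' @examples
#' assign_guilds(c("10Me-C16:0", "C16:1w7"))
assign_guilds <- function(fa_names) {
  canon <- gsub("ω", "w", fa_names)
  guild <- ifelse(canon %in% .fa_guilds$cyano, "cyanobacteria",
           ifelse(canon %in% .fa_guilds$srb, "SRB",
           ifelse(canon %in% .fa_guilds$sob, "SOB", "other")))
  if (any(guild == "other"))
    .warnf("unrecognized fatty acid(s) assigned to 'other': %s",
           paste(fa_names[guild == "other"], collapse = ", "))
  sub <- .fa_guilds$sub[canon]
  sub[is.na(sub)] <- "ungrouped"
  data.frame(fa = fa_names, guild = guild, subgroup = unname(sub))
}
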