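#' A single microsensor depth profile
#'
#' Container for one analyte's concentration (or pH) versus depth at one
#' light state and time. Depth is in mm, zero at the mat surface, positive
#' downward; overlying-water points are negative. Rows are sorted by depth
#' on construction.
#'
#' Small negative concentration readings (baseline drift within
#' `2 * sensor_sd`) are clipped to zero with a warning; larger negatives are
#' rejected as gross errors.
#'
#' @param analyte one of `"O2"`, `"H2S"`, `"pH"`, `"S_tot"`
#' @param depth_mm depths in mm; must be unique
#' @param value concentrations in umol L^-1, or pH units
#' @param light_intensity incident irradiance, umol photons m^-2 s^-1
#' @param time_h hours since incubation start
#' @param replicate_id replicate label
#' @param measurement_angle sensor angle from vertical, degrees, in [0, 80]
#' @param sensor_sd sensor noise scale (umol L^-1) used for the negative-
#'   reading clip rule
#' @return an object of class `depth_profile` (also a data.frame with
#'   columns `depth_mm`, `value`)
#' @export
#' @examples
#' depth_profile("O2", depth_mm = c(-0.2, 0, 0.2), value = c(80, 60, 20))
depth_profile <- function(analyte = c("O2", "H2S", "pH", "S_tot"),
                          depth_mm, value,
                          light_intensity = NA_real_, time_h = NA_real_,
                          replicate_id = "r1", measurement_angle = 0,
                          sensor_sd = 1) {
  analyte <- match.arg(analyte)
  if (length(depth_mm) != length(value))
    .stopf("invalid input: depth_mm and value differ in length")
  if (anyNA(depth_mm) || anyNA(value))
    .stopf("invalid input: missing values in profile")
  ord <- order(depth_mm)
  depth_mm <- depth_mm[ord]; value <- value[ord]
  if (any(diff(depth_mm) <= 0))
    .stopf("format error: field 'depth_mm' has duplicated depths")
  .check_number(measurement_angle, "measurement_angle", 0, 80)
  if (analyte == "pH") {
    .check_number(value, "pH", 0, 14, strict_lower = TRUE,
                  strict_upper = TRUE)
  } else {
    if (any(value < -2 * sensor_sd))
      .stopf("invalid input: %s readings below -2 * sensor_sd; not clipping",
             analyte)
    if (any(value < 0)) {
      .warnf("clipped %d small negative %s reading(s) to 0",
             sum(value < 0), analyte)
      value[value < 0] <- 0
    }
  }
  structure(
    data.frame(depth_mm = depth_mm, value = value),
    analyte = analyte, light_intensity = light_intensity, time_h = time_h,
    replicate_id = replicate_id, measurement_angle = measurement_angle,
    class = c("depth_profile", "data.frame"))
}

#' @export
print.depth_profile <- function(x, ...) {
  cat(sprintf("<depth_profile> %s: %d points, %.2f to %.2f mm",
              attr(x, "analyte"), nrow(x), min(x$depth_mm), max(x$depth_mm)))
  if (!is.na(attr(x, "light_intensity")))
    cat(sprintf(", I = %g umol photons m-2 s-1", attr(x, "light_intensity")))
  cat("\n")
  invisible(x)
}

#' @export
plot.depth_profile <- function(x, ...) {
  graphics::plot(x$value, x$depth_mm, type = "o", ylim = rev(range(x$depth_mm)),
                 xlab = paste0(attr(x, "analyte"),
                               if (attr(x, "analyte") != "pH") " (umol L-1)"),
                 ylab = "depth (mm)", ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' Co-located profile set
#'
#' Groups the O2, H2S and pH profiles measured in one spot at one time, plus
#' (after [derive_stot()]) the total-sulfide profile computed from H2S and
#' pH. Member profiles must share replicate and time metadata.
#'
#' @param o2,h2s,ph [depth_profile()] objects (any may be `NULL`)
#' @param s_tot optional derived S_tot profile
#' @return an object of class `profile_set`
#' @export
profile_set <- function(o2 = NULL, h2s = NULL, ph = NULL, s_tot = NULL) {
  members <- Filter(Negate(is.null), list(O2 = o2, H2S = h2s, pH = ph,
                                          S_tot = s_tot))
  if (!length(members)) .stopf("invalid input: empty profile set")
  for (nm in names(members)) {
    if (!inherits(members[[nm]], "depth_profile"))
      .stopf("invalid input: '%s' is not a depth_profile", nm)
    if (attr(members[[nm]], "analyte") != nm)
      .stopf("invalid input: slot '%s' holds analyte '%s'", nm,
             attr(members[[nm]], "analyte"))
  }
  ids <- unique(vapply(members, attr, "", "replicate_id"))
  ts <- unique(vapply(members, attr, 0, "time_h"))
  if (length(ids) > 1 || length(ts[!is.na(ts)]) > 1)
    .stopf("invalid input: profile set members disagree on replicate/time")
  structure(list(o2 = o2, h2s = h2s, ph = ph, s_tot = s_tot),
            class = "profile_set")
}

#' @export
print.profile_set <- function(x, ...) {
  have <- names(Filter(Negate(is.null), unclass(x)))
  cat("<profile_set> analytes:", paste(have, collapse = ", "), "\n")
  invisible(x)
}

#' Add a total-sulfide profile to a profile set
#'
#' Interpolates pH onto the H2S depths (linear, no extrapolation: H2S points
#' outside the pH coverage are dropped) and applies [stot_from_h2s()].
#'
#' @param ps a [profile_set()] with `h2s` and `ph` members
#' @param params a [speciation_params()] object
#' @return the profile set with the `s_tot` slot filled
#' @export
derive_stot <- function(ps, params = speciation_params()) {
  stopifnot(inherits(ps, "profile_set"))
  if (is.null(ps$h2s) || is.null(ps$ph))
    .stopf("invalid input: derive_stot needs both h2s and ph profiles")
  keep <- ps$h2s$depth_mm >= min(ps$ph$depth_mm) &
    ps$h2s$depth_mm <= max(ps$ph$depth_mm)
  if (!any(keep)) .stopf("invalid input: h2s and ph depth ranges are disjoint")
  d <- ps$h2s$depth_mm[keep]
  ph_i <- stats::approx(ps$ph$depth_mm, ps$ph$value, xout = d)$y
  ps$s_tot <- depth_profile(
    "S_tot", d, stot_from_h2s(ps$h2s$value[keep], ph_i, params),
    light_intensity = attr(ps$h2s, "light_intensity"),
    time_h = attr(ps$h2s, "time_h"),
    replicate_id = attr(ps$h2s, "replicate_id"),
    measurement_angle = attr(ps$h2s, "measurement_angle"))
  ps
}

#' Layer model of the mat
#'
#' Named, non-overlapping depth intervals (mm), half-open `[top, bottom)`,
#' ordered by depth. Typical names: `water_column`, `dbl`, `sob_layer`,
#' `cyano_layer`, `production_zone`. The SOB layer may sit either above or
#' below the cyanobacterial layer (the population migrates).
#'
#' @param ... named length-2 numeric vectors `c(top, bottom)`
#' @return an object of class `layer_model`
#' @export
#' @examples
#' layer_model(dbl = c(-0.5, 0), sob_layer = c(0, 0.3),
#'             cyano_layer = c(0.3, 1.1))
layer_model <- function(...) {
  iv <- list(...)
  if (!length(iv) || is.null(names(iv)) || any(names(iv) == ""))
    .stopf("invalid input: layers must be named")
  for (nm in names(iv)) {
    v <- iv[[nm]]
    if (length(v) != 2 || anyNA(v) || v[1] >= v[2])
      .stopf("invalid input: layer '%s' must be c(top, bottom), top < bottom",
             nm)
  }
  iv <- iv[order(vapply(iv, `[`, 0, 1))]
  tops <- vapply(iv, `[`, 0, 1); bots <- vapply(iv, `[`, 0, 2)
  if (any(tops[-1] < bots[-length(bots)] - 1e-12))
    .stopf("invalid input: overlapping layers")
  structure(iv, class = "layer_model")
}

#' @export
print.layer_model <- function(x, ...) {
  for (nm in names(x))
    cat(sprintf("  %-16s [%6.2f, %6.2f) mm\n", nm, x[[nm]][1], x[[nm]][2]))
  invisible(x)
}

.meta_keys <- c("analyte", "light_intensity", "time_h", "replicate_id",
                "measurement_angle", "units")

#' Write a profile set to a delimited text file
#'
#' Wide format: `#`-prefixed `key: value` metadata header, then a delimited
#' table with a `depth_mm` column and one column per analyte (missing depths
#' left empty). Readable back with [read_profiles()].
#'
#' @param ps a [profile_set()]
#' @param path output file
#' @param sep field delimiter, `","` or `"\t"`
#' @export
write_profiles <- function(ps, path, sep = ",") {
  stopifnot(inherits(ps, "profile_set"))
  members <- Filter(Negate(is.null), unclass(ps))
  ref <- members[[1]]
  depths <- sort(unique(unlist(lapply(members, `[[`, "depth_mm"))))
  tab <- data.frame(depth_mm = depths)
  for (m in members) {
    col <- rep(NA_real_, length(depths))
    col[match(m$depth_mm, depths)] <- m$value
    tab[[attr(m, "analyte")]] <- col
  }
  hdr <- c(
    sprintf("# units: umol_per_L"),
    sprintf("# light_intensity: %g", attr(ref, "light_intensity")),
    sprintf("# time_h: %g", attr(ref, "time_h")),
    sprintf("# replicate_id: %s", attr(ref, "replicate_id")),
    sprintf("# measurement_angle: %g", attr(ref, "measurement_angle")))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(tab, con, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a profile set from a delimited text file
#'
#' Accepts the wide dialect written by [write_profiles()] (a `depth_mm`
#' column plus one column per analyte) or a long dialect with columns
#' `depth_mm`, `analyte`, `value`. Metadata are taken from `#`-prefixed
#' `key: value` header lines. Comma and tab delimiters are auto-detected.
#'
#' @param path input file
#' @return a [profile_set()]
#' @export
read_profiles <- function(path) {
  lines <- readLines(path)
  is_meta <- grepl("^#", lines)
  meta <- list()
  for (l in sub("^#\\s*", "", lines[is_meta])) {
    kv <- regmatches(l, regexpr(":", l), invert = TRUE)[[1]]
    if (length(kv) == 2) meta[[trimws(kv[1])]] <- trimws(kv[2])
  }
  if (!is.null(meta$units) && meta$units != "umol_per_L")
    .stopf("format error: field 'units' unknown ('%s')", meta$units)
  body <- lines[!is_meta]
  if (!length(body)) .stopf("format error: no table body")
  sep <- if (grepl("\t", body[1])) "\t" else ","
  tab <- utils::read.table(text = body, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  if (!"depth_mm" %in% names(tab))
    .stopf("format error: field 'depth_mm' missing")
  num <- function(k, def) if (is.null(meta[[k]])) def else as.numeric(meta[[k]])
  mk <- function(analyte, depth, value) {
    keep <- !is.na(value)
    depth_profile(analyte, depth[keep], value[keep],
                  light_intensity = num("light_intensity", NA_real_),
                  time_h = num("time_h", NA_real_),
                  replicate_id = if (is.null(meta$replicate_id)) "r1"
                                 else meta$replicate_id,
                  measurement_angle = num("measurement_angle", 0))
  }
  slots <- list(o2 = NULL, h2s = NULL, ph = NULL, s_tot = NULL)
  if (all(c("analyte", "value") %in% names(tab))) {           # long dialect
    for (a in unique(tab$analyte)) {
      rows <- tab$analyte == a
      slots[[.slot_for(a)]] <- mk(a, tab$depth_mm[rows], tab$value[rows])
    }
  } else {                                                    # wide dialect
    acols <- setdiff(names(tab), "depth_mm")
    if (!length(acols)) .stopf("format error: no analyte columns")
    for (a in acols) slots[[.slot_for(a)]] <- mk(a, tab$depth_mm, tab[[a]])
  }
  profile_set(o2 = slots$o2, h2s = slots$h2s, ph = slots$ph,
              s_tot = slots$s_tot)
}

.slot_for <- function(analyte) {
  slot <- c(O2 = "o2", H2S = "h2s", pH = "ph", S_tot = "s_tot")[analyte]
  if (is.na(slot)) .stopf("format error: unknown analyte column '%s'", analyte)
  unname(slot)
}

#' Correct measured depths for the sensor angle
#'
#' Microsensors are often driven into the mat at an angle to avoid
#' self-shading; the along-axis travel overestimates vertical depth by
#' `1/cos(angle)`. This rescales depths to vertical and resets the angle
#' metadata to zero. Applying it twice is a no-op (with a warning).
#'
#' @param profile a [depth_profile()]
#' @return the corrected profile
#' @export
correct_depth_for_angle <- function(profile) {
  stopifnot(inherits(profile, "depth_profile"))
  ang <- attr(profile, "measurement_angle")
  if (ang >= 90) .stopf("invalid input: measurement angle >= 90 degrees")
  if (ang == 0) {
    .warnf("measurement_angle is already 0; profile returned unchanged")
    return(profile)
  }
  profile$depth_mm <- profile$depth_mm * cos(ang * pi / 180)
  attr(profile, "measurement_angle") <- 0
  profile
}

#' Shift depths so a chosen interface sits at zero
#'
#' @param profile a [depth_profile()]
#' @param interface_depth_mm depth (mm, current coordinates) of the mat
#'   surface; must lie within the measured range
#' @return the shifted profile
#' @export
align_to_interface <- function(profile, interface_depth_mm) {
  stopifnot(inherits(profile, "depth_profile"))
  if (interface_depth_mm < min(profile$depth_mm) ||
      interface_depth_mm > max(profile$depth_mm))
    .stopf("invalid input: interface outside measured range")
  profile$depth_mm <- profile$depth_mm - interface_depth_mm
  profile
}

#' Compare two profiles for steady state
#'
#' Two successive profiles of the same analyte are considered at steady
#' state when their pointwise relative deviation, after linear interpolation
#' to the overlapping depths, stays below `tol`. The denominator is
#' `max(|a|, |b|, floor)` so the test is symmetric and robust near zero
#' concentrations.
#'
#' @param a,b [depth_profile()] objects of the same analyte with overlapping
#'   depth ranges
#' @param tol relative tolerance (default 0.05)
#' @param floor concentration floor for the denominator (umol L^-1)
#' @return a list with `steady` (logical) and `max_rel_dev`
#' @export
check_steady_state <- function(a, b, tol = 0.05, floor = 1) {
  stopifnot(inherits(a, "depth_profile"), inherits(b, "depth_profile"))
  if (attr(a, "analyte") != attr(b, "analyte"))
    .stopf("invalid input: profiles are of different analytes")
  lo <- max(min(a$depth_mm), min(b$depth_mm))
  hi <- min(max(a$depth_mm), max(b$depth_mm))
  if (lo >= hi) .stopf("invalid input: disjoint depth ranges")
  d <- sort(unique(c(a$depth_mm, b$depth_mm)))
  d <- d[d >= lo & d <= hi]
  av <- stats::approx(a$depth_mm, a$value, xout = d)$y
  bv <- stats::approx(b$depth_mm, b$value, xout = d)$y
  rel <- abs(av - bv) / pmax(abs(av), abs(bv), floor)
  dev <- max(rel)
  list(steady = dev <= tol, max_rel_dev = dev)
}
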