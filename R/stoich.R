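# Element / charge composition of the species that appear in the built-in
# reactions. Rows: H, O, S, C, charge.
.species_matrix <- local({
  m <- rbind(
    H2S    = c(H = 2, O = 0, S = 1, C = 0, charge = 0),
    O2     = c(H = 0, O = 2, S = 0, C = 0, charge = 0),
    CO2    = c(H = 0, O = 2, S = 0, C = 1, charge = 0),
    H2O    = c(H = 2, O = 1, S = 0, C = 0, charge = 0),
    S0     = c(H = 0, O = 0, S = 1, C = 0, charge = 0),
    SO4    = c(H = 0, O = 4, S = 1, C = 0, charge = -2),
    CH2O   = c(H = 2, O = 1, S = 0, C = 1, charge = 0),
    Hplus  = c(H = 1, O = 0, S = 0, C = 0, charge = 1))
  t(m)
})

#' Define a reaction by its stoichiometric coefficients
#'
#' Coefficients are signed: negative for consumed species, positive for
#' produced. Known species: `H2S`, `O2`, `CO2`, `H2O`, `S0`, `SO4`, `CH2O`,
#' `Hplus`.
#'
#' @param label short name
#' @param ... named coefficients, e.g. `H2S = -1, O2 = -0.4`
#' @return an object of class `reaction`
#' @seealso [mat_reactions()], [check_reaction_balance()]
#' @export
reaction <- function(label, ...) {
  co <- c(...)
  unknown <- setdiff(names(co), colnames(.species_matrix))
  if (length(unknown))
    .stopf("invalid input: unknown species %s", paste(unknown, collapse = ", "))
  structure(list(label = label, coefficients = co), class = "reaction")
}

#' @export
print.reaction <- function(x, ...) {
  co <- x$coefficients
  side <- function(s) {
    cc <- co[sign(co) == s]
    paste(sprintf("%s%s", ifelse(abs(cc) == 1, "", paste0(abs(cc), " ")),
                  names(cc)), collapse = " + ")
  }
  cat(sprintf("%s: %s -> %s\n", x$label, side(-1), side(1)))
  invisible(x)
}

#' The built-in photosynthesis and sulfide-oxidation reactions
#'
#' The four reactions that convert measured rates into predicted
#' CO2-fixation rates:
#' \describe{
#'   \item{OP}{oxygenic photosynthesis, `H2O + CO2 -> O2 + CH2O` --- 1 mol C
#'     fixed per mol O2 produced.}
#'   \item{AP}{anoxygenic photosynthesis with sulfide as electron donor,
#'     `2 H2S + CO2 -> 2 S0 + CH2O + H2O` --- 0.5 mol C per mol sulfide.}
#'   \item{SOX_incomplete}{chemolithoautotrophic aerobic sulfide oxidation
#'     stopping at zero-valent sulfur,
#'     `H2S + 0.4 O2 + 0.1 CO2 -> S0 + 0.1 CH2O + 0.9 H2O` --- the
#'     low-O2-demand, low-C-yield end member.}
#'   \item{SOX_complete}{oxidation through to sulfate,
#'     `H2S + 1.5 O2 + 0.5 CO2 + 0.5 H2O -> SO4 + 0.5 CH2O + 2 H+` --- the
#'     high-O2-demand, high-C-yield end member.}
#' }
#' The two SOX end members embody a fixed energy-conservation efficiency of
#' 16.9 % for autotrophic aerobic sulfide oxidation; mixing them against an
#' observed S_tot:O2 consumption ratio is done by
#' [sob_partition_from_ratio()].
#'
#' @return named list of [reaction()] objects
#' @export
mat_reactions <- function() {
  list(
    OP = reaction("OP", H2O = -1, CO2 = -1, O2 = 1, CH2O = 1),
    AP = reaction("AP", H2S = -2, CO2 = -1, S0 = 2, CH2O = 1, H2O = 1),
    SOX_incomplete = reaction("SOX_incomplete",
      H2S = -1, O2 = -0.4, CO2 = -0.1, S0 = 1, CH2O = 0.1, H2O = 0.9),
    SOX_complete = reaction("SOX_complete",
      H2S = -1, O2 = -1.5, CO2 = -0.5, H2O = -0.5,
      SO4 = 1, CH2O = 0.5, Hplus = 2))
}

#' Element and charge balance of a reaction
#'
#' @param rxn a [reaction()]
#' @return named numeric residuals for H, O, S, C and charge; all exactly 0
#'   for a balanced reaction
#' @export
#' @examples
#' check_reaction_balance(mat_reactions()$SOX_incomplete)
check_reaction_balance <- function(rxn) {
  stopifnot(inherits(rxn, "reaction"))
  drop(.species_matrix[, names(rxn$coefficients), drop = FALSE] %*%
         rxn$coefficients)
}

# SOX end-member constants (per mol H2S oxidized)
.SOX <- list(o2 = c(incomplete = 0.4, complete = 1.5),
             cyield = c(incomplete = 0.1, complete = 0.5))

#' Predicted C fixation from gross oxygenic photosynthesis
#'
#' OP fixes one mol CO2 per mol O2 produced, so the conversion factor is 1.
#'
#' @param gross_op_areal depth-integrated gross OP, nmol O2 cm^-2 s^-1 (>= 0)
#' @return nmol C cm^-2 s^-1
#' @export
cfix_from_op <- function(gross_op_areal) {
  .check_number(gross_op_areal, "gross_op_areal", 0)
  gross_op_areal
}

#' Predicted C fixation from gross anoxygenic photosynthesis
#'
#' AP oxidizes sulfide to zero-valent sulfur; each sulfide donates two
#' electrons, and four electrons are needed per CO2, so two mol sulfide are
#' consumed per mol C fixed (default `multiplier = 0.5` on the sulfide
#' consumption rate). The multiplier is configurable because conversion
#' conventions differ between rate bookkeeping in sulfide vs O2-equivalent
#' units; any non-default choice is reported via a message.
#'
#' @param gross_ap_areal depth-integrated gross AP as sulfide consumption,
#'   nmol S cm^-2 s^-1 (>= 0)
#' @param multiplier mol C fixed per mol sulfide (default 0.5)
#' @return nmol C cm^-2 s^-1
#' @export
cfix_from_ap <- function(gross_ap_areal, multiplier = 0.5) {
  .check_number(gross_ap_areal, "gross_ap_areal", 0)
  .check_number(multiplier, "multiplier", 0, strict_lower = TRUE)
  if (multiplier != 0.5)
    message(sprintf("cfix_from_ap: using non-default multiplier %g mol C (mol S)-1",
                    multiplier))
  multiplier * gross_ap_areal
}

#' Partition sulfide oxidation between the two end members
#'
#' The two limiting aerobic sulfide-oxidation reactions (see
#' [mat_reactions()]) consume 0.4 and 1.5 mol O2 and fix 0.1 and 0.5 mol C
#' per mol sulfide. An observed S_tot:O2 consumption ratio `r` fixes the
#' mixing fraction `f_S0` of sulfide oxidized only to S0 through
#' `0.4 f + 1.5 (1 - f) = 1/r`; the carbon yield is the same mixture of the
#' end-member yields. Ratios outside `[2/3, 2.5]` cannot be produced by any
#' mixture: the function then signals an error of class
#' `sulfmat_infeasible_ratio` carrying the nearest feasible end member ---
#' in a live mat such a flux imbalance is what drives the SOB population to
#' migrate.
#'
#' @param r observed S_tot:O2 consumption ratio (> 0)
#' @param efficiency energy-conservation efficiency carried as metadata
#'   (the end-member yields already embody it)
#' @return an object of class `sob_partition`: list with `f_S0`, `o2_per_s`,
#'   `c_yield`, `efficiency`, `r`
#' @export
#' @examples
#' sob_partition_from_ratio(2.3)$c_yield # ~0.113
sob_partition_from_ratio <- function(r, efficiency = 0.169) {
  .check_number(r, "r", 0, strict_lower = TRUE)
  o2_per_s <- 1 / r
  f <- (.SOX$o2["complete"] - o2_per_s) /
    (.SOX$o2["complete"] - .SOX$o2["incomplete"])
  f <- unname(f)
  if (f < -1e-12 || f > 1 + 1e-12) {
    nearest <- if (f > 1) "incomplete" else "complete"
    cond <- structure(
      class = c("sulfmat_infeasible_ratio", "error", "condition"),
      list(message = sprintf(
        paste0("infeasible ratio: S_tot:O2 = %g lies outside the aerobic ",
               "sulfide-oxidation window [2/3, 2.5]; nearest end member: %s ",
               "oxidation"), r, nearest),
        call = sys.call(-1), r = r, nearest = nearest))
    stop(cond)
  }
  f <- min(max(f, 0), 1)
  structure(list(
    f_S0 = f, o2_per_s = o2_per_s,
    c_yield = unname(f * .SOX$cyield["incomplete"] +
                       (1 - f) * .SOX$cyield["complete"]),
    efficiency = efficiency, r = r), class = "sob_partition")
}

#' @export
print.sob_partition <- function(x, ...) {
  cat(sprintf(
    "SOB partition at S_tot:O2 = %.3g: f_S0 = %.3f, O2 per S = %.3f, C yield = %.3f mol C (mol S)-1\n",
    x$r, x$f_S0, x$o2_per_s, x$c_yield))
  invisible(x)
}

#' S_tot:O2 ratio implied by a mixing fraction
#'
#' Inverse of [sob_partition_from_ratio()]: given the fraction of sulfide
#' oxidized only to S0, returns the consumption ratio.
#'
#' @param f_S0 mixing fraction in [0, 1]
#' @return S_tot:O2 consumption ratio
#' @export
ratio_from_f_s0 <- function(f_S0) {
  .check_number(f_S0, "f_S0", 0, 1)
  1 / (f_S0 * .SOX$o2["incomplete"] + (1 - f_S0) * .SOX$o2["complete"])
}

#' Predicted C fixation by sulfur-oxidizing bacteria
#'
#' @param j_stot_sob sulfide flux into the aerobic sulfide-oxidation zone,
#'   nmol cm^-2 s^-1 (>= 0)
#' @param partition a [sob_partition_from_ratio()] result
#' @return nmol C cm^-2 s^-1
#' @export
sob_cfix <- function(j_stot_sob, partition) {
  stopifnot(inherits(partition, "sob_partition"))
  .check_number(j_stot_sob, "j_stot_sob", 0)
  unname(j_stot_sob * partition$c_yield)
}

#' Assemble the predicted CO2-fixation budget
#'
#' Converts depth-integrated gross OP and AP and the sulfide flux into the
#' SOB layer to C-fixation units and stacks them, with the AP share of
#' total photosynthesis reported in C-fixation units (an electron-unit
#' alternative is available: each sulfide carries 2 electrons against 4 per
#' O2, so AP is halved relative to OP before forming the share).
#'
#' @param gross_op,gross_ap depth-integrated gross rates,
#'   nmol O2 (resp. S) cm^-2 s^-1
#' @param j_stot_sob sulfide flux into the SOB zone, nmol cm^-2 s^-1
#' @param r observed S_tot:O2 consumption ratio of the SOB zone
#' @param ap_multiplier passed to [cfix_from_ap()]
#' @param ap_fraction_units `"carbon"` (default) or `"electron"`
#' @return an object of class `photo_budget` with `cfix_OP`, `cfix_AP`,
#'   `cfix_SOB`, `cfix_total` and `ap_fraction`
#' @export
budget <- function(gross_op, gross_ap, j_stot_sob = 0, r = 2.3,
                   ap_multiplier = 0.5,
                   ap_fraction_units = c("carbon", "electron")) {
  ap_fraction_units <- match.arg(ap_fraction_units)
  .check_number(j_stot_sob, "j_stot_sob", 0)
  cop <- cfix_from_op(gross_op)
  cap <- cfix_from_ap(gross_ap, ap_multiplier)
  csob <- if (j_stot_sob > 0) sob_cfix(j_stot_sob, sob_partition_from_ratio(r))
          else 0
  apf <- if (ap_fraction_units == "carbon") {
    if (cap + cop > 0) cap / (cap + cop) else NA_real_
  } else {
    e_ap <- 2 * gross_ap; e_op <- 4 * gross_op
    if (e_ap + e_op > 0) e_ap / (e_ap + e_op) else NA_real_
  }
  structure(list(gross_OP_areal = gross_op, gross_AP_areal = gross_ap,
                 cfix_OP = cop, cfix_AP = cap, cfix_SOB = csob,
                 cfix_total = cop + cap + csob, ap_fraction = apf),
            class = "photo_budget")
}

#' @export
print.photo_budget <- function(x, ...) {
  cat("Predicted CO2 fixation (nmol C cm-2 s-1):\n")
  cat(sprintf("  OP  %.4g\n  AP  %.4g\n  SOB %.4g\n  total %.4g\n",
              x$cfix_OP, x$cfix_AP, x$cfix_SOB, x$cfix_total))
  cat(sprintf("  AP fraction of photosynthesis: %.3f\n", x$ap_fraction))
  invisible(x)
}
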