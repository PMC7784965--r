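#' Define one mat layer of a forward-model scenario
#'
#' @param name layer label
#' @param top,bottom depth interval in mm, half-open `[top, bottom)`
#' @param rate static volumetric net rates, nmol cm^-3 s^-1 (positive =
#'   production): a named vector/list with entries `O2` and/or `S_tot`; an
#'   entry may also be a function of depth (mm) for smoothly varying rates
#' @param photo additional light-dependent rates, same form; these are the
#'   terms zeroed at a light-dark shift
#' @param limited when `TRUE`, consumption (negative total rate) in this
#'   layer is attenuated by a Monod factor where the solute is depleted
#'   (see [solve_steady_state()])
#' @return an object of class `mat_layer`
#' @export
mat_layer <- function(name, top, bottom, rate = list(), photo = list(),
                      limited = FALSE) {
  if (top >= bottom) .stopf("invalid input: layer '%s' has top >= bottom", name)
  ok <- function(r) all(names(r) %in% c("O2", "S_tot"))
  if (!ok(rate) || !ok(photo))
    .stopf("invalid input: layer '%s' rates must be named O2 / S_tot", name)
  structure(list(name = name, top = top, bottom = bottom,
                 rate = as.list(rate), photo = as.list(photo),
                 limited = limited), class = "mat_layer")
}

#' Specify a 1D reaction-diffusion mat scenario
#'
#' Geometry, transport and reaction terms of a layered mat overlying a
#' sulfide reservoir, as solved by [solve_steady_state()] and
#' [simulate_lightdark()]. Depth is mm, 0 at the mat surface, negative in
#' the overlying water; both domain ends carry fixed (Dirichlet)
#' concentrations.
#'
#' @param domain_mm `c(top, bottom)` of the modelled column
#' @param h_mm grid spacing (must not exceed 1/3 of the thinnest layer)
#' @param boundary list with `O2 = c(top, bottom)` and
#'   `S_tot = c(top, bottom)` concentrations, umol L^-1
#' @param layers list of [mat_layer()]s; they must tile `domain_mm`
#' @param light incident irradiance, umol photons m^-2 s^-1 (metadata; the
#'   `photo` terms are on whenever the light is on)
#' @param D named diffusion coefficients, cm^2 s^-1
#' @param noise_sd per-analyte Gaussian noise for [sample_profiles()]
#' @param seed default seed for noisy sampling
#' @return an object of class `mat_scenario`
#' @export
mat_scenario <- function(domain_mm = c(-0.5, 5), h_mm = 0.02,
                         boundary = list(O2 = c(60, 0), S_tot = c(50, 400)),
                         layers = list(), light = 0,
                         D = c(O2 = diffusion_coefficient("O2"),
                               S_tot = diffusion_coefficient("sulfide")),
                         noise_sd = c(O2 = 1, S_tot = 1), seed = 1L) {
  if (domain_mm[1] >= domain_mm[2]) .stopf("invalid input: empty domain")
  if (!length(layers)) .stopf("invalid input: at least one layer required")
  layers <- layers[order(vapply(layers, `[[`, 0, "top"))]
  tops <- vapply(layers, `[[`, 0, "top")
  bots <- vapply(layers, `[[`, 0, "bottom")
  if (abs(tops[1] - domain_mm[1]) > 1e-9 ||
      abs(bots[length(bots)] - domain_mm[2]) > 1e-9 ||
      any(abs(tops[-1] - bots[-length(bots)]) > 1e-9))
    .stopf("invalid input: layers must tile the domain without gaps")
  if (h_mm > min(bots - tops) / 3 + 1e-12)
    .stopf("invalid input: grid spacing must be <= 1/3 of the thinnest layer")
  n <- (domain_mm[2] - domain_mm[1]) / h_mm
  if (abs(n - round(n)) > 1e-8)
    .stopf("invalid input: domain length must be a multiple of h_mm")
  for (s in c("O2", "S_tot"))
    if (length(boundary[[s]]) != 2 || anyNA(boundary[[s]]))
      .stopf("invalid input: boundary$%s must be c(top, bottom)", s)
  structure(list(domain_mm = domain_mm, h_mm = h_mm, boundary = boundary,
                 layers = layers, light = light, D = D,
                 noise_sd = noise_sd, seed = seed),
            class = "mat_scenario")
}

#' @export
print.mat_scenario <- function(x, ...) {
  cat(sprintf("<mat_scenario> %g to %g mm, h = %g mm, light = %g\n",
              x$domain_mm[1], x$domain_mm[2], x$h_mm, x$light))
  for (l in x$layers)
    cat(sprintf("  %-16s [%5.2f, %5.2f)%s\n", l$name, l$top, l$bottom,
                if (l$limited) " (substrate-limited)" else ""))
  invisible(x)
}

.scenario_grid <- function(scen) {
  seq(scen$domain_mm[1], scen$domain_mm[2], by = scen$h_mm)
}

# Per-node rate vectors (nmol cm^-3 s^-1) for one solute; half-open layers.
.rate_field <- function(scen, solute, light_on = TRUE) {
  z <- .scenario_grid(scen)
  r <- numeric(length(z))
  limited <- logical(length(z))
  evalr <- function(term) {
    if (is.null(term)) 0
    else if (is.function(term)) term(z[inside])
    else term
  }
  for (l in scen$layers) {
    inside <- z >= l$top - 1e-12 & z < l$bottom - 1e-12
    add <- evalr(l$rate[[solute]])
    if (light_on) add <- add + evalr(l$photo[[solute]])
    r[inside] <- r[inside] + add
    if (l$limited) limited[inside] <- TRUE
  }
  list(rate = r, limited = limited)
}

# Dirichlet tridiagonal solve of D C'' + R = 0 on the interior nodes.
# Substrate-limited consumption is attenuated by a (smoothed) Monod factor
# C/(C + K); the nonlinear system is solved by damped Newton iteration, then
# a final linear solve with the frozen effective rates makes the returned
# `conc` the exact solution of the returned `rate_eff`, so the discrete flux
# identity J(bottom) - J(top) = h * sum(rate_eff) holds to machine precision.
.steady_solve_one <- function(z_mm, D, rate, bc, limited,
                              clamp = TRUE, monod_k = 1, max_iter = 50) {
  n <- length(z_mm)
  h <- cm_from_mm(z_mm[2] - z_mm[1])
  ni <- n - 2
  k <- D / h^2
  A <- Matrix::bandSparse(ni, ni, k = -1:1,
                          diagonals = list(rep(k, ni - 1), rep(-2 * k, ni),
                                           rep(k, ni - 1)))
  solve_with <- function(r_eff) {
    b <- -r_eff[2:(n - 1)]
    b[1] <- b[1] - k * bc[1]
    b[ni] <- b[ni] - k * bc[2]
    as.numeric(Matrix::solve(A, b))
  }
  lim <- (limited & rate < 0)[2:(n - 1)]
  r_int <- rate[2:(n - 1)]
  if (!clamp || !any(lim)) {
    cint <- solve_with(rate)
    r_eff <- rate
  } else {
    eps <- 1e-6
    gfun <- function(x) {            # smoothed positive-part Monod factor
      cs <- 0.5 * (x + sqrt(x^2 + eps^2))
      list(g = cs / (cs + monod_k),
           dg = monod_k / (cs + monod_k)^2 *
             0.5 * (1 + x / sqrt(x^2 + eps^2)))
    }
    rates_at <- function(x) {
      gg <- gfun(x)
      list(r = ifelse(lim, r_int * gg$g, r_int),
           dr = ifelse(lim, r_int * gg$dg, 0))
    }
    resid <- function(x, r) {
      bterm <- c(k * bc[1], rep(0, ni - 2), k * bc[2])
      as.numeric(A %*% x) + bterm + r
    }
    # start from the solution without the limited consumption terms
    x <- solve_with(ifelse(c(FALSE, lim, FALSE), 0, rate))
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      ra <- rates_at(x)
      Fx <- resid(x, ra$r)
      fn <- max(abs(Fx))
      if (fn < 1e-9 * k * (max(abs(bc)) + 1)) { converged <- TRUE; break }
      J <- A + Matrix::Diagonal(ni, ra$dr)
      dx <- as.numeric(Matrix::solve(J, -Fx))
      t <- 1
      repeat {
        xn <- x + t * dx
        if (max(abs(resid(xn, rates_at(xn)$r))) < fn || t < 1 / 128) break
        t <- t / 2
      }
      x <- x + t * dx
    }
    if (!converged)
      .warnf("substrate-limitation Newton iteration not fully converged")
    r_eff <- rate
    r_eff[2:(n - 1)] <- rates_at(x)$r
    cint <- solve_with(r_eff)
  }
  conc <- c(bc[1], cint, bc[2])
  j_top <- -D * (conc[2] - conc[1]) / h
  j_bot <- -D * (conc[n] - conc[n - 1]) / h
  list(conc = conc, rate_eff = r_eff,
       flux = c(top = j_top, bottom = j_bot),
       areal = h * sum(r_eff[2:(n - 1)]))
}

#' Solve a scenario to steady state
#'
#' Solves `D C'' + R(z) = 0` per solute with Dirichlet boundary
#' concentrations on the uniform grid, via a sparse tridiagonal solve.
#' Substrate-limited consumption terms are attenuated by a Monod factor
#' `C / (C + K)` (half-saturation `K` = 1 umol L^-1) so consumption dies
#' off smoothly where the solute is depleted; the nonlinearity is resolved
#' by a damped fixed-point iteration. The result carries the exact imposed
#' (effective) rates and the discrete boundary fluxes as a truth record: by
#' construction `flux[bottom] - flux[top] = h * sum(R)` to machine
#' precision, because `conc` solves the returned `rate_eff` exactly.
#'
#' @param scenario a [mat_scenario()]
#' @param light_on include the `photo` rate terms?
#' @param clamp apply the substrate-limitation rule?
#' @return an object of class `mat_steady`: list with `depth_mm`, `conc`
#'   (list of node vectors per solute) and `truth` (per solute: `rate_eff`,
#'   `flux`, `areal`)
#' @export
solve_steady_state <- function(scenario, light_on = TRUE, clamp = TRUE) {
  stopifnot(inherits(scenario, "mat_scenario"))
  z <- .scenario_grid(scenario)
  out <- list(depth_mm = z, conc = list(), truth = list(),
              scenario = scenario, light_on = light_on)
  for (s in c("O2", "S_tot")) {
    rf <- .rate_field(scenario, s, light_on)
    sol <- tryCatch(
      .steady_solve_one(z, scenario$D[[s]], rf$rate, scenario$boundary[[s]],
                        rf$limited, clamp = clamp),
      error = function(e) .stopf("numerical failure (%s): %s", s,
                                 conditionMessage(e)))
    out$conc[[s]] <- sol$conc
    out$truth[[s]] <- sol[c("rate_eff", "flux", "areal")]
  }
  class(out) <- "mat_steady"
  out
}

#' @export
print.mat_steady <- function(x, ...) {
  cat(sprintf("<mat_steady> %d nodes, light %s\n", length(x$depth_mm),
              if (x$light_on) "on" else "off"))
  for (s in names(x$conc))
    cat(sprintf("  %-6s J(top) %.4g, J(bottom) %.4g nmol cm-2 s-1\n",
                s, x$truth[[s]]$flux["top"], x$truth[[s]]$flux["bottom"]))
  invisible(x)
}

#' Sample a steady solution at sensor resolution
#'
#' Downsamples the forward-model grid to a measurement spacing, optionally
#' adds Gaussian sensor noise, and emulates the raw measurables: a linear pH
#' profile between `ph_range` end values, and H2S back-computed from the
#' (noisy) S_tot and that pH, so that [derive_stot()] applied to the output
#' reproduces the S_tot column exactly.
#'
#' @param steady a [solve_steady_state()] result
#' @param spacing_mm sampling interval (a multiple of the grid spacing)
#' @param noise_sd named per-analyte noise, umol L^-1; defaults to the
#'   scenario's (set to 0 for noiseless)
#' @param seed RNG seed for the noise; defaults to the scenario's
#' @param ph_range `c(top_pH, bottom_pH)` of the emulated linear pH profile
#' @param params [speciation_params()] used for the H2S back-calculation
#' @return a [profile_set()] with `O2`, `H2S`, `pH` and `S_tot` profiles
#' @export
sample_profiles <- function(steady, spacing_mm = 0.18, noise_sd = NULL,
                            seed = NULL, ph_range = c(7.4, 6.9),
                            params = speciation_params()) {
  stopifnot(inherits(steady, "mat_steady"))
  scen <- steady$scenario
  if (is.null(noise_sd)) noise_sd <- scen$noise_sd
  if (is.null(seed)) seed <- scen$seed
  z <- steady$depth_mm
  step <- round(spacing_mm / scen$h_mm)
  if (step < 1 || abs(step * scen$h_mm - spacing_mm) > 1e-9)
    .stopf("invalid input: spacing_mm must be a positive multiple of h_mm")
  idx <- unique(c(seq(1, length(z), by = step), length(z)))
  zz <- z[idx]
  vals <- lapply(steady$conc, function(cc) pmax(cc[idx], 0))
  .with_seed(seed, {
    for (s in names(vals)) {
      sd_s <- if (s %in% names(noise_sd)) noise_sd[[s]] else 0
      if (sd_s > 0)
        vals[[s]] <- pmax(vals[[s]] + stats::rnorm(length(idx), 0, sd_s), 0)
    }
  })
  ph <- ph_range[1] + (ph_range[2] - ph_range[1]) *
    (zz - zz[1]) / (zz[length(zz)] - zz[1])
  mk <- function(analyte, v)
    depth_profile(analyte, zz, v, light_intensity = scen$light, time_h = 0)
  profile_set(
    o2 = mk("O2", vals$O2),
    h2s = mk("H2S", vals$S_tot * h2s_fraction(ph, params)),
    ph = mk("pH", ph),
    s_tot = mk("S_tot", vals$S_tot))
}

#' Simulate a light-dark shift transient
#'
#' Starts from the illuminated steady state, zeroes all `photo` rate terms
#' at `switch_time_s`, and integrates `dC/dt = D C'' + R(z)` with an
#' unconditionally stable implicit (backward Euler) scheme on the scenario
#' grid. The substrate-limitation active set is frozen at its pre-switch
#' state so the transient operator stays linear. The record of the imposed
#' photo rates at every node is returned for oracle use: at `switch_time+`,
#' `dC/dt` at any node equals minus the photo term that was just removed.
#'
#' @param scenario a [mat_scenario()]
#' @param switch_time_s time of the dark shift (s)
#' @param duration_s total simulated time (s)
#' @param dt_s integration step (s)
#' @param output_dt_s sampling interval of the returned series (s)
#' @return an object of class `mat_transient`: `time_s`, `depth_mm`, `conc`
#'   (list of time-by-depth matrices), `photo_rate` (list of node vectors),
#'   `switch_time_s`
#' @export
simulate_lightdark <- function(scenario, switch_time_s = 5, duration_s = 20,
                               dt_s = 0.05, output_dt_s = 0.5) {
  stopifnot(inherits(scenario, "mat_scenario"))
  if (dt_s <= 0 || duration_s <= switch_time_s)
    .stopf("invalid input: need dt_s > 0 and duration_s > switch_time_s")
  z <- .scenario_grid(scenario)
  n <- length(z); ni <- n - 2
  h <- cm_from_mm(scenario$h_mm)
  init <- solve_steady_state(scenario, light_on = TRUE)
  out_t <- seq(0, duration_s, by = output_dt_s)
  conc <- list(); photo <- list()
  for (s in c("O2", "S_tot")) {
    D <- scenario$D[[s]]; bc <- scenario$boundary[[s]]
    rf_on <- .rate_field(scenario, s, light_on = TRUE)
    rf_off <- .rate_field(scenario, s, light_on = FALSE)
    # freeze the substrate-limitation attenuation of the lit steady state
    fac <- ifelse(rf_on$rate != 0, init$truth[[s]]$rate_eff / rf_on$rate, 1)
    r_on <- rf_on$rate * fac
    r_off <- rf_off$rate * fac
    photo[[s]] <- r_on - r_off
    k <- D / h^2
    L <- Matrix::bandSparse(ni, ni, k = -1:1,
      diagonals = list(rep(k, ni - 1), rep(-2 * k, ni), rep(k, ni - 1)))
    M <- Matrix::Diagonal(ni) - dt_s * L
    fac <- Matrix::Cholesky(Matrix::forceSymmetric(M))
    cc <- init$conc[[s]][2:(n - 1)]
    bvec <- function(r) {
      b <- r[2:(n - 1)]
      b[1] <- b[1] + k * bc[1]; b[ni] <- b[ni] + k * bc[2]
      b
    }
    nt <- ceiling(duration_s / dt_s)
    store <- matrix(NA_real_, length(out_t), n)
    store[1, ] <- c(bc[1], cc, bc[2])
    nxt <- 2
    for (it in seq_len(nt)) {
      tcur <- it * dt_s
      r <- if (tcur > switch_time_s) r_off else r_on
      rhs <- cc + dt_s * bvec(r)
      cc <- as.numeric(Matrix::solve(fac, rhs))
      if (any(!is.finite(cc)) || max(abs(cc)) > 1e8)
        .stopf("numerical failure: transient diverged")
      while (nxt <= length(out_t) && out_t[nxt] <= tcur + 1e-9) {
        store[nxt, ] <- c(bc[1], cc, bc[2]); nxt <- nxt + 1
      }
    }
    conc[[s]] <- store
  }
  structure(list(time_s = out_t, depth_mm = z, conc = conc,
                 photo_rate = photo, switch_time_s = switch_time_s,
                 scenario = scenario),
            class = "mat_transient")
}

#' Extract the post-shift series at one depth
#'
#' Convenience accessor returning the concentration time series at the grid
#' node nearest `depth_mm`, re-zeroed to the dark transition, ready for
#' [gross_rate_lightdark()].
#'
#' @param transient a [simulate_lightdark()] result
#' @param depth_mm target depth (mm)
#' @param solute `"O2"` or `"S_tot"`
#' @return data.frame with `time_s` (0 at the switch) and `conc`
#' @export
lightdark_series <- function(transient, depth_mm, solute = c("O2", "S_tot")) {
  solute <- match.arg(solute)
  stopifnot(inherits(transient, "mat_transient"))
  i <- which.min(abs(transient$depth_mm - depth_mm))
  keep <- transient$time_s >= transient$switch_time_s - 1e-9
  data.frame(time_s = transient$time_s[keep] - transient$switch_time_s,
             conc = transient$conc[[solute]][keep, i])
}

#' Specify a diel stable-isotope-probing scenario
#'
#' Phase schedule and label dynamics for the forward SIP model: each phase
#' imposes a constant bulk C-fixation flux, a DOC excretion intensity
#' (active only under oxygenic photosynthesis) and per-guild fatty-acid
#' labelling rates. Defaults mirror a stepwise light ramp over a sulfidic
#' mat: dark, anoxygenic photosynthesis at 7 and 19, oxygenic at 89 and 315
#' umol photons m^-2 s^-1, dark again.
#'
#' @param phases data.frame with columns `label` (`dark`/`AP`/`OP`),
#'   `start_h`, `end_h`, `light`, `cfix` (mmol C m^-2 h^-1), `doc_rate`
#'   (relative-ratio units h^-1)
#' @param guild_uptake matrix of fatty-acid labelling rates (permil h^-1):
#'   rows = phase rows, columns `cyanobacteria`, `SRB-FA1`, `SRB-FA2`,
#'   `SRB-FA3`, `SOB`
#' @param dic_atom_fraction 13C atom fraction of the labelled DIC pool
#' @param areal_carbon areal carbon content of the mat, mmol C m^-2
#' @param mat_baseline_delta natural-abundance delta 13C of mat biomass
#' @param fa_baseline_delta natural-abundance delta 13C of the fatty acids
#' @param doc_decay_per_h first-order decay of the DOC label excess in the
#'   dark, h^-1
#' @param sample_every_h output sampling interval (phase boundaries are
#'   always sampled)
#' @param noise_sd_delta Gaussian noise on delta-scale outputs (permil)
#' @param noise_sd_x Gaussian noise on the mat atom fraction
#' @param seed RNG seed for the noise
#' @return an object of class `diel_sip_scenario`
#' @export
diel_sip_scenario <- function(
    phases = data.frame(
      label = c("dark", "AP", "AP", "OP", "OP", "dark"),
      start_h = c(0, 6, 8, 10, 14, 18),
      end_h = c(6, 8, 10, 14, 18, 24),
      light = c(0, 7, 19, 89, 315, 0),
      cfix = c(0.2, 0.5, 0.8, 2, 4, 0.3),
      doc_rate = c(0, 0, 0, 0.4, 0.8, 0)),
    guild_uptake = NULL,
    dic_atom_fraction = 0.06, areal_carbon = 1000,
    mat_baseline_delta = -28, fa_baseline_delta = -30,
    doc_decay_per_h = 1, sample_every_h = 1,
    noise_sd_delta = 0, noise_sd_x = 0, seed = 1L) {
  need <- c("label", "start_h", "end_h", "light", "cfix", "doc_rate")
  if (!all(need %in% names(phases)))
    .stopf("invalid input: phases needs columns %s", paste(need, collapse = ", "))
  if (any(abs(phases$start_h[-1] - utils::head(phases$end_h, -1)) > 1e-9))
    .stopf("invalid input: phases must be contiguous")
  if (!all(phases$label %in% c("dark", "AP", "OP")))
    .stopf("invalid input: phase labels must be dark/AP/OP")
  .check_number(dic_atom_fraction, "dic_atom_fraction", 0, 1,
                strict_lower = TRUE, strict_upper = TRUE)
  .check_number(areal_carbon, "areal_carbon", 0, strict_lower = TRUE)
  if (is.null(guild_uptake)) {
    guild_uptake <- t(vapply(phases$label, function(lab) switch(lab,
      #           cyano FA1  FA2  FA3  SOB
      dark = c(0.2, 0.0, 0.3, 0.5, 0.1),
      AP   = c(1.0, 0.0, 1.0, 4.0, 0.3),
      OP   = c(6.0, 3.0, 2.0, 1.0, 1.5)), numeric(5)))
    colnames(guild_uptake) <- c("cyanobacteria", "SRB-FA1", "SRB-FA2",
                                "SRB-FA3", "SOB")
  }
  if (nrow(guild_uptake) != nrow(phases))
    .stopf("invalid input: guild_uptake must have one row per phase")
  structure(list(phases = phases, guild_uptake = guild_uptake,
                 dic_atom_fraction = dic_atom_fraction,
                 areal_carbon = areal_carbon,
                 mat_baseline_delta = mat_baseline_delta,
                 fa_baseline_delta = fa_baseline_delta,
                 doc_decay_per_h = doc_decay_per_h,
                 sample_every_h = sample_every_h,
                 noise_sd_delta = noise_sd_delta, noise_sd_x = noise_sd_x,
                 seed = seed),
            class = "diel_sip_scenario")
}

#' Simulate diel 13C label trajectories
#'
#' Forward SIP model: the bulk-mat atom fraction integrates the imposed
#' fixation flux scaled by the DIC label excess over the mat's
#' natural-abundance baseline (`dx/dt = F (x_DIC - x_nat) / C_areal`, the
#' exact inverse of [mat_cfix_flux()]); the DOC 13C/12C ratio rises only
#' during OP phases and decays first-order toward baseline in the dark;
#' each fatty acid's delta 13C integrates its guild's phase-specific
#' labelling rate. All trajectories are piecewise analytic, so the truth
#' record is exact.
#'
#' @param scenario a [diel_sip_scenario()]
#' @return list with `mat`, `dic`, `doc` ([sip_series()] objects; mat and
#'   dic on the atom-fraction scale, doc on the delta scale), `fa` (named
#'   list of delta-scale `sip_series`), `guilds` (the [assign_guilds()]
#'   table) and `truth` (imposed per-phase fluxes and uptake rates)
#' @export
simulate_diel_sip <- function(scenario) {
  stopifnot(inherits(scenario, "diel_sip_scenario"))
  ph <- scenario$phases
  t_out <- sort(unique(c(ph$start_h, ph$end_h,
                         seq(min(ph$start_h), max(ph$end_h),
                             by = scenario$sample_every_h))))
  x_nat <- delta_to_atom_fraction(scenario$mat_baseline_delta)
  excess <- scenario$dic_atom_fraction - x_nat
  if (excess <= 0)
    .stopf("invalid input: DIC label must exceed the mat baseline")

  phase_of <- function(t) max(which(ph$start_h <= t + 1e-12))
  # piecewise-linear mat atom fraction
  x_mat <- numeric(length(t_out)); x_mat[1] <- x_nat
  # DOC relative ratio and FA deltas
  rho <- numeric(length(t_out)); rho[1] <- 1
  fa_tab <- assign_guilds(c(.fa_guilds$cyano, .fa_guilds$srb, .fa_guilds$sob))
  fa_group <- ifelse(fa_tab$guild == "SRB", fa_tab$subgroup,
                     ifelse(fa_tab$guild == "cyanobacteria", "cyanobacteria",
                            "SOB"))
  fa_delta <- matrix(scenario$fa_baseline_delta, length(t_out), nrow(fa_tab),
                     dimnames = list(NULL, fa_tab$fa))
  for (i in 2:length(t_out)) {
    t0 <- t_out[i - 1]; t1 <- t_out[i]; dt <- t1 - t0
    p <- phase_of(t0)
    x_mat[i] <- x_mat[i - 1] +
      ph$cfix[p] * excess / scenario$areal_carbon * dt
    rho[i] <- if (ph$label[p] == "OP") rho[i - 1] + ph$doc_rate[p] * dt
      else if (ph$label[p] == "dark")
        1 + (rho[i - 1] - 1) * exp(-scenario$doc_decay_per_h * dt)
      else rho[i - 1]
    up <- scenario$guild_uptake[p, fa_group]
    fa_delta[i, ] <- fa_delta[i - 1, ] + up * dt
  }
  doc_delta <- (R_VPDB * (scenario$mat_baseline_delta / 1000 + 1) * rho /
                  R_VPDB - 1) * 1000

  noisy_delta <- function(v) v
  noisy_x <- function(v) v
  .with_seed(scenario$seed, {
    if (scenario$noise_sd_delta > 0)
      noisy_delta <- function(v) v + stats::rnorm(length(v), 0,
                                                  scenario$noise_sd_delta)
    if (scenario$noise_sd_x > 0)
      noisy_x <- function(v)
        pmin(pmax(v + stats::rnorm(length(v), 0, scenario$noise_sd_x),
                  1e-6), 1 - 1e-6)
    x_mat <- noisy_x(x_mat)
    doc_delta <- noisy_delta(doc_delta)
    fa_delta <- apply(fa_delta, 2, noisy_delta)
  })

  fa_series <- stats::setNames(lapply(seq_len(ncol(fa_delta)), function(j)
    sip_series(paste0("FA:", colnames(fa_delta)[j]), t_out, fa_delta[, j],
               scale = "delta")), colnames(fa_delta))
  list(
    mat = sip_series("mat_bulk", t_out, x_mat, scale = "atom_fraction"),
    dic = sip_series("DIC", t_out,
                     rep(scenario$dic_atom_fraction, length(t_out)),
                     scale = "atom_fraction"),
    doc = sip_series("DOC", t_out, doc_delta, scale = "delta"),
    fa = fa_series, guilds = fa_tab,
    truth = list(phases = ph, guild_uptake = scenario$guild_uptake,
                 areal_carbon = scenario$areal_carbon,
                 dic_excess = excess, x_nat = x_nat))
}

.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Add reproducible Gaussian noise
#'
#' @param x a numeric vector, [depth_profile()] or [sip_series()]
#' @param sigma noise standard deviation (>= 0); `sigma = 0` returns `x`
#'   unchanged
#' @param seed RNG seed; the global RNG state is restored afterwards
#' @return a noisy copy of `x`
#' @export
add_noise <- function(x, sigma, seed = 1L) UseMethod("add_noise")

#' @export
add_noise.numeric <- function(x, sigma, seed = 1L) {
  .check_number(sigma, "sigma", 0)
  if (sigma == 0) return(x)
  .with_seed(seed, x + stats::rnorm(length(x), 0, sigma))
}

#' @export
add_noise.depth_profile <- function(x, sigma, seed = 1L) {
  .check_number(sigma, "sigma", 0)
  if (sigma == 0) return(x)
  x$value <- pmax(add_noise(x$value, sigma, seed), 0)
  x
}

#' @export
add_noise.sip_series <- function(x, sigma, seed = 1L) {
  .check_number(sigma, "sigma", 0)
  if (sigma == 0) return(x)
  v <- add_noise(x$value, sigma, seed)
  if (attr(x, "scale") == "atom_fraction") v <- pmin(pmax(v, 1e-9), 1 - 1e-9)
  x$value <- v
  x
}

#' Named forward-model presets
#'
#' Deterministic scenario presets covering the canonical states of a
#' sulfidic mat under a light ramp:
#' \describe{
#'   \item{dark}{SOB layer at the surface consuming O2 and sulfide;
#'     sulfide production at 3-5 mm. O2 penetrates only the top few
#'     hundred um; S_tot peaks at depth.}
#'   \item{low_light_ap}{as dark, plus light-driven sulfide consumption
#'     (AP) in the cyanobacterial layer at 0.3-1.1 mm.}
#'   \item{op_sob_below}{higher light: OP in the cyanobacterial layer
#'     (O2 peak above the boundary concentration) with the SOB layer
#'     relocated beneath it, where the upward sulfide flux meets
#'     photosynthetic O2.}
#'   \item{dcmu}{OP poisoned: AP continues, no O2 production, O2 confined
#'     to the surface layer.}
#'   \item{three_zone}{clean quantitative scenario (no substrate
#'     limitation, concentrations positive everywhere): a sulfide-consuming
#'     layer at 0.3-1.1 mm, an inert gap, and a production zone at
#'     2.2-3 mm. Used as the forward-inverse oracle.}
#'   \item{lightdark}{like three_zone but with the consumption declared as
#'     a photo (light-dependent) term for O2 and S_tot, for light-dark
#'     shift transients.}
#'   \item{diel}{the default [diel_sip_scenario()].}
#' }
#' When the surface-layer S_tot:O2 flux-ratio leaves the aerobic
#' sulfide-oxidation window (see [sob_partition_from_ratio()]), the natural
#' response of the mat is SOB migration: `relocate_sob()` applies that rule
#' to a preset.
#'
#' @param name preset name; omit to list the available names
#' @return a [mat_scenario()] or [diel_sip_scenario()], or the preset names
#' @export
scenario_library <- function(name = NULL) {
  presets <- list(
    dark = function() mat_scenario(
      domain_mm = c(-0.5, 5), h_mm = 0.02,
      boundary = list(O2 = c(60, 0), S_tot = c(50, 400)),
      light = 0,
      layers = list(
        mat_layer("water_dbl", -0.5, 0),
        mat_layer("sob_layer", 0, 0.3,
                  rate = c(O2 = -1.5, S_tot = -0.6), limited = TRUE),
        mat_layer("cyano_layer", 0.3, 1.1,
                  rate = c(O2 = -0.1), limited = TRUE),
        mat_layer("gap", 1.1, 3),
        mat_layer("production_zone", 3, 5, rate = c(S_tot = 0.3)))),
    low_light_ap = function() mat_scenario(
      domain_mm = c(-0.5, 5), h_mm = 0.02,
      boundary = list(O2 = c(60, 0), S_tot = c(50, 400)),
      light = 7,
      layers = list(
        mat_layer("water_dbl", -0.5, 0),
        mat_layer("sob_layer", 0, 0.3,
                  rate = c(O2 = -1.5, S_tot = -0.6), limited = TRUE),
        mat_layer("cyano_layer", 0.3, 1.1,
                  rate = c(O2 = -0.1), photo = c(S_tot = -0.8),
                  limited = TRUE),
        mat_layer("gap", 1.1, 3),
        mat_layer("production_zone", 3, 5, rate = c(S_tot = 0.3)))),
    op_sob_below = function() mat_scenario(
      domain_mm = c(-0.5, 5), h_mm = 0.02,
      boundary = list(O2 = c(60, 0), S_tot = c(20, 400)),
      light = 89,
      layers = list(
        mat_layer("water_dbl", -0.5, 0),
        mat_layer("surface", 0, 0.3),
        mat_layer("cyano_layer", 0.3, 1.1,
                  photo = c(O2 = 0.6, S_tot = -0.4), limited = TRUE),
        mat_layer("sob_layer", 1.1, 1.6,
                  rate = c(O2 = -1.2, S_tot = -0.8), limited = TRUE),
        mat_layer("gap", 1.6, 3),
        mat_layer("production_zone", 3, 5, rate = c(S_tot = 0.3)))),
    dcmu = function() mat_scenario(
      domain_mm = c(-0.5, 5), h_mm = 0.02,
      boundary = list(O2 = c(60, 0), S_tot = c(50, 400)),
      light = 315,
      layers = list(
        mat_layer("water_dbl", -0.5, 0),
        mat_layer("sob_layer", 0, 0.3,
                  rate = c(O2 = -1.5, S_tot = -0.6), limited = TRUE),
        mat_layer("cyano_layer", 0.3, 1.1,
                  rate = c(O2 = -0.1), photo = c(S_tot = -0.8),
                  limited = TRUE),
        mat_layer("gap", 1.1, 3),
        mat_layer("production_zone", 3, 5, rate = c(S_tot = 0.3)))),
    three_zone = function() mat_scenario(
      domain_mm = c(-0.7, 3), h_mm = 0.02,
      boundary = list(O2 = c(100, 100), S_tot = c(300, 500)),
      light = 7,
      layers = list(
        mat_layer("water_dbl", -0.7, 0.3),
        mat_layer("cyano_layer", 0.3, 1.1, rate = c(S_tot = -0.8)),
        mat_layer("gap", 1.1, 2.2),
        mat_layer("production_zone", 2.2, 3, rate = c(S_tot = 0.5)))),
    lightdark = function() mat_scenario(
      domain_mm = c(-0.7, 3), h_mm = 0.02,
      boundary = list(O2 = c(100, 100), S_tot = c(300, 500)),
      light = 89,
      layers = list(
        mat_layer("water_dbl", -0.7, 0.3),
        mat_layer("cyano_layer", 0.3, 1.1,
                  photo = c(O2 = 0.6, S_tot = -0.8)),
        mat_layer("gap", 1.1, 2.2),
        mat_layer("production_zone", 2.2, 3, rate = c(S_tot = 0.5)))),
    diel = function() diel_sip_scenario())
  if (is.null(name)) return(names(presets))
  if (!name %in% names(presets))
    .stopf("invalid input: unknown preset '%s' (available: %s)", name,
           paste(names(presets), collapse = ", "))
  presets[[name]]()
}

#' Relocate the SOB layer beneath the cyanobacterial layer
#'
#' Applies the migration rule: when the S_tot:O2 consumption-flux ratio of
#' the surface layer leaves the feasible aerobic sulfide-oxidation window
#' `[2/3, 2.5]`, the SOB population abandons the surface and re-forms as a
#' consumption layer immediately below the cyanobacterial layer. The
#' returned scenario has the surface SOB rates moved to a layer below the
#' deepest `cyano_layer`.
#'
#' @param scenario a [mat_scenario()] containing layers named `sob_layer`
#'   and `cyano_layer`
#' @param thickness_mm thickness of the relocated SOB layer
#' @return a modified [mat_scenario()]
#' @export
relocate_sob <- function(scenario, thickness_mm = 0.5) {
  stopifnot(inherits(scenario, "mat_scenario"))
  nms <- vapply(scenario$layers, `[[`, "", "name")
  i_sob <- which(nms == "sob_layer"); i_cy <- which(nms == "cyano_layer")
  if (!length(i_sob) || !length(i_cy))
    .stopf("invalid input: scenario lacks sob_layer / cyano_layer")
  sob <- scenario$layers[[i_sob]]
  cy_bottom <- scenario$layers[[i_cy]]$bottom
  old <- c(sob$top, sob$bottom)
  # turn the old SOB interval inert
  scenario$layers[[i_sob]] <- mat_layer("surface", old[1], old[2])
  # carve the new interval out of whatever layer spans it
  new_iv <- c(cy_bottom, cy_bottom + thickness_mm)
  rebuilt <- list()
  for (l in scenario$layers) {
    if (l$top < new_iv[2] && l$bottom > new_iv[1] && l$name != "cyano_layer") {
      if (l$top < new_iv[1])
        rebuilt <- c(rebuilt, list(mat_layer(l$name, l$top, new_iv[1],
                                             l$rate, l$photo, l$limited)))
      if (l$bottom > new_iv[2])
        rebuilt <- c(rebuilt, list(mat_layer(l$name, new_iv[2], l$bottom,
                                             l$rate, l$photo, l$limited)))
    } else rebuilt <- c(rebuilt, list(l))
  }
  rebuilt <- c(rebuilt, list(mat_layer("sob_layer", new_iv[1], new_iv[2],
                                       sob$rate, sob$photo, sob$limited)))
  mat_scenario(domain_mm = scenario$domain_mm, h_mm = scenario$h_mm,
               boundary = scenario$boundary, layers = rebuilt,
               light = scenario$light, D = scenario$D,
               noise_sd = scenario$noise_sd, seed = scenario$seed)
}
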