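test_that("delta / atom-fraction conversions are exact and monotone", {
  # x = R/(1+R) with R = R_VPDB at delta = 0
  expect_equal(delta_to_atom_fraction(0), 0.0111802 / 1.0111802,
               tolerance = 1e-12)
  expect_lt(delta_to_atom_fraction(-999.999), 1e-7)
  expect_error(delta_to_atom_fraction(-1000), "delta")
  d <- seq(-900, 5000, 50)
  x <- delta_to_atom_fraction(d)
  expect_true(all(diff(x) > 0))
  expect_equal(atom_fraction_to_delta(x), d, tolerance = 1e-9)
})

test_that("label increase is measured against the first time point", {
  s <- sip_series("FA:iC15:0", c(0, 5, 10), c(-28, -20, -10))
  dd <- delta_delta(s)
  expect_equal(dd$value, c(0, 8, 18))
  const <- delta_delta(sip_series("FA:C17:0", c(0, 5), c(-25, -25)))
  expect_equal(const$value, c(0, 0))
  xf <- sip_series("DIC", c(0, 5), c(0.011, 0.06), scale = "atom_fraction")
  expect_error(delta_delta(xf), "scale mismatch")
})

test_that("bulk CO2 assimilation flux is DIC-excess-corrected", {
  x0 <- delta_to_atom_fraction(-28)
  tt <- 0:10
  dic6 <- sip_series("DIC", tt, rep(0.06, 11), scale = "atom_fraction")
  # no change in labelling -> zero flux
  flat <- sip_series("mat_bulk", tt, rep(x0, 11), scale = "atom_fraction")
  expect_equal(mat_cfix_flux(flat, dic6, 1000), 0)
  # imposed flux F: dx/dt = F * excess / C
  F <- 2.5; C <- 1000
  mat <- sip_series("mat_bulk", tt, x0 + F * (0.06 - x0) / C * tt,
                    scale = "atom_fraction")
  expect_equal(mat_cfix_flux(mat, dic6, C), F, tolerance = 1e-10)
  # doubling the DIC excess at fixed mat slope halves the flux
  dic_double <- sip_series("DIC", tt, rep(x0 + 2 * (0.06 - x0), 11),
                           scale = "atom_fraction")
  expect_equal(mat_cfix_flux(mat, dic_double, C), F / 2, tolerance = 1e-10)
  # invariance under a uniform time shift
  mat_s <- sip_series("mat_bulk", tt + 7, mat$value, scale = "atom_fraction")
  dic_s <- sip_series("DIC", tt + 7, dic6$value, scale = "atom_fraction")
  expect_equal(mat_cfix_flux(mat_s, dic_s, C), F, tolerance = 1e-10)
  # unlabelled DIC is uninterpretable
  dic_nat <- sip_series("DIC", tt, rep(x0, 11), scale = "atom_fraction")
  expect_error(mat_cfix_flux(mat, dic_nat, C), "excess")
})

test_that("DOC enrichment is reported relative to the first time point", {
  doc <- sip_series("DOC", 0:3, rep(-27, 4))
  rel <- doc_relative_enrichment(doc)
  expect_equal(rel$rel, rep(1, 4))
  expect_equal(doc_relative_enrichment(doc, output = "difference")$rel,
               rep(0, 4))
  up <- sip_series("DOC", 0:3, c(-27, -20, -10, 5))
  expect_true(all(diff(doc_relative_enrichment(up)$rel) > 0))
})

test_that("FA-RUR normalises labelling rates within the group", {
  mk <- function(nm, slope) sip_series(paste0("FA:", nm), c(0, 2),
                                       c(0, 2 * slope))
  r <- fa_rur(list(a = mk("a", 2), b = mk("b", 1), c = mk("c", 1)), c(0, 2))
  expect_equal(unname(r$rur), c(0.5, 0.25, 0.25))
  expect_true(r$defined)
  # equal slopes -> 1/n each
  eq <- fa_rur(list(a = mk("a", 3), b = mk("b", 3), c = mk("c", 3),
                    d = mk("d", 3)), c(0, 2))
  expect_equal(unname(eq$rur), rep(0.25, 4))
  # single labelled FA takes everything
  one <- fa_rur(list(a = mk("a", 0), b = mk("b", 5)), c(0, 2))
  expect_equal(unname(one$rur), c(0, 1))
  # random signed slopes with positive total: contributions sum to 1
  set.seed(21)
  for (i in 1:20) {
    sl <- rnorm(5)
    if (sum(sl) <= 0) sl <- sl - 2 * sum(sl) / 5
    series <- setNames(lapply(sl, function(s) mk("x", s)), letters[1:5])
    expect_equal(sum(fa_rur(series, c(0, 2))$rur), 1, tolerance = 1e-12)
  }
  # non-positive denominator: undefined, not renormalised
  und <- fa_rur(list(a = mk("a", -2), b = mk("b", 1)), c(0, 2))
  expect_false(und$defined)
  expect_true(all(is.na(und$rur)))
  expect_error(fa_rur(list(a = mk("a", 1)), c(0, 2), members = c("a", "z")),
               "not measured")
  expect_error(fa_rur(list(a = mk("a", 1)), c(0, 3)), "endpoints")
})

test_that("guild assignment reproduces the biomarker tables", {
  g <- assign_guilds(c("10Me-C16:0", "C16:1w7", "aiC15:0", "C16:1w9",
                       "iC17:1", "C17:1"))
  expect_equal(g$guild,
               c("SRB", "SOB", "SRB", "cyanobacteria", "SRB", "SRB"))
  expect_equal(g$subgroup[g$fa == "10Me-C16:0"], "SRB-FA1")
  expect_equal(g$subgroup[g$fa == "iC17:1"], "SRB-FA1")
  expect_equal(g$subgroup[g$fa == "C17:1"], "SRB-FA2")
  expect_equal(g$subgroup[g$fa == "aiC15:0"], "SRB-FA3")
  expect_equal(g$subgroup[g$fa == "C16:1w9"], "ungrouped")
  # omega spelled with the Greek letter
  expect_equal(assign_guilds("C18:1ω7")$guild, "SOB")
  expect_warning(g2 <- assign_guilds("C99:9"), "unrecognized")
  expect_equal(g2$guild, "other")
  # full SRB list has nine members across the three subgroups
  srb <- c("aiC15:0", "iC15:0", "10Me-C16:0", "aiC17:0", "iC17:0", "iC17:1",
           "C15:1", "C17:0", "C17:1")
  gs <- assign_guilds(srb)
  expect_true(all(gs$guild == "SRB"))
  expect_equal(sort(unique(gs$subgroup)), c("SRB-FA1", "SRB-FA2", "SRB-FA3"))
})
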