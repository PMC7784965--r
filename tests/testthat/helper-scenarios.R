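# Shared fixtures, all generated in code.

D_O2 <- diffusion_coefficient("O2")
D_S <- diffusion_coefficient("sulfide")

# the clean quantitative scenario: AP-like consumption, inert gap, production
three_zone_truth <- list(
  rates = c(cyano = -0.8, gap = 0, production = 0.5),
  knots = c(0.3, 1.1, 2.2, 3),
  areal_ap = 0.8 * 0.08)   # nmol cm^-2 s^-1 consumed in [0.3, 1.1]

steady_three_zone <- local({
  solve_steady_state(scenario_library("three_zone"))
})

# trim a depth profile to an interval (keeps metadata)
trim_profile <- function(pr, lo, hi) {
  keep <- pr$depth_mm >= lo - 1e-9 & pr$depth_mm <= hi + 1e-9
  depth_profile(attr(pr, "analyte"), pr$depth_mm[keep], pr$value[keep],
                light_intensity = attr(pr, "light_intensity"),
                time_h = attr(pr, "time_h"),
                replicate_id = attr(pr, "replicate_id"))
}
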