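# Shared small fixtures: a reduced-resolution white-pine section (8 wedges,
# 2 mm spacing) and a short bench-style heating pulse. All fixtures are built
# in code; nothing is read from disk except the shipped species table.

small_setup <- function(n_wedges = 8L, radial_spacing = 0.002,
                        diameter_mm = 80, bark_thickness_mm = 4) {
  section_setup("Pinus strobus", n_wedges = n_wedges,
                radial_spacing = radial_spacing,
                diameter_mm = diameter_mm,
                bark_thickness_mm = bark_thickness_mm)
}

small_pulse <- function(peak = 2e4, ramp = 60, hold = 240, cool = 300,
                        T_ambient = 295) {
  synthetic_lab_pulse(peak, ramp, hold, cool, T_ambient = T_ambient)
}

# constant properties used by the analytic solver benchmarks
const_props <- list(k = 0.2, rho = 500, cp = 2000)

dummy_params <- function() species_params(500, 0.5)

# copy a species_params object with fields changed
within_params <- function(p, ...) {
  mods <- list(...)
  for (nm in names(mods)) p[[nm]] <- mods[[nm]]
  p
}
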