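# Fixtures built in code; nothing binary ships with the package.

# Hand-checkable TAC: mid-times 5..30 s at 5 s spacing, one steep downslope.
worked_tac <- function() {
  sch <- frame_schedule(seq(2.5, 27.5, by = 5), rep(5, 6))
  tac(c(5, 10, 15, 20, 25, 30), c(0, 100, 60, 40, 34, 30), sch)
}

# Small two-population phantom: disjoint voxel blocks carrying gamma-variate
# TACs peaking at 10 s and 18 s (alpha = 3, beta = 2.5 -> arrivals 2.5 and
# 10.5 s), no myocardium. Small grid keeps tests fast.
two_pop_config <- function(noise = 0, seed = 1L) {
  geom <- list(arterial = list(center_frac = c(0.70, 0.5), radius_mm = 9,
                               z_margin_frac = 0.2),
               venous = list(center_frac = c(0.30, 0.5), radius_mm = 9,
                             z_margin_frac = 0.2),
               myocardium = NULL)
  phantom_config(fsv_true = 80, heart_rate = 60,
                 venous_delay_s = 2.5, arterial_delay_s = 10.5,
                 recirculation_fraction = 0,
                 noise_sd_fraction = noise, seed = seed,
                 grid_shape = c(24, 24, 12), spacing_mm = 3,
                 geometry = geom)
}

dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# Default-world phantom on a reduced grid (runtime); physical geometry in mm
# is unchanged.
small_phantom_config <- function(...) {
  phantom_config(grid_shape = c(48, 48, 24), ...)
}
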