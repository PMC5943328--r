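# shared fixtures: unit-cube domains and simple analytic fields

unit_domain <- function(res) domain(c(0, 0, 0), c(1, 1, 1), res)

# signed sphere field |r - c| - R on the unit cube
sphere_field <- function(R = 0.3, center = c(0.5, 0.5, 0.5)) {
  function(p) sqrt(rowSums(sweep(p, 2, center)^2)) - R
}

# linear ramp along x, zero at x0
ramp_field <- function(x0 = 0.5) function(p) p[, 1] - x0

all_presets <- c("P", "D", "G", "TGab", "TGc")
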