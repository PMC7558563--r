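# Shared fixtures, built in code.

# Representative ensembles from the packaged scenario registry.
fixture_nc4_ensemble <- function() clothing_ensemble(icl = 1.08, rt_static = 0.0421, imt = 0.37)
fixture_sc_ensemble <- function() clothing_ensemble(icl = 2.01, rt_static = 0.1224, imt = 0.20)
fixture_lc_ensemble <- function() clothing_ensemble(icl = 0.48, rt_static = 0.0198, imt = 0.49)

fixture_nc4_scenario <- function() chamber_scenarios()[["NC-4"]]
fixture_sc2_scenario <- function() chamber_scenarios()[["SC-2"]]

# The speed grid used for the algorithm comparisons; air speed doubles as
# the relative air velocity.
fixture_speed_grid <- function() expand.grid(va = c(0.5, 1, 3), vw = c(0.4, 0.8, 1.2))

# A quiet dynamic_clothing call (clamping messages silenced).
dyn_quiet <- function(ens, kin, algorithm, ...) {
  suppressMessages(dynamic_clothing(ens, kin, algorithm, ...))
}
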