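# Shared fixtures: the averaged parameter set, reactor configuration and a
# few canned states used across the suite.

mean_params <- function(...) kinetic_parameters(...)

# averaged parameters with osmolarity inhibition effectively disabled, as in
# the low-substrate estimation stage
params_no_osm <- function(...) {
  kinetic_parameters(OSM_crit = 1e3, R_LacF_OSM = 0, ...)
}

default_cfg <- function(...) reactor_config(...)

# quiet wrapper: the optimizer probes pathological parameter corners where
# the solver legitimately complains
quiet <- function(expr) suppressWarnings(suppressMessages(expr))
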