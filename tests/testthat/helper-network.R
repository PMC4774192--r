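# Shared fixtures, memoized so expensive objects are built once per test run.
.hf_cache <- new.env(parent = emptyenv())

hf_net <- function() {
  if (is.null(.hf_cache$net)) .hf_cache$net <- build_network()
  .hf_cache$net
}

# Canonical MCA states: fasted hypoglycemic (4 mM, low store) and fed
# hyperglycemic (10 mM, high store).
hf_clamps_fasted <- function() clamp_set(glucose = 4, glycogen = 0.1)
hf_clamps_fed <- function() clamp_set(glucose = 10, glycogen = 0.85)

hf_ss <- function(key, state, clamps) {
  if (is.null(.hf_cache[[key]]))
    .hf_cache[[key]] <- steady_state(hf_net(), state, clamps)
  .hf_cache[[key]]
}
hf_ss_fasted <- function() hf_ss("ss_fasted", "fasted", hf_clamps_fasted())
hf_ss_fed <- function() hf_ss("ss_fed", "fed", hf_clamps_fed())

hf_control_fasted <- function() {
  if (is.null(.hf_cache$ct_fasted))
    .hf_cache$ct_fasted <- control_coefficients(hf_net(), "fasted",
                                                hf_clamps_fasted())
  .hf_cache$ct_fasted
}
hf_control_fed <- function() {
  if (is.null(.hf_cache$ct_fed))
    .hf_cache$ct_fed <- control_coefficients(hf_net(), "fed",
                                             hf_clamps_fed())
  .hf_cache$ct_fed
}

hf_normal_reference <- function() {
  if (is.null(.hf_cache$ref)) .hf_cache$ref <- normal_reference(hf_net())
  .hf_cache$ref
}

# A tiny random positive concentration state around the defaults (dynamic
# species only; clamped pools stay at their fixed values).
hf_random_conc <- function(net, seed) {
  set.seed(seed)
  cc <- species_concentrations(net)
  dyn <- !net$species$clamped
  cc[dyn] <- cc[dyn] * stats::runif(sum(dyn), 0.5, 2)
  cc
}
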