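# F2-like parameter set used across tests
test_params <- function(...) {
  gdm_params(lci_t = 0.42, k_b22 = 29, c1 = 364, c1t_fraction = 0.61,
             c2 = 1238, c3 = 397, ...)
}

# named state vector matching the integrator layout
test_state <- function(params = test_params()) {
  c(time = 0,
    c1d = (1 - params$c1t_fraction) * params$c1,
    c1t = params$c1t_fraction * params$c1,
    c2 = params$c2, c3 = params$c3,
    b1 = params$b1, b2 = params$b2, b3 = params$b3,
    cum_co2 = 0, cum_released = 0, necromass = 0)
}

total_carbon <- function(state) {
  sum(state[c("c1d", "c1t", "c2", "c3", "b1", "b2", "b3",
              "cum_co2", "necromass")])
}
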