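# Hand-checkable 3-atom charge-state triple used across local-descriptor
# tests: f- = q(N-1) - q(N) = (0.5, 0.2, 0.3), f+ = q(N) - q(N+1) =
# (0.6, 0.2, 0.2), dual = (0.1, 0.0, -0.1).
toy_triple <- function() {
  els <- c("O", "C", "H")
  list(neutral = population_table(els, c(0.0, 0.2, -0.2), charge_state = 0L),
       cation  = population_table(els, c(0.5, 0.4, 0.1), charge_state = 1L,
                                  multiplicity_hint = 2L),
       anion   = population_table(els, c(-0.6, 0.0, -0.4), charge_state = -1L,
                                  multiplicity_hint = 2L))
}

# Published reference tables, embedded independently of the packaged JSON
# so fixture-bundle tests have a checksum to compare against.
reference_global <- function() {
  m <- rbind(
    Alaviroidin   = c(-6.072, -1.700, 4.372, 284, 3.886, 1.727, 5.670, 1.784, 7.454, 12.69),
    Deoxoviroidin = c(-5.929, -1.467, 4.462, 278, 3.698, 1.533, 5.193, 1.495, 6.688, 12.62),
    Deoxoviroisin = c(-5.681, -1.228, 4.453, 278, 3.454, 1.340, 4.685, 1.231, 5.916, 12.63),
    Viroidin      = c(-6.056, -1.622, 4.434, 280, 3.839, 1.662, 5.520, 1.682, 7.202, 12.64),
    Viroisin      = c(-5.888, -1.593, 4.295, 289, 3.740, 1.629, 5.396, 1.655, 7.051, 12.76))
  colnames(m) <- c("homo", "lumo", "gap", "lambda_max", "chi", "omega",
                   "omega_minus", "omega_plus", "net_electrophilicity", "pka")
  m
}
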