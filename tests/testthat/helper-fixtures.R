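# shared designs kept small so the default test run stays fast

# two-fold series 62.5-1000 nM (the cytokine/complement design)
nM_series <- function() 1000e-9 / 2^(4:0)

fast_design <- function(...) {
  assay_design(nM_series(), t_assoc = 1200, t_dissoc = 300,
               t_baseline = 10, sample_rate = 1, ...)
}

# a competition pair at a given overlap; ligand 1 saturating and
# non-dissociating unless overridden
competition_pair <- function(phi, koff1 = 0, conc1 = 10e-6,
                             conc2 = 500e-9, ...) {
  p1 <- kinetic_params(1e5, koff1, 1)
  p2 <- kinetic_params(1e5, 1e-3, 1)
  alone <- simulate_sequential(
    sequential_design(p1, p2, 0, conc2, phi, ligand1 = "L1", ligand2 = "L2"), ...)
  comp <- simulate_sequential(
    sequential_design(p1, p2, conc1, conc2, phi, ligand1 = "L1", ligand2 = "L2"), ...)
  list(alone = alone, competed = comp)
}
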