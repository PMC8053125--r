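# Shared fixtures: compact experiment designs that keep property tests fast
# while preserving the structure of the reference design.

small_sf_design <- function(n_points = 150L, duration_s = 2,
                            ligands = c(4, 12, 20)) {
  stopped_flow_design(ligand_concs_uM = ligands, duration_s = duration_s,
                      n_points = n_points, shots_per_concentration = 10L)
}

quiet_fit <- function(...) suppressWarnings(global_fit(...))

# linearized pseudo-first-order rate matrix of the two-step scheme in the
# reduced (I, B) coordinates, ligand clamped at L0; returns |eigenvalues|
two_step_pfo_eigenrates <- function(k1, k_m1, k2, k_m2, L0) {
  M <- matrix(c(-k1 * L0 - k_m1 - k2, -k1 * L0 + k_m2,
                k2, -k_m2), 2, 2, byrow = TRUE)
  sort(abs(eigen(M, only.values = TRUE)$values))
}
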