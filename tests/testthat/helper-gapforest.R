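# shared fixtures built in code

# a parameter table with simple hand-checkable allometry:
# h0 huge => h(d) ~ h1 for d > 0, so biomass is (pi/4) d^2 h1 f rho
toy_params <- function(h1 = 30, f = 0.25, rho = 0.6, n_pft = 2) {
  p <- pft_parameters()[seq_len(n_pft), ]
  p$h0 <- 1e9
  p$h1 <- h1
  p$form_factor <- f
  p$rho <- rho
  p$d_max <- 10  # far away so the cap plays no role
  p
}

# parameters with all stochastic processes switched off
quiet_params <- function() {
  p <- pft_parameters()
  p$m_base <- 0
  p$ms0 <- 0
  p$msen <- 0
  p$m_stress <- 0
  p$p_fall <- 0
  p$n_seed <- 0
  p
}

# a minimal trees tibble for light/demography tests
make_trees <- function(crown_top, crown_base, leaf_area, patch = 1L) {
  tibble::tibble(crown_top = crown_top, crown_base = crown_base,
                 leaf_area = leaf_area, patch = patch)
}
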