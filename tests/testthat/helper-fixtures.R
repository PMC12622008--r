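# Shared fixtures, generated once per test run.

.fixtures <- new.env(parent = emptyenv())

# compact three-TLS tissue used across geometry and axis tests
small_tissue <- function() {
  if (is.null(.fixtures$small)) {
    cfg <- sim_config(field_width = 2000, field_height = 2000,
                      n_tls = 3, tls_radius_mean = 120, tls_radius_sd = 10,
                      n_bronchi = 1, n_vessels = 1,
                      densities = c(tls = 50, bronchi = 40, vessel = 30,
                                    capsule = 20, parenchyma = 3),
                      structure_gap = 150, seed = 42L)
    .fixtures$small <- generate_tissue(cfg)
  }
  .fixtures$small
}

# CD4-rich tissue matching the gradient-recovery study conditions
# (a = 20, lambda = 100 um, b = 1, Poisson counts)
gradient_tissue <- function() {
  if (is.null(.fixtures$gradient)) {
    mx <- tlsniche::default_mixtures()
    mx$parenchyma <- c(B = 0, CD4_Th0 = 0.30, CD4_Th2 = 0.30,
                       CD4_other = 0.10, epithelial_bronchus = 0,
                       mesothelial = 0, macrophage = 0.12, cDC2 = 0.05,
                       endothelial = 0, other = 0.13)
    cfg <- sim_config(field_width = 3500, field_height = 3500,
                      n_tls = 3, n_bronchi = 2, n_vessels = 2,
                      densities = c(tls = 60, bronchi = 40, vessel = 30,
                                    capsule = 20, parenchyma = 7),
                      mixtures = mx,
                      gradient_amplitude = 20, gradient_scale = 100,
                      gradient_baseline = 1, dispersion = Inf,
                      seed = 101L)
    .fixtures$gradient <- generate_tissue(cfg)
  }
  .fixtures$gradient
}
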