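# Shared fixtures: a small reconstruction grid keeps phantom tests cheap
# while preserving the clinical timing and RF schedule.
small_geometry <- function(n_coils = 4L, n_slices = 1L, recon = 32L) {
  acq_geometry(recon_matrix = recon, acq_matrix = recon, n_slices = n_slices,
               n_coils = n_coils, excitations_per_frame = 5L)
}

default_bolus <- function() gamma_variate_bolus()

# Noiseless course pair at given parameters (pure continuous model unless
# depletion is requested).
noiseless_courses <- function(k_pl, t1_eff = 30, geometry = acq_geometry(),
                              rf_depletion = FALSE) {
  simulate_two_site_exchange(kinetic_params(k_pl, t1_eff), default_bolus(),
                             geometry, rf_depletion = rf_depletion)
}
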