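# shared small fixtures, rebuilt per test run

ointment_space <- ointment_factors()
study_models <- ointment_models()
study_limits <- spec_limits()

# the study's reported optimal settings and printed predictions
printed_optimum <- optimal_settings()
printed_predictions <- c(yield_stress = 44.98, high_shear_visc = 5.32,
                         low_shear_visc = 14608, storage_modulus = 530.7)

# a small continuous-only space used by generic design tests
small_space <- function(m) {
  factor_space(lapply(seq_len(m), function(j)
    qbd_factor(paste0("x", j), low = -10, high = 10)))
}
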