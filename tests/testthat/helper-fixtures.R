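# Shared fixtures: small, fast objects built in code.

default_seq <- tracking_seq()
default_tl <- tracking_times(default_seq)
default_ac <- acoustics_spec()
no_atten <- acoustics_spec(attenuation_db_cm_mhz = 0)

# A small study-scale phantom spec (256 x 40 grid over 40 x 20 mm).
small_phantom_spec <- function(...) {
  args <- list(grid_shape = c(256, 40), axial_spacing = 40 / 256,
               background_E = 5, background_mu = 2,
               lesion_center = c(9.75, 20), lesion_axes = c(6, 4),
               lesion_E = 10, lesion_mu = 4, heterogeneity_cv = 0,
               seed = 1)
  args[names(list(...))] <- list(...)
  do.call(phantom_spec, args)
}

# Analytic double-push profile for a material point under unit forcing.
voigt_profile_for <- function(E, mu, amplitude = 1, seq = default_seq) {
  voigt_response(material_point(E, mu), force_schedule(seq, amplitude),
                 tracking_times(seq)$sample_times_s)
}

# True relative parameters implied by the forward model, for comparing
# against fit_visr output.
true_relative_params <- function(E, mu, amplitude = 1) {
  A <- visreb:::visr_force_scale * amplitude / (E * 1000)
  re <- 1 / A
  tau_ms <- mu / E
  list(re = re, rv = tau_ms * re, tau_ms = tau_ms)
}

# Band-limited subsample shift of a trace (FFT phase ramp); oracle for
# subsample displacement recovery.
shift_trace <- function(x, shift_samples) {
  n <- length(x)
  f <- c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1) / n
  if (n %% 2 == 0) f[n / 2 + 1] <- 0  # drop ambiguous Nyquist phase
  Re(stats::fft(stats::fft(x) * exp(-2i * pi * f * shift_samples),
                inverse = TRUE) / n)
}
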