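#' Acoustic parameters for RF synthesis and tracking
#'
#' @param track_freq tracking-pulse center frequency in MHz.
#' @param track_cycles tracking-pulse length in carrier cycles.
#' @param sampling_freq RF sampling frequency in MHz (must exceed twice
#'   the tracking frequency).
#' @param sound_speed speed of sound in m/s.
#' @param rf_noise_db additive white-noise RF SNR in dB.
#' @param attenuation_db_cm_mhz frequency-dependent attenuation driving
#'   the push amplitude-versus-depth profile.
#' @param focal_depth_mm nominal push focal depth (reference depth for
#'   the calibration curves).
#' @return An object of class `visr_acoustics`.
#' @export
acoustics_spec <- function(track_freq = 6.15, track_cycles = 2,
                           sampling_freq = 40, sound_speed = 1540,
                           rf_noise_db = 30, attenuation_db_cm_mhz = 0.5,
                           focal_depth_mm = 20) {
  stopifnot(sampling_freq > 2 * track_freq, sound_speed > 0,
            track_cycles >= 1, attenuation_db_cm_mhz >= 0)
  structure(list(track_freq = track_freq, track_cycles = track_cycles,
                 sampling_freq = sampling_freq, sound_speed = sound_speed,
                 rf_noise_db = rf_noise_db,
                 attenuation_db_cm_mhz = attenuation_db_cm_mhz,
                 focal_depth_mm = focal_depth_mm),
            class = "visr_acoustics")
}

#' Push amplitude versus depth
#'
#' Relative radiation-force amplitude at depth `z`, following one-way
#' intensity attenuation of the push beam:
#' `10^(-attenuation * f_push * z_cm / 10)`.
#'
#' @param ac an [acoustics_spec()].
#' @param z_mm depths in mm.
#' @param push_freq_mhz push carrier frequency in MHz.
#' @return Dimensionless amplitudes in (0, 1].
#' @export
depth_amplitude <- function(ac, z_mm, push_freq_mhz = 4.21) {
  10^(-(ac$attenuation_db_cm_mhz * push_freq_mhz * z_mm / 10) / 10)
}

# RF axial sample spacing in mm (round-trip convention).
rf_sample_mm <- function(ac) ac$sound_speed / (2 * ac$sampling_freq * 1e6) * 1e3

# Gaussian-windowed tone pulse evaluated at depth offsets u (mm).
rf_pulse <- function(u_mm, ac) {
  lambda <- ac$sound_speed / (ac$track_freq * 1e6) * 1e3  # mm
  sigma <- (ac$track_cycles * lambda / 2) / 2.355         # FWHM = pulse len
  exp(-u_mm^2 / (2 * sigma^2)) * cos(2 * pi * (2 / lambda) * u_mm)
}

# Render one RF trace from displaced scatterers by windowed deposition.
render_trace <- function(z_grid_mm, scat_z_mm, refl, ac) {
  dz <- z_grid_mm[2] - z_grid_mm[1]
  lambda <- ac$sound_speed / (ac$track_freq * 1e6) * 1e3
  sigma <- (ac$track_cycles * lambda / 2) / 2.355
  w <- ceiling(4 * sigma / dz)
  center <- round((scat_z_mm - z_grid_mm[1]) / dz) + 1
  offs <- -w:w
  idx <- outer(center, offs, "+")
  u <- z_grid_mm[1] + (idx - 1) * dz - scat_z_mm   # recycled by column
  vals <- refl * rf_pulse(u, ac)
  keep <- idx >= 1 & idx <= length(z_grid_mm)
  tr <- numeric(length(z_grid_mm))
  acc <- rowsum(as.vector(vals[keep]), group = as.vector(idx[keep]))
  tr[as.integer(rownames(acc))] <- acc[, 1]
  tr
}

#' Synthesize RF speckle for a double-push acquisition
#'
#' For each lateral line, convolves a Gaussian-windowed tone with the
#' phantom's point scatterers to produce a reference RF trace and one
#' trace per tracking sample time.  At each tracking time the scatterers
#' are displaced axially by the local closed-form Voigt response to that
#' line's pushes, with the push amplitude scaled by the depth-attenuation
#' profile.  White noise is added at `rf_noise_db` SNR.  Deterministic
#' for a fixed seed.
#'
#' @param phantom a [make_phantom()] result.
#' @param seq a [tracking_seq()].
#' @param ac an [acoustics_spec()].
#' @param seed integer seed for the additive noise.
#' @param lines indices of lateral lines to synthesize (default all).
#' @return An object of class `visr_rf`: per-line reference trace and
#'   tracking-trace matrix, plus geometry and the tracking timeline.
#' @export
synth_rf <- function(phantom, seq = tracking_seq(), ac = acoustics_spec(),
                     seed = 1, lines = NULL) {
  stopifnot(inherits(phantom, "visr_phantom"))
  tl <- tracking_times(seq)
  track_idx <- which(!tl$is_reference)
  track_times <- tl$sample_times_s[track_idx]
  dz <- rf_sample_mm(ac)
  depth_extent <- max(phantom$axial_mm)
  z_grid <- seq(0, depth_extent, by = dz)
  lines <- lines %||% seq_along(phantom$lateral_mm)
  sched0 <- force_schedule(seq, 1)
  noise_seed <- derive_seed(seed, "rfnoise")
  out_lines <- lapply(lines, function(j) {
    sc <- phantom$scatterers[[j]]
    # material at each scatterer from the nearest grid pixel
    row <- pmin(pmax(round(sc$axial_mm / phantom$spec$axial_spacing) + 1, 1),
                nrow(phantom$E_map))
    E <- phantom$E_map[cbind(row, j)]
    mu <- phantom$mu_map[cbind(row, j)]
    amp <- depth_amplitude(ac, sc$axial_mm, seq$push_freq)
    tau_s <- (mu / E) * 1e-3
    A <- visr_force_scale * amp / (E * 1000)
    # microns -> mm displacement of every scatterer at every tracking time
    disp_um <- voigt_profile_matrix(tau_s, A, track_times,
                                    tl$push_onsets_s, tl$push_dur_s)
    ref <- render_trace(z_grid, sc$axial_mm, sc$reflectivity, ac)
    tracks <- vapply(seq_along(track_times), function(k) {
      render_trace(z_grid, sc$axial_mm + disp_um[, k] * 1e-3,
                   sc$reflectivity, ac)
    }, numeric(length(z_grid)))
    list(ref = ref, tracks = tracks)
  })
  # additive white noise at the requested SNR, seeded once for the frame
  if (is.finite(ac$rf_noise_db)) {
    out_lines <- with_seed(noise_seed, {
      lapply(out_lines, function(ln) {
        p_sig <- mean(ln$ref^2)
        sd_n <- sqrt(p_sig / 10^(ac$rf_noise_db / 10))
        ln$ref <- ln$ref + stats::rnorm(length(ln$ref), sd = sd_n)
        ln$tracks <- ln$tracks +
          matrix(stats::rnorm(length(ln$tracks), sd = sd_n),
                 nrow(ln$tracks), ncol(ln$tracks))
        ln
      })
    })
  }
  structure(list(lines = out_lines, line_index = lines,
                 z_mm = z_grid, sample_mm = dz,
                 track_times_s = track_times, seq = seq, ac = ac),
            class = "visr_rf")
}

#' Speckle-tracking kernel settings
#'
#' @param kernel_length_mm correlation-kernel length in mm; default 4
#'   tracking wavelengths (~1 mm).  Shorter kernels (1.5 wavelengths)
#'   track sharper axial gradients but suffer displacement dropouts at
#'   speckle-amplitude nulls, losing a few percent of pixels to
#'   non-convergence.
#' @param search search range in RF samples around zero lag.
#' @param overlap fractional overlap between consecutive depth kernels.
#' @param ac an [acoustics_spec()] used to resolve the default kernel
#'   length.
#' @return An object of class `visr_kernel`.
#' @export
kernel_spec <- function(kernel_length_mm = NULL, search = 8, overlap = 0.5,
                        ac = acoustics_spec()) {
  if (is.null(kernel_length_mm)) {
    lambda <- ac$sound_speed / (ac$track_freq * 1e6) * 1e3
    kernel_length_mm <- 4 * lambda
  }
  stopifnot(kernel_length_mm > 0, search >= 1, overlap >= 0, overlap < 1)
  structure(list(kernel_length_mm = kernel_length_mm, search = search,
                 overlap = overlap), class = "visr_kernel")
}

# Normalized cross-correlation of one reference trace against one
# displaced trace for all depth kernels and integer lags at once.
# Returns ncc matrix (n_kernels x n_lags).
ncc_all_kernels <- function(ref, trk, starts, klen, lags) {
  n <- length(ref)
  roll <- function(v, len) {
    cs <- c(0, cumsum(v))
    cs[starts + len] - cs[starts]
  }
  ref_seg <- matrix(0, length(starts), length(lags))
  ss_ref <- roll(ref * ref, klen)
  out <- matrix(NA_real_, length(starts), length(lags))
  for (li in seq_along(lags)) {
    l <- lags[li]
    trk_s <- if (l >= 0) c(trk[(1 + l):n], rep(0, l)) else
      c(rep(0, -l), trk[1:(n + l)])
    num <- roll(ref * trk_s, klen)
    ss_trk <- roll(trk_s * trk_s, klen)
    out[, li] <- num / sqrt(pmax(ss_ref * ss_trk, .Machine$double.eps))
  }
  out
}

#' Track axial displacement by normalized cross-correlation
#'
#' For each depth kernel and tracking time, finds the integer lag
#' maximizing the normalized cross-correlation between the reference and
#' the tracking trace, refines it by parabolic interpolation of the
#' correlation peak (ties broken toward the smaller absolute lag), and
#' converts lags to microns via `sound_speed / (2 * sampling_freq)`.
#'
#' @param rf a [synth_rf()] result.
#' @param k a [kernel_spec()].
#' @return An object of class `visr_track`: per line, a displacement
#'   matrix (`n_kernels x n_tracking_times`, microns), the corresponding
#'   correlation-coefficient matrix, and the kernel center depths in mm.
#' @export
ncc_track <- function(rf, k = kernel_spec(ac = rf$ac)) {
  stopifnot(inherits(rf, "visr_rf"))
  dz <- rf$sample_mm
  klen <- max(3L, round(k$kernel_length_mm / dz))
  n <- length(rf$z_mm)
  step <- max(1L, round(klen * (1 - k$overlap)))
  lags <- -k$search:k$search
  if (1 + k$search > n - klen + 1 - k$search) {
    stop("search window exceeds trace bounds: kernel of ", klen,
         " samples with search +/-", k$search,
         " does not fit a trace of ", n, " samples")
  }
  starts <- seq(1 + k$search, n - klen + 1 - k$search, by = step)
  centers_mm <- rf$z_mm[starts] + (klen - 1) / 2 * dz
  lag_order <- order(abs(lags))          # tie-break toward |lag| small
  res <- lapply(rf$lines, function(ln) {
    nt <- ncol(ln$tracks)
    disp <- matrix(0, length(starts), nt)
    ccm <- matrix(0, length(starts), nt)
    for (ti in seq_len(nt)) {
      ncc <- ncc_all_kernels(ln$ref, ln$tracks[, ti], starts, klen, lags)
      best_rel <- apply(ncc[, lag_order, drop = FALSE], 1, which.max)
      best <- lag_order[best_rel]
      cmax <- ncc[cbind(seq_along(best), best)]
      lm <- pmax(best - 1, 1); lp <- pmin(best + 1, length(lags))
      cm <- ncc[cbind(seq_along(best), lm)]
      cp <- ncc[cbind(seq_along(best), lp)]
      denom <- cm - 2 * cmax + cp
      delta <- ifelse(abs(denom) > 1e-300, 0.5 * (cm - cp) / denom, 0)
      delta[best == 1 | best == length(lags)] <- 0
      # a perfect correlation peak is an exact integer lag; the
      # neighbouring normalizations would otherwise skew the parabola
      delta[cmax >= 1 - 1e-12] <- 0
      delta <- pmin(pmax(delta, -1), 1)
      disp[, ti] <- (lags[best] + delta) * dz * 1e3   # microns
      ccm[, ti] <- cmax
    }
    list(disp_um = disp, cc = ccm)
  })
  structure(list(lines = res, line_index = rf$line_index,
                 kernel_centers_mm = centers_mm,
                 track_times_s = rf$track_times_s, seq = rf$seq, ac = rf$ac),
            class = "visr_track")
}

#' Envelope of an RF trace
#'
#' Magnitude of the analytic signal (one-sided spectrum), used for
#' B-mode rendering and speckle statistics.
#'
#' @param x real RF trace.
#' @return Envelope of `x`.
#' @export
rf_envelope <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(X * h, inverse = TRUE) / n)
}
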