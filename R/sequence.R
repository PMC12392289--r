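#' Double-push ARFI tracking sequence
#'
#' Describes the timing of a double-push acoustic radiation force impulse
#' (ARFI) acquisition: two reference pulses, a first push, a block of
#' tracking pulses, a second push, and a final block of tracking pulses.
#' Every event (reference, push, or tracking pulse) occupies one slot of
#' the pulse repetition clock, so the slot width is `1 / track_prf`.
#'
#' @param n_ref number of reference pulses before the first push.
#' @param push_cycles number of carrier cycles per ARFI excitation.
#' @param push_freq push carrier frequency in MHz.
#' @param track_prf pulse repetition frequency in kHz.
#' @param n_track_between tracking pulses between the two pushes.
#' @param n_track_after tracking pulses after the second push.
#' @param n_lines lateral lines per frame.
#' @param fov lateral field of view in cm.
#'
#' @return An object of class `visr_seq`.
#' @export
#' @examples
#' seq <- tracking_seq()
#' tracking_times(seq)$slot_s * 1e6   # slot width in microseconds
tracking_seq <- function(n_ref = 2, push_cycles = 300, push_freq = 4.21,
                         track_prf = 11.5, n_track_between = 8,
                         n_track_after = 43, n_lines = 40, fov = 2) {
  stopifnot(n_ref >= 1, push_cycles >= 1, push_freq > 0, track_prf > 0,
            n_track_between >= 1, n_track_after >= 1, n_lines >= 1, fov > 0)
  slot_s <- 1 / (track_prf * 1e3)
  push_dur_s <- push_cycles / (push_freq * 1e6)
  if (push_dur_s >= slot_s) {
    stop("push duration (", signif(push_dur_s * 1e6, 4),
         " us) must be shorter than one PRF slot (",
         signif(slot_s * 1e6, 4), " us)")
  }
  structure(list(n_ref = n_ref, push_cycles = push_cycles,
                 push_freq = push_freq, track_prf = track_prf,
                 n_track_between = n_track_between,
                 n_track_after = n_track_after,
                 n_lines = n_lines, fov = fov,
                 slot_s = slot_s, push_dur_s = push_dur_s),
            class = "visr_seq")
}

#' Event timeline of a tracking sequence
#'
#' Lays the sequence events out on consecutive PRF slots, in the order
#' reference pulses, first push, inter-push tracking pulses, second push,
#' post-push tracking pulses.  Each event time is the start of its slot.
#' Sample times are the reference and tracking slots; displacement is
#' referenced to the last reference sample, so pushes contribute no
#' samples themselves.
#'
#' @param seq a [tracking_seq()] object.
#' @return A list with `push_onsets_s` (length 2), `sample_times_s`,
#'   `is_reference` (logical, which samples are reference slots),
#'   `slot_s` and `push_dur_s`.
#' @export
tracking_times <- function(seq) {
  stopifnot(inherits(seq, "visr_seq"))
  slots_ref <- seq_len(seq$n_ref) - 1
  slot_push1 <- seq$n_ref
  slots_mid <- slot_push1 + seq_len(seq$n_track_between)
  slot_push2 <- slot_push1 + seq$n_track_between + 1
  slots_after <- slot_push2 + seq_len(seq$n_track_after)
  sample_slots <- c(slots_ref, slots_mid, slots_after)
  list(push_onsets_s = c(slot_push1, slot_push2) * seq$slot_s,
       sample_times_s = sample_slots * seq$slot_s,
       is_reference = sample_slots < slot_push1,
       slot_s = seq$slot_s,
       push_dur_s = seq$push_dur_s)
}

#' Radiation-force schedule
#'
#' Converts a tracking sequence into the boxcar forcing intervals used by
#' the forward models: one interval per push, each with the push duration
#' and a relative (dimensionless) amplitude.  The amplitude carries any
#' depth-dependent push-intensity factor.
#'
#' @param seq a [tracking_seq()] object.
#' @param amplitude relative force amplitude applied to both pushes, or a
#'   vector of one amplitude per push.
#' @return A data frame with columns `onset_s`, `duration_s`, `amplitude`.
#' @export
force_schedule <- function(seq, amplitude = 1) {
  tl <- tracking_times(seq)
  amp <- rep_len(amplitude, 2)
  stopifnot(all(amp > 0))
  sched <- data.frame(onset_s = tl$push_onsets_s,
                      duration_s = rep(tl$push_dur_s, 2),
                      amplitude = amp)
  class(sched) <- c("visr_schedule", class(sched))
  sched
}

#' Viscoelastic material point
#'
#' A Voigt material point: spring (elasticity `E`) and damper (viscosity
#' `mu`) in parallel, with relaxation time `tau = mu / E`.  With `E` in
#' kPa and `mu` in Pa.s, `tau` is in ms.
#'
#' @param E elasticity in kPa (> 0).
#' @param mu viscosity in Pa.s (>= 0).
#' @return An object of class `visr_material`.
#' @export
material_point <- function(E, mu) {
  stopifnot(E > 0, mu >= 0)
  structure(list(E = E, mu = mu, tau_ms = mu / E), class = "visr_material")
}

# Force-to-displacement scale: displacement amplitude A (micron) of a unit
# relative force held forever is visr_force_scale * amplitude / E_Pa.
# The value is an arbitrary simulation constant chosen so that typical
# soft-tissue parameters yield peak displacements of a few microns.
visr_force_scale <- 1e5

# Closed-form Voigt response to a set of boxcar pushes, vectorized over a
# (pixel x time) layout: tau_s and A are per-pixel vectors, times_s a
# vector; returns a length(tau_s) x length(times_s) matrix in microns.
# Samples are assumed never to fall inside a push (pushes occupy their own
# PRF slots), so only the rise-complete decay branch is evaluated; the
# tau -> 0 limit is the step response.
voigt_profile_matrix <- function(tau_s, A, times_s, onsets_s, push_dur_s) {
  np <- length(tau_s); nt <- length(times_s)
  out <- matrix(0, np, nt)
  inv_tau <- ifelse(tau_s > 0, 1 / tau_s, Inf)
  rise <- ifelse(tau_s > 0, 1 - exp(-push_dur_s * inv_tau), 1)
  for (on in onsets_s) {
    dt <- times_s - on - push_dur_s
    post <- dt >= 0
    if (any(post)) {
      # outer(inv_tau, dt[post]) can be large; exp(-Inf * 0) guarded above
      dec <- exp(-outer(inv_tau, dt[post]))
      dec[!is.finite(inv_tau), ] <- ifelse(dt[post] > 0, 0, 1)
      out[, post] <- out[, post] + (A * rise) * dec
    }
  }
  out
}

#' Closed-form Voigt displacement response
#'
#' Displacement of a Voigt material point under a schedule of boxcar
#' radiation-force pushes, by superposition of single-push responses.
#' A unit-amplitude push of duration `Tp` starting at `t0` contributes
#' `A * (1 - exp(-(t - t0)/tau))` during the push and
#' `A * (1 - exp(-Tp/tau)) * exp(-(t - t0 - Tp)/tau)` afterwards, with
#' `A = visr_force_scale * amplitude / E` (E in Pa) in microns and
#' `tau = mu / E`.  The `tau = 0` limit is a step to `A` during the push
#' and zero after.
#'
#' @param m a [material_point()].
#' @param schedule a [force_schedule()] data frame.
#' @param times_s sample times in seconds.
#' @return A `visr_profile` object: data frame with `time_s` and
#'   `disp_um`.
#' @export
voigt_response <- function(m, schedule, times_s) {
  stopifnot(inherits(m, "visr_material"), is.numeric(times_s))
  tau_s <- m$tau_ms * 1e-3
  disp <- numeric(length(times_s))
  for (k in seq_len(nrow(schedule))) {
    on <- schedule$onset_s[k]; Tp <- schedule$duration_s[k]
    A <- visr_force_scale * schedule$amplitude[k] / (m$E * 1000)
    if (A == 0) next
    dt <- times_s - on
    during <- dt >= 0 & dt < Tp
    post <- dt >= Tp
    if (tau_s > 0) {
      disp[during] <- disp[during] + A * (1 - exp(-dt[during] / tau_s))
      disp[post] <- disp[post] +
        A * (1 - exp(-Tp / tau_s)) * exp(-(dt[post] - Tp) / tau_s)
    } else {
      disp[during] <- disp[during] + A
    }
  }
  displacement_profile(times_s, disp)
}

#' Sampled displacement profile
#'
#' @param times_s strictly increasing sample times in seconds.
#' @param disp_um axial displacement in microns.
#' @return A `visr_profile` data frame.
#' @export
displacement_profile <- function(times_s, disp_um) {
  stopifnot(length(times_s) == length(disp_um),
            all(diff(times_s) > 0), times_s[1] >= 0)
  structure(data.frame(time_s = times_s, disp_um = disp_um),
            class = c("visr_profile", "data.frame"))
}

#' Numerically integrated mass-spring-damper response
#'
#' Integrates `mass * x'' + mu * x' + E * x = F(t)` with boxcar forcing,
#' as an independent oracle for the closed-form Voigt response (the
#' `mass = 0` case) and for inspecting inertial effects.  Integration is
#' piecewise between forcing discontinuities with tight tolerances.
#'
#' @param m a [material_point()].
#' @param mass inertial term in arbitrary units (Pa.s^2); `0` recovers the
#'   first-order Voigt equation.
#' @param schedule a [force_schedule()].
#' @param times_s output sample times in seconds.
#' @param rtol,atol integration tolerances.
#' @return A `visr_profile` object.
#' @export
msd_response_numeric <- function(m, mass, schedule, times_s,
                                 rtol = 1e-11, atol = 1e-13) {
  stopifnot(inherits(m, "visr_material"), mass >= 0)
  k <- m$E * 1000                        # Pa
  cc <- m$mu                             # Pa.s
  force_at <- function(t) {
    f <- 0
    for (j in seq_len(nrow(schedule))) {
      if (t >= schedule$onset_s[j] &&
          t < schedule$onset_s[j] + schedule$duration_s[j]) {
        f <- f + visr_force_scale * schedule$amplitude[j]
      }
    }
    f
  }
  breaks <- sort(unique(c(0, schedule$onset_s,
                          schedule$onset_s + schedule$duration_s,
                          times_s)))
  if (mass == 0 && cc == 0) {
    disp <- vapply(times_s, function(t) force_at(t) / k, numeric(1))
    return(displacement_profile(times_s, disp))
  }
  state <- if (mass == 0) c(x = 0) else c(x = 0, v = 0)
  out_disp <- numeric(length(times_s))
  t_now <- 0
  # record t = 0 if requested
  hit <- which(abs(times_s - 0) < 1e-15)
  if (length(hit)) out_disp[hit] <- state[["x"]]
  for (i in seq_len(length(breaks) - 1)) {
    t0 <- breaks[i]; t1 <- breaks[i + 1]
    if (t1 <= t_now) next
    f <- force_at((t0 + t1) / 2)
    deriv <- if (mass == 0) {
      function(t, y, p) list((f - k * y[1]) / cc)
    } else {
      function(t, y, p) list(c(y[2], (f - cc * y[2] - k * y[1]) / mass))
    }
    sol <- deSolve::lsoda(y = state, times = c(t0, t1), func = deriv,
                          rtol = rtol, atol = atol, maxsteps = 1e5)
    if (attr(sol, "istate")[1] < 0) {
      stop("stiff integration failure at E=", m$E, " kPa, mu=", m$mu,
           " Pa.s, mass=", mass)
    }
    state <- sol[nrow(sol), -1]
    names(state) <- if (mass == 0) "x" else c("x", "v")
    hit <- which(abs(times_s - t1) < 1e-15)
    if (length(hit)) out_disp[hit] <- state[["x"]]
    t_now <- t1
  }
  displacement_profile(times_s, out_disp)
}

#' Peak displacement of a profile
#'
#' The maximum of the sampled displacement profile over time; the ARFI
#' peak-displacement (PD) parameter.
#'
#' @param profile a `visr_profile`.
#' @return Peak displacement in microns.
#' @export
peak_displacement <- function(profile) {
  stopifnot(nrow(profile) > 0)
  max(profile$disp_um)
}

#' Fit settings for the Voigt double-push model
#'
#' @param tau_min_s,tau_max_s relaxation-time bounds for the fit.
#' @param n_tau number of coarse log-spaced relaxation times scanned
#'   before local refinement.
#' @param resid_frac convergence threshold: the fit is flagged converged
#'   when the residual RMS is below `resid_frac` times the profile's peak
#'   displacement.
#' @return A list of fit settings.
#' @export
visr_fit_config <- function(tau_min_s = 1e-6, tau_max_s = 50e-3,
                            n_tau = 48, resid_frac = 0.2) {
  stopifnot(tau_min_s > 0, tau_max_s > tau_min_s, n_tau >= 8,
            resid_frac > 0)
  list(tau_min_s = tau_min_s, tau_max_s = tau_max_s, n_tau = n_tau,
       resid_frac = resid_frac)
}

# Unit-amplitude double-push model shape at the sequence sample times for
# a vector of candidate relaxation times: ntau x ntimes matrix.
visr_shape_matrix <- function(tau_s, seq) {
  tl <- tracking_times(seq)
  voigt_profile_matrix(tau_s, rep(1, length(tau_s)), tl$sample_times_s,
                       tl$push_onsets_s, tl$push_dur_s)
}

#' Fit the Voigt double-push model to a displacement profile
#'
#' Two-parameter nonlinear least squares of the closed-form double-push
#' Voigt response against a sampled displacement profile.  The model is
#' linear in the displacement amplitude `A` given the relaxation time
#' `tau`, so the fit is solved by variable projection: the profile is
#' projected onto the unit-amplitude model shape and the residual is
#' minimized over `log(tau)` (coarse scan plus Brent refinement).
#'
#' Reported parameters follow the relative-force convention: relative
#' elasticity `RE = 1/A` (stiffness per unit applied force) and relative
#' viscosity `RV = tau * RE` with `tau` in ms, so `tau = RV / RE` exactly.
#'
#' @param profile a `visr_profile` sampled on the sequence timeline.
#' @param seq the [tracking_seq()] the profile was acquired with.
#' @param cfg fit settings from [visr_fit_config()].
#' @return An object of class `visr_fit`: list with `re`, `rv`, `tau_ms`,
#'   `pd`, `residual_rms`, `converged`, `amplitude`.
#' @export
fit_visr <- function(profile, seq, cfg = visr_fit_config()) {
  tl <- tracking_times(seq)
  if (nrow(profile) != length(tl$sample_times_s) ||
      max(abs(profile$time_s - tl$sample_times_s)) > tl$slot_s / 2) {
    stop("profile is not sampled on the sequence timeline (expected ",
         length(tl$sample_times_s), " samples)")
  }
  y <- profile$disp_um
  pd <- max(y)
  ltau <- seq(log(cfg$tau_min_s), log(cfg$tau_max_s),
              length.out = cfg$n_tau)
  rss_of <- function(lt) {
    s <- drop(visr_shape_matrix(exp(lt), seq))
    ss <- sum(s * s)
    if (ss == 0) return(sum(y * y))
    a <- sum(y * s) / ss
    sum((y - a * s)^2)
  }
  rss_grid <- vapply(ltau, rss_of, numeric(1))
  k <- which.min(rss_grid)
  lo <- ltau[max(k - 1, 1)]; hi <- ltau[min(k + 1, length(ltau))]
  opt <- stats::optimize(rss_of, c(lo, hi), tol = 1e-10)
  tau_s <- exp(opt$minimum)
  s <- drop(visr_shape_matrix(tau_s, seq))
  a <- sum(y * s) / sum(s * s)
  resid <- sqrt(mean((y - a * s)^2))
  converged <- is.finite(a) && a > 0 && pd > 0 && resid < cfg$resid_frac * pd
  re <- if (is.finite(a) && a > 0) 1 / a else NA_real_
  tau_ms <- tau_s * 1e3
  structure(list(re = re, rv = if (is.na(re)) NA_real_ else tau_ms * re,
                 tau_ms = tau_ms, pd = pd, residual_rms = resid,
                 converged = converged, amplitude = a),
            class = "visr_fit")
}

#' Vectorized Voigt fit for many profiles at once
#'
#' Same variable-projection objective as [fit_visr()], applied to an
#' `(n_profiles x n_samples)` matrix of displacement profiles on the
#' sequence timeline: the coarse relaxation-time scan is shared across
#' profiles and refined per profile by parabolic interpolation in
#' `log(tau)`.  This is the per-pixel engine behind parametric imaging.
#'
#' @param D displacement matrix, one profile per row, in microns.
#' @param seq the [tracking_seq()].
#' @param cfg fit settings from [visr_fit_config()].
#' @return A list of per-profile vectors `re`, `rv`, `tau_ms`, `pd`,
#'   `residual_rms`, `converged`, `amplitude`.
#' @export
fit_visr_grid <- function(D, seq, cfg = visr_fit_config()) {
  tl <- tracking_times(seq)
  nt <- length(tl$sample_times_s)
  stopifnot(ncol(D) == nt)
  np <- nrow(D)
  ltau <- seq(log(cfg$tau_min_s), log(cfg$tau_max_s),
              length.out = cfg$n_tau)
  S <- visr_shape_matrix(exp(ltau), seq)         # ntau x nt
  ss <- rowSums(S * S)
  G <- D %*% t(S)                                # np x ntau
  Q <- sweep(G * G, 2, ss, "/")                  # projected energy
  k <- max.col(Q, ties.method = "first")
  h <- ltau[2] - ltau[1]
  km <- pmax(k - 1, 1); kp <- pmin(k + 1, cfg$n_tau)
  qm <- Q[cbind(seq_len(np), km)]
  q0 <- Q[cbind(seq_len(np), k)]
  qp <- Q[cbind(seq_len(np), kp)]
  denom <- qm - 2 * q0 + qp
  delta <- ifelse(abs(denom) > 0, 0.5 * (qm - qp) / denom, 0)
  delta[k == 1 | k == cfg$n_tau] <- 0
  delta <- pmin(pmax(delta, -1), 1)
  lt_hat <- ltau[k] + delta * h
  tau_s <- exp(lt_hat)
  M <- voigt_profile_matrix(tau_s, rep(1, np), tl$sample_times_s,
                            tl$push_onsets_s, tl$push_dur_s)
  mm <- rowSums(M * M)
  a <- rowSums(D * M) / mm
  resid <- sqrt(pmax(rowSums((D - a * M)^2), 0) / nt)
  pd <- do.call(pmax, as.data.frame(D))
  converged <- is.finite(a) & a > 0 & pd > 0 & resid < cfg$resid_frac * pd
  re <- ifelse(is.finite(a) & a > 0, 1 / a, NA_real_)
  tau_ms <- tau_s * 1e3
  list(re = re, rv = tau_ms * re, tau_ms = tau_ms, pd = pd,
       residual_rms = resid, converged = converged, amplitude = a)
}
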