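test_that("sequence timeline lays events on consecutive PRF slots", {
  tl <- default_tl
  expect_equal(tl$slot_s, 1 / 11500)
  expect_equal(tl$slot_s * 1e6, 86.96, tolerance = 1e-3)
  # second push starts 1 + 8 slots after the first
  expect_equal(diff(tl$push_onsets_s), 9 / 11500)
  expect_length(tl$sample_times_s, 2 + 8 + 43)
  expect_true(all(diff(tl$sample_times_s) > 0))
  expect_equal(sum(tl$is_reference), 2)
  # push fits inside one slot
  expect_lt(tl$push_dur_s, tl$slot_s)
  expect_error(tracking_seq(push_cycles = 4000), "slot")
})

test_that("Voigt response obeys linearity, steady state and tau = 0 limit", {
  m <- material_point(5, 2)
  sched0 <- force_schedule(default_seq, 1)
  sched0$amplitude <- c(1e-300, 1e-300)  # effectively zero forcing
  t_s <- default_tl$sample_times_s
  pr0 <- voigt_response(m, sched0, t_s)
  expect_true(all(abs(pr0$disp_um) < 1e-290))
  # single infinite-duration push reaches A = scale / E_Pa
  hold <- data.frame(onset_s = 0, duration_s = 10, amplitude = 1)
  A <- visreb:::visr_force_scale / (5 * 1000)
  late <- voigt_response(m, hold, c(0.5, 1))
  expect_equal(late$disp_um, c(A, A), tolerance = 1e-4)
  # tau = 0: step to A during push, zero after
  m0 <- material_point(5, 0)
  pr <- voigt_response(m0, data.frame(onset_s = 0, duration_s = 1e-4,
                                      amplitude = 1), c(5e-5, 2e-4))
  expect_equal(pr$disp_um, c(A, 0))
})

test_that("closed form matches the numeric MSD oracle with zero mass", {
  sched <- force_schedule(default_seq, 1)
  t_s <- default_tl$sample_times_s
  # the end-of-push displacement of a single short push: A(1 - e^(-Tp/tau))
  m1 <- material_point(1, 1)  # tau = 1 ms
  Tp <- 71.26e-6
  one_push <- data.frame(onset_s = 0, duration_s = Tp, amplitude = 1)
  A <- visreb:::visr_force_scale / 1000
  end_disp <- voigt_response(m1, one_push, c(Tp - 1e-12))$disp_um
  expect_equal(end_disp / A, 1 - exp(-Tp / 1e-3), tolerance = 1e-6)
  expect_equal(end_disp / A, 0.0688, tolerance = 2e-3)
  ode <- msd_response_numeric(m1, 0, one_push, c(Tp - 1e-12))$disp_um
  expect_equal(end_disp, ode, tolerance = 1e-8)
  # random draws on the double-push schedule
  set.seed(42)
  for (i in 1:12) {
    E <- runif(1, 1, 30); mu <- runif(1, 0.05, 10)
    m <- material_point(E, mu)
    a <- voigt_response(m, sched, t_s)$disp_um
    b <- msd_response_numeric(m, 0, sched, t_s)$disp_um
    expect_lt(max(abs(a - b)) / max(abs(a)), 1e-6)
  }
})

test_that("small inertia overshoots the Voigt peak and decays to rest", {
  # an under-damped mass whose natural period matches the push duration
  # rings past the quasi-static Voigt response
  m <- material_point(5, 0.05)
  k <- m$E * 1000
  mass <- 5e-7                     # zeta = mu/(2 sqrt(mass k)) = 0.5
  sched <- force_schedule(default_seq, 1)
  t_dense <- seq(1e-6, 2e-3, by = 2e-6)
  voigt_pk <- peak_displacement(voigt_response(m, sched, t_dense))
  with_mass <- msd_response_numeric(m, mass, sched, t_dense)
  expect_gt(peak_displacement(with_mass), voigt_pk)
  # dissipative: displacement returns to zero after forcing ends
  late <- msd_response_numeric(m, mass, sched, c(20e-3))
  expect_lt(abs(late$disp_um), 1e-3 * voigt_pk)
})

test_that("double-push superposition and sampled peak location hold", {
  t_s <- default_tl$sample_times_s
  sched <- force_schedule(default_seq, 1)
  m <- material_point(5, 2)
  both <- voigt_response(m, sched, t_s)$disp_um
  p1 <- voigt_response(m, sched[1, ], t_s)$disp_um
  p2 <- voigt_response(m, sched[2, ], t_s)$disp_um
  A <- visreb:::visr_force_scale / (5 * 1000)
  expect_lt(max(abs(both - (p1 + p2))), 1e-9 * A)
  # peak at the first sample at/after the end of the second push
  pk_idx <- which.max(both)
  t_push2_end <- default_tl$push_onsets_s[2] + default_tl$push_dur_s
  expect_equal(pk_idx, which(t_s >= t_push2_end)[1])
  # sampled peak equals the superposition algebra evaluated there
  tau_s <- 2 / 5 * 1e-3
  Tp <- default_tl$push_dur_s
  delta <- diff(default_tl$push_onsets_s)
  t_pk <- t_s[pk_idx]
  expected <- A * (1 - exp(-Tp / tau_s)) *
    (1 + exp(-delta / tau_s)) * exp(-(t_pk - t_push2_end) / tau_s)
  expect_equal(both[pk_idx], expected, tolerance = 1e-10)
  # peak_displacement is a plain max
  expect_equal(peak_displacement(displacement_profile(1:4, c(0, 1, 3, 2))), 3)
})

test_that("PD decreases monotonically in elasticity and in viscosity", {
  t_s <- default_tl$sample_times_s
  sched <- force_schedule(default_seq, 1)
  # fixed tau, increasing E
  taus <- 0.4e-3
  pd_E <- vapply(seq(2, 20, length.out = 10), function(E) {
    peak_displacement(voigt_response(material_point(E, E * taus * 1e3),
                                     sched, t_s))
  }, numeric(1))
  expect_true(all(diff(pd_E) < 0))
  # fixed E, increasing mu (beyond the sampled-PD peak)
  pd_mu <- vapply(seq(1, 20, length.out = 10), function(mu) {
    peak_displacement(voigt_response(material_point(5, mu), sched, t_s))
  }, numeric(1))
  expect_true(all(diff(pd_mu) < 0))
})

test_that("fit_visr inverts the forward model", {
  # noise-free: exact inverse up to solver tolerance across tau range
  for (tau_ms in c(0.05, 0.2, 1, 5)) {
    E <- 5; mu <- tau_ms * E
    pr <- voigt_profile_for(E, mu)
    truth <- true_relative_params(E, mu)
    f <- fit_visr(pr, default_seq)
    expect_true(f$converged)
    expect_equal(f$re, truth$re, tolerance = 1e-3)
    expect_equal(f$rv, truth$rv, tolerance = 1e-3)
    expect_equal(f$tau_ms, f$rv / f$re)
  }
  # near-step profile (tau -> 0 limit): recovered tau below one PRF slot
  pr_step <- voigt_profile_for(5, 5 * 0.005)
  f0 <- fit_visr(pr_step, default_seq)
  expect_lt(f0$tau_ms * 1e-3, default_tl$slot_s)
  # length mismatch errors
  bad <- displacement_profile(default_tl$sample_times_s[1:10], rep(1, 10))
  expect_error(fit_visr(bad, default_seq), "timeline")
})

test_that("fit_visr tolerates additive noise with bounded error", {
  set.seed(7)
  E <- 5; mu <- 2
  pr <- voigt_profile_for(E, mu)
  truth <- true_relative_params(E, mu)
  pk <- peak_displacement(pr)
  n_trials <- 60
  err_re <- err_rv <- numeric(n_trials)
  for (i in seq_len(n_trials)) {
    noisy <- pr
    noisy$disp_um <- pr$disp_um + rnorm(nrow(pr), sd = 0.05 * pk)
    f <- fit_visr(noisy, default_seq)
    err_re[i] <- (f$re - truth$re) / truth$re
    err_rv[i] <- (f$rv - truth$rv) / truth$rv
  }
  expect_lt(sqrt(mean(err_re^2)), 0.10)
  expect_lt(sqrt(mean(err_rv^2)), 0.10)
})

test_that("vectorized grid fit agrees with the per-profile fit", {
  Es <- c(2, 5, 12, 25); mus <- c(0.5, 2, 5, 1)
  D <- t(vapply(seq_along(Es), function(i) {
    voigt_profile_for(Es[i], mus[i])$disp_um
  }, numeric(length(default_tl$sample_times_s))))
  g <- fit_visr_grid(D, default_seq)
  for (i in seq_along(Es)) {
    f <- fit_visr(voigt_profile_for(Es[i], mus[i]), default_seq)
    expect_equal(g$re[i], f$re, tolerance = 5e-3)
    expect_equal(g$rv[i], f$rv, tolerance = 2e-2)
  }
  expect_true(all(g$converged))
})
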