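test_that("degenerate uniform phantom is constant at the background", {
  sp <- small_phantom_spec(lesion_E = 5, lesion_mu = 2,
                           margin_E_factor = 1, margin_mu_factor = 1,
                           heterogeneity_cv = 0)
  ph <- make_phantom(sp)
  expect_true(all(ph$E_map == 5))
  expect_true(all(ph$mu_map == 2))
})

test_that("mask area matches the ellipse and phantoms are deterministic", {
  sp <- small_phantom_spec(lesion_axes = c(6, 4), heterogeneity_cv = 0.2)
  ph <- make_phantom(sp)
  px_area <- sp$axial_spacing * sp$lateral_spacing
  expect_equal(sum(ph$bmode_mask) * px_area, pi * 6 * 4, tolerance = 0.02)
  ph2 <- make_phantom(sp)
  expect_identical(ph$E_map, ph2$E_map)
  expect_identical(ph$scatterers, ph2$scatterers)
  # different seed changes the heterogeneity field
  sp3 <- small_phantom_spec(lesion_axes = c(6, 4), heterogeneity_cv = 0.2,
                            seed = 2)
  expect_false(identical(make_phantom(sp3)$E_map, ph$E_map))
})

test_that("out-of-grid lesions are rejected naming the violating axis", {
  expect_error(make_phantom(small_phantom_spec(lesion_center = c(2, 20))),
               "lateral")
  expect_error(make_phantom(small_phantom_spec(lesion_center = c(9.75, 3))),
               "axial")
  expect_error(phantom_spec(margin_width = 5, lesion_axes = c(6, 4)),
               "semi-minor")
})

test_that("margin annulus is placed on the correct side of the boundary", {
  # positive margin: altered material outside the B-mode ellipse
  sp_pos <- small_phantom_spec(margin_width = 1.5, margin_E_factor = 3)
  ph <- make_phantom(sp_pos)
  q <- ph$lesion_q
  expect_true(all(ph$E_map[q <= 1] == sp_pos$lesion_E))
  ann <- q > 1 & ph$E_map > 5 + 1e-9
  expect_true(any(ann))
  expect_true(all(ph$E_map[ann] == 15))
  # negative margin: outer lesion ring reverts to factor-scaled background
  sp_neg <- small_phantom_spec(margin_width = -1.5)
  ph2 <- make_phantom(sp_neg)
  ring <- ph2$lesion_q <= 1 & ph2$E_map == 5
  expect_true(any(ring))
  # B-mode mask unchanged by the margin
  expect_equal(ph$bmode_mask, ph2$bmode_mask)
})

test_that("material maps stay positive across random specs", {
  set.seed(5)
  for (i in 1:25) {
    sp <- small_phantom_spec(
      lesion_axes = sort(runif(2, 2.5, 6), decreasing = TRUE),
      lesion_rotation = runif(1, 0, 180),
      margin_width = runif(1, -1.5, 1.5),
      margin_E_factor = runif(1, 0.3, 3),
      margin_mu_factor = runif(1, 0.3, 3),
      heterogeneity_cv = runif(1, 0, 0.5),
      seed = i)
    ph <- make_phantom(sp)
    expect_true(all(ph$E_map > 0))
    expect_true(all(ph$mu_map >= 0))
  }
})

test_that("boundary polygon reproduces circle geometry", {
  sp <- small_phantom_spec(grid_shape = c(512, 80), axial_spacing = 40 / 512,
                           lateral_spacing = 0.25,
                           lesion_axes = c(5, 5), lesion_center = c(9.875, 20))
  ph <- make_phantom(sp)
  b <- lesion_boundary(ph)
  expect_gte(nrow(b), 256)
  pm <- polygon_measures(b)
  expect_equal(pm$perimeter, 10 * pi, tolerance = 0.01)
  expect_equal(pm$area, 25 * pi, tolerance = 0.01)
  expect_gt(pm$signed_area, 0)  # counter-clockwise convention
})

test_that("polygon area agrees with mask pixel area on random ellipses", {
  set.seed(9)
  for (i in 1:10) {
    axes <- sort(runif(2, 3, 6), decreasing = TRUE)
    sp <- small_phantom_spec(grid_shape = c(512, 160),
                             axial_spacing = 40 / 512,
                             lateral_spacing = 0.125,
                             lesion_center = c(9.9375, 20),
                             lesion_axes = axes,
                             lesion_rotation = runif(1, 0, 180))
    ph <- make_phantom(sp)
    pm <- polygon_measures(lesion_boundary(ph))
    mask_area <- sum(ph$bmode_mask) * sp$axial_spacing * sp$lateral_spacing
    expect_equal(pm$area, mask_area, tolerance = 0.02)
  }
})

test_that("cohorts respect the label counting rule and determinism", {
  cs <- cohort_spec(n_lesions = 20, benign_fraction = 0.65,
                    rotations = c(0, 90), grid_shape = c(64, 40), seed = 3)
  coh <- sample_cohort(cs)
  labels <- vapply(coh, `[[`, character(1), "label")
  expect_equal(sum(labels == "benign"), 13)
  expect_equal(sum(labels == "malignant"), 7)
  coh2 <- sample_cohort(cs)
  expect_identical(labels, vapply(coh2, `[[`, character(1), "label"))
  expect_identical(coh[[1]]$phantoms[[1]]$E_map,
                   coh2[[1]]$phantoms[[1]]$E_map)
  # each lesion carries one phantom per rotation
  expect_true(all(vapply(coh, function(l) length(l$phantoms), integer(1)) == 2))
})

test_that("rotating an ellipse by 90 degrees swaps its apparent axes", {
  sp0 <- small_phantom_spec(lesion_axes = c(5, 3), lesion_rotation = 0)
  sp90 <- small_phantom_spec(lesion_axes = c(5, 3), lesion_rotation = 90)
  m0 <- make_phantom(sp0)$bmode_mask
  m90 <- make_phantom(sp90)$bmode_mask
  lat_extent <- function(m) diff(range(which(apply(m, 2, any))))
  ax_extent <- function(m) diff(range(which(apply(m, 1, any))))
  expect_gt(lat_extent(m0), lat_extent(m90))
  expect_lt(ax_extent(m0) * 40 / 256, ax_extent(m90) * 40 / 256)
})

test_that("benign and malignant cohorts encode opposite margin signs", {
  cs <- cohort_spec(n_lesions = 12, grid_shape = c(64, 40), seed = 4)
  coh <- sample_cohort(cs)
  mw <- vapply(coh, function(l) l$params$margin_width, numeric(1))
  lab <- vapply(coh, `[[`, character(1), "label")
  expect_true(all(mw[lab == "benign"] < 0))
  expect_true(all(mw[lab == "malignant"] > 0))
  # programmed parametric/B-mode extent ratio straddles 1 by class
  ratio <- 1 + mw / vapply(coh, function(l) l$params$semi_major, numeric(1))
  expect_lt(median(ratio[lab == "benign"]), 1)
  expect_gt(median(ratio[lab == "malignant"]), 1)
})

test_that("confound pairs match sampled PD while halving elasticity", {
  cp <- confound_pair(5, 2, default_seq)
  expect_equal(cp$E2, 2.5)
  expect_gt(cp$mu2, 2)
  expect_gt(cp$mu2 / cp$E2, 2 / 5)  # slower time constant
  expect_gt(cp$pd_ratio, 0.99)
  expect_lt(cp$pd_ratio, 1.01)
  # independent check of the matched PD via the numeric MSD oracle
  sched <- force_schedule(default_seq, 1)
  t_s <- default_tl$sample_times_s
  pd1 <- peak_displacement(msd_response_numeric(material_point(5, 2), 0,
                                                sched, t_s))
  pd2 <- peak_displacement(msd_response_numeric(
    material_point(cp$E2, cp$mu2), 0, sched, t_s))
  expect_equal(pd2 / pd1, 1, tolerance = 0.01)
  # unreachable level sets are reported with the bracket
  expect_error(pd_matched_pair(5, 2, default_seq, E2 = 50), "bracket")
})
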