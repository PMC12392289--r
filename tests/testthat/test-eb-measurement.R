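# Circle boundary polygon built directly.
circle_polygon <- function(r = 5, center = c(10, 20), n = 256) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  structure(data.frame(lateral_mm = center[1] + r * cos(th),
                       axial_mm = center[2] + r * sin(th)),
            class = c("visr_polygon", "data.frame"), source = "bmode")
}

ellipse_polygon <- function(a, b, rot_deg = 0, center = c(10, 20), n = 256) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  phi <- rot_deg * pi / 180
  x <- a * cos(th); y <- b * sin(th)
  structure(data.frame(
    lateral_mm = center[1] + x * cos(phi) - y * sin(phi),
    axial_mm = center[2] + x * sin(phi) + y * cos(phi)),
    class = c("visr_polygon", "data.frame"), source = "bmode")
}

test_that("largest diameter matches circle and rotated-ellipse geometry", {
  d <- largest_diameter(circle_polygon(5))
  expect_equal(d$length, 10, tolerance = 0.01)
  d30 <- largest_diameter(ellipse_polygon(8, 3, rot_deg = 30))
  expect_equal(d30$length, 16, tolerance = 0.01)
  ang <- abs(atan2(diff(d30$endpoints[, 2]),
                   diff(d30$endpoints[, 1]))) %% pi
  expect_equal(unname(min(ang, pi - ang)), 30 * pi / 180,
               tolerance = 0.02)
  deg <- circle_polygon(0)
  expect_error(largest_diameter(deg), "degenerate")
})

test_that("largest diameter is invariant to vertex order and start", {
  set.seed(13)
  for (i in 1:15) {
    axes <- sort(runif(2, 2, 7), decreasing = TRUE)
    p <- ellipse_polygon(axes[1], axes[2], runif(1, 0, 180), n = 128)
    # radial perturbation keeps the polygon simple but irregular
    r <- sqrt((p$lateral_mm - 10)^2 + (p$axial_mm - 20)^2)
    f <- 1 + 0.1 * sin(3 * atan2(p$axial_mm - 20, p$lateral_mm - 10) + i)
    q <- p
    q$lateral_mm <- 10 + (p$lateral_mm - 10) * f
    q$axial_mm <- 20 + (p$axial_mm - 20) * f
    ref <- largest_diameter(q)$length
    # brute-force oracle over all pairs
    dx <- outer(q$lateral_mm, q$lateral_mm, "-")
    dy <- outer(q$axial_mm, q$axial_mm, "-")
    expect_equal(ref, sqrt(max(dx^2 + dy^2)))
    # rotate starting vertex and reverse orientation
    k <- sample(nrow(q), 1)
    q2 <- q[c(k:nrow(q), seq_len(k - 1)), ]
    q3 <- q2[nrow(q2):1, ]
    expect_equal(largest_diameter(q2)$length, ref)
    expect_equal(largest_diameter(q3)$length, ref)
  }
})

# Step-profile image: value `hi` inside an ellipse extended by `extend`
# mm beyond the B-mode ellipse (a, b), `lo` outside.
step_image <- function(a, b, extend, hi = 2, lo = 1,
                       nz = 256, nx = 40, center = c(9.75, 20)) {
  axial <- (seq_len(nz) - 1) * 40 / nz
  lateral <- (seq_len(nx) - 1) * 0.5
  lat_g <- matrix(lateral, nz, nx, byrow = TRUE)
  ax_g <- matrix(axial, nz, nx)
  q <- ((lat_g - center[1]) / (a + extend))^2 +
    ((ax_g - center[2]) / (b + extend))^2
  img <- matrix(lo, nz, nx)
  img[q <= 1] <- hi
  list(img = img, axial = axial, lateral = lateral)
}

test_that("endpoint adjustment recovers programmed step extensions", {
  bnd <- ellipse_polygon(6, 4, center = c(9.75, 20))
  broi <- largest_diameter(bnd)
  expect_equal(broi$length, 12, tolerance = 1e-6)
  # coextensive step: length unchanged
  s0 <- step_image(6, 4, 0)
  roi0 <- adjust_endpoints(broi, s0$img, s0$axial, s0$lateral, bnd)
  expect_equal(eb_ratio(roi0, broi), 1, tolerance = 0.01)
  # step extended by 1.5 mm beyond each endpoint: length + 3 mm
  s1 <- step_image(6, 4, 1.5)
  roi1 <- adjust_endpoints(broi, s1$img, s1$axial, s1$lateral, bnd)
  expect_equal(roi1$length, 15, tolerance = 0.5)   # one lateral pixel
  expect_equal(eb_ratio(roi1, broi), 15 / 12, tolerance = 0.05)
  # receded step: length shrinks symmetrically
  s2 <- step_image(6, 4, -1.5)
  roi2 <- adjust_endpoints(broi, s2$img, s2$axial, s2$lateral, bnd)
  expect_equal(roi2$length, 9, tolerance = 0.5)
  # flat profile: unchanged with the low-contrast marker
  flat <- s1; flat$img[] <- 1
  roif <- adjust_endpoints(broi, flat$img, flat$axial, flat$lateral, bnd)
  expect_equal(roif$length, broi$length)
  expect_true(attr(roif, "low_contrast"))
  # E/B is invariant to positive rescaling of the image
  roi_sc <- adjust_endpoints(broi, 7.3 * s1$img, s1$axial, s1$lateral, bnd)
  expect_equal(roi_sc$length, roi1$length)
  # dark lesions (contrast reversal) measure identically
  roi_inv <- adjust_endpoints(broi, max(s1$img) - s1$img + 1,
                              s1$axial, s1$lateral, bnd)
  expect_equal(roi_inv$length, roi1$length, tolerance = 1e-6)
})

test_that("eb_ratio is plain arithmetic with guarded degenerate input", {
  r1 <- visreb:::new_roi(c(0, 0), c(12, 0), "re")
  r2 <- visreb:::new_roi(c(0, 0), c(10, 0), "bmode")
  expect_equal(eb_ratio(r1, r2), 1.2)
  expect_equal(eb_ratio(r2, r2), 1)
  bad <- r2; bad$length <- 0
  expect_error(eb_ratio(r1, bad), "positive")
})

test_that("CNR arithmetic and the unsure rule behave as specified", {
  bnd <- circle_polygon(4, center = c(10, 20))
  nz <- 256; nx <- 40
  axial <- (seq_len(nz) - 1) * 40 / nz
  lateral <- (seq_len(nx) - 1) * 0.5
  img <- matrix(1, nz, nx)
  qf0 <- quality_flag(img + 0, axial, lateral, bnd)
  expect_equal(qf0$cnr, 0)
  expect_true(qf0$unsure)
  # mean_in 2, mean_out 1, sd 0.5 each: CNR = 1/sqrt(0.5) = 1.414
  masks <- boundary_masks(axial, lateral, bnd)
  set.seed(1)
  img[masks$inside] <- 2
  noise_in <- rnorm(sum(masks$inside)); noise_out <- rnorm(sum(masks$annulus))
  img[masks$inside] <- 2 + 0.5 * scale(noise_in)
  img[masks$annulus] <- 1 + 0.5 * scale(noise_out)
  qf <- quality_flag(img, axial, lateral, bnd, masks = masks)
  expect_equal(qf$cnr, sqrt(2), tolerance = 1e-6)
  expect_false(qf$unsure)
})

test_that("median CNR falls as material heterogeneity grows", {
  cnr_at <- vapply(c(0.1, 0.3, 0.6), function(cv) {
    med <- vapply(1:3, function(s) {
      ph <- make_phantom(small_phantom_spec(lesion_E = 10, lesion_mu = 4,
                                            heterogeneity_cv = cv, seed = s))
      img <- compute_images(ph, default_seq, no_atten, mode = "ideal",
                            seed = s)
      bnd <- lesion_boundary(ph)
      quality_flag(img$re, img$axial_mm, img$lateral_mm, bnd)$cnr
    }, numeric(1))
    median(med)
  }, numeric(1))
  expect_true(all(diff(cnr_at) < 0))
})

test_that("lesion characteristics match closed-form shape measures", {
  circ <- lesion_characteristics(circle_polygon(5), list())
  expect_equal(circ$circularity, 1, tolerance = 0.02)
  expect_equal(circ$depth, 20, tolerance = 1e-6)
  expect_equal(circ$area, 25 * pi, tolerance = 0.01)
  ell <- lesion_characteristics(ellipse_polygon(6, 3), list())
  expect_lt(ell$circularity, 1)
  # single rotation: DoA absent, not 1
  ph <- make_phantom(small_phantom_spec())
  img <- compute_images(ph, default_seq, no_atten, mode = "ideal")
  one <- lesion_characteristics(lesion_boundary(ph), list(img))
  expect_true(is.na(one$doa_re))
})

test_that("isotropic phantoms have DoA near one across rotations", {
  cs <- cohort_spec(n_lesions = 2, benign_fraction = 0.5,
                    rotations = c(0, 30, 60, 90), heterogeneity_cv = 0.1,
                    seed = 8)
  coh <- sample_cohort(cs)
  les <- coh[[1]]
  imgs <- lapply(les$phantoms, function(ph)
    compute_images(ph, default_seq, no_atten, mode = "ideal"))
  bnds <- lapply(les$phantoms, lesion_boundary)
  ch <- lesion_characteristics(bnds[[1]], imgs, bnds)
  expect_equal(ch$doa_pd, 1, tolerance = 0.05)
  expect_equal(ch$doa_re, 1, tolerance = 0.05)
  expect_equal(ch$doa_rv, 1, tolerance = 0.05)
  expect_gte(ch$doa_re, 1)
})

test_that("B-mode measured against itself yields E/B of exactly one", {
  ph <- make_phantom(small_phantom_spec())
  bnd <- lesion_boundary(ph)
  broi <- largest_diameter(bnd)
  expect_identical(eb_ratio(broi, broi), 1)
})
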