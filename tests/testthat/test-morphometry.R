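test_that("solid metrics match closed forms on canonical solids", {
  # sphere r = 40: Wadell sphericity ~ 1
  s <- make_sphere(40, n = 92)
  ms <- solid_metrics(s, 1000)
  expect_gte(ms$sphericity, 0.97); expect_lte(ms$sphericity, 1.03)
  expect_equal(ms$L_W, 1, tolerance = 0.03)
  # cube: (pi/6)^(1/3) ~ 0.806
  cube <- array(FALSE, c(60, 60, 60)); cube[11:50, 11:50, 11:50] <- TRUE
  expect_lt(abs(solid_metrics(cube, 1000)$sphericity - (pi / 6)^(1 / 3)), 0.03)
  # prolate spheroid (1,1,2): closed-form area
  sp <- make_ellipsoid(20, 20, 40, n = 92)
  msp <- solid_metrics(sp, 1000)
  V <- 4 / 3 * pi * 20^2 * 40
  true_sph <- pi^(1 / 3) * (6 * V)^(2 / 3) / spheroid_area(20, 40)
  expect_equal(msp$sphericity, true_sph, tolerance = 0.02)
  expect_equal(msp$L_W, 2, tolerance = 0.05)
  expect_error(solid_metrics(array(FALSE, c(9, 9, 9)), 100), "empty")
})

test_that("mesh-enclosed volume agrees with voxel counting within 3%", {
  for (m in list(make_sphere(18, 48), make_ellipsoid(10, 12, 20, 52))) {
    iso <- olivemorph:::mask_isosurface(m)
    expect_lt(abs(iso$volume / sum(m) - 1), 0.03)
  }
})

test_that("sphericity converges to 1 with sphere resolution", {
  sph <- vapply(c(10, 20, 40), function(r) {
    solid_metrics(make_sphere(r), 1000)$sphericity
  }, 0)
  expect_lt(abs(sph[3] - 1), abs(sph[1] - 1) + 0.02)
  expect_true(all(sph <= 1.05))
})

test_that("position of the maximum transverse area is signed toward the apex", {
  e <- make_ellipsoid(10, 10, 20, n = 52)
  expect_equal(position_of_mta(e), 0, tolerance = 1)
  sp <- phantom_spec(mta_offset = 10, voxel_size = 250, seed = 3)
  al <- align_to_major_axis(generate_drupe_phantom(sp)$truth$fruit, apex = "+z")
  expect_equal(position_of_mta(al$mask), 10, tolerance = 1.5)
  sp2 <- phantom_spec(mta_offset = -5, voxel_size = 250, seed = 4)
  al2 <- align_to_major_axis(generate_drupe_phantom(sp2)$truth$fruit, apex = "+z")
  expect_equal(position_of_mta(al2$mask), -5, tolerance = 1.5)
})

test_that("asymmetry coefficient is high for symmetric solids and falls with bend", {
  e <- make_ellipsoid(10, 11, 20, n = 52)
  expect_gte(asymmetry_coefficient(e, step_deg = 3), 0.98)
  vals <- vapply(c(0, 10, 20), function(b) {
    sp <- phantom_spec(bend_angle = b, voxel_size = 300, seed = 5)
    al <- align_to_major_axis(generate_drupe_phantom(sp)$truth$fruit, apex = "+z")
    asymmetry_coefficient(al$mask, step_deg = 3)
  }, 0)
  expect_true(all(diff(vals) < 0))
  # reflection invariance
  m <- make_ellipsoid(9, 11, 18, n = 48)
  mm <- m[dim(m)[1]:1, , ]
  expect_equal(asymmetry_coefficient(m, 5), asymmetry_coefficient(mm, 5),
               tolerance = 1e-6)
})

test_that("groove counting recovers the seeded groove number", {
  mk <- function(k) {
    sp <- phantom_spec(stone_semi_axes = c(3.2, 3.0, 7), groove_count = k,
                       groove_depth = 0.05, voxel_size = 150, seed = k + 1)
    align_to_major_axis(generate_drupe_phantom(sp)$truth$stone, apex = "+z")$mask
  }
  expect_equal(count_grooves(mk(0L)), 0L)
  expect_equal(count_grooves(mk(4L)), 4L)
  expect_equal(count_grooves(mk(8L)), 8L)
})

test_that("lenticel detection counts seeded marks within 5%", {
  sp <- phantom_spec(lenticel_count = 100L, voxel_size = 150, seed = 11)
  ph <- generate_drupe_phantom(sp)
  al <- align_segmentation(segment_drupe(ph$volume), ph$volume, apex = "+z")
  area_cm2 <- solid_metrics(al$masks$fruit, 150)$surface_area / 100
  res <- lenticel_density(al$volume, al$masks$fruit, area_cm2)
  n_true <- nrow(ph$truth$lenticels)
  expect_lte(abs(res$count - n_true) / n_true, 0.05)
  expect_lte(abs(res$density - n_true / area_cm2) / (n_true / area_cm2), 0.1)
  # doubling the mark contrast leaves the count within 5%
  sp2 <- phantom_spec(lenticel_count = 100L, lenticel_contrast = 90,
                      voxel_size = 150, seed = 11)
  ph2 <- generate_drupe_phantom(sp2)
  al2 <- align_segmentation(segment_drupe(ph2$volume), ph2$volume, apex = "+z")
  res2 <- lenticel_density(al2$volume, al2$masks$fruit, area_cm2)
  expect_lte(abs(res2$count - res$count) / res$count, 0.05)
  # no marks -> zero
  sp0 <- phantom_spec(lenticel_count = 0L, voxel_size = 150, seed = 11)
  ph0 <- generate_drupe_phantom(sp0)
  al0 <- align_segmentation(segment_drupe(ph0$volume), ph0$volume, apex = "+z")
  expect_equal(lenticel_density(al0$volume, al0$masks$fruit, area_cm2)$count, 0)
})

test_that("rugosity index is ~1 for convex stones and grows with groove depth", {
  mk <- function(depth) {
    k <- if (depth > 0) 4L else 0L
    sp <- phantom_spec(stone_semi_axes = c(3.2, 3.2, 7), groove_count = k,
                       groove_depth = max(depth, 0.05), voxel_size = 150, seed = 2)
    if (depth == 0) sp$groove_depth <- 0
    align_to_major_axis(generate_drupe_phantom(sp)$truth$stone, apex = "+z")$mask
  }
  r0 <- rugosity_index(mk(0))
  r1 <- rugosity_index(mk(0.05))
  r2 <- rugosity_index(mk(0.12))
  expect_equal(r0, 1, tolerance = 0.03)
  expect_gt(r1, r0)
  expect_gt(r2, r1)
  # scale invariance: same stone at finer resolution agrees within 2%
  spc <- phantom_spec(stone_semi_axes = c(3.2, 3.2, 7), groove_count = 4L,
                      voxel_size = 250, seed = 2)
  coarse <- rugosity_index(align_to_major_axis(
    generate_drupe_phantom(spc)$truth$stone, apex = "+z")$mask)
  expect_lt(abs(coarse - r1), 0.02)
})

test_that("measure_olive populates every trait and recovers the phantom", {
  ph <- default_test_phantom()
  m <- segment_drupe(ph$volume)
  row <- measure_olive(ph$volume, m, olive_id = "ph1",
                       asymmetry_step_deg = 3, apex = "+z")
  expect_true(all(trait_names() %in% names(row)))
  expect_false(any(is.na(row[trait_names()])))
  tr <- ph$truth$true_traits
  rel_ok <- function(x, truth, tol) expect_lt(abs(x / truth - 1), tol)
  rel_ok(row$D_Volume, tr$fruit$volume / 1000, 0.05)
  rel_ok(row$E_Volume, tr$stone$volume / 1000, 0.05)
  rel_ok(row$C_Volume, tr$cavity$volume, 0.05)
  rel_ok(row$D_Surface_area, tr$fruit$surface_area / 100, 0.10)
  rel_ok(row$E_Surface_area, tr$stone$surface_area / 100, 0.10)
  rel_ok(row$D_Sphericity, tr$fruit$sphericity, 0.05)
  rel_ok(row$D_L_W, tr$fruit$L_W, 0.05)
  expect_equal(row$D_Position_of_MTA, 10, tolerance = 1.5)
  expect_equal(row$E_Number_of_grooves, 4)
  # weights are density-derived
  expect_equal(row$D_Weight, 0.96 * row$D_Volume, tolerance = 1e-10)
  expect_equal(row$E_Weight, 1.07 * row$E_Volume, tolerance = 1e-10)
})

test_that("sphere-mode phantom yields unit elongation", {
  sp <- phantom_spec(fruit_semi_axes = c(5, 5, 5) * 1.0001,
                     stone_semi_axes = c(2, 2, 2.6), voxel_size = 200, seed = 2)
  ph <- generate_drupe_phantom(sp)
  m <- segment_drupe(ph$volume)
  row <- measure_olive(ph$volume, m, asymmetry_step_deg = 5, apex = "+z")
  expect_equal(row$D_L_W, 1, tolerance = 0.02)
})
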