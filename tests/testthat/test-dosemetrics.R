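grid_pair <- function(seed, shape = c(12, 12, 12), spacing = 2, smooth = 1.5,
                      perturb = 0.08) {
  set.seed(seed)
  base <- gauss <- array(rnorm(prod(shape)), shape)
  base <- pbmcdose:::gauss_smooth_3d(base, smooth)
  base <- base - min(base) + 0.1
  ref <- volume_grid(base, rep(spacing, 3))
  ev <- volume_grid(base * (1 + perturb * pbmcdose:::gauss_smooth_3d(
    array(rnorm(prod(shape)), shape), smooth)), rep(spacing, 3))
  list(ref = ref, ev = ev)
}

test_that("gamma is zero for identical doses and bounded for uniform scaling", {
  p <- grid_pair(1)
  g <- gamma_3d(p$ref, p$ref, 3, 3, 10)
  expect_equal(passing_rate(g), 100)
  expect_equal(max(g$gamma_values, na.rm = TRUE), 0)
  ## uniform 3% inflation passes 3%/x mm at exactly 100% under global norm
  scaled <- p$ref; scaled$values <- scaled$values * 1.03
  for (dta in c(1, 3))
    expect_equal(passing_rate(gamma_3d(p$ref, scaled, 3, dta, 10)), 100)
})

test_that("the gamma threshold and mask define the evaluated voxel set", {
  p <- grid_pair(2)
  mask <- volume_grid((p$ref$values > median(p$ref$values)) * 1,
                      p$ref$spacing, p$ref$origin, mask = TRUE)
  g <- gamma_3d(p$ref, p$ev, 3, 3, 25, mask)
  expected <- mask$values > 0.5 &
    p$ref$values >= 0.25 * max(p$ref$values[mask$values > 0.5])
  expect_identical(g$evaluated_mask, expected)
  expect_error(gamma_3d(p$ref, p$ev, 3, 3, 10,
                        volume_grid(p$ref$values * 0, p$ref$spacing,
                                    p$ref$origin, mask = TRUE)),
               "empty")
})

test_that("production gamma matches the brute-force oracle on random grids", {
  for (seed in 1:4) {
    p <- grid_pair(seed, perturb = 0.1)
    g <- gamma_3d(p$ref, p$ev, 3, 3, 10)
    o <- oracle_gamma(p$ref, p$ev, 3, 3, 10)
    expect_lt(max(abs(g$gamma_values - o), na.rm = TRUE), 0.02)
  }
})

test_that("gamma passing is monotone in the criteria (1/1 <= 2/2 <= 3/3)", {
  p <- grid_pair(5, perturb = 0.15)
  pr <- vapply(1:3, function(k)
    passing_rate(gamma_3d(p$ref, p$ev, k, k, 10)), 0)
  expect_true(all(diff(pr) >= 0))
})

test_that("passing_rate counts the gamma = 1 boundary and drops NaN voxels", {
  r <- structure(list(gamma_values = array(c(0.5, 1, 1.5, 2, NA, NA, 0, 3),
                                           c(2, 2, 2))), class = "gamma_result")
  expect_equal(passing_rate(r), 100 * 3 / 6)
  r$gamma_values[] <- NA
  expect_error(passing_rate(r), "no evaluated")
})

## Range map fixtures: profiles laid out along the RL (third) axis.
profile_grid <- function(profiles, spacing = 2) {
  n <- length(profiles[[1]])
  arr <- array(0, c(length(profiles), 1, n))
  for (i in seq_along(profiles)) arr[i, 1, ] <- profiles[[i]]
  volume_grid(arr, rep(spacing, 3))
}

test_that("range extraction interpolates the distal crossing", {
  ## profile crossing 90% of prescription exactly at a voxel center
  presc <- 1
  prof <- c(1, 1.2, 1.2, 0.9, 0.6, 0.2, 0, 0)   # crosses 0.9 at index 4 (depth 6 mm)
  rm <- range_map(profile_grid(list(prof)), 0.9, presc)
  expect_equal(rm$ranges[1, 1], 3 * 2)
  ## two excursions above threshold: take the distal-most crossing
  prof2 <- c(1.0, 0.2, 0.2, 1.1, 1.0, 0.3, 0, 0)
  rm2 <- range_map(profile_grid(list(prof2)), 0.9, presc)
  expect_gt(rm2$ranges[1, 1], 4 * 2)
  ## never reaching the threshold gives NaN
  rm3 <- range_map(profile_grid(list(prof * 0.1)), 0.9, presc)
  expect_true(is.na(rm3$ranges[1, 1]))
})

test_that("axis-ray R90 of a water SOBP matches the analytic model crossing", {
  ph <- make_phantom(phantom_spec(shape = c(16, 24, 24), spacing_mm = 5,
                                  n_air_cavities = 0, n_bone_slabs = 0,
                                  seed = 3))
  spec <- beam_sim_spec(gantry_deg = 270, couch_deg = 0,
                        isocenter = ph$ctv_center, range_mm = 55, mod_mm = 25,
                        field_halfwidth_mm = 18, prescribed_dose = 2,
                        entrance_sigma_mm = 3, sigma_growth = 0,
                        pb_beamlet_width_mm = 5)
  dd <- build_sobp(55, 25, K = 25, sigma_peak = 5, sigma_d = 3)
  mc <- simulate_mc_like(ph$ct, ph$body, ph$ctv, spec, dd)
  cfg <- canonical_config(shape = dim(mc$values), spacing_mm = 5)
  rm <- range_map(pbmcdose:::to_canonical_grid(
    mc, beam_geometry(270, 0, spec$isocenter, 2), cfg, 0), 0.9, 2)
  ci <- dim(mc$values) %/% 2L
  axis_range <- rm$ranges[ci[1] + 1, ci[2] + 1]
  ## analytic: depth where the SOBP falls below 0.9 x plateau, converted to
  ## the canonical-lattice depth coordinate through the body entry offset
  fine <- seq(40, 70, by = 0.01)
  plateau <- median(eval_depth_dose(dd, seq(38, 50, by = 0.5)))
  cross_wed <- max(fine[eval_depth_dose(dd, fine) >= 0.9 * plateau])
  ## entry depth on the axis ray (water: WED = geometric depth)
  body_c <- pbmcdose:::to_canonical_grid(
    ph$body, beam_geometry(270, 0, spec$isocenter, 2), cfg, 0,
    method = "nearest")
  entry_k <- which(body_c$values[ci[1] + 1, ci[2] + 1, ] > 0)[1]
  expected <- (entry_k - 1) * 5 + cross_wed
  expect_lt(abs(axis_range - expected), 6)  # within ~1.2 voxels
})

test_that("range maps shift linearly with a distal translation of the dose", {
  set.seed(8)
  prof <- c(0.2, 0.5, 1, 1, 1, 0.8, 0.3, 0.1, 0, 0, 0, 0)
  g <- profile_grid(list(prof, prof * 1.1))
  rm0 <- range_map(g, 0.5, 1)
  shifted <- g
  shifted$values <- g$values[, , c(10:12, 1:9), drop = FALSE]  # 3 voxels distal
  rm1 <- range_map(shifted, 0.5, 1)
  d <- rm1$ranges - rm0$ranges
  expect_equal(unname(d[is.finite(d)]), rep(3 * 2, sum(is.finite(d))),
               tolerance = 1e-9)
})

test_that("ARD follows its defining algebra", {
  mk_map <- function(m) structure(list(ranges = m), class = "range_map")
  a <- mk_map(matrix(c(100, 150, 200, NA), 2))
  expect_equal(ard(a, a), 0)
  b <- mk_map(a$ranges * 1.02)
  expect_equal(ard(a, b), -2)
  ## hand-computed two-ray example
  r_mc <- mk_map(matrix(c(100, 200), 1))
  r_dl <- mk_map(matrix(c(99, 202), 1))
  expect_equal(ard(r_mc, r_dl), 100 * 0.5 * (1 / 100 - 2 / 200))
  ## NaN rays are dropped; all-NaN errors
  expect_error(ard(mk_map(matrix(NA_real_, 2)), mk_map(matrix(NA_real_, 2))),
               "finite")
})

test_that("MAE is the thresholded mean absolute difference", {
  v <- array(seq(0, 2, length.out = 27), c(3, 3, 3))
  ref <- volume_grid(v, c(2, 2, 2))
  ev <- volume_grid(v + 0.5, c(2, 2, 2))
  expect_equal(mae(ref, ref, threshold_fraction = 0.1, prescribed_dose = 1), 0)
  expect_equal(mae(ref, ev, threshold_fraction = 0.1, prescribed_dose = 1), 0.5)
  ## explicit 3-voxel set with |differences| 1, 2, 6
  r2 <- volume_grid(array(c(1, 1, 1, rep(0, 5)), c(2, 2, 2)), c(1, 1, 1))
  e2 <- volume_grid(array(c(2, 3, 7, rep(0, 5)), c(2, 2, 2)), c(1, 1, 1))
  expect_equal(mae(r2, e2, threshold_fraction = 0.5, prescribed_dose = 1), 3)
  expect_equal(mae(r2, e2, threshold_fraction = 0.5, prescribed_dose = 1),
               mae(e2, r2, threshold_fraction = 0.5, prescribed_dose = 1))
})

test_that("isodose DSC matches its set definition and is symmetric", {
  v <- array(0, c(10, 10, 1))
  a <- volume_grid(v + c(rep(0.5, 50), rep(0, 50)), c(1, 1, 1))
  expect_equal(isodose_dsc(a, a, 10, 90, 1), 1)
  b <- volume_grid(v + c(rep(0, 50), rep(0.5, 50)), c(1, 1, 1))
  expect_equal(isodose_dsc(a, b, 10, 90, 1), 0)
  ## |A| = 100, |B| = 80, |A n B| = 60 -> 2*60/180
  va <- array(0, c(20, 10, 1)); va[1:100] <- 0.5
  vb <- array(0, c(20, 10, 1)); vb[41:120] <- 0.5
  ga <- volume_grid(va, c(1, 1, 1)); gb <- volume_grid(vb, c(1, 1, 1))
  expect_equal(isodose_dsc(ga, gb, 10, 90, 1), 2 * 60 / 180)
  expect_equal(isodose_dsc(ga, gb, 10, 90, 1), isodose_dsc(gb, ga, 10, 90, 1))
  expect_error(isodose_dsc(ga, gb, 90, 10, 1), "band")
})

test_that("DVH metrics match a sort-based percentile oracle", {
  v <- array(0, c(10, 10, 1))
  v[1:100] <- 1:100
  dose <- volume_grid(v, c(2, 2, 2))
  mask <- volume_grid(v * 0 + 1, c(2, 2, 2), mask = TRUE)
  curve <- dvh(dose, mask)
  expect_equal(curve$volume_pct[1], 100)
  expect_true(all(diff(curve$volume_pct) <= 0))
  expect_equal(dvh_metric(curve, 50), 50.5)
  ## sort-based oracle at several volume points
  for (x in c(98, 95, 50, 2)) {
    oracle <- unname(quantile(1:100, 1 - x / 100, type = 7))
    expect_equal(dvh_metric(curve, x), oracle)
  }
  ## D_x nonincreasing in x
  ds <- vapply(c(98, 95, 50, 2), dvh_metric, 0, curve = curve)
  expect_true(all(diff(ds) >= 0))
  ## uniform dose: all metrics equal the dose
  u <- volume_grid(v * 0 + 3.3, c(2, 2, 2))
  cu <- dvh(u, mask)
  for (x in c(98, 50, 2)) expect_equal(dvh_metric(cu, x), 3.3)
  expect_error(dvh(dose, volume_grid(v * 0, c(2, 2, 2), mask = TRUE)),
               "empty")
})

test_that("RDE follows Eq-style algebra", {
  expect_equal(rde(50, 50), 0)
  expect_equal(rde(1.037 * 50, 50), 3.7)
  expect_equal(rde(51, 50), 2)
  expect_error(rde(1, 0), "zero")
})

test_that("identity conversion yields a perfect beam and plan report", {
  ph <- make_phantom(phantom_spec(shape = c(16, 24, 24), spacing_mm = 5,
                                  n_air_cavities = 1, n_bone_slabs = 1,
                                  cavity_semi_range = c(7, 11), seed = 8))
  spec <- beam_sim_spec(gantry_deg = 150, couch_deg = -20,
                        isocenter = ph$ctv_center, range_mm = 50, mod_mm = 22,
                        field_halfwidth_mm = 14, prescribed_dose = 2,
                        sigma_growth = 0.08, pb_beamlet_width_mm = 20)
  dd <- build_sobp(50, 22, K = 25, sigma_peak = 5, sigma_d = 3)
  mc <- simulate_mc_like(ph$ct, ph$body, ph$ctv, spec, dd)
  pb <- simulate_pb_like(ph$ct, ph$body, ph$ctv, spec, dd)
  beam <- beam_geometry(150, -20, ph$ctv_center, 2)
  rep_b <- evaluate_beam(mc, mc, pb, beam, ph$body)
  expect_equal(rep_b$dl$gamma_pass, 100)
  expect_equal(rep_b$dl$ard_r90, 0)
  expect_equal(rep_b$dl$ard_r50, 0)
  expect_equal(rep_b$dl$mae, 0)
  expect_lt(rep_b$pb$gamma_pass, 100)

  ## plan with one beam equals that beam; identity cascade at plan level
  rep_p <- evaluate_plan(list(mc), list(mc), ph$body, ph$ctv, 2)
  for (g in rep_p$gamma) expect_equal(g$passing, 100)
  expect_equal(rep_p$mae, 0)
  for (d in rep_p$dsc) expect_equal(d$dsc, 1)
  for (r in rep_p$rde) expect_equal(r$rde, 0)

  ## report serialization round-trips through JSON
  f <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(rep_p, f, auto_unbox = TRUE, digits = NA, force = TRUE)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$mae, rep_p$mae)
  expect_equal(back$gamma$passing, vapply(rep_p$gamma, `[[`, 0, "passing"))
})
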