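tiny_shape <- c(16, 24, 24)

test_that("degenerate phantom spec gives uniform soft tissue inside the body", {
  ph <- make_phantom(phantom_spec(shape = tiny_shape, spacing_mm = 5,
                                  n_air_cavities = 0, n_bone_slabs = 0,
                                  seed = 3))
  inside <- ph$body$values > 0.5
  expect_true(all(ph$ct$values[inside] == 0))
  expect_true(all(ph$ct$values[!inside] == -1000))
  expect_true(all(ph$ctv$values[ph$body$values == 0] == 0))
})

test_that("phantom generation is deterministic and components are countable", {
  spec <- phantom_spec(shape = tiny_shape, spacing_mm = 5,
                       n_air_cavities = 3, n_bone_slabs = 1,
                       cavity_semi_range = c(7, 11), seed = 17)
  a <- make_phantom(spec)
  b <- make_phantom(spec)
  expect_identical(a$ct$values, b$ct$values)
  ## exactly 3 connected air-cavity components (BFS oracle, pre-smoothing)
  expect_identical(count_components(a$labels == 3L), 3L)
  ## body mask is a single connected component
  expect_identical(count_components(a$body$values > 0.5), 1L)
})

test_that("HU-to-stopping-power calibration hits its anchors and clamps", {
  expect_equal(hu_to_rsp(0), 1.0)
  expect_equal(hu_to_rsp(-1000), 0.001)
  expect_equal(hu_to_rsp(350), 1.22)   # halfway between water and bone
  expect_equal(hu_to_rsp(3000), hu_to_rsp(700))
  expect_equal(hu_to_rsp(-2000), hu_to_rsp(-1000))
  m <- matrix(c(0, 700, -1000, 350), 2, 2)
  expect_identical(dim(hu_to_rsp(m)), dim(m))
})

test_that("SOBP construction enforces preconditions and plateau flatness", {
  expect_error(build_sobp(150, 60, K = 1), "K")
  expect_error(build_sobp(150, 200, K = 10), "M < R")
  dd <- build_sobp(150, 60, K = 25)
  d <- seq(150 - 60 + 3, 150 - 3, by = 0.25)
  plateau <- eval_depth_dose(dd, d)
  expect_lte(max(abs(plateau - mean(plateau))) / mean(plateau), 0.02)
  ## distal falloff: < 1% of plateau beyond R + 5 sigma_d
  expect_lt(eval_depth_dose(dd, 150 + 5 * dd$sigma_d), 0.01 * mean(plateau))
  expect_true(all(eval_depth_dose(dd, seq(0, 200, by = 1)) >= 0))
})

water_beam <- function(gantry = 270, couch = 0, growth = 0, beamlet = 5,
                       hw = 18, R = 55, M = 25) {
  ph <- make_phantom(phantom_spec(shape = tiny_shape, spacing_mm = 5,
                                  n_air_cavities = 0, n_bone_slabs = 0,
                                  seed = 3))
  spec <- beam_sim_spec(gantry_deg = gantry, couch_deg = couch,
                        isocenter = ph$ctv_center, range_mm = R, mod_mm = M,
                        field_halfwidth_mm = hw, prescribed_dose = 2,
                        entrance_sigma_mm = 3, sigma_growth = growth,
                        pb_beamlet_width_mm = beamlet)
  dd <- build_sobp(R, M, K = 25, sigma_peak = 5, sigma_d = 3)
  list(ph = ph, spec = spec, dd = dd)
}

test_that("PB-like equals MC-like when beamlet = spacing and no scatter growth", {
  w <- water_beam()
  mc <- simulate_mc_like(w$ph$ct, w$ph$body, w$ph$ctv, w$spec, w$dd)
  pb <- simulate_pb_like(w$ph$ct, w$ph$body, w$ph$ctv, w$spec, w$dd)
  expect_lt(max(abs(mc$values - pb$values)), 1e-6)
})

test_that("homogeneous water: depth dose follows the SOBP model and doses agree", {
  ## flat-entry water slab (the beamlet window then sees identical WEDs),
  ## modest scatter growth, and a narrow field so the 5-sigma lateral
  ## falloff fits inside the grid
  sp <- 5
  co <- lapply(tiny_shape, function(n) (0:(n - 1)) * sp - sp * (n - 1) / 2)
  slab <- array(0, tiny_shape)
  for (k in seq_len(tiny_shape[3])) slab[, , k] <- as.numeric(abs(co[[3]][k]) < 45)
  origin <- sapply(co, `[`, 1)
  ct <- volume_grid(slab * 1000 - 1000, rep(sp, 3), origin)   # water 0 HU in slab
  body <- volume_grid(slab, rep(sp, 3), origin, mask = TRUE)
  ctv_arr <- array(0, tiny_shape)
  ci <- tiny_shape %/% 2L
  ctv_arr[ci[1] + (-1:1), ci[2] + (-1:1), ci[3] + (-1:1)] <- 1
  ph <- list(ct = ct, body = body,
             ctv = volume_grid(ctv_arr, rep(sp, 3), origin, mask = TRUE),
             ctv_center = c(0, 0, 0))
  w <- water_beam(growth = 0.02, beamlet = 20, hw = 12)
  w$ph <- ph
  w$spec$isocenter <- c(0, 0, 0)
  mc <- simulate_mc_like(w$ph$ct, w$ph$body, w$ph$ctv, w$spec, w$dd)
  pb <- simulate_pb_like(w$ph$ct, w$ph$body, w$ph$ctv, w$spec, w$dd)
  expect_true(all(is.finite(mc$values)) && min(mc$values) >= 0)
  ## CTV median normalization
  expect_equal(median(mc$values[w$ph$ctv$values > 0.5]), 2)
  ## voxelwise PB/MC agreement away from lateral field edges: compare on
  ## the central axis column where no heterogeneity exists
  ci <- dim(mc$values) %/% 2L
  ax_mc <- mc$values[ci[1] + 1, ci[2] + 1, ]
  ax_pb <- pb$values[ci[1] + 1, ci[2] + 1, ]
  expect_lt(max(abs(ax_mc - ax_pb)) / max(ax_mc), 0.03)
  ## dose outside the aperture (beyond 5 sigma laterally) is < 1% of plateau
  far <- mc$values[1:2, , ]
  expect_lt(max(far) / max(mc$values), 0.01)
})

test_that("an air gap on the axis deepens the distal range by its thickness", {
  w <- water_beam(hw = 12)
  mc0 <- simulate_mc_like(w$ph$ct, w$ph$body, w$ph$ctv, w$spec, w$dd)
  ## carve an air slab (2 voxels = 10 mm thick) across the beam path,
  ## proximal of the isocenter (beam travels +RL)
  ct2 <- w$ph$ct
  ci <- dim(ct2$values) %/% 2L
  ks <- (ci[3] - 5):(ci[3] - 4)
  ct2$values[, , ks] <- -1000
  mc1 <- simulate_mc_like(ct2, w$ph$body, w$ph$ctv, w$spec, w$dd)
  rm0 <- range_map(pbmcdose:::to_canonical_grid(
    mc0, beam_geometry(270, 0, w$spec$isocenter, 2),
    canonical_config(shape = dim(mc0$values), spacing_mm = 5), 0), 0.9, 2)
  rm1 <- range_map(pbmcdose:::to_canonical_grid(
    mc1, beam_geometry(270, 0, w$spec$isocenter, 2),
    canonical_config(shape = dim(mc1$values), spacing_mm = 5), 0), 0.9, 2)
  axis_shift <- rm1$ranges[ci[1] + 1, ci[2] + 1] - rm0$ranges[ci[1] + 1, ci[2] + 1]
  gap_wed <- 10 * (1 - hu_to_rsp(-1000))    # thickness x (1 - rsp_air)
  expect_lt(abs(axis_shift - gap_wed), 5)   # within one voxel
})

test_that("PB and MC diverge behind an off-axis air cavity", {
  ph <- make_phantom(phantom_spec(shape = tiny_shape, spacing_mm = 5,
                                  n_air_cavities = 1, n_bone_slabs = 0,
                                  cavity_semi_range = c(9, 12), seed = 21))
  spec <- beam_sim_spec(gantry_deg = 270, couch_deg = 0,
                        isocenter = ph$ctv_center, range_mm = 55, mod_mm = 25,
                        field_halfwidth_mm = 15, prescribed_dose = 2,
                        entrance_sigma_mm = 3, sigma_growth = 0.08,
                        pb_beamlet_width_mm = 20)
  dd <- build_sobp(55, 25, K = 25, sigma_peak = 5, sigma_d = 3)
  mc <- simulate_mc_like(ph$ct, ph$body, ph$ctv, spec, dd)
  pb <- simulate_pb_like(ph$ct, ph$body, ph$ctv, spec, dd)
  g <- gamma_3d(mc, pb, 3, 3, 10, ph$body)
  expect_lt(passing_rate(g), 100)
})

test_that("simulation errors are raised for beams that miss the body", {
  w <- water_beam()
  spec <- w$spec
  spec$isocenter <- c(500, 500, 500)   # far outside the phantom
  expect_error(simulate_mc_like(w$ph$ct, w$ph$body, w$ph$ctv, spec, w$dd),
               "intersect|dose")
})

test_that("WED along rays is nondecreasing and doses are finite/nonnegative", {
  ph <- make_phantom(phantom_spec(shape = tiny_shape, spacing_mm = 5,
                                  n_air_cavities = 2, n_bone_slabs = 1,
                                  cavity_semi_range = c(7, 11), seed = 5))
  spec <- beam_sim_spec(gantry_deg = 120, couch_deg = 15,
                        isocenter = ph$ctv_center, range_mm = 50, mod_mm = 22,
                        field_halfwidth_mm = 12, prescribed_dose = 2)
  dd <- build_sobp(50, 22, K = 25, sigma_peak = 5, sigma_d = 3)
  mc <- simulate_mc_like(ph$ct, ph$body, ph$ctv, spec, dd)
  expect_true(all(is.finite(mc$values)))
  expect_gte(min(mc$values), 0)
})

test_that("dataset bookkeeping: counts, splits, disjoint plans, determinism", {
  opts <- list(sigma_peak = 5, sigma_d = 3, n_air_cavities = 1,
               n_bone_slabs = 1, cavity_semi_range = c(7, 11))
  ds <- make_dataset(5, 2, master_seed = 9, shape = tiny_shape,
                     spacing_mm = 5, beams_per_plan = 3, opts = opts)
  expect_length(ds$beams, 7)
  splits <- vapply(ds$beams, function(b) b$split, "")
  expect_identical(sum(splits == "train"), 5L)
  expect_identical(sum(splits == "test"), 2L)
  train_plans <- unique(vapply(ds$beams[splits == "train"], function(b) b$plan, ""))
  test_plans <- unique(vapply(ds$beams[splits == "test"], function(b) b$plan, ""))
  expect_length(intersect(train_plans, test_plans), 0)
  ds2 <- make_dataset(5, 2, master_seed = 9, shape = tiny_shape,
                      spacing_mm = 5, beams_per_plan = 3, opts = opts)
  expect_identical(ds$beams[[1]]$mc$values, ds2$beams[[1]]$mc$values)
  expect_identical(ds$manifest, ds2$manifest)
})

test_that("about 40% of beams are non-coplanar, in 10-30 degree couch range", {
  o <- pbmcdose:::dataset_opts(tiny_shape, 5)
  ph <- make_phantom(phantom_spec(shape = tiny_shape, spacing_mm = 5,
                                  n_air_cavities = 0, n_bone_slabs = 0,
                                  seed = 2))
  couch <- vapply(1:200, function(i)
    pbmcdose:::draw_beam_spec(o, ph, 1000L + i)$couch_deg, 0)
  frac <- mean(couch != 0)
  expect_gt(frac, 0.4 - 3 * sqrt(0.4 * 0.6 / 200))
  expect_lt(frac, 0.4 + 3 * sqrt(0.4 * 0.6 / 200))
  nz <- couch[couch != 0]
  dev <- pmin(nz, 360 - nz)     # couch magnitude regardless of sign wrap
  expect_true(all(dev >= 10 - 1e-9 & dev <= 30 + 1e-9))
})

test_that("dataset round-trips through the on-disk NRRD/JSON container", {
  opts <- list(sigma_peak = 5, sigma_d = 3, n_air_cavities = 1,
               n_bone_slabs = 0, cavity_semi_range = c(7, 11))
  ds <- make_dataset(2, 1, master_seed = 4, shape = c(8, 12, 12),
                     spacing_mm = 8, beams_per_plan = 2, opts = opts)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  ds2 <- read_dataset(dir)
  expect_length(ds2$beams, 3)
  expect_identical(ds2$beams[[1]]$mc$values, ds$beams[[1]]$mc$values)
  expect_identical(ds2$beams[[2]]$id, ds$beams[[2]]$id)
  expect_equal(ds2$beams[[3]]$beam$gantry_deg, ds$beams[[3]]$beam$gantry_deg)
})
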