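test_that("the canonical beam (gantry 270, couch 0) rotates as the identity", {
  g <- blob_grid(shape = c(12, 16, 16), spacing = 4, sigma = 12)
  beam <- beam_geometry(270, 0, c(0, 0, 0), 2)
  fw <- rotate_about_isocenter(g, beam, "forward")
  expect_lt(max(abs(fw$values - g$values)), 1e-9)
})

test_that("forward/backward rotation round-trips smooth fields on the interior", {
  g <- blob_grid(shape = c(48, 48, 48), spacing = 2, sigma = 14)
  set.seed(11)
  for (t in 1:5) {
    beam <- beam_geometry(runif(1, 0, 360),
                          if (t %% 2) 0 else runif(1, 10, 30) * sample(c(-1, 1), 1),
                          c(0, 0, 0), 2)
    bk <- rotate_about_isocenter(
      rotate_about_isocenter(g, beam, "forward"), beam, "backward")
    d <- dim(g$values)
    err <- max(abs((bk$values - g$values)[3:(d[1] - 2), 3:(d[2] - 2),
                                          3:(d[3] - 2)])) / max(g$values)
    expect_lt(err, 0.02)
  }
})

test_that("rotation maps the beam axis to +RL (slab-field gradient aligns)", {
  beam <- beam_geometry(130, 15, c(0, 0, 0), 2)
  u <- beam_direction(beam)
  expect_equal(sum(u^2), 1)
  shape <- c(32, 40, 40); sp <- 2
  co <- lapply(1:3, function(a) (0:(shape[a] - 1)) * sp - sp * (shape[a] - 1) / 2)
  f <- array(0, shape)
  for (i in seq_len(shape[1])) for (j in seq_len(shape[2]))
    f[i, j, ] <- exp(-(u[1] * co[[1]][i] + u[2] * co[[2]][j] +
                         u[3] * co[[3]])^2 / (2 * 10^2))
  g <- volume_grid(f, rep(sp, 3), sapply(co, `[`, 1))
  fw <- rotate_about_isocenter(g, beam, "forward")
  v <- fw$values
  ctr <- list(8:24, 12:28, 12:28)
  gi <- mean(v[ctr[[1]] + 1, ctr[[2]], ctr[[3]]] - v[ctr[[1]] - 1, ctr[[2]], ctr[[3]]])
  gj <- mean(v[ctr[[1]], ctr[[2]] + 1, ctr[[3]]] - v[ctr[[1]], ctr[[2]] - 1, ctr[[3]]])
  gk <- mean(v[ctr[[1]], ctr[[2]], ctr[[3]] + 1] - v[ctr[[1]], ctr[[2]], ctr[[3]] - 1])
  ang <- acos(abs(gk) / sqrt(gi^2 + gj^2 + gk^2)) * 180 / pi
  expect_lt(ang, 1)
})

test_that("zoom is identity at factor 1, respects its window, and scales volumes", {
  g <- blob_grid(shape = c(24, 24, 24), spacing = 4, sigma = 12)
  z1 <- zoom_about_isocenter(g, 1.0, c(0, 0, 0))
  expect_lt(max(abs(z1$values - g$values)), 1e-9)
  expect_error(zoom_about_isocenter(g, 1.5, c(0, 0, 0)), "0.7")
  expect_error(zoom_about_isocenter(g, 0.5, c(0, 0, 0)), "0.7")
  ## sphere mask of radius 24 mm zoomed by 1.2 -> volume ratio 1.2 within 3%
  co <- lapply(1:3, function(a) (0:23) * 4 - 46)
  r2 <- array(0, c(24, 24, 24))
  for (i in 1:24) for (j in 1:24)
    r2[i, j, ] <- co[[1]][i]^2 + co[[2]][j]^2 + co[[3]]^2
  sph <- volume_grid((r2 <= 24^2) * 1, rep(4, 3), sapply(co, `[`, 1),
                     mask = TRUE)
  zs <- zoom_about_isocenter(sph, 1.2, c(0, 0, 0))
  ratio <- (sum(zs$values) / sum(sph$values))^(1 / 3)
  expect_lt(abs(ratio - 1.2), 0.03)
})

test_that("zoom(1.25) then zoom(0.8) recovers the field on the interior", {
  g <- blob_grid(shape = c(32, 32, 32), spacing = 2, sigma = 10)
  z <- zoom_about_isocenter(zoom_about_isocenter(g, 1.25, c(0, 0, 0)),
                            0.8, c(0, 0, 0))
  d <- dim(g$values)
  err <- max(abs((z$values - g$values)[5:(d[1] - 4), 5:(d[2] - 4),
                                       5:(d[3] - 4)])) / max(g$values)
  expect_lt(err, 0.02)
})

canonical_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ph <- make_phantom(phantom_spec(shape = c(16, 24, 24), spacing_mm = 5,
                                      n_air_cavities = 1, n_bone_slabs = 1,
                                      cavity_semi_range = c(7, 11), seed = 8))
      spec <- beam_sim_spec(gantry_deg = 150, couch_deg = -20,
                            isocenter = ph$ctv_center, range_mm = 50,
                            mod_mm = 22, field_halfwidth_mm = 14,
                            prescribed_dose = 2, sigma_growth = 0.08,
                            pb_beamlet_width_mm = 20)
      dd <- build_sobp(50, 22, K = 25, sigma_peak = 5, sigma_d = 3)
      cache <<- list(
        ph = ph,
        beam = beam_geometry(150, -20, ph$ctv_center, 2),
        mc = simulate_mc_like(ph$ct, ph$body, ph$ctv, spec, dd),
        pb = simulate_pb_like(ph$ct, ph$body, ph$ctv, spec, dd))
    }
    cache
  }
})

test_that("canonicalization normalizes, centers the isocenter, and windows CT", {
  fx <- canonical_fixture()
  cfg <- canonical_config(shape = c(16, 24, 24), spacing_mm = 5)
  s <- to_canonical(fx$ph$ct, fx$pb, fx$mc, fx$beam, cfg,
                    body = fx$ph$body, ctv = fx$ph$ctv)
  expect_identical(max(s$pb_norm), 1)
  expect_true(all(s$ct_norm >= 0 & s$ct_norm <= 1))
  ## the isocenter maps to the center voxel: CTV mass sits at the center
  ci <- cfg$shape %/% 2L
  expect_equal(s$ctv[ci[1] + 1, ci[2] + 1, ci[3] + 1], 1)
  ## uniform 0 HU body: the dominant tissue value is 1000/3000 (air and
  ## interpolated boundary voxels excluded)
  tissue <- s$ct_norm[s$ct_norm > 0.1]
  mode_val <- as.numeric(names(which.max(table(round(tissue, 4)))))
  expect_equal(mode_val, round(1 / 3, 4))
  ## degenerate beam: all-zero PB
  zero_pb <- volume_grid(fx$pb$values * 0, fx$pb$spacing, fx$pb$origin)
  expect_error(to_canonical(fx$ph$ct, zero_pb, NULL, fx$beam, cfg),
               "degenerate")
})

test_that("from_canonical inverts to_canonical within interpolation tolerance", {
  fx <- canonical_fixture()
  cfg <- canonical_config(shape = c(16, 24, 24), spacing_mm = 5)
  s <- to_canonical(fx$ph$ct, fx$pb, fx$mc, fx$beam, cfg)
  back <- from_canonical(s$pb_norm, s, fx$pb)
  ## compare where the back-rotated crop support covers the dose
  sel <- fx$pb$values > 0.05 * max(fx$pb$values) & back$values > 0
  err <- max(abs(back$values[sel] - fx$pb$values[sel])) / max(fx$pb$values)
  expect_lt(err, 0.05)
  ## linearity and scaling contracts
  zero <- from_canonical(s$pb_norm * 0, s, fx$pb)
  expect_true(all(zero$values == 0))
  expect_error(from_canonical(array(0, c(4, 4, 4)), s, fx$pb), "shape")
})

test_that("zoom augmentation multiplies counts and leaves originals untouched", {
  fx <- canonical_fixture()
  cfg <- canonical_config(shape = c(16, 24, 24), spacing_mm = 5)
  s <- to_canonical(fx$ph$ct, fx$pb, fx$mc, fx$beam, cfg)
  aug <- augment_training_set(list(s, s), factors = c(0.8, 1.2))
  expect_length(aug, 6)
  expect_identical(aug[[1]]$pb_norm, s$pb_norm)    # originals bitwise equal
  expect_identical(aug[[1]]$mc_norm, s$mc_norm)
  expect_identical(max(aug[[3]]$pb_norm), 1)       # zoomed copies renormalized
  expect_identical(aug[[3]]$zoom, 0.8)
  expect_identical(augment_training_set(list(s), factors = NULL), list(s))
})
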