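# Shared fixtures and independent oracles for the test suite.

## Smooth compact Gaussian blob on a centered grid (world center 0).
blob_grid <- function(shape = c(24, 32, 32), spacing = 4, sigma = 14,
                      center = c(0, 0, 0)) {
  co <- lapply(1:3, function(a) (0:(shape[a] - 1)) * spacing -
                 spacing * (shape[a] - 1) / 2)
  v <- array(0, shape)
  for (i in seq_len(shape[1]))
    for (j in seq_len(shape[2]))
      v[i, j, ] <- exp(-((co[[1]][i] - center[1])^2 +
                         (co[[2]][j] - center[2])^2 +
                         (co[[3]] - center[3])^2) / (2 * sigma^2))
  volume_grid(v, rep(spacing, 3), sapply(co, `[`, 1))
}

## Small smooth canonical samples for network tests (Gaussian "doses").
toy_sample <- function(seed, shape = c(8, 8, 8), identity_target = FALSE) {
  set.seed(seed)
  co <- lapply(shape, function(n) seq(-1, 1, length.out = n))
  ctr <- runif(3, -0.3, 0.3); w <- runif(1, 0.3, 0.6)
  f <- array(0, shape)
  for (i in seq_len(shape[1]))
    for (j in seq_len(shape[2]))
      f[i, j, ] <- exp(-((co[[1]][i] - ctr[1])^2 + (co[[2]][j] - ctr[2])^2 +
                           (co[[3]] - ctr[3])^2) / w^2)
  pb <- f / max(f)
  structure(list(ct_norm = f * 0.5 + 0.2, pb_norm = pb,
                 mc_norm = if (identity_target) pb else
                   0.85 * pb + 0.1 * (f * 0.5 + 0.2)),
            class = "canonical_sample")
}

## Brute-force gamma oracle: dense exhaustive minimization over the
## dta/3 candidate lattice within radius 3*dta, evaluated dose trilinearly
## interpolated in plain R.  Independent of the C++ search kernel.
oracle_gamma <- function(reference, evaluated, dose_pct, dta, threshold_pct,
                         mask = NULL) {
  d <- dim(reference$values)
  sp <- reference$spacing
  m <- if (is.null(mask)) array(TRUE, d) else mask$values > 0.5
  norm_dose <- max(reference$values[m])
  dd_abs <- dose_pct / 100 * norm_dose
  thr <- threshold_pct / 100 * norm_dose
  step <- dta / 3; r_steps <- ceiling(3 * dta / step)
  off1 <- (-r_steps:r_steps) * step
  offs <- as.matrix(expand.grid(off1, off1, off1))
  keep <- rowSums(offs^2) <= (3 * dta)^2 + 1e-9
  offs <- offs[keep, , drop = FALSE]
  d2 <- rowSums(offs^2)

  interp <- function(x, y, z) {
    ## trilinear interpolation of evaluated at continuous 0-based coords
    i0 <- pmax(pmin(floor(x), d[1] - 2), 0)
    j0 <- pmax(pmin(floor(y), d[2] - 2), 0)
    k0 <- pmax(pmin(floor(z), d[3] - 2), 0)
    fx <- x - i0; fy <- y - j0; fz <- z - k0
    v <- evaluated$values
    g <- function(a, b, cc) v[cbind(a + 1, b + 1, cc + 1)]
    (g(i0, j0, k0) * (1 - fx) + g(i0 + 1, j0, k0) * fx) * (1 - fy) * (1 - fz) +
      (g(i0, j0 + 1, k0) * (1 - fx) + g(i0 + 1, j0 + 1, k0) * fx) * fy * (1 - fz) +
      (g(i0, j0, k0 + 1) * (1 - fx) + g(i0 + 1, j0, k0 + 1) * fx) * (1 - fy) * fz +
      (g(i0, j0 + 1, k0 + 1) * (1 - fx) + g(i0 + 1, j0 + 1, k0 + 1) * fx) * fy * fz
  }

  out <- array(NA_real_, d)
  idx <- which(m & reference$values >= thr, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    vox <- idx[r, ] - 1
    dref <- reference$values[idx[r, 1], idx[r, 2], idx[r, 3]]
    x <- vox[1] + offs[, 1] / sp[1]
    y <- vox[2] + offs[, 2] / sp[2]
    z <- vox[3] + offs[, 3] / sp[3]
    ok <- x >= 0 & x <= d[1] - 1 & y >= 0 & y <= d[2] - 1 &
      z >= 0 & z <= d[3] - 1
    de <- interp(x[ok], y[ok], z[ok])
    g2 <- (de - dref)^2 / dd_abs^2 + d2[ok] / dta^2
    out[idx[r, 1], idx[r, 2], idx[r, 3]] <- sqrt(min(g2))
  }
  out
}

## Connected-component count (6-connectivity) by BFS flood fill.
count_components <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  n <- 0L
  nb <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
              c(0, 0, 1), c(0, 0, -1))
  todo <- which(mask & lab == 0L)
  for (s in todo) {
    if (lab[s] != 0L) next
    n <- n + 1L
    queue <- s
    lab[s] <- n
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      ci <- arrayInd(cur, d)
      for (q in 1:6) {
        p <- ci + nb[q, ]
        if (any(p < 1) || any(p > d)) next
        if (mask[p[1], p[2], p[3]] && lab[p[1], p[2], p[3]] == 0L) {
          lab[p[1], p[2], p[3]] <- n
          queue <- c(queue, (p[3] - 1) * d[1] * d[2] + (p[2] - 1) * d[1] + p[1])
        }
      }
    }
  }
  n
}

## Mean dose-gradient direction of a canonical-frame beam: average gradient
## over mid-dose voxels; lateral penumbra gradients cancel by symmetry so
## the mean aligns with the beam axis.
beam_axis_angle_deg <- function(dose_grid) {
  v <- dose_grid$values
  d <- dim(v)
  i <- 2:(d[1] - 1); j <- 2:(d[2] - 1); k <- 2:(d[3] - 1)
  gi <- v[i + 1, j, k] - v[i - 1, j, k]
  gj <- v[i, j + 1, k] - v[i, j - 1, k]
  gk <- v[i, j, k + 1] - v[i, j, k - 1]
  sel <- v[i, j, k] > 0.2 * max(v) & v[i, j, k] < 0.8 * max(v)
  g <- c(mean(gi[sel]), mean(gj[sel]), mean(gk[sel]))
  acos(abs(g[3]) / sqrt(sum(g^2))) * 180 / pi
}
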