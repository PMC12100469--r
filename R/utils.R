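# Small internal helpers shared across modules.

## Evaluate expr with a temporarily seeded RNG, restoring caller state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

## Deterministic sub-seed derivation (LCG step), kept below 2^31.
derive_seed <- function(master, index) {
  as.integer((as.numeric(master) * 48271 + as.numeric(index) * 16807) %% 2147483629)
}

## Truncated-window running mean of width w (voxels) along the rows of a
## matrix; edges use the available part of the window.
running_mean_rows <- function(m, w) {
  if (w <= 1) return(m)
  n <- nrow(m)
  h1 <- (w - 1L) %/% 2L
  h2 <- w - 1L - h1
  cs <- rbind(0, apply(m, 2, cumsum))
  lo <- pmax(seq_len(n) - h1, 1L)
  hi <- pmin(seq_len(n) + h2, n)
  (cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]) / (hi - lo + 1L)
}

## Separable 2D Gaussian blur of a matrix, sigma in voxels; edge-truncated
## kernels are renormalized so a constant field stays constant.
gauss_blur_mat <- function(m, sigma) {
  if (sigma <= 1e-8) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  blur1 <- function(x) {   # along rows
    n <- nrow(x)
    acc <- matrix(0, n, ncol(x)); wt <- numeric(n)
    for (s in (-r):r) {
      src <- (1:n) - s
      ok <- src >= 1 & src <= n
      acc[ok, ] <- acc[ok, ] + k[s + r + 1] * x[src[ok], , drop = FALSE]
      wt[ok] <- wt[ok] + k[s + r + 1]
    }
    acc / wt
  }
  t(blur1(t(blur1(m))))
}

## Separable 3D Gaussian smoothing of an array, sigma in voxels per axis.
gauss_smooth_3d <- function(arr, sigma) {
  d <- dim(arr)
  sigma <- rep(sigma, length.out = 3)
  for (ax in 1:3) {
    if (sigma[ax] <= 1e-8) next
    perm <- c(ax, setdiff(1:3, ax))
    a <- aperm(arr, perm)
    dd <- dim(a)
    dim(a) <- c(dd[1], dd[2] * dd[3])
    r <- max(1L, ceiling(3 * sigma[ax]))
    k <- exp(-((-r):r)^2 / (2 * sigma[ax]^2))
    n <- nrow(a)
    acc <- matrix(0, n, ncol(a)); wt <- numeric(n)
    for (s in (-r):r) {
      src <- (1:n) - s
      ok <- src >= 1 & src <= n
      acc[ok, ] <- acc[ok, ] + k[s + r + 1] * a[src[ok], , drop = FALSE]
      wt[ok] <- wt[ok] + k[s + r + 1]
    }
    a <- acc / wt
    dim(a) <- dd
    arr <- aperm(a, order(perm))
  }
  arr
}

## Lawson-Hanson nonnegative least squares (no NNLS package installed).
nnls_lh <- function(A, b, tol = 1e-10) {
  n <- ncol(A)
  P <- logical(n)
  x <- numeric(n)
  w <- drop(crossprod(A, b - A %*% x))
  iter <- 0
  while (any(!P) && max(w[!P]) > tol && iter < 30 * n) {
    iter <- iter + 1
    cand <- which(!P)
    P[cand[which.max(w[cand])]] <- TRUE
    repeat {
      s <- numeric(n)
      s[P] <- qr.coef(qr(A[, P, drop = FALSE]), b)
      s[is.na(s)] <- 0
      if (all(s[P] > tol)) { x <- s; break }
      q <- which(P & s <= tol)
      alpha <- min(x[q] / (x[q] - s[q]))
      x <- x + alpha * (s - x)
      P[P & x <= tol] <- FALSE
      x[!P] <- 0
    }
    w <- drop(crossprod(A, b - A %*% x))
  }
  x
}
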