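#' Volumetric scalar grid
#'
#' The core container for CT volumes (HU), dose grids (GyRBE) and binary
#' masks.  A `volume_grid` is a 3D array plus geometry: per-axis voxel
#' spacing (mm) and the world position (mm) of the *center* of voxel
#' `(0,0,0)`.  The axis convention is fixed package-wide: index axis 1 is
#' patient superior--inferior (SI), axis 2 anterior--posterior (AP) and
#' axis 3 right--left (RL).  World coordinates use the same (SI, AP, RL)
#' order, in mm.
#'
#' @param values numeric 3D array.  For masks, only values 0 and 1.
#' @param spacing numeric length-3, voxel spacing in mm; strictly positive.
#' @param origin numeric length-3, world coordinates (mm) of the center of
#'   voxel `(0,0,0)`.
#' @param mask logical; if `TRUE` the values are checked to be in `{0,1}`.
#' @return an object of class `volume_grid`.
#' @export
volume_grid <- function(values, spacing, origin = c(0, 0, 0), mask = FALSE) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("'values' must be a 3D array")
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("invalid 'spacing': must be 3 strictly positive finite numbers")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("invalid 'origin': must be 3 finite numbers")
  if (any(!is.finite(values)))
    stop("invalid 'values': non-finite entries")
  if (mask && !all(values %in% c(0, 1)))
    stop("invalid mask 'values': entries outside {0,1}")
  structure(list(values = values, spacing = spacing, origin = origin,
                 mask = isTRUE(mask)),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("volume_grid %dx%dx%d (SI,AP,RL), spacing %s mm, origin %s mm%s\n",
              d[1], d[2], d[3],
              paste(format(x$spacing), collapse = "x"),
              paste(format(x$origin), collapse = ", "),
              if (x$mask) ", mask" else ""))
  cat(sprintf("  value range [%g, %g]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' @export
dim.volume_grid <- function(x) dim(x$values)

#' Beam delivery geometry
#'
#' Gantry and couch angle (degrees, normalized to `[0, 360)`), isocenter in
#' world mm (SI, AP, RL), and the per-beam prescribed dose in GyRBE.  The
#' geometry defines the canonicalization rotation that maps the beam to the
#' reference direction (gantry 270 degrees, couch 0).
#'
#' @param gantry_deg,couch_deg angles in degrees (any real; normalized mod 360).
#' @param isocenter world position, mm, length 3.
#' @param prescribed_dose GyRBE, strictly positive.
#' @return an object of class `beam_geometry`.
#' @export
beam_geometry <- function(gantry_deg, couch_deg = 0, isocenter = c(0, 0, 0),
                          prescribed_dose = 2) {
  isocenter <- as.numeric(isocenter)
  if (length(isocenter) != 3L || any(!is.finite(isocenter)))
    stop("invalid 'isocenter'")
  if (!is.finite(prescribed_dose) || prescribed_dose <= 0)
    stop("'prescribed_dose' must be > 0")
  structure(list(gantry_deg = as.numeric(gantry_deg) %% 360,
                 couch_deg = as.numeric(couch_deg) %% 360,
                 isocenter = isocenter,
                 prescribed_dose = as.numeric(prescribed_dose)),
            class = "beam_geometry")
}

#' World/voxel coordinate transforms
#'
#' Voxel indices are 0-based and continuous; index `(0,0,0)` maps to
#' `grid$origin`.  Points may fall outside the array: indices may then be
#' negative or exceed the shape.
#'
#' @param grid a [volume_grid].
#' @param points numeric length-3 vector or n-by-3 matrix of world mm
#'   (for `world_to_voxel`) or continuous voxel indices (for
#'   `voxel_to_world`).
#' @return matrix (or vector, matching the input) of the converted
#'   coordinates.
#' @export
world_to_voxel <- function(grid, points) {
  p <- if (is.matrix(points)) points else matrix(points, ncol = 3)
  out <- sweep(sweep(p, 2, grid$origin, "-"), 2, grid$spacing, "/")
  if (is.matrix(points)) out else drop(out)
}

#' @rdname world_to_voxel
#' @export
voxel_to_world <- function(grid, points) {
  p <- if (is.matrix(points)) points else matrix(points, ncol = 3)
  out <- sweep(sweep(p, 2, grid$spacing, "*"), 2, grid$origin, "+")
  if (is.matrix(points)) out else drop(out)
}

## 0-based voxel index triples for every element of a (n1,n2,n3) array,
## in R's column-major storage order.
grid_index_table <- function(shape) {
  n1 <- shape[1]; n2 <- shape[2]; n3 <- shape[3]
  cbind(rep.int(0:(n1 - 1), n2 * n3),
        rep.int(rep(0:(n2 - 1), each = n1), n3),
        rep(0:(n3 - 1), each = n1 * n2))
}

## Catmull-Rom cubic kernel weights for fractional offset f in [0,1):
## taps at -1, 0, +1, +2.
catmull_weights <- function(f) {
  f2 <- f * f; f3 <- f2 * f
  cbind(-0.5 * f3 + f2 - 0.5 * f,
        1.5 * f3 - 2.5 * f2 + 1,
        -1.5 * f3 + 2 * f2 + 0.5 * f,
        0.5 * f3 - 0.5 * f2)
}

## Sample grid values at continuous 0-based voxel coordinates (n x 3).
## method "linear" = trilinear, "cubic" = separable Catmull-Rom (sharper,
## used for dose resampling; may overshoot, so callers clamp), "nearest"
## for masks.  Points outside the support box [0, dim-1] return `fill`.
sample_at_voxel <- function(grid, idx, fill = 0,
                            method = c("linear", "nearest", "cubic")) {
  method <- match.arg(method)
  v <- grid$values
  d <- dim(v)
  ok <- idx[, 1] >= 0 & idx[, 1] <= d[1] - 1 &
        idx[, 2] >= 0 & idx[, 2] <= d[2] - 1 &
        idx[, 3] >= 0 & idx[, 3] <= d[3] - 1
  out <- rep(as.numeric(fill), nrow(idx))
  if (!any(ok)) return(out)
  ix <- idx[ok, , drop = FALSE]
  if (method == "nearest") {
    i0 <- pmin(pmax(round(ix[, 1]), 0), d[1] - 1)
    j0 <- pmin(pmax(round(ix[, 2]), 0), d[2] - 1)
    k0 <- pmin(pmax(round(ix[, 3]), 0), d[3] - 1)
    out[ok] <- v[1 + i0 + d[1] * (j0 + d[2] * k0)]
    return(out)
  }
  if (method == "cubic") {
    i0 <- floor(ix[, 1]); j0 <- floor(ix[, 2]); k0 <- floor(ix[, 3])
    wi <- catmull_weights(ix[, 1] - i0)
    wj <- catmull_weights(ix[, 2] - j0)
    wk <- catmull_weights(ix[, 3] - k0)
    acc <- 0
    for (ck in 1:4) {
      kq <- pmin(pmax(k0 + ck - 2, 0), d[3] - 1)
      for (cj in 1:4) {
        jq <- pmin(pmax(j0 + cj - 2, 0), d[2] - 1)
        wjk <- wj[, cj] * wk[, ck]
        for (ci in 1:4) {
          iq <- pmin(pmax(i0 + ci - 2, 0), d[1] - 1)
          acc <- acc + v[1 + iq + d[1] * (jq + d[2] * kq)] * wi[, ci] * wjk
        }
      }
    }
    out[ok] <- acc
    return(out)
  }
  i0 <- floor(ix[, 1]); j0 <- floor(ix[, 2]); k0 <- floor(ix[, 3])
  fi <- ix[, 1] - i0;   fj <- ix[, 2] - j0;   fk <- ix[, 3] - k0
  ## clamp the upper corner so points exactly on the far face stay in range
  i1 <- pmin(i0 + 1, d[1] - 1); j1 <- pmin(j0 + 1, d[2] - 1); k1 <- pmin(k0 + 1, d[3] - 1)
  lin <- function(i, j, k) v[1 + i + d[1] * (j + d[2] * k)]
  acc <- lin(i0, j0, k0) * (1 - fi) * (1 - fj) * (1 - fk) +
         lin(i1, j0, k0) * fi       * (1 - fj) * (1 - fk) +
         lin(i0, j1, k0) * (1 - fi) * fj       * (1 - fk) +
         lin(i1, j1, k0) * fi       * fj       * (1 - fk) +
         lin(i0, j0, k1) * (1 - fi) * (1 - fj) * fk +
         lin(i1, j0, k1) * fi       * (1 - fj) * fk +
         lin(i0, j1, k1) * (1 - fi) * fj       * fk +
         lin(i1, j1, k1) * fi       * fj       * fk
  out[ok] <- acc
  out
}

## Resample src onto an explicit target lattice after mapping each target
## world point through `map_world` (NULL = identity).  This is the single
## interpolation primitive behind plain resampling, rotation and zoom, so
## composed transforms interpolate only once.
resample_transformed <- function(src, target_spacing, target_shape, target_origin,
                                 map_world = NULL, fill = 0,
                                 method = c("linear", "nearest", "cubic")) {
  method <- match.arg(method)
  target_spacing <- as.numeric(target_spacing)
  target_shape <- as.integer(target_shape)
  if (any(target_spacing <= 0) || any(target_shape <= 0))
    stop("target spacing and shape must be strictly positive")
  idx <- grid_index_table(target_shape)
  w <- sweep(sweep(idx, 2, target_spacing, "*"), 2, as.numeric(target_origin), "+")
  if (!is.null(map_world)) w <- map_world(w)
  src_idx <- sweep(sweep(w, 2, src$origin, "-"), 2, src$spacing, "/")
  vals <- sample_at_voxel(src, src_idx, fill = fill, method = method)
  volume_grid(array(vals, dim = target_shape), target_spacing,
              as.numeric(target_origin), mask = src$mask)
}

#' Resample a grid onto a new lattice
#'
#' Trilinear interpolation of the values onto the requested target lattice
#' (`"nearest"` for masks); voxels outside the source support take `fill`.
#' Output metadata equals the requested target exactly.
#'
#' @param grid a [volume_grid].
#' @param spacing,shape,origin target lattice (mm / voxels / mm).  Defaults
#'   reuse the source geometry.
#' @param fill scalar for out-of-support voxels (-1000 for CT, 0 for dose
#'   and masks).
#' @param method `"linear"` or `"nearest"`.
#' @return a [volume_grid] on the target lattice.
#' @export
resample <- function(grid, spacing = grid$spacing, shape = dim(grid$values),
                     origin = grid$origin, fill = 0,
                     method = if (grid$mask) "nearest" else "linear") {
  resample_transformed(grid, spacing, shape, origin, NULL, fill, method)
}

# ---------------------------------------------------------------------------
# NRRD I/O.  Minimal NRRD0004 subset: 3-D, type double or uint8, encodings
# raw (little endian) or ascii, per-axis "spacings" and "axis mins" (= world
# coordinate of the first voxel center).  No installed package reads NRRD,
# so the parser lives here; raw round-trips are bit exact.
# ---------------------------------------------------------------------------

#' Read / write volumes as NRRD
#'
#' `write_volume` stores a [volume_grid] as NRRD (attached header; encoding
#' `"raw"` little-endian doubles, or `"ascii"` for small text fixtures).
#' `read_volume` reads it back; a raw round-trip preserves values
#' bit-exactly and geometry to better than 1e-6 mm.  Invalid headers
#' (non-positive spacing, inconsistent sizes) and, when `mask = TRUE`,
#' values outside `{0,1}` raise errors naming the offending field.
#'
#' @param grid a [volume_grid].
#' @param path file path ending in `.nrrd`.
#' @param encoding `"raw"` or `"ascii"`.
#' @param mask logical; require and mark a `{0,1}` mask volume.
#' @return `read_volume` returns a [volume_grid]; `write_volume` returns
#'   `path` invisibly.
#' @export
write_volume <- function(grid, path, encoding = c("raw", "ascii")) {
  encoding <- match.arg(encoding)
  if (!grepl("\\.nrrd$", path, ignore.case = TRUE))
    stop("unsupported volume format: expected a .nrrd path, got ", path)
  d <- dim(grid$values)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("NRRD0004",
           "# pbmcdose volume",
           "type: double",
           "dimension: 3",
           paste("sizes:", paste(d, collapse = " ")),
           paste("spacings:", paste(format(grid$spacing, digits = 17), collapse = " ")),
           paste("axis mins:", paste(format(grid$origin, digits = 17), collapse = " ")),
           paste("encoding:", encoding),
           if (encoding == "raw") "endian: little",
           paste("content:", if (grid$mask) "mask" else "volume"),
           "")
  writeLines(hdr, con, sep = "\n")
  if (encoding == "raw") {
    writeBin(as.numeric(grid$values), con, size = 8, endian = "little")
  } else {
    writeLines(paste(format(as.numeric(grid$values), digits = 17),
                     collapse = "\n"), con)
  }
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path, mask = FALSE) {
  if (!grepl("\\.nrrd$", path, ignore.case = TRUE))
    stop("unsupported volume format: expected a .nrrd path, got ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1)
  if (!grepl("^NRRD", magic)) stop("corrupt header: missing NRRD magic in ", path)
  fields <- list()
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0) stop("corrupt header: no blank line terminator")
    if (line == "") break
    if (grepl("^#", line)) next
    kv <- regmatches(line, regexec("^([^:]+): *(.*)$", line))[[1]]
    if (length(kv) == 3) fields[[tolower(kv[2])]] <- kv[3]
  }
  need <- function(key) {
    if (is.null(fields[[key]])) stop("corrupt header: missing field '", key, "'")
    fields[[key]]
  }
  if (need("type") != "double") stop("unsupported type field: ", fields$type)
  sizes <- as.integer(strsplit(need("sizes"), " +")[[1]])
  if (length(sizes) != 3 || any(is.na(sizes)) || any(sizes <= 0))
    stop("invalid field 'sizes': ", fields$sizes)
  spacing <- as.numeric(strsplit(need("spacings"), " +")[[1]])
  if (length(spacing) != 3 || any(is.na(spacing)) || any(spacing <= 0))
    stop("invalid field 'spacings': ", fields$spacings)
  origin <- if (is.null(fields[["axis mins"]])) c(0, 0, 0) else
    as.numeric(strsplit(fields[["axis mins"]], " +")[[1]])
  n <- prod(sizes)
  enc <- need("encoding")
  vals <- if (enc == "raw") {
    readBin(con, "double", n = n, size = 8, endian = "little")
  } else if (enc == "ascii") {
    as.numeric(scan(con, what = character(), n = n, quiet = TRUE))
  } else stop("unsupported field 'encoding': ", enc)
  if (length(vals) != n) stop("corrupt data: expected ", n, " values, got ", length(vals))
  want_mask <- mask || identical(fields[["content"]], "mask")
  if (mask && !all(vals %in% c(0, 1)))
    stop("invalid mask values: entries outside {0,1} in ", path)
  volume_grid(array(vals, dim = sizes), spacing, origin, mask = want_mask)
}
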