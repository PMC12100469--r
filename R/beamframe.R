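# Beam-frame preprocessing: rotate each beam's CT and dose about the
# isocenter into the canonical gantry/couch frame (gantry 270, couch 0),
# zoom augmentation, crop/normalize to the model tensor, and the inverse
# mapping for model output.

deg2rad <- function(d) d * pi / 180

## Rotation about the SI axis (axis 1): rotates the AP-RL plane.
rot_si <- function(alpha_deg) {
  a <- deg2rad(alpha_deg)
  matrix(c(1, 0, 0,
           0, cos(a), sin(a),
           0, -sin(a), cos(a)), 3, 3)
}

## Rotation about the AP axis (axis 2): rotates the RL-SI plane.
rot_ap <- function(beta_deg) {
  b <- deg2rad(beta_deg)
  matrix(c(cos(b), 0, -sin(b),
           0, 1, 0,
           sin(b), 0, cos(b)), 3, 3)
}

#' Canonicalization rotation matrix for a beam
#'
#' The forward map takes native patient-frame content to the canonical
#' beam frame: it first undoes the couch rotation (about the AP axis
#' through the isocenter), then the gantry offset from 270 degrees (about
#' the SI axis).  The canonical beam direction is +RL (the beam travels
#' from the patient's right to left at gantry 270, couch 0).
#'
#' @param beam a [beam_geometry].
#' @return 3x3 rotation matrix `R` such that `R %*% beam_direction(beam)`
#'   is the +RL unit vector.
#' @export
canonical_rotation <- function(beam) {
  rot_si(-(beam$gantry_deg - 270)) %*% rot_ap(-beam$couch_deg)
}

#' @rdname canonical_rotation
#' @export
beam_direction <- function(beam) {
  drop(t(canonical_rotation(beam)) %*% c(0, 0, 1))
}

#' Rotate a volume about the beam isocenter
#'
#' `direction = "forward"` rotates native content into the canonical beam
#' frame (beam along +RL); `"backward"` applies the exact inverse
#' composition.  The result lives on the *same* lattice as the input;
#' out-of-support regions take `fill`.  The isocenter voxel value is
#' invariant up to interpolation tolerance.
#'
#' @param grid a [volume_grid].
#' @param beam a [beam_geometry].
#' @param direction `"forward"` or `"backward"`.
#' @param fill out-of-support fill value (-1000 for CT, 0 for dose/masks).
#' @param method interpolation; defaults to trilinear, nearest for masks.
#' @return a [volume_grid] on the input lattice.
#' @export
rotate_about_isocenter <- function(grid, beam,
                                   direction = c("forward", "backward"),
                                   fill = 0,
                                   method = if (grid$mask) "nearest" else "linear") {
  direction <- match.arg(direction)
  R <- canonical_rotation(beam)
  ## out(x) = in(Rinv (x - iso) + iso); for backward the content rotation
  ## is R^-1 so we sample through R.
  M <- if (direction == "forward") t(R) else R
  iso <- beam$isocenter
  map <- function(w) sweep(sweep(w, 2, iso, "-") %*% t(M), 2, iso, "+")
  resample_transformed(grid, grid$spacing, dim(grid$values), grid$origin,
                       map, fill, method)
}

#' Zoom a volume about the isocenter
#'
#' Isotropic scaling of the *content* by `factor` about the isocenter, onto
#' the same lattice (spacing metadata unchanged); values are not rescaled.
#' A sphere of radius r becomes a sphere of radius `factor * r`.
#'
#' @param grid a [volume_grid].
#' @param factor zoom factor in the explored window `[0.7, 1.3]`.
#' @param isocenter world mm; the fixed point of the scaling.
#' @param fill,method as in [rotate_about_isocenter].
#' @return a [volume_grid] on the input lattice.
#' @export
zoom_about_isocenter <- function(grid, factor, isocenter,
                                 fill = 0,
                                 method = if (grid$mask) "nearest" else "linear") {
  if (!is.finite(factor) || factor < 0.7 || factor > 1.3)
    stop("zoom 'factor' must lie in [0.7, 1.3], got ", factor)
  iso <- as.numeric(isocenter)
  map <- function(w) sweep(sweep(w, 2, iso, "-") / factor, 2, iso, "+")
  resample_transformed(grid, grid$spacing, dim(grid$values), grid$origin,
                       map, fill, method)
}

#' Canonical tensor configuration
#'
#' Geometry and normalization settings for the model tensor: shape
#' (divisible by `2^(n_levels-1)` of the network), isotropic spacing, the
#' fixed HU window mapped to `[0,1]`, and whether beams are rotated into
#' the canonical frame (`rotate = FALSE` gives the ablation baseline that
#' feeds beams at their native angles).
#'
#' @param shape tensor shape in voxels (SI, AP, RL).
#' @param spacing_mm isotropic voxel size, mm.
#' @param hu_window CT window (HU) mapped linearly onto `[0, 1]`, clamped.
#' @param rotate logical; apply the canonical beam-frame rotation.
#' @export
canonical_config <- function(shape = c(96, 160, 160), spacing_mm = 2,
                             hu_window = c(-1000, 2000), rotate = TRUE) {
  shape <- as.integer(shape)
  if (length(shape) != 3 || any(shape <= 0)) stop("invalid tensor 'shape'")
  if (spacing_mm <= 0) stop("'spacing_mm' must be > 0")
  list(shape = shape, spacing = rep(spacing_mm, 3),
       hu_window = as.numeric(hu_window), rotate = isTRUE(rotate))
}

canonical_origin <- function(config, beam) {
  beam$isocenter - config$spacing * (config$shape %/% 2L)
}

## One-interpolation transform of a native grid onto the canonical tensor
## lattice (rotation and crop composed into a single resampling).
to_canonical_grid <- function(grid, beam, config, fill,
                              method = if (grid$mask) "nearest" else "linear") {
  map <- NULL
  if (config$rotate) {
    R <- canonical_rotation(beam)
    iso <- beam$isocenter
    map <- function(w) sweep(sweep(w, 2, iso, "-") %*% R, 2, iso, "+")
  }
  resample_transformed(grid, config$spacing, config$shape,
                       canonical_origin(config, beam), map, fill, method)
}

#' Canonicalize a beam sample for the network
#'
#' Forward-rotates CT, PB dose and (optionally) MC dose and masks into the
#' canonical beam frame, crops the configured tensor shape centered on the
#' isocenter (the isocenter maps to voxel `shape %/% 2`), rescales the CT
#' through the configured HU window to `[0,1]`, and divides both doses by
#' the maximum of the cropped PB dose (`pb_max`), so that
#' `max(pb_norm) == 1` exactly.  The MC dose deliberately keeps the PB
#' normalization constant so the network can learn amplitude differences.
#'
#' @param ct,pb [volume_grid]s sharing a world frame; `mc`, `body`, `ctv`
#'   optional.
#' @param beam a [beam_geometry].
#' @param config a [canonical_config].
#' @return an object of class `canonical_sample` with fields `ct_norm`,
#'   `pb_norm`, `mc_norm` (or NULL), `pb_max`, `beam`, `config`, plus
#'   canonical `body`/`ctv` mask arrays when supplied.
#' @export
to_canonical <- function(ct, pb, mc = NULL, beam, config = canonical_config(),
                         body = NULL, ctv = NULL) {
  ct_c <- to_canonical_grid(ct, beam, config, fill = -1000)
  ## doses use Catmull-Rom resampling (sharper distal edges than trilinear);
  ## overshoot is clamped to nonnegative
  pb_c <- to_canonical_grid(pb, beam, config, fill = 0, method = "cubic")
  pb_c$values <- pmax(pb_c$values, 0)
  pb_max <- max(pb_c$values)
  if (!is.finite(pb_max) || pb_max <= 0)
    stop("degenerate beam: cropped PB dose has no positive values")
  w <- config$hu_window
  ct_norm <- pmin(pmax((ct_c$values - w[1]) / (w[2] - w[1]), 0), 1)
  pb_norm <- pb_c$values / pb_max
  pb_norm[arrayInd(which.max(pb_norm), dim(pb_norm))] <- 1  # exact unit max
  out <- list(ct_norm = ct_norm, pb_norm = pb_norm,
              mc_norm = if (!is.null(mc))
                pmax(to_canonical_grid(mc, beam, config, fill = 0,
                                       method = "cubic")$values, 0) / pb_max,
              pb_max = pb_max, beam = beam, config = config,
              zoom = 1)
  if (!is.null(body)) out$body <- to_canonical_grid(body, beam, config, 0)$values
  if (!is.null(ctv)) out$ctv <- to_canonical_grid(ctv, beam, config, 0)$values
  structure(out, class = "canonical_sample")
}

#' Map a canonical-frame dose back to a native grid
#'
#' Multiplies the normalized dose by the sample's `pb_max`, embeds it on
#' the canonical lattice, and backward-rotates it onto `target_grid`'s
#' lattice (identity rotation when the sample was built with
#' `rotate = FALSE`).
#'
#' @param dose_norm 3D array with the sample's tensor shape (PB-max units).
#' @param sample a `canonical_sample`.
#' @param target_grid [volume_grid] providing the output lattice.
#' @return a [volume_grid] with dose in GyRBE on the target lattice.
#' @export
from_canonical <- function(dose_norm, sample, target_grid) {
  config <- sample$config
  if (!identical(dim(dose_norm), as.integer(config$shape)))
    stop("dose_norm shape ", paste(dim(dose_norm), collapse = "x"),
         " does not match tensor shape ",
         paste(config$shape, collapse = "x"))
  canon <- volume_grid(dose_norm * sample$pb_max, config$spacing,
                       canonical_origin(config, sample$beam))
  map <- NULL
  if (config$rotate) {
    R <- canonical_rotation(sample$beam)
    iso <- sample$beam$isocenter
    map <- function(w) sweep(sweep(w, 2, iso, "-") %*% t(R), 2, iso, "+")
  }
  out <- resample_transformed(canon, target_grid$spacing,
                              dim(target_grid$values),
                              target_grid$origin, map, 0, "cubic")
  out$values <- pmax(out$values, 0)
  out
}

## Zoom one canonical array (content scaling about the tensor center).
zoom_canonical_array <- function(arr, factor, config, beam, fill = 0) {
  g <- volume_grid(arr, config$spacing, canonical_origin(config, beam))
  zoom_about_isocenter(g, factor, beam$isocenter, fill = fill)$values
}

#' Zoom augmentation of a canonical training set
#'
#' Returns the original samples followed by one zoomed copy per factor per
#' sample (output count `(1 + length(factors)) * length(samples)`); the
#' zoom is applied identically to the CT and both dose channels.  Zoomed
#' copies are renormalized so `max(pb_norm) == 1` again (interpolation
#' perturbs the maximum), with `mc_norm` divided by the same constant.
#' Originals are returned untouched.
#'
#' @param samples list of `canonical_sample`s.
#' @param factors zoom factors; the defaults 0.8 and 1.2 triple the set
#'   (334 beams become 1002 training cases).
#' @return list of `canonical_sample`s, originals first.
#' @export
augment_training_set <- function(samples, factors = c(0.8, 1.2)) {
  if (length(factors) == 0) return(samples)
  zoomed <- list()
  for (s in samples) {
    for (f in factors) {
      z <- s
      z$ct_norm <- zoom_canonical_array(s$ct_norm, f, s$config, s$beam, fill = 0)
      z$pb_norm <- zoom_canonical_array(s$pb_norm, f, s$config, s$beam, fill = 0)
      renorm <- max(z$pb_norm)
      if (renorm <= 0) stop("degenerate zoomed sample: PB dose vanished")
      z$pb_norm <- z$pb_norm / renorm
      z$pb_norm[arrayInd(which.max(z$pb_norm), dim(z$pb_norm))] <- 1
      if (!is.null(s$mc_norm))
        z$mc_norm <- zoom_canonical_array(s$mc_norm, f, s$config, s$beam) / renorm
      z$zoom <- f
      zoomed[[length(zoomed) + 1L]] <- z
    }
  }
  c(samples, zoomed)
}
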