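# Dosimetric evaluation: global 3D gamma analysis, beam's-eye-view range
# maps with average range difference (ARD), MAE, isodose-band Dice
# coefficients, DVH metrics and relative dose errors (RDE).

#' Global 3D gamma analysis
#'
#' For each reference voxel inside the analysis mask with reference dose at
#' least `threshold_pct` of the normalization dose, computes
#' \deqn{\gamma(r) = \min_{r'} \sqrt{ (D_e(r') - D_r(r))^2/\Delta D^2 +
#'   |r' - r|^2/\delta d^2 }}
#' with global normalization `\Delta D = dose_pct/100 * max(reference in
#' mask)` and `\delta d = dta_mm`.  The evaluated dose is trilinearly
#' interpolated on a candidate lattice of step `dta_mm/3` within a search
#' sphere of radius `3 * dta_mm`, with an early exit once the geometric
#' term alone exceeds the current minimum.  Excluded voxels are `NaN`.
#'
#' @param reference,evaluated dose [volume_grid]s on the same lattice
#'   (reference = MC ground truth).
#' @param dose_pct dose criterion, percent of the normalization dose.
#' @param dta_mm distance-to-agreement criterion, mm.
#' @param threshold_pct lower dose cutoff, percent of the normalization
#'   dose, applied to the reference.
#' @param mask analysis mask [volume_grid] (e.g. the body); `NULL` = all.
#' @return object of class `gamma_result`: `gamma_values` array, criteria
#'   and the evaluated-voxel mask.
#' @export
gamma_3d <- function(reference, evaluated, dose_pct = 3, dta_mm = 3,
                     threshold_pct = 10, mask = NULL) {
  if (!identical(dim(reference$values), dim(evaluated$values)) ||
      max(abs(reference$spacing - evaluated$spacing)) > 1e-9)
    stop("reference and evaluated grids must share a lattice")
  m <- if (is.null(mask)) array(TRUE, dim(reference$values)) else {
    if (!identical(dim(mask$values), dim(reference$values)))
      stop("mask lattice mismatch")
    mask$values > 0.5
  }
  if (!any(m)) stop("empty analysis mask")
  norm_dose <- max(reference$values[m])
  if (norm_dose <= 0) stop("reference dose is nonpositive inside the mask")
  dd_abs <- dose_pct / 100 * norm_dose
  thr_abs <- threshold_pct / 100 * norm_dose
  step <- dta_mm / 3
  radius <- 3 * dta_mm
  r_steps <- ceiling(radius / step)
  off1 <- (-r_steps:r_steps) * step
  offs <- as.matrix(expand.grid(off1, off1, off1))
  d2 <- rowSums(offs^2)
  keep <- d2 <= radius^2 + 1e-9
  offs <- offs[keep, , drop = FALSE]; d2 <- d2[keep]
  ord <- order(d2)
  offs <- offs[ord, , drop = FALSE]; d2 <- d2[ord]
  gv <- .gamma_search(reference$values, evaluated$values,
                      dim(reference$values), reference$spacing,
                      m, dd_abs, dta_mm, thr_abs, offs, d2)
  structure(list(gamma_values = gv,
                 criteria = c(dose_pct = dose_pct, dta_mm = dta_mm),
                 normalization_dose = norm_dose,
                 threshold_pct = threshold_pct,
                 evaluated_mask = !is.na(gv)),
            class = "gamma_result")
}

#' Gamma passing rate
#'
#' Percent of evaluated voxels with gamma at most 1 (the boundary counts
#' as passing); excluded (`NaN`) voxels enter neither numerator nor
#' denominator.
#'
#' @param result a `gamma_result`.
#' @return passing rate in percent.
#' @export
passing_rate <- function(result) {
  g <- result$gamma_values
  g <- g[!is.na(g)]
  if (length(g) == 0) stop("no evaluated voxels")
  ## 1e-9 absorbs floating-point rounding at the exact gamma = 1 boundary
  100 * sum(g <= 1 + 1e-9) / length(g)
}

#' Beam's-eye-view range map
#'
#' For a dose in the canonical beam frame (beam along +RL), extracts per
#' lateral ray (SI, AP index) the distal-most depth at which the
#' depth-dose profile crosses `threshold_fraction * prescribed_dose`,
#' located by linear interpolation between the bracketing voxels.  Rays
#' never reaching the threshold are `NaN`.  Depths are in mm along the RL
#' axis from the first voxel plane.
#'
#' @param dose a dose [volume_grid] in the canonical frame.
#' @param threshold_fraction e.g. 0.9 for R90, 0.5 for R50.
#' @param prescribed_dose GyRBE.
#' @return object of class `range_map` with a 2D `ranges` matrix (mm).
#' @export
range_map <- function(dose, threshold_fraction, prescribed_dose) {
  if (prescribed_dose <= 0) stop("prescribed_dose must be > 0")
  thr <- threshold_fraction * prescribed_dose
  v <- dose$values
  d <- dim(v)
  sp <- dose$spacing[3]
  n_ray <- d[1] * d[2]
  prof <- v; dim(prof) <- c(n_ray, d[3])
  ranges <- rep(NA_real_, n_ray)
  above <- prof >= thr
  any_above <- rowSums(above) > 0
  ## distal-most downward crossing: last k with prof[k] >= thr and
  ## (k == n3 or prof[k+1] < thr); interpolate into the falling segment
  for (r in which(any_above)) {
    ks <- which(above[r, ])
    k <- ks[length(ks)]
    if (k == d[3]) { ranges[r] <- (k - 1) * sp; next }
    y0 <- prof[r, k]; y1 <- prof[r, k + 1]
    frac <- if (y0 > y1) (y0 - thr) / (y0 - y1) else 0
    ranges[r] <- ((k - 1) + frac) * sp
  }
  structure(list(ranges = matrix(ranges, d[1], d[2]),
                 threshold_dose = thr, spacing = sp),
            class = "range_map")
}

#' Average range difference (ARD)
#'
#' `100 * mean((R_ref(i) - R_eval(i)) / R_ref(i))` over rays finite in
#' both maps; evaluated ranges deeper than the reference give negative
#' ARD.
#'
#' @param ref_map,eval_map congruent `range_map`s (reference = MC).
#' @return ARD in percent.
#' @export
ard <- function(ref_map, eval_map) {
  if (!identical(dim(ref_map$ranges), dim(eval_map$ranges)))
    stop("range maps are not congruent")
  ok <- is.finite(ref_map$ranges) & is.finite(eval_map$ranges)
  if (!any(ok)) stop("no jointly finite rays")
  100 * mean((ref_map$ranges[ok] - eval_map$ranges[ok]) / ref_map$ranges[ok])
}

#' Mean absolute dose error
#'
#' `mean(|D_ref - D_eval|)` over voxels in the analysis mask whose
#' reference dose is at least `threshold_fraction * prescribed_dose`.
#'
#' @param reference,evaluated dose [volume_grid]s on one lattice.
#' @param mask analysis mask (e.g. body); `NULL` = all voxels.
#' @param threshold_fraction,prescribed_dose dose cutoff definition.
#' @return MAE in GyRBE.
#' @export
mae <- function(reference, evaluated, mask = NULL, threshold_fraction = 0.1,
                prescribed_dose = 1) {
  if (!identical(dim(reference$values), dim(evaluated$values)))
    stop("lattice mismatch")
  sel <- reference$values >= threshold_fraction * prescribed_dose
  if (!is.null(mask)) sel <- sel & mask$values > 0.5
  if (!any(sel)) stop("no voxels above threshold in the analysis mask")
  mean(abs(reference$values[sel] - evaluated$values[sel]))
}

#' Isodose-band Dice similarity coefficient
#'
#' Dice overlap `2|A n B| / (|A| + |B|)` between the voxel sets with dose
#' in `[band_low_pct, band_high_pct)` percent of the prescription
#' (half-open band) for the reference and evaluated dose.
#'
#' @param reference,evaluated dose [volume_grid]s on one lattice.
#' @param band_low_pct,band_high_pct band bounds, percent of prescription.
#' @param prescribed_dose GyRBE.
#' @return DSC in `[0, 1]`.
#' @export
isodose_dsc <- function(reference, evaluated, band_low_pct, band_high_pct,
                        prescribed_dose) {
  if (!identical(dim(reference$values), dim(evaluated$values)))
    stop("lattice mismatch")
  if (band_low_pct >= band_high_pct) stop("band_low must be < band_high")
  lo <- band_low_pct / 100 * prescribed_dose
  hi <- band_high_pct / 100 * prescribed_dose
  A <- reference$values >= lo & reference$values < hi
  B <- evaluated$values >= lo & evaluated$values < hi
  if (!any(A) && !any(B)) stop("both isodose sets are empty")
  2 * sum(A & B) / (sum(A) + sum(B))
}

#' Cumulative dose--volume histogram
#'
#' @param dose a dose [volume_grid].
#' @param mask structure mask [volume_grid] (nonempty).
#' @param n_bins resolution of the tabulated curve.
#' @return object of class `dvh_curve`: `dose` axis (GyRBE, ascending),
#'   `volume_pct` (nonincreasing from 100), and the sorted voxel doses
#'   used for exact metric inversion.
#' @export
dvh <- function(dose, mask, n_bins = 400) {
  sel <- mask$values > 0.5
  if (!any(sel)) stop("empty structure mask")
  doses <- sort(dose$values[sel])
  dmax <- max(doses)
  axis <- seq(0, max(dmax * 1.05, 1e-9), length.out = n_bins)
  vol <- vapply(axis, function(t) 100 * mean(doses >= t), 0)
  structure(list(dose = axis, volume_pct = vol, voxel_doses = doses),
            class = "dvh_curve")
}

#' DVH dose metric D_x%
#'
#' The dose received by at least `x_pct` percent of the structure volume:
#' the `(100 - x)`th percentile of the voxel doses, linearly interpolated
#' (type-7 quantile).
#'
#' @param curve a `dvh_curve`.
#' @param x_pct volume percentage (e.g. 98, 95, 50, 2).
#' @return dose in GyRBE.
#' @export
dvh_metric <- function(curve, x_pct) {
  unname(quantile(curve$voxel_doses, probs = 1 - x_pct / 100, type = 7))
}

#' Relative dose error (RDE)
#'
#' `100 * (D - D_ref) / D_ref` for a DVH metric.
#'
#' @param metric_eval,metric_ref doses in GyRBE; `metric_ref` nonzero.
#' @return RDE in percent.
#' @export
rde <- function(metric_eval, metric_ref) {
  if (metric_ref == 0) stop("reference metric is zero")
  100 * (metric_eval - metric_ref) / metric_ref
}

#' Single-field beam evaluation report
#'
#' Gamma (3%/3 mm by default, 10% threshold of the maximum MC dose in the
#' body) and R90/R50 range-map ARD for the converted (DL) and PB dose
#' against the MC reference.  Range maps are computed in the canonical
#' beam frame on a shared lattice; rays are paired by lateral index.
#'
#' @param mc,dl,pb dose [volume_grid]s on the clinical lattice.
#' @param beam a [beam_geometry].
#' @param body body mask [volume_grid].
#' @param gamma_criteria numeric `c(dose_pct, dta_mm)`.
#' @param threshold_pct gamma threshold (percent of max MC in body).
#' @return list (class `beam_report`) of per-dose metrics.
#' @export
evaluate_beam <- function(mc, dl, pb, beam, body,
                          gamma_criteria = c(3, 3), threshold_pct = 10) {
  cfg <- canonical_config(shape = dim(mc$values),
                          spacing_mm = mc$spacing[1], rotate = TRUE)
  canon <- lapply(list(mc = mc, dl = dl, pb = pb), to_canonical_grid,
                  beam = beam, config = cfg, fill = 0)
  maps <- lapply(c(r90 = 0.9, r50 = 0.5), function(f)
    lapply(canon, range_map, threshold_fraction = f,
           prescribed_dose = beam$prescribed_dose))
  ## a dose that never reaches a threshold has no range rays; report NA
  ## for that ARD instead of failing the whole report
  ard_or_na <- function(ref_map, eval_map)
    tryCatch(ard(ref_map, eval_map), error = function(e) NA_real_)
  one <- function(ev, nm) {
    g <- gamma_3d(mc, ev, gamma_criteria[1], gamma_criteria[2],
                  threshold_pct = threshold_pct, mask = body)
    list(gamma_pass = passing_rate(g),
         ard_r90 = ard_or_na(maps$r90$mc, maps$r90[[nm]]),
         ard_r50 = ard_or_na(maps$r50$mc, maps$r50[[nm]]),
         mae = mae(mc, ev, mask = body, threshold_fraction = 0.1,
                   prescribed_dose = beam$prescribed_dose))
  }
  structure(list(gamma_criteria = gamma_criteria,
                 dl = one(dl, "dl"), pb = one(pb, "pb")),
            class = "beam_report")
}

#' Plan-level evaluation report
#'
#' Plan dose = voxelwise sum of the per-beam doses.  Reports gamma passing
#' at 1%/1 mm, 2%/2 mm and 3%/3 mm (10% threshold, body mask), MAE for
#' voxels at or above 10% of the prescription, isodose-band DSC for the
#' bands 10--30, 10--50, 10--70 and 10--90% of prescription, and RDE of
#' the CTV D98/D95/D50/D2.
#'
#' @param mc_beams,eval_beams lists of per-beam dose [volume_grid]s.
#' @param body,ctv masks on the same lattice.
#' @param prescribed_dose plan prescription, GyRBE (sum of beam
#'   prescriptions).
#' @param gamma_criteria list of `c(dose_pct, dta_mm)` pairs.
#' @param dsc_bands list of `c(low_pct, high_pct)` pairs.
#' @param dvh_points volume percentages for the RDE metrics.
#' @return list (class `plan_report`).
#' @export
evaluate_plan <- function(mc_beams, eval_beams, body, ctv, prescribed_dose,
                          gamma_criteria = list(c(1, 1), c(2, 2), c(3, 3)),
                          dsc_bands = list(c(10, 30), c(10, 50),
                                           c(10, 70), c(10, 90)),
                          dvh_points = c(98, 95, 50, 2)) {
  sum_dose <- function(beams) {
    acc <- beams[[1]]
    if (length(beams) > 1)
      for (b in beams[-1]) acc$values <- acc$values + b$values
    acc
  }
  mc <- sum_dose(mc_beams); ev <- sum_dose(eval_beams)
  gammas <- lapply(gamma_criteria, function(cr) {
    g <- gamma_3d(mc, ev, cr[1], cr[2], threshold_pct = 10, mask = body)
    list(criteria = cr, passing = passing_rate(g))
  })
  dscs <- lapply(dsc_bands, function(b)
    list(band = b, dsc = isodose_dsc(mc, ev, b[1], b[2], prescribed_dose)))
  mc_dvh <- dvh(mc, ctv); ev_dvh <- dvh(ev, ctv)
  rdes <- lapply(dvh_points, function(x) {
    dm <- dvh_metric(mc_dvh, x); de <- dvh_metric(ev_dvh, x)
    list(x_pct = x, d_ref = dm, d_eval = de, rde = rde(de, dm))
  })
  structure(list(
    gamma = gammas,
    mae = mae(mc, ev, mask = body, threshold_fraction = 0.1,
              prescribed_dose = prescribed_dose),
    dsc = dscs, rde = rdes, prescribed_dose = prescribed_dose),
    class = "plan_report")
}
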