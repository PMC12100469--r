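# Dataset assembly: plans (synthetic "patients" sharing a phantom), beams
# with varied gantry/couch geometry, paired PB-like/MC-like doses, and
# NRRD + JSON on-disk form.

dataset_opts <- function(shape, spacing_mm, opts = list()) {
  half <- spacing_mm * shape / 2
  body_semi <- 0.82 * half
  o <- list(
    n_air_cavities = 3, n_bone_slabs = 2,
    cavity_semi_range = c(4, 9),
    slab_thickness_range = c(3, 7),
    slab_width_range = c(12, 30),
    smooth_sigma_mm = 0,
    dist_margin_range = c(10, 18), prox_margin = 12,
    m_range = c(0.35, 0.5) * body_semi[3],
    hw_range = c(0.25, 0.4) * min(body_semi[1:2]),
    couch_frac = 0.4, couch_mag = c(10, 30),
    entrance_sigma_mm = 3, sigma_growth = 0.04,
    pb_beamlet_width_mm = 10, prescribed_dose = 2,
    sobp_k = 25, sigma_peak = 3, sigma_d = 1.5,
    body_semi_axes = body_semi, ctv_semi_axes = NULL)
  o[names(opts)] <- opts
  o
}

## Draw one beam's geometry and SOBP parameters (deterministic per seed):
## gantry uniform in [0,360); couch 0 with probability 1-couch_frac, else
## +/- uniform(couch_mag).  The nominal range is planned against the
## geometry: R = WED from body entry to the isocenter plus a distal
## margin, and the modulation is widened if needed so the plateau starts
## at least prox_margin proximal of the isocenter (the SOBP must cover
## the CTV, as in any clinical plan).
draw_beam_spec <- function(o, ph, seed) {
  with_seed(seed, {
    gantry <- runif(1, 0, 360)
    couch <- if (runif(1) < o$couch_frac)
      sample(c(-1, 1), 1) * runif(1, o$couch_mag[1], o$couch_mag[2]) else 0
    hw <- runif(2, o$hw_range[1], o$hw_range[2])
    wed_iso <- wed_to_isocenter(ph$ct, ph$body, gantry, couch, ph$ctv_center)
    R <- wed_iso + runif(1, o$dist_margin_range[1], o$dist_margin_range[2])
    M <- runif(1, o$m_range[1], o$m_range[2])
    M <- max(M, R - wed_iso + o$prox_margin)
    M <- min(M, 0.8 * R)
    beam_sim_spec(
      gantry_deg = gantry, couch_deg = couch, isocenter = ph$ctv_center,
      range_mm = R, mod_mm = M, field_halfwidth_mm = hw,
      prescribed_dose = o$prescribed_dose,
      entrance_sigma_mm = o$entrance_sigma_mm,
      sigma_growth = o$sigma_growth,
      pb_beamlet_width_mm = o$pb_beamlet_width_mm,
      seed = seed)
  })
}

#' Generate a synthetic paired-dose dataset
#'
#' Beams are grouped into plans; all beams of a plan share one phantom
#' ("patient") and train/test phantoms are disjoint.  Gantry angles are
#' uniform in `[0, 360)`; about `couch_frac` (default 40%) of beams are
#' non-coplanar with couch magnitude in 10--30 degrees.  Deterministic
#' given `master_seed`.
#'
#' @param n_train_beams,n_test_beams beam counts (each at least 1).
#' @param master_seed integer; all per-plan and per-beam seeds derive
#'   from it.
#' @param shape,spacing_mm grid geometry (default desk-scale 48x80x80 at
#'   2 mm, half the clinical 96x160x160 tensor).
#' @param beams_per_plan target beams per plan.
#' @param opts named list overriding simulation defaults (see
#'   `pbmcdose:::dataset_opts`), e.g. `r_range`, `sigma_growth`,
#'   `n_air_cavities`.
#' @return an object of class `beam_dataset`: `$beams` (list of records
#'   with `ct`, `pb`, `mc`, `body`, `ctv`, `beam`, `sim`, `plan`, `split`)
#'   and `$manifest`.
#' @export
make_dataset <- function(n_train_beams, n_test_beams, master_seed = 1,
                         shape = c(48, 80, 80), spacing_mm = 2,
                         beams_per_plan = 3, opts = list()) {
  if (n_train_beams < 1 || n_test_beams < 1) stop("beam counts must be >= 1")
  o <- dataset_opts(shape, spacing_mm, opts)
  splits <- list(train = n_train_beams, test = n_test_beams)
  beams <- list()
  for (split in names(splits)) {
    n <- splits[[split]]
    n_plans <- ceiling(n / beams_per_plan)
    counts <- rep(n %/% n_plans, n_plans)
    if (n %% n_plans) counts[seq_len(n %% n_plans)] <- counts[seq_len(n %% n_plans)] + 1
    for (p in seq_len(n_plans)) {
      plan_id <- sprintf("%s_plan%02d", split, p)
      ph_seed <- derive_seed(master_seed, p + if (split == "test") 10000L else 0L)
      ph <- make_phantom(phantom_spec(
        shape = shape, spacing_mm = spacing_mm,
        body_semi_axes = o$body_semi_axes,
        n_air_cavities = o$n_air_cavities, n_bone_slabs = o$n_bone_slabs,
        cavity_semi_range = o$cavity_semi_range,
        slab_thickness_range = o$slab_thickness_range,
        slab_width_range = o$slab_width_range,
        ctv_semi_axes = o$ctv_semi_axes,
        smooth_sigma_mm = o$smooth_sigma_mm, seed = ph_seed))
      for (bi in seq_len(counts[p])) {
        beam_seed <- derive_seed(ph_seed, bi)
        spec <- draw_beam_spec(o, ph, beam_seed)
        dd <- build_sobp(spec$range_mm, spec$mod_mm, K = o$sobp_k,
                         sigma_peak = o$sigma_peak, sigma_d = o$sigma_d)
        rec <- list(id = sprintf("%s_b%02d", plan_id, bi), plan = plan_id,
                    split = split,
                    beam = beam_geometry(spec$gantry_deg, spec$couch_deg,
                                         ph$ctv_center, o$prescribed_dose),
                    sim = spec,
                    ct = ph$ct, body = ph$body, ctv = ph$ctv,
                    mc = simulate_mc_like(ph$ct, ph$body, ph$ctv, spec, dd),
                    pb = simulate_pb_like(ph$ct, ph$body, ph$ctv, spec, dd))
        beams[[length(beams) + 1L]] <- rec
      }
    }
  }
  manifest <- list(master_seed = master_seed,
                   n_train_beams = n_train_beams, n_test_beams = n_test_beams,
                   shape = shape, spacing_mm = spacing_mm,
                   beams = lapply(beams, function(b)
                     list(id = b$id, plan = b$plan, split = b$split,
                          gantry_deg = b$beam$gantry_deg,
                          couch_deg = b$beam$couch_deg,
                          seed = b$sim$seed)))
  structure(list(beams = beams, manifest = manifest), class = "beam_dataset")
}

#' Write / read a beam dataset on disk
#'
#' One subdirectory per beam holding NRRD volumes (`ct`, `pb`, `mc`,
#' `body`, `ctv`) and a `beam.json` with geometry and simulation
#' parameters, plus a top-level `manifest.json`.
#'
#' @param ds a `beam_dataset`.
#' @param dir output directory (created if needed).
#' @return `write_dataset` returns `dir` invisibly; `read_dataset` a
#'   `beam_dataset`.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (b in ds$beams) {
    bd <- file.path(dir, b$id)
    dir.create(bd, showWarnings = FALSE)
    for (nm in c("ct", "pb", "mc", "body", "ctv"))
      write_volume(b[[nm]], file.path(bd, paste0(nm, ".nrrd")))
    meta <- list(id = b$id, plan = b$plan, split = b$split,
                 beam = unclass(b$beam), sim = unclass(b$sim))
    jsonlite::write_json(meta, file.path(bd, "beam.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(ds$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  ids <- manifest$beams$id
  beams <- lapply(ids, function(id) {
    bd <- file.path(dir, id)
    meta <- jsonlite::read_json(file.path(bd, "beam.json"),
                                simplifyVector = TRUE)
    b <- list(id = meta$id, plan = meta$plan, split = meta$split,
              beam = beam_geometry(meta$beam$gantry_deg, meta$beam$couch_deg,
                                   unlist(meta$beam$isocenter),
                                   meta$beam$prescribed_dose),
              sim = meta$sim)
    for (nm in c("ct", "pb", "mc"))
      b[[nm]] <- read_volume(file.path(bd, paste0(nm, ".nrrd")))
    for (nm in c("body", "ctv"))
      b[[nm]] <- read_volume(file.path(bd, paste0(nm, ".nrrd")), mask = TRUE)
    b
  })
  structure(list(beams = beams, manifest = manifest), class = "beam_dataset")
}
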