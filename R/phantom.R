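# Synthetic phantoms: anatomy, metric maps, cohorts and expression matrices
# with known ground truth. Geometry is ellipsoidal shells, not brain-shaped:
# the downstream analysis depends only on the distance structure.

#' Specification of a geometric phantom
#'
#' @param grid_shape voxels per axis (length 3).
#' @param spacing_mm voxel edge lengths in mm (length 3, may be anisotropic).
#' @param ventricle_radii_mm ellipsoid semi-axes of the ventricular mask.
#' @param wm_outer_radii_mm ellipsoid semi-axes of the outer white-matter
#'   surface; must exceed `ventricle_radii_mm` on every axis.
#' @param wmh_count number of spherical white-matter-hyperintensity blobs.
#' @param wmh_radius_mm blob radius in mm.
#' @param seed integer seed for blob placement.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(grid_shape = c(96, 96, 96),
                         spacing_mm = c(1, 1, 1),
                         ventricle_radii_mm = c(8, 12, 8),
                         wm_outer_radii_mm = c(42, 44, 42),
                         wmh_count = 3,
                         wmh_radius_mm = 4,
                         seed = 1) {
  stopifnot(length(grid_shape) == 3, length(spacing_mm) == 3,
            length(ventricle_radii_mm) == 3, length(wm_outer_radii_mm) == 3)
  if (any(ventricle_radii_mm <= 0) || any(wm_outer_radii_mm <= 0)) {
    stop_pv("all radii must be positive")
  }
  if (any(wm_outer_radii_mm <= ventricle_radii_mm)) {
    stop_pv("wm_outer_radii_mm must exceed ventricle_radii_mm on every axis")
  }
  if (wmh_count < 0 || wmh_radius_mm <= 0) {
    stop_pv("wmh_count must be >= 0 and wmh_radius_mm positive")
  }
  structure(list(grid_shape = as.integer(grid_shape),
                 spacing_mm = as.numeric(spacing_mm),
                 ventricle_radii_mm = as.numeric(ventricle_radii_mm),
                 wm_outer_radii_mm = as.numeric(wm_outer_radii_mm),
                 wmh_count = as.integer(wmh_count),
                 wmh_radius_mm = as.numeric(wmh_radius_mm),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# physical coordinates of voxel centres relative to the grid centre, per axis
.axis_coords <- function(n, h) (seq_len(n) - (n + 1) / 2) * h

.ellipsoid_mask <- function(grid_shape, spacing_mm, radii) {
  cx <- .axis_coords(grid_shape[1], spacing_mm[1]) / radii[1]
  cy <- .axis_coords(grid_shape[2], spacing_mm[2]) / radii[2]
  cz <- .axis_coords(grid_shape[3], spacing_mm[3]) / radii[3]
  e <- outer(outer(cx^2, cy^2, `+`), cz^2, `+`)
  e <= 1
}

#' Generate phantom anatomy
#'
#' Builds nested ellipsoidal masks on one grid: ventricle at the centre, a
#' white-matter shell between the ventricle (plus a 1 mm margin emulating the
#' ependymal/CSF interface) and the outer WM surface, a gray-matter shell
#' outside it, and a brain mask enclosing everything. WMH lesions are
#' spherical blobs seeded at random WM locations.
#'
#' @param spec a [phantom_spec()].
#' @return A [tissue_segmentation()].
#' @export
make_anatomy <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  gm_margin <- 2
  brain_radii <- spec$wm_outer_radii_mm + gm_margin
  half_extent <- (spec$grid_shape - 1) / 2 * spec$spacing_mm
  too_small <- which(brain_radii > half_extent)
  if (length(too_small)) {
    stop_pv("grid too small for requested radii on axis ",
            paste(c("x", "y", "z")[too_small], collapse = ", "),
            " (need half-extent >= ", paste(round(brain_radii[too_small], 1),
                                            collapse = ", "), " mm)",
            class = "pvgrad_sizing_error")
  }
  vent <- .ellipsoid_mask(spec$grid_shape, spec$spacing_mm,
                          spec$ventricle_radii_mm)
  inner <- .ellipsoid_mask(spec$grid_shape, spec$spacing_mm,
                           spec$ventricle_radii_mm + 1)
  wm_outer <- .ellipsoid_mask(spec$grid_shape, spec$spacing_mm,
                              spec$wm_outer_radii_mm)
  brain <- .ellipsoid_mask(spec$grid_shape, spec$spacing_mm, brain_radii)
  wm <- wm_outer & !inner
  gm <- brain & !wm_outer
  wmh <- array(FALSE, spec$grid_shape)
  if (spec$wmh_count > 0) {
    wm_idx <- which(wm)
    centres <- with_seed(spec$seed,
                         sample(wm_idx, spec$wmh_count, replace = FALSE))
    pos <- arrayInd(centres, spec$grid_shape)
    cx <- .axis_coords(spec$grid_shape[1], spec$spacing_mm[1])
    cy <- .axis_coords(spec$grid_shape[2], spec$spacing_mm[2])
    cz <- .axis_coords(spec$grid_shape[3], spec$spacing_mm[3])
    for (b in seq_len(spec$wmh_count)) {
      d2 <- outer(outer((cx - cx[pos[b, 1]])^2, (cy - cy[pos[b, 2]])^2, `+`),
                  (cz - cz[pos[b, 3]])^2, `+`)
      wmh <- wmh | (d2 <= spec$wmh_radius_mm^2)
    }
    wmh <- wmh & wm
  }
  tissue_segmentation(ventricle = vent, wm = wm, wmh = wmh, gm = gm,
                      brain = brain, spacing_mm = spec$spacing_mm)
}

#' Generate a synthetic metric map with a linear distance gradient
#'
#' Stands in for a NODDI metric map (NDI/ODI): each white-matter voxel gets
#' `intercept + slope_per_mm * d + Normal(0, noise_sd)` where `d` is the
#' distance to the ventricles. Values are clipped to `[0, 1]` (NODDI indices
#' are tissue fractions); a warning is emitted when clipping touches more
#' than 1% of WM voxels. Voxels outside WM are `NA`.
#'
#' @param seg a [tissue_segmentation()].
#' @param dist a [distance_map()] on the same grid.
#' @param intercept,slope_per_mm linear model of the metric vs distance (mm).
#' @param noise_sd voxel noise SD (>= 0).
#' @param seed integer seed.
#' @return numeric 3D array.
#' @export
make_metric_map <- function(seg, dist, intercept, slope_per_mm,
                            noise_sd = 0, seed = 1) {
  stopifnot(inherits(seg, "tissue_segmentation"))
  check_same_shape(seg$wm_mask, dist, what = "mask and distance map")
  if (noise_sd < 0) {
    stop_pv("noise_sd must be >= 0", class = "pvgrad_validation_error")
  }
  out <- array(NA_real_, dim(seg$wm_mask))
  wm <- which(seg$wm_mask)
  vals <- intercept + slope_per_mm * unclass(dist)[wm]
  if (noise_sd > 0) {
    vals <- vals + with_seed(seed, rnorm(length(wm), 0, noise_sd))
  }
  n_clip <- sum(vals < 0 | vals > 1)
  if (n_clip > 0.01 * length(wm)) {
    warning(sprintf("clipping to [0,1] affected %.1f%% of WM voxels",
                    100 * n_clip / length(wm)))
  }
  out[wm] <- pmin(1, pmax(0, vals))
  out
}

.default_groups <- function() {
  g <- function(n, age, slope) {
    list(n_subjects = n, age_range = age, slope_mean = slope,
         slope_sd = 0.005, intercept_mean = 0, intercept_sd = 0.3,
         voxel_noise_sd = 0.2)
  }
  # slope means mirror the reported gradient magnitudes per group
  list(younger_hc = g(100, c(16, 45), 0),
       middle_hc  = g(100, c(45.01, 60), 0.0064),
       older_hc   = g(100, c(60.01, 89), 0.019),
       ad         = g(100, c(42, 87), 0.022),
       pd         = g(100, c(45, 86), 0.011),
       csvd       = g(100, c(19, 84), 0.032),
       ms         = g(100, c(16, 80), 0.023))
}

#' Specification of a synthetic cohort
#'
#' Defines per-group sample sizes, age ranges and gradient (slope)
#' distributions, plus the coefficients of a linear structural causal model
#' (SCM): exposure (choroid plexus volume, CPV) -> subject gradient ->
#' outcomes (log WMH volume, NAWM metric, WMV, GMV) -> cognitive scores.
#' Ring profiles are generated on the normalized (z) scale directly, so
#' `slope_mean` is in z-units per ring, matching the scale on which group
#' gradients are reported.
#'
#' @param groups named list; each element a list with `n_subjects`,
#'   `age_range`, `slope_mean`, `slope_sd`, `intercept_mean`, `intercept_sd`,
#'   `voxel_noise_sd`. Defaults mirror a seven-group design (three HC age
#'   strata plus AD, PD, CSVD, MS) with slope means spanning 0 to 0.032.
#' @param n_rings rings per profile.
#' @param scm list of SCM coefficients: `a` (exposure -> gradient, in z/ring
#'   per ml CPV; the default 0.008 matches the magnitude of gradient-on-CPV
#'   regression coefficients in this literature), `b` (gradient -> outcome,
#'   outcome units per z/ring), `c_direct` (exposure -> outcome), `cpv_mean`,
#'   `cpv_sd`, `outcome_noise_sd`, `score_coefs` (named, outcome -> score),
#'   `score_noise_sd`.
#' @param seed root seed; each subject draws from its own child stream, so
#'   adding a subject never changes another subject's data.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(groups = .default_groups(), n_rings = 10,
                        scm = list(a = 0.008, b = 30, c_direct = 0.3,
                                   cpv_mean = 2, cpv_sd = 0.5,
                                   outcome_noise_sd = 0.5,
                                   score_coefs = c(wmv = 0.05, gmv = 0.05),
                                   score_noise_sd = 0.5),
                        seed = 1) {
  for (nm in names(groups)) {
    gr <- groups[[nm]]
    if (gr$n_subjects < 2) {
      stop_pv("group '", nm, "' has n_subjects < 2",
              class = "pvgrad_validation_error")
    }
    sds <- c(gr$slope_sd, gr$intercept_sd, gr$voxel_noise_sd)
    if (any(sds < 0)) {
      stop_pv("group '", nm, "' has a negative SD",
              class = "pvgrad_validation_error")
    }
  }
  structure(list(groups = groups, n_rings = as.integer(n_rings),
                 scm = scm, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic cohort with known causal structure
#'
#' Per subject: exposure CPV is drawn, the true subject gradient is
#' `b_i = slope_mean + a * (CPV - cpv_mean) + Normal(0, slope_sd)`, the ring
#' profile is `z_ik = intercept_i + b_i * k + Normal(0, voxel_noise_sd)`,
#' each outcome is `c_direct * CPV + b * b_i + noise` (WMH volume is stored
#' on the natural scale, `exp()` of its linear value, so that downstream
#' log-transformation recovers the linear SCM), and scores are linear in the
#' outcomes. Age, sex and TIV are drawn independently of the SCM (causally
#' inert confounders, carried for adjustment interfaces).
#'
#' @param cspec a [cohort_spec()].
#' @return list with `cohort` (one row per subject: ids, group, covariates,
#'   exposure, outcomes, scores), `profiles` (long data.frame: subject, ring,
#'   value) and `truth` (true subject gradients and SCM paths).
#' @export
make_cohort <- function(cspec) {
  stopifnot(inherits(cspec, "cohort_spec"))
  scm <- cspec$scm
  rows <- list(); profs <- list(); truth_b <- list()
  subj_counter <- 0L
  for (gname in names(cspec$groups)) {
    gr <- cspec$groups[[gname]]
    for (i in seq_len(gr$n_subjects)) {
      subj_counter <- subj_counter + 1L
      sid <- sprintf("s%04d", subj_counter)
      draws <- with_seed(child_seed(cspec$seed, subj_counter), {
        age <- runif(1, gr$age_range[1], gr$age_range[2])
        sex <- rbinom(1, 1, 0.5)
        tiv <- rnorm(1, 1400, 120)
        cpv <- rnorm(1, scm$cpv_mean, scm$cpv_sd)
        b_i <- gr$slope_mean + scm$a * (cpv - scm$cpv_mean) +
          rnorm(1, 0, gr$slope_sd)
        int_i <- rnorm(1, gr$intercept_mean, gr$intercept_sd)
        k <- seq_len(cspec$n_rings)
        z <- int_i + b_i * k + rnorm(cspec$n_rings, 0, gr$voxel_noise_sd)
        lin <- function() scm$c_direct * cpv + scm$b * b_i +
          rnorm(1, 0, scm$outcome_noise_sd)
        log_wmh <- lin(); nawm_ndi <- lin(); wmv <- lin(); gmv <- lin()
        score_lin <- scm$score_coefs[["wmv"]] * wmv +
          scm$score_coefs[["gmv"]] * gmv
        mmse <- score_lin + rnorm(1, 0, scm$score_noise_sd)
        moca <- score_lin + rnorm(1, 0, scm$score_noise_sd)
        list(age = age, sex = sex, tiv = tiv, cpv = cpv, b_i = b_i,
             int_i = int_i, z = z, log_wmh = log_wmh, nawm_ndi = nawm_ndi,
             wmv = wmv, gmv = gmv, mmse = mmse, moca = moca)
      })
      rows[[subj_counter]] <- data.frame(
        subject = sid, group = gname, age = draws$age, sex = draws$sex,
        tiv = draws$tiv, cpv = draws$cpv,
        wmh_volume = exp(draws$log_wmh), nawm_ndi = draws$nawm_ndi,
        wmv = draws$wmv, gmv = draws$gmv,
        mmse = draws$mmse, moca = draws$moca, stringsAsFactors = FALSE)
      profs[[subj_counter]] <- data.frame(
        subject = sid, group = gname, ring = seq_len(cspec$n_rings),
        value = draws$z, stringsAsFactors = FALSE)
      truth_b[[subj_counter]] <- data.frame(
        subject = sid, group = gname, b_i = draws$b_i,
        intercept_i = draws$int_i, stringsAsFactors = FALSE)
    }
  }
  list(cohort = do.call(rbind, rows),
       profiles = do.call(rbind, profs),
       truth = list(subjects = do.call(rbind, truth_b),
                    paths = list(a = scm$a, b = scm$b,
                                 c_direct = scm$c_direct,
                                 indirect = scm$a * scm$b,
                                 total = scm$c_direct + scm$a * scm$b),
                    score_coefs = scm$score_coefs))
}

#' Specification of a synthetic ring-wise expression dataset
#'
#' @param n_genes total genes.
#' @param n_associated genes truly covarying with the ring profile (half
#'   positively, half negatively).
#' @param effect_size association strength, in units of the profile SD (the
#'   profile is standardized internally before signal construction).
#' @param noise_sd noise SD for associated genes; null genes are unit-SD
#'   noise.
#' @param samples_per_ring samples emitted per ring.
#' @param seed integer seed.
#' @export
expression_spec <- function(n_genes = 1000, n_associated = 50,
                            effect_size = 1, noise_sd = 0.1,
                            samples_per_ring = 3, seed = 1) {
  if (n_associated < 0 || n_associated > n_genes) {
    stop_pv("n_associated must be in [0, n_genes]",
            class = "pvgrad_validation_error")
  }
  if (samples_per_ring < 1) {
    stop_pv("samples_per_ring must be >= 1", class = "pvgrad_validation_error")
  }
  structure(list(n_genes = as.integer(n_genes),
                 n_associated = as.integer(n_associated),
                 effect_size = effect_size, noise_sd = noise_sd,
                 samples_per_ring = as.integer(samples_per_ring),
                 seed = as.integer(seed)),
            class = "expression_spec")
}

#' Generate a sample-level expression table tied to a ring profile
#'
#' Emulates regional (atlas-derived) expression samples falling at known
#' distances from the ventricles. Associated genes follow
#' `sign * effect_size * standardized(ring_profile) + Normal(0, noise_sd)`;
#' the remaining genes are pure unit-variance noise. Each sample's distance
#' is drawn uniformly within its ring's bounds.
#'
#' @param espec an [expression_spec()].
#' @param ring_profile numeric vector (one value per ring, >= 3 rings): the
#'   per-ring response the associated genes track.
#' @param atlas optional [build_rings()] atlas supplying ring bounds for the
#'   sample distances; defaults to the 10 x 3 mm design.
#' @return list with `samples` (data.frame: sample, ring, distance_mm, one
#'   column per gene) and `truth` (data.frame: gene, associated, sign).
#' @export
make_expression <- function(espec, ring_profile, atlas = NULL) {
  stopifnot(inherits(espec, "expression_spec"))
  R <- length(ring_profile)
  if (R < 3) stop_pv("ring_profile needs >= 3 rings",
                     class = "pvgrad_validation_error")
  if (is.null(atlas)) atlas <- build_rings(array(0, c(1, 1, 1)), 3, R)
  prof <- if (sd(ring_profile) > 0) as.numeric(scale(ring_profile))
          else rep(0, R)
  genes <- sprintf("g%04d", seq_len(espec$n_genes))
  n_pos <- ceiling(espec$n_associated / 2)
  sign_vec <- integer(espec$n_genes)
  if (espec$n_associated > 0) {
    sign_vec[seq_len(n_pos)] <- 1L
    if (espec$n_associated > n_pos)
      sign_vec[(n_pos + 1):espec$n_associated] <- -1L
  }
  n_samp <- R * espec$samples_per_ring
  ring_of <- rep(seq_len(R), each = espec$samples_per_ring)
  mat <- with_seed(espec$seed, {
    dist_mm <- runif(n_samp, atlas$bounds_mm$lower[ring_of],
                     atlas$bounds_mm$upper[ring_of])
    m <- matrix(0, n_samp, espec$n_genes)
    for (j in seq_len(espec$n_genes)) {
      m[, j] <- if (sign_vec[j] != 0) {
        sign_vec[j] * espec$effect_size * prof[ring_of] +
          rnorm(n_samp, 0, espec$noise_sd)
      } else rnorm(n_samp, 0, 1)
    }
    list(dist_mm = dist_mm, m = m)
  })
  samples <- data.frame(sample = sprintf("smp%03d", seq_len(n_samp)),
                        ring = ring_of, distance_mm = mat$dist_mm,
                        stringsAsFactors = FALSE)
  expr <- as.data.frame(mat$m)
  names(expr) <- genes
  list(samples = cbind(samples, expr),
       truth = data.frame(gene = genes, associated = sign_vec != 0L,
                          sign = sign_vec, stringsAsFactors = FALSE))
}
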