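#' Bundle aligned tissue masks into a segmentation object
#'
#' Collects the binary masks used by the ring analysis (ventricles, white
#' matter, white-matter hyperintensities, gray matter, whole brain) on a
#' single voxel grid with known physical spacing.
#'
#' @param ventricle,wm,wmh,gm,brain logical/0-1 3D arrays on one grid. `gm`
#'   may be `NULL` (it is not needed for the ring analysis itself).
#' @param spacing_mm numeric length-3, voxel edge lengths in mm (anisotropic
#'   spacing allowed).
#' @return An object of class `tissue_segmentation`.
#' @export
tissue_segmentation <- function(ventricle, wm, wmh = NULL, gm = NULL, brain,
                                spacing_mm = c(1, 1, 1)) {
  if (length(dim(ventricle)) != 3L) stop_pv("masks must be 3D arrays")
  if (is.null(wmh)) wmh <- array(FALSE, dim(wm))
  check_same_shape(ventricle, wm, wmh, brain, what = "masks")
  if (!is.null(gm)) check_same_shape(wm, gm, what = "masks")
  for (nm in c("ventricle", "wm", "wmh", "brain")) {
    check_binary(get(nm), nm)
  }
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0)) {
    stop_pv("spacing_mm must be 3 positive voxel sizes")
  }
  structure(list(
    ventricle_mask = array(as.logical(ventricle), dim(ventricle)),
    wm_mask = array(as.logical(wm), dim(wm)),
    wmh_mask = array(as.logical(wmh), dim(wmh)),
    gm_mask = if (is.null(gm)) NULL else array(as.logical(gm), dim(gm)),
    brain_mask = array(as.logical(brain), dim(brain)),
    spacing_mm = as.numeric(spacing_mm)
  ), class = "tissue_segmentation")
}

#' @export
print.tissue_segmentation <- function(x, ...) {
  cat("tissue_segmentation:", paste(dim(x$wm_mask), collapse = " x "),
      "voxels @", paste(signif(x$spacing_mm, 4), collapse = " x "), "mm\n")
  for (nm in c("ventricle_mask", "wm_mask", "wmh_mask", "gm_mask", "brain_mask")) {
    if (!is.null(x[[nm]])) cat(sprintf("  %-15s %d voxels\n", nm, sum(x[[nm]])))
  }
  invisible(x)
}

#' Euclidean distance map from the ventricular mask
#'
#' Computes, for every voxel, the exact Euclidean distance in mm from the
#' voxel centre to the centre of the nearest ventricular voxel (exact
#' separable distance transform; anisotropic spacing is honoured).
#' Ventricular voxels have distance 0. The convention is voxel-centre to
#' voxel-centre, not distance to the mask surface.
#'
#' @param seg a [tissue_segmentation()].
#' @return A 3D numeric array of distances (mm) with attribute `spacing_mm`,
#'   of class `distance_map`.
#' @export
distance_map <- function(seg) {
  stopifnot(inherits(seg, "tissue_segmentation"))
  if (!any(seg$ventricle_mask)) {
    stop_pv("ventricle mask is empty; distances are undefined",
            class = "pvgrad_validation_error")
  }
  d <- .edt3d(seg$ventricle_mask, dim(seg$ventricle_mask), seg$spacing_mm)
  attr(d, "spacing_mm") <- seg$spacing_mm
  class(d) <- c("distance_map", class(d))
  d
}

#' Concentric ring atlas over a distance map
#'
#' Partitions distance into `n_rings` contiguous half-open shells
#' `[start + (k-1) * thickness, start + k * thickness)`, k = 1..n_rings.
#' With the defaults (3 mm thickness, 10 rings, start at one ring-width) the
#' design spans 3 mm to 33 mm from the ventricles; the innermost 0-3 mm shell
#' is excluded to limit CSF partial-volume effects. The 15 x 1.5 mm and
#' 20 x 1 mm variants likewise start at one ring-width.
#'
#' @param dist a [distance_map()] (or plain numeric array of mm distances).
#' @param thickness_mm ring thickness in mm.
#' @param n_rings number of rings.
#' @param start_mm inner bound of ring 1; defaults to `thickness_mm`.
#' @return A `ring_atlas`: integer label array (0 = unassigned) plus ring
#'   bounds.
#' @export
build_rings <- function(dist, thickness_mm = 3, n_rings = 10,
                        start_mm = thickness_mm) {
  if (thickness_mm <= 0) stop_pv("thickness_mm must be positive")
  if (n_rings < 2) stop_pv("n_rings must be at least 2")
  lower <- start_mm + (seq_len(n_rings) - 1) * thickness_mm
  upper <- start_mm + seq_len(n_rings) * thickness_mm
  lab <- floor((unclass(dist) - start_mm) / thickness_mm) + 1
  lab[!is.finite(lab) | lab < 1 | lab > n_rings] <- 0
  lab <- array(as.integer(lab), dim(dist))
  structure(list(
    labels = lab,
    bounds_mm = data.frame(ring = seq_len(n_rings), lower = lower, upper = upper),
    thickness_mm = thickness_mm,
    n_rings = as.integer(n_rings),
    start_mm = start_mm
  ), class = "ring_atlas")
}

#' @export
print.ring_atlas <- function(x, ...) {
  cat(sprintf("ring_atlas: %d rings of %g mm spanning [%g, %g) mm\n",
              x$n_rings, x$thickness_mm, x$start_mm,
              x$start_mm + x$n_rings * x$thickness_mm))
  invisible(x)
}

#' Normal-appearing white matter mask
#'
#' NAWM is the white matter with visible lesions (WMH) removed:
#' `wm_mask AND NOT wmh_mask`.
#'
#' @param seg a [tissue_segmentation()].
#' @return logical 3D array.
#' @export
nawm_mask <- function(seg) {
  stopifnot(inherits(seg, "tissue_segmentation"))
  check_same_shape(seg$wm_mask, seg$wmh_mask, what = "wm/wmh masks")
  seg$wm_mask & !seg$wmh_mask
}

#' Per-ring means of a metric over NAWM
#'
#' Averages a voxelwise metric within each ring restricted to the NAWM mask.
#' Rings with fewer than `min_voxels` contributing voxels are flagged missing
#' (mean `NA`); they are later dropped from slope fits, never imputed.
#'
#' @param metric numeric 3D array (non-tissue voxels may be `NA`).
#' @param atlas a [build_rings()] atlas on the same grid.
#' @param nawm logical mask, typically [nawm_mask()].
#' @param min_voxels minimum voxel count for a ring mean to be reported.
#' @param subject,metric_name optional identifiers carried into the output.
#' @return data.frame of class `ring_profile` with columns
#'   `subject, metric, ring, mean, n_voxels, missing`.
#' @export
extract_ring_means <- function(metric, atlas, nawm, min_voxels = 10,
                               subject = NA_character_,
                               metric_name = NA_character_) {
  stopifnot(inherits(atlas, "ring_atlas"))
  check_same_shape(metric, atlas$labels, nawm, what = "metric/atlas/mask")
  lab <- atlas$labels
  sel <- nawm & lab > 0L & !is.na(metric)
  k <- factor(lab[sel], levels = seq_len(atlas$n_rings))
  n_vox <- as.integer(table(k))
  if (all(n_vox == 0L)) {
    stop_pv("no ring contains any NAWM voxel",
            class = "pvgrad_empty_profile_error")
  }
  sums <- tapply(metric[sel], k, sum)
  m <- as.numeric(sums) / n_vox
  m[is.na(as.numeric(sums))] <- NA_real_
  missing <- n_vox < min_voxels
  m[missing] <- NA_real_
  out <- data.frame(subject = subject, metric = metric_name,
                    ring = seq_len(atlas$n_rings), mean = m,
                    n_voxels = n_vox, missing = missing,
                    stringsAsFactors = FALSE)
  class(out) <- c("ring_profile", class(out))
  out
}
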