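# Independent oracles used across tests. Each is deliberately brute-force
# and shares no code with the implementation it checks.

# O(N^2) nearest-ventricular-voxel distance: for every voxel, the minimum
# over ventricle voxels of the centre-to-centre distance in mm.
brute_force_distance <- function(vent, spacing) {
  dm <- dim(vent)
  vi <- which(vent, arr.ind = TRUE)
  idx <- arrayInd(seq_len(prod(dm)), dm)
  out <- rep(Inf, prod(dm))
  for (v in seq_len(nrow(vi))) {
    dd <- sqrt(((idx[, 1] - vi[v, 1]) * spacing[1])^2 +
               ((idx[, 2] - vi[v, 2]) * spacing[2])^2 +
               ((idx[, 3] - vi[v, 3]) * spacing[3])^2)
    out <- pmin(out, dd)
  }
  array(out, dm)
}

# literal Benjamini-Hochberg step-up: q_i = min_{j >= i} p_(j) * m / j,
# mapped back to the original order
bh_stepup_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- pmin(1, rev(cummin(rev(ps * m / seq_len(m)))))
  out <- numeric(m)
  out[o] <- q
  out
}

# exact upper-tail hypergeometric by direct enumeration of overlap outcomes
hyper_upper_oracle <- function(overlap, set_size, universe, list_size) {
  js <- overlap:min(set_size, list_size)
  js <- js[js >= max(0, list_size - (universe - set_size))]
  if (!length(js)) return(0)
  sum(choose(set_size, js) * choose(universe - set_size, list_size - js)) /
    choose(universe, list_size)
}

# a small random segmentation on an arbitrary grid (ventricle blob in the
# centre, everything else brain/WM, a few WMH voxels)
random_seg <- function(dm = c(14, 12, 10), spacing = c(1, 1, 1),
                       wmh_frac = 0.05, seed = 1) {
  set.seed(seed)
  vent <- array(FALSE, dm)
  c0 <- pmax(1, round(dm / 2))
  vent[c0[1] + (-1:1), c0[2] + (-1:1), c0[3] + (-1:1)] <- runif(27) < 0.7
  if (!any(vent)) vent[c0[1], c0[2], c0[3]] <- TRUE
  wm <- array(TRUE, dm) & !vent
  wmh <- array(runif(prod(dm)) < wmh_frac, dm) & wm
  tissue_segmentation(ventricle = vent, wm = wm, wmh = wmh,
                      brain = array(TRUE, dm), spacing_mm = spacing)
}

# single-group cohort spec shorthand for gradient scenarios (no exposure
# coupling unless asked for)
scenario_cohort <- function(n = 100, slope = 0.019, slope_sd = 0.005,
                            noise_sd = 0.2, intercept_sd = 0.3, a = 0,
                            b = 0.4, c_direct = 0.3, outcome_noise_sd = 1,
                            seed = 1, n_rings = 10) {
  cohort_spec(
    groups = list(g = list(n_subjects = n, age_range = c(20, 80),
                           slope_mean = slope, slope_sd = slope_sd,
                           intercept_mean = 0, intercept_sd = intercept_sd,
                           voxel_noise_sd = noise_sd)),
    n_rings = n_rings,
    scm = list(a = a, b = b, c_direct = c_direct, cpv_mean = 2, cpv_sd = 0.5,
               outcome_noise_sd = outcome_noise_sd,
               score_coefs = c(wmv = 0.05, gmv = 0.05),
               score_noise_sd = 1),
    seed = seed)
}
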