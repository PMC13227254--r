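test_that("make_anatomy builds disjoint nested masks with seeded lesions", {
  spec <- phantom_spec(wmh_count = 3, seed = 5)
  seg <- make_anatomy(spec)
  expect_equal(sum(seg$ventricle_mask & seg$wm_mask), 0)
  expect_equal(sum(seg$wm_mask & seg$gm_mask), 0)
  expect_true(all(seg$wm_mask[seg$wmh_mask]))           # WMH inside WM
  expect_true(all(seg$brain_mask[seg$ventricle_mask]))
  expect_true(all(seg$brain_mask[seg$wm_mask]))
  expect_true(all(seg$brain_mask[seg$gm_mask]))

  seg2 <- make_anatomy(spec)
  expect_identical(seg, seg2)                            # determinism

  seg0 <- make_anatomy(phantom_spec(wmh_count = 0))
  expect_equal(sum(seg0$wmh_mask), 0)
  expect_identical(seg0$wm_mask, seg$wm_mask)            # WM unaffected
})

test_that("make_anatomy rejects grids too small for the radii", {
  err <- expect_error(
    make_anatomy(phantom_spec(grid_shape = c(96, 60, 96))),
    class = "pvgrad_sizing_error")
  expect_match(conditionMessage(err), "axis y")
})

test_that("default phantom spans the full 10 x 3 mm ring design", {
  seg <- make_anatomy(phantom_spec(wmh_count = 0))
  d <- distance_map(seg)
  atlas <- build_rings(d)
  nw <- nawm_mask(seg)
  counts <- vapply(1:10, function(k) sum(atlas$labels == k & nw), 1L)
  expect_true(all(counts >= 10))
  expect_gte(max(unclass(d)[nw]), 33)
})

test_that("make_metric_map realizes the linear distance model", {
  seg <- random_seg(dm = c(16, 16, 14), seed = 2, wmh_frac = 0)
  d <- distance_map(seg)

  m0 <- make_metric_map(seg, d, intercept = 0.65, slope_per_mm = 0, noise_sd = 0)
  expect_true(all(m0[seg$wm_mask] == 0.65))
  expect_true(all(is.na(m0[!seg$wm_mask])))

  m1 <- make_metric_map(seg, d, intercept = 0.65, slope_per_mm = -0.003,
                        noise_sd = 0)
  v10 <- which(abs(unclass(d) - 10) < 1e-9 & seg$wm_mask)
  if (length(v10)) expect_equal(unname(m1[v10][1]), 0.62)
  expect_equal(m1[seg$wm_mask], 0.65 - 0.003 * unclass(d)[seg$wm_mask])

  expect_error(make_metric_map(seg, d, 0.5, 0, noise_sd = -1),
               class = "pvgrad_validation_error")
})

test_that("ring means of a noisy metric map recover the generating slope", {
  seg <- make_anatomy(phantom_spec(wmh_count = 0))
  d <- distance_map(seg)
  atlas <- build_rings(d)
  nw <- nawm_mask(seg)
  m <- make_metric_map(seg, d, intercept = 0.65, slope_per_mm = -0.003,
                       noise_sd = 0.02, seed = 8)
  prof <- extract_ring_means(m, atlas, nw)
  mid <- (atlas$bounds_mm$lower + atlas$bounds_mm$upper) / 2
  # ring means vs mean member distance; use the actual mean distance per ring
  dbar <- vapply(prof$ring, function(k)
    mean(unclass(d)[atlas$labels == k & nw]), 1)
  fit <- lm(prof$mean ~ dbar)
  est <- summary(fit)$coefficients["dbar", ]
  expect_lt(abs(est["Estimate"] - (-0.003)), 3 * est["Std. Error"] + 1e-6)
  expect_true(all(abs(mid - dbar) < 1.6))  # ring centres track mean distance
})

test_that("make_cohort honours the structural causal model", {
  # null SCM: exposure uncorrelated with outcomes
  cs0 <- scenario_cohort(n = 400, slope = 0.02, a = 0, b = 0, c_direct = 0,
                         seed = 3)
  sim0 <- make_cohort(cs0)
  n <- nrow(sim0$cohort)
  for (out in c("nawm_ndi", "wmv", "gmv")) {
    expect_lt(abs(cor(sim0$cohort$cpv, sim0$cohort[[out]])), 2.5 / sqrt(n))
  }

  # noise-free limit: b_i exactly slope_mean + a (CPV - mean)
  csn <- scenario_cohort(n = 50, slope = 0.02, slope_sd = 0, noise_sd = 0,
                         intercept_sd = 0, a = 0.5, seed = 4)
  simn <- make_cohort(csn)
  expect_equal(simn$truth$subjects$b_i,
               0.02 + 0.5 * (simn$cohort$cpv - 2), tolerance = 1e-12)

  # large-n total effect equals c' + a b = 0.5
  cs <- scenario_cohort(n = 5000, slope = 0, slope_sd = 1, a = 0.5, b = 0.4,
                        c_direct = 0.3, outcome_noise_sd = 1, seed = 5)
  sim <- make_cohort(cs)
  fit <- lm(wmv ~ cpv, data = sim$cohort)
  est <- summary(fit)$coefficients["cpv", ]
  expect_lt(abs(est["Estimate"] - 0.5), 3 * est["Std. Error"])

  expect_error(cohort_spec(groups = list(g = list(
    n_subjects = 1, age_range = c(20, 30), slope_mean = 0, slope_sd = 0,
    intercept_mean = 0, intercept_sd = 0, voxel_noise_sd = 0))),
    class = "pvgrad_validation_error")
})

test_that("cohort generation is deterministic and per-subject stable", {
  cs <- scenario_cohort(n = 20, seed = 7)
  s1 <- make_cohort(cs)
  s2 <- make_cohort(cs)
  expect_identical(s1, s2)
  # adding subjects leaves earlier subjects' draws untouched
  cs_big <- scenario_cohort(n = 30, seed = 7)
  s3 <- make_cohort(cs_big)
  expect_equal(s1$cohort, s3$cohort[seq_len(20), ], ignore_attr = TRUE)
  expect_equal(s1$profiles$value, s3$profiles$value[seq_len(200)])
})

test_that("make_expression ties associated genes to the ring profile", {
  y <- 0.02 * (1:10)

  ex0 <- make_expression(expression_spec(n_genes = 50, n_associated = 0,
                                         seed = 1), y)
  expect_true(all(!ex0$truth$associated))

  # effect 1, noise 0.1: associated genes correlate strongly with the profile
  ex <- make_expression(expression_spec(n_genes = 200, n_associated = 20,
                                        effect_size = 1, noise_sd = 0.1,
                                        samples_per_ring = 1, seed = 2), y)
  g <- as.matrix(ex$samples[, ex$truth$gene])
  cors <- abs(cor(g, as.numeric(scale(y))))
  expect_gt(mean(cors[ex$truth$associated]), 0.9)

  # degenerate effect: associated and null genes indistinguishable
  exz <- make_expression(expression_spec(n_genes = 400, n_associated = 40,
                                         effect_size = 0, noise_sd = 1,
                                         samples_per_ring = 1, seed = 3), y)
  gz <- as.matrix(exz$samples[, exz$truth$gene])
  cz <- as.vector(cor(gz, as.numeric(scale(y))))
  tt <- t.test(cz[exz$truth$associated], cz[!exz$truth$associated])
  expect_gt(tt$p.value, 0.01)

  expect_error(expression_spec(n_genes = 10, n_associated = 11),
               class = "pvgrad_validation_error")
  expect_error(make_expression(expression_spec(n_genes = 5), y[1:2]),
               class = "pvgrad_validation_error")
})
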